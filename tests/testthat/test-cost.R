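# The SD-banded, weighted biomarker cost and the bounded objective.

means_vector <- function() {
  r <- experimental_ranges()
  setNames(r$mean, r$biomarker)
}

test_that("cost is zero when every biomarker sits at its experimental mean", {
  cc <- biomarker_cost(means_vector())
  expect_equal(cc$total, 0)
  expect_true(all(cc$breakdown$in_range))
  expect_false(cc$failed)
})

test_that("one biomarker at mean + 2 SD with weight 1 costs exactly 1", {
  r <- experimental_ranges()
  sim <- means_vector()
  sim["APD90"] <- r$mean[r$biomarker == "APD90"] +
    2 * r$sd[r$biomarker == "APD90"]
  expect_equal(biomarker_cost(sim)$total, 1)
})

test_that("doubling a weight exactly doubles that contribution", {
  r <- experimental_ranges()
  sim <- means_vector()
  sim["FREQ"] <- r$mean[r$biomarker == "FREQ"] + 3 * r$sd[r$biomarker == "FREQ"]
  base <- biomarker_cost(sim, r)$total
  r2 <- r
  r2$weight[r2$biomarker == "FREQ"] <- 2 * r2$weight[r2$biomarker == "FREQ"]
  expect_equal(biomarker_cost(sim, r2)$total, 2 * base)
})

test_that("the zero set is exactly the mean +/- SD box", {
  r <- experimental_ranges()
  set.seed(11)
  for (i in 1:30) {
    k <- sample(nrow(r), 1)
    sim <- means_vector()
    inside <- runif(1) < 0.5
    eps <- runif(1, 0.01, 0.5)
    sim[r$biomarker[k]] <- r$mean[k] +
      sample(c(-1, 1), 1) * r$sd[k] * (if (inside) 1 - eps else 1 + eps)
    cc <- biomarker_cost(sim, r)
    if (inside) expect_equal(cc$total, 0) else expect_gt(cc$total, 0)
  }
})

test_that("missing biomarkers are penalized and flagged, never dropped", {
  sim <- means_vector()
  sim["FREQ"] <- NA
  cc <- biomarker_cost(sim, penalty = 1000)
  expect_equal(cc$total, 1000)
  expect_equal(cc$n_missing, 1L)
  expect_true(cc$failed)
})

test_that("the sigmoid transform keeps every parameter inside +/-20% bounds", {
  fn <- make_objective(base = "paci2013-baseline", settle_s = 0, window_s = 5)
  to_params <- attr(fn, "to_params")
  base <- load_parameters("paci2013-baseline")
  nm <- optimized_parameter_names()
  set.seed(5)
  for (i in 1:20) {
    theta <- rnorm(length(nm), sd = 5)
    p <- to_params(theta)
    ratio <- unlist(unclass(p)[nm]) / unlist(unclass(base)[nm])
    expect_true(all(ratio >= 0.8 - 1e-12 & ratio <= 1.2 + 1e-12))
  }
  expect_equal(unname(attr(fn, "start")), rep(0, length(nm)))
})

test_that("the objective is deterministic and penalizes out-of-bounds vectors", {
  fn <- make_objective(base = "paci2018-optimized", settle_s = 0,
                       window_s = 8)
  th <- rep(0, length(optimized_parameter_names()))
  expect_identical(fn(th), fn(th))
  fp <- make_objective(base = "paci2018-optimized", settle_s = 0,
                       window_s = 8, transform = "penalty")
  ones <- rep(1, length(optimized_parameter_names()))
  expect_gt(fp(1.5 * ones), 1000)   # strictly above the penalty floor
})
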