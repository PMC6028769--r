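# The SR release subsystem: luminal modulation factor, gate steady states,
# release flux. Expected values frozen from direct evaluation of the
# closed-form sigmoids.

test_that("luminal Ca modulation hits its midpoint, limits and printed form", {
  expect_equal(ryr_casr_modulation(0.3), 0.5)
  expect_lt(abs(ryr_casr_modulation(10) - 1), 1e-10)
  # direct evaluation at an empty store: 1 - 1/(1 + exp(-3))
  expect_equal(ryr_casr_modulation(0), 1 - 1 / (1 + exp(-3)), tolerance = 1e-12)
  expect_equal(ryr_casr_modulation(0), 0.04742587, tolerance = 1e-7)
  expect_error(ryr_casr_modulation(-0.1), "non-negative")
})

test_that("luminal Ca modulation is strictly increasing and bounded", {
  grid <- seq(0, 2, by = 0.01)
  v <- ryr_casr_modulation(grid)
  expect_true(all(diff(v) > 0))
  expect_true(all(v > 0 & v < 1))
})

test_that("gate steady states sit at 0.5 at their half-activation points", {
  p <- load_parameters("paci2018-optimized")
  ryra <- 0.02  # a representative adaptation working point (uM scale)
  ca_o_half <- (ryra + p$RyR_o_half) / 1000  # mM giving the o-gate midpoint
  ss <- ryr_gate_steady_states(ca_o_half, ryra, p)
  expect_equal(ss$RyR_o_ss, 0.5, tolerance = 1e-12)
  ca_c_half <- (ryra + p$RyR_c_half) / 1000
  ss <- ryr_gate_steady_states(ca_c_half, ryra, p)
  expect_equal(ss$RyR_c_ss, 0.5, tolerance = 1e-12)
})

test_that("adaptation gate saturates at RyR_a1 for large Ca and gates are monotone", {
  p <- load_parameters("paci2018-optimized")
  ss_inf <- ryr_gate_steady_states(10, 0.02, p)   # 10 mM >> any half point
  expect_equal(ss_inf$RyR_a_ss, p$RyR_a1, tolerance = 1e-9)
  ca <- seq(0, 6e-5, length.out = 80)  # cytosolic range before the sigmoids
                                       # saturate to 1.0 in double precision
  ss <- ryr_gate_steady_states(ca, 0.02, p)
  expect_true(all(diff(ss$RyR_a_ss) > 0))
  expect_true(all(diff(ss$RyR_o_ss) > 0))
  expect_true(all(diff(ss$RyR_c_ss) < 0))
  expect_true(all(ss$RyR_o_ss > 0 & ss$RyR_o_ss < 1))
  expect_true(all(ss$RyR_c_ss > 0 & ss$RyR_c_ss < 1))
  expect_error(ryr_gate_steady_states(-1e-5, 0.02, p), "non-negative")
})

test_that("release flux is the product of its printed factors", {
  st <- initial_state()
  # zero gradient
  st[c("Ca_SR", "Ca_i")] <- 2e-4
  expect_equal(compute_irel(st), 0)
  # closed channel
  st <- initial_state()
  st["RyR_o"] <- 0
  expect_equal(compute_irel(st), 0)
  # I_rel_max 62.5434 with RyR_CaSR = 0.5, o = 0.1, c = 1, gradient 0.2 mM
  st <- initial_state()
  st["Ca_SR"] <- 0.3            # sigmoid midpoint -> factor 0.5
  st["Ca_i"] <- 0.1
  st["RyR_o"] <- 0.1
  st["RyR_c"] <- 1
  expect_equal(compute_irel(st), 62.5434 * 0.5 * 0.1 * 1 * 0.2,
               tolerance = 1e-12)
  expect_equal(compute_irel(st), 0.625434, tolerance = 1e-9)
})

test_that("release follows the SR-to-cytosol gradient for random valid states", {
  set.seed(42)
  for (i in 1:50) {
    st <- initial_state()
    st["Ca_SR"] <- runif(1, 0.01, 3)
    st["Ca_i"] <- runif(1, 1e-6, st[["Ca_SR"]])
    st["RyR_o"] <- runif(1)
    st["RyR_c"] <- runif(1)
    expect_gte(compute_irel(st), 0)
  }
})
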