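# Simulation engine contracts: continuity, determinism, chaining, capture.

test_that("very short runs return at least two samples and barely move", {
  st <- packaged_state("spontaneous")
  tr <- simulate_cm("paci2018-optimized", protocol_spontaneous(),
                    duration = 1e-3, init = st, dt = 1e-3)
  expect_gte(nrow(tr), 2)
  drift <- abs(final_state(tr) - st)
  expect_lt(drift[["Vm"]], 1e-3)          # < 1 mV in 1 ms of diastole-free run
  expect_lt(drift[["Ca_i"]], 1e-5)
})

test_that("identical calls give bit-identical traces", {
  run <- function() simulate_cm("paci2018-optimized", protocol_spontaneous(),
                                duration = 2, init = packaged_state("spontaneous"),
                                dt = 1e-3, keep_currents = FALSE)
  expect_identical(as.data.frame(run()), as.data.frame(run()))
})

test_that("a run can be chained through its terminal state", {
  st <- packaged_state("spontaneous")
  run <- function(dur, init) simulate_cm(
    "paci2018-optimized", protocol_spontaneous(), duration = dur,
    init = init, dt = 1e-3, keep_currents = FALSE, hmax = 0.002)
  whole <- run(4, st)
  a <- run(2, st)
  b <- run(2, final_state(a))
  second_half <- whole$Vm[whole$t >= 2 - 1e-9]
  expect_lt(max(abs(second_half - b$Vm)) * 1000, 0.1)  # < 0.1 mV
})

test_that("trace time grid is uniform, increasing and NaN-free", {
  tr <- spontaneous_window(dt = 1e-4)
  expect_true(all(diff(tr$t) > 0))
  expect_lt(max(abs(diff(tr$t) - 1e-4)), 1e-9)
  expect_false(anyNA(tr))
})

test_that("1 Hz pacing captures exactly one AP per stimulus", {
  tr <- cm_cached("paced10", simulate_cm(
    "paci2018-optimized", protocol_paced(1, 550), duration = 10,
    init = packaged_state("paced-1hz-550pA"), dt = 1e-4,
    keep_currents = FALSE))
  ap <- ap_biomarkers(tr)
  expect_equal(ap$n_ap, 9)  # 10 upstrokes, 9 complete cycles
  expect_equal(mean(ap$per_ap$CL), 1000, tolerance = 1e-3)
  expect_false(hipsccm:::check_capture_failure(tr))
})

test_that("the stimulus current appears only inside the pulse", {
  tr <- simulate_cm("paci2018-optimized", protocol_paced(1, 550, 5),
                    duration = 2, init = packaged_state("paced-1hz-550pA"),
                    dt = 1e-4, keep_currents = TRUE)
  on <- tr$I_stim[tr$t %% 1 < 0.005 - 1e-9]
  off <- tr$I_stim[tr$t %% 1 > 0.005 + 1e-9]
  expect_true(all(abs(off) < 1e-12))
  expect_gt(mean(on > 0), 0.95)
  expect_equal(max(tr$I_stim), 550e-12 / 9.87109e-11, tolerance = 1e-6)
})

test_that("environment override equal to baseline reports a 0% change", {
  res <- run_environment_series(overrides = list(list()),
                                settle_s = 30, window_s = 30)
  expect_equal(res$change_pct[2], 0)
  expect_false(any(res$activity_stopped))
})
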