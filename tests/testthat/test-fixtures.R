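# Round-trip property: extracted biomarkers match the closed-form truth for
# randomized waveform specs.

test_that("AP-family fixtures round-trip within the interpolation bound", {
  set.seed(7)
  for (i in 1:8) {
    rect <- runif(1) < 0.5
    # integer-ms durations keep the waveform vertices on the 0.1 ms
    # sampling grid, so the closed-form truth is exact
    spec <- if (rect)
      waveform_spec("rectangular", baseline = runif(1, -80, -70),
                    amplitude = runif(1, 80, 120),
                    plateau_ms = sample(200:400, 1),
                    period_ms = sample(800:1500, 1), n = 4)
    else
      waveform_spec("triangular", signal = "vm",
                    baseline = runif(1, -80, -70),
                    amplitude = runif(1, 80, 120),
                    rise_ms = sample(2:8, 1), plateau_ms = 0,
                    decay_ms = sample(150:400, 1),
                    period_ms = sample(800:1500, 1), n = 4)
    fx <- generate_waveform(spec)
    m <- ap_biomarkers(fx$trace)$mean
    for (b in c("CL", "APD10", "APD30", "APD90"))
      expect_lt(abs(m[[b]] - fx$truth[[b]]), 0.5)
    for (b in c("APA", "MDP"))
      expect_lt(abs(m[[b]] - fx$truth[[b]]), 0.1)
  }
})

test_that("Ca-transient fixtures round-trip within the interpolation bound", {
  set.seed(8)
  for (i in 1:8) {
    expo <- runif(1) < 0.5
    spec <- if (expo)
      waveform_spec("piecewise-exponential", baseline = runif(1, 0, 0.2),
                    amplitude = runif(1, 0.5, 2),
                    rise_ms = sample(50:150, 1), plateau_ms = 0,
                    decay_ms = sample(400:600, 1),
                    tau_ms = runif(1, 80, 150),
                    period_ms = sample(900:1500, 1), n = 4)
    else
      waveform_spec("triangular", baseline = runif(1, 0, 0.2),
                    amplitude = runif(1, 0.5, 2),
                    rise_ms = sample(50:150, 1), plateau_ms = 0,
                    decay_ms = sample(200:500, 1),
                    period_ms = sample(900:1500, 1), n = 4)
    fx <- generate_waveform(spec)
    m <- cat_biomarkers(fx$trace)$mean
    for (b in c("DURATION", "TPEAK", "RT1050", "RT1090", "DT9010"))
      expect_lt(abs(m[[b]] - fx$truth[[b]]), 0.5)
    expect_equal(m[["FREQ"]], fx$truth[["FREQ"]], tolerance = 1e-3)
  }
})

test_that("the seed contract makes noisy fixtures reproducible", {
  spec <- function(sd, seed) waveform_spec("triangular", rise_ms = 100,
                                           decay_ms = 400, plateau_ms = 0,
                                           baseline = 0, amplitude = 1,
                                           noise_sd = sd, seed = seed)
  expect_identical(generate_waveform(spec(0, 1))$trace,
                   generate_waveform(spec(0, 2))$trace)
  expect_identical(generate_waveform(spec(0.05, 3))$trace,
                   generate_waveform(spec(0.05, 3))$trace)
  expect_false(identical(generate_waveform(spec(0.05, 3))$trace,
                         generate_waveform(spec(0.05, 4))$trace))
})

test_that("overlapping events are rejected", {
  expect_error(waveform_spec("triangular", rise_ms = 300, plateau_ms = 300,
                             decay_ms = 500, period_ms = 1000),
               "overlap")
})
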