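# DAD detection on constructed traces with known ground truth.

flat_trace <- function(level_mV = -75, dur = 5, dt = 1e-3) {
  structure(data.frame(t = seq(0, dur, by = dt), Vm = level_mV / 1000),
            class = c("cm_trace", "data.frame"))
}

ap_train <- function() generate_waveform(
  waveform_spec("rectangular", baseline = -75, amplitude = 100,
                plateau_ms = 300, period_ms = 1200, n = 4))$trace

test_that("a flat diastole contains no events", {
  expect_identical(nrow(detect_dads(flat_trace())), 0L)
})

test_that("an injected 3 mV bump is found once, at the right time", {
  tr <- inject_dad(ap_train(), time = 1.9, amplitude_mV = 3, width_s = 0.1)
  ev <- detect_dads(tr)
  sub <- ev[ev$classification == "subthreshold_dad", ]
  expect_equal(nrow(sub), 1L)
  expect_lt(abs(sub$onset_s - 1.9), 0.005)
  expect_equal(sub$amplitude_mV, 3, tolerance = 0.3)
})

test_that("a bump below the threshold is ignored", {
  tr <- inject_dad(ap_train(), time = 1.9, amplitude_mV = 0.1, width_s = 0.1)
  expect_identical(nrow(detect_dads(tr)), 0L)
})

test_that("a slow depolarization reaching -10 mV is a triggered event", {
  tr <- inject_dad(ap_train(), time = 1.9, amplitude_mV = 65, width_s = 0.2)
  ev <- detect_dads(tr)
  expect_true(any(ev$classification == "triggered_ap"))
})

test_that("injection inside an AP is refused", {
  expect_error(inject_dad(ap_train(), time = 1.35, amplitude_mV = 3),
               "diastole")
})
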