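# Biomarker extraction against closed-form waveform fixtures and the
# simulated limit cycle.

test_that("rectangular AP train yields its exact geometric biomarkers", {
  fx <- generate_waveform(waveform_spec("rectangular", baseline = -75,
                                        amplitude = 100, plateau_ms = 300,
                                        period_ms = 1000, n = 5))
  ap <- ap_biomarkers(fx$trace)
  m <- ap$mean
  expect_equal(m[["APA"]], 100, tolerance = 0.1)
  expect_equal(m[["MDP"]], -75, tolerance = 0.1)
  expect_equal(m[["CL"]], 1000, tolerance = 0.5)
  for (x in c("APD10", "APD30", "APD90"))
    expect_equal(m[[x]], 300, tolerance = 0.5)
})

test_that("linear repolarization gives uniform APD spacing and ratio 1", {
  fx <- generate_waveform(waveform_spec("triangular", signal = "vm",
                                        baseline = -75, amplitude = 100,
                                        rise_ms = 4, plateau_ms = 0,
                                        decay_ms = 300, period_ms = 900,
                                        n = 5))
  ap <- ap_biomarkers(fx$trace)
  m <- ap$mean
  expect_equal(m[["APD30"]] - m[["APD40"]], m[["APD70"]] - m[["APD80"]],
               tolerance = 0.3)
  expect_equal(m[["Triangulation"]], 1, tolerance = 0.02)
  tri <- triangulation(m[["APD30"]], m[["APD40"]], m[["APD70"]], m[["APD80"]])
  expect_identical(tri$classification, "atrial-like")
})

test_that("triangulation handles degenerate shapes and refuses undefined ratios", {
  sq <- triangulation(300, 300, 350, 340)
  expect_equal(sq$value, 0)
  expect_true(sq$degenerate)
  expect_identical(sq$classification, "atrial-like")
  expect_error(triangulation(100, 120, 200, 200), "undefined")
})

test_that("triangular Ca transient yields its exact rise/decay biomarkers", {
  fx <- generate_waveform(waveform_spec("triangular", signal = "cai",
                                        baseline = 0.1, amplitude = 1,
                                        rise_ms = 100, plateau_ms = 0,
                                        decay_ms = 400, period_ms = 1000,
                                        n = 5))
  m <- cat_biomarkers(fx$trace)$mean
  expect_equal(m[["RT1050"]], 40, tolerance = 0.5)
  expect_equal(m[["RT1090"]], 80, tolerance = 0.5)
  expect_equal(m[["DT9010"]], 320, tolerance = 0.5)
  expect_equal(m[["TPEAK"]], 90, tolerance = 0.5)
  expect_equal(m[["DURATION"]], 450, tolerance = 0.5)
  expect_equal(m[["FREQ"]], 1, tolerance = 1e-3)
})

test_that("order invariants hold on fixtures and the simulated limit cycle", {
  tr <- spontaneous_window()
  ap <- ap_biomarkers(tr)$mean
  expect_lte(ap[["APD10"]], ap[["APD30"]])
  expect_lte(ap[["APD30"]], ap[["APD90"]])
  cat <- cat_biomarkers(tr)$mean
  expect_lte(cat[["RT1050"]], cat[["RT1090"]])
  expect_identical(
    triangulation(ap[["APD30"]], ap[["APD40"]], ap[["APD70"]],
                  ap[["APD80"]])$classification,
    "ventricular-like")
})

test_that("halving the sampling interval changes biomarkers by < 0.1%", {
  b1 <- biomarker_set(spontaneous_window(dt = 1e-4))
  b2 <- biomarker_set(spontaneous_window(dt = 5e-5))
  rel <- abs(b2 - b1) / abs(b1)
  expect_lt(max(rel, na.rm = TRUE), 1e-3)
})

test_that("insufficient events raise informative errors", {
  one_ap <- generate_waveform(waveform_spec("rectangular", n = 1))
  expect_error(ap_biomarkers(one_ap$trace), "insufficient|at least 2")
  flat <- data.frame(t = seq(0, 5, 1e-3), Ca_i = seq(1, 2, length.out = 5001))
  expect_error(cat_biomarkers(flat), "insufficient|monotone")
})

test_that("biomarker_set reports NA for an absent signal family", {
  fx <- generate_waveform(waveform_spec("rectangular", n = 4))
  bm <- biomarker_set(fx$trace)       # Vm only, no Ca_i
  expect_false(anyNA(bm[c("APA", "CL", "APD90")]))
  expect_true(all(is.na(bm[c("FREQ", "DT9010")])))
})
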