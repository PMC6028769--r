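# The assembled right-hand side: relaxation-form gate kinetics, calcium
# bookkeeping, quiescence, boundedness.

test_that("state vector has the 23 published slots", {
  expect_length(state_names(), 23)
  expect_length(initial_state(), 23)
  expect_true(all(c("Vm", "Ca_SR", "Ca_i", "Na_i", "RyR_a", "RyR_o",
                    "RyR_c") %in% state_names()))
})

test_that("gate derivatives follow (x_ss - x)/tau: linearity and closed form", {
  # rhs is affine in each isolated gate at fixed (Vm, Ca): two evaluations
  # identify x_ss and tau, a third checks linearity, and the closed-form
  # exponential relaxation then reproduces the derivative by finite
  # differences
  st0 <- initial_state()
  for (gate in c("m", "Xf", "q", "RyR_o", "f2")) {
    st1 <- st0; st1[gate] <- 0.2
    st2 <- st0; st2[gate] <- 0.8
    d1 <- model_rhs(0, st1)$derivatives[[gate]]
    d2 <- model_rhs(0, st2)$derivatives[[gate]]
    tau <- (st2[[gate]] - st1[[gate]]) / (d1 - d2)
    x_ss <- st1[[gate]] + d1 * tau
    expect_gt(tau, 0)
    # derivative vanishes at the inferred steady state
    st3 <- st0; st3[gate] <- x_ss
    expect_lt(abs(model_rhs(0, st3)$derivatives[[gate]]), 1e-9 / tau)
    # linearity at a third point
    st4 <- st0; st4[gate] <- 0.5
    expect_equal(model_rhs(0, st4)$derivatives[[gate]],
                 (x_ss - 0.5) / tau, tolerance = 1e-10)
    # closed-form relaxation x(t) = x_ss + (x0 - x_ss) exp(-t/tau):
    # its finite-difference slope matches the rhs at t = 0
    h <- tau * 1e-8
    x_h <- x_ss + (st1[[gate]] - x_ss) * exp(-h / tau)
    expect_equal((x_h - st1[[gate]]) / h, d1, tolerance = 1e-7)
  }
})

test_that("non-finite states are rejected with the offending name", {
  st <- initial_state()
  st["Ca_i"] <- NaN
  expect_error(model_rhs(0, st), "Ca_i")
})

test_that("SR is an isolated compartment when all its fluxes vanish", {
  p <- pars_with(V_max_up = 0, I_leak_max = 0, I_rel_max = 0)
  st <- initial_state()
  st["RyR_o"] <- 0
  d <- model_rhs(0, st, p)$derivatives
  expect_equal(d[["Ca_SR"]], 0)
})

test_that("total Ca is conserved when sarcolemmal Ca fluxes are zeroed", {
  p <- apply_block("paci2018-optimized",
                   c(G_CaL = 0, G_bCa = 0, G_pCa = 0, I_NaCa_max = 0))
  tr <- simulate_cm(p, protocol_spontaneous(), duration = 10,
                    init = packaged_state("spontaneous"), dt = 1e-3,
                    keep_currents = FALSE)
  # free + buffer-bound Ca, volume-weighted over cytosol and SR
  buf_c <- 0.25 * tr$Ca_i / (tr$Ca_i + 0.001)
  buf_sr <- 10 * tr$Ca_SR / (tr$Ca_SR + 0.3)
  vc <- 8800; vsr <- 583.73
  total <- vc * (tr$Ca_i + buf_c) + vsr * (tr$Ca_SR + buf_sr)
  expect_lt(max(abs(total - total[1])) / total[1], 1e-5)
})

test_that("membrane rests at the K+ Nernst potential when only K currents remain", {
  p <- apply_block("paci2018-optimized",
                   c(G_Na = 0, G_NaL = 0, G_CaL = 0, G_f = 0, G_bNa = 0,
                     G_bCa = 0, I_NaCa_max = 0, I_NaK_max = 0, G_pCa = 0))
  e_k <- 8.314472 * 310 / 96485.3415 * log(5.4 / 150)
  st <- initial_state()
  st["Vm"] <- e_k
  # membrane currents sum to zero at the fixed point
  cur <- model_rhs(0, st, p)$currents
  mem <- cur[c("I_Na", "I_NaL", "I_CaL", "I_f", "I_to", "I_Kr", "I_Ks",
               "I_K1", "I_NaK", "I_NaCa", "I_pCa", "I_bNa", "I_bCa")]
  expect_lt(sum(abs(mem)), 1e-10)
  tr <- simulate_cm(p, protocol_spontaneous(), duration = 10, init = st,
                    dt = 1e-2, keep_currents = FALSE)
  expect_lt(max(abs(tr$Vm - e_k)) * 1000, 1)  # < 1 mV drift
})

test_that("all Hodgkin-Huxley gates stay in [0,1] over a 60 s simulation", {
  tr <- cm_cached("spont60", simulate_cm(
    "paci2018-optimized", protocol_spontaneous(), duration = 60,
    init = packaged_state("spontaneous"), dt = 1e-3,
    keep_currents = FALSE))
  gates <- c("d", "f1", "f2", "fCa", "Xr1", "Xr2", "Xs", "h", "j", "m",
             "Xf", "q", "r", "mL", "hL", "RyR_o", "RyR_c")
  for (g in gates) {
    expect_gte(min(tr[[g]]), -1e-5)
    expect_lte(max(tr[[g]]), 1 + 1e-5)
  }
  expect_gt(min(tr$Ca_i), 0)
  expect_gt(min(tr$Ca_SR), 0)
  expect_gt(min(tr$Na_i), 0)
})

test_that("apply_block scales only the named maxima", {
  p <- load_parameters("paci2018-optimized")
  expect_identical(unclass(apply_block(p, NULL))[names(p)], unclass(p)[names(p)])
  ttx <- apply_block(p, c(G_Na = 0.18))
  expect_equal(ttx$G_Na, p$G_Na * 0.18)
  expect_identical(unclass(ttx)[setdiff(names(p), "G_Na")],
                   unclass(p)[setdiff(names(p), "G_Na")])
  iva <- apply_block(p, c(G_f = 0.59))
  expect_equal(iva$G_f, 30.10312 * 0.59)
  expect_error(apply_block(p, c(G_bogus = 0.5)), "G_Na.*G_NaL|valid names")
  expect_error(apply_block(p, c(G_Na = 1.2)), "\\[0, 1\\]")
})

test_that("the immature-RyR edit is exactly invertible", {
  p <- load_parameters("paci2018-optimized")
  imm <- make_immature_ryr(p)
  expect_equal(imm$RyR_o_half, p$RyR_o_half - 0.002)
  expect_equal(imm$RyR_c_half, p$RyR_c_half + 0.002)
  expect_equal(imm$tau_RyR_o, p$tau_RyR_o * 2)
  expect_equal(imm$tau_RyR_c, p$tau_RyR_c / 2)
  undone <- load_parameters(list(
    RyR_o_half = imm$RyR_o_half + 0.002,
    RyR_c_half = imm$RyR_c_half - 0.002,
    tau_RyR_o = imm$tau_RyR_o / 2,
    tau_RyR_c = imm$tau_RyR_c * 2), base = imm)
  expect_equal(unlist(unclass(undone)), unlist(unclass(p)), tolerance = 1e-12)
})
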