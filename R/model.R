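#' Luminal Ca2+ modulation of the ryanodine receptor
#'
#' Sigmoid factor through which the sarcoplasmic-reticulum Ca2+ content
#' modulates the release flux: `1 - 1/(1 + exp((Ca_SR - 0.3)/0.1))`. It is
#' strictly increasing in `Ca_SR` and bounded in (0, 1), so release shuts down
#' as the store empties and saturates as it overfills.
#'
#' @param Ca_SR SR Ca2+ concentration (mM), non-negative.
#' @return Dimensionless factor in (0, 1).
#' @export
#' @examples
#' ryr_casr_modulation(0.3)  # midpoint: 0.5
ryr_casr_modulation <- function(Ca_SR) {
  if (any(!is.finite(Ca_SR)) || any(Ca_SR < 0))
    stop("Ca_SR must be finite and non-negative")
  1 - 1 / (1 + exp((Ca_SR - 0.3) / 0.1))
}

#' Steady states of the three ryanodine-receptor gates
#'
#' The adaptation gate `RyR_a` tracks a Ca2+-concentration-valued working
#' point; the open (`RyR_o`) and closed (`RyR_c`) gates are sigmoids in
#' cytosolic Ca2+ whose midpoints ride on the current working point. All
#' sigmoid constants are in micromolar, so the cytosolic concentration is
#' converted from mM before comparison.
#'
#' @param Ca_i Cytosolic Ca2+ concentration (mM), non-negative.
#' @param RyR_a Current adaptation-gate working point (uM scale).
#' @param params A `cm_parameters` object (or registry name) supplying the RyR
#'   constants.
#' @return Named list with `RyR_a_ss`, `RyR_o_ss`, `RyR_c_ss`.
#' @export
ryr_gate_steady_states <- function(Ca_i, RyR_a,
                                   params = "paci2018-optimized") {
  if (any(!is.finite(Ca_i)) || any(Ca_i < 0))
    stop("Ca_i must be finite and non-negative")
  p <- load_parameters(params)
  ca <- 1000 * Ca_i   # uM
  list(
    RyR_a_ss = p$RyR_a1 - p$RyR_a2 / (1 + exp((ca - p$RyR_a_half) / p$RyR_a_k)),
    RyR_o_ss = 1 - 1 / (1 + exp((ca - (RyR_a + p$RyR_o_half)) / p$RyR_o_k)),
    RyR_c_ss = 1 / (1 + exp((ca - (RyR_a + p$RyR_c_half)) / p$RyR_c_k))
  )
}

#' SR Ca2+ release flux through the ryanodine receptor
#'
#' `I_rel = I_rel_max * RyR_CaSR * RyR_o * RyR_c * (Ca_SR - Ca_i)` (mM/s).
#' The flux follows the SR-to-cytosol gradient and vanishes when any gating
#' factor is zero.
#'
#' @param state Named state vector (needs `Ca_SR`, `Ca_i`, `RyR_o`, `RyR_c`),
#'   e.g. from [initial_state()] or a simulation.
#' @param params A `cm_parameters` object (or registry name).
#' @return Release flux (mM/s).
#' @export
compute_irel <- function(state, params = "paci2018-optimized") {
  p <- load_parameters(params)
  st <- as.list(state)
  p$I_rel_max * ryr_casr_modulation(st$Ca_SR) * st$RyR_o * st$RyR_c *
    (st$Ca_SR - st$Ca_i)
}

#' Evaluate the model right-hand side at one point
#'
#' Computes the time derivative of all 23 state slots and the instantaneous
#' membrane currents (A/F) and SR fluxes (mM/s). Mostly useful for
#' diagnostics and testing; simulations use the compiled path directly.
#'
#' @param t Time (s); only relevant for the stimulus phase when `stim` is set.
#' @param state Named 23-element state vector (see [initial_state()]).
#' @param params A `cm_parameters` object (or registry name).
#' @param stim Optional stimulus description as returned by
#'   [protocol_paced()]'s `stim` element, or `NULL` for no stimulus.
#' @return List with `derivatives` (named, 1/s units of each state) and
#'   `currents` (named).
#' @export
model_rhs <- function(t, state, params = "paci2018-optimized", stim = NULL) {
  state <- as_state_vector(state)
  if (any(!is.finite(state))) {
    bad <- paste(names(state)[!is.finite(state)], collapse = ", ")
    stop("non-finite state variable(s): ", bad)
  }
  pv <- as_parms_vector(load_parameters(params), stim = stim)
  res <- .Call("hipsccm_rhs_call", as.numeric(t), as.numeric(state),
               as.numeric(pv), PACKAGE = "hipsccm")
  list(derivatives = setNames(res[[1]], .state_names),
       currents = setNames(res[[2]], .current_names))
}

as_state_vector <- function(state) {
  state <- unlist(state)
  if (length(state) != length(.state_names))
    stop("state vector must have ", length(.state_names), " elements")
  if (!is.null(names(state)) && all(.state_names %in% names(state)))
    state <- state[.state_names]
  setNames(as.numeric(state), .state_names)
}

#' Names of the model state variables
#' @return Character vector of the 23 state slot names. The `g_legacy` slot is
#'   the vestigial SR-release inactivation gate of the predecessor model,
#'   retained (frozen at its initial value) for layout compatibility with the
#'   published 23-variable ordering.
#' @export
state_names <- function() .state_names

#' A rough depolarized-rest initial condition
#'
#' Generic starting point for long pre-runs; use [packaged_state()] for
#' limit-cycle initial conditions.
#'
#' @return Named 23-element state vector (V, mM, dimensionless gates).
#' @export
initial_state <- function() {
  setNames(c(
    -0.070,   # Vm (V)
    0.32,     # Ca_SR (mM)
    2e-5,     # Ca_i (mM)
    0,        # legacy gate slot
    0, 1, 1, 1,       # d, f1, f2, fCa
    0, 1, 0,          # Xr1, Xr2, Xs
    0.75, 0.75, 0,    # h, j, m
    0.1,              # Xf
    1, 0,             # q, r
    9.2,              # Na_i (mM)
    0, 0.75,          # mL, hL
    0.02, 0.01, 0.9   # RyR_a, RyR_o, RyR_c
  ), .state_names)
}
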