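# Biomarker-range cost function and the bounded Nelder-Mead calibration
# driver. The cost is zero while every biomarker sits inside its
# experimental mean +/- SD band and grows linearly (in SD units, weighted)
# outside it; the optimizer works in a per-parameter sigmoid-transformed
# coordinate so the simplex is unconstrained while parameters stay inside
# +/-20% of baseline.

#' Experimental biomarker ranges used for calibration
#'
#' The 8 AP biomarkers (patch-clamp dataset of spontaneous ventricular-like
#' hiPSC-CM APs) and 6 Ca2+-transient biomarkers (fluorescence dataset, 15
#' cells / 218 transients) with their cost-function weights. Only the
#' maximum diastolic potential and the cycle length - the two biomarkers most
#' characteristic of the hiPSC-CM phenotype - carry weight 2.
#'
#' @return Data frame with `biomarker`, `mean`, `sd`, `weight`, `units`.
#' @export
experimental_ranges <- function() {
  data.frame(
    biomarker = c("APA", "MDP", "CL", "Vmax", "APD10", "APD30", "APD90",
                  "Triangulation", "DURATION", "TPEAK", "RT1050", "RT1090",
                  "DT9010", "FREQ"),
    mean = c(104, -75.6, 1700.0, 27.8, 74.1, 180, 414.7, 2.5,
             804.5, 270.4, 82.9, 167.3, 409.8, 0.70),
    sd = c(6.0, 6.6, 547.7, 26.3, 26.3, 58.6, 119.4, 1.1,
           188.0, 108.3, 50.5, 69.8, 100.1, 0.38),
    weight = c(1, 2, 2, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
    units = c("mV", "mV", "ms", "V/s", "ms", "ms", "ms", "-",
              "ms", "ms", "ms", "ms", "ms", "Hz"),
    stringsAsFactors = FALSE)
}

#' Reference biomarker values of the calibrated model
#'
#' The spontaneous-steady-state biomarker values that the calibrated
#' parameter set is expected to reproduce (model reference: spontaneous
#' biomarkers). Used by the reproduction harness as packaged expectations.
#'
#' @return Named numeric vector of the 14 biomarkers.
#' @export
reference_biomarkers <- function() {
  c(APA = 109.6, MDP = -75.8, CL = 1549.3, Vmax = 24.8,
    APD10 = 85.8, APD30 = 241.8, APD90 = 379.8, Triangulation = 3.0,
    DURATION = 617.8, TPEAK = 165.9, RT1050 = 47.7, RT1090 = 106.0,
    DT9010 = 367.6, FREQ = 0.65)
}

#' Weighted SD-banded biomarker cost
#'
#' Each biomarker contributes `w * (|mean - sim| - SD) / SD` when the
#' simulated value lies outside the experimental mean +/- SD band and zero
#' inside it, so the total cost is zero exactly when all biomarkers are
#' in-range. Missing biomarkers (e.g. no spontaneous activity) incur
#' `penalty` each and are flagged, never silently dropped.
#'
#' @param simulated Named numeric vector of simulated biomarkers (as from
#'   [biomarker_set()]).
#' @param ranges Data frame as from [experimental_ranges()].
#' @param penalty Cost per missing biomarker.
#' @return List with `total`, `breakdown` (per-biomarker data frame),
#'   `n_missing`, `failed` flag.
#' @export
biomarker_cost <- function(simulated, ranges = experimental_ranges(),
                           penalty = 1000) {
  stopifnot(all(c("biomarker", "mean", "sd", "weight") %in% names(ranges)))
  if (any(ranges$sd <= 0) || any(ranges$weight <= 0))
    stop("ranges must have positive sd and weight")
  sim <- simulated[ranges$biomarker]
  dev <- abs(ranges$mean - sim)
  cost_i <- ifelse(is.na(sim), penalty,
                   ifelse(dev > ranges$sd,
                          ranges$weight * (dev - ranges$sd) / ranges$sd, 0))
  breakdown <- data.frame(biomarker = ranges$biomarker,
                          simulated = as.numeric(sim),
                          mean = ranges$mean, sd = ranges$sd,
                          weight = ranges$weight,
                          in_range = !is.na(sim) & dev <= ranges$sd,
                          cost = cost_i, stringsAsFactors = FALSE)
  n_missing <- sum(is.na(sim))
  list(total = sum(cost_i), breakdown = breakdown,
       n_missing = n_missing, failed = n_missing > 0)
}

#' Names of the parameters opened to optimization
#' @return Character vector of the 12 optimized parameter names.
#' @export
optimized_parameter_names <- function() {
  c("V_max_up", "I_rel_max", "RyR_a1", "RyR_a2", "RyR_a_half",
    "RyR_o_half", "RyR_c_half", "I_NaCa_max", "I_NaK_max", "K_up",
    "I_leak_max", "alpha")
}

# smooth bijection R -> (lo, hi); theta = 0 maps to the midpoint
sigmoid_map <- function(theta, lo, hi) lo + (hi - lo) / (1 + exp(-theta))
sigmoid_unmap <- function(x, lo, hi) {
  f <- (x - lo) / (hi - lo)
  f <- pmin(pmax(f, 1e-12), 1 - 1e-12)
  log(f / (1 - f))
}

#' Build the calibration objective
#'
#' Maps a free-parameter vector to a full parameter set, simulates
#' spontaneous activity from the packaged limit cycle (settling run plus
#' analysis window), extracts the 14 biomarkers and returns the
#' [biomarker_cost()]. Simulation failures and missing biomarkers return the
#' penalty value so the simplex moves away from non-oscillating regions.
#' A limit-cycle check (cycle-length drift across the window) is recorded
#' with each evaluation.
#'
#' @param base Baseline parameter set the free parameters scale.
#' @param names Optimized parameter names.
#' @param bound_frac Symmetric bound as a fraction of baseline (0.2 = +/-20%).
#' @param ranges Experimental ranges.
#' @param settle_s,window_s Settling run and analysis window (s).
#' @param transform `"sigmoid"` (bounded coordinates; default) or
#'   `"penalty"` (raw scale factors with an out-of-bounds penalty).
#' @param rtol Solver tolerance inside the objective.
#' @param log_env Optional environment collecting an evaluation log.
#' @return Function mapping the free vector (length `length(names)`) to a
#'   scalar cost. The mapping from free coordinates to scale factors is
#'   exposed via attributes `to_params` and `start`.
#' @export
make_objective <- function(base = "paci2013-baseline",
                           names = optimized_parameter_names(),
                           bound_frac = 0.2,
                           ranges = experimental_ranges(),
                           settle_s = 300, window_s = 20,
                           transform = c("sigmoid", "penalty"),
                           rtol = 1e-6,
                           log_env = NULL) {
  base <- load_parameters(base)
  transform <- match.arg(transform)
  base_vals <- unlist(unclass(base)[names])
  lo <- (1 - bound_frac) * base_vals
  hi <- (1 + bound_frac) * base_vals
  init_state <- packaged_state("spontaneous")
  to_params <- function(theta) {
    vals <- switch(transform,
                   sigmoid = sigmoid_map(theta, lo, hi),
                   penalty = theta * base_vals)
    load_parameters(as.list(setNames(vals, names)), base = base)
  }
  fn <- function(theta) {
    if (length(theta) != length(names))
      stop("free-parameter vector must have length ", length(names))
    oob <- 0
    if (transform == "penalty") {
      viol <- pmax(theta - (1 + bound_frac), (1 - bound_frac) - theta, 0)
      oob <- 1000 * sum(viol > 0) + 1e4 * sum(viol)
    }
    p <- to_params(theta)
    cost <- tryCatch({
      st <- init_state
      if (settle_s > 0) {
        pre <- simulate_cm(p, protocol_spontaneous(), duration = settle_s,
                           init = st, dt = 0.01, keep_currents = FALSE,
                           rtol = rtol)
        st <- final_state(pre)
      }
      tr <- simulate_cm(p, protocol_spontaneous(), duration = window_s,
                        init = st, dt = 1e-4, keep_currents = FALSE,
                        rtol = rtol)
      bm <- biomarker_set(tr)
      cc <- biomarker_cost(bm, ranges)
      drift <- tryCatch({
        cl <- ap_biomarkers(tr)$per_ap$CL
        if (length(cl) >= 3) abs(cl[length(cl)] - cl[1]) / mean(cl) else NA
      }, error = function(e) NA)
      if (!is.null(log_env))
        log_env$log[[length(log_env$log) + 1]] <-
          list(theta = theta, cost = cc$total, drift = drift,
               missing = cc$n_missing)
      cc$total
    }, error = function(e) {
      if (!is.null(log_env))
        log_env$log[[length(log_env$log) + 1]] <-
          list(theta = theta, cost = NA, error = conditionMessage(e))
      1000 + length(names)
    })
    cost + oob
  }
  attr(fn, "to_params") <- to_params
  start <- switch(transform,
                  sigmoid = sigmoid_unmap(base_vals, lo, hi),
                  penalty = rep(1, length(names)))
  # exact zeros matter: optim's simplex seeds its step from |par|, so a
  # round-off-sized coordinate would get a degenerate ~1e-17 initial step
  start[abs(start) < 1e-9] <- 0
  attr(fn, "start") <- start
  fn
}

#' Calibrate parameters against the biomarker ranges
#'
#' Bounded Nelder-Mead minimization of the biomarker-range cost, starting
#' from the baseline values (the RyR constants of the baseline set are
#' already the 1/10-rescaled seeds of their atrial-model source). The
#' optimum is a zero-cost *region*, not a unique point: success means a
#' terminal cost of 0 with every parameter inside the bounds, not recovery
#' of any particular published value.
#'
#' @inheritParams make_objective
#' @param maxit Maximum number of objective evaluations for the simplex.
#' @param reltol,abstol Simplex convergence tolerances.
#' @return List with `params` (calibrated set), `cost`, `scale`
#'   (optimized/baseline ratios), `converged`, `counts`, `log`
#'   (per-evaluation records).
#' @export
optimize_parameters <- function(base = "paci2013-baseline",
                                names = optimized_parameter_names(),
                                bound_frac = 0.2,
                                ranges = experimental_ranges(),
                                settle_s = 300, window_s = 20,
                                transform = "sigmoid",
                                maxit = 400,
                                reltol = 1e-3, abstol = 1e-3,
                                rtol = 1e-6) {
  log_env <- new.env()
  log_env$log <- list()
  fn <- make_objective(base = base, names = names, bound_frac = bound_frac,
                       ranges = ranges, settle_s = settle_s,
                       window_s = window_s, transform = transform,
                       rtol = rtol, log_env = log_env)
  start <- attr(fn, "start")
  f0 <- fn(start)
  if (f0 <= 0) {
    p0 <- attr(fn, "to_params")(start)
    return(list(params = p0, cost = f0,
                scale = setNames(rep(1, length(names)), names),
                converged = TRUE, counts = c(`function` = 1L), log = log_env$log))
  }
  # parscale sets the initial simplex size: 0.1 * parscale in free
  # coordinates, i.e. roughly a 7% parameter displacement per vertex
  res <- optim(start, fn, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = reltol,
                              abstol = abstol,
                              parscale = rep(8, length(start))))
  best <- attr(fn, "to_params")(res$par)
  base_p <- load_parameters(base)
  scale <- unlist(unclass(best)[names]) / unlist(unclass(base_p)[names])
  list(params = best, cost = res$value, scale = setNames(scale, names),
       converged = res$value <= 0,
       counts = res$counts, log = log_env$log)
}
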