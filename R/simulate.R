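#' Stimulation protocols
#'
#' A protocol bundles the stimulation mode and environment for a simulation.
#' `protocol_spontaneous()` lets the cell beat on its own;
#' `protocol_paced()` applies a rectangular current pulse train.
#' Stimulus amplitudes are given in pA (absolute current) and converted to
#' A/F through the membrane capacitance inside the model; the pulse duration
#' is an explicit, overridable choice (default 5 ms). Under the strongest
#' Na+-channel block arms a 5 ms / 750 pA pulse yields 2:1 capture; the
#' block-experiment result reports this per arm rather than hiding it.
#'
#' @param rate_hz Pacing rate (Hz), > 0.
#' @param amplitude_pA Pulse amplitude (pA), depolarizing positive.
#' @param duration_ms Pulse width (ms).
#' @param start_s Time of the first pulse (s) relative to simulation start.
#' @return A `cm_protocol` object.
#' @export
protocol_paced <- function(rate_hz = 1, amplitude_pA = 550,
                           duration_ms = 5, start_s = 0) {
  stopifnot(rate_hz > 0, duration_ms > 0, duration_ms / 1000 < 1 / rate_hz)
  structure(list(
    mode = "paced",
    stim = list(amplitude_A = amplitude_pA * 1e-12,
                period_s = 1 / rate_hz,
                duration_s = duration_ms / 1000,
                start_s = start_s)
  ), class = "cm_protocol")
}

#' @rdname protocol_paced
#' @export
protocol_spontaneous <- function() {
  structure(list(mode = "spontaneous", stim = NULL), class = "cm_protocol")
}

.default_atol <- function() {
  a <- rep(1e-6, length(.state_names))
  names(a) <- .state_names
  a[["Ca_i"]] <- 1e-10
  a[["Ca_SR"]] <- 1e-8
  a[["RyR_a"]] <- 1e-9
  a[["RyR_o"]] <- 1e-8
  a[["RyR_c"]] <- 1e-8
  a
}

#' Simulate the model
#'
#' Integrates the stiff ODE system with `deSolve`'s LSODA (switching
#' Adams/BDF) solver, using the compiled right-hand side. The returned trace
#' is sampled on a uniform grid; the terminal state is attached so runs can be
#' chained. Results are deterministic given identical inputs and solver
#' settings.
#'
#' @param params A `cm_parameters` object or registry name.
#' @param protocol A `cm_protocol`; default spontaneous.
#' @param duration Simulated time (s), > 0.
#' @param init Initial 23-element state; defaults to the packaged spontaneous
#'   limit-cycle state.
#' @param dt Output sampling interval (s). Use 1e-4 (0.1 ms) for biomarker
#'   work (upstroke-velocity fidelity); coarser grids save memory in pre-runs.
#' @param rtol,atol Solver tolerances. `atol` may be a per-state vector; the
#'   default is scaled to each state's magnitude (cytosolic Ca2+ lives near
#'   1e-5 mM and needs a much tighter absolute floor than the gates).
#' @param keep_currents Record membrane currents and SR fluxes per timepoint.
#' @param hmax Maximum internal step (s). For paced runs it defaults to half
#'   the pulse width so no stimulus is stepped over; otherwise unlimited.
#' @param maxsteps Maximum internal steps per output interval.
#' @return A `cm_trace` data frame with column `t` plus state (and current)
#'   columns, and attributes `state_final`, `protocol`, `params_name`,
#'   `solver`.
#' @export
simulate_cm <- function(params = "paci2018-optimized",
                        protocol = protocol_spontaneous(),
                        duration = 10,
                        init = NULL,
                        dt = 1e-4,
                        rtol = 1e-6,
                        atol = NULL,
                        keep_currents = TRUE,
                        hmax = NULL,
                        maxsteps = 50000) {
  stopifnot(inherits(protocol, "cm_protocol"), duration > 0, dt > 0)
  params <- load_parameters(params)
  if (is.null(init)) init <- packaged_state("spontaneous")
  y0 <- as_state_vector(init)
  if (any(!is.finite(y0)))
    stop("non-finite initial state variable(s): ",
         paste(names(y0)[!is.finite(y0)], collapse = ", "))
  if (is.null(atol)) atol <- .default_atol()
  if (is.null(hmax))
    hmax <- if (identical(protocol$mode, "paced"))
      protocol$stim$duration_s / 2 else Inf
  pv <- as_parms_vector(params, stim = protocol$stim)
  times <- seq(0, duration, by = dt)
  if (length(times) < 2) times <- c(0, duration)
  nout <- if (keep_currents) length(.current_names) else 0L
  sol <- deSolve::lsoda(
    y = y0, times = times, func = "hipsccm_derivs", parms = pv,
    dllname = "hipsccm", initfunc = "hipsccm_initmod",
    nout = length(.current_names), outnames = .current_names,
    rtol = rtol, atol = atol, hmax = hmax, maxsteps = maxsteps)
  attr_sol <- attributes(sol)
  if (!is.null(attr_sol$istate) && attr_sol$istate[1] < 0) {
    last <- sol[nrow(sol), ]
    stop("solver failed (istate = ", attr_sol$istate[1],
         ") at t = ", signif(last[["time"]], 6),
         " s; last Vm = ", signif(last[["Vm"]], 6), " V")
  }
  df <- as.data.frame(sol)
  names(df)[1] <- "t"
  if (!keep_currents) df <- df[, c("t", .state_names)]
  yT <- setNames(as.numeric(df[nrow(df), .state_names]), .state_names)
  structure(df,
            state_final = yT,
            protocol = protocol,
            params_name = attr(params, "name"),
            solver = list(method = "lsoda", rtol = rtol, atol = atol,
                          dt = dt, hmax = hmax),
            class = c("cm_trace", "data.frame"))
}

#' Terminal state of a simulated trace
#' @param trace A `cm_trace`.
#' @return Named 23-element state vector.
#' @export
final_state <- function(trace) attr(trace, "state_final")

#' Packaged limit-cycle states
#'
#' States obtained by integrating the calibrated model for 800 s (spontaneous,
#' or paced at 1 Hz with the stated stimulus) so that simulations can start on
#' the limit cycle. Regenerate with [regenerate_steady_states()] after any
#' model change.
#'
#' @param name One of `"spontaneous"`, `"paced-1hz-550pA"`, `"paced-1hz-750pA"`.
#' @return Named 23-element state vector.
#' @export
packaged_state <- function(name = "spontaneous") {
  name <- match.arg(name, c("spontaneous", "paced-1hz-550pA",
                            "paced-1hz-750pA"))
  key <- paste0("state_", name)
  if (!is.null(.param_cache[[key]])) return(.param_cache[[key]])
  path <- system.file("extdata", "states", paste0(name, ".csv"),
                      package = "hipsccm", mustWork = TRUE)
  df <- read.csv(path, comment.char = "#")
  st <- setNames(df$value, df$state)
  st <- as_state_vector(st)
  .param_cache[[key]] <- st
  st
}

#' Regenerate the packaged limit-cycle states
#'
#' Maintenance command: runs the calibrated model for `duration` seconds from
#' a rough resting state (spontaneous, paced 1 Hz at 550 pA, paced 1 Hz at
#' 750 pA) and writes the terminal states as plain-text CSV.
#'
#' @param dir Output directory (defaults to the source tree's
#'   `inst/extdata/states`).
#' @param duration Pre-run length (s).
#' @param params Parameter set to pre-run.
#' @return Invisible list of the three states.
#' @export
regenerate_steady_states <- function(dir = "inst/extdata/states",
                                     duration = 800,
                                     params = "paci2018-optimized") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  runs <- list(
    "spontaneous"      = protocol_spontaneous(),
    "paced-1hz-550pA"  = protocol_paced(1, 550),
    "paced-1hz-750pA"  = protocol_paced(1, 750)
  )
  out <- list()
  for (nm in names(runs)) {
    tr <- simulate_cm(params, runs[[nm]], duration = duration,
                      init = initial_state(), dt = 0.01,
                      keep_currents = FALSE)
    st <- final_state(tr)
    df <- data.frame(state = names(st), value = unname(st))
    path <- file.path(dir, paste0(nm, ".csv"))
    con <- file(path, "w")
    writeLines(paste0("# terminal state after ", duration,
                      " s pre-run; protocol: ", nm), con)
    write.csv(df, con, row.names = FALSE, quote = FALSE)
    close(con)
    out[[nm]] <- st
  }
  invisible(out)
}

#' Paced control + block experiment
#'
#' Runs a 1 Hz paced control arm and a conductance-block arm, both from the
#' paced limit cycle, and reports biomarkers plus relative changes in percent
#' (blocked / control x 100). The drug arm is pre-run under block for
#' `drug_s` seconds before the analysis window. If any stimulus in the
#' analysis window fails to elicit an AP (peak below 0 mV within 100 ms), the
#' result carries a `capture_failure` flag rather than failing silently.
#'
#' @param params A `cm_parameters` object or registry name.
#' @param block Named remaining-fraction map (see [apply_block()]).
#' @param stim_amplitude_pA Stimulus amplitude (550 pA standard; 750 pA for
#'   strong Na+-channel block).
#' @param drug_s Pre-run length under block before the analysis window (s).
#' @param window_s Analysis window length (s).
#' @param init Paced limit-cycle initial state; defaults to the packaged one
#'   matching `stim_amplitude_pA`.
#' @param rtol Solver relative tolerance.
#' @return List with `control`, `blocked` (AP biomarker sets),
#'   `relative_pct` (named vector), `capture_failure` flags.
#' @export
run_block_experiment <- function(params = "paci2018-optimized",
                                 block = NULL,
                                 stim_amplitude_pA = 550,
                                 drug_s = 400,
                                 window_s = 20,
                                 init = NULL,
                                 rtol = 1e-6) {
  params <- load_parameters(params)
  proto <- protocol_paced(1, stim_amplitude_pA)
  if (is.null(init)) {
    init <- if (stim_amplitude_pA >= 650)
      packaged_state("paced-1hz-750pA") else packaged_state("paced-1hz-550pA")
  }
  run_arm <- function(p) {
    st <- init
    if (drug_s > 0) {
      pre <- simulate_cm(p, proto, duration = drug_s, init = st, dt = 0.01,
                         keep_currents = FALSE, rtol = rtol)
      st <- final_state(pre)
    }
    simulate_cm(p, proto, duration = window_s, init = st, dt = 1e-4,
                keep_currents = FALSE, rtol = rtol)
  }
  ctrl_tr <- run_arm(params)
  blk_tr  <- run_arm(apply_block(params, block))
  ctrl <- ap_biomarkers(ctrl_tr)
  blk  <- ap_biomarkers(blk_tr)
  rel <- 100 * blk$mean / ctrl$mean
  list(control = ctrl, blocked = blk, relative_pct = rel,
       capture_failure = c(control = check_capture_failure(ctrl_tr),
                           blocked = check_capture_failure(blk_tr)))
}

# TRUE when some stimulus in a paced trace fails to elicit an AP
check_capture_failure <- function(trace, peak_threshold_mV = 0,
                                  within_ms = 100) {
  proto <- attr(trace, "protocol")
  if (is.null(proto) || !identical(proto$mode, "paced")) return(FALSE)
  per <- proto$stim$period_s
  t0 <- proto$stim$start_s
  stim_times <- seq(t0, max(trace$t) - within_ms / 1000, by = per)
  vm_mV <- trace$Vm * 1000
  for (ts in stim_times) {
    idx <- trace$t >= ts & trace$t <= ts + within_ms / 1000
    if (!any(vm_mV[idx] > peak_threshold_mV)) return(TRUE)
  }
  FALSE
}

#' Hypercalcemia challenge for delayed afterdepolarizations
#'
#' From the spontaneous limit cycle at Ca_o = 1.8 mM, the extracellular Ca2+
#' concentration is switched instantaneously to `ca_o` (default 3.945 mM,
#' Ca2+-overload) and spontaneous (or, optionally, paced) activity is
#' simulated. DAD-like diastolic depolarizations appear in the overloaded
#' trace and are absent in a 1.8 mM control.
#'
#' @param params A `cm_parameters` object or registry name.
#' @param ca_o Post-switch extracellular Ca2+ (mM).
#' @param duration Post-switch simulated time (s).
#' @param pacing_hz Optional pacing rate (`NULL` = spontaneous).
#' @param stim_amplitude_pA Stimulus amplitude when paced.
#' @param init Initial state (defaults to the packaged spontaneous limit
#'   cycle, i.e. after an 800 s pre-run at 1.8 mM).
#' @return A `cm_trace` of the post-switch simulation.
#' @export
run_hypercalcemia_dad <- function(params = "paci2018-optimized",
                                  ca_o = 3.945,
                                  duration = 60,
                                  pacing_hz = NULL,
                                  stim_amplitude_pA = 550,
                                  init = NULL) {
  params <- load_parameters(params)
  if (is.null(init)) init <- packaged_state("spontaneous")
  p2 <- load_parameters(list(Ca_o = ca_o), base = params)
  proto <- if (is.null(pacing_hz)) protocol_spontaneous()
           else protocol_paced(pacing_hz, stim_amplitude_pA)
  simulate_cm(p2, proto, duration = duration, init = init, dt = 1e-3)
}

#' Spontaneous-rate response to environment changes
#'
#' For each override of an extracellular concentration (or an already-blocked
#' parameter set), simulates spontaneous activity from the limit cycle, lets
#' the rhythm settle, and reports the Ca2+-transient rate and its percent
#' change versus the baseline row. Rows with no detectable transient in the
#' analysis window are reported as `activity_stopped`.
#'
#' @param params Baseline parameter set.
#' @param overrides List of named lists, e.g.
#'   `list(list(K_o = 8), list(Ca_o = 0.1))`. Values must be positive
#'   concentrations (mM). An empty list entry reproduces the baseline.
#' @param settle_s Settling time before the analysis window (s).
#' @param window_s Analysis window (s).
#' @return Data frame: one baseline row plus one row per override, with
#'   columns `label`, `rate_hz`, `change_pct`, `activity_stopped`.
#' @export
run_environment_series <- function(params = "paci2018-optimized",
                                   overrides = list(),
                                   settle_s = 200,
                                   window_s = 60) {
  params <- load_parameters(params)
  measure <- function(p) {
    st <- packaged_state("spontaneous")
    if (settle_s > 0) {
      pre <- simulate_cm(p, protocol_spontaneous(), duration = settle_s,
                         init = st, dt = 0.01, keep_currents = FALSE)
      st <- final_state(pre)
    }
    tr <- simulate_cm(p, protocol_spontaneous(), duration = window_s,
                      init = st, dt = 1e-3, keep_currents = FALSE)
    cat <- try(cat_biomarkers(tr), silent = TRUE)
    if (inherits(cat, "try-error")) NA_real_ else cat$mean[["FREQ"]]
  }
  base_rate <- measure(params)
  rows <- data.frame(label = "baseline", rate_hz = base_rate,
                     change_pct = 0,
                     activity_stopped = is.na(base_rate),
                     stringsAsFactors = FALSE)
  for (ov in overrides) {
    if (length(ov) && any(unlist(ov) <= 0) &&
        any(names(ov) %in% c("Na_o", "K_o", "Ca_o")))
      stop("extracellular concentrations must be positive")
    p <- if (length(ov)) load_parameters(ov, base = params) else params
    r <- measure(p)
    lab <- if (length(ov))
      paste(names(ov), unlist(ov), sep = "=", collapse = ",") else "baseline"
    rows <- rbind(rows, data.frame(
      label = lab, rate_hz = r,
      change_pct = if (is.na(r)) NA_real_ else 100 * (r - base_rate) / base_rate,
      activity_stopped = is.na(r), stringsAsFactors = FALSE))
  }
  rows
}
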