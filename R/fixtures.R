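# Synthetic AP-like and Ca2+-transient-like waveform generator with
# analytically known biomarkers, so the extraction and cost code can be
# validated without running the ODE model.

#' Specify a synthetic waveform train
#'
#' Families: `"rectangular"` (baseline -> instant rise -> plateau -> instant
#' fall), `"triangular"` (linear rise then linear decay) and
#' `"piecewise-exponential"` (linear rise, exponential-shaped decay that
#' reaches baseline exactly at the end of the event window, keeping all
#' crossing times closed-form). `signal` selects whether the trace is written
#' as a membrane potential (`"vm"`, values in mV converted to V) or a Ca2+
#' signal (`"cai"`, arbitrary units).
#'
#' @param family Waveform family.
#' @param signal `"vm"` or `"cai"`; defaults to `"vm"` for rectangular and
#'   `"cai"` otherwise.
#' @param baseline,amplitude Baseline level and event amplitude (mV for vm).
#' @param rise_ms,plateau_ms,decay_ms Segment durations (ms); `decay_ms` is
#'   the full decay duration (for the exponential family the event window
#'   within which the decay completes; `tau_ms` sets its time constant).
#' @param tau_ms Exponential decay constant (exponential family only).
#' @param period_ms,n Event period (ms) and number of events.
#' @param noise_sd Additive white Gaussian noise SD (same units as the
#'   signal).
#' @param seed RNG seed making noisy output reproducible.
#' @return A `waveform_spec` list.
#' @export
waveform_spec <- function(family = c("rectangular", "triangular",
                                     "piecewise-exponential"),
                          signal = NULL,
                          baseline = -75, amplitude = 100,
                          rise_ms = 0, plateau_ms = 300, decay_ms = 0,
                          tau_ms = 100,
                          period_ms = 1000, n = 5,
                          noise_sd = 0, seed = 1L) {
  family <- match.arg(family)
  if (is.null(signal))
    signal <- if (family == "rectangular") "vm" else "cai"
  signal <- match.arg(signal, c("vm", "cai"))
  event_ms <- rise_ms + plateau_ms + decay_ms
  if (event_ms >= period_ms)
    stop("overlapping events: rise + plateau + decay must be < period")
  structure(list(family = family, signal = signal, baseline = baseline,
                 amplitude = amplitude, rise_ms = rise_ms,
                 plateau_ms = plateau_ms, decay_ms = decay_ms,
                 tau_ms = tau_ms, period_ms = period_ms, n = n,
                 noise_sd = noise_sd, seed = seed),
            class = "waveform_spec")
}

# waveform value at time u (ms) within one event, u in [0, period)
waveform_value <- function(spec, u) {
  b <- spec$baseline; A <- spec$amplitude
  r <- spec$rise_ms; p <- spec$plateau_ms; d <- spec$decay_ms
  v <- rep(b, length(u))
  if (r > 0) {
    i <- u >= 0 & u < r
    v[i] <- b + A * u[i] / r
  }
  i <- u >= r & u < r + p
  v[i] <- b + A
  if (d > 0) {
    i <- u >= r + p & u < r + p + d
    ud <- u[i] - (r + p)
    if (spec$family == "piecewise-exponential") {
      S <- exp(-d / spec$tau_ms)
      v[i] <- b + A * (exp(-ud / spec$tau_ms) - S) / (1 - S)
    } else {
      v[i] <- b + A * (1 - ud / d)
    }
  }
  v
}

# time (ms past peak start of decay) at which the decay crosses fraction f
decay_cross_ms <- function(spec, f) {
  d <- spec$decay_ms
  if (spec$family == "piecewise-exponential") {
    S <- exp(-d / spec$tau_ms)
    -spec$tau_ms * log(f * (1 - S) + S)
  } else {
    d * (1 - f)
  }
}

#' Generate a synthetic trace and its ground-truth biomarkers
#'
#' Samples the waveform train on a uniform grid and returns the closed-form
#' biomarkers implied by the geometry, so extracted values can be compared to
#' exact truth.
#'
#' @param spec A [waveform_spec()].
#' @param dt Sampling interval (s).
#' @return List with `trace` (a `cm_trace`-shaped data frame: `t` plus `Vm`
#'   or `Ca_i`) and `truth` (named vector; AP biomarkers for `"vm"` signals,
#'   Ca2+-transient biomarkers for `"cai"`).
#' @export
generate_waveform <- function(spec, dt = 1e-4) {
  stopifnot(inherits(spec, "waveform_spec"))
  total_s <- spec$n * spec$period_ms / 1000
  t <- seq(0, total_s, by = dt)
  u <- (t * 1000) %% spec$period_ms
  x <- waveform_value(spec, u)
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    x <- x + rnorm(length(x), sd = spec$noise_sd)
  }
  r <- spec$rise_ms; p <- spec$plateau_ms; d <- spec$decay_ms
  A <- spec$amplitude
  if (spec$signal == "vm") {
    apd <- function(f) {
      # from upstroke (start of rise; max-dV/dt instant) to f% repolarization
      if (d == 0) r + p else r + p + decay_cross_ms(spec, 1 - f / 100)
    }
    truth <- c(APA = A, MDP = spec$baseline, CL = spec$period_ms,
               APD10 = apd(10), APD30 = apd(30), APD40 = apd(40),
               APD50 = apd(50), APD70 = apd(70), APD80 = apd(80),
               APD90 = apd(90))
    truth <- c(truth, Triangulation =
                 unname((truth[["APD30"]] - truth[["APD40"]]) /
                        (truth[["APD70"]] - truth[["APD80"]])))
    df <- data.frame(t = t, Vm = x / 1000)
  } else {
    rise_cross <- function(f) r * f          # linear rise from baseline
    truth <- c(
      DURATION = (r - rise_cross(0.10)) + p + decay_cross_ms(spec, 0.10),
      TPEAK = r - rise_cross(0.10) + if (p > 0) 0 else 0,
      RT1050 = rise_cross(0.50) - rise_cross(0.10),
      RT1090 = rise_cross(0.90) - rise_cross(0.10),
      DT9010 = decay_cross_ms(spec, 0.10) - decay_cross_ms(spec, 0.90),
      FREQ = 1000 / spec$period_ms)
    df <- data.frame(t = t, Ca_i = x)
  }
  structure(list(trace = structure(df, class = c("cm_trace", "data.frame")),
                 truth = truth, spec = spec),
            class = "cm_fixture")
}

#' Inject a smooth DAD-like bump into a diastolic interval
#'
#' Adds a raised-cosine bump to the membrane potential at `time`; errors if
#' `time` falls inside an AP (membrane above the diastolic band). The
#' ground-truth event is recorded so detectors can be validated.
#'
#' @param trace A `cm_trace` with `Vm` (V).
#' @param time Bump center (s), must lie in diastole.
#' @param amplitude_mV Bump height (mV).
#' @param width_s Full bump width (s).
#' @return The modified trace with attribute `dad_truth`
#'   (`data.frame(onset_s, amplitude_mV)`).
#' @export
inject_dad <- function(trace, time, amplitude_mV = 3, width_s = 0.1) {
  vm <- trace$Vm * 1000
  i0 <- which.min(abs(trace$t - time))
  diastolic_ceiling <- min(vm) + 0.25 * (max(vm) - min(vm))
  if (vm[i0] > diastolic_ceiling)
    stop("injection time lies inside an action potential, not in diastole")
  w <- abs(trace$t - time) <= width_s / 2
  bump <- amplitude_mV * 0.5 * (1 + cos(2 * pi * (trace$t[w] - time) / width_s))
  vm[w] <- vm[w] + bump
  out <- trace
  out$Vm <- vm / 1000
  attr(out, "dad_truth") <- data.frame(onset_s = time,
                                       amplitude_mV = amplitude_mV)
  out
}
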