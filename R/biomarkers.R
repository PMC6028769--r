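# Event detection and biomarker extraction from membrane-potential and
# cytosolic-Ca2+ traces. Conventions (documented in the methods vignette):
#  - AP durations are measured from the maximum-upstroke-velocity instant,
#    repolarization fractions on the peak-to-MDP span, linear interpolation
#    at threshold crossings;
#  - cycle length is the interval between successive max-dV/dt instants;
#  - per-trace biomarkers are means over all complete events in the window.

# central-difference dV/dt in V/s for a mV trace on a uniform grid.
# Second order: well-behaved at waveform kinks, used for event timing.
central_dvdt <- function(vm_mV, dt) {
  n <- length(vm_mV)
  d <- c(vm_mV[2] - vm_mV[1],
         (vm_mV[3:n] - vm_mV[1:(n - 2)]) / 2,
         vm_mV[n] - vm_mV[n - 1]) / (dt * 1000)
  d
}

# fourth-order interior derivative, used only for the upstroke-velocity
# *value*, whose grid-refinement stability needs the higher order
dvdt4 <- function(vm_mV, dt) {
  d <- central_dvdt(vm_mV, dt)
  n <- length(vm_mV)
  if (n >= 5) {
    i <- 3:(n - 2)
    d[i] <- (-vm_mV[i + 2] + 8 * vm_mV[i + 1] -
             8 * vm_mV[i - 1] + vm_mV[i - 2]) / (12 * dt * 1000)
  }
  d
}

# locate upstrokes: crossings of `threshold` with dV/dt above `dvdt_min`
detect_upstrokes <- function(t, vm_mV, threshold_mV = -20, dvdt_min = 5,
                             refractory_s = 0.05) {
  n <- length(t)
  if (n < 3) return(numeric(0))
  dt <- t[2] - t[1]
  dvdt <- central_dvdt(vm_mV, dt)  # V/s
  cross <- which(vm_mV[-n] < threshold_mV & vm_mV[-1] >= threshold_mV)
  ups <- numeric(0)
  last <- -Inf
  for (i in cross) {
    if (t[i] - last < refractory_s) next
    # refine to the max-dV/dt instant in a window around the crossing
    lo <- max(1, i - round(0.05 / dt))
    hi <- min(n - 1, i + round(0.02 / dt))
    seg <- dvdt[lo:hi]
    if (max(seg, na.rm = TRUE) < dvdt_min) next
    # first sample within round-off of the maximum slope, so a constant-slope
    # upstroke is referenced at its start rather than at float-noise ties
    k <- lo + which(seg >= max(seg, na.rm = TRUE) * (1 - 1e-6))[1] - 1
    ups <- c(ups, t[k])
    last <- t[k]
  }
  ups
}

# maximum of a sampled curve with parabolic vertex refinement, so the
# upstroke-velocity estimate is stable under grid refinement
refine_peak <- function(y, from, to) {
  i <- from + which.max(y[from:to]) - 1
  if (i <= from || i >= to) return(y[i])
  delta <- (y[i + 1] - y[i - 1]) / 2
  gamma <- y[i + 1] - 2 * y[i] + y[i - 1]
  if (gamma >= 0) return(y[i])
  y[i] - delta^2 / (2 * gamma)
}

interp_cross <- function(t1, t2, v1, v2, level) {
  if (v2 == v1) return(t1)
  t1 + (level - v1) * (t2 - t1) / (v2 - v1)
}

# first crossing of `level` in direction ("down"/"up") after index `from`
first_crossing <- function(t, v, level, from, to = length(v),
                           direction = "down") {
  idx <- from:(to - 1)
  hit <- if (direction == "down")
    which(v[idx] >= level & v[idx + 1] < level)
  else
    which(v[idx] < level & v[idx + 1] >= level)
  if (!length(hit)) return(NA_real_)
  i <- idx[hit[1]]
  interp_cross(t[i], t[i + 1], v[i], v[i + 1], level)
}

#' Action-potential biomarkers of a trace
#'
#' Detects APs via threshold crossing refined to the maximum-upstroke-velocity
#' instant and measures, per AP and as the mean over all complete APs:
#' amplitude (APA, mV), maximum diastolic potential (MDP, mV), cycle length
#' (CL, ms), maximum upstroke velocity (Vmax, V/s), durations at 10--90%
#' repolarization (ms) and the triangulation shape factor.
#'
#' @param trace A `cm_trace` (or any data frame with `t` in s and `Vm` in V)
#'   with at least 2 complete APs on a uniform time grid.
#' @param ap_threshold_mV Detection threshold for the upstroke.
#' @param dvdt_min Minimum upstroke velocity (V/s) for an AP.
#' @return List with `per_ap` (data frame, one row per complete AP), `mean`
#'   (named vector incl. `Triangulation`), `n_ap`, and `flags` (per-AP
#'   non-repolarizing markers).
#' @export
ap_biomarkers <- function(trace, ap_threshold_mV = -20, dvdt_min = 5) {
  t <- trace$t
  vm <- trace$Vm * 1000  # mV
  ups <- detect_upstrokes(t, vm, ap_threshold_mV, dvdt_min)
  if (length(ups) < 2)
    stop("insufficient data: need at least 2 complete action potentials, found ",
         length(ups))
  dt <- t[2] - t[1]
  dvdt <- central_dvdt(vm, dt)
  dvdt_hi <- dvdt4(vm, dt)
  fracs <- c(10, 30, 40, 50, 70, 80, 90)
  rows <- list()
  flags <- logical(0)
  for (k in seq_len(length(ups) - 1)) {
    u <- ups[k]; u_next <- ups[k + 1]
    sel <- which(t >= u & t < u_next)
    if (length(sel) < 10) next
    pk_i <- sel[which.max(vm[sel])]
    peak <- vm[pk_i]
    mdp_i <- sel[which.min(vm[sel[sel >= pk_i]])]
    mdp_sel <- sel[sel >= pk_i]
    mdp_i <- mdp_sel[which.min(vm[mdp_sel])]
    mdp <- vm[mdp_i]
    apa <- peak - mdp
    vmax <- refine_peak(dvdt_hi, sel[1], pk_i)
    apd <- setNames(rep(NA_real_, length(fracs)), paste0("APD", fracs))
    nonrepol <- FALSE
    for (f in fracs) {
      level <- peak - f / 100 * apa
      tc <- first_crossing(t, vm, level, from = pk_i, to = mdp_i)
      if (is.na(tc)) nonrepol <- TRUE
      apd[[paste0("APD", f)]] <- (tc - u) * 1000
    }
    rows[[length(rows) + 1]] <- data.frame(
      t_up = u, APA = apa, MDP = mdp, CL = (u_next - u) * 1000,
      Vmax = vmax, t(apd))
    flags <- c(flags, nonrepol)
  }
  if (!length(rows))
    stop("insufficient data: no complete action potential could be measured")
  per <- do.call(rbind, rows)
  mean_v <- colMeans(per[, -1, drop = FALSE], na.rm = TRUE)
  tri <- triangulation(mean_v[["APD30"]], mean_v[["APD40"]],
                       mean_v[["APD70"]], mean_v[["APD80"]])
  mean_v <- c(mean_v, Triangulation = unname(tri$value))
  list(per_ap = per, mean = mean_v, n_ap = nrow(per), flags = flags)
}

#' AP shape factor (triangulation)
#'
#' `(APD30 - APD40) / (APD70 - APD80)`; values above 1.5 classify an AP as
#' ventricular-like, below 1.5 as atrial-like. A perfectly linear
#' repolarization gives 1 (uniform APD spacing); a square AP gives 0 and is
#' flagged degenerate.
#'
#' @param apd30,apd40,apd70,apd80 AP durations (ms).
#' @param tol Numeric tolerance on the denominator.
#' @return List with `value`, `classification`
#'   (`"ventricular-like"`/`"atrial-like"`), `degenerate` flag.
#' @export
triangulation <- function(apd30, apd40, apd70, apd80, tol = 1e-9) {
  den <- apd70 - apd80
  if (!is.finite(den) || abs(den) <= tol)
    stop("undefined triangulation: APD70 and APD80 coincide within tolerance")
  val <- (apd30 - apd40) / den
  list(value = val,
       classification = if (val > 1.5) "ventricular-like" else "atrial-like",
       degenerate = abs(apd30 - apd40) <= tol)
}

# peak/trough segmentation of an oscillating signal
detect_transients <- function(t, x, min_prominence_frac = 0.25) {
  n <- length(x)
  rng <- max(x) - min(x)
  if (rng <= 0) return(NULL)
  d <- diff(x)
  s <- sign(d)
  s[s == 0] <- 1
  pk <- which(diff(s) < 0) + 1   # local maxima
  tr <- which(diff(s) > 0) + 1   # local minima
  # keep only prominent peaks
  keep <- logical(length(pk))
  for (i in seq_along(pk)) {
    left <- tr[tr < pk[i]]
    right <- tr[tr > pk[i]]
    base <- max(
      if (length(left)) x[max(left)] else min(x),
      if (length(right)) x[min(right)] else min(x))
    keep[i] <- (x[pk[i]] - base) >= min_prominence_frac * rng
  }
  pk <- pk[keep]
  if (length(pk) < 2) return(NULL)
  list(peaks = pk, troughs = tr)
}

#' Ca2+-transient biomarkers of a trace
#'
#' Per transient: amplitude from the preceding diastolic minimum to the peak;
#' rise times between amplitude fractions on the rising limb (RT1050,
#' RT1090, ms); decay time from 90 to 10% on the falling limb (DT9010, ms);
#' DURATION between the 10%-amplitude up- and down-crossings; TPEAK from the
#' 10%-amplitude up-crossing to the peak; FREQ as the reciprocal mean
#' inter-peak interval (Hz). Crossings are linearly interpolated.
#' Amplitude-relative definitions make all six biomarkers well-defined on
#' un-calibrated (fluorescence) signals.
#'
#' @param trace A `cm_trace` (or data frame with `t` and `Ca_i`; any `value`
#'   column is accepted as the signal when `Ca_i` is absent).
#' @return List with `per_transient`, `mean` (named vector), `n_transients`.
#' @export
cat_biomarkers <- function(trace) {
  t <- trace$t
  x <- if (!is.null(trace$Ca_i)) trace$Ca_i else trace$value
  if (is.null(x)) stop("trace must contain a Ca_i (or value) column")
  seg <- detect_transients(t, x)
  if (is.null(seg) || length(seg$peaks) < 2)
    stop("insufficient data: need at least 2 Ca2+ transients (signal may be monotone)")
  pk <- seg$peaks; tr <- seg$troughs
  rows <- list()
  for (i in seq_along(pk)) {
    p <- pk[i]
    left_tr <- tr[tr < p]
    right_tr <- tr[tr > p]
    if (!length(left_tr) || !length(right_tr)) next   # incomplete edge event
    lo <- max(left_tr)
    hi <- min(right_tr)
    base <- x[lo]
    amp <- x[p] - base
    if (amp <= 0) next
    lev <- function(f) base + f * amp
    t10u <- first_crossing(t, x, lev(0.10), from = lo, to = p, "up")
    t50u <- first_crossing(t, x, lev(0.50), from = lo, to = p, "up")
    t90u <- first_crossing(t, x, lev(0.90), from = lo, to = p, "up")
    t90d <- first_crossing(t, x, lev(0.90), from = p, to = hi, "down")
    t10d <- first_crossing(t, x, lev(0.10), from = p, to = hi, "down")
    rows[[length(rows) + 1]] <- data.frame(
      t_peak = t[p],
      DURATION = (t10d - t10u) * 1000,
      TPEAK = (t[p] - t10u) * 1000,
      RT1050 = (t50u - t10u) * 1000,
      RT1090 = (t90u - t10u) * 1000,
      DT9010 = (t10d - t90d) * 1000)
  }
  if (length(rows) < 2)
    stop("insufficient data: fewer than 2 complete Ca2+ transients")
  per <- do.call(rbind, rows)
  freq <- 1 / mean(diff(per$t_peak))
  mean_v <- c(colMeans(per[, -1, drop = FALSE], na.rm = TRUE), FREQ = freq)
  list(per_transient = per, mean = mean_v, n_transients = nrow(per))
}

#' The full 14-biomarker set of a spontaneous trace
#'
#' Combines [ap_biomarkers()] and [cat_biomarkers()] into the named vector
#' used by the cost function: APA, MDP, CL, Vmax, APD10, APD30, APD90,
#' Triangulation, DURATION, TPEAK, RT1050, RT1090, DT9010, FREQ.
#'
#' @param trace A `cm_trace` containing `Vm` and `Ca_i`.
#' @return Named numeric vector of length 14 (NA entries if a family of
#'   events could not be measured).
#' @export
biomarker_set <- function(trace) {
  out <- setNames(rep(NA_real_, 14),
                  c("APA", "MDP", "CL", "Vmax", "APD10", "APD30", "APD90",
                    "Triangulation", "DURATION", "TPEAK", "RT1050", "RT1090",
                    "DT9010", "FREQ"))
  ap <- try(ap_biomarkers(trace), silent = TRUE)
  if (!inherits(ap, "try-error")) {
    m <- ap$mean
    out[c("APA", "MDP", "CL", "Vmax", "APD10", "APD30", "APD90",
          "Triangulation")] <-
      m[c("APA", "MDP", "CL", "Vmax", "APD10", "APD30", "APD90",
          "Triangulation")]
  }
  cat <- try(cat_biomarkers(trace), silent = TRUE)
  if (!inherits(cat, "try-error")) {
    m <- cat$mean
    out[c("DURATION", "TPEAK", "RT1050", "RT1090", "DT9010", "FREQ")] <-
      m[c("DURATION", "TPEAK", "RT1050", "RT1090", "DT9010", "FREQ")]
  }
  out
}

#' Detect premature diastolic Ca2+ release events
#'
#' Scans the diastolic interval of each cycle (between the end of the Ca2+
#' transient decay and the next AP upstroke) for secondary local maxima of
#' cytosolic Ca2+ — the signature of spontaneous SR release through a leaky
#' or immature RyR. Useful together with [detect_dads()]: a diastolic Ca2+
#' release only becomes a membrane DAD when the Na+/Ca2+ exchanger
#' transduces it into inward current.
#'
#' @param trace A `cm_trace` with `t`, `Vm`, `Ca_i`.
#' @param margin_s Time after the upstroke excluded from the scan (covers
#'   the primary transient).
#' @param min_amplitude_uM Minimum bump height above the local diastolic
#'   minimum (uM).
#' @return Data frame with `onset_s`, `amplitude_uM`.
#' @export
detect_ca_releases <- function(trace, margin_s = 0.45,
                               min_amplitude_uM = 0.002) {
  t <- trace$t
  vm <- trace$Vm * 1000
  ca <- trace$Ca_i * 1000  # uM
  ups <- detect_upstrokes(t, vm)
  out <- data.frame(onset_s = numeric(0), amplitude_uM = numeric(0))
  if (length(ups) < 2) return(out)
  for (k in seq_len(length(ups) - 1)) {
    sel <- which(t > ups[k] + margin_s & t < ups[k + 1] - 0.02)
    if (length(sel) < 10) next
    x <- ca[sel]
    d <- diff(x)
    s <- sign(d); s[s == 0] <- 1
    pk <- which(diff(s) < 0) + 1
    for (p in pk) {
      amp <- x[p] - min(x)
      if (amp >= min_amplitude_uM)
        out <- rbind(out, data.frame(onset_s = t[sel[p]],
                                     amplitude_uM = amp))
    }
  }
  out
}

#' Detect delayed afterdepolarizations
#'
#' A DAD is a local membrane-potential elevation during diastole (between the
#' end of repolarization and the next upstroke) whose height above the
#' resumed diastolic course exceeds `amp_threshold_mV` without reaching the
#' AP detection threshold. Diastolic bumps that do reach the AP threshold but
#' lack a fast upstroke, and full APs that arrive prematurely (cycle length
#' below `premature_frac` of the trace median), are classified as triggered
#' events.
#'
#' @param trace A `cm_trace` (needs `t`, `Vm`).
#' @param amp_threshold_mV Minimum bump height (mV).
#' @param ap_threshold_mV AP detection threshold (mV).
#' @param dvdt_min Minimum AP upstroke velocity (V/s).
#' @param premature_frac An AP with CL below this fraction of the median CL
#'   is classified as a triggered (anticipated) beat.
#' @return Data frame with `onset_s`, `amplitude_mV`, `classification`
#'   (`"subthreshold_dad"` or `"triggered_ap"`); zero rows when diastole is
#'   clean.
#' @export
detect_dads <- function(trace, amp_threshold_mV = 1, ap_threshold_mV = -20,
                        dvdt_min = 5, premature_frac = 0.75) {
  t <- trace$t
  vm <- trace$Vm * 1000
  empty <- data.frame(onset_s = numeric(0), amplitude_mV = numeric(0),
                      classification = character(0),
                      stringsAsFactors = FALSE)
  ups <- detect_upstrokes(t, vm, ap_threshold_mV, dvdt_min)
  events <- empty
  # diastolic intervals: from 90% repolarization of one AP to the next upstroke
  intervals <- list()
  if (length(ups) >= 2) {
    for (k in seq_len(length(ups) - 1)) {
      sel <- which(t >= ups[k] & t < ups[k + 1])
      if (length(sel) < 10) next
      pk_i <- sel[which.max(vm[sel])]
      mdp_sel <- sel[sel >= pk_i]
      mdp_i <- mdp_sel[which.min(vm[mdp_sel])]
      level <- vm[pk_i] - 0.9 * (vm[pk_i] - vm[mdp_i])
      t90 <- first_crossing(t, vm, level, from = pk_i, to = mdp_i)
      if (is.na(t90)) next
      intervals[[length(intervals) + 1]] <-
        c(t90 + 0.02, ups[k + 1] - 0.01)
    }
  } else {
    intervals[[1]] <- c(min(t), max(t))  # quiescent trace: all diastole
  }
  for (iv in intervals) {
    sel <- which(t >= iv[1] & t <= iv[2])
    if (length(sel) < 5) next
    xs <- vm[sel]
    d <- diff(xs)
    s <- sign(d); s[s == 0] <- 1
    pk <- which(diff(s) < 0) + 1
    for (p in pk) {
      after <- xs[p:length(xs)]
      nextmin <- min(after)
      amp <- xs[p] - nextmin
      if (amp < amp_threshold_mV) next
      cls <- if (xs[p] >= ap_threshold_mV) "triggered_ap" else "subthreshold_dad"
      events <- rbind(events, data.frame(
        onset_s = t[sel[p]], amplitude_mV = amp, classification = cls,
        stringsAsFactors = FALSE))
    }
  }
  # premature full beats
  if (length(ups) >= 3) {
    cls <- diff(ups)
    med <- median(cls)
    prem <- which(cls < premature_frac * med)
    for (i in prem) {
      events <- rbind(events, data.frame(
        onset_s = ups[i + 1], amplitude_mV = NA_real_,
        classification = "triggered_ap", stringsAsFactors = FALSE))
    }
  }
  if (nrow(events)) events <- events[order(events$onset_s), , drop = FALSE]
  rownames(events) <- NULL
  events
}
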