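#' @useDynLib hipsccm
#' @importFrom stats approx optim median sd setNames rnorm
#' @importFrom utils modifyList read.csv write.csv
NULL

# order of the numeric parameter slots expected by the compiled model code
.param_fields <- c(
  "Cm", "Vc", "V_SR", "Na_o", "K_o", "Ca_o", "K_i",
  "G_Na", "G_CaL", "G_Kr", "G_Ks", "G_K1", "G_f", "G_to",
  "G_bNa", "G_bCa", "G_pCa", "K_pCa",
  "I_NaK_max", "Km_K", "Km_Na",
  "I_NaCa_max", "Km_Ca", "Km_Nai", "K_sat", "gamma", "alpha",
  "G_NaL", "Vh_hL", "tau_hL",
  "V_max_up", "K_up", "I_leak_max", "I_rel_max",
  "RyR_a1", "RyR_a2", "RyR_a_half", "RyR_o_half", "RyR_c_half",
  "RyR_a_k", "RyR_o_k", "RyR_c_k",
  "tau_RyR_a", "tau_RyR_o", "tau_RyR_c",
  "E_f", "P_kNa"
)

.state_names <- c(
  "Vm", "Ca_SR", "Ca_i", "g_legacy", "d", "f1", "f2", "fCa",
  "Xr1", "Xr2", "Xs", "h", "j", "m", "Xf", "q", "r",
  "Na_i", "mL", "hL", "RyR_a", "RyR_o", "RyR_c"
)

.current_names <- c(
  "I_Na", "I_NaL", "I_CaL", "I_f", "I_to", "I_Kr", "I_Ks", "I_K1",
  "I_NaK", "I_NaCa", "I_pCa", "I_bNa", "I_bCa",
  "I_rel", "I_up", "I_leak", "I_stim", "I_fNa"
)

.param_cache <- new.env(parent = emptyenv())

#' Names of the scalable maxima (the conductance registry)
#'
#' These names are the stable public interface for conductance blocks and for
#' parameter optimization: each is a maximal conductance, pump/exchanger
#' maximum, or SR flux maximum of the model.
#'
#' @return Character vector of registry names.
#' @export
conductance_registry <- function() {
  c("G_Na", "G_NaL", "G_CaL", "G_f", "G_to", "G_Kr", "G_Ks", "G_K1",
    "I_NaCa_max", "I_NaK_max", "V_max_up", "I_rel_max", "I_leak_max",
    "G_bNa", "G_bCa", "G_pCa")
}

#' Names of the packaged parameter sets
#' @return Character vector of registry names usable with [load_parameters()].
#' @export
parameter_sets <- function() c("paci2018-optimized", "paci2013-baseline")

new_cm_parameters <- function(values, name = "custom") {
  missing <- setdiff(.param_fields, names(values))
  if (length(missing))
    stop("parameter set is missing required fields: ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(values), .param_fields)
  if (length(extra))
    stop("unknown parameter fields: ", paste(extra, collapse = ", "))
  values <- lapply(values[.param_fields], as.numeric)
  bad <- names(values)[!vapply(values, function(x)
    length(x) == 1L && is.finite(x), logical(1))]
  if (length(bad))
    stop("non-finite or non-scalar parameter values: ",
         paste(bad, collapse = ", "))
  structure(values, name = name, class = "cm_parameters")
}

#' Load a model parameter set
#'
#' Reads a packaged parameter set by registry name, or a YAML file. A partial
#' file (or list) is overlaid on a named baseline, so a config only needs to
#' state the values it changes.
#'
#' RyR half-activations, adaptation constants and sigmoid slopes are stored in
#' the units in which they are conventionally printed (micromolar); the model
#' right-hand side compares them against `1000 * Ca_i` so that the cytosolic
#' Ca2+ state stays in mM like every other concentration.
#'
#' @param source Registry name (see [parameter_sets()]), path to a YAML file,
#'   or a named list/vector of parameter values.
#' @param base Baseline set (registry name or `cm_parameters`) that `source`
#'   overlays. Defaults to `"paci2018-optimized"` when `source` is partial.
#' @return A `cm_parameters` object.
#' @export
load_parameters <- function(source = "paci2018-optimized", base = NULL) {
  if (inherits(source, "cm_parameters")) return(source)
  name <- "custom"
  if (is.character(source) && length(source) == 1L) {
    if (source %in% parameter_sets()) {
      key <- source
      if (!is.null(.param_cache[[key]])) return(.param_cache[[key]])
      path <- system.file("extdata", "params", paste0(key, ".yaml"),
                          package = "hipsccm", mustWork = TRUE)
      cfg <- yaml::read_yaml(path)
      out <- new_cm_parameters(cfg$parameters, name = key)
      .param_cache[[key]] <- out
      return(out)
    }
    if (!file.exists(source))
      stop("'", source, "' is neither a registered parameter set (",
           paste(parameter_sets(), collapse = ", "), ") nor an existing file")
    cfg <- yaml::read_yaml(source)
    vals <- if (!is.null(cfg$parameters)) cfg$parameters else cfg
    name <- if (!is.null(cfg$name)) cfg$name else basename(source)
  } else if (is.list(source) || is.numeric(source)) {
    vals <- as.list(source)
  } else {
    stop("unsupported parameter source of class ", class(source)[1])
  }
  if (length(setdiff(.param_fields, names(vals)))) {
    base <- if (is.null(base)) "paci2018-optimized" else base
    base <- load_parameters(base)
    full <- modifyList(unclass(base), vals)
    return(new_cm_parameters(full, name = name))
  }
  new_cm_parameters(vals, name = name)
}

#' Write a parameter set to a YAML config
#'
#' The serialization is value-preserving: reading the file back yields a
#' parameter set identical to `params`.
#'
#' @param params A `cm_parameters` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  params <- load_parameters(params)
  yaml::write_yaml(
    list(name = attr(params, "name"),
         parameters = unclass(params)),
    path, precision = 17)
  invisible(path)
}

#' Scale maximal conductances by remaining fractions
#'
#' Simulates a channel/transporter block by multiplying registry maxima by the
#' *remaining* fraction, following the convention "18% G_Na" = 18 percent of
#' the conductance left.
#'
#' @param params A `cm_parameters` object (or registry name).
#' @param block Named numeric vector/list: registry name -> remaining fraction
#'   in \[0, 1\]. An empty block returns `params` unchanged.
#' @return A new `cm_parameters` object.
#' @export
#' @examples
#' p <- load_parameters("paci2018-optimized")
#' ttx <- apply_block(p, c(G_Na = 0.18))
apply_block <- function(params, block = NULL) {
  params <- load_parameters(params)
  if (is.null(block) || length(block) == 0L) return(params)
  block <- unlist(block)
  unknown <- setdiff(names(block), conductance_registry())
  if (length(unknown))
    stop("unknown conductance name(s): ", paste(unknown, collapse = ", "),
         "; valid names: ", paste(conductance_registry(), collapse = ", "))
  if (any(!is.finite(block)) || any(block < 0) || any(block > 1))
    stop("block fractions must be remaining fractions in [0, 1]")
  vals <- unclass(params)
  for (nm in names(block)) vals[[nm]] <- vals[[nm]] * block[[nm]]
  new_cm_parameters(vals, name = paste0(attr(params, "name"), "+block"))
}

#' Immature ryanodine-receptor variant
#'
#' Returns a parameter set describing a less mature RyR release machinery:
#' the open-gate half-activation is shifted down by 0.002, the closed-gate
#' half-activation up by 0.002 (in the micromolar units of the stored
#' half-activations), the open-gate time constant is doubled and the
#' closed-gate time constant halved. At normal extracellular Ca2+ this variant
#' produces premature diastolic Ca2+ releases.
#'
#' @param params A `cm_parameters` object (or registry name).
#' @return A new `cm_parameters` object.
#' @export
make_immature_ryr <- function(params = "paci2018-optimized") {
  params <- load_parameters(params)
  vals <- unclass(params)
  vals$RyR_o_half <- vals$RyR_o_half - 0.002
  vals$RyR_c_half <- vals$RyR_c_half + 0.002
  vals$tau_RyR_o  <- vals$tau_RyR_o * 2
  vals$tau_RyR_c  <- vals$tau_RyR_c * 0.5
  new_cm_parameters(vals, name = paste0(attr(params, "name"), "+immature-ryr"))
}

# numeric vector in compiled-code order, with stimulus slots appended
as_parms_vector <- function(params, stim = NULL) {
  params <- load_parameters(params)
  v <- unlist(unclass(params)[.param_fields], use.names = FALSE)
  if (is.null(stim)) {
    stim_v <- c(0, 0, 1, 0.005, 0)
  } else {
    stim_v <- c(1, stim$amplitude_A, stim$period_s, stim$duration_s,
                stim$start_s)
  }
  c(v, stim_v)
}

#' @export
print.cm_parameters <- function(x, ...) {
  cat("<cm_parameters> set:", attr(x, "name"), "\n")
  v <- unlist(unclass(x))
  print(v)
  invisible(x)
}
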