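# Trace readers/writers: CSV with a one-line `# units:` comment header and an
# optional JSON metadata sidecar capturing protocol, parameter set and solver
# settings, so any run can be re-executed.

.trace_units <- function(cols) {
  u <- rep("dimensionless", length(cols))
  names(u) <- cols
  u[cols == "t"] <- "s"
  u[cols == "Vm"] <- "V"
  u[cols %in% c("Ca_i", "Ca_SR", "Na_i")] <- "mM"
  u[grepl("^I_", cols)] <- "A/F"
  u[cols %in% c("I_rel", "I_up", "I_leak")] <- "mM/s"
  u
}

#' Write a trace to CSV (with units header and metadata sidecar)
#'
#' @param trace A `cm_trace`.
#' @param path Output CSV path; a sidecar `<path>.meta.json` is written
#'   unless `sidecar = FALSE`.
#' @param sidecar Write the JSON metadata sidecar.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, sidecar = TRUE) {
  cols <- names(trace)
  con <- file(path, "w")
  writeLines(paste0("# units: ",
                    paste(cols, .trace_units(cols), sep = "=",
                          collapse = " ")), con)
  write.csv(as.data.frame(trace), con, row.names = FALSE, quote = FALSE)
  close(con)
  if (sidecar) {
    proto <- attr(trace, "protocol")
    meta <- list(
      package = as.character(utils::packageVersion("hipsccm")),
      params_name = attr(trace, "params_name"),
      protocol = if (!is.null(proto)) unclass(proto) else NULL,
      solver = attr(trace, "solver"),
      state_final = as.list(attr(trace, "state_final")))
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read a trace written by [write_trace()] (or any time/value table)
#'
#' Columns are keyed by name, so column order does not matter; a `t` column
#' is required. The metadata sidecar is re-attached when present.
#'
#' @param path CSV path.
#' @return A `cm_trace` data frame.
#' @export
read_trace <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#") && !grepl(",", first, fixed = TRUE))
    stop("malformed trace header at line 1: expected '# units:' comment or ",
         "a comma-separated column header")
  df <- read.csv(path, comment.char = "#")
  if (!"t" %in% names(df))
    stop("trace file is missing the required time column 't'")
  lead <- intersect(c("t", .state_names, .current_names), names(df))
  df <- df[, c(lead, setdiff(names(df), lead)), drop = FALSE]
  meta_path <- paste0(path, ".meta.json")
  tr <- structure(df, class = c("cm_trace", "data.frame"))
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    attr(tr, "params_name") <- meta$params_name
    attr(tr, "solver") <- meta$solver
    if (!is.null(meta$state_final))
      attr(tr, "state_final") <- as_state_vector(unlist(meta$state_final))
  }
  tr
}
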