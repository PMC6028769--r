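# Shared memoized simulations so heavy runs are computed once per session.
.cm_test_cache <- new.env(parent = emptyenv())

cm_cached <- function(key, expr) {
  if (is.null(.cm_test_cache[[key]]))
    assign(key, force(expr), envir = .cm_test_cache)
  .cm_test_cache[[key]]
}

# 20 s dense spontaneous window on the calibrated limit cycle
spontaneous_window <- function(dt = 1e-4, rtol = 1e-6) {
  cm_cached(sprintf("spont_%g_%g", dt, rtol),
            simulate_cm("paci2018-optimized", protocol_spontaneous(),
                        duration = 20, init = packaged_state("spontaneous"),
                        dt = dt, rtol = rtol, keep_currents = FALSE))
}

# named list -> full parameter set on the calibrated baseline
pars_with <- function(...) load_parameters(list(...))
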