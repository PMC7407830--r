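# Shared fixtures and independent oracles for the test suite.

# Tiny well-formed long table: one IL-6 stimulated control, one inactivated
# control, one treated well.
minimal_long_df <- function() {
  data.frame(
    endpoint = "IL6", compartment = "macrophage_basolateral",
    treatment = c("control", "control", "myrrh"),
    control_class = c("s", "ua", "treated"),
    concentration_ug_ml = c(0, 0, 10),
    time_h = 48, replicate = 1L,
    value = c(850, 100, 400),
    value_before = NA_real_, value_after = NA_real_,
    stringsAsFactors = FALSE
  )
}

# Independent brute-force combination index: straight transcription of the
# defining equation, kept free of the package's own code path.
oracle_ci <- function(ic50s, comb_total) {
  ic50_comb <- comb_total / 3
  sum(ic50_comb / ic50s[!is.na(ic50s)])
}

# Hand-built concentration-response series, bypassing extract_series.
make_series <- function(conc, resp, endpoint = "IL6",
                        scale = "percent_of_stimulated",
                        direction = NULL) {
  info <- ternci::endpoint_registry()
  i <- match(endpoint, info$endpoint)
  structure(list(
    endpoint = endpoint, label = info$label[i],
    direction = if (is.null(direction)) info$direction[i] else direction,
    treatment_label = "test", time_h = 48,
    concentration = conc, response = resp,
    s_mean = 100, ref_mean = 10, ref_class = info$reference[i],
    scale = scale
  ), class = "cr_series")
}

noise_free_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- ternci::generate_assay(
        ternci::generator_config(noise_cv = 0, seed = 1))
    }
    cache
  }
})
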