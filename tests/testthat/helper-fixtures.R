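# Shared fixture: one default-parameter synthetic cohort with a fitted
# two-subtype model, computed once per test run.
.fixture_env <- new.env(parent = emptyenv())

default_fit_fixture <- function() {
  if (is.null(.fixture_env$fit)) {
    spec <- default_cohort_spec()
    cohort <- generate_baseline(spec, seed = 11)
    fit <- suppressWarnings(
      pd_subtype(cohort$data, schema = spec$schema, k = 2,
                 n_restarts = 25, seed = 11))
    longitudinal <- generate_longitudinal(cohort$labels, spec, seed = 12)
    .fixture_env$spec <- spec
    .fixture_env$cohort <- cohort
    .fixture_env$fit <- fit
    .fixture_env$longitudinal <- longitudinal
  }
  as.list(.fixture_env)
}
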