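# The paired crowded/uncrowded ensemble used by the acceptance comparisons
# is expensive (~5 min); compute it once per test run and share it.
.study_cache <- new.env(parent = emptyenv())

acceptance_study <- function() {
  if (is.null(.study_cache$study)) {
    .study_cache$study <- run_crowding_study(n_pairs = 13, seed = 20260101)
    .study_cache$tests <- crowding_tests(.study_cache$study)
  }
  .study_cache
}
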