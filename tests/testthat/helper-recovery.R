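# The simulate-and-refit study (20 noise seeds per formulation fixture) is
# used by several test files; compute it once per test session.

.recovery_cache <- new.env(parent = emptyenv())

recovery_results <- function(fixture) {
  if (is.null(.recovery_cache[[fixture]]))
    .recovery_cache[[fixture]] <- suppressWarnings(suppressMessages(
      run_recover(fixture, n_seeds = 20)))
  .recovery_cache[[fixture]]
}

recovery_summary <- function(fixture) attr(recovery_results(fixture), "summary")
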