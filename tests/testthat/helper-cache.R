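# memoised heavyweight objects shared across test files (built once per run)
.test_cache <- new.env()

default_landscape <- function() {
  if (is.null(.test_cache$L)) {
    .test_cache$L <- generate_landscape(generator_config(seed = 1))
  }
  .test_cache$L
}

# the 100-replicate constrained random-order scenario in truncate mode used
# by the cap-compliance checks
reference_runs <- function() {
  if (is.null(.test_cache$runs)) {
    .test_cache$runs <- run_scenario(
      default_landscape(),
      cap_policy(overshoot_mode = "truncate"),
      scenario_spec("random", constrained = TRUE, n_runs = 100, seed = 1)
    )
  }
  .test_cache$runs
}

small_landscape <- function() {
  if (is.null(.test_cache$small)) {
    .test_cache$small <- generate_landscape(small_config(seed = 7))
  }
  .test_cache$small
}
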