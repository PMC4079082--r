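# Memoized full-scale condition runs shared across test files, so each
# 50-replication simulation happens at most once per test run.

.cond_cache <- new.env(parent = emptyenv())

cached_condition <- function(key, spec) {
  if (is.null(.cond_cache[[key]]))
    assign(key, run_condition(spec), envir = .cond_cache)
  get(key, envir = .cond_cache)
}

# The study conditions: 80-trial blocks, 50 replications.
study_conditions <- list(
  delay500 = condition_spec(delay_ms = 500, n_blocks = 5, seed = 101L),
  delay0 = condition_spec(delay_ms = 0, n_blocks = 5, seed = 102L),
  delay1000 = condition_spec(delay_ms = 1000, n_blocks = 5, seed = 103L),
  delay2500 = condition_spec(delay_ms = 2500, n_blocks = 5, seed = 104L),
  masked500 = condition_spec(delay_ms = 500, n_blocks = 4,
                             sigma_C = striat_constants()$network$sigma_C_mask,
                             seed = 105L),
  # The delay-variance effect is small, so the two variance conditions are
  # compared with common random numbers (same seed): a paired design that
  # removes shared replication-level noise from the contrast.
  var75 = condition_spec(delay_mean_ms = 500, delay_sd_ms = 75,
                         n_blocks = 5, seed = 106L),
  var150 = condition_spec(delay_mean_ms = 500, delay_sd_ms = 150,
                          n_blocks = 5, seed = 106L)
)

study_curve <- function(name)
  cached_condition(name, study_conditions[[name]])

final_block_accuracy <- function(lc)
  lc$curve$mean_accuracy[nrow(lc$curve)]
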