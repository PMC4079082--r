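# Trial pipeline, condition orchestration, and the mixture model.

test_that("run_trial returns a complete record and updates state", {
  set.seed(30)
  st <- model_state()
  stim <- sample_sequence(st$structure, 1)
  out <- run_trial(st, stim, delay_ms = 500)
  r <- out$record
  expect_true(all(c("response", "correct", "RPE", "S_JD_A", "S_JD_B",
                    "response_time", "D") %in% names(r)))
  expect_true(r$response %in% c("A", "B"))
  expect_equal(r$correct, r$response == stim$label)
  expect_equal(out$state$trial_index, 1L)
  expect_equal(r$RPE, as.numeric(r$correct) - 0.5)
})

test_that("a 10 s feedback delay carries no plasticity signal", {
  # same seed: the network trial (and hence the response) is identical,
  # only the dopamine burst placement differs
  st0 <- model_state()
  stim <- {
    set.seed(31)
    sample_sequence(st0$structure, 1)
  }
  set.seed(32); near <- run_trial(st0, stim, delay_ms = 500)
  set.seed(32); far <- run_trial(st0, stim, delay_ms = 10000)
  expect_identical(near$record$response, far$record$response)
  # at 10 s the burst misses the glutamate trace: the overlap stays in the
  # tonic band around the dopamine baseline instead of signaling feedback
  expect_lt(abs(far$record$S_JD_A - 0.2), 0.25)
  # and synapses change far less than with well-timed feedback
  expect_lt(far$record$mean_abs_dw, 0.3 * near$record$mean_abs_dw)
})

test_that("the full pipeline is reproducible under a fixed seed", {
  spec <- condition_spec(n_blocks = 1, trials_per_block = 30,
                         n_replications = 2, seed = 77L)
  a <- run_condition(spec, keep_trials = TRUE)
  b <- run_condition(spec, keep_trials = TRUE)
  expect_identical(a$block_accuracy, b$block_accuracy)
  expect_identical(a$trials, b$trials)
})

test_that("condition specs validate their fields", {
  expect_error(condition_spec(delay_ms = -5))
  expect_error(condition_spec(n_blocks = 0))
  expect_error(condition_spec(task = "XX"))
  s <- condition_spec(delay_mean_ms = 500, delay_sd_ms = 75)
  expect_equal(s$delay_sd_ms, 75)
})

test_that("learning-curve bookkeeping has the right shape", {
  spec <- condition_spec(n_blocks = 2, trials_per_block = 10,
                         n_replications = 3, seed = 5L)
  lc <- run_condition(spec)
  expect_s3_class(lc, "learning_curve")
  expect_equal(dim(lc$block_accuracy), c(3, 2))
  expect_equal(nrow(lc$curve), 2)
  expect_true(all(lc$curve$mean_accuracy >= 0 & lc$curve$mean_accuracy <= 1))
})

test_that("raising premotor noise degrades early learning", {
  # two short paired runs: heavy premotor noise should keep accuracy near
  # chance while baseline noise allows learning to take hold
  spec_lo <- condition_spec(delay_ms = 500, n_blocks = 2,
                            n_replications = 12, seed = 61L)
  spec_hi <- condition_spec(delay_ms = 500, n_blocks = 2, sigma_C = 400,
                            n_replications = 12, seed = 61L)
  acc_lo <- run_condition(spec_lo)$curve$mean_accuracy[2]
  acc_hi <- run_condition(spec_hi)$curve$mean_accuracy[2]
  expect_gt(acc_lo, acc_hi)
  expect_lt(abs(acc_hi - 0.5), 0.08)
})

test_that("mixture accuracy reproduces the documented worked example", {
  # 15 procedural, 4 rule users, 1 guesser:
  # 0.75 * 0.8 + 0.20 * 0.7 + 0.05 * 0.5 = 0.765
  expect_equal(mixture_accuracy(0.8, 0.7, c(15, 4, 1)), 0.765)
  # degenerate mixtures
  expect_equal(mixture_accuracy(c(0.6, 0.8), 0.7, c(10, 0, 0)), c(0.6, 0.8))
  expect_equal(mixture_accuracy(c(0.6, 0.8), 0.7, c(0, 0, 7)), c(0.5, 0.5))
  expect_error(mixture_accuracy(0.8, 0.7, c(0, 0, 0)), "positive")
})

test_that("variance accounted for behaves like R^2 on block means", {
  obs <- c(0.6, 0.7, 0.8)
  expect_equal(variance_accounted(obs, obs), 100)
  expect_equal(variance_accounted(rep(mean(obs), 3), obs), 0)
  # toy vectors: SS_res = 0.02^2 + 0.01^2 + 0.01^2 = 6e-4; SS_tot = 0.02
  expect_equal(variance_accounted(c(0.62, 0.69, 0.81), obs),
               100 * (1 - 6e-4 / 0.02))
  expect_error(variance_accounted(obs, rep(0.5, 3)), "zero variance")
})
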