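test_that("RB structures have axis-parallel bounds, II structures oblique", {
  rb <- make_structure("RB")
  expect_true(is.infinite(rb$optimal_bound$slope))
  expect_equal(rb$optimal_bound$intercept,
               mean(c(rb$mean_A[1], rb$mean_B[1])))

  ii <- make_structure("II")
  expect_equal(ii$optimal_bound$slope, 1)
  expect_equal(ii$optimal_bound$intercept, 0, tolerance = 1e-10)
  expect_gt(abs(ii$optimal_bound$slope), 0)
  expect_true(is.finite(ii$optimal_bound$slope))
})

test_that("both default structures separate categories with > 0.9 accuracy", {
  expect_gt(optimal_accuracy(make_structure("II")), 0.9)
  expect_gt(optimal_accuracy(make_structure("RB")), 0.9)
})

test_that("closed-form optimal accuracy matches Monte-Carlo classification", {
  ii <- make_structure("II")
  set.seed(11)
  n <- 2e5
  xa <- sample_gaussian(n, ii$mean_A, ii$cov_A)
  xb <- sample_gaussian(n, ii$mean_B, ii$cov_B)
  b <- ii$optimal_bound
  mc <- (mean(xa %*% b$w < b$c) + mean(xb %*% b$w > b$c)) / 2
  # binomial SE at n = 4e5 pooled is ~0.0005
  expect_equal(optimal_accuracy(ii), mc, tolerance = 3 * 5e-4)
})

test_that("non-positive-definite covariances are rejected", {
  expect_error(make_structure("II", cov_A = matrix(c(1, 2, 2, 1), 2)),
               "positive-definite")
  expect_error(make_structure("II", cov_A = matrix(c(1, 0.5, 0, 1), 2)),
               "symmetric")
})

test_that("sampled sequences are balanced, randomized, and reproducible", {
  ii <- make_structure("II")
  set.seed(21)
  s80 <- sample_sequence(ii, 80)
  expect_equal(as.numeric(table(s80$label)), c(40, 40))

  s81 <- sample_sequence(ii, 81)
  expect_lte(abs(diff(as.numeric(table(s81$label)))), 1)

  set.seed(33); a <- sample_sequence(ii, 50)
  set.seed(33); b <- sample_sequence(ii, 50)
  expect_identical(a, b)
})

test_that("sample means converge to the generating category means", {
  ii <- make_structure("II")
  set.seed(5)
  s <- sample_sequence(ii, 1e4)
  xa <- as.matrix(s[s$label == "A", c("frequency", "orientation")])
  se <- sqrt(diag(ii$cov_A) / nrow(xa))
  expect_true(all(abs(colMeans(xa) - ii$mean_A) < 3 * se))
  # label proportions tend to 0.5 (balance contract makes this exact)
  expect_equal(mean(s$label == "A"), 0.5, tolerance = 1e-3)
})

test_that("noise-free 1D rule on RB equals the RB optimal accuracy", {
  rb <- make_structure("RB")
  acc <- best_1d_rule_accuracy(rb, 0, 0, n_criteria = 2001)
  expect_equal(as.numeric(acc), optimal_accuracy(rb), tolerance = 1e-4)
  expect_equal(attr(acc, "dimension"), 1L)
})

test_that("1D rule accuracy collapses to chance under extreme noise", {
  ii <- make_structure("II")
  expect_equal(as.numeric(best_1d_rule_accuracy(ii, 1e6, 1e6)), 0.5,
               tolerance = 1e-3)
})

test_that("II best 1D rule matches a brute-force Monte-Carlo observer", {
  # independent oracle: simulate noisy rule use on sampled stimuli over a
  # dense criterion grid
  ii <- make_structure("II")
  set.seed(7)
  n <- 1e5
  x <- rbind(sample_gaussian(n, ii$mean_A, ii$cov_A),
             sample_gaussian(n, ii$mean_B, ii$cov_B))
  lab <- rep(c("A", "B"), each = n)
  sp <- 4; sc <- 2
  percept <- x[, 1] + rnorm(2 * n, 0, sp)
  best_mc <- 0.5
  for (crit in seq(20, 80, by = 0.5)) {
    eff <- crit + rnorm(2 * n, 0, sc)
    acc <- mean((percept < eff) == (lab == "A"))
    best_mc <- max(best_mc, acc, 1 - acc)
  }
  acc_pkg <- best_1d_rule_accuracy(ii, sp, sc)
  expect_equal(as.numeric(acc_pkg), best_mc, tolerance = 0.01)
})

test_that("the II structure defeats any 1D rule at any noise level", {
  ii <- make_structure("II")
  opt <- optimal_accuracy(ii)
  for (noise in c(0, 2, 4, 8))
    expect_lt(as.numeric(best_1d_rule_accuracy(ii, noise, noise / 2)), opt)
})
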