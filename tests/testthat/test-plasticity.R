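# The three-factor weight update.

pp <- plasticity_params(alpha_w = 1e-3, beta_w = 1e-3, gamma_w = 1e-4,
                        theta_NMDA = 9, theta_AMPA = 4, D_base = 0.2)

test_that("no change below the AMPA threshold with baseline overlap", {
  W <- matrix(c(0.3, 0.6), 1, 2)
  W2 <- update_weights(W, I = 500, S_J = c(2, 2), S_JD = c(0.2, 0.2), pp)
  expect_identical(W2, W)
})

test_that("potentiation saturates at w = 1 and depression at w = 0", {
  W <- matrix(c(1, 0), 1, 2)
  terms <- decompose_update(W, I = 500, S_J = c(20, 20), S_JD = c(0.9, 0.05),
                            params = pp)
  expect_equal(terms$ltp[1, 1], 0)      # (1 - w) factor
  expect_equal(terms$da_dip[1, 2], 0)   # w factor
  W2 <- update_weights(W, I = 500, S_J = c(20, 20), S_JD = c(0.9, 0.05), pp)
  expect_equal(W2[1, 1], 1)
  expect_equal(W2[1, 2], 0)
})

test_that("potentiation arithmetic follows the update rule exactly", {
  # w = 0.5, I = 1, S_JD = D_base + 0.5, S_J above theta_NMDA, alpha = 0.1:
  # delta = 0.1 * 1 * 0.5 * (1 - 0.5) = 0.025
  W <- matrix(0.5, 1, 1)
  W2 <- update_weights(W, I = 1, S_J = 10, S_JD = 0.7,
                       plasticity_params(alpha_w = 0.1, beta_w = 0.1,
                                         gamma_w = 0.01, theta_NMDA = 9,
                                         theta_AMPA = 4, D_base = 0.2))
  expect_equal(W2[1, 1], 0.525)
})

test_that("the three decomposed terms activate under the right conditions", {
  W <- matrix(0.5, 2, 2)
  I <- c(300, 0)
  # error trial: strong activation but overlap below baseline
  terr <- decompose_update(W, I, S_J = c(15, 15), S_JD = c(0.05, 0.05),
                           params = pp)
  expect_true(all(terr$ltp == 0))
  expect_gt(terr$da_dip[1, 1], 0)
  # correct trial with strong activation: no dopamine-dip depression
  tcor <- decompose_update(W, I, S_J = c(15, 15), S_JD = c(0.8, 0.8),
                           params = pp)
  expect_true(all(tcor$da_dip == 0))
  expect_gt(tcor$ltp[1, 1], 0)
  # intermediate activation: subthreshold depression regardless of dopamine
  tmid <- decompose_update(W, I, S_J = c(6, 6), S_JD = c(0.8, 0.05),
                           params = pp)
  expect_gt(tmid$subthreshold_ltd[1, 1], 0)
  expect_gt(tmid$subthreshold_ltd[1, 2], 0)
  # zero-input rows never change
  expect_true(all(terr$da_dip[2, ] == 0))
  expect_true(all(tcor$ltp[2, ] == 0))
  # signed sum equals the applied delta
  W2 <- update_weights(W, I, S_J = c(6, 6), S_JD = c(0.8, 0.05), pp)
  expect_equal(W2 - W, tmid$ltp - tmid$da_dip - tmid$subthreshold_ltd)
})

test_that("weights stay in [0, 1] across 10^4 random-input updates", {
  set.seed(20)
  p_real <- plasticity_params()  # the frozen model rates
  W <- init_weights(40)
  ok <- TRUE
  for (i in 1:10000) {
    I <- runif(40, 0, 600)
    S_J <- runif(2, 0, 15)
    S_JD <- runif(2, 0, 1.5)
    W <- update_weights(W, I, S_J, S_JD, p_real)
    if (any(W < 0) || any(W > 1)) { ok <- FALSE; break }
  }
  expect_true(ok)
})

test_that("increasing overlap weakly increases the updated weight", {
  W <- matrix(0.4, 1, 1)
  w_next <- vapply(seq(0, 1.2, by = 0.1), function(sjd)
    update_weights(W, I = 400, S_J = 12, S_JD = sjd, pp)[1, 1], numeric(1))
  expect_true(all(diff(w_next) >= 0))
})

test_that("zero cortical input leaves all weights unchanged", {
  set.seed(2)
  W <- init_weights(30)
  W2 <- update_weights(W, I = numeric(30), S_J = c(10, 3),
                       S_JD = c(0.9, 0.01), pp)
  expect_identical(W2, W)
})

test_that("threshold ordering and init range are enforced", {
  expect_error(plasticity_params(theta_NMDA = 2, theta_AMPA = 4),
               "theta_NMDA")
  set.seed(1)
  W <- init_weights(100)
  expect_true(all(W >= 0.15 & W <= 0.35))
  expect_equal(dim(W), c(100, 2))
})

test_that("pathological rates clip with a warning", {
  W <- matrix(0.9, 1, 1)
  expect_warning(
    W2 <- update_weights(W, I = 600, S_J = 15, S_JD = 2,
                         plasticity_params(alpha_w = 1, beta_w = 0,
                                           gamma_w = 0, theta_NMDA = 9,
                                           theta_AMPA = 4)),
    "clipped")
  expect_equal(W2[1, 1], 1)
})
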