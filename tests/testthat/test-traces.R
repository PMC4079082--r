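# Alpha kernels, trace superposition, and the overlap integral.

# Independent quadrature oracle: evaluate both kernels analytically at a
# fine grid and integrate the product by the trapezoid rule, without using
# the package's trace machinery.
oracle_overlap <- function(glu_spikes, da_spikes, lo = -700, hi = 4000) {
  tt <- seq(lo, hi, by = 1)
  kern <- function(t, lag, lam) {
    s <- (t - lag) / lam
    ifelse(s > 0, s * exp(1 - s), 0)
  }
  glu <- Reduce(`+`, lapply(glu_spikes, function(s0) kern(tt - s0, 550, 200)),
                accumulate = FALSE, init = numeric(length(tt)))
  da <- Reduce(`+`, lapply(da_spikes, function(s0) kern(tt - s0, 0, 100)),
               accumulate = FALSE, init = numeric(length(tt)))
  p <- glu * da
  sum((p[-1] + p[-length(p)]) / 2)
}

test_that("alpha kernel: zero before onset, unit peak at lag + lambda", {
  gp <- glutamate_trace_params()
  expect_equal(alpha_kernel(gp$lag_ms, gp), 0)
  expect_equal(alpha_kernel(gp$lag_ms - 100, gp), 0)
  expect_equal(alpha_kernel(gp$lag_ms + gp$lambda_ms, gp), 1)
  expect_equal(alpha_kernel(750, gp), 1)  # glutamate peak at 550 + 200 ms
  dp <- dopamine_trace_params()
  expect_equal(alpha_kernel(100, dp), 1)  # dopamine peak at 0 + 100 ms
  # unimodal: rises then decays
  tt <- seq(550, 3000, by = 1)
  v <- alpha_kernel(tt, gp)
  expect_equal(which.max(v), 201)
  expect_true(all(diff(v[201:length(v)]) <= 0))
})

test_that("trace parameters are validated", {
  expect_error(trace_params(-1, 100))
  expect_error(trace_params(0, 0))
})

test_that("spike traces superpose kernels linearly", {
  gp <- glutamate_trace_params()
  tg <- trace_grid()
  expect_equal(spike_trace(numeric(0), gp, tg)$value, numeric(length(tg)))

  one <- spike_trace(-100, gp, tg)
  expect_equal(one$value, alpha_kernel(tg - (-100), gp))

  two <- spike_trace(c(-100, -90), gp, tg)
  expect_equal(two$value,
               alpha_kernel(tg + 100, gp) + alpha_kernel(tg + 90, gp))
  expect_true(all(two$value >= 0))
})

test_that("overlap integral matches an independent quadrature", {
  set.seed(8)
  for (i in 1:20) {
    glu_spk <- sort(runif(sample(3:25, 1), -650, 0))
    da_spk <- sort(runif(sample(3:20, 1), 0, 1200))
    tg <- trace_grid()
    got <- overlap_integral(spike_trace(glu_spk, glutamate_trace_params(), tg),
                            spike_trace(da_spk, dopamine_trace_params(), tg))
    want <- oracle_overlap(glu_spk, da_spk)
    expect_equal(got, want, tolerance = 1e-3)
  }
})

test_that("overlap is zero for disjoint supports and positive for identical traces", {
  tg <- trace_grid(until = 14000)
  glu <- spike_trace(c(-300, -200, -100), glutamate_trace_params(), tg)
  da_far <- spike_trace(c(10000, 10050), dopamine_trace_params(), tg)
  expect_equal(overlap_integral(glu, da_far), 0)
  v <- glu$value
  expect_equal(overlap_integral(glu, glu),
               sum((v[-1]^2 + v[-length(v)]^2) / 2))
  expect_gt(overlap_integral(glu, glu), 0)
})

test_that("overlap errors on mismatched grids", {
  glu <- spike_trace(-100, glutamate_trace_params(), seq(-700, 2000, 1))
  da <- spike_trace(100, dopamine_trace_params(), seq(-700, 2500, 1))
  expect_error(overlap_integral(glu, da), "grid")
})

test_that("overlap is symmetric and bilinear in trace amplitude", {
  tg <- trace_grid()
  a <- spike_trace(c(-400, -200), glutamate_trace_params(), tg)
  b <- spike_trace(c(300, 450), dopamine_trace_params(), tg)
  expect_equal(overlap_integral(a, b), overlap_integral(b, a))
  a3 <- a; a3$value <- 3 * a$value
  expect_equal(overlap_integral(a3, b), 3 * overlap_integral(a, b))
})

test_that("response-locked spiking makes ~500 ms the best feedback delay", {
  # spikes concentrated just before the response, as the trained network
  # produces
  spk <- seq(-250, 0, by = 12.5)
  d <- optimal_delay(spk, delay_grid = seq(0, 2500, by = 10))
  expect_gte(as.numeric(d), 400)
  expect_lte(as.numeric(d), 600)
  ov <- attr(d, "overlap")
  ov500 <- ov$overlap[ov$delay_ms == 500]
  expect_gt(ov500, ov$overlap[ov$delay_ms == 0])
  expect_gt(ov500, ov$overlap[ov$delay_ms == 1000])
  expect_lt(ov$overlap[ov$delay_ms == 2500], 0.01 * max(ov$overlap))
})

test_that("removing the glutamate lag shifts the optimal delay earlier", {
  spk <- seq(-250, 0, by = 12.5)
  with_lag <- optimal_delay(spk)
  no_lag <- optimal_delay(spk, glu_params = trace_params(0, 200))
  expect_lt(as.numeric(no_lag), as.numeric(with_lag))
})

test_that("single-kernel overlap is unimodal in delay with a brute-force mode", {
  # one glutamate kernel vs one dopamine kernel shifted across delays at
  # 1 ms resolution
  tg <- trace_grid()
  glu <- spike_trace(0, glutamate_trace_params(), tg)
  delays <- seq(0, 2000, by = 1)
  ov <- vapply(delays, function(d)
    overlap_integral(glu, spike_trace(d, dopamine_trace_params(), tg)),
    numeric(1))
  m <- which.max(ov)
  expect_true(all(diff(ov[seq_len(m)]) >= 0))
  expect_true(all(diff(ov[m:length(ov)]) <= 0))
  d_coarse <- optimal_delay(0, da_burst_template = 0,
                            delay_grid = seq(0, 2000, by = 1))
  expect_equal(as.numeric(d_coarse), delays[m])
})
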