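# Postsynaptic-effect traces.
#
# A spike's postsynaptic biochemical effect is delayed and smeared in time
# by an alpha function. Superposing one kernel per spike gives a trace; the
# area under the product of the glutamate trace (per MSN) and the dopamine
# trace is the plasticity-gating overlap S_JD. The glutamate trace carries a
# long onset lag (dendritic depolarization / partial CaMKII phosphorylation)
# so the overlap — and therefore learning — peaks when feedback arrives
# roughly 500 ms after the response.

#' Trace parameters
#'
#' @param lag_ms Onset delay of the postsynaptic effect (>= 0).
#' @param lambda_ms Decay constant of the alpha function (> 0).
#' @return List of class `trace_params`.
#' @export
trace_params <- function(lag_ms, lambda_ms) {
  stopifnot(lag_ms >= 0, lambda_ms > 0)
  structure(list(lag_ms = lag_ms, lambda_ms = lambda_ms),
            class = "trace_params")
}

#' @rdname trace_params
#' @details `glutamate_trace_params()` returns the glutamate defaults
#'   (lag 550 ms, decay 200 ms); `dopamine_trace_params()` the dopamine
#'   defaults (no lag, decay 100 ms).
#' @export
glutamate_trace_params <- function()
  trace_params(.striat$traces$glu_lag, .striat$traces$glu_lambda)

#' @rdname trace_params
#' @export
dopamine_trace_params <- function()
  trace_params(.striat$traces$da_lag, .striat$traces$da_lambda)

#' Alpha-function kernel
#'
#' Unit-peak alpha function with onset lag: 0 for `t < lag_ms`, and
#' `s * exp(1 - s)` with `s = (t - lag_ms) / lambda_ms` afterwards, so the
#' peak (value 1) sits at `t = lag_ms + lambda_ms`. All amplitude scaling
#' is absorbed into the plasticity learning rates.
#'
#' @param t Time(s) in ms since the spike.
#' @param params A `trace_params`.
#' @return Kernel value(s), same length as `t`.
#' @examples
#' alpha_kernel(750, glutamate_trace_params())  # 1: peak at 550 + 200 ms
#' @export
alpha_kernel <- function(t, params) {
  s <- (t - params$lag_ms) / params$lambda_ms
  ifelse(s > 0, s * exp(1 - s), 0)
}

#' Default time grid around the response
#'
#' 1 ms resolution spanning `[-700, max(4000, until)]` ms relative to the
#' response (time 0), wide enough to cover the longest informative feedback
#' delay plus trace tails.
#'
#' @param until Optional minimum upper limit in ms.
#' @return Numeric vector of times (ms).
#' @export
trace_grid <- function(until = NULL) {
  hi <- max(.striat$traces$grid_hi, if (is.null(until)) -Inf else until)
  seq(.striat$traces$grid_lo, hi, by = 1)
}

#' Postsynaptic trace of a spike train
#'
#' Superposition (sum) of one alpha kernel per spike, sampled on `t_grid`.
#'
#' @param spike_times Spike times in ms (same reference frame as `t_grid`).
#' @param params A `trace_params`.
#' @param t_grid Regular time grid in ms (see [trace_grid()]).
#' @return An object of class `trace`: list with `t` and `value`.
#' @export
spike_trace <- function(spike_times, params, t_grid = trace_grid()) {
  stopifnot(inherits(params, "trace_params"))
  value <- cpp_spike_trace(as.numeric(spike_times), params$lag_ms,
                           params$lambda_ms, as.numeric(t_grid))
  structure(list(t = t_grid, value = value), class = "trace")
}

#' Area under the product of two traces
#'
#' Trapezoidal integral of the pointwise product of two traces sharing a
#' time grid. This is the overlap `S_JD` that gates potentiation: it is
#' large only when the dopamine trace rises while the glutamate trace is
#' still elevated.
#'
#' @param trace_glu,trace_da Objects of class `trace` on identical grids.
#' @return Nonnegative scalar area (ms x trace-units^2).
#' @export
overlap_integral <- function(trace_glu, trace_da) {
  stopifnot(inherits(trace_glu, "trace"), inherits(trace_da, "trace"))
  if (length(trace_glu$t) != length(trace_da$t) ||
      any(trace_glu$t != trace_da$t))
    stop("traces must share a time grid")
  p <- trace_glu$value * trace_da$value
  n <- length(p)
  dt <- trace_glu$t[2] - trace_glu$t[1]
  sum((p[-1] + p[-n]) / 2) * dt
}

#' Feedback delay maximizing the trace overlap
#'
#' Shifts a dopamine burst template across a grid of candidate feedback
#' delays and returns the delay with the largest overlap against the
#' glutamate trace of the given MSN spike train. With default parameters
#' the argmax falls in the 400-600 ms range.
#'
#' @param glu_spikes MSN spike times in ms relative to the response
#'   (typically negative: spikes occur while the stimulus is on).
#' @param da_burst_template Dopamine spike times in ms relative to feedback
#'   onset (e.g. a short burst `c(0, 20, 40, 60, 80)`).
#' @param delay_grid Candidate delays in ms.
#' @param glu_params,da_params Trace parameters.
#' @return The delay (ms) with maximal overlap, with attribute `overlap`
#'   giving the full overlap-vs-delay curve.
#' @export
optimal_delay <- function(glu_spikes, da_burst_template = seq(0, 80, by = 20),
                          delay_grid = seq(0, 2500, by = 10),
                          glu_params = glutamate_trace_params(),
                          da_params = dopamine_trace_params()) {
  tg <- trace_grid(until = max(delay_grid) + max(da_burst_template) +
                     8 * da_params$lambda_ms)
  glu <- spike_trace(glu_spikes, glu_params, tg)
  ov <- vapply(delay_grid, function(d) {
    da <- spike_trace(da_burst_template + d, da_params, tg)
    overlap_integral(glu, da)
  }, numeric(1))
  structure(delay_grid[which.max(ov)],
            overlap = data.frame(delay_ms = delay_grid, overlap = ov))
}

#' Write a trace as a two-column CSV
#' @param trace A `trace`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  write.csv(data.frame(t_ms = trace$t, value = trace$value), path,
            row.names = FALSE)
  invisible(path)
}
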