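# The spiking basal-ganglia loop for one trial.
#
# Two channels (one per category response): cortical drive excites a
# striatal MSN; the MSN inhibits a tonically active GPi unit; suppressing
# GPi releases a thalamic unit from inhibition; the thalamus excites a
# premotor unit. MSNs and premotor units laterally inhibit each other.
# Premotor "output" is the alpha-smoothed cumulative spike activation; the
# first channel whose output crosses the threshold gives the response.

#' Network simulation parameters
#'
#' Integration settings, premotor noise, response threshold and projection
#' gains for [simulate_trial()]. Defaults are the frozen calibrated values
#' from [striat_constants()].
#'
#' @param dt Euler step in ms (0 < dt <= 1).
#' @param duration Stimulus window in ms (response-terminated; default 700).
#' @param sigma_C SD of the Gaussian white-noise current added to each
#'   premotor unit per step. Raised to model the visual mask.
#' @param threshold Premotor output threshold for responding (default 5).
#' @param ... Named overrides of projection gains or synapse time constants
#'   (`g_ctx`, `g_msn_msn`, `g_msn_gpi`, `I_gpi`, `g_gpi_thal`, `I_thal`,
#'   `g_thal_pm`, `g_pm_pm`, `tau_syn`, `tau_pm`).
#' @return List of class `network_params`.
#' @export
network_params <- function(dt = .striat$network$dt,
                           duration = .striat$network$duration,
                           sigma_C = .striat$network$sigma_C,
                           threshold = .striat$network$threshold, ...) {
  stopifnot(dt > 0, dt <= 1, duration > 0, sigma_C >= 0, threshold > 0)
  p <- .striat$network
  p$dt <- dt; p$duration <- duration
  p$sigma_C <- sigma_C; p$threshold <- threshold
  extra <- list(...)
  unknown <- setdiff(names(extra), names(p))
  if (length(unknown))
    stop("unknown network parameter(s): ", paste(unknown, collapse = ", "))
  p[names(extra)] <- extra
  structure(p, class = "network_params")
}

#' Simulate one trial of the basal-ganglia loop
#'
#' Integrates the full two-channel loop for up to `duration` ms. Each MSN
#' receives `g_ctx * sum_K w_KJ I_K` plus lateral inhibition; the
#' GPi-thalamus-premotor chain converts striatal activity into a response
#' race. The simulation stops at the first premotor threshold crossing
#' (the stimulus is response-terminated); if neither output crosses by
#' stimulus offset, or both cross on the same step, the response is chosen
#' uniformly at random.
#'
#' @param grid_activation Cortical activation vector from [activate()].
#' @param weights Cortical-striatal weight matrix (`length(grid_activation)`
#'   rows, 2 columns).
#' @param params A [network_params()] object.
#' @param return_dynamics If `TRUE`, also return per-step premotor outputs
#'   and all spike trains of the loop.
#' @return List of class `trial_dynamics`:
#'   `response` ("A" or "B"), `response_time` (ms), `msn_spikes`
#'   (list of two spike-time vectors, ms from stimulus onset), `crossed`
#'   (logical: did a premotor output cross the threshold), and, when
#'   requested, `premotor_output` (steps x 2 matrix) plus `gpi_spikes`,
#'   `thal_spikes`, `pm_spikes`.
#' @export
simulate_trial <- function(grid_activation, weights,
                           params = network_params(),
                           return_dynamics = FALSE) {
  stopifnot(inherits(params, "network_params"),
            is.matrix(weights), ncol(weights) == 2,
            nrow(weights) == length(grid_activation))
  if (any(weights < 0 | weights > 1)) stop("weights must lie in [0, 1]")
  drive <- params$g_ctx * as.numeric(crossprod(weights, grid_activation))
  res <- cpp_simulate_trial(.striat$units$msn, .striat$units$qif,
                            drive, unclass(params), isTRUE(return_dynamics))
  res$response <- c("A", "B")[res$response + 1L]
  class(res) <- "trial_dynamics"
  res
}

#' First-crossing response rule
#'
#' Given per-step premotor output time series, the unit whose output first
#' reaches the threshold determines the response; if neither crosses, or
#' both cross on the same step, the response is uniform random.
#'
#' @param premotor_outputs Numeric matrix (steps x 2) of premotor outputs.
#' @param threshold Crossing threshold (default 5).
#' @param dt Step size in ms.
#' @return List with `response` ("A"/"B"), `time` (ms of the deciding step,
#'   or the final step when no crossing occurred) and `crossed` (logical).
#' @export
select_response <- function(premotor_outputs,
                            threshold = .striat$network$threshold, dt = 1) {
  stopifnot(is.matrix(premotor_outputs), ncol(premotor_outputs) == 2,
            threshold > 0)
  cross <- premotor_outputs >= threshold
  first <- apply(cross, 2, function(x) if (any(x)) which(x)[1] else Inf)
  if (all(is.infinite(first)) || first[1] == first[2]) {
    resp <- sample(c("A", "B"), 1)
    t_ms <- (if (all(is.infinite(first))) nrow(premotor_outputs)
             else first[1]) * dt
    crossed <- !all(is.infinite(first))
  } else {
    resp <- c("A", "B")[which.min(first)]
    t_ms <- min(first) * dt
    crossed <- TRUE
  }
  list(response = resp, time = t_ms, crossed = crossed)
}
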