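# Reward prediction, prediction error, and phasic dopamine.
#
# The reward network upstream of the dopamine neuron is modeled abstractly:
# a Bush-Mosteller single-operator update tracks the predicted reward RP,
# the prediction error RPE = R - RP sets the trial's dopamine level, and a
# regular-spiking neuron converts that level into a tonic spike train with
# a phasic burst (positive RPE) or pause (negative RPE) at feedback time.

#' Initialize the reward state
#'
#' @param RP0 Initial reward prediction (default 0.5, maximal uncertainty).
#' @param alpha_pr Single-operator learning rate (default 0.075).
#' @param D_base Baseline dopamine level (default 0.2).
#' @return List of class `reward_state` with fields `RP`, `R`, `RPE`,
#'   `alpha_pr`, `D_base`.
#' @export
reward_state <- function(RP0 = .striat$reward$RP0,
                         alpha_pr = .striat$reward$alpha_pr,
                         D_base = .striat$reward$D_base) {
  stopifnot(RP0 >= 0, RP0 <= 1, alpha_pr > 0, alpha_pr < 1,
            D_base >= 0, D_base <= 1)
  structure(list(RP = RP0, R = NA_real_, RPE = NA_real_,
                 alpha_pr = alpha_pr, D_base = D_base),
            class = "reward_state")
}

#' Single-operator reward-prediction update
#'
#' Computes `RPE = R - RP` and then `RP <- RP + alpha_pr * RPE`
#' (Bush-Mosteller). Under constant reward RP converges exponentially to
#' the expected reward: `RP_n = R - (R - RP_0) (1 - alpha_pr)^n`.
#'
#' @param state A `reward_state`.
#' @param R Obtained reward: 1 (correct) or 0 (error).
#' @return The updated `reward_state`, with `R` and `RPE` set to the values
#'   of this trial (RPE is computed against the pre-update prediction).
#' @examples
#' s <- reward_state()
#' s <- update_reward_prediction(s, 1)
#' s$RPE   # 0.5
#' s$RP    # 0.5375
#' @export
update_reward_prediction <- function(state, R) {
  stopifnot(inherits(state, "reward_state"), R %in% c(0, 1))
  state$R <- R
  state$RPE <- R - state$RP
  state$RP <- state$RP + state$alpha_pr * state$RPE
  state
}

#' Trial dopamine level from the prediction error
#'
#' `D = clip(D_base + gain * RPE, 0, 1)`: no surprise leaves dopamine at
#' baseline, positive RPE raises it toward 1 (phasic burst), negative RPE
#' lowers it toward 0 (pause).
#'
#' @param RPE Reward prediction error in \[-1, 1\].
#' @param D_base Baseline dopamine level.
#' @param gain Slope of the dopamine response (default 0.8).
#' @return Dopamine level in \[0, 1\].
#' @export
dopamine_level <- function(RPE, D_base = .striat$reward$D_base,
                           gain = .striat$reward$da_gain) {
  stopifnot(RPE >= -1, RPE <= 1)
  min(max(D_base + gain * RPE, 0), 1)
}

#' Simulate the dopamine neuron for one trial
#'
#' A regular-spiking unit fires tonically under constant drive; at
#' `burst_onset_ms` (response time + feedback delay) a current step
#' proportional to `D - D_base` is injected for `burst_dur` ms. Above
#' baseline this produces a burst, below baseline a pause (the drive drops
#' below rheobase and the unit falls silent for the window).
#'
#' @param D Trial dopamine level from [dopamine_level()].
#' @param burst_onset_ms Feedback time in the trace frame (response = 0).
#' @param t_start,t_end Simulation window in ms (trace frame).
#' @param D_base Baseline dopamine level.
#' @param dt Euler step (ms).
#' @return Numeric vector of dopamine spike times in ms.
#' @export
simulate_da_neuron <- function(D, burst_onset_ms,
                               t_start = .striat$traces$grid_lo,
                               t_end = .striat$traces$grid_hi,
                               D_base = .striat$reward$D_base, dt = 1) {
  stopifnot(D >= 0, D <= 1, t_end > t_start)
  rw <- .striat$reward
  cpp_simulate_da(.striat$units$regular, t_start, t_end, dt,
                  rw$I_da_tonic, rw$g_da_burst * (D - D_base),
                  burst_onset_ms, rw$burst_dur)
}
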