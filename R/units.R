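# Single-unit membrane models and one-step Euler updates.
#
# These R steppers are the reference definition of the dynamics; the trial
# simulator in compiled code applies the identical update, so step-by-step
# equivalence is testable.

#' Membrane parameters for a unit model
#'
#' `"msn"` returns the two-variable striatal medium-spiny-neuron
#' parameterization, `"regular"` the regular-spiking parameterization used
#' for the dopamine neuron (both in the Izhikevich 2007, p. 312 form), and
#' `"qif"` the quadratic integrate-and-fire constants used for all other
#' units (GPi, thalamus, premotor).
#'
#' @param kind One of "msn", "regular", "qif".
#' @return Named numeric vector of membrane constants.
#' @export
unit_params <- function(kind = c("msn", "regular", "qif")) {
  kind <- match.arg(kind)
  .striat$units[[kind]]
}

#' One Euler step of the medium-spiny-neuron model
#'
#' Updates `C dv/dt = k (v - vr)(v - vt) - u + I` and
#' `du/dt = a (b (v - vr) - u)`; when `v` crosses `vpeak` the state is
#' reset (`v <- c`, `u <- u + d`) and a spike is flagged.
#'
#' @param state Numeric `c(v, u)`; use [rest_state()] to initialize.
#' @param input_current Injected current (model units).
#' @param dt Time step in ms, in (0, 1].
#' @param params Membrane constants, default `unit_params("msn")`.
#' @return List with `state` (updated `c(v, u)`) and logical `spiked`.
#' @export
step_msn <- function(state, input_current, dt = 1, params = unit_params("msn")) {
  stopifnot(dt > 0, dt <= 1)
  if (!all(is.finite(state))) stop("non-finite membrane state")
  v <- state[1]; u <- state[2]
  p <- params
  v_new <- v + dt * (p[["k"]] * (v - p[["vr"]]) * (v - p[["vt"]]) - u +
                       input_current) / p[["C"]]
  u_new <- u + dt * p[["a"]] * (p[["b"]] * (v - p[["vr"]]) - u)
  spiked <- v_new >= p[["vpeak"]]
  if (spiked) { v_new <- p[["c"]]; u_new <- u_new + p[["d"]] }
  if (!is.finite(v_new)) stop("membrane potential diverged")
  list(state = c(v_new, u_new), spiked = spiked)
}

#' One Euler step of the quadratic integrate-and-fire model
#'
#' Updates `C dv/dt = k (v - vr)(v - vt) + I`; when `v` crosses `vpeak`
#' it is reset to `vreset` and a spike is flagged. Below rheobase
#' (`I < k (vt - vr)^2 / 4`) the membrane settles to a fixed point.
#'
#' @param state Numeric scalar membrane potential `v`.
#' @inheritParams step_msn
#' @return List with `state` (updated `v`) and logical `spiked`.
#' @export
step_qif <- function(state, input_current, dt = 1, params = unit_params("qif")) {
  stopifnot(dt > 0, dt <= 1)
  if (!is.finite(state[1])) stop("non-finite membrane state")
  v <- state[1]; p <- params
  v_new <- v + dt * (p[["k"]] * (v - p[["vr"]]) * (v - p[["vt"]]) +
                       input_current) / p[["C"]]
  spiked <- v_new >= p[["vpeak"]]
  if (spiked) v_new <- p[["vreset"]]
  if (!is.finite(v_new)) stop("membrane potential diverged")
  list(state = c(v = unname(v_new)), spiked = spiked)
}

#' Resting initial state for a unit model
#' @param kind One of "msn", "regular", "qif".
#' @return `c(v, u)` for two-variable models, `c(v)` for QIF.
#' @export
rest_state <- function(kind = c("msn", "regular", "qif")) {
  kind <- match.arg(kind)
  p <- .striat$units[[kind]]
  if (kind == "qif") c(v = unname(p[["vr"]])) else c(v = unname(p[["vr"]]), u = 0)
}

# Spike times (ms) of a unit integrated for `duration` ms under a constant
# current, via the compiled stepper. Used for calibration and tests.
#' Simulate a single unit under constant current
#'
#' @param kind Unit model ("msn", "regular", "qif").
#' @param input_current Constant injected current.
#' @param duration Simulation length in ms.
#' @param dt Euler step (ms).
#' @return Numeric vector of spike times in ms.
#' @export
simulate_unit <- function(kind = c("msn", "regular", "qif"),
                          input_current, duration = 1000, dt = 1) {
  kind <- match.arg(kind)
  p <- .striat$units[[kind]]
  if (kind == "qif")
    cpp_qif_constant(p, input_current, duration, dt)
  else
    cpp_izh_constant(p, input_current, duration, dt)
}
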