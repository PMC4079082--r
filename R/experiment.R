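# Experiment orchestration: trials -> blocks -> replications -> learning
# curves, plus the strategy-mixture accuracy model.

#' Specify a simulated experiment condition
#'
#' A condition is a task, a feedback-delay distribution (fixed or Gaussian
#' with truncation at 0), a block design, a premotor noise level and a
#' replication count. The three published designs are covered by:
#' 4 blocks with elevated `sigma_C` (masked 2003 design), 5 blocks with
#' fixed delays 0/500/1000 ms (2013 Experiment 1), and 5 blocks with
#' Gaussian delays of SD 75 or 150 ms around 500 ms (2013 Experiment 2).
#'
#' @param task "II" or "RB" (structure defaults from [make_structure()]).
#' @param delay_ms Fixed feedback delay in ms, or `NULL` when
#'   `delay_mean_ms` is given.
#' @param delay_mean_ms,delay_sd_ms Gaussian delay distribution (truncated
#'   at 0 ms); used when `delay_sd_ms > 0`.
#' @param n_blocks Number of blocks.
#' @param trials_per_block Trials per block (default 80).
#' @param sigma_C Premotor noise SD; default baseline, set to
#'   `striat_constants()$network$sigma_C_mask` for masked conditions.
#' @param n_replications Independent model replications (default 50).
#' @param seed Optional integer seed applied at the start of
#'   [run_condition()].
#' @return List of class `condition_spec`.
#' @export
condition_spec <- function(task = "II", delay_ms = 500,
                           delay_mean_ms = NULL, delay_sd_ms = 0,
                           n_blocks = 5,
                           trials_per_block = .striat$experiment$trials_per_block,
                           sigma_C = .striat$network$sigma_C,
                           n_replications = .striat$experiment$n_replications,
                           seed = NULL) {
  if (!is.null(delay_mean_ms)) {
    stopifnot(delay_mean_ms >= 0, delay_sd_ms >= 0)
  } else {
    stopifnot(delay_ms >= 0)
  }
  stopifnot(n_blocks >= 1, trials_per_block >= 1, n_replications >= 1,
            sigma_C >= 0, task %in% c("II", "RB"))
  structure(list(task = task, delay_ms = delay_ms,
                 delay_mean_ms = delay_mean_ms, delay_sd_ms = delay_sd_ms,
                 n_blocks = n_blocks, trials_per_block = trials_per_block,
                 sigma_C = sigma_C, n_replications = n_replications,
                 seed = seed),
            class = "condition_spec")
}

draw_delay <- function(spec) {
  if (!is.null(spec$delay_mean_ms) && spec$delay_sd_ms > 0)
    max(rnorm(1, spec$delay_mean_ms, spec$delay_sd_ms), 0)
  else if (!is.null(spec$delay_mean_ms)) spec$delay_mean_ms
  else spec$delay_ms
}

#' Initialize a fresh model for one replication
#'
#' Bundles the category structure, cortical grid, randomly initialized
#' weights, reward state and parameter sets into a mutable model state.
#'
#' @param structure A `category_structure` (default from the task).
#' @param grid A `cortical_grid`.
#' @param net A `network_params`.
#' @param plast A `plasticity_params`.
#' @param rstate A `reward_state`.
#' @return List of class `model_state`.
#' @export
model_state <- function(structure = make_structure("II"),
                        grid = cortical_grid(),
                        net = network_params(),
                        plast = plasticity_params(),
                        rstate = reward_state()) {
  n_units <- grid$n_rows * grid$n_cols
  structure(list(structure = structure, grid = grid, net = net,
                 plast = plast, reward = rstate,
                 W = init_weights(n_units), trial_index = 0L),
            class = "model_state")
}

#' Run one trial of the full pipeline
#'
#' Cortical activation -> spiking network -> response -> feedback
#' (R = 1 iff the response matches the true label) -> reward-prediction
#' update -> dopamine spike train at `response_time + delay` -> glutamate
#' and dopamine traces -> overlap `S_JD` -> three-factor weight update.
#'
#' @param state A `model_state`.
#' @param stimulus One stimulus: numeric `(frequency, orientation)` plus a
#'   `label` entry, or a one-row data frame from [sample_sequence()].
#' @param delay_ms Feedback delay in ms (from response/stimulus offset).
#' @return List with the updated `state` and a one-row data frame `record`
#'   (response, correctness, RPE, dopamine level, response time, `S_J` and
#'   `S_JD` per striatal unit, mean absolute weight change).
#' @export
run_trial <- function(state, stimulus, delay_ms) {
  stopifnot(inherits(state, "model_state"), delay_ms >= 0)
  if (is.data.frame(stimulus)) {
    label <- stimulus$label[1]
    coords <- c(stimulus$frequency[1], stimulus$orientation[1])
  } else {
    label <- attr(stimulus, "label")
    coords <- as.numeric(stimulus[1:2])
  }

  # rare Gaussian tail stimuli land outside the representable space; the
  # display range is the grid range, so clip deliberately (no warning)
  coords <- pmin(pmax(coords, state$grid$space[1]), state$grid$space[2])
  I <- activate(state$grid, coords)
  dyn <- simulate_trial(I, state$W, state$net)
  correct <- identical(dyn$response, label)
  R <- as.numeric(correct)

  state$reward <- update_reward_prediction(state$reward, R)
  D <- dopamine_level(state$reward$RPE, state$reward$D_base)

  # Trace frame: response at 0. MSN spikes precede the response; the
  # dopamine burst starts at the feedback delay.
  tr <- .striat$traces
  t_hi <- max(tr$grid_hi, delay_ms + .striat$reward$burst_dur +
                8 * tr$da_lambda)
  t_grid <- seq(tr$grid_lo, t_hi, by = 1)
  da_spikes <- simulate_da_neuron(D, burst_onset_ms = delay_ms,
                                  t_start = tr$grid_lo, t_end = t_hi,
                                  D_base = state$reward$D_base)
  da_trace <- spike_trace(da_spikes, dopamine_trace_params(), t_grid)

  S_J <- numeric(2); S_JD <- numeric(2)
  for (j in 1:2) {
    glu <- spike_trace(dyn$msn_spikes[[j]] - dyn$response_time,
                       glutamate_trace_params(), t_grid)
    S_J[j] <- tr$S_J_scale * sum(glu$value)          # 1 ms grid: sum = area
    S_JD[j] <- tr$overlap_scale * overlap_integral(glu, da_trace)
  }

  W_old <- state$W
  state$W <- update_weights(state$W, I, S_J, S_JD, state$plast)
  state$trial_index <- state$trial_index + 1L

  record <- data.frame(
    trial = state$trial_index, frequency = coords[1],
    orientation = coords[2], label = label, response = dyn$response,
    correct = correct, delay_ms = delay_ms, response_time = dyn$response_time,
    crossed = dyn$crossed, RPE = state$reward$RPE, RP = state$reward$RP,
    D = D, S_J_A = S_J[1], S_J_B = S_J[2], S_JD_A = S_JD[1],
    S_JD_B = S_JD[2], mean_abs_dw = mean(abs(state$W - W_old)),
    stringsAsFactors = FALSE)
  list(state = state, record = record)
}

#' Run a full simulated condition
#'
#' Runs `n_replications` independent models (fresh weights and reward state
#' each) through `n_blocks` x `trials_per_block` trials and aggregates
#' per-block accuracy across replications into a learning curve.
#'
#' @param spec A [condition_spec()].
#' @param structure Optional `category_structure` overriding the task
#'   default.
#' @param keep_trials If `TRUE`, attach the per-trial records of every
#'   replication (memory-heavy; default `FALSE`).
#' @param progress If `TRUE`, print a line per replication.
#' @return Object of class `learning_curve`: list with `curve` (data frame:
#'   block, mean_accuracy, sd_accuracy, se_accuracy), `block_accuracy`
#'   (replications x blocks matrix), `spec`, and optionally `trials`.
#' @export
run_condition <- function(spec, structure = NULL, keep_trials = FALSE,
                          progress = FALSE) {
  stopifnot(inherits(spec, "condition_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  if (is.null(structure)) structure <- make_structure(spec$task)
  grid <- cortical_grid()
  net <- network_params(sigma_C = spec$sigma_C)
  n_trials <- spec$n_blocks * spec$trials_per_block

  acc <- matrix(NA_real_, spec$n_replications, spec$n_blocks)
  all_trials <- if (keep_trials) vector("list", spec$n_replications)

  for (rep in seq_len(spec$n_replications)) {
    st <- model_state(structure = structure, grid = grid, net = net)
    seq_df <- sample_sequence(structure, n_trials)
    correct <- logical(n_trials)
    recs <- if (keep_trials) vector("list", n_trials)
    for (i in seq_len(n_trials)) {
      out <- run_trial(st, seq_df[i, ], draw_delay(spec))
      st <- out$state
      correct[i] <- out$record$correct
      if (keep_trials) recs[[i]] <- out$record
    }
    block_of <- rep(seq_len(spec$n_blocks), each = spec$trials_per_block)
    acc[rep, ] <- tapply(correct, block_of, mean)
    if (keep_trials) {
      df <- do.call(rbind, recs)
      df$replication <- rep
      df$block <- block_of
      all_trials[[rep]] <- df
    }
    if (progress)
      message(sprintf("replication %d/%d: final block %.3f",
                      rep, spec$n_replications, acc[rep, spec$n_blocks]))
  }

  curve <- data.frame(
    block = seq_len(spec$n_blocks),
    mean_accuracy = colMeans(acc),
    sd_accuracy = apply(acc, 2, sd),
    se_accuracy = apply(acc, 2, sd) / sqrt(spec$n_replications))
  out <- list(curve = curve, block_accuracy = acc, spec = spec)
  if (keep_trials) out$trials <- do.call(rbind, all_trials)
  structure(out, class = "learning_curve")
}

#' @export
print.learning_curve <- function(x, ...) {
  s <- x$spec
  delay <- if (!is.null(s$delay_mean_ms))
    sprintf("delay ~ N(%g, %g) ms", s$delay_mean_ms, s$delay_sd_ms)
  else sprintf("delay %g ms", s$delay_ms)
  cat(sprintf("<learning_curve> %s task, %s, %d x %d trials, %d replications\n",
              s$task, delay, s$n_blocks, s$trials_per_block,
              s$n_replications))
  print(x$curve, row.names = FALSE)
  invisible(x)
}

#' Strategy-mixture predicted accuracy
#'
#' Human samples mix procedural learners, explicit-rule users and guessers.
#' Predicted group accuracy is the convex combination of the procedural
#' model's curve, the best-1D-rule accuracy and chance, weighted by the
#' participant counts of each strategy class.
#'
#' @param procedural_curve Numeric vector of per-block procedural-model
#'   accuracies (or a `learning_curve`).
#' @param rule_accuracy Accuracy of explicit-rule users (scalar or
#'   per-block), e.g. [best_1d_rule_accuracy()].
#' @param weights Integer counts `c(n_procedural, n_rule, n_guess)`.
#' @param guess_accuracy Accuracy of guessers (default 0.5).
#' @return Numeric vector of predicted per-block accuracies.
#' @examples
#' mixture_accuracy(0.8, 0.7, c(15, 4, 1))  # 0.75*0.8 + 0.20*0.7 + 0.05*0.5
#' @export
mixture_accuracy <- function(procedural_curve, rule_accuracy, weights,
                             guess_accuracy = 0.5) {
  if (inherits(procedural_curve, "learning_curve"))
    procedural_curve <- procedural_curve$curve$mean_accuracy
  stopifnot(length(weights) == 3, all(weights >= 0))
  if (sum(weights) == 0) stop("at least one strategy count must be positive")
  p <- weights / sum(weights)
  as.numeric(p[1] * procedural_curve + p[2] * rule_accuracy +
               p[3] * guess_accuracy)
}

#' Percent of variance accounted for
#'
#' `100 * (1 - SS_residual / SS_total)` with the total sum of squares taken
#' about the observed grand mean.
#'
#' @param predicted,observed Equal-length numeric vectors of block (or
#'   block x condition) mean accuracies.
#' @return Percent of variance accounted for (can be negative for a model
#'   worse than the grand mean).
#' @export
variance_accounted <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(observed) > 1)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("observed means have zero variance")
  100 * (1 - sum((observed - predicted)^2) / ss_tot)
}
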