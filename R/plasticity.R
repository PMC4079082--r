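# Three-factor reinforcement learning at cortical-striatal synapses.
#
# The per-trial weight update for synapse (K, J):
#
#   w' = w + alpha_w I_K [S_JD - D_base]+ (1 - w)
#          - beta_w  I_K [D_base - S_JD]+ w
#          - gamma_w I_K [theta_NMDA - S_J]+ [S_J - theta_AMPA]+ w
#
# with [x]+ = max(x, 0). Line 1 strengthens a synapse when presynaptic
# activation (I_K), strong postsynaptic activation, and above-baseline
# dopamine coincide (S_JD above D_base); line 2 weakens it when dopamine
# overlap is below baseline; line 3 weakens it when postsynaptic activation
# sits between the AMPA and NMDA thresholds. Below the AMPA threshold with
# baseline overlap, nothing changes.

#' Plasticity parameters
#'
#' Learning rates and receptor-activation thresholds for the three-factor
#' update. Defaults are the frozen calibrated values; `theta_NMDA` must
#' exceed `theta_AMPA` (NMDA receptors need stronger activation).
#'
#' @param alpha_w Potentiation rate (dopamine burst overlap above baseline).
#' @param beta_w Depression rate (overlap below baseline, e.g. error trials
#'   or mistimed feedback).
#' @param gamma_w Depression rate for intermediate postsynaptic activation.
#' @param theta_NMDA,theta_AMPA Postsynaptic activation thresholds on `S_J`.
#' @param D_base Baseline dopamine level compared against `S_JD`.
#' @return List of class `plasticity_params`.
#' @export
plasticity_params <- function(alpha_w = .striat$plasticity$alpha_w,
                              beta_w = .striat$plasticity$beta_w,
                              gamma_w = .striat$plasticity$gamma_w,
                              theta_NMDA = .striat$plasticity$theta_NMDA,
                              theta_AMPA = .striat$plasticity$theta_AMPA,
                              D_base = .striat$reward$D_base) {
  stopifnot(alpha_w >= 0, beta_w >= 0, gamma_w >= 0)
  if (!(theta_NMDA > theta_AMPA))
    stop("theta_NMDA must exceed theta_AMPA")
  structure(list(alpha_w = alpha_w, beta_w = beta_w, gamma_w = gamma_w,
                 theta_NMDA = theta_NMDA, theta_AMPA = theta_AMPA,
                 D_base = D_base),
            class = "plasticity_params")
}

#' Initialize the cortical-striatal weight matrix
#'
#' Independent uniform draws per synapse in a small symmetric range, so the
#' untrained network responds near chance while both striatal units receive
#' enough drive to spike.
#'
#' @param n_cortical Number of cortical units (rows).
#' @param n_striatal Number of striatal units (columns, default 2).
#' @param range Uniform range of initial weights.
#' @return `n_cortical x n_striatal` matrix with entries in \[0, 1\].
#' @export
init_weights <- function(n_cortical, n_striatal = 2,
                         range = .striat$plasticity$w_init) {
  matrix(runif(n_cortical * n_striatal, range[1], range[2]),
         n_cortical, n_striatal)
}

relu <- function(x) pmax(x, 0)

# The three signed update terms; update_weights and decompose_update share
# this single implementation.
plasticity_terms <- function(W, I, S_J, S_JD, params) {
  stopifnot(is.matrix(W), length(I) == nrow(W),
            length(S_J) == ncol(W), length(S_JD) == ncol(W),
            all(S_J >= 0), all(S_JD >= 0))
  p <- params
  ltp <- sweep((1 - W) * I, 2, p$alpha_w * relu(S_JD - p$D_base), "*")
  dip <- sweep(W * I, 2, p$beta_w * relu(p$D_base - S_JD), "*")
  sub <- sweep(W * I, 2,
               p$gamma_w * relu(p$theta_NMDA - S_J) * relu(S_J - p$theta_AMPA),
               "*")
  list(ltp = ltp, da_dip = dip, subthreshold_ltd = sub)
}

#' Apply the three-factor weight update
#'
#' @param W Weight matrix (cortical units x striatal units), entries in
#'   \[0, 1\].
#' @param I Cortical activation vector `I_K` (length `nrow(W)`).
#' @param S_J Integrated glutamate-trace activation per striatal unit
#'   (length `ncol(W)`).
#' @param S_JD Glutamate x dopamine overlap per striatal unit.
#' @param params A `plasticity_params`.
#' @return The updated weight matrix. Weights are clipped into \[0, 1\]
#'   only if a pathological parameter choice would leave the interval, with
#'   a warning.
#' @examples
#' p <- plasticity_params(alpha_w = 0.1, theta_NMDA = 9, theta_AMPA = 4)
#' W <- matrix(0.5, 1, 2)
#' # potentiation of unit 1 only: S_JD above baseline, S_J above theta_NMDA
#' update_weights(W, I = 1, S_J = c(10, 10), S_JD = c(0.7, 0.2), p)
#' @export
update_weights <- function(W, I, S_J, S_JD, params = plasticity_params()) {
  terms <- plasticity_terms(W, I, S_J, S_JD, params)
  W_new <- W + terms$ltp - terms$da_dip - terms$subthreshold_ltd
  if (any(W_new < 0) || any(W_new > 1)) {
    warning("weights left [0, 1] and were clipped; ",
            "learning rates are too large for these inputs")
    W_new <- pmin(pmax(W_new, 0), 1)
  }
  W_new
}

#' Decompose the weight update into its three terms
#'
#' Returns the potentiation term, the dopamine-dip depression term and the
#' subthreshold depression term separately (all nonnegative matrices);
#' `ltp - da_dip - subthreshold_ltd` equals the delta applied by
#' [update_weights()] (before any clipping).
#'
#' @inheritParams update_weights
#' @return List of matrices `ltp`, `da_dip`, `subthreshold_ltd`.
#' @export
decompose_update <- function(W, I, S_J, S_JD, params = plasticity_params()) {
  plasticity_terms(W, I, S_J, S_JD, params)
}

#' Write a weight snapshot as CSV
#' @param W Weight matrix.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_weights_csv <- function(W, path) {
  df <- data.frame(K = rep(seq_len(nrow(W)), ncol(W)),
                   J = rep(seq_len(ncol(W)), each = nrow(W)),
                   w = as.numeric(W))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
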