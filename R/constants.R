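# Versioned model constants.
#
# Membrane constants follow the published parameterizations they cite:
# the striatal medium spiny neuron and the regular-spiking cell use the
# Izhikevich (2007, p. 312) two-variable form
#   C dv/dt = k (v - vr)(v - vt) - u + I,   du/dt = a [ b (v - vr) - u ],
# with reset v <- c, u <- u + d at v >= vpeak; all other units use the
# quadratic integrate-and-fire form (no recovery variable).
#
# Projection gains, trace scales and the Eq.-style learning constants are
# not published; they were calibrated once against the behavioral targets
# (untrained network near chance, trained network > 90% correct, final-block
# accuracy near 0.80 at a 500 ms feedback delay) and frozen here. See the
# methods vignette for the calibration protocol.

.striat <- list(
  version = "1.0",

  units = list(
    msn = c(C = 50, vr = -80, vt = -25, k = 1, a = 0.01, b = -20,
            c = -55, d = 150, vpeak = 40),
    regular = c(C = 100, vr = -60, vt = -40, k = 0.7, a = 0.03, b = -2,
                c = -50, d = 100, vpeak = 35),
    qif = c(C = 25, vr = -60, vt = -40, k = 0.7, vreset = -50, vpeak = 35)
  ),

  cortex = list(n_rows = 20, n_cols = 20, height = 600, spread = 0.8,
                space = c(0, 100)),

  network = list(
    dt = 1,                 # ms, Euler step
    duration = 700,         # ms, response-terminated stimulus window
    threshold = 5,          # premotor output threshold
    sigma_C = 12,           # premotor current noise SD per step (baseline)
    sigma_C_mask = 198,      # elevated value modeling the visual mask
    tau_syn = 20,           # ms, exponential synaptic filter
    tau_pm = 150,            # ms, premotor output alpha filter
    g_ctx = 1,              # cortical drive gain on sum_K w_KJ I_K
    g_msn_msn = 250,        # lateral MSN inhibition
    g_msn_gpi = 100,        # MSN -> GPi inhibition
    I_gpi = 120,            # GPi tonic drive
    g_gpi_thal = 40,        # GPi -> thalamus inhibition
    I_thal = 100,           # thalamic tonic drive
    g_thal_pm = 60,         # thalamus -> premotor excitation
    g_pm_pm = 40            # premotor lateral inhibition
  ),

  traces = list(
    glu_lag = 550, glu_lambda = 200,   # glutamate trace: lag, decay (ms)
    da_lag = 0,    da_lambda = 100,    # dopamine trace
    grid_lo = -700, grid_hi = 4000,    # default grid around response (ms)
    S_J_scale = 1e-3,                  # glutamate-trace area -> S_J units
    overlap_scale = 6.6e-5             # product area -> S_JD units
  ),

  reward = list(
    RP0 = 0.5, alpha_pr = 0.075,
    D_base = 0.2, da_gain = 0.8,
    I_da_tonic = 55,        # tonic DA-neuron drive (low-rate firing)
    g_da_burst = 400,       # phasic current gain on (D - D_base)
    burst_dur = 100         # ms
  ),

  plasticity = list(
    alpha_w = 3e-4, beta_w = 5e-5, gamma_w = 1e-6,
    theta_NMDA = 3.8, theta_AMPA = 1.1,
    w_init = c(0.15, 0.35)
  ),

  experiment = list(trials_per_block = 80, n_replications = 50)
)

#' Model constants
#'
#' Returns the versioned list of frozen model constants (membrane
#' parameters, projection gains, trace scales, learning constants).
#' Individual values can be overridden through the parameter constructors
#' ([network_params()], [plasticity_params()], ...) or a config file.
#'
#' @return A named list of constant groups.
#' @export
striat_constants <- function() .striat
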