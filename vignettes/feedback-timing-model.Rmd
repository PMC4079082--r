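---
title: "A spiking corticostriatal model of procedural category learning and feedback timing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spiking corticostriatal model of procedural category learning and feedback timing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(striatlearn)
```

## The scientific problem

Information-integration (II) category learning — where the optimal decision
bound integrates two stimulus dimensions and cannot be verbalized — is
mediated by procedural memory in the striatum, and it is exquisitely
sensitive to *when* feedback arrives. Human learners acquire II categories
best when corrective feedback follows the response by about 500 ms, slightly
worse at 0 or 1000 ms, and essentially not at all when feedback is delayed
2.5 s or longer. Rule-based learning, relying on working memory, is
indifferent to such delays.

`striatlearn` implements a computational account of this timing window.
Learning lives at cortical-striatal synapses and requires three factors to
coincide: strong presynaptic (cortical) activation, strong postsynaptic
(striatal) activation, and dopamine above baseline. The postsynaptic
biochemical consequences of glutamate release (NMDA-receptor activation and
partial CaMKII phosphorylation) build up and decay over hundreds of
milliseconds, as does the intracellular cascade triggered by dopamine at D1
receptors. Synaptic change is driven by the *temporal overlap* of these two
processes, so there is a physiological optimum for feedback delivery:
feedback that arrives too early or too late finds the glutamate cascade
still rising or already decayed.

## Architecture

Each trial runs a two-channel spiking loop:

1. **Visual cortex**: a 20 x 20 grid of units tuned to (spatial frequency,
   orientation). A stimulus activates the best-matching unit at 600 and its
   neighbors through a Gaussian receptive field with spread 0.8 in
   grid-index units (`activate()`).
2. **Striatum**: two medium spiny neurons (MSNs), one per category
   response, modeled with the two-variable Izhikevich MSN parameterization.
   MSN J receives `sum_K w_KJ I_K` plus lateral inhibition from the other
   MSN. The lateral inhibition implements a winner-take-all competition
   that concentrates postsynaptic activity — and therefore plasticity
   credit — on the channel that drives the response.
3. **Pallidum, thalamus, premotor cortex**: quadratic integrate-and-fire
   units. GPi fires tonically and is inhibited by its MSN; the thalamic
   unit is held down by GPi and released (disinhibited) when the MSN fires;
   the thalamus excites a premotor unit. Premotor units laterally inhibit
   each other and receive additive Gaussian current noise of SD `sigma_C`
   per step.
4. **Response rule**: the premotor "output" is the alpha-smoothed
   cumulative premotor spike activation; the first output to cross 5
   determines the response and terminates the stimulus. If neither output
   crosses within the 700 ms stimulus window, or both cross on the same
   step, the response is chosen at random.

All membrane equations are integrated with Euler's method at `dt = 1` ms
(configurable; a step-refinement test guards the QIF integration).

## Plasticity

Spikes do not act on the synapse directly. Each MSN spike contributes a
delayed, smeared postsynaptic effect — an alpha function with a 550 ms
onset lag and decay constant 200 ms (the *glutamate trace*). Dopamine spikes
contribute a faster trace with no lag and decay constant 100 ms. On each
trial the overlap `S_JD` is the area under the product of MSN J's glutamate
trace and the dopamine trace, and the per-synapse update is

```
w' = w + alpha_w I_K [S_JD - D_base]+ (1 - w)
       - beta_w  I_K [D_base - S_JD]+ w
       - gamma_w I_K [theta_NMDA - S_J]+ [S_J - theta_AMPA]+ w
```

with `[x]+ = max(x, 0)` and `S_J` the integrated glutamate trace. The first
line strengthens synapses when a well-timed dopamine burst overlaps strong
postsynaptic activation; the second weakens them when the overlap falls
below baseline (an error-driven dopamine pause, or feedback so mistimed
that the burst misses the glutamate window); the third weakens synapses
whose postsynaptic activation lands between the AMPA and NMDA receptor
thresholds. Below the AMPA threshold with baseline overlap nothing changes.

Dopamine itself follows reward prediction error. A Bush-Mosteller single
operator tracks the predicted reward (`RP`, learning rate 0.075, initial
value 0.5 = maximal uncertainty); `RPE = R - RP`; the trial's dopamine
level is `D = clip(D_base + 0.8 RPE, 0, 1)` with baseline `D_base = 0.2`.
A regular-spiking dopamine neuron fires tonically and receives a current
step proportional to `D - D_base` for 100 ms starting at
`response time + feedback delay`: a burst for positive RPE, a pause for
negative RPE.

## Why the model cares about feedback delay

The glutamate trace of a trial's MSN spikes (which end at the response)
rises from about 300 ms after the response, peaks near 500-700 ms, and
decays by roughly 2 s. A dopamine burst at a 500 ms delay lands on the
peak; at 0 ms it leads the trace; at 1000 ms it catches the falling flank;
at 2.5 s it misses entirely, leaving only the tonic-firing floor. Because
the dopamine-trace scale is calibrated so that tonic firing alone yields
`S_JD ~ D_base` for a typical trial, a 2.5 s delay produces neither
potentiation nor systematic depression — no learning, rather than
unlearning — which is exactly the empirical signature of long delays.

```{r overlap, eval = FALSE}
spk <- seq(-250, 0, by = 12.5)        # response-locked striatal burst
best <- optimal_delay(spk)
as.numeric(best)                       # ~500 ms
head(attr(best, "overlap"))            # full overlap-vs-delay curve
```

## Calibration protocol (frozen values)

Membrane constants are taken verbatim from the published MSN and
regular-spiking parameterizations, and the QIF constants from the standard
form. The quantities below are not published; each was calibrated once
against its stated behavioral target and then frozen in
`striat_constants()`. They are deliberately not fit per condition — only
`sigma_C` differs between experiments, to model the visual mask.

* **Projection gains** (`g_ctx = 1`, `g_msn_gpi = 100`, `I_gpi = 120`,
  `g_gpi_thal = 40`, `I_thal = 100`, `g_thal_pm = 60`, `g_pm_pm = 40`):
  set so an untrained network (weights uniform in \[0.15, 0.35\]) responds
  near chance with response times of 300-700 ms, and a differentiated
  network (0.7 vs 0.15) responds correctly on > 90% of trials.
* **MSN lateral inhibition** (`g_msn_msn = 250`): strong winner-take-all
  at the striatal level. This is the credit-assignment mechanism — with
  weak lateral inhibition both MSNs fire comparably, the dopamine burst
  potentiates both channels equally, and learning stalls near chance.
* **Premotor integration** (`tau_pm = 150` ms): sets the response-time
  scale. Much faster integration makes trained responses so quick that the
  glutamate trace has barely risen when an immediate (0 ms) burst decays,
  exaggerating the delay-0 deficit.
* **Trace scales** (`overlap_scale = 6.6e-5`, `S_J_scale = 1e-3`): place
  tonic-only overlap near `D_base` and typical burst-driven overlap at
  0.4-1.2.
* **Receptor thresholds** (`theta_AMPA = 1.1`, `theta_NMDA = 3.8`): the
  20th and 60th percentiles of the untrained network's realized `S_J`
  distribution.
* **Learning rates** (`alpha_w = 3e-4`, `beta_w = 5e-5`, `gamma_w = 1e-6`):
  set so the 500 ms condition reaches a final-block accuracy near 0.80 in
  5 blocks of 80 trials. Depression must be an order of magnitude slower
  than potentiation: line 2 applies to the losing channel on every trial,
  and overly fast depression drains the weight matrix faster than correct
  trials can build it.
* **Premotor noise** (`sigma_C = 12` baseline, `198` masked): the race
  integrates white noise away, so accuracy is flat in `sigma_C` up to
  ~150 and then degrades steeply; the masked value reproduces the ~0.73
  final-block accuracy of the masked 500 ms condition. This is the only
  constant that differs between simulated experiments.

## The stimulus generator

The paper's category structures are published only graphically, so the
generator defines them parametrically. The II structure uses bivariate
Gaussians mirrored about the 45 degree bound (means (40, 60) and (60, 40)
in the normalized \[0, 100\]^2 space, covariance elongated along the bound)
with the dispersion chosen so the optimal bound attains ~0.95 while the
best one-dimensional rule attains ~0.75 — the qualitative gap that defines
an II task. The RB structure puts the same 0.95 optimum on a single
dimension. Label sequences are balanced to within one trial and shuffled.
All parameters can be overridden through `make_structure()` or the
`stimuli:` config section.

What the generator deliberately does not emulate: perceptual scaling of
physical units (cycles/degree, degrees of tilt), trial-to-trial perceptual
noise (the model's only stochasticity is premotor noise, initial weights,
and spike timing), session breaks, and participant heterogeneity beyond the
strategy mixture. Passing tests therefore show that the *mechanism*
produces the delay-sensitivity pattern under the stated study conditions,
not that it quantitatively fits any individual human learner.

## Study conditions and problem sizes

`run_condition()` reproduces the three simulated experiments at their
published scale — 80-trial blocks, 50 independent replications with fresh
weights, feedback delay fixed (0, 500, 1000, 2500 ms) or Gaussian
(mean 500, SD 75 or 150 ms, truncated at 0):

```{r conditions, eval = FALSE}
lc <- run_condition(condition_spec(delay_ms = 500, n_blocks = 5, seed = 1))
lc$curve          # per-block mean / sd / se over 50 replications

masked <- condition_spec(delay_ms = 500, n_blocks = 4,
                         sigma_C = striat_constants()$network$sigma_C_mask,
                         seed = 1)
```

The 4-block design with elevated `sigma_C` models the masked 2003
experiment; 5-block designs model the 2013 experiments. Human samples mix
strategies, so predicted group accuracy combines the procedural curve with
the best-1D-rule accuracy (`best_1d_rule_accuracy()`) and chance via
`mixture_accuracy()`; with counts (15, 4, 1) this is
`0.75 x procedural + 0.20 x rule + 0.05 x 0.5`. `variance_accounted()`
computes the percent of variance in observed block means captured by
predicted ones; the package ships no digitized human curves, so observed
means are a user input.

## Numerical choices and degenerate inputs

* Traces are sampled at 1 ms on `[-700, max(4000, delay + tail)]` ms
  around the response; the overlap is a trapezoidal sum, tested to < 0.1%
  against an independent quadrature.
* Feedback delay is measured from the response (= stimulus offset), which
  is also the origin of the trace time axis. Random delays are truncated
  at 0 ms.
* The response race breaks exact ties (and no-crossing trials) uniformly
  at random; with `sigma_C = 0` and fixed weights a trial is
  bit-reproducible under a fixed seed.
* Weights are clipped into \[0, 1\] only if a pathological parameter
  choice would exit the interval, with a warning; at the frozen rates the
  update cannot leave the interval.
* A silent MSN has `S_J = S_JD = 0`: its active synapses are weakened
  through line 2, the printed form of "any factor absent weakens the
  synapse".
* Stimuli outside the normalized space are clipped to the boundary with a
  warning.

## Known limitations

* At a 0 ms delay the model learns, but more weakly than human 0 ms groups
  (final block ~0.55 vs ~0.72): trained responses are fast enough that an
  immediate burst decays before the lagged glutamate trace rises. The
  qualitative ordering (500 best, 0 and 1000 worse, 2500 absent) is robust.
* `S_JD` is compared against the scalar `D_base` exactly as the update
  rule is printed, although the two quantities scale differently (the
  overlap grows with MSN spike count). The trace scales are calibrated so
  the comparison is meaningful in the regime the network actually visits;
  far outside that regime (for example, enormous spike counts from
  hand-built inputs) line 1 can potentiate without reward.
* The explicit-rule system is not modeled mechanistically; rule users
  enter only through the accuracy mixture. Decision-bound strategy
  classification of real participants is out of scope.
* One dopamine neuron stands in for the population; the reward network
  upstream of it is abstracted into the RPE drive.
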