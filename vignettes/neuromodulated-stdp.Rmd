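---
title: "Neuromodulated STDP and receptive-field plasticity: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neuromodulated STDP and receptive-field plasticity: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stdpmod)
```

## The scientific question

Neuromodulators (acetylcholine, noradrenaline, dopamine) regulate cortical
plasticity through at least two distinct mechanisms: they *gate learning*,
reshaping the spike-timing-dependent plasticity (STDP) window itself, and
they *upregulate activity*, for example by suppressing inhibition. This
package implements a deliberately minimal feedforward model to ask two
questions:

1. How do differently shaped STDP windows — stand-ins for different
   neuromodulatory states — affect the development and adaptation of a
   receptive field?
2. Is increasing the learning rate equivalent to increasing presynaptic
   activity? (It is not: the two modulations dissociate.)

The model is a bank of feature-tuned input neurons firing as correlated
inhomogeneous Poisson processes, projecting onto one postsynaptic neuron.
Synapses are plastic under one of four pair-based STDP windows, named by the
sign of their acausal/causal branches:

* **DP** (Depression–Potentiation): the standard antisymmetric Hebbian
  window — `t_pre < t_post` potentiates, the reverse depresses.
* **PP** (Potentiation–Potentiation): every pairing potentiates.
* **UP** (Unchanged–Potentiation): causal pairings only.
* **DU** (Depression–Unchanged): acausal pairings only, depressing.

A branch contributes `alpha * a * exp(-|dt|/tau)` per spike pair, with
`dt = t_post - t_pre`, `|a| = 0.01` and `tau = 20 ms` on active branches by
default, and a global learning-rate multiplier `alpha` (the gating knob).
Exactly coincident spikes contribute nothing. An optional triplet extension
adds the standard two-slow-trace nonlinearity (slow time constants 101 ms
and 125 ms) and reduces exactly to the pair rule when its amplitudes are
zero.

## The input ensemble

`input_ensemble_config()` describes the afferent bank. Independent rate
"signals" — one per feature channel — follow an exact-step
Ornstein–Uhlenbeck process with correlation time `signal_timescale`
(default 50 ms), rectified at 0 Hz on emission. The latent mean is shifted
analytically so that the rectified signal averages exactly `base_rate`.
Each neuron's rate is a row-normalized Gaussian mixture of the signals over
index distance (`mixing_width`, default 1 index), so neighboring inputs
(similar tone frequency, similar orientation) co-fluctuate while every
input keeps the same mean rate. Spikes are Bernoulli-sampled per 0.1 ms bin
(`rate * dt < 1` enforced; at most one spike per bin).

A "training input" can be over-represented: its rate is multiplied by
`training_gain` (2.0 = "100% stronger") and its immediate neighbors by half
the excess (1.5), a configurable profile. Feature axes are not circular, so
the default boundary mode clips rather than wraps.

What the generator emulates — and what it does not: it produces stationary,
feature-correlated stochastic drive with a controllable burst structure. It
has no stimulus sequence structure, no adaptation, no across-trial
nonstationarity, and no inhibitory pathway; conclusions from these
simulations are about the plasticity dynamics under stationary statistics,
not about responses to structured sensory episodes.

## The postsynaptic neuron

`neuron_params()` defines a current-based leaky integrate-and-fire neuron
(membrane time constant 20 ms, threshold 20 units above rest, reset to
rest, 2 ms refractory period). Each presynaptic spike injects a current
step `weight * syn_gain` decaying with `tau_syn = 2 ms`; with the default
`syn_gain = 10`, a synapse at the strong probe weight `w = 7` produces an
EPSP of roughly a quarter of the rest-to-threshold distance, and a synapse
at `w = 3` roughly a tenth.

Spike emission uses **escape noise with a saturating hazard**: spikes are
emitted stochastically at rate

    lambda(V) = r0 * exp((V - V_T) / Delta)  /  (1 + r0 * exp((V - V_T)/Delta) / lambda_max)

with `r0 = 500 Hz`, `Delta = 3` voltage units and `lambda_max = 250 Hz`,
followed by reset and refractoriness. The hazard is cut to zero more than
six e-folds below threshold, so a neuron at rest with no background current
is strictly silent. A hard deterministic threshold (`escape_width = 0`)
with an optional Gaussian white noise current (`noise_sd`) is retained as a
variant.

This choice is the central design decision of the neuron module, made after
exploring the alternatives:

* With a *hard threshold and diffusive noise* at a 10 Hz baseline, the
  stationary membrane distribution is broad near threshold, and the
  postsynaptic response to an EPSP is nearly linear in its amplitude. The
  relative weight change `dw/w` then barely depends on `w`, and the
  weight-dependence orderings of the modulation experiments do not emerge
  robustly.
* The *exponential* escape hazard makes the response to a strong EPSP
  supralinear (a strong synapse recruits spikes far more effectively per
  unit weight than a weak one), which produces the low-rate regime where
  strong weights grow relatively faster.
* The *saturation* of the hazard is what turns the output rate into a
  competitive signal: once the neuron is strongly driven, additional input
  recruits few extra causal pairings while acausal chance pairings keep
  growing with the output rate. Without it, causal and acausal terms both
  scale multiplicatively with the output rate and the slight depression
  excess of the DP window can never win for any synapse — competitive
  symmetry breaking requires this saturation.

The mean background current `noise_mean` is calibrated once by
deterministic bisection (`calibrate_noise()`, common random numbers across
candidates) so the zero-weight firing rate is 10 Hz; the shipped default
(9.64) gives 10.0 Hz averaged over ten 100 s runs. Integration is forward
Euler at `dt = 0.1 ms` on a clock shared with the input sampler.

## Plasticity implementation and its oracles

The simulation engine (C++ via Rcpp) implements the all-to-all pair rule
with exponentially decaying eligibility traces — one presynaptic trace per
synapse per branch, one postsynaptic trace per branch — updated per time
step; trace increments happen at the end of a step, so same-bin pre/post
pairs contribute zero, matching the `dt = 0` convention. The triplet
extension multiplies the branch amplitude by the slow trace of the
triggering side, evaluated just before the triggering spike; with zero
triplet amplitudes the engine's arithmetic is unchanged, so pair-rule and
zero-triplet trajectories are bit-identical.

Two independent oracles guard this machinery:

* `brute_force_pair_sum()` enumerates every (pre, post) pair;
  `brute_force_triplet_sum()` enumerates the triplet interactions
  exhaustively.
* `online_stdp()` is an event-driven R implementation with exact
  exponential decays between events.

The test suite checks `online_stdp()` against both enumerations at 1e-12
relative tolerance on random trains (including exact coincidences), and the
C++ engine against the pair sum on its own emitted spike trains.

Weights are hard-clipped to `[0, 10]` after every update (additive STDP
with hard bounds — the regime whose signature is a bimodal final weight
distribution). Optional normalization restores the initial weight sum at
100 ms intervals under one of two schemes: multiplicative rescaling
(shape-preserving, the exported `normalize_weights()` default) or a uniform
subtractive shift solved under the bound clipping. The experiments use the
subtractive scheme by default because it is the competitive one: equal
additive growth plus multiplicative rescaling flattens a tuning curve
(small weights gain relatively more), whereas the subtractive scheme
removes the common component of growth so that only differential,
correlation-driven growth survives — which is what sharpens tuning under
potentiation-dominated windows and flattens it under DU.

## The experiments and their frozen conditions

All experiment-level parameters that the underlying study left unstated
were fixed once, during model exploration, and are recorded here; every
value is an explicit argument and can be changed.

**Symmetry breaking** (`run_symmetry_breaking()`): many inputs (100 by
default; 50 in the scaled-down test runs) with equal initial weights at 10%
of the ceiling, weakly modulated rates (signal sd 30% of the 10 Hz base)
and `alpha = 2` for DP. The DP window carries a 2% depression excess, so
its integral is slightly negative. Starting weak and learning slowly lets
correlated clusters differentiate while crossing the bistable region:
winners reach the ceiling, the rising output rate strengthens acausal
depression, and the rest are driven to the floor — a genuinely two-sided
bimodal distribution (upper and lower modes both populated), not uniform
saturation. This development takes ~2000 s of simulated time: the net
drift under the near-balanced window is the small residual of two large
opposing terms. The monotone rules need no such residual and run at
`alpha = 6`, reaching their bound within 10 s.

**Receptive-field adaptation** (`run_rf_adaptation()`): 10 inputs at 5 Hz,
strongly modulated (signal sd 80% of base — burst-like co-activation is
what lets the boosted training cluster recruit the postsynaptic neuron),
initial Gaussian tuning peaked at input 7 with peak 45% of the ceiling and
baseline 20%, `alpha = 2.3`, 40 s horizon, trajectories averaged over
trials. The initial peak is set at 45% rather than higher because the
hard upper bound otherwise pins the initially preferred weight before the
boosted training input (input 4, 100% stronger, neighbors 50%) can
overtake it within the horizon; with this profile the potentiation-only
rules shift the preference (the "input specificity" `w4 - w7` crosses
zero) while DP keeps its peak at input 7 at 40 s and DU depresses
everything, its specificity relaxing toward zero from below.

**Normalized adaptation** (`run_rf_adaptation_normalized()`): the same
protocol with subtractive normalization, 200 s horizon for the
sharpening/flattening comparisons and 400 s for the boosted peak shift
(competition under a conserved weight budget is slower than unconstrained
saturation).

**Modulation sweeps** (`run_modulation_pair_sweep()`): one presynaptic
neuron at constant rate `nu`, standard antisymmetric window with unit
branch amplitudes, learning rate `alpha` around the reference
`alpha0 = 5e-4`, probe weights `w in {3, 7}`. The weight is *frozen* at its
probe value: plasticity is accumulated without being applied, so `dw/w`
measures the instantaneous modulation state rather than a trajectory. A
consequence of this protocol is that `dw/w` is exactly proportional to
`alpha` for a fixed noise stream — the fitted line through the origin and
its residual are still reported. Ten-second trials; 200 trials per grid
point at full scale.

**Network modulation** (`run_modulation_network()`): 10 inputs with the
tuned profile peaked at input 7 (peak 7.0, baseline 2.0), the antisymmetric
window at `alpha in {0.01, 0.02}` and `nu in {1, 10}` Hz, 150 s, final
tuning curves rescaled to unit maximum and compared by width at half
maximum (linearly interpolated; a flat curve returns the full index
extent by convention).

## Numerical choices

* Time step 0.1 ms everywhere; `rate * dt` stays well below 1 at all rates
  used, and the step resolves the 20 ms STDP time constants and the 2 ms
  synaptic kernel.
* Spike times are bin centers; the engine works on integer steps, so
  pre/post coincidence is exact and excluded on both sides.
* Seeds: every experiment takes one master seed and expands it into
  per-trial seeds via R's RNG; a trial rerun alone with its derived seed
  reproduces its batched result bit-for-bit.
* The subtractive normalization offset is solved by 60 bisection steps on
  the clipped sum (monotone in the offset), giving machine-precision sum
  conservation whenever clipping does not bind.
* `calibrate_noise()` evaluates every candidate mean current on the same
  noise realization, making the estimated rate monotone in the parameter
  and the bisection deterministic for a given seed.

## Scaled-down test conditions

The shipped test suite runs the full pipeline at reduced scale: 50 inputs
instead of 100 for symmetry breaking, 8–10 trials instead of 100 for the
adaptation experiments, 100–200 trials instead of 200 for the sweep grid
points, and 15–40 trials instead of 50 for the network modulation runs,
with assertions on orderings and signs rather than exact magnitudes. These
sizes were chosen so the documented effects are several standard errors
wide at test scale; the full-scale defaults remain the function defaults
where feasible.

## Known limitations

* One postsynaptic neuron; inhibition and disinhibition are represented
  only implicitly through the rate and learning-rate parameters.
* The neuron model is a calibrated stand-in: the original study's
  postsynaptic model is not derivable from its main text, and the results
  here were verified robust to the pair-vs-triplet rule choice but not to
  every conceivable neuron model.
* Conductance-based synapses, voltage/calcium plasticity models and
  reward-modulated three-factor rules are out of scope.
* Weight dependence is additive with hard bounds; soft-bound
  (multiplicative) STDP would change the weight distributions
  qualitatively.
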