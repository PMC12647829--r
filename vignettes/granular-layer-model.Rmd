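---
title: "A calibrated spiking model of the cerebellar granular layer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A calibrated spiking model of the cerebellar granular layer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

The cerebellar granular layer expands a few hundred mossy-fiber (MF) inputs
onto thousands of granule cells (GrCs) under the inhibitory control of a
handful of Golgi cells (GoCs). `grclayer` reconstructs a local volume of this
circuit — cell placement, the five synapse classes, conductance-based
leaky integrate-and-fire (LIF) dynamics — drives it with spatially
correlated binary MF activity patterns, and analyzes the resulting
population code with rate-based response measures, a linear decoder and
population coding metrics. This vignette documents the model, its
assumptions, the calibration of its free constants, and what the synthetic
protocols can and cannot say about real tissue.

## The anatomical model

Cells live in a cube (default side 100 µm) whose opposite faces are
identified, so all distances are toroidal and there are no boundary
artifacts. Populations are placed by sequential random placement with
per-population exclusion radii (uniform positions conditional on a minimum
inter-soma distance) and Poisson-distributed counts around
`density x volume`. Default densities put ≈300 glomeruli (one per MF),
≈3700 GrCs and ≈8 GoCs in the default volume.

Five synapse classes are wired from geometry:

* **MF→GrC** — each GrC contacts its 4 nearest glomeruli within a 40 µm
  dendritic reach (exactly four distinct afferents; ties broken by seeded
  random draws).
* **MF→GoC** — glomeruli within the 50 µm basal-dendrite field, subsampled
  to a convergence target (default 100).
* **GrC→GoC** via ascending axon — GrCs whose vertical axon passes within
  the 50 µm apical field (lateral x–y distance), subsampled to 400.
* **GrC→GoC** via parallel fiber — GrCs whose full-length x-axis fiber
  passes within the apical field (y–z distance), subsampled to 1200.
* **GoC→GrC** — a GoC inhibits every GrC that contacts at least one
  glomerulus inside its 100 µm axonal field, one synapse per pair.

The reaches and convergence targets are provisional defaults from the
granular-layer modelling literature and are all exposed in
`connectivity_config()`; the tested contract is the wiring rules, the
exact-4 MF convergence, degree bookkeeping and translation invariance on
the torus.

## Input patterns

`generate_patterns()` draws binary MF patterns by dichotomizing a latent
Gaussian field: fibers i, j have latent correlation
`exp(-d_ij^2 / (2 sigma^2))` with `d` toroidal, and each fiber is active
when its latent value exceeds the upper-`f` normal quantile, so the marginal
active probability is exactly `f`. Large `sigma` produces spatial clusters
of co-active fibers; `sigma -> 0` gives independent coin flips.

The distance kernel is used directly as the latent correlation (no inverse
dichotomization), so the *binary* correlations are lower than the latent
ones; the observable contract is the calibrated marginal and the
distance-decaying co-activation. The toroidal Gaussian kernel is not
guaranteed positive definite. A minimal diagonal ridge (≤ 1e-6) is tried
first; when the deficit is larger — common at `sigma` ≥ 20 µm — the
covariance is repaired by clamping negative eigenvalues to zero and
rescaling to unit marginal variances. The repair shifts pairwise
correlations slightly; the test suite validates the dichotomization against
bivariate-normal orthant probabilities computed at the *repaired*
correlations.

One practical consequence of large `sigma`: a single draw realizes an
active fraction that can be far from `f` (few independent clusters fit in
the volume; we observed realized fractions from 0.02 to 0.57 at
`sigma = 40`). Stimulation protocols that present a single pattern therefore
select a draw whose realized fraction matches the target within 0.005 (or
the fiber-count granularity, if coarser), mirroring the experimental
practice of selecting stimuli by their active-fiber share. Pattern *sets*
for the decoder are used as drawn.

`apply_noise()` re-samples the state of exactly `round(noise_frac x n_MF)`
fibers, each becoming active with probability `f`, which preserves the
set-average activity in expectation.

## Neuron model and integration

Both populations are conductance-based LIF neurons:

    Cm dV/dt = gA(t) (E_ampa - V) + gG(t) (E_gaba - V) + g_rest (E_rest - V)

with each receptor conductance incremented by the synaptic peak weight on
spike arrival and decaying exponentially (`tau_ampa`, `tau_gaba`).
Integration is time-driven (default `dt` = 0.1 ms, required ≤ min(tau)/5):
conductances decay, delayed increments are applied, then the membrane
advances by the exponential-Euler closed form treating each conductance as
constant within the step *at its exact step average*
`g (tau/dt)(1 - exp(-dt/tau))`. The step average matters: with the
step-start value the charge delivered per synaptic event grows with `dt`
(≈10% at 0.1 ms for `tau` = 0.5 ms) and halving `dt` shifted population
spike counts by >10%; with the average the per-event charge is exact for
any `dt` and the halving test passes below 1%. Threshold crossing emits a
spike, resets `V` and clamps it for the absolute refractory period.
Synaptic delays default to 1 ms everywhere (not stated by the source
model); all delays are configuration.

Synaptic weights follow the published calibration: MF→GrC total 4.0 nS
split over the four dendrites (1.0 nS each), GoC→GrC fixed at 0.5 nS, and
the inhibition level steered through the feedforward (MF→GoC) and feedback
(GrC→GoC) drives — 0.1 and 0.015 nS in the control condition, both zero in
the DART condition (blocked inhibition: silent GoCs), and the named
`weight_presets()` spanning Feedforward/Feedback/Combined at two strengths.

### Calibration of the LIF constants

The source model's per-population constants live in supplementary material
that is not part of the published text, so they are re-derived here from
the functional constraints the text does state, in this order of authority:

1. a GrC with 1.0 nS AMPA synapses needs **at least three near-coincident
   MF spikes** to fire — one or two must not suffice;
2. the population mean firing probability (50 ms windows) under
   auditory-like stimulation (f = 0.45, 50 Hz, sigma = 5 µm, 3 s) is ≈0.13
   with inhibition and ≈0.34 without;
3. the somatosensory-like protocol (f = 0.35, 100 Hz, sigma = 40 µm,
   500 ms) gives ≈0.08 with inhibition.

The resulting defaults are GrC {Cm 3 pF, g_rest 0.3 nS (tau_m 10 ms),
E_rest −70 mV, V_th −48.5 mV, V_reset −70 mV, refractory 1 ms, tau_ampa
0.5 ms, tau_gaba 10 ms} and GoC {Cm 28 pF, g_rest 3 nS, E_rest −65 mV,
V_th −54 mV, V_reset −67 mV, refractory 2 ms, tau_ampa 1.5 ms, tau_gaba
10 ms}, with MF→GoC convergence 100. Under these constants the model
reproduces 0.136 / 0.346 / 0.075 for the three probability targets
(averaged over protocol seeds). The
constants are a consistent solution, not a unique one; they are all
exposed through `neuron_params()`.

A related caveat: even with the fraction matched, *which* clusters a
`sigma = 40` pattern activates relative to the Golgi cells changes the
somatosensory response probability substantially from draw to draw
(0.04-0.12 observed across seeds around a mean of ~0.08). Reported
somatosensory summaries therefore average the protocol over five
independent pattern draws.

## Response analysis

* `dff_trace()` — the fluorescence-change analog: firing-rate change in
  50 ms windows divided by the pre-stimulus baseline rate. Silent-baseline
  cells use a floor of one spike per baseline duration, which keeps
  silent-then-active cells finite and monotone in their stimulus rate.
* `response_probability()` — per cell, the fraction of 50 ms stimulus
  windows (pooled over trials) containing at least one spike.
* `significant_responders()` — per cell, a paired t-test across trials of
  stimulus- vs baseline-window rates (p < 0.05, positive change).
  `sensory_summary()` additionally requires a mean amplitude above 7 dF/F
  units for a cell to count as a *responder*; this floor is the package's
  operational reading of "significant response" and was fixed, once,
  against the published responder census of the auditory protocol
  (control ≈14% of cells, blocked inhibition ≈50%). With a 3-second
  stimulus and ten trials the bare t-test alone is so powerful that over
  half the population is "significant" at vanishing effect sizes, which is
  clearly not what an imaging-based census counts.
* `categorize_multisensory()` — the four-way classification of combined-
  stimulus responses. The threshold T is the larger of the two individual
  mean responses and M the largest per-trial peak over the individual
  patterns; a response at exactly T counts as above threshold, but a
  non-positive response never does (so cells silent for both individual
  stimuli and driven by the combination are *emergent*). The protocol-level
  `combined_categories()` feeds it responder-gated means and a per-cell
  tolerance band (the 95% CI half-width of the trial-wise difference
  between the combination and the stronger individual); without the band,
  Poisson fluctuation alone would label about half of all matched cells
  suppressed or facilitated, which contradicts the near-absence of
  suppressed cells when inhibition is blocked.
* `preference_analysis()` — argmax stimulus preference with ties to the
  lowest index and per-cell max-normalized responses.

## Decoder and coding metrics

`train_slp()` is a single-layer perceptron: linear map plus softmax,
categorical cross-entropy, mini-batch SGD (batch 32, learning rate 0.001),
raw spike counts as input, 70/10/20 train/validation/test split, early
stopping on validation accuracy (patience 5) or a fixed epoch budget (50
for the quick protocol, 500 for the noisy sweeps). Initialization is small
seeded uniform noise. One point worth stressing: the classification task
assigns *random* classes to patterns, so a decoder can only generalize
across repeated noisy presentations of the same patterns — with a single
presentation per pattern the test set consists of never-seen patterns with
random labels and accuracy is chance by construction. All classification
protocols therefore present every pattern repeatedly (default 10 times).

The population metrics are the standard ones: population sparseness
`(N - (Σx)^2/Σx^2)/(N-1)` averaged over patterns (all-zero patterns
contribute 0), total variance (the covariance trace, computed through the
smaller Gram matrix when neurons outnumber samples), population correlation
`N/(N-1) (max(sqrt(lambda))/Σ sqrt(lambda) - 1/N)` with tiny negative
eigenvalues clamped at 1e-10 of the largest, and mean pairwise Jaccard
overlap of active cell sets (the intersection-over-minimum variant is an
option; two empty sets count as identical).

## Problem sizes, determinism and reproducibility

Protocol-level analyses run at the study's own sizes: a 100 µm cube
(≈4000 neurons), ten trials per condition, 640-pattern classification with
ten presentations (6400 samples). The test suite exercises the wiring and
analysis logic on a 25 µm fixture and reserves full-scale runs for the
reproduction checks. Every source of randomness draws from a named
sub-seed of the user-facing seed (placement, wiring, patterns, labels,
per-trial Poisson drive, per-presentation noise, decoder splits and
initialization), so every deterministic stage reproduces bit-identically
from its manifest and every stochastic stage distributionally.

## Known limitations

* The reconstruction reproduces the sensory-protocol probability and
  responder-census targets, but two quantities resist the joint fit: the
  control-condition responder amplitude comes out high (≈9.5 vs ≈6.6 dF/F
  units — any responder cut that yields a ≈15% census forces the mean
  amplitude of the selected cells above that cut), and in the combined
  protocol the inhibition recruited by the union pattern (f ≈ 0.64) is
  strong enough to suppress it globally, leaving no emergent cells in the
  control condition, where the source model reports ≈5%. Both trace back
  to how steeply GoC output grows with total MF drive, a property the
  published text does not pin down.
* Gap junctions between GoCs, Lugaro and unipolar brush cells, tonic
  inhibition, NMDA/spillover conductances and all forms of plasticity are
  deliberately absent, as in the source model.
* GoC axonal fields are isotropic spheres; real GoC axons are anisotropic
  in the sagittal plane.
* The dichotomized-Gaussian patterns are stationary within a presentation;
  there are no within-pattern rate envelopes.
* Passing the synthetic protocols shows the circuit logic and analysis
  chain are faithful at the model's scale; it does not validate the model
  against raw imaging data, which the package never ingests.
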