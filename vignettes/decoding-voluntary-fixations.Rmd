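---
title: "Decoding voluntary eye fixations from single-trial MEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding voluntary eye fixations from single-trial MEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Gaze-based interfaces issue a command when the user's eyes dwell on a target
for longer than a threshold (here 500 ms). The hard part is that spontaneous
dwells — eyes resting on a target during natural exploration — look exactly
like intentional ones to the eye tracker, so the interface fires false
selections. A passive brain-signal classifier can in principle tell the two
apart: an intentional dwell is accompanied by preparatory and
feedback-expectation brain activity that a spontaneous dwell lacks.
`fixdecode` implements the full analysis chain for this question on epoched
planar-gradiometer MEG: dwell labeling from gaze logs, epoch preprocessing,
two compact convolutional decoders, nested cross-validated evaluation with
permutation significance, and an interpretability chain that maps the
decoders' spatial weights back onto the sensors.

Real recordings of this paradigm are not publicly downloadable, so the
package ships a synthetic generator that plants the assumed signal structure
with known ground truth; every stage of the pipeline is exercised end to end
against that ground truth.

## Trial taxonomy

`label_fixations()` classifies every ball dwell in a gaze event log:

* dwells shorter than the 500 ms threshold never trigger feedback and are
  excluded (`below-threshold`);
* dwells whose first detected fixation starts more than 50 ms after the
  dwell onset are excluded (`late-onset`);
* dwells that end within 500 ms of the selection feedback **and** are
  followed by a confirmation fixation within 200 ms are voluntary;
* dwells followed by a confirmation outside those windows are excluded
  (`delayed-confirmation`) — a late confirmation may be a post-hoc decision
  on a dwell that was actually spontaneous;
* dwells not followed by a confirmation at all are spontaneous.

The 200 ms confirmation window is anchored at the dwell end by default. The
alternative anchoring at the feedback time is stricter (it rejects any dwell
ending later than 200 ms after feedback) and is available via
`confirm_anchor = "feedback"`; only the dwell-end reading admits the full
range of dwell lengths the 500 ms saccade window allows, which is why it is
the default.

Class balancing (`balance_classes()`) removes uniformly random trials from
the larger class (in this paradigm, always the spontaneous one) and
participants with fewer than 70 voluntary trials are dropped
(`participant_filter()`).

## Preprocessing

`preprocess_epochs()` runs crop → lowpass → normalise → decimate:

1. **Crop** to the analysis window, half-open `[start, end)` relative to
   fixation onset. The main window is −0.2…0.5 s (all data available before
   the interface feedback); the control window −0.2…1.0 s additionally
   contains the feedback response.
2. **Lowpass below 45 Hz**, zero phase. The filter is a linear-phase
   windowed-sinc FIR (order `0.192 × fs`, i.e. 193 taps at 1000 Hz) applied
   with odd-reflection padding and group-delay compensation. Zero phase
   matters because a phase shift would misalign the 0.5 s feedback landmark
   across frequencies. The design attenuates the post-decimation Nyquist
   (62.5 Hz) by ~55 dB in steady state; edge transients are confined to
   roughly half a kernel length (~0.1 s) per epoch edge, which is
   unavoidable for any finite-epoch filter.
3. **Normalise per trial**: subtract each channel's mean over the trial and
   divide by the single pooled standard deviation of the centred trial
   (idempotent; a constant trial raises rather than emitting NaN).
4. **Decimate to 125 Hz** by keeping every 8th sample from the first one,
   output length floored — the only convention that maps a 700-sample
   (0.7 s) epoch to exactly 87 timepoints.

The canonical network input is therefore 204 × 87 (short window) or
204 × 150 (long window).

## The decoders

Both variants share a generative premise: the sensor data are a linear
mixture of a small number of latent sources, `X = A S + noise`. The first
layer is a spatial convolution `W` (channels × k, default k = 16) projecting
each trial onto k latent time courses. The temporal layer differs:

* **LF** — one FIR filter of 14 samples per latent source, no cross-source
  mixing: each source has its own spectral fingerprint;
* **VAR** — a spatiotemporal (vector-autoregressive) filter bank
  (k × k × 14): each filtered output draws on all k sources.

ReLU, non-overlapping max-pooling over 4 adjacent samples ("same" temporal
padding, so the pooled length is `floor(n_times / 4)` = 21 for the short
window), dropout (0.5), and a single dense softmax layer over the two
classes complete the network. Training minimises binary cross-entropy with
Adam (batch 100, learning rate 3e-4) plus an l1 penalty (3e-4) on both
convolutional layers; all randomness (initialisation, batch order, dropout)
derives from one seed, so training is bit-reproducible. The forward and
backward passes are implemented in compiled code and verified against
finite-difference gradients in the test suite.

Two initialisation choices are deliberate. Convolutional layers use
Glorot-scaled Gaussians. The dense output layer starts near zero
(sd 0.01): the magnitude of a trained output weight then reflects the
latent source's learned contribution rather than the initialisation scale,
which the latent-source attribution below relies on; empirically this also
acts as a strong implicit regulariser (the spatial layer moves only once
the readout has formed) and improves held-out AUC noticeably.

"Training iterations" means minibatch updates; the validation AUC is
recorded after every update into the model's trace.

## Evaluation

`nested_cv()` follows a two-loop design. The outer loop is stratified
5-fold CV for test performance. Within each outer training set, an inner
stratified 4-fold CV (train:validation 3:1) trains one model per fold; the
optimal iteration count is the mean over inner folds of the earliest index
at which each validation trace attains its maximum (`select_iterations()`,
rounded, floor 1). Two test estimates follow:

* **naive** — a fresh model retrained on the entire outer training set for
  the optimal number of iterations;
* **ensemble** — the four inner models' voluntary-class probabilities on
  the test fold, averaged.

Each test AUC gets a label-permutation p-value
(`p = (1 + #{permuted AUC >= observed}) / (n_perm + 1)`, default 1000
permutations). AUC is the Mann–Whitney concordance probability with ties
credited 0.5. `group_summary()` aggregates participants: mean ± SD per
metric, Pearson correlation between test AUC and trials per class, and a
paired two-sided Wilcoxon signed-rank test between the two variants (p
defined as 1 when all paired differences vanish).

One behaviour worth knowing: on data so separable that the inner validation
traces saturate within a few updates, the earliest-maximum rule selects a
very small iteration budget, and the naive model retrained from a fresh
initialisation for that budget is not guaranteed to have converged — the
ensemble (whose members train to the full cap) is the more reliable
estimate in that regime. The test suite pins this down.

## Interpretation

Spatial filters are not directly interpretable; the package converts them
to activation patterns via the covariance transform
`A = Σ_X W Σ_Ŝ⁻¹` (`compute_patterns()`), where `Σ_X` is the channel
covariance of the data concatenated over trials and time and `Σ_Ŝ` the
covariance of the latent time courses `Ŝ = WᵀX`. `Σ_Ŝ` is inverted by
pseudo-inverse with a relative singular-value cutoff of 1e-10; a condition
number above 1e10 flags the result as degenerate (duplicated or dead
latents under strong regularisation).

Per-class latent-source contributions (`ls_class_weights()`) are the
normalised L1 norms of each source's output weights; they are nonnegative
and sum to 1, and for a well-regularised redundant model they fluctuate
near the mean weight 1/k. `average_pattern()` collapses pattern columns
under these weights (or uniformly). `fve_map()` reconstructs the sensor
signal from the latent subspace (`X_rec = A Ŝ`) and reports per channel the
squared Pearson correlation with the original, a fraction of explained
variance; `full_fve` is its unweighted mean over channels (constant
channels are flagged and excluded).

The ocular-artifact diagnostic (`frontal_diagnostic()`) correlates, across
latent sources, the L1 norm of frontal-sensor loadings with the L1 norm of
output weights for the voluntary class. A strongly positive correlation
indicates the classifier leans on frontal (eye-movement-prone) sources.
Either the patterns `A` or the raw filters `W` can supply the loadings; the
two are not interchangeable: the pattern transform renormalises every
latent by its variance, so latents pruned to near-zero filters still
receive full-size (junk) patterns, and only the filter-based loadings
separate live from pruned latents. The acceptance checks therefore use `W`.

Two identifiability caveats, established on synthetic ground truth:

* **Per-column pattern recovery degrades with latent redundancy.** Any
  rotation of the latent space leaves the model's predictions unchanged, so
  with k = 16 the individual pattern columns are arbitrary mixtures within
  the signal subspace (best single-column correlation with a planted source
  ~0.65); with a single-component decoder (k = 1) the pattern recovers the
  planted source topography essentially perfectly (|r| ≥ 0.99). Weighted
  *averages* of patterns remain meaningful at any k.
* **Dropout dilutes per-source attribution.** Redundant representations
  spread output weight nearly uniformly (≈1/k per source). The planted
  artifact diagnostic therefore trains its probe model without dropout and
  with a stronger l1 (3e-3), which prunes uninformative latents and
  concentrates output weight on the sources that drive classification.

## The synthetic generator

`simulate_epochs()` draws every trial as `X = A_true S + ε` with white
Gaussian sensor noise. The planted sources are:

* a **slow deflection** — a quarter-sine ramp from fixation onset to the
  0.5 s feedback time, then held — present only in voluntary trials,
  loading on left central/parietal sensors;
* an **evoked feedback transient** — a damped 5 Hz sinusoid over
  0.5–0.9 s — present in both classes with doubled voluntary gain;
* an optional **frontal artifact** — a smooth step at a random pre-feedback
  time, loading on the frontal sensors, stronger in voluntary trials
  (amplitude 0, i.e. absent, by default);
* **oscillatory background** — 10 Hz sinusoids with a fresh uniform random
  phase per trial, class-neutral.

Mixing columns are unit-norm spatial Gaussians on a schematic unit-disc
sensor layout (102 positions on concentric rings, two gradiometer channels
each; the top ~10% of channels by vertical coordinate form the frontal
mask). Defaults: 204 channels, 1000 Hz, epochs −0.2…1.0 s, 200 trials per
class, `noise_sd = 1`, `background_amplitude = 1`, `slow_amplitude = 0.4`,
`evoked_amplitude = 2.5`. The two effect amplitudes are free parameters of
the generator — nothing in the real paradigm pins them — and were
calibrated once so that the synthetic study reproduces the qualitative
regime of interest: the pre-feedback window is hard but clearly above the
permutation chance band (single-fold ensemble AUC roughly 0.72–0.91 across
seeds for the LF variant, higher for VAR), while the post-feedback window
is far easier (≈1.0), mirroring the characteristic jump when the feedback
response enters the epoch.

What the generator does **not** emulate: realistic head geometry and
forward fields, correlated sensor noise, non-stationary artifacts,
inter-participant variability in source topography, or vendor
interference-suppression preprocessing. Passing tests demonstrate that the
pipeline recovers what it assumes — linear mixtures of a few latent
sources — not that real MEG satisfies those assumptions.

## Desk-scale study conditions

The test suite and `scripts/acceptance.R` run everything at sizes chosen
for a single CPU:

* structural checks of the nested CV use 100 trials per class and a
  50-update training budget;
* the planted-effect detection and window-ordering checks use the full
  204-channel generator at 200 trials per class, seeds 1–5 (detection) and
  1–3 (ordering), a single outer fold per seed, and a 300-update budget —
  the point at which the LF ensemble has converged at these trial counts;
* the permutation type-I check and the artifact diagnostic run on reduced
  configurations (32 and 64 channels at 250 Hz, which decimates to the same
  87-sample epochs); both properties are indifferent to channel count and
  sampling rate;
* pattern recovery uses a high-SNR scenario (`slow_amplitude = 2`,
  `background_amplitude = 0.1`, `noise_sd = 0.1`) and a k = 1 decoder, per
  the identifiability caveat above.

## Numerical choices and degenerate inputs

* Decimation requires an integer factor; anything else is an error, never a
  silent resample.
* A constant (zero pooled SD) trial, a single-class training set, an empty
  trace, a missing class in CV, and an all-zero output-weight class each
  raise a descriptive error rather than propagating NaN.
* Ties in validation traces resolve to the earliest iteration; ties in AUC
  rank statistics use midranks (0.5 credit).
* The permutation p-value uses the add-one estimator, so p > 0 always.
* Fold assignment is stratified by class in both CV loops.
* `Σ_Ŝ` inversion uses a pseudo-inverse (relative cutoff 1e-10) with a
  degeneracy warning instead of failing on rank-deficient latents.

## Known limitations

* The decoders are trained by non-convex optimisation; only seeded
  reproducibility is guaranteed, not a global optimum.
* Per-column activation patterns are unidentifiable at redundant k (see
  above); use weighted averages or a compact decoder for source-level
  claims.
* The naive testing procedure inherits the early-stopping budget from the
  inner loop and can be undertrained when validation traces saturate
  immediately.
* The synthetic generator's effect sizes are stipulations, not estimates of
  any real dataset; absolute AUC values on synthetic data say nothing about
  real-data performance.
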