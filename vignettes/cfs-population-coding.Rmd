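---
title: "Population orientation coding under continuous flash suppression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population orientation coding under continuous flash suppression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cfspopcode)
```

## The scientific problem

Continuous flash suppression (CFS) is a dichoptic paradigm: a flashing
noise masker shown to one eye suppresses the visibility of a target
grating shown to the other. This package implements, end to end, the
analysis chain used to quantify how such interocular suppression degrades
orientation coding in a population of early-visual-cortex neurons recorded
with two-photon calcium imaging: cell detection from differential images,
per-neuron orientation tuning and ocular dominance, population tuning
curves and Fisher information, an ocular-dominance-dependent gain-control
model of the suppression, linear decoding, and image reconstruction with
a minimal self-attention network.

Every stage runs on data from the package's own synthetic generator, so
the whole chain is testable without any recording. The generator is a
forward model of the study design, not of a particular dataset; what
passing tests demonstrate is that the *analysis* recovers what the
*generator* planted, under noise assumptions spelled out below — not that
real cortical data behave this way.

## The stimulus protocol

One block contains 242 conditions: 96 CFS conditions (2 grating eyes x 2
spatial frequencies x 12 orientations, 0-165 degrees in 15-degree steps,
x 2 drift directions), 96 matching monocular (baseline) conditions, 48
binocular conditions, and 2 masker-only conditions (one per eye). Each
condition is repeated 10, 12 or 14 times depending on the field of view.
Drift direction is treated purely as a trial-splitting device: the two
directions of one orientation are averaged before all tuning analyses.

## The synthetic generator

Each neuron has an ocular dominance index (ODI) drawn from a normal
distribution with mean 0 and SD 0.35 truncated to [-1, 1] (a unimodal,
mostly binocular population), a uniform preferred orientation, a preferred
spatial frequency (3 or 6 cpd, attenuation 0.5 at the non-preferred SF),
a base-2 Gaussian tuning curve with half-width-at-half-height ~30 degrees
(SD 3), amplitude ~0.5 dF/F0 (SD 0.05), and a response floor of 0.05.

The eye weight w maps ODI into [0, 1]: w = (ODI + 1)/2 for a grating in
the contralateral eye, 1 - (ODI + 1)/2 for ipsilateral, so *smaller* w
means a stronger preference for the eye seeing the grating. The monocular
gain is w^s. We use a negative exponent (default s = -1): neurons
preferring the stimulated eye must respond more strongly, so the gain must
*decrease* with w. (With a positive exponent the masker-eye-preferring
group would paradoxically have the largest baseline amplitude.) For
response generation, per-neuron weights are clipped into [0.1, 0.9]: with
s < 0 an exactly monocular neuron would otherwise get unbounded gain, and
rare near-monocular neurons would dominate subgroup means.

Under CFS, the generator applies the same gain-control model that the
analysis fits (see below), with one deliberate choice: each neuron is
suppressed by its *own* masker response — the population masker response
N scaled by the neuron's masker-eye weight gain — rather than by a single
population constant. A shared constant would suppress all ocular-dominance
subgroups identically; physiologically (and in the recorded data this
chain was designed for), neurons that respond strongly to the masker are
the ones whose grating response is most suppressed. Binocular-condition
means are max(monocular contra, monocular ipsi); these trials are only
used for ROI screening and tuning selection, never analyzed
quantitatively.

Trial noise is Gaussian and independent, with SD following the mean
tuning: sd = 0.08 + 0.10 x mean (dF/F0). The affine form makes the SD
tuning curve Gaussian-shaped, matching the Fisher-information fitting
assumption. The fixed floor matters: with purely mean-proportional noise,
divisive suppression would leave the signal-to-noise ratio — and hence
Fisher information — unchanged; the floor is what turns suppression into
a contrast-to-noise loss. The magnitudes are a realism choice, not a fit
to any recording: the paper-scale datasets this emulates do not publish
trial-noise magnitudes.

## ROI screening

Cell bodies are detected from the 242 differential images (post-onset
minus pre-onset frame means, trial averaged) processed in protocol order,
twice. Per image: pixels of already-accepted ROIs are set to the image
mean (this progressively lowers the image SD and lets dimmer cells
surface), the image is band-pass filtered with a difference of Gaussians
(sigma 2 and 10 px), pixels above mean + 3 SD are kept, and 8-connected
components larger than 25 px become candidates. A candidate overlapping
an existing ROI is kept, discarded, or merged according to whether the
overlap is below 1/4, between 1/4 and 3/4, or above 3/4 of its area
(computed against the single most-overlapping ROI; equalities fall to the
lower rule). Finally ROIs must have roundness sqrt(4 pi A)/P > 0.9.

Two perimeter conventions are implemented. The *crack* convention counts
boundary edges of the pixel set exactly: an L x L square has perimeter 4L
(roundness sqrt(pi)/2 ~ 0.886 at any size) and a 1 x 25 line 52
(roundness ~ 0.34) — these closed forms are what the tests pin down. But
the crack perimeter of a rasterized disc is 8r, a 4/pi inflation of the
true circumference, so under it even a perfect disc scores pi/4 ~ 0.785
and *nothing* could pass 0.9. Screening therefore uses the *smoothed*
convention: the sub-pixel 0.5-level contour of the Gaussian-blurred mask
(sigma 1 px), under which discs score ~1 (slightly above 1 is possible
for small discs — the blurred contour is marginally shorter than the true
circle) and elongated neuropil-like shapes remain well below 0.9. Shapes
too thin to reach the 0.5 level after blurring fall back to the crack
perimeter.

The ROI sets produced by the sequential algorithm are order-independent
in *content* (same cells, one-to-one matched across orderings) but not in
exact pixel boundaries: earlier-claimed ROIs reshape later thresholding
and merge unions. The tests assert the bounded form of the invariant
(IoU > 0.5 per matched pair on noise-free planted stacks).

## Tuning, selectivity, ocular dominance

Per-trial responses are dF/F0 with F the best of the three 4-frame
post-onset windows (5th-8th, 6th-9th, 7th-10th) and F0 the trial-averaged
pre-onset baseline. For each viewing condition (monocular contra/ipsi,
binocular), a neuron's preferred orientation and SF are the argmax of its
direction-averaged condition means (ties to the lowest orientation, then
the lowest SF). Orientation selectivity is a Friedman test (trials as
blocks, 12 orientations as treatments) at alpha = 0.01, passed under at
least one viewing condition; the binocular arm counts by default
(flag-switchable). ODI = (R_i - R_c)/(R_i + R_c) with peaks rectified at
zero (keeps the index in [-1, 1] with noisy baselines); neurons whose
rectified peaks are both zero are excluded from OD analyses.

## Population curves, suppression metrics, Fisher information

Tuned neurons are snapped to 15-degree preference bins. For each
presented orientation, each neuron contributes its preferred-SF mean
response at the relative orientation (preference bin minus presented
orientation, wrapped into (-90, 90]); contributions are averaged into 12
bins centred at -75..+90. CFS curves reuse the preferences of the
matching monocular arm. Curves are fitted with the base-2 Gaussian
R(theta) = a 2^-((theta-theta0)/sigma)^2 + b (so sigma *is* the
half-width at half-height) by bounded Levenberg-Marquardt from multiple
starts (sigma in {15, 30, 60}, theta0 at the argmax and 0).

The amplitude decrease is 100 (1 - a_cfs/a_base). The paper-style "slope"
metric is not operationally defined in the source material; we define it
as the maximal absolute derivative of the fitted curve, which for the
base-2 Gaussian is a sqrt(2 ln 2 / e) / sigma in closed form (so the
slope decrease is scale-invariant and responds to both amplitude loss and
bandwidth broadening). The discrete bin-to-bin alternative can be
computed from the curves but is not the default.

Fisher information assumes independent Gaussian noise: per neuron,
I_i(theta) = f_i'(theta)^2 / sigma_i(theta)^2 with f_i the fitted mean
tuning and sigma_i the fitted SD tuning (both base-2 Gaussians over the
neuron's 12 relative orientations). Numerical guards: the fitted SD is
floored at 1e-3 dF/F0, and the tuning-width lower bound is 10 degrees —
tuning sampled every 15 degrees cannot support a narrower Gaussian, and
without the bound trial noise masquerades as arbitrarily steep,
information-rich tuning. The population curve is the mean across neurons;
the summary is its average within 15 degrees of the preferred
orientation, and the headline statistic is the CFS/baseline ratio of that
summary.

## The OD-dependent gain-control model

Neurons are split by ODI at +/-0.2 into grating-eye-preferring, binocular
and masker-eye-preferring subgroups, combining the two grating-eye arms
as the ODI sign prescribes. Step I fits the OD-weighted Gaussian basis

R = w^s [A exp(-(theta/sigma)^2) + B]

jointly across the three baseline subgroup curves (one shared parameter
set; the subgroup enters only through its empirical mean weight w).
Step II freezes (A, sigma, s, B) and fits the CFS curves with

R' = w^s [A exp(-(theta/(sigma w^t))^2) + B],  R_CFS = R'/(a N^k) + b N^m

where N is the empirical subgroup-mean masker-only response, w^t broadens
the tuning of masker-eye-preferring groups, a N^k is divisive interocular
suppression and b N^m additive binocular summation. Both steps use
bounded Levenberg-Marquardt from 20 Latin-hypercube starts
(seed-controlled); bounds are s in [-5, 5] (negative values are the
physiological regime, see above), t, k, m in [0, 5], a, b in [1e-6, 1e3].
Because N enters only through the scalars a N^k and b N^m, (a, k) and
(b, m) are identifiable only up to that degeneracy; the fitted *curves*
are the contract, and the tests assert predicted-curve recovery rather
than raw-parameter recovery.

## Decoding

A one-vs-one linear SVM (66 pairwise classifiers, C = 1) classifies the
12 orientations from trial-level population responses (neurons as
features, both SFs pooled as samples: 2 x 12 x trials samples per arm).
Stratified 10-fold cross-validation; features are standardized with
training-fold statistics only — the leakage-safe reading of
"standardized population activity". The chance level is 1/12, and the
permutation null is checked against the exact multinomial band.

## Reconstruction

The reconstruction network embeds each neuron's scalar response with a
learned 2-vector (d_model = 2), applies single-head self-attention
(softmax(QK'/sqrt(d_k)) V with d_k = d_model), unembeds each token to a
scalar with a per-neuron 2-vector, and maps the n-vector to 4900 pixels
with one affine layer (no activation), reshaped to 70 x 70. Targets are
noise-free circular-aperture square-wave gratings rendered at phase 0
without anti-aliasing (a fixture convention). Training minimizes MSE with
full-batch RMSprop (rho = 0.85) on data augmented 4x by per-condition
normal resampling, min-max normalized per neuron, 6% held out for
validation. Weight init is uniform in +/- 1/sqrt(fan_in),
seed-controlled; the forward pass and backpropagation are hand-derived
and implemented in compiled code, cross-checked in the tests against a
pure-R reference forward and finite-difference gradients.

The two-phase procedure fits the validation-loss curve (discarding a
burn-in prefix) with the sigmoid loss(t) = A - C/(1 + e^(k(b-t))) and
stops at b + ln(3)/k, the epoch at which 75% of the total decrease C is
complete (the fitted loss there is A - 0.75 C exactly); both arms are
retrained from scratch to the *baseline* arm's stop epoch and scored with
the single-window SSIM (c1 = 1e-4, c2 = 9e-4 for unit dynamic range) on
the original, non-augmented samples; contralateral and ipsilateral
samples are pooled before taking medians.

**Problem sizes.** The package default learning rate is 5e-5, the
full-scale setting; at that rate meaningful convergence takes on the
order of 10^4 epochs. The analysis scripts and the acceptance run use a
desk-scale configuration chosen once — 30 neurons, 10 trials, 500 phase-1
epochs, burn-in 150, lr = 2e-3 — which reaches the same qualitative
regime (baseline reconstructions clearly better than CFS under strong
suppression) in minutes. Other stages run at 150-300 neurons with 12
trials, the 242-condition protocol throughout, and ROI screening at the
full 531 x 531 px field with 200 planted somas.

## Degenerate inputs and edge rules

Flat curves fit with a ~ 0 or are flagged unfittable; an unfittable CFS
curve reports a 100% amplitude decrease with the flag set and no slope.
Argmax ties break to the lowest orientation then lowest SF. Overlap-rule
equalities fall to the lower branch. Zero-variance frames in motion
correction return zero shift with a warning flag. Zero-SD neurons
augment to their means. A zero divisive gain (a N^k = 0) is a generation
error naming the offending parameters.

## Known limitations

The generator has no optics, no calcium-indicator kinetics, no
spike-to-fluorescence model, and no noise correlations (the Fisher
analysis assumes independence — by design, as does the source analysis).
Real-data mode expects tabular trial responses in the package's CSV
layout via `read_response_csv()`; the deposited-data adapter is a thin
mapping and is exercised only through synthetic round-trips here. The
"slope" metric and the perimeter convention are package definitions of
quantities the source material leaves unspecified; both are flagged where
they matter and both alternatives are implemented.
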