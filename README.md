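# cfspopcode

Analysis chain for population orientation coding in macaque early visual
cortex under **continuous flash suppression (CFS)** — the dichoptic
paradigm in which a flashing noise masker in one eye suppresses a grating
target shown to the other. The package re-implements, as tested and
reusable R code over a synthetic-data generator, the full computational
pipeline of a two-photon calcium-imaging study of this paradigm:

1. **Synthetic recordings** — trial-by-trial ΔF/F0 responses of a
   ground-truth neuron population under the 242-condition protocol
   (96 CFS + 96 monocular + 48 binocular + 2 masker-only), with optional
   rendered differential-image stacks with planted cell bodies.
2. **ROI screening** — sequential differential-image cell detection:
   difference-of-Gaussians band-pass, 3-SD threshold, >25-px connected
   components, 1/4–3/4 overlap resolution, two passes, roundness
   `sqrt(4πA)/P > 0.9`.
3. **Tuning and ocular dominance** — window-maximized ΔF/F0 responses,
   Friedman orientation selectivity (α = 0.01), preferred
   orientation/SF, `ODI = (R_i − R_c)/(R_i + R_c)` and the eye weight
   `w = (ODI+1)/2` (or its complement, by grating eye).
4. **Population coding** — 12-bin relative-orientation tuning curves,
   base-2 Gaussian fits `R(θ) = a·2^−((θ−θ₀)/σ)² + b`, amplitude/slope
   decrease metrics, and Fisher information `I = Σ f′(θ)²/σ(θ)²`.
5. **OD-dependent gain control** — Step I fits the OD-weighted basis
   `R = w^s [A e^−(θ/σ)² + B]` jointly to the three ocular-dominance
   subgroup baselines; Step II freezes it and fits the CFS curves with
   bandwidth inhibition and interocular suppression/summation,
   `R_CFS = w^s [A e^−(θ/(σw^t))² + B] / (aN^k) + bN^m`.
6. **Decoding** — one-vs-one linear SVM over neurons-as-features,
   stratified 10-fold CV, leakage-safe standardization, permutation
   chance at 1/12.
7. **Reconstruction** — a minimal self-attention network (2-d embedding,
   single-head attention, per-neuron unembedding, one affine layer to
   70×70 pixels) trained with full-batch RMSprop on 4×-augmented data;
   two-plateau sigmoid learning-curve fit with the 75%-decrease stop rule
   `stop = b + ln(3)/k`; SSIM scoring of reconstructed gratings.

The methods vignette (`vignettes/cfs-population-coding.Rmd`) documents
the models, parameter choices, numerical conventions and limitations.

## Worked example

The analysis is organised as numbered drivers under `analysis/`
(each writes its tables under `results/`):

```sh
Rscript analysis/01_simulate.R          # synthetic recording -> CSV/JSON
Rscript analysis/02_roi_screening.R     # rendered stack -> ROI table
Rscript analysis/03_tuning_profiles.R   # preferences, Friedman, ODI, w
Rscript analysis/04_population_tuning.R # curves, fits, Fisher information
Rscript analysis/05_gain_model.R        # Step I / Step II fits
Rscript analysis/06_decoding.R          # SVM accuracies
Rscript analysis/07_reconstruction.R    # transformer + SSIM
```

On the default simulated recording (300 neurons, 12 trials/condition,
strong-suppression regime, seed 1) this prints:

```
Detected 199 ROIs; 99 % of planted somas recovered at IoU > 0.5

all                amplitude decrease  90.82%  slope decrease  86.63%
grating_eye_pref   amplitude decrease  88.29%  slope decrease  80.93%
binocular          amplitude decrease  91.70%  slope decrease  89.09%
masker_eye_pref    amplitude decrease  94.59%  slope decrease  93.56%
Fisher information within 15 deg: CFS at 27.0% of baseline

Step I  (A, sigma, B, s) = (0.462, 36.0, 0.051, -1.12), R2 = 1.000
Step II (t, a, k, b, m) = (0.42, 18.79, 0.96, 0.301, 1.01), R2 = 0.999

baseline_contra  accuracy 100.0%  (95% CI 100.0-100.0)
cfs_contra       accuracy  89.6%  (95% CI  85.4- 93.8)
permutation chance 7.9% (multinomial 95% band 5.2-11.8%)

sigmoid stop point: epoch 369 (k = 0.0121, b = 128)
median SSIM: baseline 0.21, CFS 0.13
```

Reading: CFS abolishes the tuning of masker-eye-preferring neurons
almost completely while the grating-eye-preferring subgroup is least
affected; Fisher information near the preferred orientation collapses to
about a quarter of baseline; yet coarse orientation classification
survives (~90% vs a chance level of 8.3%). The Step-II fit recovers the
generator's suppression parameters (ground truth t = 0.4, a = 20, k = 1,
b = 0.3, m = 1) up to the documented (a, k)/(b, m) degeneracy.

Equivalently in R: `report <- run_pipeline(pipeline_config(seed = 1))`.

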