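---
title: "Methods: GAF-imaged volumetric capnography and the CapnoNet classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GAF-imaged volumetric capnography and the CapnoNet classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capnonet)
```

## The signal and its model

A volumetric capnogram plots exhaled CO2 concentration against cumulative
exhaled volume over one breath. Its canonical shape has three phases:
phase I, the anatomical dead space emptying with near-zero CO2; phase II,
the ascending branch where dead-space and alveolar gas mix; phase III, the
alveolar plateau. In health the plateau is nearly flat; airway obstruction
steepens it (ventilation inhomogeneity) and flattens phase II (slower
washout). These two features carry the diagnostic signal this package is
built around.

`capnonet` classifies breaths by converting each standardized breath
series into a Gramian Angular Field (GAF) image and training a compact
multi-scale CNN on those images. This vignette records the modelling
choices, their defaults, and what the synthetic experiments do and do not
establish.

## Synthetic capnograms

No clinical recordings ship with the package; `simulate_breath()` provides
a minimal generative model of one exhalation:

* **Flow** is a non-negative half-sine over `exhale_duration` (default
  2.5 s) scaled so its time integral equals the tidal volume (default
  500 mL).
* **CO2 vs volume** is `sigmoid(k (v − v_d)) · (EtCO2 − s3 (V_T − v)/1000)`:
  a logistic gate of steepness `k` (per mL) centred at the dead-space
  volume `v_d` (default 150 mL), multiplying a plateau line that reaches
  the end-tidal value `EtCO2` at end-exhalation with slope `s3` (% per L).
  Both factors are positive and non-decreasing, so the noise-free curve is
  non-decreasing; in the plateau (gate ≈ 1) the slope is exactly `s3`.
* **Noise** is i.i.d. Gaussian on the CO2 channel (default sd 0.05 %),
  emulating sensor noise.

Severity is expressed through the two discriminative features only:
`grade_morphology()` maps normal → GOLD4 to strictly decreasing phase II
steepness (0.25 → 0.065 per mL) and strictly increasing phase III slope
(0.4 → 3.6 % per L), with end-tidal CO2 drifting mildly upward (5.2 →
6.0 %). The magnitudes are stand-ins chosen to be physiologically
plausible and clearly ordered, not estimates of any clinical cohort: no
published distribution of these slopes was available to calibrate
against. Per-subject morphology is jittered lognormally at 10%
coefficient of variation, which makes neighbouring grades overlap mildly
while keeping normal-vs-severe clearly separable — the regime an
end-to-end training sanity check needs.

The default device sampling rate is 80 Hz, deliberately below the 200 Hz
pipeline target so that resampling is non-trivially exercised. The
generator does not model inspiration, cardiogenic oscillations, coughs or
sensor drift; consequently, passing end-to-end tests demonstrate that the
pipeline and optimizer work, not that the architecture reaches any
particular accuracy on real patients.

## Preprocessing

`preprocess_record()` composes five stages:

1. **Alignment/resampling** — CO2 and flow are linearly interpolated onto
   a shared uniform grid, 200 Hz by default.
2. **Filtering** — a 3rd-order Butterworth low-pass, cutoff 10 Hz by
   default, applied forward-backward. Zero-phase application was chosen so
   that phase II/III slopes are not phase-distorted; the 10 Hz default
   preserves breath morphology (breathing energy lives below a few Hz)
   while crushing mains interference at 50/60 Hz by more than four orders
   of magnitude in the two-pass response. Both are configurable.
3. **Segmentation** — exhalations are maximal runs of flow above
   0.02 L/s, trimmed back to the last CO2 trough before the run and
   forward to the end-tidal CO2 peak within it. Runs shorter than 16
   samples or with CO2 rise under 1.0 % are discarded; these gates are the
   package's operationalization of a "valid, calm breath" and are
   deliberately conservative.
4. **Volume domain** — cumulative trapezoidal integration of flow (mL);
   negative flow inside a segment is clipped to zero with a warning.
5. **PAA** — the volume-ordered CO2 series is reduced to exactly 224
   samples with fractional frame boundaries (frame width `n/m`), so every
   sample contributes and the global mean is preserved whenever `m`
   divides `n`; series shorter than the target are linearly interpolated
   up. PAA frames are taken over the sample axis of the volume-ordered
   curve — within one exhalation that ordering coincides with time
   ordering, and the alternative (uniform-volume frames) was left as a
   sensitivity question rather than a default.

## GAF encoding

With the series normalized to `[-1, 1]` (exact endpoint mapping; constant
series are rejected as degenerate breaths), each sample becomes an angle
`φ = arccos(x̃) ∈ [0, π]` and the image is either
`GASF = cos(φ_i + φ_j)` (symmetric, diagonal `2x̃² − 1`) or
`GADF = sin(φ_i − φ_j)` (antisymmetric, zero diagonal). The radius
`r_i = t_i/N` (1-based index; only `r` depends on that origin choice) is
computed and stored for temporal bookkeeping but does not enter the
matrices. Quantization to 8-bit grayscale is linear from `[-1, 1]` to
`[0, 255]` with round-half-to-even; an unquantized float matrix is
available via `gasf_matrix()`/`gadf_matrix()` for testing and inspection.
The implementation uses the outer-product form and the tests verify it
against the elementwise trigonometric definition to 1e-12.

## Augmentation

`expand_training_set()` triples a training set: originals, plus one
Gaussian-noise copy each (mean 0, variance 15, interpreted in 8-bit
intensity units and applied to the quantized image — the natural scale
for an image-space perturbation), plus one elastic deformation each. The
elastic operator draws per-pixel uniform fields, smooths them with a
Gaussian kernel (σ = 20 px), scales by α = 200, composes with a random
affine map from perturbing three anchor corners by ±10 px, and resamples
bilinearly with reflection borders. Border mode and interpolation are
pinned here; they are standard choices for this parameterization.
Augmentation is applied by the harness strictly inside training folds —
held-out images never pass through these operators — which avoids the
leakage that fold-agnostic augmentation would introduce.

## CapnoNet

The classifier is a deliberately small inception-style CNN (see
`summary(build_capnonet())`): 3×3 stem to 32 channels, three 2×2/stride-2
max pools (224 → 28), an inception module with four parallel
1×1/3×3/5×5/7×7 branches of width 26 (concatenated to 104 channels), two
more pools (28 → 7), a second inception module of branch width 108 (→ 432
channels), global average pooling, dropout 0.4, and a fully connected
softmax head. Every convolution is stride-1 with "same" zero-padding and
is bias-free because batch normalization follows it; all downsampling is
pooling.

The channel widths (32; 4×26; 4×108) and the pooling schedule are pinned
jointly by the model's two published complexity figures — 1.02 M
parameters and 0.23 GFLOPs per forward pass — under the convention
FLOPs = 2 × multiply-accumulates of convolutions and the FC layer
(batch norm, activations and pooling excluded). `count_parameters()` and
`count_flops()` reproduce 1,015,666 and 230,949,312 exactly; whether the
original accounting included BN or counted MACs singly is unknowable from
the printed figures, so this convention is documented rather than
asserted as the original authors'. Dropout sits between global average
pooling and the FC layer in this implementation.

Because no deep-learning framework is a dependency, the network is
implemented directly: im2col + GEMM convolutions, explicit backward
passes for every layer, batch-norm running statistics (momentum 0.1,
eps 1e-5), inverted dropout, and Adam (β₁ = 0.9, β₂ = 0.999, eps 1e-8).
He-normal initialization is used for convolutions. Gradients are verified
against central finite differences in the test suite. Training defaults
follow the published protocol: Adam, learning rate 0.001, batch 32,
cross-entropy loss; the epoch count is problem-dependent and exposed.

## Evaluation

`stratified_subject_folds()` assigns *subjects* (never individual
breaths) to folds by seeded per-class round-robin, so per-fold class
proportions deviate from the global ones by at most one subject per
class. `run_cv()` trains a fresh network per fold, classifies held-out
breaths, aggregates to subjects by majority vote (ties broken by summed
probability), and pools subject-level confusions across folds.
Subject-level splitting and voting were chosen to preclude breath-level
leakage; breath-level metrics can be recovered from the per-fold
predictions if needed. Metrics follow the confusion-matrix definitions;
beyond two classes, precision/recall/F1 are macro-averaged with F1
averaged per class (not recomputed from averaged precision and recall) —
the convention consistent with the published grading-task figures, whose
printed F1 differs from the harmonic mean of the printed macro precision
and recall.

## Desk-scale problem sizes

The package's own end-to-end experiment (mirrored in the test suite) uses
a 40-subject cohort (20 normal, 20 GOLD3 — a cleanly separated pair), 2
breaths per subject, GASF encoding at side 48 (PAA to 48), 10 folds, 5
epochs. The encoding side only changes the image resolution fed to the
network — parameter counts are side-independent, and the 224 geometry is
exercised separately — while keeping a full 10-fold run to a few minutes
on one CPU. On this configuration the pooled subject-level accuracy
reaches 0.95 (seed-fixed); numbers of that kind characterize the
synthetic benchmark, not clinical performance.

## Known limitations

* The synthetic morphology model is three-phase and expiration-only; its
  severity parameterization is ordinal and plausible but uncalibrated.
* Training in base R is CPU-bound and practical at reduced image sides
  and desk-scale cohorts; full 224×224 training of many folds is possible
  but slow.
* Batch-norm statistics make per-sample inference depend on training-time
  running averages; very small training sets give noisy estimates.
* The elastic operator's border and interpolation conventions, the
  quantization map, and the FLOP convention are pinned implementation
  choices; alternative conventions would change none of the package's
  interfaces but could shift third-party comparisons.
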