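---
title: "Quantifying and predicting sub-solid nodule growth: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and predicting sub-solid nodule growth: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Sub-solid pulmonary nodules (SSNs) — ground-glass and part-solid nodules on
chest CT — carry an elevated malignancy risk but usually grow slowly, so
management hinges on whether a nodule is *growing* during follow-up.
`ssngrowth` implements a complete desk-scale pipeline for that question:

1. **Measurement** — diameter, volume and mass from a segmentation mask;
2. **Growth statistics** — increase rates and doubling times across exams;
3. **Labelling** — the mass-based growth criterion (≥ 25% per year);
4. **Pairing** — rigid alignment of consecutive scans and matching of the
   same nodule across time points;
5. **Prediction** — a Siamese vision-transformer regressor over paired
   volumes of interest (VOIs), plus a radiomics LASSO-logistic baseline;
6. **Evaluation** — ROC/AUC with non-parametric bootstrap intervals;
7. **Simulation** — a longitudinal nodule-phantom generator with analytic
   ground truth, so that every stage is testable without clinical data.

## Measurements

Given a VOI and a binary nodule mask with voxel spacing in mm:

* **Volume** `V` (mm³) is the foreground voxel count times the single-voxel
  volume.
* **Mean attenuation** `A` (HU) is the mean intensity under the mask.
* **Mass** `M = V (A + 1000) / 1000` (mg): attenuation is linear in
  physical density between air (−1000 HU, ~0 g/mL) and water (0 HU, 1 g/mL),
  so this is the integrated density of the lesion. Mass responds to both
  volume growth and densification, which is why it is the most sensitive of
  the three measurements for SSNs.
* **Diameter** `d` (mm) is the longest side of the minimum-area rotated
  rectangle circumscribing the mask foreground on the axial slice with the
  largest foreground area (ties broken toward the lowest slice index, axial
  because that is the acquisition plane). The rectangle is computed by
  rotating calipers over the convex hull of the *outer corners* of the
  foreground pixels, mapped to mm before the search; the corner convention
  makes a single voxel measure one in-plane spacing and an axis-aligned
  cuboid measure exactly its edge length. No resampling is performed for
  measurement.

**Growth statistics.** The increase rate between consecutive exams is
`(X_t − X_{t−1}) / X_{t−1}`. The doubling time assumes exponential growth,
`DT = Δt · ln 2 / ln(X_t / X_{t−1})`, is undefined (stored as `NA`, never
infinity, to keep summary code total) when the metric did not strictly
increase, and cohort quartiles use only defined values within [1, 1000]
days — wilder values are numerically meaningless at typical screening
intervals. Group comparisons use Welch's t-test (the unequal-variance
variant, chosen because cohort variances are demonstrably unequal between
cancer and non-cancer groups).

## The growth label

Growth is an increase in mass of at least 25% within one year. The relative
increase is annualised **linearly** (`y = rate × 365 / Δt`), matching how
increase rates are tabulated, rather than compounded; the boundary
`y = 0.25` is labelled growth (the criterion reads as inclusive). Both
choices are configurable. The regression target fed to the model is this
annualised rate `y`; the loss-weighting threshold `r = 0.1` below is a
separate constant — the two are deliberately independent knobs, as their
relationship is not specified.

## The growth-prediction model

Input is the pair of nodule-centred VOIs (prior `T_{t−1}`, current `T_t`),
32³ voxels at 1 mm isotropic spacing, intensities clipped to [−1000, 400] HU
and scaled to [0, 1] (a documented constant; the clip range covers lung
through soft tissue).

**Encoder.** One shared-weight ("Siamese") 3D vision transformer embeds
both VOIs: non-overlapping 8³ patches, linear patch embedding, learned
positional embeddings, a class token, pre-norm attention/MLP blocks. The
desk-scale `"tiny"` variant is 4 layers × 128 channels × 4 heads
(MLP ratio 2); a `"vit-b"` flag selects the full-scale geometry. Three
embeddings are pooled:

* `FG_t` — the class token of the **current** VOI (global context; the
  global appearance of the surrounding lung is assumed unchanged between
  exams, so no global embedding is computed for the prior);
* `FL_t`, `FL_prev` — the mean of patch tokens whose patch centres fall in
  a central cube of half the VOI extent (local nodule appearance at each
  time point). Local pooling by a fixed central cube means inference needs
  no mask.
* When no prior scan exists (two-exam subjects), `FL_prev` is a **learnable
  substitute vector** trained with everything else.

**Fusion (spatial-temporal mixer).** The three embeddings are mixed by one
token-mixing MLP (across the 3 tokens, per channel) and one channel MLP,
each with layer norm and a residual connection — an MLP-Mixer-style block.
A single fully connected layer regresses the scalar growth rate `p`. The
precise mixer internals are not prescribed anywhere, so this minimal
residual token/channel pair is this package's own documented choice.

**Loss.** The weighted smooth-L1 on the predicted vs true rate:

\[ L = \alpha\,\mathrm{SmoothL1}(p, y)\,\mathbb{1}[y \ge r] +
      \mathrm{SmoothL1}(p, y)\,\mathbb{1}[y < r], \]

with `SmoothL1(d) = d²/2β` for `|d| < β`, else `|d| − β/2`. Defaults
`α = 3` (the value found best in the source experiments), `r = 0.1`,
`β = 1` (β is never specified; 1 is the conventional default). Weighting
the scarce high-rate examples counteracts the ~7% growth prevalence.
Regressing the rate rather than classifying keeps the supervision ordinal;
classification is derived afterwards.

**Optimisation.** AdamW (first-moment decay 0.9 — "momentum" read as β₁ —
second moment 0.999, the standard default), weight decay 0.05 applied only
to weight matrices, batch 16, linear warmup from 1e-5 (the printed "10e-6"
read literally) to `lr × batch/64` with `lr = 5e-4`, then cosine annealing
to zero. The reference protocol is 100 epochs; the desk-scale acceptance
run uses 12 epochs (2 warmup) because a single CPU must finish in minutes —
this scales the schedule, not the task, and the 12-epoch run already
saturates the synthetic benchmark.

**Decision.** `prob = 1/(1 + exp(−(p − th)/τ))` with sharpening coefficient
`τ = 0.1`; `prob ≥ 0.5` (equivalently `p ≥ th`) is called growth. The
operating threshold `th` maximises Youden's J on a validation set, ties
resolved toward the smaller threshold.

**Implementation note.** No deep-learning runtime exists in the target R
stack, so forward and backward passes are hand-derived over BLAS matrix
algebra with small C++ kernels (attention, layer norm, GELU, AdamW). GELU
uses the sigmoid approximation `x·σ(1.702x)`. Correctness is enforced by a
finite-difference gradient check across every parameter tensor in the test
suite, and training is bit-reproducible given the config seed.

## Radiomics baseline

The comparator extracts a documented 72-feature set from the current VOI
under its mask — 18 first-order intensity, 14 shape, 24 grey-level
co-occurrence and 16 run-length features, optionally tripled by
Gaussian-smoothed and gradient-magnitude filter banks — then selects
features by cross-validated LASSO (`glmnet`, 5 seed-controlled folds) and
scores with a lightly ridge-regularised logistic model (so complete
separation cannot crash the fit). The full feature inventory of the
original (1,218 features) is not enumerated anywhere; reproducibility
*within this package* is the contract, and the count is recorded in the
output metadata. Texture matrices aggregate the 13 unique 3D unit
directions, which makes them invariant to 90° grid rotations. Intensities
are discretised at a fixed 25 HU bin width. Surface area — the input to
sphericity and compactness — integrates the gradient magnitude of a
Gaussian-smoothed (σ = 1 voxel) mask indicator via the coarea formula;
counting exposed voxel faces would overestimate a sphere's area by ~50%
and make sphericity meaningless.

## Registration and pairing

Consecutive scans are aligned by maximising intensity cross-correlation
over integer translations (FFT), refined per axis by a quadratic fit
through the correlation peak. Rotation is reported as identity: at VOI
scale the translational component dominates, and nothing downstream
consumes a rotation. Degenerate inputs (uncorrelated noise, constant
images) are detected by the correlation-peak z-score (threshold 6; a pure
noise field peaks near √(2 ln N) ≈ 4.5) and raise an error rather than
returning a silently wrong transform. Lesion correspondence is
mutual-nearest-neighbour matching of transformed centroids within a 10 mm
gate — tight enough that distinct nodules (typically cm apart) cannot
cross-match, loose enough for residual misalignment. VOIs are extracted as
cubes at 1 mm isotropic spacing (trilinear for intensities, nearest
neighbour for masks), padded with −1000 HU outside the scan.

## The phantom simulator

The generator emulates what the downstream stages need and nothing more: a
soft-edged ellipsoidal ground-glass lesion in noisy parenchyma.

* Lesion membership is a Gaussian-smoothed indicator of the ellipsoid
  (scale `edge_softness`, default 0.8 mm — ground-glass margins are soft);
  the ground-truth mask is membership ≥ 0.5, i.e. voxel centres inside the
  ellipsoid, so the mask stays crisp while the image is soft.
* Defaults: parenchyma −850 HU with σ = 25 HU Gaussian noise, lesion
  −650 HU — within the attenuation range reported for screening-cohort
  SSNs. Initial maximal diameter must lie in the 5–30 mm inclusion window.
* **Truth is defined on the voxelised mask** (count × voxel volume; mean
  of the pre-noise image under the mask; mass by the formula), not on the
  continuous ellipsoid, so measurement can be checked exactly rather than
  to a tolerance. Noise is added only outside the lesion so that the
  under-mask mean stays analytic.
* Trajectories scale each semi-axis by `radius_scale_per_year^t` and drift
  the attenuation by `hu_delta_per_year · t` over 2–3 exams, optionally
  with a recorded random rigid offset emulating inter-scan misalignment.
* `generate_cohort()` draws class-conditional parameters: growth-class
  nodules are larger (log-normal around 10 mm vs 6.5 mm) and denser
  (≈ −590 vs −640 HU) at baseline, mirroring the reported univariate
  contrast between growing and non-growing SSNs; target annualised mass
  rates are ≈ N(0.5, 0.1) for growth and N(0, 0.05) for non-growth, and
  the per-year radius scaling is solved in closed form so the final
  interval hits the drawn target exactly (up to voxelisation). Default
  prevalence is 7% (screening-like); ~15% of trajectories have only two
  exams and exercise the learnable-substitute path. Inter-exam gaps are
  uniform on 300–430 days.

**What a green test does and does not establish.** The phantoms have no
vessels, airways, pleura or reconstruction-kernel texture, and the growth
signal is geometrically clean. Passing the learning benchmark shows the
architecture, loss, optimiser and data plumbing are correct and can extract
longitudinal and cross-sectional growth signal; it says nothing about
clinical performance on real CT. Conversely, the measurement, statistics,
pairing and evaluation stages are exact or oracle-checked, and those
guarantees do transfer.

Worth knowing: a voxelised sphere's lattice-count volume deviates from
4/3·πr³ by up to ~5.4% at the worst sub-voxel alignment (radius 5 mm,
centre on a half-integer lattice point); random centre placements stay
within 5%.

## Numerical and design choices

* Axis order is (z, y, x) everywhere; world mm = origin + index × spacing,
  0-based indices in the convention, 1-based in R arrays.
* NIfTI-1 I/O is a minimal hand-written subset (little-endian single-file,
  five datatypes, pixdim + axis-aligned sform) because no NIfTI package
  exists in the target stack.
* χ² tests are computed without Yates continuity correction (configurable),
  matching the hand-computable Σ(O−E)²/E definition.
* Bootstrap CIs are percentile (not BCa), B = 2000 by default, resampling
  at the nodule level; single-class resamples are redrawn and counted.
* The AUC is the tie-aware normalised Mann–Whitney statistic; the decision
  rule is closed at the threshold (`score ≥ th`).
* The learning experiment in the acceptance suite uses a balanced cohort
  (growth fraction 0.5): it is a designed experiment about whether the
  model can learn, not a prevalence study; the generator's *default*
  prevalence remains 7%.

## Known limitations

* Rotation is not estimated during registration; strongly rotated
  follow-ups would need an external rigid pre-alignment.
* The radiomics feature set is a representative, documented subset, not a
  re-implementation of any specific library's 1,218 features.
* Doubling-time summaries use the raw inter-exam interval (whether the
  reference tables annualised first is unstated).
* The full-scale `"vit-b"` configuration is provided but untested at scale
  here; CPU training at that size is impractical.
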