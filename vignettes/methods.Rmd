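---
title: "Methods: MVF projection, normalization, and stage-independent classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MVF projection, normalization, and stage-independent classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the scientific and numerical choices behind
`octfundus`: the models and procedures each stage implements, the
parameters that matter and their defaults, what the synthetic cohort
generator does and does not emulate, and the package's known limitations.

## Study design and terminology

The package targets a two-group longitudinal retinal-imaging design:
wild-type (`WT`) and transgenic (`TG`) animals, both eyes (`OD`/`OS`),
imaged at ages 1, 2, 3, 4, 8 and 12 months. The transgenic group is the
positive class throughout — sensitivity is the true-positive rate on `TG`
animals, specificity the true-negative rate on `WT`.

The central evaluation is *stage extrapolation*: classifiers are trained
and validated only on acquisitions at 3, 4 and 8 months, and then tested
either within that window (the `within_age` scenario) or exclusively
outside it, at 1, 2 and 12 months (`outside_age`). A classifier that
performs well outside the training window has learned features stable
across disease stage and age, which is what would make early, pre-symptom
screening conceivable.

## Mean-value fundus projection

An OCT volume is an array `I(b, a, z)` of B-scans × A-scans × depth.
A layer segmentation supplies six boundary surfaces
`boundary_0 .. boundary_5` (depth indices per A-scan); layer `k` occupies
the **0-based, half-open** interval `[boundary_k, boundary_{k+1})`. The MVF
image of a layer is the en-face map of mean intensity within that
interval. Choices worth stating:

* **Half-open, 0-based indexing** is the package's convention; whether a
  closed interval was intended by any particular upstream segmentation is
  unknowable from the data, and half-open intervals make adjacent layers
  partition the depth axis exactly.
* **Zero-thickness columns** (equal consecutive boundaries) have no mean.
  The default policy is an error naming the offending `(b, a)` location,
  because the synthetic generator guarantees at least one voxel per layer
  and silent gaps usually indicate a segmentation fault; `missing` is
  available for robustness on real data and yields `NA` pixels.
* MVF images stay floating point through the pipeline; 8-bit quantization
  happens only at PNG export, after normalization.

The implementation is a vectorized cumulative-sum along depth; the test
suite checks it against a literal triple-loop mean at tolerance 1e-9, and
checks permutation invariance of voxels within a layer column.

## Intensity normalization

The chain is, in order:

1. **CLAHE** — tile-wise histogram equalization with clipping. The input
   range is quantized into 256 bins; per tile of an 8 × 8 grid the
   histogram is clipped at `max(1, round(clip × n_tile))` counts
   (`clip = 0.01`) and the excess is redistributed uniformly in a single
   pass (floor share to every bin, remainder one count each to the lowest
   bins — deterministic, no re-clipping); the tile's CDF maps bins back
   onto the input range, and per-pixel outputs are bilinearly interpolated
   between the four nearest tile centres. Tile grid and clip limit are
   exposed parameters; the defaults are conventional values, as CLAHE
   implementations go, and the single-tile configuration is pinned to a
   brute-force clipped-equalization oracle in the tests.
2. **Gaussian low-pass filter** of the CLAHE output — separable
   convolution, kernel 121 × 121 pixels, σ = 25 pixels, reflect borders.
   The reflection is a folded index (period `2n`), so kernels wider than
   the image — the default kernel on a 32 × 64 MVF, for instance — are
   handled without special cases. The LPF estimates the smooth
   illumination field.
3. **Element-wise division** CLAHE / (LPF + ε), ε = 1e-6, a standard
   flat-field correction guarding against zero denominators.
4. **z-score, then ×8 + 128**: the output has mean 128 and standard
   deviation 8 on the 8-bit scale. "Adjusting the variance by
   multiplying by 8" is read as multiplying *values* by 8 (giving sd 8,
   variance 64), because that is what keeps z-scores within an 8-bit
   range around 128; the alternative reading (target variance 8) would
   compress images to a ~3-grey-level band. The sample standard deviation
   (denominator `n − 1`) is used consistently, so re-measuring the output
   with `sd()` returns exactly 8.

A degenerate (zero-variance) ratio image returns a constant 128 image with
a warning rather than NaNs. The chain's purpose is to equalize the first
two intensity moments of every image and remove smooth illumination
gradients, so that downstream discrimination cannot rest on global
intensity differences between groups — the tests verify that a planted
+60 global offset leaves no group-mean difference after normalization.

One ambiguity deserves a flag: the LPF input is taken to be the CLAHE
output (the natural reading of a sequential chain); applying the LPF to
the raw image instead would change the correction slightly. The choice is
fixed and documented here.

**Augmentation** applies to training images only and produces exactly two
copies per image: the vertical (top–bottom) flip, and a rotation by 90° or
270° chosen uniformly at random — tripling the training set. No test-time
augmentation is performed. For non-square inputs a 90°/270° rotation
changes the image shape, which a fixed-input classifier cannot accept, so
the rotated copy of a non-square image is replaced by the
shape-preserving 180° rotation; with square inputs the 90°/270° behaviour
is exact.

## Splitting

The unit of assignment is the **animal**: all eyes and ages of one animal
share one bucket, so no subject's data can appear in more than one of
train/validation/test. Per group, `round(0.2 n)` animals go to test and
the remainder splits 75/25 into train/validation, with round-half-up
counts (57 animals per group gives 11 test, then 34 train and 12
validation — matching the printed design sizes this convention was chosen
to reproduce). Assignment is stratified by group, so buckets are balanced
to within one animal. Quality-based exclusion of individual acquisitions
is modelled upstream (the generator's `cell_counts`), never by the
splitter. Augmented copies inherit their source's bucket and are generated
only for the train bucket.

## Classifier

The classifier follows a transfer-learning contract: a convolutional
feature extractor whose parameters are fixed, global average pooling, and
a single fully-connected sigmoid unit giving the probability of the
transgenic class. One independent model is trained per retinal layer (five
in the full pipeline); layer runs share no state.

The provided backbone (`small_cnn`) is four 3 × 3 convolution blocks
(8/16/32/64 feature maps, ReLU, 2 × 2 max pooling after the first three
blocks), with parameters drawn once from a seeded He-scaled normal
distribution and then frozen. Inputs are standardized as
`(x − 128) / 8`, matching the normalization chain's output moments. With
`trainable_scope = "head_only"` (default) training touches only the head;
`"head_plus_last_block"` additionally fine-tunes the last block by
analytic backpropagation through conv → ReLU → GAP at a lower learning
rate. The frozen scope is asserted in tests by comparing parameter
checksums before and after training.

Training choices (none of which have canonical values for this design, so
they are package defaults, exposed in `classifier_config()`): binary
cross-entropy loss with L2 penalty 1e-4 on head weights; Adam with
learning rate 1e-3 for the head and 1e-4 for the fine-tuned block;
mini-batches of 32; at most 30 epochs with early stopping at patience 5 on
validation loss, returning the state at the best validation epoch; the
head starts from small seeded random weights (sd 0.01) so that gradients
reach the fine-tuned block from the first step; decision threshold 0.5
with ties classified as transgenic. Training is exactly reproducible under
a fixed seed.

A pretrained ImageNet-scale backbone would replicate the original
transfer-learning setting more literally, but requires downloaded weights
and GPU-scale compute; the compact frozen backbone implements the same
contract (frozen features + trained sigmoid head) at desk scale and is the
only mode exercised by the tests.

## Evaluation

`compute_metrics()` reports accuracy `(TP+TN)/n`, sensitivity `TP/(TP+FN)`,
specificity `TN/(TN+FP)` and F1 `2TP/(2TP+FP+FN)`, rounded **half away
from zero** to three decimals (the convention that matches printed
tables), with unrounded values retained. `recover_confusion()` inverts
rounded sensitivity/specificity back to integer confusion counts given the
class sizes, erroring on ambiguous recoveries (two integers equally close)
rather than guessing — this supports consistency checks of published
3-decimal tables, and the test suite shows that most printed rows
round-trip exactly while flagging cells that are internally inconsistent.
`build_error_table()` aggregates per-acquisition outcomes into
errors/cases per (layer, group, age) with subtotals, per-layer totals and
a grand total, verifying that case counts agree across layers;
`age_error_share()` reports the integer percentage of all errors occurring
at one age. Per-eye error balance is available as a diagnostic only.

## The synthetic cohort generator

The generator emulates the study design so that every stage is testable:

* **Design**: 57 animals per group by default, ages 1/2/3/4/8/12 months,
  both eyes, one acquisition per eye per age. A mortality schedule
  removes animals between consecutive ages (defaults: 7 of 57 WT and 13
  of 57 TG over the study, in intervals 1–2: 4+1, 2–3: 0+1, 3–4: 0+2,
  4–8: 2+4, 8–12: 1+5); death truncates an animal's ages to a prefix of
  the age list. Per-age body weights are drawn from normal distributions
  (means 14.9, 22.4, 25.4, 27.2, 31.6, 33.5 g; sds 2.6, 2.0, 2.1, 2.1,
  3.4, 3.8) and are metadata only — they never influence images. An
  optional `cell_counts` table caps acquisitions per (group, eye, age)
  cell, emulating quality exclusions so printed acquisition tables can be
  matched exactly.
* **Volumes**: default 32 × 64 × 128 voxels (B-scans × A-scans × depth), a
  desk-scale stand-in for real acquisition geometry. Boundaries are
  smooth integer surfaces: a top surface near 15% depth plus five
  per-layer thickness increments (fractions 0.18/0.22/0.15/0.12/0.33 of
  55% of depth), each jittered by a smooth field (default amplitude 1.5
  voxels) and clamped to at least one voxel, so layers always have
  positive thickness; columns that would overflow the depth are slid up
  and, if necessary, compressed from the bottom.
* **Intensities**: per-layer baselines (170, 130, 90, 120, 80; background
  40) plus a smooth zero-mean per-layer texture field (amplitude 8,
  smoothness σ = 6 pixels), additive Gaussian voxel noise (sd 10), and
  clamping at zero.
* **The planted effect**: transgenic animals receive an additional smooth
  low-spatial-frequency texture (unit-sd field × amplitude) in the
  configured `affected_layers`, scaled by `effect_size ×
  maturity_factor(age)`. The maturity factor is a linear ramp in
  postnatal weeks (1 month = 4.345 weeks): 0 at or below 4 weeks, 1 at or
  above 15 weeks by default — anchored on the window over which the
  rodent CNS gains mass, so a "developmental" effect can be silenced at
  the youngest ages. Every random field is drawn regardless of group, so
  at `effect_size = 0` the group label provably has no influence on the
  generated data. Which layers carry a real discriminative signal is
  unknown, so `affected_layers` is free; the default is the three
  innermost layers, where inner-retina changes would be expected to show
  first.

What the generator does **not** emulate: OCT speckle statistics, depth
attenuation, optical shadowing, vessel patterns, eye-specific or
animal-specific anatomy, or any real biological contrast between the
groups. The planted effect is a controllable stand-in. Consequently,
passing recovery tests demonstrates that the pipeline's machinery —
projection, normalization, leakage-free splitting, training, evaluation —
works and can detect a planted group difference that survives
normalization, including out of the training age range; it says nothing
about the detectability of real disease effects in real retinas.

## Experiment scale in the test suite

The bundled experiments use cohorts of 20 animals per group (volumes
32 × 64 × 128, single affected layer, effect amplitude 30 against noise
sd 10 — an effect deliberately far above noise), three seeds each, with
the median reported: parameter recovery (outside-age accuracy high and
close to within-age when the effect is age-independent; chance-level
accuracy under a null effect) and a stage-dependence mirror (silencing the
effect below 2 months makes 1-month test cases dominate the errors while
12-month cases stay well classified). These sizes keep a full suite run in
single-digit minutes of CPU while leaving the recovery conclusions
unambiguous. The end-to-end pipeline demo uses 8 animals per group on
16 × 24 × 48 volumes.

## Known limitations

* The compact backbone's random frozen features suffice for strong planted
  texture effects but are not a substitute for learned hierarchical
  features when contrasts are subtle.
* CLAHE's clip-redistribution is single-pass, so bins can marginally
  exceed the clip limit — a documented, deterministic simplification
  shared with common implementations.
* With non-square inputs the rotation augmentation substitutes a 180°
  rotation, slightly reducing augmentation diversity.
* `recover_confusion()` assumes the printed values were rounded from an
  exact integer-ratio rate; it cannot repair tables whose cells are
  internally inconsistent, and deliberately refuses ambiguous cases.
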