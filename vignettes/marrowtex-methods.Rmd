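---
title: "Methods: texture descriptors, group testing and the synthetic cohort"
author: "marrowtex developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: texture descriptors, group testing and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marrowtex)
```

# Scope and model

`marrowtex` analyses 2D masked bone-marrow MRI regions of interest
(ROIs) from three diagnostic groups — bone-marrow edema (BME), recent
injury (INJ), osteoarthritis (OST) — each imaged in two sequence
channels (PD-FSE, STIR). The analysis has three stages: an
81-descriptor texture extractor, a per-feature three-group statistical
comparison with false-discovery-rate control, and a combinatorial
feature-selection / classification protocol. A calibrated synthetic
cohort generator makes every stage testable without clinical data.

# Quantization

All gray-level matrix descriptors operate on quantized levels: the
in-mask intensity range `[lo, hi]` is split into `Ng` equal-width bins
(default `Ng = 32`), pixel `x` maps to
`floor((x - lo)/(hi - lo) * Ng) + 1` clipped to `[1, Ng]` (the top edge
falls in bin `Ng`), and a constant ROI maps to level 1. Min–max
calibration inside the mask makes every downstream matrix descriptor
exactly invariant to affine intensity rescaling — the right property
for non-quantitative MRI units. `Ng` is configurable; 32 is common
radiomics practice and keeps the matrices well-conditioned on ROIs of a
few hundred to a few thousand pixels. First-order descriptors are
computed on the *raw* masked intensities (quantizing first would
discard the dispersion information that MAD and friends carry); their
histogram-based entropy and energy use 32 equal-width bins over the
masked range, mirroring the quantizer.

# The 81 descriptors

* **First order (17)**: mean, population std and variance, Pearson
  moment skewness and kurtosis (a normal sample has kurtosis 3; both
  defined as 0 for a constant sample), median, p10/p25/p75/p90 with
  linear interpolation between order statistics, min, max, range, IQR,
  MAD (mean absolute deviation from the mean), 32-bin histogram energy
  and entropy (bits, `0 log 0 = 0`). The published family list is
  open-ended ("such as ..."); this fixed set of 17 is frozen here and
  includes MAD because it is one of the composite descriptors.
* **GLCM (22)**: Haralick-family descriptors of the normalized
  co-occurrence matrix at 1-pixel offset. The four axis directions
  N/S/E/W are the offsets (-1,0), (1,0), (0,1), (0,-1); only pixel
  pairs with both ends inside the mask count. Per-direction descriptor
  values are averaged (not the matrices) over the non-degenerate
  directions; since opposite directions give transposed matrices the
  average behaves like a symmetric-matrix evaluation. Degenerate
  conventions: correlation = 0 when a marginal variance vanishes;
  information measures 0 when `max(HX, HY) = 0`; the maximal
  correlation coefficient is `sqrt` of the second-largest eigenvalue
  magnitude of Haralick's Q matrix, 0 when the occupied support has
  rank < 2.
* **GLRLM (16)**: maximal constant-level runs along the same four
  directions, broken at mask boundaries; descriptor values averaged
  over the four directions (opposite directions are identical, so this
  equals the two-axis average). Single pixels are runs of length 1.
* **GLSZM (16)**: zones are 8-connected components of equal-level
  masked pixels (the standard 2D convention). `glszm_glzv` is the
  gray-level variance over the zone distribution, `glszm_zsv` the
  zone-size variance.
* **Tamura (6)**: the classical per-pixel optimal-scale coarseness
  procedure with moving-average windows of size `2^k`, `k = 0..4`
  (truncated means at image borders), horizontal/vertical difference
  offsets `max(1, 2^(k-1))`, per-pixel argmax with ties to the smaller
  scale, coarseness value `2^k_opt`. The published descriptor names
  "coarseness 1–4" are not defined there; the decision here is the
  mean, std, median and 32-bin entropy of the masked coarseness map,
  restricted to pixels whose largest (16 x 16) window fits inside the
  image. Contrast is `sigma / alpha4^(1/4)` over masked intensities (0
  for constant ROIs); roughness is coarseness-mean + contrast, per the
  original formulation.
* **LBP (4)**: radius-1, 8-neighbor codes with the `neighbor >= center`
  convention (a constant ROI codes to 255), computed for masked pixels
  whose eight neighbors are all masked, no interpolation. Descriptors
  of the normalized 256-bin histogram: mean code, weighted-median code,
  number of strict local maxima over occupied bins in circular code
  space (a single occupied bin counts as one peak), uniformity (sum of
  squared frequencies).

Total: 17 + 22 + 16 + 16 + 6 + 4 = 81, names namespaced by family and
ordered family-block-then-alphabetical in every table the package
writes.

# Group testing

Per sequence channel and per descriptor: each of the three groups is
tested for normality with Jarque–Bera
(`JB = n/6 (S^2 + (K-3)^2/4)`, chi-square(2) upper tail; groups smaller
than 8 or constant are treated as non-normal). The feature enters the
ANOVA branch only if all three groups pass at `alpha_norm = 0.05`,
otherwise the Kruskal–Wallis branch (rank test with tie correction).
Degenerate inputs are defined rather than propagated: identical values
everywhere give p = 1; distinct means with zero within-group variance
give p = 0.

Benjamini–Hochberg step-up adjustment
(`adj_p(i) = min_{j>=i} m p_(j) / j`, capped at 1) is applied *within
each branch family separately* — matching the way the two branch counts
are reported separately in the source study — with a `fdr_scope =
"global"` option for a single 81-test family. Features are flagged at
adjusted p < 0.001 (`alpha_strict`); flagged features get post hoc
pairwise comparisons (Tukey HSD on the ANOVA branch, Dunn mean-rank
z-tests with Bonferroni-times-3 correction on the KW branch) at the
same level. Screening counts at raw p < 0.05 and rejections at the FDR
level q are also reported, because the published per-channel counts mix
both conventions.

# Classification protocol

The two channels are joined into one 162-column row per subject. A
random-forest classifier — implemented in C++ in this package
(bootstrap + `mtry` Gini CART, impurity-decrease importance,
probability prediction by averaging leaf class distributions), since no
tree-ensemble package is available in the target environment — ranks
all features by mean impurity decrease. All subsets of the top 20
features with at most 5 members (21,699) are the candidate
combinations.

Evaluation of a combination: stratified 70/30 subject split; the
training partition is bootstrap-augmented per class (factor 2 by
default; factor 1 is the identity) and equalized by SMOTE (uniform
interpolation toward one of the 5 nearest same-class neighbors, `k =
n-1` below 6 samples); a stratified 10-fold CV over a small grid (trees
in {100, 300, 500}, depth in {unlimited, 5, 10}) selects
hyperparameters; the refit model is scored on the untouched 30% by
accuracy, per-class TPR and macro one-vs-rest AUC (rank-statistic
computation, ties averaged). The whole procedure repeats on 10
independent splits and reports mean and sd.

**Leakage**: the published protocol text orders augmentation and SMOTE
*before* the train/test split, which would leak synthetic copies of
test subjects into training. This package balances training partitions
only and tags every balanced row with its source subject so the
separation is auditable (`balance_provenance`); the original order
remains available behind `paper_order = TRUE` for comparison.

Composite selection evaluates each candidate combination per
repetition with a cheap fixed-configuration forest; an optional
`budget` random-subsamples the 21,699 candidates *once per run* (a
shared pool makes per-repetition winners comparable, so the majority
vote is over a common candidate set). The best combination of each
repetition is recorded (by test AUC; ties to the smaller, then
lexicographically first set) and the composite is the set of features
present in a strict majority of the winners; a degenerate majority
(fewer than two features) falls back to the modal winning combination.
Because texture descriptors come in near-collinear families, the
per-repetition winners freely substitute siblings (long-run emphasis
for run-length variance, intensity range or std for MAD): the majority
composite reliably identifies the discriminative *axes* but not
necessarily the individual planted descriptor names, and its size
varies run to run. This is an intrinsic property of
best-subset-by-test-AUC selection at these sample sizes, not an
implementation artifact; the decisions ledger and the acceptance suite
treat exact-name recovery accordingly.

# The synthetic cohort

The generator emulates the *statistical structure* of the study — 3
groups of 41/37/43 subjects, two channels per subject, and the
direction of the five composite descriptors — not knee anatomy or MRI
physics. Each 48 x 48 ROI is built, in order, from:

1. a correlated Gaussian random field (white noise convolved with a
   Gaussian kernel of the cell's `correlation_length`, unit variance,
   amplitude 20 around base level 100) plus reference white noise of
   sd 2;
2. dark bar-shaped piecewise-constant plateaus (trabecular-like
   hypointense structures) that *replace* the field. Total coverage is
   fixed (~13% of the grid) so `blob_density` trades structure length
   against structure count — the size-vs-number axis that run-length
   and zone-size descriptors measure — without moving the intensity
   histogram. All bars of one ROI share a base dark level
   (100 minus 40–50); each bar's level adds an upward-only jitter of
   sd `12 * min(smoothing, 0.5)`, so small `smoothing` makes the
   plateaus pairwise identical (one dominant co-occurrence cell, high
   joint maximum);
3. sparse single-pixel zones at moderately deviant levels
   (count `29 (smoothing - 0.5)^1.5` above the dead zone 0.5, levels
   ±(0.56–0.71) of the anchor span): each is one connected zone but
   nearly massless in the pixel histogram, so it moves the gray-level
   variance of the zone distribution with ~3x the leverage it has on
   any pixel-weighted descriptor;
4. one small group-independent "artifact patch" (0–28 pixels at a
   near-extreme level), which adds between-subject noise to the
   heavy-tail moments (std, variance) while barely moving the robust
   MAD;
5. two anchor pixels near the extremes (levels ±85 with a small
   lognormal jitter, like calibration markers): they pin the
   quantization range across groups, which keeps the quantized position
   of every structure stable and makes the gain knob exactly affine;
6. an affine intensity gain `noise_sd / 2` about the image mean — the
   dispersion knob: it scales MAD, std, IQR and friends while leaving
   every quantization-invariant matrix descriptor untouched;
7. a per-ROI brightness offset (sd 30), mimicking uncalibrated MRI
   units: absolute-location descriptors (mean, median, percentiles)
   carry no group information.

Subject-level realism comes from differentiated lognormal jitter on the
cell parameters (structure parameters ~20–24%, gain ~7.5%; scanner gain
is more stable than lesion texture). The default parameter table is
calibrated once (and frozen) so that, at the study's group sizes:

* PD-FSE `glcm_jmx`, `glrlm_lrlge`, `glrlm_rlv` are ordered
  BME > INJ > OST (edema: fewer, longer, more level-concentrated
  structures);
* STIR `fo_mad`, `glszm_glzv` are ordered BME < OST < INJ (edema: more
  homogeneous signal, fewer deviant zones).

What a green end-to-end test establishes: the pipeline recovers
*planted, approximately axis-aligned* group contrasts at the study's
sample sizes. What it does not establish: performance on real marrow
texture, where descriptor correlations, artifacts and segmentation
variability are unmodeled; the generator has no Rician noise, no
anatomy, and group contrasts concentrated in five descriptors by
construction. Texture descriptors are intrinsically correlated, so a
handful of siblings of the planted descriptors (e.g. run-length
emphasis next to run-length variance, std/IQR next to MAD) genuinely
co-vary and are expected to appear among flagged features at a rate
under 10% of the 157 null (channel, descriptor) pairs, aggregated over
seeds; the published tables on real data show the same phenomenon at a
higher rate. For the same reason the recovered composite may swap an
individual planted descriptor for a near-collinear sibling in any
single run.

# Numerical choices and limitations

* Ties in the per-pixel Tamura argmax go to the smaller scale; windows
  are truncated at image borders; the coarseness map is restricted to
  pixels whose 16 x 16 window fits inside the image.
* GLCM per-direction normalization happens before feature computation;
  features, not matrices, are averaged. Degenerate directions (no
  valid pair) are skipped; all four degenerate is an error.
* The minimum ROI size is 16 masked pixels (smallest size at which the
  second-order matrices are non-degenerate); Tamura additionally needs
  a 16 x 16 mask bounding box, LBP at least one fully-interior masked
  pixel.
* BH adjustment is monotone by construction (suffix minimum); adjusted
  p-values never fall below raw ones.
* The forest is deterministic given its seed (single-threaded C++
  `mt19937`); every protocol stage derives child seeds from the caller
  seed, so end-to-end runs are bit-reproducible.
* File formats: PNG (via the `png` package), ASCII PGM and plain-text
  grids. DICOM is out of scope here: no reader exists in the target
  environment and descriptor values do not depend on the container
  because of in-mask quantization.
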