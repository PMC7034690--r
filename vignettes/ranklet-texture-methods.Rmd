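---
title: "Intensity-invariant texture radiomics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intensity-invariant texture radiomics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rankletRadiomics)
```

## The problem

Texture statistics computed on absolute pixel intensities are fragile when
images come from different scanners or acquisition settings: a brightness
offset, a contrast rescaling or a display gamma shifts every gray-level bin
and with it every co-occurrence feature, even though the underlying tissue
pattern is unchanged. For small clinical cohorts pooled across
institutions — for instance glioblastoma cases whose IDH genotype is to be
predicted from a tumor region on contrast-enhanced T1-weighted MRI — this
acquisition variance can be larger than the biological signal.

This package addresses the problem by computing texture features not on
intensities but on *ranklet coefficients*: local, orientation-selective
Wilcoxon rank-sum statistics that depend only on the ordering of pixel
values. Any strictly increasing intensity map preserves orderings, so every
ranklet coefficient — and every feature computed from the quantized
coefficients — is *exactly* invariant under such maps. This is a theorem,
not an approximation, and the test suite asserts it bit-for-bit.

## The ranklet transform

The image is tiled with square blocks of side `resolution` (default 4, so
`C = 16` pixels per block), anchored at the top-left corner of the ROI
bounding box. Each block is split into two equal pixel sets X and Y along
one of three Haar-style orientations:

* **vertical** — X = left half-columns, Y = right half-columns;
* **horizontal** — X = top half-rows, Y = bottom half-rows;
* **diagonal** — Y = top-left and bottom-right quadrants, X = the other two.

Ranks `pi(p)` are assigned over all `C` pixels of the block, with mid-ranks
for ties. The Mann–Whitney count

\[ U \;=\; \sum_{p \in Y} \pi(p) \;-\; \frac{C/2\,(C/2+1)}{2} \]

equals the number of cross pairs \((y \in Y, x \in X)\) with \(y > x\),
ties counting one half, out of \(C^2/4\) pairs in total. The coefficient

\[ R \;=\; \frac{U}{C^2/8} - 1 \;\in\; [-1, 1] \]

is \(+1\) when every Y pixel exceeds every X pixel, \(-1\) in the opposite
case and \(0\) for a constant block. The equality between the rank-sum form
and direct pair counting is verified against a brute-force oracle on
thousands of random blocks.

Three conventions had to be fixed where the method description leaves them
open, and are frozen for reproducibility:

* **Ties** take mid-ranks (the standard Wilcoxon treatment), equivalently
  one half per tied cross pair; this is what makes constant blocks map to
  exactly 0.
* **Which half is Y** only flips coefficient signs globally; the assignment
  above is documented and fixed. Features on quantized coefficients are
  unaffected up to bin reflection.
* **Tiling** is non-overlapping (`stride = resolution`). A sliding-window
  variant is available through the `stride` argument, but all defaults and
  all tests use the separated tiling.

Blocks only partially inside the ROI are masked out of downstream feature
extraction so that tumor texture is never contaminated with background.
The transform therefore requires the ROI bounding box to hold at least one
block and fails with an explicit error otherwise.

## Texture features

Coefficients are quantized into `rankletLevels = 8` equal-width bins over
\([-1, 1]\) (the last bin closed so \(+1\) is representable); raw
intensities are quantized into `rawLevels = 32` equal-width bins over
0–255. Neither bin count is prescribed by the method's source material;
8 bins keep the three-level coefficient images well resolved at typical
block counts, and 32 is the common default for 8-bit radiomics. Both are
configurable through `defaultConfig()`.

Gray-level co-occurrence matrices are accumulated at distance `d = 1` and
the four directions 0°, 45°, 90° and 135°, each direction's 14 features
averaged (`averageOverAngles()`). Accumulation is *symmetric* (each pair
counted both ways), the standard Haralick practice, which makes θ and
θ + 180° coincide. Only pairs with **both** endpoints inside the mask are
counted. The 14 features are the classic name set (autocorrelation,
contrast, correlation, cluster prominence, cluster shade, dissimilarity,
energy, entropy, homogeneity, difference variance, difference entropy,
information measure of correlation, inverse difference normalized, inverse
difference moment). Three ambiguities in that list are resolved as
follows, all documented in `?glcmFeatures`:

* *information measure of correlation* is Haralick's first variant,
  \((HXY - HXY1)/\max(HX, HY)\);
* *homogeneity* uses the \(1 + |i-j|\) denominator while *inverse
  difference moment* uses the normalized squared form
  \(1 + (i-j)^2/G^2\) — the two names denote distinct standard features;
* *difference variance* is the variance of the \(p_{x-y}\) distribution.

All entropies use natural logarithms with \(0 \log 0 := 0\). Run-length
matrices (`computeGLRLM()`) count maximal same-level runs per direction,
truncated at mask boundaries, and feed the 11 classical statistics (SRE,
LRE, GLN, RLN, RP, LGRE, HGRE, SRLGE, SRHGE, LRLGE, LRHGE); gray levels
are weighted 1-based so low-gray emphasis stays finite at level 0.

Per case, `extractCaseFeatures()` emits eight panels: raw and three
ranklet-orientation GLCM panels (14 features each) and the four matching
GLRLM panels (11 each) — 100 named values.

## Classification and validation

Feature panels are evaluated separately. The default classifier is
unpenalized maximum-likelihood logistic regression; KNN (`k = 5`,
standardized features) and an RBF SVM (`cost = 1`) are available through
`classifierSpec()` — none of these hyperparameters is prescribed by the
source method, so the defaults are conventional values, echoed in the run
provenance.

*Leave-one-out*: each case is predicted by a model fitted on the other
N − 1 cases; standardization statistics are learned on those N − 1 only
(the suite asserts this against an independently coded fold oracle).
Probabilities at or above the 0.5 threshold call the positive class — the
tie goes to positive so the rule is deterministic. Logistic fits that fail
to converge, separate perfectly, or have aliased coefficients (p ≥ n) fall
back to a lightly ridge-penalized likelihood (λ = 0.01 on standardized
features, fitted by BFGS) and the fold is flagged in the result; cohorts
of a few dozen cases separate routinely, and an unpenalized separated fit
would return degenerate probabilities.

*Stepwise backward elimination* starts from a panel's full feature set and
repeatedly removes the feature whose removal gives the lowest LOO error,
stopping when no removal strictly lowers it. Ties are broken by the
largest Wald p-value in a full-data logistic fit, then lexicographically,
so the procedure is fully deterministic. Selection uses the whole cohort
with LOO error as its criterion — deliberately reproducing the classical
(optimistically biased) protocol in which selection and validation share
the data; the reported LOO accuracy is therefore a *resubstitution-flavored*
estimate, not an honest generalization bound.

Per-feature screening first checks normality per class with the
Lilliefors-corrected Kolmogorov–Smirnov test — the correction is needed
because mean and SD are estimated from the sample — then applies Student's
t-test when both classes pass at α = 0.05 and the Mann–Whitney U test
otherwise. P-values are reported raw, with a Bonferroni column alongside.
Classifier accuracies are compared with Pearson's chi-squared test on the
2 × 2 correct/incorrect table, without continuity correction.

## The synthetic cohort generator

`generateTextureImage()` draws a Gaussian random field: white noise
smoothed with a Gaussian kernel of scale `correlationLength` pixels, mixed
with weight `heterogeneity` with a rougher field (quarter the correlation
length), standardized and mapped affinely to integers in [30, 220]. The
sub-range leaves headroom so brightness/contrast jitter and the standard
perturbation set remain strictly monotone without clipping; the pipeline's
normalization stretches to the full 0–255 before features anyway. The ROI
is a centered ellipse (semi-axes 20% of each side, ≈13% of the image
area) with a small seeded angular ripple so the boundary is irregular.

The default two-class conditions are `correlationLength = 8,
heterogeneity = 0.1` for the negative (wild-type-like, smoother) class and
`correlationLength = 2, heterogeneity = 0.5` for the positive
(mutant-like) class — one scalar axis, spatial homogeneity, mirrors the
direction in which mutant tumors are reported to differ, and the defaults
were fixed once at values giving a clear but not trivial contrast at the
32 + 7 cohort scale. `generateCohort()` derives per-case sub-seeds as
`(seed + 7919 · index) mod (2³¹ − 1)` so any case is reproducible
independent of generation order, and applies per-case brightness (±12) and
contrast (×0.9–1.1) jitter to mimic cross-scanner variation.

What the generator does *not* emulate: brain anatomy, MR physics (bias
fields, Rician noise), partial-volume tumor margins, 3D structure, or
class differences beyond spatial correlation. Passing tests therefore
demonstrate that the pipeline recovers a texture-homogeneity contrast
under cross-scanner-style intensity nuisance — they do not certify
clinical performance on real MRI.

`invarianceReport()` quantifies the motivating claim on any case: features
are extracted from the original and from perturbed versions (defaults:
gamma 0.8 and 1.25, brightness +20, contrast ×1.1) and the per-feature SD
across versions is tabulated for the raw panel against the ranklet panels.
Two choices matter here. Perturbed images are *not* re-normalized before
feature extraction — min–max normalization commutes with affine maps, so
re-stretching would exactly undo brightness/contrast changes and the
comparison would degenerate; the report emulates acquisitions reaching the
feature stage as they are. And perturbations are propagated unrounded by
default (`round = FALSE`), which makes the ranklet-panel SD *exactly* zero;
with integer rounding new ties can form and the SDs are merely near zero.
Saturating magnitudes are rejected so the invariance theorem's hypothesis
(strict monotonicity on the observed range) always holds.

## Numerical and degenerate-input conventions

* Intensity normalization rounds half-up (`floor(x + 0.5)`), not to even;
  a constant image maps to zeros with a warning rather than an error.
* A GLCM with no valid pair, an empty mask, or an ROI bounding box smaller
  than one block each raise explicit errors; a constant-texture GLCM
  reports correlation 0 with a warning (its defining ratio is 0/0).
* A feature constant in both classes yields the degenerate convention
  p = 1, flagged, from `featureSignificance()`.
* Identical classifier outcome tables short-circuit the chi-squared
  comparison to p = 1 exactly.

## Problem sizes used in the checks

The packaged checks run on deliberately small instances chosen to make the
properties sharp rather than to benchmark: 48–64 px synthetic images, a
39-case (32 + 7) default cohort and a 40-case balanced cohort for the
class-contrast test, 1,000 random 4 × 4 blocks for the rank-sum oracle,
200 random masked 8 × 8 images for the co-occurrence oracle, 200 null
draws for type-I calibration and 20 label permutations for the null-LOO
baseline. All randomness is seeded; every generator output is a pure
function of its seed and parameters.

## Known limitations

* Single representative 2D slice per case; no 3D co-occurrence.
* PNG/TIFF input only; DICOM files must be converted upstream.
* The intensity-invariance guarantee applies to strictly monotone maps
  without saturation; clipped highlights break the hypothesis and are
  rejected rather than silently accepted.
* Stepwise selection under whole-cohort LOO error is optimistically
  biased by construction (see above); treat reported accuracies as
  protocol-faithful, not unbiased.
* The GLRLM path shares the ranklet quantization; run-length features on
  three-level-dominated coefficient images are coarse descriptors.
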