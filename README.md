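# rankletRadiomics

Texture radiomics that survive scanner changes. The package predicts a
binary tumor genotype (the motivating application is IDH wild-type vs
mutant glioblastoma on contrast-enhanced axial T1-weighted MRI) from the
texture of a delineated tumor region, using features that are **exactly
invariant** to strictly monotone intensity maps — brightness offsets,
contrast scalings and gamma curves of the kind that differ between
scanners and institutions.

It is written for imaging researchers who have, per case, one grayscale
slice and one binary ROI mask, and want a small, fully deterministic,
testable pipeline: transform → features → feature selection → leave-one-out
validation → metric panel, plus a seeded synthetic-image module so that
every stage can be exercised without clinical data.

## The method

**Ranklet transform.** The image is tiled with `r × r` blocks (default
`r = 4`, `C = r² = 16` pixels), anchored at the ROI bounding box. Each
block is split into equal halves X and Y along three Haar-style
orientations (vertical, horizontal, diagonal). With ranks π(p) over the
block (mid-ranks for ties), the Mann–Whitney count

    U = Σ_{p∈Y} π(p) − (C/2)(C/2+1)/2

counts the cross pairs (y ∈ Y, x ∈ X) with y > x among the C²/4 pairs
(ties ½), and the ranklet coefficient is

    R = U / (C²/8) − 1  ∈  [−1, 1],

+1 when Y dominates X completely, −1 in the opposite case, 0 for flat
blocks. Only rank orderings enter, so R is unchanged by any strictly
increasing intensity map — the invariance is exact and is asserted
bit-for-bit in the tests.

**Features.** Coefficients are quantized to 8 bins over [−1, 1] and raw
intensities to 32 bins over 0–255; masked gray-level co-occurrence
matrices (d = 1; θ = 0°, 45°, 90°, 135°, symmetric, features averaged over
angles) yield the classic 14 Haralick-type statistics per panel, and
masked run-length matrices yield the 11 classical GLRLM statistics.

**Classification.** Per feature panel: stepwise backward elimination under
leave-one-out error with a logistic-regression classifier (KNN and RBF-SVM
available), confusion-metric panel (accuracy, sensitivity, specificity,
PPV, NPV), per-feature significance tests (Lilliefors-screened t or
Mann–Whitney), and chi-squared comparisons between panels.

## Worked example

```r
library(rankletRadiomics)

## one synthetic "mutant-like" case: rough, heterogeneous texture
case <- generateTextureImage(
  textureParams(correlationLength = 2, heterogeneity = 0.5), seed = 7)
case
#> TextureCase 'synth_7': 64 x 64 image, 517 ROI pixels, label NA

rk <- rankletTransform(normalizeIntensity(case@image), roiMask(case))
rk
#> RankletStack: 6 x 6 blocks (resolution 4, stride 4), 23 fully in ROI

row <- extractCaseFeatures(case)   # 4 x 14 GLCM + 4 x 11 GLRLM = 100 values
round(row$features[c("ranklet_vertical_homogeneity",
                     "ranklet_vertical_entropy", "raw_contrast")], 4)
#> ranklet_vertical_homogeneity     ranklet_vertical_entropy
#>                       0.4618                       3.0550
#>                 raw_contrast
#>                      20.1698

## cross-scanner robustness: feature SD across gamma/brightness/contrast
## versions of the same image
rep <- invarianceReport(case)
round(rep$sd[c("autocorrelation", "cluster_prominence", "homogeneity"), ], 4)
#>                          raw ranklet
#> autocorrelation      64.8939       0
#> cluster_prominence 1193.0988       0
#> homogeneity           0.0134       0
```

Raw-intensity features drift by orders of magnitude across perturbed
versions; every ranklet feature is bit-identical (SD exactly 0).

```r
## end to end on the default 32 + 7 synthetic cohort
cohort <- generateCohort(32, 7, seed = 1234)
rows <- lapply(cohort, extractCaseFeatures)
writeFeatureTable(rows, "features.csv")
ds <- readFeatureTable("features.csv")
ds
#> TextureDataset: 39 cases x 100 features (7 positive, 32 negative)

sel <- stepwiseBackwardSelect(ds, classifierSpec("logistic"),
                              features = panelColumns("ranklet_vertical"))
m <- confusionMetrics(sel)
sprintf("LOO accuracy %.3f  sensitivity %.3f  specificity %.3f",
        m$accuracy, m$sensitivity, m$specificity)
#> "LOO accuracy 1.000  sensitivity 1.000  specificity 1.000"
sel$trace
#>                   removed errorCount  errorRate
#> 1                  <none>          1 0.02564103
#> 2 ranklet_vertical_energy          0 0.00000000
```

The selection trace reads bottom-up: the full 14-feature vertical panel
misclassifies one case under leave-one-out; dropping `energy` removes that
error and no further removal improves, so 13 features are kept. On this
well-separated synthetic cohort the selected model classifies all 39 cases
correctly; real cohorts will not be this clean.

A thin command-line front end over the same functions lives at
`inst/cli/rankletcad.R` (verbs `synth`, `extract`, `classify`,
`invariance`).

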