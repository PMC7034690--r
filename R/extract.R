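#' Default extraction / classification configuration
#'
#' Collects every tunable of the pipeline with its default:
#' `resolution = 4` (ranklet block side), `stride = resolution`
#' (non-overlapping tiling), `distance = 1` and
#' `angles = c(0, 45, 90, 135)` for co-occurrence offsets, symmetric GLCM
#' accumulation, `rawLevels = 32` gray bins for the raw-intensity path,
#' `rankletLevels = 8` bins for quantized coefficients, classifier
#' `"logistic"` with probability threshold 0.5, `knn_k = 5`,
#' `svm_cost = 1` with an RBF kernel, and feature standardization on.
#' Any element can be overridden via `...`.
#'
#' @param ... named overrides, e.g. `defaultConfig(rawLevels = 16)`.
#' @return Named list of settings.
#' @export
defaultConfig <- function(...) {
  cfg <- list(
    resolution = 4L, stride = NULL, distance = 1L,
    angles = c(0, 45, 90, 135), symmetric = TRUE,
    rawLevels = 32L, rankletLevels = 8L,
    classifier = "logistic", threshold = 0.5,
    knn_k = 5L, svm_cost = 1, svm_kernel = "radial",
    standardize = TRUE, seed = 1L)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    cfg[names(over)] <- over
  }
  if (is.null(cfg$stride)) cfg$stride <- cfg$resolution
  cfg
}

# Quantize 0..255 intensities to G equal-width bins over the 8-bit range.
quantizeIntensity <- function(p, levels) {
  b <- floor(p * levels / 256)
  b[b > levels - 1L] <- levels - 1L
  storage.mode(b) <- "integer"
  b
}

panelGLCM <- function(qimg, mask, levels, cfg) {
  averageOverAngles(lapply(cfg$angles, function(th)
    glcmFeatures(computeGLCM(qimg, mask, d = cfg$distance, theta = th,
                             levels = levels, symmetric = cfg$symmetric))))
}

panelGLRLM <- function(qimg, mask, levels, cfg) {
  averageOverAngles(lapply(cfg$angles, function(th)
    glrlmFeatures(computeGLRLM(qimg, mask, theta = th, levels = levels))))
}

#' Names of the per-case feature panels
#'
#' @return Character vector of the eight panel names emitted by
#'   [extractCaseFeatures()]: a raw-intensity and three ranklet-orientation
#'   GLCM panels (14 features each) and the matching GLRLM panels
#'   (11 features each).
#' @export
featurePanels <- function() c(
  "raw", "ranklet_vertical", "ranklet_horizontal", "ranklet_diagonal",
  "raw_glrlm", "ranklet_vertical_glrlm", "ranklet_horizontal_glrlm",
  "ranklet_diagonal_glrlm")

#' Column names belonging to one feature panel
#'
#' @param panel one of [featurePanels()].
#' @return Character vector of CSV column names (`<panel>_<feature>`).
#' @export
panelColumns <- function(panel) {
  panel <- match.arg(panel, featurePanels())
  base <- if (grepl("glrlm$", panel)) glrlmFeatureNames() else glcmFeatureNames()
  paste(panel, base, sep = "_")
}

#' Extract all texture feature panels for one case
#'
#' Runs the full per-case pipeline: intensity normalization to 0..255,
#' then (a) the raw path — gray levels reduced to `rawLevels` bins,
#' masked GLCM at the four directions averaged into 14 features, plus the
#' 11 run-length features — and (b) the ranklet path — the
#' orientation-selective transform of [rankletTransform()], coefficients
#' quantized to `rankletLevels` bins, and the same GLCM/GLRLM statistics
#' per orientation, restricted to blocks fully inside the ROI. Panels stay
#' separate (named `<panel>_<feature>`) so classifiers can be run per
#' orientation set.
#'
#' @param case a [TextureCase-class].
#' @param config settings list from [defaultConfig()].
#' @param normalize stretch intensities to 0..255 first (default `TRUE`).
#' @return A list with `case_id`, `label` and `features` (named numeric
#'   vector of 4 x 14 + 4 x 11 = 100 values), ready for
#'   [writeFeatureTable()].
#' @examples
#' case <- generateTextureImage(textureParams(), seed = 7)
#' row <- extractCaseFeatures(case)
#' row$features[["ranklet_vertical_homogeneity"]]
#' @export
extractCaseFeatures <- function(case, config = defaultConfig(),
                                normalize = TRUE) {
  cfg <- config
  img <- if (normalize) normalizeIntensity(case@image) else case@image
  mask <- roiMask(case)
  qraw <- quantizeIntensity(pixels(img), cfg$rawLevels)
  feats <- c()
  raw14 <- panelGLCM(qraw, mask, cfg$rawLevels, cfg)
  names(raw14) <- paste("raw", names(raw14), sep = "_")
  raw11 <- panelGLRLM(qraw, mask, cfg$rawLevels, cfg)
  names(raw11) <- paste("raw_glrlm", names(raw11), sep = "_")
  rk <- rankletTransform(img, mask, resolution = cfg$resolution,
                         stride = cfg$stride)
  q <- quantizeCoefficients(rk, cfg$rankletLevels)
  rk14 <- c(); rk11 <- c()
  for (o in rankletOrientations()) {
    f14 <- panelGLCM(q[[o]], q$mask, cfg$rankletLevels, cfg)
    names(f14) <- paste("ranklet", o, names(f14), sep = "_")
    f11 <- panelGLRLM(q[[o]], q$mask, cfg$rankletLevels, cfg)
    names(f11) <- paste("ranklet", o, "glrlm", names(f11), sep = "_")
    rk14 <- c(rk14, f14); rk11 <- c(rk11, f11)
  }
  ord <- unlist(lapply(featurePanels(), panelColumns))
  features <- c(raw14, rk14, raw11, rk11)[ord]
  list(case_id = case@caseId, label = caseLabel(case), features = features)
}
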