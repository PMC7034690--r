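#' Texture parameters of the synthetic tumor generator
#'
#' The generator draws a Gaussian random field: white noise smoothed with a
#' Gaussian kernel of scale `correlationLength` (pixels), optionally mixed
#' with a second, rougher field component (correlation length one quarter
#' of the first) weighted by `heterogeneity`. Larger correlation length
#' and lower heterogeneity give the visually homogeneous texture of the
#' negative (wild-type-like) class; the positive (mutant-like) class uses
#' a short correlation length and higher heterogeneity, matching the
#' observation that mutant tumors image less homogeneously.
#'
#' @param correlationLength spatial smoothing scale in pixels (>= 0; 0
#'   gives white noise).
#' @param baseMean,baseSd target mean and spread of the mapped intensities.
#' @param heterogeneity mixing weight of the rough component, in `[0, 1]`.
#' @return A list of class `textureParams`.
#' @export
textureParams <- function(correlationLength = 8, baseMean = 125,
                          baseSd = 45, heterogeneity = 0.1) {
  stopifnot(correlationLength >= 0, heterogeneity >= 0, heterogeneity <= 1)
  structure(list(correlationLength = correlationLength, baseMean = baseMean,
                 baseSd = baseSd, heterogeneity = heterogeneity),
            class = "textureParams")
}

#' Default class parameters of the two-class study cohort
#'
#' The negative class is a long-correlation, low-heterogeneity (smooth)
#' texture; the positive class a short-correlation, high-heterogeneity
#' (rough) texture.
#'
#' @return A list with elements `neg` and `pos`, each a [textureParams()].
#' @export
defaultClassParams <- function() list(
  neg = textureParams(correlationLength = 8, heterogeneity = 0.1),
  pos = textureParams(correlationLength = 2, heterogeneity = 0.5))

# Separable Gaussian smoothing with kernel-mass renormalization at the
# borders, via band-matrix multiplication (images here are small).
smoothField <- function(m, scale) {
  if (scale <= 0) return(m)
  bandKernel <- function(n) {
    r <- ceiling(3 * scale)
    k <- exp(-(-r:r)^2 / (2 * scale^2))
    A <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- max(1L, i - r):min(n, i + r)
      A[i, j] <- k[j - i + r + 1L]
    }
    A / rowSums(A)
  }
  bandKernel(nrow(m)) %*% m %*% t(bandKernel(ncol(m)))
}

ellipseMask <- function(shape, jitterPhase = 0) {
  H <- shape[1L]; W <- shape[2L]
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  a <- 0.2 * H; b <- 0.2 * W
  yy <- matrix(seq_len(H), H, W); xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  theta <- atan2(yy - cy, xx - cx)
  # slightly irregular boundary: low-order angular ripple on the radius
  wobble <- 1 + 0.08 * sin(3 * theta + jitterPhase)
  ((yy - cy) / (a * wobble))^2 + ((xx - cx) / (b * wobble))^2 <= 1
}

#' Generate one synthetic tumor-like case
#'
#' Draws a seeded Gaussian-random-field texture (see [textureParams()]),
#' maps it affinely to integers in `[30, 220]` — inside the 8-bit range but
#' with headroom so brightness/contrast perturbations stay strictly
#' monotone without saturating — and places an irregular elliptical ROI
#' (semi-axes 20% of each image side, about 13% of the image area) at the
#' center. Output is a pure function of `params`, `shape` and `seed`.
#'
#' @param params a [textureParams()].
#' @param shape image shape `c(height, width)`, each >= 32.
#' @param seed integer RNG seed.
#' @param label optional binary label to attach.
#' @param caseId identifier (default derived from the seed).
#' @return An unlabeled (or labeled) [TextureCase-class].
#' @examples
#' case <- generateTextureImage(textureParams(), seed = 42)
#' case
#' @export
generateTextureImage <- function(params = textureParams(),
                                 shape = c(64L, 64L), seed,
                                 label = NA_integer_,
                                 caseId = paste0("synth_", seed)) {
  if (length(shape) != 2L || any(shape < 32L))
    stop("parameter error: shape must be at least 32 x 32", call. = FALSE)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  rng <- getRNGState()
  on.exit(restoreRNGState(rng))
  set.seed(as.integer(seed))
  H <- shape[1L]; W <- shape[2L]
  f1 <- smoothField(matrix(stats::rnorm(H * W), H, W), params$correlationLength)
  f2 <- smoothField(matrix(stats::rnorm(H * W), H, W),
                    params$correlationLength / 4)
  std <- function(m) if (stats::sd(m) > 0) (m - mean(m)) / stats::sd(m) else m
  field <- (1 - params$heterogeneity) * std(f1) + params$heterogeneity * std(f2)
  lo <- min(field); hi <- max(field)
  if (hi <= lo) stop("degenerate field: no dynamic range", call. = FALSE)
  p <- roundHalfUp(30 + 190 * (field - lo) / (hi - lo))
  mask <- ellipseMask(shape, jitterPhase = stats::runif(1, 0, 2 * pi))
  textureCase(caseId, grayImage(p), mask, label)
}

getRNGState <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
restoreRNGState <- function(s) {
  if (is.null(s)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", s, envir = globalenv())
}

#' Strictly monotone intensity perturbations
#'
#' Emulates cross-scanner acquisition differences: brightness shift
#' `v + b`, contrast scaling `mean + c (v - mean)` around the image mean,
#' and gamma `255 (v/255)^g`. Each map must remain strictly increasing and
#' non-saturating on the observed value range; magnitudes that would clip
#' against 0 or 255 are rejected so that the rank structure — and hence
#' every ranklet coefficient — is exactly preserved. With `round = TRUE`
#' (default) results are rounded half-up to integers, which can introduce
#' new ties; pass `round = FALSE` to propagate exact values.
#'
#' @param img a [TextureImage-class].
#' @param kind `"brightness"`, `"contrast"` or `"gamma"`.
#' @param magnitude shift `b`, scale `c > 0`, or exponent `g > 0`.
#' @param round round result to integers (half-up).
#' @return A perturbed [TextureImage-class].
#' @examples
#' img <- grayImage(matrix(c(40, 90, 120, 200), 2, 2))
#' pixels(perturbIntensity(img, "brightness", 30))
#' @export
perturbIntensity <- function(img, kind = c("brightness", "contrast", "gamma"),
                             magnitude, round = TRUE) {
  kind <- match.arg(kind)
  p <- pixels(img)
  out <- switch(kind,
    brightness = {
      if (min(p) + magnitude < 0 || max(p) + magnitude > img@bitDepth)
        stop("saturating magnitude: brightness shift of ", magnitude,
             " clips against [0, ", img@bitDepth, "]", call. = FALSE)
      p + magnitude
    },
    contrast = {
      if (magnitude <= 0)
        stop("saturating magnitude: contrast scale must be > 0", call. = FALSE)
      m <- mean(p)
      q <- m + magnitude * (p - m)
      if (min(q) < 0 || max(q) > img@bitDepth)
        stop("saturating magnitude: contrast scale of ", magnitude,
             " clips against [0, ", img@bitDepth, "]", call. = FALSE)
      q
    },
    gamma = {
      if (magnitude <= 0)
        stop("saturating magnitude: gamma must be > 0", call. = FALSE)
      img@bitDepth * (p / img@bitDepth)^magnitude
    })
  if (round) out <- roundHalfUp(out)
  grayImage(out, img@bitDepth)
}

#' Generate a labeled two-class synthetic cohort
#'
#' Produces `nNeg` negative and `nPos` positive cases. Each case gets a
#' deterministic sub-seed, `(seed + 7919 * index) mod (2^31 - 1)`, so any
#' case is reproducible independently of generation order, and a per-case
#' random brightness (within ±12) and contrast (within ×0.9–1.1) jitter to
#' mimic cross-scanner intensity variation.
#'
#' @param nNeg,nPos class sizes, each >= 2 (defaults 32 and 7, a small
#'   imbalanced cohort typical of rare-genotype studies).
#' @param paramsNeg,paramsPos per-class [textureParams()]
#'   (defaults [defaultClassParams()]).
#' @param seed master seed.
#' @param shape image shape.
#' @return List of labeled [TextureCase-class] objects (negatives first).
#' @examples
#' cohort <- generateCohort(4, 3, seed = 11)
#' length(cohort)
#' @export
generateCohort <- function(nNeg = 32L, nPos = 7L,
                           paramsNeg = defaultClassParams()$neg,
                           paramsPos = defaultClassParams()$pos,
                           seed, shape = c(64L, 64L)) {
  if (nNeg < 2L || nPos < 2L)
    stop("parameter error: need at least 2 cases per class", call. = FALSE)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  rng <- getRNGState()
  on.exit(restoreRNGState(rng))
  n <- nNeg + nPos
  labels <- c(rep(0L, nNeg), rep(1L, nPos))
  lapply(seq_len(n), function(i) {
    subSeed <- (as.numeric(seed) + 7919 * i) %% (2^31 - 1)
    params <- if (labels[i] == 0L) paramsNeg else paramsPos
    case <- generateTextureImage(params, shape, seed = subSeed,
                                 label = labels[i],
                                 caseId = sprintf("case_%03d", i))
    set.seed(as.integer((subSeed + 1) %% (2^31 - 1)))
    b <- stats::runif(1, -12, 12)
    cc <- stats::runif(1, 0.9, 1.1)
    img <- perturbIntensity(case@image, "contrast", cc)
    img <- perturbIntensity(img, "brightness", b)
    textureCase(case@caseId, img, roiMask(case), labels[i])
  })
}

#' Cross-scanner invariance report for one case
#'
#' Extracts the raw-intensity GLCM panel and the three ranklet GLCM panels
#' from the original image and from each perturbed version, and reports the
#' per-feature standard deviation across versions for the raw panel versus
#' the ranklet panels. Features are extracted from the given pixel values
#' directly (no re-normalization — re-stretching would exactly undo affine
#' perturbations and mask the raw panel's sensitivity). With exact
#' (unrounded) perturbations every ranklet-panel SD is exactly 0, because
#' strictly monotone maps preserve all within-block ranks; raw-panel SDs
#' are generally positive.
#'
#' @param case a [TextureCase-class].
#' @param perturbations list of `list(kind=, magnitude=)` specs; at least
#'   one, giving >= 2 versions with the original. Default: gamma 0.8 and
#'   1.25, brightness +20, contrast 1.1.
#' @param config settings list from [defaultConfig()].
#' @param round round perturbed intensities to integers before feature
#'   extraction (default `FALSE`: the exact-invariance path).
#' @return A list of class `invarianceReport`: `sd` (features x 2 matrix,
#'   columns `raw` and `ranklet` = the maximum SD over the three
#'   orientations), `values` (feature values per version and panel), and
#'   `perturbations`.
#' @export
invarianceReport <- function(case,
                             perturbations = list(
                               list(kind = "gamma", magnitude = 0.8),
                               list(kind = "gamma", magnitude = 1.25),
                               list(kind = "brightness", magnitude = 20),
                               list(kind = "contrast", magnitude = 1.1)),
                             config = defaultConfig(), round = FALSE) {
  if (length(perturbations) < 1L)
    stop("need at least one perturbation (>= 2 versions in total)",
         call. = FALSE)
  versions <- c(list(original = case@image),
                stats::setNames(
                  lapply(perturbations, function(sp)
                    perturbIntensity(case@image, sp$kind, sp$magnitude,
                                     round = round)),
                  vapply(perturbations, function(sp)
                    paste0(sp$kind, "_", sp$magnitude), "")))
  mask <- roiMask(case)
  panels <- lapply(versions, function(img) {
    qraw <- quantizeIntensity(pixels(img), config$rawLevels)
    raw <- panelGLCM(qraw, mask, config$rawLevels, config)
    rk <- rankletTransform(img, mask, resolution = config$resolution,
                           stride = config$stride)
    q <- quantizeCoefficients(rk, config$rankletLevels)
    ranklet <- lapply(stats::setNames(nm = rankletOrientations()), function(o)
      panelGLCM(q[[o]], q$mask, config$rankletLevels, config))
    c(list(raw = raw), ranklet)
  })
  sdOver <- function(panel) apply(
    do.call(rbind, lapply(panels, `[[`, panel)), 2L, stats::sd)
  rawSd <- sdOver("raw")
  rkSd <- do.call(pmax, lapply(rankletOrientations(), sdOver))
  structure(list(sd = cbind(raw = rawSd, ranklet = rkSd),
                 values = panels, perturbations = perturbations),
            class = "invarianceReport")
}
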