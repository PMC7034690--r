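#' @import methods
NULL

#' TextureImage: a 2D grayscale intensity grid
#'
#' The unit of all transforms in the package: a height x width matrix of
#' non-negative intensities with a nominal bit depth (maximum representable
#' value, 255 for 8-bit data). Pixels are usually integers; real-valued
#' pixels are permitted so that strictly monotone intensity perturbations can
#' be propagated without rounding (see [perturbIntensity()]).
#'
#' @slot pixels numeric matrix of intensities, all in `[0, bitDepth]`.
#' @slot bitDepth nominal maximum representable value (default 255).
#'
#' @seealso [grayImage()], [normalizeIntensity()]
#' @exportClass TextureImage
setClass("TextureImage",
  slots = c(pixels = "matrix", bitDepth = "numeric"),
  validity = function(object) {
    p <- object@pixels
    if (!is.numeric(p)) return("pixels must be a numeric matrix")
    if (nrow(p) < 1L || ncol(p) < 1L) return("image must have at least one pixel")
    if (length(object@bitDepth) != 1L || object@bitDepth <= 0)
      return("bitDepth must be a single positive number")
    if (anyNA(p)) return("pixels must not contain NA")
    if (min(p) < 0 || max(p) > object@bitDepth)
      return(sprintf("pixel values must lie in [0, %g]", object@bitDepth))
    TRUE
  }
)

#' Construct a TextureImage
#'
#' @param pixels numeric matrix of intensities.
#' @param bitDepth nominal maximum representable value; 255 for 8-bit images.
#' @return A [TextureImage-class] object.
#' @examples
#' img <- grayImage(matrix(0:254, 15, 17))
#' dim(pixels(img))
#' @export
grayImage <- function(pixels, bitDepth = 255) {
  storage.mode(pixels) <- "double"
  new("TextureImage", pixels = pixels, bitDepth = as.numeric(bitDepth))
}

#' TextureCase: one case (image + ROI mask + optional label)
#'
#' Pairs a [TextureImage-class] with a congruent binary region-of-interest
#' mask marking the tumor pixels, a case identifier, and an optional binary
#' label (0 = wild-type / negative, 1 = mutant / positive).
#'
#' @slot caseId character scalar, unique within a cohort.
#' @slot image a [TextureImage-class].
#' @slot mask logical matrix, same shape as the image, at least one `TRUE`.
#' @slot label integer, 0, 1 or `NA` when unlabeled.
#'
#' @seealso [textureCase()], [loadCase()], [generateTextureImage()]
#' @exportClass TextureCase
setClass("TextureCase",
  slots = c(caseId = "character", image = "TextureImage",
            mask = "matrix", label = "integer"),
  validity = function(object) {
    if (length(object@caseId) != 1L || !nzchar(object@caseId))
      return("caseId must be a non-empty string")
    if (!is.logical(object@mask)) return("mask must be a logical matrix")
    if (!identical(dim(object@mask), dim(object@image@pixels)))
      return("mask shape must equal image shape")
    if (!any(object@mask)) return("mask must contain at least one ROI pixel")
    if (length(object@label) != 1L || (!is.na(object@label) && !object@label %in% c(0L, 1L)))
      return("label must be 0, 1 or NA")
    TRUE
  }
)

#' Construct a TextureCase
#'
#' @param caseId case identifier.
#' @param image a [TextureImage-class] (or a plain matrix, coerced with
#'   default bit depth).
#' @param mask logical or 0/1 matrix congruent with the image; any nonzero
#'   value counts as ROI.
#' @param label 0 (negative), 1 (positive) or `NA`.
#' @return A [TextureCase-class] object.
#' @export
textureCase <- function(caseId, image, mask, label = NA_integer_) {
  if (is.matrix(image)) image <- grayImage(image)
  if (is.numeric(mask)) mask <- mask != 0
  new("TextureCase", caseId = as.character(caseId), image = image,
      mask = mask, label = as.integer(label))
}

#' RankletStack: orientation-selective ranklet coefficient images
#'
#' Result of [rankletTransform()]: one coefficient grid per orientation
#' (vertical, horizontal, diagonal), each value a normalized rank-sum
#' statistic in `[-1, 1]`, plus a congruent block mask marking the grid
#' cells whose source block lies entirely inside the ROI.
#'
#' @slot coefficients named list of three numeric matrices
#'   (`vertical`, `horizontal`, `diagonal`), identical shapes.
#' @slot mask logical matrix, same shape as each coefficient grid.
#' @slot resolution even block side length in source pixels.
#' @slot stride block origin step in source pixels (equals `resolution`
#'   for the default non-overlapping tiling).
#' @slot anchor integer (row, col) of the tiling origin in the source image.
#'
#' @exportClass RankletStack
setClass("RankletStack",
  slots = c(coefficients = "list", mask = "matrix",
            resolution = "integer", stride = "integer", anchor = "integer"),
  validity = function(object) {
    if (!identical(sort(names(object@coefficients)), sort(rankletOrientations())))
      return("coefficients must be named vertical, horizontal, diagonal")
    d <- dim(object@coefficients[[1L]])
    for (m in object@coefficients) {
      if (!identical(dim(m), d)) return("coefficient grids must share one shape")
      if (length(m) && (min(m) < -1 - 1e-12 || max(m) > 1 + 1e-12))
        return("coefficients must lie in [-1, 1]")
    }
    if (!identical(dim(object@mask), d)) return("block mask shape mismatch")
    if (object@resolution < 2L || object@resolution %% 2L != 0L)
      return("resolution must be even and >= 2")
    TRUE
  }
)

#' GLCMatrix: normalized gray-level co-occurrence matrix
#'
#' A G x G table of probabilities p(i, j | d, theta): how often quantized
#' gray level i co-occurs with level j at offset distance d in direction
#' theta, restricted to pixel pairs whose both endpoints lie inside the ROI
#' mask.
#'
#' @slot p numeric G x G matrix summing to 1.
#' @slot levels number of gray levels G.
#' @slot distance offset distance d in pixels.
#' @slot angle direction theta in degrees (0, 45, 90 or 135).
#' @slot symmetric whether reversed pairs were accumulated too.
#'
#' @seealso [computeGLCM()], [glcmFeatures()]
#' @exportClass GLCMatrix
setClass("GLCMatrix",
  slots = c(p = "matrix", levels = "integer", distance = "integer",
            angle = "numeric", symmetric = "logical"),
  validity = function(object) {
    if (!identical(dim(object@p), c(object@levels, object@levels)))
      return("p must be levels x levels")
    if (min(object@p) < 0) return("probabilities must be non-negative")
    if (abs(sum(object@p) - 1) > 1e-12) return("probabilities must sum to 1")
    if (object@symmetric && max(abs(object@p - t(object@p))) > 1e-12)
      return("symmetric flag set but p is not symmetric")
    TRUE
  }
)

#' RunLengthMatrix: gray-level run-length counts
#'
#' A G x Lmax table r(g, l) counting maximal runs of l consecutive pixels of
#' quantized level g along direction theta, runs truncated at ROI boundaries.
#'
#' @slot counts numeric G x Lmax matrix of non-negative integer counts.
#' @slot levels number of gray levels G.
#' @slot angle direction theta in degrees.
#' @slot nPixels number of in-mask pixels (denominator of run percentage).
#'
#' @seealso [computeGLRLM()], [glrlmFeatures()]
#' @exportClass RunLengthMatrix
setClass("RunLengthMatrix",
  slots = c(counts = "matrix", levels = "integer", angle = "numeric",
            nPixels = "integer"),
  validity = function(object) {
    if (nrow(object@counts) != object@levels)
      return("counts must have one row per gray level")
    if (min(object@counts) < 0 || any(object@counts != round(object@counts)))
      return("counts must be non-negative integers")
    if (object@nPixels < 1L) return("nPixels must be positive")
    TRUE
  }
)

#' TextureDataset: case-by-feature matrix with binary labels
#'
#' Classification-ready container: a numeric cases x features matrix with
#' named columns, one binary label per case (1 = positive class) and unique
#' case identifiers.
#'
#' @slot x numeric matrix, cases in rows, named features in columns.
#' @slot labels integer vector of 0/1 labels, one per case.
#' @slot caseIds character vector of unique case identifiers.
#'
#' @seealso [textureDataset()], [readFeatureTable()], [looEvaluate()]
#' @exportClass TextureDataset
setClass("TextureDataset",
  slots = c(x = "matrix", labels = "integer", caseIds = "character"),
  validity = function(object) {
    if (nrow(object@x) != length(object@labels))
      return("one label per case required")
    if (nrow(object@x) != length(object@caseIds))
      return("one case id per case required")
    if (anyDuplicated(object@caseIds)) return("case ids must be unique")
    if (is.null(colnames(object@x))) return("features must be named")
    if (anyNA(object@x)) return("feature matrix must not contain NA")
    if (anyNA(object@labels) || !all(object@labels %in% c(0L, 1L)))
      return("labels must be 0 or 1")
    TRUE
  }
)

#' Construct a TextureDataset
#'
#' @param x numeric cases x features matrix with column names.
#' @param labels 0/1 vector, one per row of `x` (1 = positive class).
#' @param caseIds unique case identifiers; defaults to rownames of `x` or
#'   `case_1 ... case_n`.
#' @return A [TextureDataset-class].
#' @export
textureDataset <- function(x, labels, caseIds = NULL) {
  x <- as.matrix(x)
  if (is.null(caseIds)) {
    caseIds <- if (!is.null(rownames(x))) rownames(x) else paste0("case_", seq_len(nrow(x)))
  }
  new("TextureDataset", x = x, labels = as.integer(labels),
      caseIds = as.character(caseIds))
}
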