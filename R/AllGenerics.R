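#' Accessors for package classes
#'
#' Small accessor generics: `pixels()` returns the intensity matrix of a
#' [TextureImage-class] or [TextureCase-class]; `roiMask()` the logical ROI
#' mask; `caseLabel()` the binary label; `coefficientImages()` the list of
#' orientation coefficient grids of a [RankletStack-class]; `glcmProb()` the
#' probability table of a [GLCMatrix-class]; `runCounts()` the run-count
#' table of a [RunLengthMatrix-class]; `featureMatrix()`, `caseLabels()` and
#' `caseIds()` the components of a [TextureDataset-class].
#'
#' @param object an object of the documented class.
#' @return The slot value (matrix, list or vector, see above).
#' @name accessors
#' @examples
#' img <- grayImage(matrix(1:12, 3, 4))
#' pixels(img)
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("roiMask", function(object) standardGeneric("roiMask"))
#' @rdname accessors
#' @export
setGeneric("caseLabel", function(object) standardGeneric("caseLabel"))
#' @rdname accessors
#' @export
setGeneric("coefficientImages", function(object) standardGeneric("coefficientImages"))
#' @rdname accessors
#' @export
setGeneric("glcmProb", function(object) standardGeneric("glcmProb"))
#' @rdname accessors
#' @export
setGeneric("runCounts", function(object) standardGeneric("runCounts"))
#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(object) standardGeneric("featureMatrix"))
#' @rdname accessors
#' @export
setGeneric("caseLabels", function(object) standardGeneric("caseLabels"))
#' @rdname accessors
#' @export
setGeneric("caseIds", function(object) standardGeneric("caseIds"))

#' @rdname accessors
setMethod("pixels", "TextureImage", function(object) object@pixels)
#' @rdname accessors
setMethod("pixels", "TextureCase", function(object) object@image@pixels)
#' @rdname accessors
setMethod("roiMask", "TextureCase", function(object) object@mask)
#' @rdname accessors
setMethod("roiMask", "RankletStack", function(object) object@mask)
#' @rdname accessors
setMethod("caseLabel", "TextureCase", function(object) object@label)
#' @rdname accessors
setMethod("coefficientImages", "RankletStack", function(object) object@coefficients)
#' @rdname accessors
setMethod("glcmProb", "GLCMatrix", function(object) object@p)
#' @rdname accessors
setMethod("runCounts", "RunLengthMatrix", function(object) object@counts)
#' @rdname accessors
setMethod("featureMatrix", "TextureDataset", function(object) object@x)
#' @rdname accessors
setMethod("caseLabels", "TextureDataset", function(object) object@labels)
#' @rdname accessors
setMethod("caseIds", "TextureDataset", function(object) object@caseIds)

setMethod("show", "TextureImage", function(object) {
  p <- object@pixels
  cat(sprintf("TextureImage %d x %d, bit depth %g, range [%g, %g]\n",
              nrow(p), ncol(p), object@bitDepth, min(p), max(p)))
})

setMethod("show", "TextureCase", function(object) {
  cat(sprintf("TextureCase '%s': %d x %d image, %d ROI pixels, label %s\n",
              object@caseId, nrow(object@image@pixels), ncol(object@image@pixels),
              sum(object@mask),
              if (is.na(object@label)) "NA" else as.character(object@label)))
})

setMethod("show", "RankletStack", function(object) {
  d <- dim(object@coefficients[[1L]])
  cat(sprintf(paste0("RankletStack: %d x %d blocks (resolution %d, stride %d),",
                     " %d fully in ROI\n"),
              d[1L], d[2L], object@resolution, object@stride, sum(object@mask)))
})

setMethod("show", "GLCMatrix", function(object) {
  cat(sprintf("GLCMatrix: %d levels, d = %d, theta = %g deg, %s\n",
              object@levels, object@distance, object@angle,
              if (object@symmetric) "symmetric" else "asymmetric"))
})

setMethod("show", "RunLengthMatrix", function(object) {
  cat(sprintf("RunLengthMatrix: %d levels, max run %d, theta = %g deg, %d runs\n",
              object@levels, ncol(object@counts), object@angle,
              as.integer(sum(object@counts))))
})

setMethod("show", "TextureDataset", function(object) {
  cat(sprintf("TextureDataset: %d cases x %d features (%d positive, %d negative)\n",
              nrow(object@x), ncol(object@x), sum(object@labels == 1L),
              sum(object@labels == 0L)))
})
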