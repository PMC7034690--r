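#' Orientations of the ranklet transform
#'
#' @return `c("vertical", "horizontal", "diagonal")` — the three Haar-style
#'   split orientations used by the transform.
#' @export
rankletOrientations <- function() c("vertical", "horizontal", "diagonal")

#' Split a square block into the two Haar half-sets X and Y
#'
#' Each even-sided block is partitioned into two equal pixel sets following
#' the Haar wavelet supports: `vertical` compares left vs right half-columns
#' (X = left, Y = right), `horizontal` compares top vs bottom half-rows
#' (X = top, Y = bottom), and `diagonal` compares the quadrant pairs
#' (Y = top-left + bottom-right, X = top-right + bottom-left). The
#' assignment of which half is Y is a fixed convention: swapping it only
#' flips the sign of every coefficient.
#'
#' @param side even block side length.
#' @param orientation one of [rankletOrientations()].
#' @return A logical `side x side` matrix, `TRUE` marking Y-set pixels.
#' @examples
#' splitBlock(4, "vertical")
#' @export
splitBlock <- function(side, orientation) {
  side <- as.integer(side)
  if (side < 2L || side %% 2L != 0L)
    stop("geometry error: block side must be even and >= 2", call. = FALSE)
  orientation <- match.arg(orientation, rankletOrientations())
  h <- side %/% 2L
  row <- matrix(seq_len(side), side, side)
  col <- matrix(seq_len(side), side, side, byrow = TRUE)
  switch(orientation,
    vertical   = col > h,
    horizontal = row > h,
    diagonal   = (row <= h & col <= h) | (row > h & col > h))
}

#' Ranklet coefficient of one block
#'
#' The Wilcoxon rank-sum statistic of the block's Y half against its X half,
#' normalized to `[-1, 1]`. With ranks `pi(p)` assigned over all `C` pixels
#' of the block (mid-ranks for ties),
#' `U = sum(pi(p), p in Y) - (C/2)(C/2 + 1)/2` counts, out of the
#' `C^2/4` cross pairs `(y, x)`, those with `y > x` (ties count 1/2), and
#' the coefficient is `R = U / (C^2/8) - 1`. `R = +1` iff every Y pixel
#' exceeds every X pixel, `-1` in the opposite case, and 0 for an all-tie
#' (constant) block. Because only ranks enter, the coefficient is exactly
#' invariant under any strictly increasing intensity map.
#'
#' @param block square numeric matrix with even side.
#' @param orientation one of [rankletOrientations()].
#' @return A number in `[-1, 1]`.
#' @examples
#' rankletCoefficient(matrix(c(1, 2, 3, 4), 2, 2), "vertical")  # +1
#' @export
rankletCoefficient <- function(block, orientation) {
  ySet <- splitBlock(nrow(block), orientation)
  if (ncol(block) != nrow(block))
    stop("geometry error: block must be square", call. = FALSE)
  C <- length(block)
  ranks <- rank(block, ties.method = "average")
  U <- sum(ranks[ySet]) - (C / 2) * (C / 2 + 1) / 2
  U / (C^2 / 8) - 1
}

#' Ranklet transform of a masked image
#'
#' Tiles the image with `resolution x resolution` blocks anchored at the
#' top-left corner of the ROI bounding box and computes, for every block and
#' each of the three orientations, the normalized rank-sum coefficient of
#' [rankletCoefficient()]. The default `stride = resolution` gives
#' non-overlapping blocks; trailing blocks that would cross the bounding box
#' are discarded. A block-grid mask cell is `TRUE` only when every source
#' pixel of its block lies inside the ROI, so partially covered blocks are
#' excluded from downstream feature extraction.
#'
#' @param img a [TextureImage-class] (typically [normalizeIntensity()]
#'   output) or plain matrix.
#' @param mask logical ROI matrix congruent with the image.
#' @param resolution even block side in pixels (default 4).
#' @param stride block origin step; defaults to `resolution`
#'   (non-overlapping tiling).
#' @return A [RankletStack-class] with one coefficient grid per orientation.
#' @examples
#' img <- matrix(rep(c(0, 0, 200, 200), each = 4), 4, 4, byrow = TRUE)
#' rk <- rankletTransform(grayImage(img), matrix(TRUE, 4, 4))
#' coefficientImages(rk)$horizontal
#' @export
rankletTransform <- function(img, mask, resolution = 4L, stride = resolution) {
  p <- if (is(img, "TextureImage")) img@pixels else as.matrix(img)
  resolution <- as.integer(resolution); stride <- as.integer(stride)
  if (resolution < 2L || resolution %% 2L != 0L)
    stop("geometry error: resolution must be even and >= 2", call. = FALSE)
  if (stride < 1L) stop("stride must be >= 1", call. = FALSE)
  if (!identical(dim(mask), dim(p)))
    stop("shape mismatch between image and mask", call. = FALSE)
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  bbH <- rr[2L] - rr[1L] + 1L; bbW <- cc[2L] - cc[1L] + 1L
  if (bbH < resolution || bbW < resolution)
    stop(sprintf("too-small ROI: bounding box %d x %d cannot hold one %d x %d block",
                 bbH, bbW, resolution, resolution), call. = FALSE)
  origR <- seq.int(rr[1L], rr[2L] - resolution + 1L, by = stride)
  origC <- seq.int(cc[1L], cc[2L] - resolution + 1L, by = stride)
  ySets <- lapply(rankletOrientations(), function(o) splitBlock(resolution, o))
  names(ySets) <- rankletOrientations()
  C <- resolution^2
  base <- (C / 2) * (C / 2 + 1) / 2
  coefs <- lapply(rankletOrientations(), function(o)
    matrix(0, length(origR), length(origC)))
  names(coefs) <- rankletOrientations()
  bmask <- matrix(FALSE, length(origR), length(origC))
  for (i in seq_along(origR)) {
    for (j in seq_along(origC)) {
      blk <- p[origR[i]:(origR[i] + resolution - 1L),
               origC[j]:(origC[j] + resolution - 1L)]
      ranks <- rank(blk, ties.method = "average")
      for (o in rankletOrientations())
        coefs[[o]][i, j] <- (sum(ranks[ySets[[o]]]) - base) / (C^2 / 8) - 1
      bmask[i, j] <- all(mask[origR[i]:(origR[i] + resolution - 1L),
                              origC[j]:(origC[j] + resolution - 1L)])
    }
  }
  new("RankletStack", coefficients = coefs, mask = bmask,
      resolution = resolution, stride = stride,
      anchor = c(rr[1L], cc[1L]))
}

#' Quantize ranklet coefficients to integer gray levels
#'
#' Linear binning of `[-1, 1]` into `G` equal-width bins for co-occurrence /
#' run-length analysis: bins are half-open `[lo, hi)` except the last, which
#' is closed, so `-1` maps to bin 0 and `+1` to bin `G - 1`.
#'
#' @param rimg a [RankletStack-class], or a single numeric coefficient
#'   matrix with values in `[-1, 1]`.
#' @param levels number of bins `G >= 2` (default 8).
#' @return For a matrix: an integer matrix of bins `0..G-1`. For a
#'   [RankletStack-class]: a named list of such matrices plus the block mask
#'   (`$mask`).
#' @examples
#' quantizeCoefficients(matrix(c(-1, 0, 0.999, 1), 2, 2), 8)
#' @export
quantizeCoefficients <- function(rimg, levels = 8L) {
  levels <- as.integer(levels)
  if (levels < 2L) stop("parameter error: levels must be >= 2", call. = FALSE)
  binOne <- function(m) {
    if (length(m) && (min(m) < -1 - 1e-12 || max(m) > 1 + 1e-12))
      stop("coefficients must lie in [-1, 1]", call. = FALSE)
    b <- floor((m + 1) / 2 * levels)
    b[b > levels - 1L] <- levels - 1L   # +1 falls in the closed last bin
    storage.mode(b) <- "integer"
    b
  }
  if (is(rimg, "RankletStack")) {
    out <- lapply(coefficientImages(rimg), binOne)
    out$mask <- roiMask(rimg)
    out
  } else binOne(as.matrix(rimg))
}
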