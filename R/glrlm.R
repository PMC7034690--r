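# Extract the pixel sequences ("chords") of an image along direction theta,
# as a list of integer vectors with NA at out-of-mask pixels. Runs are
# broken at NA, so mask boundaries truncate runs.
directionLines <- function(img, mask, theta) {
  v <- img
  v[!mask] <- NA_integer_
  H <- nrow(v); W <- ncol(v)
  switch(as.character(theta),
    "0"   = lapply(seq_len(H), function(r) v[r, ]),
    "90"  = lapply(seq_len(W), function(c) v[, c]),
    # 45 deg runs along (-1, +1): anti-diagonals, constant r + c
    "45"  = {
      rc <- row(v) + col(v)
      lapply(sort(unique(as.vector(rc))), function(s) {
        sel <- which(rc == s)
        sel <- sel[order(-((sel - 1L) %% H))]   # ascending column = ascending -row
        v[sel]
      })
    },
    # 135 deg runs along (-1, -1): main diagonals, constant r - c
    "135" = {
      rc <- row(v) - col(v)
      lapply(sort(unique(as.vector(rc))), function(s) {
        sel <- which(rc == s)
        sel <- sel[order((sel - 1L) %% H)]      # ascending row
        v[sel]
      })
    },
    stop("angle must be one of 0, 45, 90, 135 degrees", call. = FALSE))
}

#' Masked gray-level run-length matrix
#'
#' Counts maximal runs of consecutive equal gray levels along direction
#' `theta` into a table `r(g, l)` (gray level by run length). Only in-mask
#' pixels participate; a run is truncated where the line leaves the mask.
#'
#' @param img integer matrix of gray levels in `0..levels-1`.
#' @param mask logical matrix congruent with `img` (default: all `TRUE`).
#' @param theta direction in degrees: 0, 45, 90 or 135.
#' @param levels number of gray levels G.
#' @return A [RunLengthMatrix-class].
#' @examples
#' img <- matrix(c(0L, 0L, 0L, 1L, 1L), 1, 5)
#' runCounts(computeGLRLM(img, theta = 0, levels = 2))
#' @export
computeGLRLM <- function(img, mask = NULL, theta = 0, levels) {
  img <- as.matrix(img)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(img), ncol(img))
  if (!identical(dim(mask), dim(img)))
    stop("shape mismatch between image and mask", call. = FALSE)
  if (!any(mask)) stop("degenerate run-length input: empty mask", call. = FALSE)
  levels <- as.integer(levels)
  if (min(img[mask]) < 0L || max(img[mask]) > levels - 1L)
    stop("gray levels must lie in 0..levels-1", call. = FALSE)
  runs <- list()
  for (line in directionLines(img, mask, theta)) {
    r <- rle(as.vector(line))
    keep <- !is.na(r$values)
    if (any(keep)) runs[[length(runs) + 1L]] <-
      cbind(g = r$values[keep], l = r$lengths[keep])
  }
  runs <- do.call(rbind, runs)
  Lmax <- max(runs[, "l"])
  counts <- matrix(0, levels, Lmax)
  for (k in seq_len(nrow(runs)))
    counts[runs[k, "g"] + 1L, runs[k, "l"]] <-
      counts[runs[k, "g"] + 1L, runs[k, "l"]] + 1
  new("RunLengthMatrix", counts = counts, levels = levels,
      angle = as.numeric(theta), nPixels = as.integer(sum(mask)))
}

#' Names of the 11 run-length features
#'
#' @return Character vector of the 11 classical GLRLM statistics in their
#'   fixed output order: SRE, LRE, GLN, RLN, RP, LGRE, HGRE, SRLGE, SRHGE,
#'   LRLGE, LRHGE.
#' @export
glrlmFeatureNames <- function() c(
  "sre", "lre", "gln", "rln", "rp",
  "lgre", "hgre", "srlge", "srhge", "lrlge", "lrhge")

#' The 11 classical run-length features
#'
#' With `r(g, l)` the run counts, `Nr` the total number of runs, `Np` the
#' number of in-mask pixels, run length `l` and gray level `g` indexed from
#' 1 (level 0 is weighted as 1 so low-gray emphasis stays finite):
#' short/long run emphasis `sum r / l^2 / Nr`, `sum r l^2 / Nr`; gray-level
#' and run-length non-uniformity `sum_g (sum_l r)^2 / Nr`,
#' `sum_l (sum_g r)^2 / Nr`; run percentage `Nr / Np`; low/high gray-level
#' run emphasis with `1/g^2` and `g^2` weights; and the four joint
#' short/long x low/high emphases.
#'
#' @param R a [RunLengthMatrix-class].
#' @return Named numeric vector of length 11, names [glrlmFeatureNames()].
#' @export
glrlmFeatures <- function(R) {
  r <- runCounts(R)
  Nr <- sum(r)
  Np <- R@nPixels
  g <- matrix(seq_len(nrow(r)), nrow(r), ncol(r))          # 1-based level
  l <- matrix(seq_len(ncol(r)), nrow(r), ncol(r), byrow = TRUE)
  out <- c(
    sre = sum(r / l^2), lre = sum(r * l^2),
    gln = sum(rowSums(r)^2), rln = sum(colSums(r)^2),
    rp = Nr / Np * Nr,                                      # scaled below
    lgre = sum(r / g^2), hgre = sum(r * g^2),
    srlge = sum(r / (g^2 * l^2)), srhge = sum(r * g^2 / l^2),
    lrlge = sum(r * l^2 / g^2), lrhge = sum(r * g^2 * l^2))
  out / Nr
}
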