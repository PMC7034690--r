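# Row/col offsets for the four standard GLCM/GLRLM directions, in the
# matrix convention (row grows downward): 0 deg -> (0,+d), 45 -> (-d,+d),
# 90 -> (-d,0), 135 -> (-d,-d).
angleOffset <- function(theta, d = 1L) {
  switch(as.character(theta),
    "0"   = c(0L, d),
    "45"  = c(-d, d),
    "90"  = c(-d, 0L),
    "135" = c(-d, -d),
    stop("angle must be one of 0, 45, 90, 135 degrees", call. = FALSE))
}

#' Masked gray-level co-occurrence matrix
#'
#' Counts, over all pixel pairs at offset distance `d` in direction `theta`
#' whose **both** endpoints lie inside the mask, the co-occurrence of
#' quantized gray levels `(i, j)`, and normalizes the counts to
#' probabilities `p(i, j | d, theta)`. In symmetric mode (the default,
#' standard Haralick practice) each pair is also counted reversed, so the
#' matrix is symmetric and directions `theta` and `theta + 180` coincide.
#' No padding or reflection at mask or image boundaries.
#'
#' @param img integer matrix of gray levels in `0..levels-1`.
#' @param mask logical matrix congruent with `img`.
#' @param d offset distance in pixels (default 1).
#' @param theta direction in degrees: 0, 45, 90 or 135.
#' @param levels number of gray levels G.
#' @param symmetric accumulate reversed pairs as well (default `TRUE`).
#' @return A [GLCMatrix-class].
#' @examples
#' img <- matrix(c(0L, 0L, 1L, 1L), 2, 2)   # columns 0 0 | 1 1
#' computeGLCM(img, matrix(TRUE, 2, 2), theta = 0, levels = 2)
#' @export
computeGLCM <- function(img, mask = NULL, d = 1L, theta = 0, levels,
                        symmetric = TRUE) {
  img <- as.matrix(img)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(img), ncol(img))
  if (!identical(dim(mask), dim(img)))
    stop("shape mismatch between image and mask", call. = FALSE)
  levels <- as.integer(levels)
  if (d < 1L) stop("offset distance d must be >= 1", call. = FALSE)
  if (min(img[mask]) < 0L || max(img[mask]) > levels - 1L)
    stop("gray levels must lie in 0..levels-1", call. = FALSE)
  off <- angleOffset(theta, as.integer(d))
  H <- nrow(img); W <- ncol(img)
  rlo <- max(1L, 1L - off[1L]); rhi <- min(H, H - off[1L])
  clo <- max(1L, 1L - off[2L]); chi <- min(W, W - off[2L])
  counts <- matrix(0, levels, levels)
  if (rlo <= rhi && clo <= chi) {
    r0 <- rlo:rhi; c0 <- clo:chi
    a <- img[r0, c0, drop = FALSE]
    b <- img[r0 + off[1L], c0 + off[2L], drop = FALSE]
    ok <- mask[r0, c0, drop = FALSE] & mask[r0 + off[1L], c0 + off[2L], drop = FALSE]
    if (any(ok)) {
      idx <- a[ok] * levels + b[ok]          # 0-based (i, j) -> linear
      tab <- tabulate(idx + 1L, nbins = levels * levels)
      counts <- matrix(tab, levels, levels, byrow = TRUE)
    }
  }
  if (sum(counts) == 0)
    stop("degenerate matrix: no valid pixel pair inside the mask", call. = FALSE)
  if (symmetric) counts <- counts + t(counts)
  new("GLCMatrix", p = counts / sum(counts), levels = levels,
      distance = as.integer(d), angle = as.numeric(theta),
      symmetric = isTRUE(symmetric))
}

#' Marginal and entropy statistics of a GLCM
#'
#' Intermediate quantities shared by the Haralick-type features: marginal
#' distributions `px`, `py` with means/SDs, the sum distribution `px+y(k)`
#' over `k = i + j`, the absolute-difference distribution `px-y(k)` over
#' `k = |i - j|`, and the entropy terms `HX`, `HY`, `HXY`
#' (`-sum p log p`) and `HXY1` (`-sum p(i,j) log(px(i) py(j))`). Natural
#' logarithms; `0 log 0 := 0`. Indices run `0..G-1`.
#'
#' @param P a [GLCMatrix-class].
#' @return A list with elements `px, py, mux, muy, sdx, sdy, pxy_sum,
#'   pxy_diff, HX, HY, HXY, HXY1`.
#' @export
glcmStats <- function(P) {
  p <- glcmProb(P)
  G <- P@levels
  i <- 0:(G - 1L)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(i * px); muy <- sum(i * py)
  sdx <- sqrt(sum((i - mux)^2 * px)); sdy <- sqrt(sum((i - muy)^2 * py))
  im <- matrix(i, G, G); jm <- t(im)
  sumIdx <- im + jm; diffIdx <- abs(im - jm)
  pxySum <- vapply(0:(2L * G - 2L), function(k) sum(p[sumIdx == k]), 0)
  pxyDiff <- vapply(0:(G - 1L), function(k) sum(p[diffIdx == k]), 0)
  names(pxySum) <- 0:(2L * G - 2L); names(pxyDiff) <- 0:(G - 1L)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  pospq <- p > 0
  HXY1 <- -sum(p[pospq] * log((px[row(p)[pospq]] * py[col(p)[pospq]])))
  list(px = px, py = py, mux = mux, muy = muy, sdx = sdx, sdy = sdy,
       pxy_sum = pxySum, pxy_diff = pxyDiff,
       HX = ent(px), HY = ent(py), HXY = ent(p), HXY1 = HXY1)
}

#' Names of the 14 co-occurrence features
#'
#' @return Character vector of the 14 GLCM feature names in their fixed
#'   output order.
#' @export
glcmFeatureNames <- function() c(
  "autocorrelation", "contrast", "correlation", "cluster_prominence",
  "cluster_shade", "dissimilarity", "energy", "entropy", "homogeneity",
  "difference_variance", "difference_entropy",
  "information_measure_of_correlation", "inverse_difference_normalized",
  "inverse_difference_moment")

#' The 14 Haralick-type co-occurrence features
#'
#' With indices `i, j` in `0..G-1` and `p = p(i, j | d, theta)`:
#' autocorrelation `sum ij p`; contrast `sum (i-j)^2 p`; correlation
#' `(sum ij p - mux muy) / (sdx sdy)` (0 with a warning when a marginal SD
#' is zero); cluster prominence `sum (i+j-mux-muy)^4 p`; cluster shade the
#' third-power analogue; dissimilarity `sum |i-j| p`; energy `sum p^2`;
#' entropy `-sum p log p`; homogeneity `sum p / (1 + |i-j|)`; difference
#' variance = variance of the `px-y` distribution; difference entropy
#' `-sum px-y log px-y`; information measure of correlation
#' `(HXY - HXY1) / max(HX, HY)` (first Haralick variant); inverse
#' difference normalized `sum p / (1 + |i-j|/G)`; inverse difference moment
#' `sum p / (1 + (i-j)^2/G^2)` (normalized form). Natural logarithms
#' throughout. Homogeneity and the two inverse-difference forms are
#' distinct features; the formulae here are reconstructions of the classic
#' 14-name feature list from the standard texture-analysis literature.
#'
#' @param P a [GLCMatrix-class].
#' @return Named numeric vector of length 14, names [glcmFeatureNames()].
#' @examples
#' img <- matrix(c(0L, 1L, 0L, 1L), 2, 2)
#' glcmFeatures(computeGLCM(img, theta = 0, levels = 2))
#' @export
glcmFeatures <- function(P) {
  p <- glcmProb(P)
  G <- P@levels
  s <- glcmStats(P)
  i <- 0:(G - 1L)
  im <- matrix(i, G, G); jm <- t(im)
  adiff <- abs(im - jm)
  corr <- if (s$sdx * s$sdy == 0) {
    warning("constant texture: marginal SD is zero; correlation reported as 0")
    0
  } else (sum(im * jm * p) - s$mux * s$muy) / (s$sdx * s$sdy)
  k <- as.numeric(names(s$pxy_diff))
  muDiff <- sum(k * s$pxy_diff)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  imc <- {
    denom <- max(s$HX, s$HY)
    if (denom == 0) 0 else (s$HXY - s$HXY1) / denom
  }
  out <- c(
    autocorrelation = sum(im * jm * p),
    contrast = sum((im - jm)^2 * p),
    correlation = corr,
    cluster_prominence = sum((im + jm - s$mux - s$muy)^4 * p),
    cluster_shade = sum((im + jm - s$mux - s$muy)^3 * p),
    dissimilarity = sum(adiff * p),
    energy = sum(p^2),
    entropy = ent(p),
    homogeneity = sum(p / (1 + adiff)),
    difference_variance = sum((k - muDiff)^2 * s$pxy_diff),
    difference_entropy = ent(s$pxy_diff),
    information_measure_of_correlation = imc,
    inverse_difference_normalized = sum(p / (1 + adiff / G)),
    inverse_difference_moment = sum(p / (1 + (im - jm)^2 / G^2)))
  out[glcmFeatureNames()]
}

#' Average feature vectors over the four directions
#'
#' Element-wise arithmetic mean of feature vectors computed at
#' `theta = 0, 45, 90, 135` degrees, the standard direction-pooling of
#' co-occurrence and run-length features.
#'
#' @param featureList list of named numeric vectors with identical name
#'   sets (one per direction).
#' @return Named numeric vector of the same length.
#' @export
averageOverAngles <- function(featureList) {
  stopifnot(length(featureList) >= 1L)
  nm <- names(featureList[[1L]])
  for (f in featureList)
    if (!identical(names(f), nm))
      stop("schema error: feature vectors have mismatched name sets",
           call. = FALSE)
  colMeans(do.call(rbind, featureList))
}
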