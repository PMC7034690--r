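# Brute-force oracles, written independently of the package internals.

# Haar split geometry re-derived from scratch: TRUE marks the Y set.
oracleYSet <- function(side, orientation) {
  h <- side / 2
  m <- matrix(FALSE, side, side)
  for (r in seq_len(side)) for (c in seq_len(side)) {
    m[r, c] <- switch(orientation,
      vertical = c > h,
      horizontal = r > h,
      diagonal = (r <= h && c <= h) || (r > h && c > h))
  }
  m
}

# Ranklet coefficient by direct enumeration of the C/2 x C/2 cross pairs,
# counting y > x as 1 and ties as 1/2.
oracleRanklet <- function(block, orientation) {
  ySet <- oracleYSet(nrow(block), orientation)
  yv <- block[ySet]; xv <- block[!ySet]
  U <- 0
  for (y in yv) for (x in xv) U <- U + (y > x) + 0.5 * (y == x)
  U / (length(block)^2 / 8) - 1
}

# GLCM by exhaustive pixel-pair enumeration.
oracleGLCM <- function(img, mask, d, theta, levels, symmetric = TRUE) {
  off <- switch(as.character(theta),
    "0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0), "135" = c(-d, -d))
  counts <- matrix(0, levels, levels)
  H <- nrow(img); W <- ncol(img)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    r2 <- r + off[1]; c2 <- c + off[2]
    if (r2 >= 1 && r2 <= H && c2 >= 1 && c2 <= W && mask[r, c] && mask[r2, c2]) {
      i <- img[r, c] + 1; j <- img[r2, c2] + 1
      counts[i, j] <- counts[i, j] + 1
      if (symmetric) counts[j, i] <- counts[j, i] + 1
    }
  }
  counts / sum(counts)
}

# Total number of maximal runs along theta by a pixel-by-pixel scanner.
oracleRunCount <- function(img, mask, theta) {
  off <- switch(as.character(theta),
    "0" = c(0, 1), "45" = c(-1, 1), "90" = c(-1, 0), "135" = c(-1, -1))
  H <- nrow(img); W <- ncol(img)
  inside <- function(r, c) r >= 1 && r <= H && c >= 1 && c <= W && mask[r, c]
  runs <- 0
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (!mask[r, c]) next
    # a run starts where the previous pixel along the direction is absent
    # or differs in value
    pr <- r - off[1]; pc <- c - off[2]
    starts <- !inside(pr, pc) || img[pr, pc] != img[r, c]
    if (starts) runs <- runs + 1
  }
  runs
}

# A random test case: smooth-ish integer image with an irregular mask.
randomMaskedImage <- function(side = 8, levels = 4, maskFrac = 0.8) {
  img <- matrix(sample(0:(levels - 1), side * side, replace = TRUE), side, side)
  mask <- matrix(stats::runif(side * side) < maskFrac, side, side)
  if (!any(mask)) mask[1, 1] <- TRUE
  list(img = img, mask = mask)
}
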