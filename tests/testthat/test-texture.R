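test_that("computeGLCM counts masked pairs per the standard offsets", {
  img <- matrix(c(0L, 0L, 1L, 1L), 2, 2)     # columns 0 0 | 1 1
  P <- computeGLCM(img, theta = 0, levels = 2)
  expect_equal(glcmProb(P), matrix(c(0, 0.5, 0.5, 0), 2, 2))
  expect_equal(sum(glcmProb(P)), 1)

  Pc <- computeGLCM(matrix(3L, 4, 4), theta = 45, levels = 5)
  expect_equal(glcmProb(Pc)[4, 4], 1)        # single entry p(v, v) = 1

  m <- matrix(FALSE, 3, 3); m[2, 2] <- TRUE
  expect_error(computeGLCM(matrix(0L, 3, 3), m, theta = 0, levels = 2),
               "degenerate")
})

test_that("masked GLCM equals the exhaustive pair-enumeration oracle", {
  set.seed(41)
  for (i in 1:40) {
    tc <- randomMaskedImage(8, 4)
    for (th in c(0, 45, 90, 135)) {
      ok <- tryCatch(
        computeGLCM(tc$img, tc$mask, d = 1, theta = th, levels = 4),
        error = function(e) NULL)
      if (is.null(ok)) next      # no valid pair for this draw/angle
      expect_equal(glcmProb(ok), oracleGLCM(tc$img, tc$mask, 1, th, 4))
    }
  }
})

test_that("symmetric GLCMs coincide for theta and theta + 180", {
  # theta + 180 reverses the offset; with symmetric accumulation the pair
  # set is closed under reversal, so flipping the image along the offset
  # axis must leave the matrix unchanged.
  set.seed(42)
  img <- matrix(sample(0:3, 64, TRUE), 8, 8)
  P0 <- glcmProb(computeGLCM(img, theta = 0, levels = 4))
  P180 <- glcmProb(computeGLCM(img[, 8:1], theta = 0, levels = 4))
  expect_equal(P0, P180)
  expect_equal(P0, t(P0))
})

test_that("glcmStats matches direct definitions", {
  img <- matrix(c(0L, 0L, 1L, 1L), 2, 2)
  s <- glcmStats(computeGLCM(img, theta = 0, levels = 2))
  expect_equal(s$mux, s$muy)                 # symmetric matrix
  expect_equal(s$sdx, s$sdy)
  expect_equal(s$mux, 0.5)
  expect_equal(unname(s$pxy_diff), c(0, 1))

  # diagonal p = diag(0.5, 0.5): px-y = (1, 0), mux = 0.5
  Pd <- new("GLCMatrix", p = diag(c(0.5, 0.5)), levels = 2L,
            distance = 1L, angle = 0, symmetric = TRUE)
  sd2 <- glcmStats(Pd)
  expect_equal(unname(sd2$pxy_diff), c(1, 0))
  expect_equal(sd2$mux, 0.5)

  # independence: p = px x py gives HXY = HXY1
  px <- c(0.3, 0.7); py <- c(0.6, 0.4)
  Pi <- new("GLCMatrix", p = outer(px, py), levels = 2L, distance = 1L,
            angle = 0, symmetric = FALSE)
  si <- glcmStats(Pi)
  expect_equal(si$HXY, si$HXY1)
})

test_that("closed-form feature values on degenerate and two-level images", {
  f <- suppressWarnings(   # constant texture also warns about correlation
    glcmFeatures(computeGLCM(matrix(2L, 4, 4), theta = 0, levels = 4)))
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["dissimilarity"]), 0)
  expect_equal(unname(f["energy"]), 1)
  expect_equal(unname(f["entropy"]), 0)
  expect_equal(unname(f["homogeneity"]), 1)

  # alternating 2-level image: p(0,1) = p(1,0) = 0.5
  alt <- matrix(rep_len(c(0L, 1L), 25), 5, 5)
  fa <- glcmFeatures(computeGLCM(alt, theta = 0, levels = 2))
  expect_equal(unname(fa["contrast"]), 1)
  expect_equal(unname(fa["energy"]), 0.5)
  expect_equal(unname(fa["entropy"]), log(2))
  expect_equal(unname(fa["homogeneity"]), 0.5)
  expect_equal(unname(fa["difference_variance"]), 0)

  # uniform matrix: energy 1/G^2, information measure of correlation 0
  G <- 4L
  Pu <- new("GLCMatrix", p = matrix(1 / G^2, G, G), levels = G,
            distance = 1L, angle = 0, symmetric = TRUE)
  fu <- glcmFeatures(Pu)
  expect_equal(unname(fu["energy"]), 1 / G^2)
  expect_equal(unname(fu["information_measure_of_correlation"]), 0)
})

test_that("constant texture reports correlation 0 with a warning", {
  P <- computeGLCM(matrix(2L, 4, 4), theta = 0, levels = 4)
  expect_warning(f <- glcmFeatures(P), "correlation")
  expect_equal(unname(f["correlation"]), 0)
})

test_that("averageOverAngles is the element-wise mean with schema checks", {
  v <- setNames(as.numeric(1:3), c("a", "b", "c"))
  expect_equal(averageOverAngles(list(v, v, v, v)), v)
  vs <- lapply(1:4, function(k) setNames(c(k, 0, 0), c("a", "b", "c")))
  expect_equal(averageOverAngles(vs)[["a"]], 2.5)
  bad <- list(v, setNames(1:3, c("a", "b", "z")))
  expect_error(averageOverAngles(bad), "schema")
})

test_that("disorder decreases homogeneity and increases entropy on average", {
  set.seed(77)
  swapDisorder <- function(frac) {
    img <- matrix(rep(rep(c(0L, 3L), each = 4), 16), 32, 32)  # striped
    n <- length(img)
    k <- round(frac * n / 2)
    idx <- sample(n, 2 * k)
    img[idx] <- img[rev(idx)]
    glcmFeatures(computeGLCM(img, theta = 0, levels = 4))
  }
  reps <- 10
  lowH <- mean(replicate(reps, swapDisorder(0.05)["homogeneity"]))
  hiH <- mean(replicate(reps, swapDisorder(0.5)["homogeneity"]))
  lowE <- mean(replicate(reps, swapDisorder(0.05)["entropy"]))
  hiE <- mean(replicate(reps, swapDisorder(0.5)["entropy"]))
  expect_gt(lowH, hiH)
  expect_lt(lowE, hiE)
})

test_that("run-length matrices enumerate maximal masked runs", {
  img <- matrix(c(0L, 0L, 0L, 1L, 1L), 1, 5)
  R <- computeGLRLM(img, theta = 0, levels = 2)
  counts <- runCounts(R)
  expect_equal(counts[1, 3], 1)   # run (0, length 3)
  expect_equal(counts[2, 2], 1)   # run (1, length 2)
  expect_equal(sum(counts), 2)

  # constant row of n pixels: single run, SRE = 1/n^2, LRE = n^2
  n <- 6
  Rc <- computeGLRLM(matrix(1L, 1, n), theta = 0, levels = 2)
  fc <- glrlmFeatures(Rc)
  expect_equal(unname(fc["sre"]), 1 / n^2)
  expect_equal(unname(fc["lre"]), n^2)

  chk <- outer(1:6, 1:6, function(a, b) (a + b) %% 2L)
  fck <- glrlmFeatures(computeGLRLM(chk, theta = 0, levels = 2))
  expect_equal(unname(fck["rp"]), 1)   # all runs have length 1

  # a mask boundary truncates runs
  m <- matrix(TRUE, 1, 5); m[1, 3] <- FALSE
  Rm <- computeGLRLM(matrix(0L, 1, 5), m, theta = 0, levels = 1)
  expect_equal(runCounts(Rm)[1, 2], 2)   # two runs of length 2

  expect_error(computeGLRLM(img, matrix(FALSE, 1, 5), theta = 0, levels = 2),
               "empty mask")
})

test_that("total run counts match a brute-force scanner on random inputs", {
  set.seed(51)
  for (i in 1:30) {
    tc <- randomMaskedImage(8, 3)
    for (th in c(0, 45, 90, 135)) {
      R <- computeGLRLM(tc$img, tc$mask, theta = th, levels = 3)
      expect_equal(sum(runCounts(R)), oracleRunCount(tc$img, tc$mask, th))
    }
  }
})

test_that("per-case extraction yields the full named panel set", {
  case <- generateTextureImage(textureParams(), seed = 5)
  row <- extractCaseFeatures(case)
  expect_length(row$features, 4 * 14 + 4 * 11)
  expect_equal(names(row$features),
               unlist(lapply(featurePanels(), panelColumns),
                      use.names = FALSE))
  expect_false(anyNA(row$features))

  tiny <- textureCase("t", matrix(sample(0:255, 100, TRUE), 10, 10),
                      {m <- matrix(FALSE, 10, 10); m[4:6, 4:6] <- TRUE; m})
  expect_error(extractCaseFeatures(tiny), "too-small ROI")
})

test_that("gamma perturbation leaves ranklet panels identical, raw panels not", {
  case <- generateTextureImage(textureParams(correlationLength = 3), seed = 9)
  pert <- textureCase(case@caseId,
                      perturbIntensity(case@image, "gamma", 1.3, round = FALSE),
                      roiMask(case))
  a <- extractCaseFeatures(case, normalize = FALSE)$features
  b <- extractCaseFeatures(pert, normalize = FALSE)$features
  rkCols <- unlist(lapply(grep("^ranklet", featurePanels(), value = TRUE),
                          panelColumns))
  expect_identical(a[rkCols], b[rkCols])
  expect_gt(max(abs(a[paste0("raw_", glcmFeatureNames())] -
                    b[paste0("raw_", glcmFeatureNames())])), 0)
})
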