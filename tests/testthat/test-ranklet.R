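test_that("splitBlock follows the fixed Haar conventions", {
  v <- splitBlock(4, "vertical")
  expect_equal(sum(v), 8)
  expect_true(all(v[, 3:4]) && !any(v[, 1:2]))     # Y = right half
  h <- splitBlock(4, "horizontal")
  expect_true(all(h[3:4, ]) && !any(h[1:2, ]))     # Y = bottom half
  dg <- splitBlock(4, "diagonal")
  expect_true(all(dg[1:2, 1:2]) && all(dg[3:4, 3:4]))
  expect_false(any(dg[1:2, 3:4]) || any(dg[3:4, 1:2]))
  expect_error(splitBlock(3, "vertical"), "geometry")
})

test_that("ranklet coefficients match hand-derived rank-sum values", {
  # columns of matrix(): [[1,3],[2,4]] has X = {1,2}, Y = {3,4}
  expect_equal(rankletCoefficient(matrix(c(1, 2, 3, 4), 2, 2), "vertical"), 1)
  expect_equal(rankletCoefficient(matrix(c(3, 4, 1, 2), 2, 2), "vertical"), -1)
  # X = {1,3}, Y = {4,2}: 3 of 4 cross pairs have y > x
  expect_equal(rankletCoefficient(matrix(c(1, 3, 4, 2), 2, 2), "vertical"), 0.5)
  for (o in rankletOrientations())
    expect_equal(rankletCoefficient(matrix(7, 4, 4), o), 0)
})

test_that("rank-sum formula equals brute-force pair counting with tie halves", {
  set.seed(101)
  for (i in 1:300) {
    blk <- matrix(sample(0:7, 16, replace = TRUE), 4, 4)  # many ties
    for (o in rankletOrientations())
      expect_equal(rankletCoefficient(blk, o), oracleRanklet(blk, o))
  }
})

test_that("transform tiles the ROI bounding box and masks partial blocks", {
  img <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  rk <- rankletTransform(grayImage(img), matrix(TRUE, 8, 8), resolution = 4)
  for (o in rankletOrientations())
    expect_equal(dim(coefficientImages(rk)[[o]]), c(2, 2))
  expect_true(all(roiMask(rk)))

  # partial coverage: mask missing one pixel of the first block
  m <- matrix(TRUE, 8, 8); m[1, 1] <- FALSE
  # bounding box is still 8 x 8 (other pixels in row/col 1 remain TRUE)
  rk2 <- rankletTransform(grayImage(img), m, resolution = 4)
  expect_false(roiMask(rk2)[1, 1])
  expect_true(all(roiMask(rk2)[-1]))

  expect_error(
    rankletTransform(grayImage(img),
                     rbind(cbind(matrix(TRUE, 3, 3), matrix(FALSE, 3, 5)),
                           matrix(FALSE, 5, 8)), resolution = 4),
    "too-small ROI")
})

test_that("a vertical step edge lights up only vertical coefficients", {
  img <- cbind(matrix(10, 8, 4), matrix(200, 8, 4))
  # shift mask so blocks straddle the edge: use full mask, blocks at cols 1-4, 5-8
  rk <- rankletTransform(grayImage(img), matrix(TRUE, 8, 8), resolution = 4)
  co <- coefficientImages(rk)
  expect_true(all(co$vertical == 0))       # blocks lie inside flat halves
  expect_true(all(co$horizontal == 0))
  # now an edge through block centers: left 2 dark cols, right 2 bright
  blk <- cbind(matrix(10, 4, 2), matrix(200, 4, 2))
  expect_equal(rankletCoefficient(blk, "vertical"), 1)
  expect_equal(rankletCoefficient(blk, "horizontal"), 0)
  expect_equal(rankletCoefficient(blk, "diagonal"), 0)
})

test_that("mirroring the image negates the matching orientation", {
  set.seed(21)
  for (i in 1:20) {
    blk <- matrix(sample(1:1000, 16), 4, 4)
    expect_equal(rankletCoefficient(blk[, 4:1], "vertical"),
                 -rankletCoefficient(blk, "vertical"))
    expect_equal(rankletCoefficient(blk[4:1, ], "horizontal"),
                 -rankletCoefficient(blk, "horizontal"))
  }
})

test_that("coefficients are intensity invariant under monotone maps", {
  set.seed(31)
  for (i in 1:5) {
    img <- matrix(sample(1:4096), 64, 64)   # tie-free
    mask <- matrix(TRUE, 64, 64)
    ref <- coefficientImages(rankletTransform(grayImage(img, 4096), mask))
    gam <- 255 * (img / 4096)^0.7
    aff <- 0.3 * img + 17
    for (mapped in list(gam, aff)) {
      got <- coefficientImages(
        rankletTransform(grayImage(mapped, max(mapped)), mask))
      expect_identical(got, ref)
    }
  }
})

test_that("coefficient quantization bins [-1, 1] with a closed last bin", {
  expect_equal(quantizeCoefficients(matrix(0), 8)[1, 1], 4L)   # [0, 0.25)
  for (G in c(2L, 5L, 8L)) {
    expect_equal(quantizeCoefficients(matrix(1), G)[1, 1], G - 1L)
    expect_equal(quantizeCoefficients(matrix(-1), G)[1, 1], 0L)
  }
  expect_equal(quantizeCoefficients(matrix(0.25 - 1e-9), 8)[1, 1], 4L)
  expect_equal(quantizeCoefficients(matrix(0.25), 8)[1, 1], 5L)
  expect_error(quantizeCoefficients(matrix(0), 1), "parameter")
  rk <- rankletTransform(grayImage(matrix(sample(0:255, 64, TRUE), 8, 8)),
                         matrix(TRUE, 8, 8))
  q <- quantizeCoefficients(rk, 8)
  expect_named(q, c(rankletOrientations(), "mask"), ignore.order = TRUE)
  for (o in rankletOrientations())
    expect_true(all(q[[o]] >= 0L & q[[o]] <= 7L))
})
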