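makeGaussianDataset <- function(n0, n1, delta, seed, noise = 1) {
  set.seed(seed)
  x <- cbind(f1 = c(rnorm(n0, 0, noise), rnorm(n1, delta, noise)),
             f2 = rnorm(n0 + n1))
  textureDataset(x, c(rep(0L, n0), rep(1L, n1)))
}

test_that("LOO separates well-separated clouds and returns one probability per case", {
  ds <- makeGaussianDataset(20, 20, delta = 10, seed = 1)
  res <- looEvaluate(ds, classifierSpec("logistic"))
  expect_length(res$prob, 40)
  expect_true(all(res$prob >= 0 & res$prob <= 1))
  expect_equal(res$errorRate, 0)

  for (kind in c("knn", "svm")) {
    r2 <- looEvaluate(ds, classifierSpec(kind))
    expect_equal(r2$errorRate, 0)
  }
})

test_that("LOO on permuted labels sits near the 50% baseline", {
  ds <- makeGaussianDataset(20, 20, delta = 10, seed = 2)
  set.seed(7)
  accs <- replicate(20, {
    perm <- textureDataset(featureMatrix(ds), sample(caseLabels(ds)))
    1 - looEvaluate(perm, classifierSpec("logistic"))$errorRate
  })
  expect_gt(mean(accs), 0.3)
  expect_lt(mean(accs), 0.7)
})

test_that("LOO probabilities match an independent fold-by-fold oracle", {
  # re-implements standardize-then-glm leave-one-out directly; also proves
  # fold statistics use training cases only (no leakage)
  ds <- makeGaussianDataset(15, 15, delta = 1, seed = 3)
  res <- looEvaluate(ds, classifierSpec("logistic"))
  expect_length(res$flaggedFolds, 0)   # overlapping classes: plain MLE fits
  x <- featureMatrix(ds); y <- caseLabels(ds)
  for (i in seq_len(nrow(x))) {
    xtr <- x[-i, , drop = FALSE]
    mu <- colMeans(xtr); s <- apply(xtr, 2, sd)
    ztr <- sweep(sweep(xtr, 2, mu), 2, s, "/")
    zte <- (x[i, ] - mu) / s
    fit <- suppressWarnings(
      glm(y ~ ., data = data.frame(y = y[-i], ztr), family = binomial()))
    p <- 1 / (1 + exp(-(coef(fit)[1] + sum(coef(fit)[-1] * zte))))
    expect_equal(res$prob[i], unname(p), tolerance = 1e-8)
  }
  # determinism: same inputs give bit-identical probabilities
  expect_identical(res$prob, looEvaluate(ds, classifierSpec("logistic"))$prob)
})

test_that("degenerate folds and empty subsets are rejected", {
  ds <- makeGaussianDataset(2, 1, delta = 5, seed = 4)
  expect_error(looEvaluate(ds, classifierSpec("logistic")), "degenerate fold")
  ds2 <- makeGaussianDataset(5, 5, delta = 5, seed = 4)
  expect_error(looEvaluate(ds2, features = character(0)), "non-empty")
})

test_that("backward elimination keeps signal, drops noise, and traces monotonically", {
  set.seed(5)
  n <- 40
  y <- rep(0:1, each = n / 2)
  x <- cbind(inf1 = y * 3 + rnorm(n, 0, 0.8),
             inf2 = y * 2.5 + rnorm(n, 0, 0.8),
             matrix(rnorm(n * 12), n,
                    dimnames = list(NULL, paste0("noise", 1:12))))
  ds <- textureDataset(x, y)
  sel <- stepwiseBackwardSelect(ds, classifierSpec("logistic"))
  expect_true(any(c("inf1", "inf2") %in% sel$features))
  full <- looEvaluate(ds, classifierSpec("logistic"))
  expect_lte(sel$errorCount, full$errorCount)
  expect_true(all(diff(sel$trace$errorCount) < 0))
  expect_true(all(sel$features %in% colnames(x)))

  one <- textureDataset(x[, "inf1", drop = FALSE], y)
  s1 <- stepwiseBackwardSelect(one, classifierSpec("logistic"))
  expect_equal(s1$features, "inf1")
  expect_equal(nrow(s1$trace), 1)
})

test_that("confusion metrics reproduce their defining ratios", {
  pred <- c(rep(1, 4), rep(0, 3), rep(0, 31), rep(1, 1))
  labs <- c(rep(1, 7), rep(0, 32))
  m <- confusionMetrics(pred, labs)
  expect_equal(c(m$TP, m$FN, m$TN, m$FP), c(4, 3, 31, 1))
  expect_equal(m$accuracy, 35 / 39)
  expect_equal(m$sensitivity, 4 / 7)
  expect_equal(m$specificity, 31 / 32)
  expect_equal(m$ppv, 4 / 5)
  expect_equal(m$npv, 31 / 34)

  perfect <- confusionMetrics(labs, labs)
  expect_equal(c(perfect$accuracy, perfect$sensitivity, perfect$specificity,
                 perfect$ppv, perfect$npv), rep(1, 5))

  expect_warning(u <- confusionMetrics(rep(0, 5), c(1, 1, 0, 0, 0)), "PPV")
  expect_true(is.nan(u$ppv))
  expect_error(confusionMetrics(c(0, 1), c(0, 1, 1)), "alignment")
})

test_that("metric identities hold on random confusion draws", {
  set.seed(6)
  for (i in 1:30) {
    n <- sample(10:60, 1)
    labs <- rbinom(n, 1, 0.4)
    if (length(unique(labs)) < 2) next
    pred <- rbinom(n, 1, 0.5)
    m <- suppressWarnings(confusionMetrics(pred, labs))
    expect_equal(m$TP + m$FP + m$TN + m$FN, n)
    P <- sum(labs == 1); N <- sum(labs == 0)
    if (!is.nan(m$sensitivity) && !is.nan(m$specificity))
      expect_equal(m$sensitivity * P + m$specificity * N, m$TP + m$TN)
    expect_equal(m$accuracy * n, m$TP + m$TN)
  }
})

test_that("feature significance picks the right test branch", {
  set.seed(8)
  vals <- c(rnorm(20, 0), rnorm(20, 5))
  labs <- rep(0:1, each = 20)
  r <- featureSignificance(vals, labs)
  expect_equal(r$test, "t")
  expect_lt(r$p.value, 1e-3)

  heavy <- c(rlnorm(20, 0, 1.5), rlnorm(20, 0, 1.5) + 0.1)
  rh <- featureSignificance(heavy, labs)
  expect_equal(rh$test, "mann-whitney")

  rd <- featureSignificance(rep(2, 40), labs)
  expect_equal(rd$test, "degenerate")
  expect_equal(rd$p.value, 1)
})

test_that("chi-squared comparison of classifier accuracies behaves", {
  expect_equal(comparePerformanceChi2(35, 39, 35, 39)$p.value, 1)
  mid <- comparePerformanceChi2(35, 39, 33, 39)
  expect_gt(mid$p.value, 0.05)
  expect_lt(comparePerformanceChi2(39, 39, 20, 39)$p.value, 1e-3)
  expect_error(comparePerformanceChi2(0, 0, 3, 5), "degenerate")
})
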