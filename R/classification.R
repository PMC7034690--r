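#' Classifier specification
#'
#' @param kind `"logistic"`, `"knn"` or `"svm"`.
#' @param threshold probability cut for calling the positive class; ties at
#'   the threshold classify as positive. Must lie in (0, 1).
#' @param k neighbor count for KNN (odd recommended; default 5).
#' @param kernel,cost SVM kernel and cost (defaults RBF, 1).
#' @param standardize learn per-feature mean/SD on each training fold and
#'   apply to its held-out case (default `TRUE`; no leakage across folds).
#' @param seed base seed for classifier internals that draw random numbers
#'   (the SVM probability model); folds derive sub-seeds from it so
#'   leave-one-out runs are reproducible.
#' @return A list of class `classifierSpec`.
#' @export
classifierSpec <- function(kind = c("logistic", "knn", "svm"),
                           threshold = 0.5, k = 5L, kernel = "radial",
                           cost = 1, standardize = TRUE, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(threshold > 0, threshold < 1)
  structure(list(kind = kind, threshold = threshold, k = as.integer(k),
                 kernel = kernel, cost = cost, standardize = standardize,
                 seed = as.integer(seed)),
            class = "classifierSpec")
}

# Penalized (ridge) logistic fallback for separated / non-convergent fits:
# minimizes -loglik + lambda/2 * ||beta[-1]||^2 by BFGS. Deterministic and
# valid for any number of predictors, including one.
ridgeLogistic <- function(x, y, lambda = 1e-2) {
  X <- cbind(1, x)
  softplus <- function(eta) ifelse(eta > 30, eta, log1p(exp(eta)))
  f <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - softplus(eta)) + lambda / 2 * sum(b[-1L]^2)
  }
  g <- function(b) {
    eta <- drop(X %*% b)
    mu <- 1 / (1 + exp(-eta))
    drop(-crossprod(X, y - mu)) + lambda * c(0, b[-1L])
  }
  fit <- stats::optim(numeric(ncol(X)), f, g, method = "BFGS",
                      control = list(maxit = 500))
  fit$par
}

fitPredict <- function(xtr, ytr, xte, spec, foldSeed) {
  if (spec$standardize) {
    mu <- colMeans(xtr)
    sdv <- apply(xtr, 2L, stats::sd)
    sdv[sdv == 0] <- 1
    xtr <- sweep(sweep(xtr, 2L, mu), 2L, sdv, "/")
    xte <- sweep(sweep(xte, 2L, mu), 2L, sdv, "/")
  }
  flagged <- FALSE
  prob <- switch(spec$kind,
    logistic = {
      df <- data.frame(y = ytr, xtr)
      fit <- withCallingHandlers(
        stats::glm(y ~ ., data = df, family = stats::binomial()),
        warning = function(w) {
          flagged <<- TRUE
          invokeRestart("muffleWarning")
        })
      # aliased (NA) coefficients arise when p >= n; the ridge fall-back
      # handles that regime as well as separation
      if (flagged || !fit$converged || anyNA(stats::coef(fit))) {
        flagged <- TRUE
        beta <- ridgeLogistic(xtr, ytr)
        eta <- drop(cbind(1, xte) %*% beta)
      } else {
        eta <- drop(cbind(1, xte) %*% stats::coef(fit))
      }
      1 / (1 + exp(-eta))
    },
    knn = {
      pr <- class::knn(xtr, xte, factor(ytr, levels = c(0, 1)),
                       k = spec$k, prob = TRUE)
      win <- attr(pr, "prob")
      ifelse(pr == "1", win, 1 - win)
    },
    svm = {
      set.seed(foldSeed)   # svm's probability model uses internal CV
      fit <- e1071::svm(xtr, factor(ytr, levels = c(0, 1)),
                        kernel = spec$kernel, cost = spec$cost,
                        probability = TRUE, scale = FALSE)
      pr <- stats::predict(fit, xte, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    })
  list(prob = unname(prob), flagged = flagged)
}

#' Leave-one-out evaluation of a classifier on a feature subset
#'
#' For each case `i`, fits the classifier on the remaining `N - 1` cases
#' (standardization statistics learned on those cases only) and records the
#' predicted probability of the positive class for case `i`. Predictions
#' call positive when the probability reaches the threshold
#' (`prob >= threshold`). Logistic fits that fail to converge or separate
#' perfectly fall back to a lightly ridge-penalized fit and the fold is
#' flagged.
#'
#' @param data a [TextureDataset-class].
#' @param spec a [classifierSpec()].
#' @param features character vector of feature names to use (default all).
#' @return A list of class `looResult`: `prob`, `predicted`, `features`,
#'   `flaggedFolds`, `errorCount`, `errorRate`.
#' @examples
#' set.seed(1)
#' x <- cbind(f1 = c(rnorm(10), rnorm(10, 8)), f2 = rnorm(20))
#' ds <- textureDataset(x, rep(0:1, each = 10))
#' looEvaluate(ds, classifierSpec("logistic"))$errorRate
#' @export
looEvaluate <- function(data, spec = classifierSpec(), features = NULL) {
  x <- featureMatrix(data); y <- caseLabels(data)
  if (is.null(features)) features <- colnames(x)
  if (length(features) < 1L) stop("feature subset must be non-empty", call. = FALSE)
  missing <- setdiff(features, colnames(x))
  if (length(missing)) stop("unknown features: ", paste(missing, collapse = ", "),
                            call. = FALSE)
  x <- x[, features, drop = FALSE]
  n <- nrow(x)
  if (length(unique(y)) < 2L)
    stop("degenerate fold: training data would be single-class", call. = FALSE)
  prob <- numeric(n); flagged <- logical(n)
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2L)
      stop("degenerate fold: training set for case ", i, " is single-class",
           call. = FALSE)
    fp <- fitPredict(x[-i, , drop = FALSE], ytr, x[i, , drop = FALSE],
                     spec, foldSeed = (spec$seed + i) %% .Machine$integer.max)
    prob[i] <- fp$prob; flagged[i] <- fp$flagged
  }
  predicted <- as.integer(prob >= spec$threshold)
  structure(list(prob = prob, predicted = predicted, features = features,
                 flaggedFolds = which(flagged),
                 errorCount = sum(predicted != y),
                 errorRate = mean(predicted != y),
                 labels = y, caseIds = caseIds(data)),
            class = "looResult")
}

#' Stepwise backward feature elimination under leave-one-out error
#'
#' Starts from the full feature set of one panel; at each iteration every
#' remaining feature's removal is scored by [looEvaluate()] and the removal
#' giving the lowest error is accepted, provided it strictly lowers the
#' current error; otherwise the search stops. Ties among candidate removals
#' are broken by dropping the feature with the largest Wald p-value in a
#' full-data logistic fit on the current set, then lexicographically. The
#' accepted-error sequence is strictly decreasing, so the final subset is
#' the best along the trajectory.
#'
#' @param data a [TextureDataset-class].
#' @param spec a [classifierSpec()].
#' @param features starting feature set (default all columns).
#' @return The [looEvaluate()] result of the selected subset, with an extra
#'   `trace` data frame (`removed`, `errorCount`, `errorRate` per accepted
#'   step, step 0 = full model).
#' @export
stepwiseBackwardSelect <- function(data, spec = classifierSpec(),
                                   features = NULL) {
  x <- featureMatrix(data)
  if (is.null(features)) features <- colnames(x)
  current <- features
  best <- looEvaluate(data, spec, current)
  trace <- data.frame(removed = "<none>", errorCount = best$errorCount,
                      errorRate = best$errorRate, stringsAsFactors = FALSE)
  while (length(current) > 1L) {
    errs <- vapply(current, function(f)
      looEvaluate(data, spec, setdiff(current, f))$errorCount, 0)
    if (min(errs) >= best$errorCount) break
    cand <- current[errs == min(errs)]
    drop <- if (length(cand) > 1L) tieBreakRemoval(data, current, cand) else cand
    current <- setdiff(current, drop)
    best <- looEvaluate(data, spec, current)
    trace <- rbind(trace, data.frame(removed = drop,
                                     errorCount = best$errorCount,
                                     errorRate = best$errorRate,
                                     stringsAsFactors = FALSE))
  }
  best$trace <- trace
  best
}

# Tie-break among equal-error removals: largest Wald p-value in the
# full-data logistic model on the current set; lexicographic fallback.
tieBreakRemoval <- function(data, current, candidates) {
  x <- featureMatrix(data)[, current, drop = FALSE]
  y <- caseLabels(data)
  pvals <- tryCatch({
    df <- data.frame(y = y, x, check.names = FALSE)
    fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                       family = stats::binomial()))
    cf <- summary(fit)$coefficients
    p <- cf[-1L, 4L]
    names(p) <- current[seq_along(p)]
    p
  }, error = function(e) NULL)
  cand <- sort(candidates)
  if (!is.null(pvals)) {
    pc <- pvals[cand]
    pc[is.na(pc)] <- -Inf
    cand <- cand[order(-pc, cand)]
  }
  cand[1L]
}

#' Confusion counts and the derived metric panel
#'
#' Computes TP/FP/TN/FN from predicted and true binary labels and the five
#' standard proportions: accuracy `(TP+TN)/N`, sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, PPV `TP/(TP+FP)`, NPV `TN/(TN+FN)`. A ratio
#' with zero denominator is reported as `NaN` with a warning.
#'
#' @param predicted 0/1 predictions, or a `looResult` (then `labels` may be
#'   omitted).
#' @param labels 0/1 true labels, aligned with `predicted`.
#' @return A list of class `performanceMetrics` with counts and
#'   proportions.
#' @examples
#' confusionMetrics(c(1, 1, 0, 0, 0), c(1, 0, 0, 0, 1))
#' @export
confusionMetrics <- function(predicted, labels = NULL) {
  if (inherits(predicted, "looResult")) {
    if (is.null(labels)) labels <- predicted$labels
    predicted <- predicted$predicted
  }
  if (length(predicted) != length(labels))
    stop("alignment error: predictions and labels differ in length",
         call. = FALSE)
  tp <- sum(predicted == 1L & labels == 1L)
  fp <- sum(predicted == 1L & labels == 0L)
  tn <- sum(predicted == 0L & labels == 0L)
  fn <- sum(predicted == 0L & labels == 1L)
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: zero denominator")
      return(NaN)
    }
    num / den
  }
  structure(list(
    TP = tp, FP = fp, TN = tn, FN = fn, n = length(labels),
    accuracy = (tp + tn) / length(labels),
    sensitivity = ratio(tp, tp + fn, "sensitivity"),
    specificity = ratio(tn, tn + fp, "specificity"),
    ppv = ratio(tp, tp + fp, "PPV"),
    npv = ratio(tn, tn + fn, "NPV")), class = "performanceMetrics")
}

#' Per-feature two-class significance test
#'
#' Checks normality per class with the Lilliefors-corrected
#' Kolmogorov-Smirnov test (parameters are estimated from the sample); if
#' both classes pass at `alpha`, compares class means with Student's
#' two-sample t-test, otherwise with the Mann-Whitney U test. A feature
#' constant in both classes yields the degenerate convention `p = 1`,
#' flagged.
#'
#' @param values numeric feature values, one per case.
#' @param labels 0/1 class labels.
#' @param alpha significance level of the normality screen (default 0.05).
#' @return A list: `test` ("t" or "mann-whitney" or "degenerate"),
#'   `statistic`, `p.value`, `normal` (per-class normality p-values).
#' @export
featureSignificance <- function(values, labels, alpha = 0.05) {
  g0 <- values[labels == 0L]; g1 <- values[labels == 1L]
  if (length(g0) < 3L || length(g1) < 3L)
    stop("need at least 3 cases per class", call. = FALSE)
  if (stats::sd(values) == 0)
    return(list(test = "degenerate", statistic = NA_real_, p.value = 1,
                normal = c(NA_real_, NA_real_)))
  normP <- vapply(list(g0, g1), function(g) {
    if (stats::sd(g) == 0 || length(g) < 5L) return(0)  # treat as non-normal
    nortest::lillie.test(g)$p.value
  }, 0)
  if (all(normP > alpha)) {
    ht <- stats::t.test(g0, g1, var.equal = TRUE)
    list(test = "t", statistic = unname(ht$statistic),
         p.value = ht$p.value, normal = normP)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(g0, g1, exact = FALSE,
                                              correct = TRUE))
    list(test = "mann-whitney", statistic = unname(ht$statistic),
         p.value = ht$p.value, normal = normP)
  }
}

#' Chi-squared comparison of two classifiers' correct/incorrect counts
#'
#' Pearson chi-squared test (no continuity correction) on the 2 x 2 table
#' of correct vs incorrect classifications of two methods evaluated on
#' cohorts of the stated sizes.
#'
#' @param correct1,n1 correct count and cohort size of method 1; `correct1`
#'   may also be a `performanceMetrics` object (then `n1` is taken from
#'   it).
#' @param correct2,n2 same for method 2.
#' @return A list with `statistic`, `p.value` and the 2 x 2 `table`.
#' @examples
#' comparePerformanceChi2(35, 39, 33, 39)$p.value
#' @export
comparePerformanceChi2 <- function(correct1, n1 = NULL, correct2 = NULL,
                                   n2 = NULL) {
  unpack <- function(m, n) {
    if (inherits(m, "performanceMetrics")) c(m$TP + m$TN, m$n) else c(m, n)
  }
  if (inherits(correct1, "performanceMetrics")) {
    a <- unpack(correct1); b <- unpack(n1)
  } else {
    a <- c(correct1, n1); b <- c(correct2, n2)
  }
  if (a[2L] == 0 || b[2L] == 0)
    stop("degenerate input: zero-size cohort", call. = FALSE)
  tab <- rbind(c(a[1L], a[2L] - a[1L]), c(b[1L], b[2L] - b[1L]))
  if (identical(tab[1L, ], tab[2L, ]))
    return(list(statistic = 0, p.value = 1, table = tab))
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), p.value = ht$p.value, table = tab)
}
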