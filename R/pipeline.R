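#' Write a synthetic cohort to a directory
#'
#' Companion to [runExtract()]: writes each case as `<id>_img.png` /
#' `<id>_mask.png` plus a `labels.csv` with columns `case_id,label`.
#'
#' @param cohort list of [TextureCase-class] objects.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (case in cohort) writeCasePNG(case, dir)
  labels <- data.frame(
    case_id = vapply(cohort, function(cs) cs@caseId, ""),
    label = vapply(cohort, function(cs) caseLabel(cs), 0L))
  utils::write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}

#' Extract the feature table for a cohort directory
#'
#' Reads every `<id>_img.png` / `<id>_mask.png` pair listed in the
#' directory's `labels.csv` (or discovered by filename when absent), runs
#' [extractCaseFeatures()] on each, and writes one CSV row per case.
#' Per-case failures are logged and skipped; the run only fails when no
#' case is readable.
#'
#' @param cohortDir directory in the documented layout.
#' @param outCsv output CSV path (default `features.csv` inside
#'   `cohortDir`).
#' @param config settings list from [defaultConfig()].
#' @return Path of the written CSV, invisibly; attribute `skipped` holds
#'   the ids of failed cases.
#' @export
runExtract <- function(cohortDir, outCsv = file.path(cohortDir, "features.csv"),
                       config = defaultConfig()) {
  labPath <- file.path(cohortDir, "labels.csv")
  if (file.exists(labPath)) {
    lab <- utils::read.csv(labPath)
  } else {
    ids <- sub("_img\\.png$", "", basename(
      list.files(cohortDir, pattern = "_img\\.png$")))
    lab <- data.frame(case_id = ids, label = NA_integer_)
  }
  rows <- list(); skipped <- character()
  for (k in seq_len(nrow(lab))) {
    id <- lab$case_id[k]
    row <- tryCatch({
      case <- loadCase(file.path(cohortDir, paste0(id, "_img.png")),
                       file.path(cohortDir, paste0(id, "_mask.png")),
                       caseId = id, label = lab$label[k])
      extractCaseFeatures(case, config)
    }, error = function(e) {
      message("skipping case '", id, "': ", conditionMessage(e))
      NULL
    })
    if (is.null(row)) skipped <- c(skipped, id) else rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) stop("no readable cases in ", cohortDir, call. = FALSE)
  if (length(skipped))
    message(length(skipped), " of ", nrow(lab), " cases skipped")
  writeFeatureTable(rows, outCsv)
  attr(outCsv, "skipped") <- skipped
  invisible(outCsv)
}

# Panel groups evaluated by runClassify: four GLCM panels and two GLRLM
# panels (the ranklet GLRLM panel pools all three orientations).
classificationPanels <- function() list(
  raw = panelColumns("raw"),
  ranklet_vertical = panelColumns("ranklet_vertical"),
  ranklet_horizontal = panelColumns("ranklet_horizontal"),
  ranklet_diagonal = panelColumns("ranklet_diagonal"),
  raw_glrlm = panelColumns("raw_glrlm"),
  ranklet_glrlm = c(panelColumns("ranklet_vertical_glrlm"),
                    panelColumns("ranklet_horizontal_glrlm"),
                    panelColumns("ranklet_diagonal_glrlm")))

#' Select, validate and report classifiers on every feature panel
#'
#' For each of the six panels (raw GLCM, three ranklet-orientation GLCM,
#' raw GLRLM, pooled ranklet GLRLM): stepwise backward elimination under
#' leave-one-out error, the confusion-metric panel of the selected model,
#' per-selected-feature significance tests (raw p-values plus a Bonferroni
#' column), and chi-squared comparisons of each ranklet panel against its
#' raw counterpart. The JSON report echoes the full configuration for
#' replay.
#'
#' @param featuresCsv feature table from [runExtract()] /
#'   [writeFeatureTable()]; labels must be present.
#' @param outJson optional path to write the JSON report.
#' @param config settings list from [defaultConfig()]; `classifier`,
#'   `threshold`, `knn_k`, `svm_cost`, `svm_kernel`, `standardize` and
#'   `seed` are used here.
#' @return The report, a list of class `classificationReport`.
#' @export
runClassify <- function(featuresCsv, outJson = NULL, config = defaultConfig()) {
  data <- readFeatureTable(featuresCsv)
  spec <- classifierSpec(config$classifier, threshold = config$threshold,
                         k = config$knn_k, kernel = config$svm_kernel,
                         cost = config$svm_cost,
                         standardize = config$standardize, seed = config$seed)
  panels <- classificationPanels()
  results <- lapply(panels, function(cols) {
    sel <- stepwiseBackwardSelect(data, spec, features = cols)
    metrics <- confusionMetrics(sel)
    sig <- lapply(stats::setNames(nm = sel$features), function(f)
      featureSignificance(featureMatrix(data)[, f], caseLabels(data)))
    sigTab <- data.frame(
      feature = names(sig),
      test = vapply(sig, `[[`, "", "test"),
      p_value = vapply(sig, `[[`, 0, "p.value"),
      row.names = NULL)
    sigTab$p_bonferroni <- pmin(1, sigTab$p_value * nrow(sigTab))
    list(selected = sel$features, trace = sel$trace,
         prob = sel$prob, predicted = sel$predicted,
         flaggedFolds = sel$flaggedFolds,
         metrics = metrics, significance = sigTab)
  })
  comparisons <- list()
  for (pair in list(c("ranklet_vertical", "raw"),
                    c("ranklet_horizontal", "raw"),
                    c("ranklet_diagonal", "raw"),
                    c("ranklet_glrlm", "raw_glrlm"))) {
    m1 <- results[[pair[1L]]]$metrics; m2 <- results[[pair[2L]]]$metrics
    comparisons[[paste(pair, collapse = "_vs_")]] <-
      comparePerformanceChi2(m1, m2)
  }
  report <- structure(list(
    config = config, caseIds = caseIds(data), labels = caseLabels(data),
    panels = results, comparisons = comparisons,
    provenance = list(package = "rankletRadiomics",
                      version = as.character(utils::packageVersion("rankletRadiomics")))),
    class = "classificationReport")
  if (!is.null(outJson)) {
    jsonlite::write_json(reportToJson(report), outJson, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  report
}

reportToJson <- function(report) {
  panelJson <- lapply(report$panels, function(p) list(
    selected = p$selected,
    trace = p$trace,
    prob = p$prob,
    predicted = p$predicted,
    metrics = unclass(p$metrics),
    significance = p$significance))
  list(config = report$config[setdiff(names(report$config), NULL)],
       case_ids = report$caseIds, labels = report$labels,
       panels = panelJson,
       comparisons = lapply(report$comparisons, function(cm)
         list(statistic = cm$statistic, p_value = cm$p.value)),
       provenance = report$provenance)
}
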