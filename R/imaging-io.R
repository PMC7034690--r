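# Round-half-up: deterministic .5 -> up, unlike base round()'s banker's rule.
roundHalfUp <- function(x) floor(x + 0.5)

readGrayMatrix <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png")) {
    a <- png::readPNG(path)
    scale <- 255
  } else if (ext %in% c("tif", "tiff")) {
    a <- tiff::readTIFF(path)
    scale <- 255
  } else if (ext %in% c("dcm", "dicom")) {
    stop("unsupported format: DICOM reading is not available; ",
         "convert to PNG or TIFF", call. = FALSE)
  } else {
    stop("unsupported format: '", ext, "' (expected png or tiff)", call. = FALSE)
  }
  if (length(dim(a)) == 3L) {
    # accept gray-stored-as-RGB(A); reject true color
    ch <- dim(a)[3L]
    rgb <- a[, , seq_len(min(ch, 3L)), drop = FALSE]
    if (max(abs(sweep(rgb, c(1, 2), rgb[, , 1L]))) > 1e-9)
      stop("unsupported format: color image (channels differ); ",
           "grayscale input required", call. = FALSE)
    a <- a[, , 1L]
  }
  if (length(dim(a)) != 2L)
    stop("unsupported format: expected a single-frame 2D grayscale image",
         call. = FALSE)
  roundHalfUp(a * scale)
}

#' Load one case from an image file and a mask file
#'
#' Reads a single-frame grayscale image (PNG or TIFF, 8-bit) and a congruent
#' binary ROI mask image. Any nonzero mask pixel counts as ROI. Pixels are
#' returned raw (un-normalized); call [normalizeIntensity()] before feature
#' extraction.
#'
#' @param imagePath path to the grayscale image (`.png`, `.tif`, `.tiff`).
#' @param maskPath path to the mask image, same shape.
#' @param caseId case identifier; defaults to the image file stem.
#' @param label optional binary label (0 = negative, 1 = positive).
#' @return A [TextureCase-class].
#' @examples
#' img <- file.path(tempdir(), "demo_img.png")
#' msk <- file.path(tempdir(), "demo_mask.png")
#' png::writePNG(matrix(runif(64), 8, 8), img)
#' png::writePNG(matrix(1, 8, 8), msk)
#' loadCase(img, msk)
#' @export
loadCase <- function(imagePath, maskPath, caseId = NULL, label = NA_integer_) {
  img <- readGrayMatrix(imagePath)
  msk <- readGrayMatrix(maskPath)
  if (!identical(dim(img), dim(msk)))
    stop(sprintf("shape mismatch: image is %d x %d but mask is %d x %d",
                 nrow(img), ncol(img), nrow(msk), ncol(msk)), call. = FALSE)
  msk <- msk != 0
  if (!any(msk)) stop("empty ROI: mask contains no nonzero pixel", call. = FALSE)
  if (is.null(caseId)) caseId <- tools::file_path_sans_ext(basename(imagePath))
  textureCase(caseId, grayImage(img), msk, label)
}

#' Stretch intensities to the full 8-bit range
#'
#' Min-max normalization over the whole image:
#' `v' = round(255 * (v - min) / (max - min))` with round-half-up. For any
#' non-constant input the output attains both 0 and 255, which removes
#' global brightness/contrast offsets before quantization. A constant image
#' has no dynamic range to stretch; it maps to all zeros with a warning so
#' batch runs survive degenerate inputs.
#'
#' @param img a [TextureImage-class] (or plain matrix).
#' @return A [TextureImage-class] with integer pixels in 0..255 and bit
#'   depth 255.
#' @examples
#' normalizeIntensity(grayImage(matrix(c(10, 15, 20, 10), 2, 2)))
#' @export
normalizeIntensity <- function(img) {
  p <- if (is(img, "TextureImage")) img@pixels else as.matrix(img)
  lo <- min(p); hi <- max(p)
  if (hi == lo) {
    warning("constant image: no dynamic range to normalize; returning zeros")
    return(grayImage(array(0, dim(p)), 255))
  }
  grayImage(roundHalfUp(255 * (p - lo) / (hi - lo)), 255)
}

#' Write / read a per-case feature table
#'
#' `writeFeatureTable()` writes one row per case to CSV: columns `case_id`,
#' `label`, then the features in the order of the first row. All rows must
#' share one feature-name set. `readFeatureTable()` reads such a CSV back
#' into a [TextureDataset-class]; values round-trip losslessly at 15
#' significant digits.
#'
#' @param rows list of per-case rows, each a list with elements `case_id`,
#'   `label` and `features` (named numeric vector), as produced by
#'   [extractCaseFeatures()].
#' @param path CSV file path.
#' @return `writeFeatureTable()` returns `path` invisibly;
#'   `readFeatureTable()` returns a [TextureDataset-class].
#' @examples
#' rows <- list(
#'   list(case_id = "a", label = 0L, features = c(f1 = 0.5, f2 = 1)),
#'   list(case_id = "b", label = 1L, features = c(f1 = 0.25, f2 = 2)))
#' p <- tempfile(fileext = ".csv")
#' writeFeatureTable(rows, p)
#' readFeatureTable(p)
#' @export
writeFeatureTable <- function(rows, path) {
  stopifnot(length(rows) >= 1L)
  featNames <- names(rows[[1L]]$features)
  for (r in rows) {
    if (!identical(names(r$features), featNames))
      stop("schema error: rows have inconsistent feature-name sets", call. = FALSE)
  }
  mat <- do.call(rbind, lapply(rows, function(r) unname(r$features)))
  df <- data.frame(case_id = vapply(rows, function(r) as.character(r$case_id), ""),
                   label = vapply(rows, function(r) as.integer(r$label), 0L))
  df <- cbind(df, as.data.frame(mat))
  names(df) <- c("case_id", "label", featNames)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("case_id", "label") %in% names(df)))
    stop("schema error: feature table must have case_id and label columns",
         call. = FALSE)
  x <- as.matrix(df[, setdiff(names(df), c("case_id", "label")), drop = FALSE])
  textureDataset(x, labels = df$label, caseIds = df$case_id)
}

#' Write a case to PNG image + mask files
#'
#' Companion to [loadCase()]: writes the (integer, 8-bit) image and its mask
#' as PNG files, the on-disk layout used by cohort directories
#' (`<id>_img.png`, `<id>_mask.png`).
#'
#' @param case a [TextureCase-class] with integer pixels in 0..255.
#' @param dir output directory (created if missing).
#' @return Invisibly, the two file paths written.
#' @export
writeCasePNG <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- pixels(case)
  if (max(abs(p - round(p))) > 1e-9)
    stop("writeCasePNG requires integer 8-bit pixels", call. = FALSE)
  imgPath <- file.path(dir, paste0(case@caseId, "_img.png"))
  mskPath <- file.path(dir, paste0(case@caseId, "_mask.png"))
  png::writePNG(p / 255, imgPath)
  png::writePNG(roiMask(case) * 1, mskPath)
  invisible(c(image = imgPath, mask = mskPath))
}
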