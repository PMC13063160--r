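#' @include AllClasses.R texture-features.R
NULL

#' Feature-extraction configuration
#'
#' @param gabor list of [gaborBank()] arguments.
#' @param lbp list with `radius` and `points` (the 3 x 3, 8-neighbor
#'   operator is the only implemented geometry; kept for forward
#'   compatibility and validated).
#' @param mask list with `enabled` (logical) controlling Otsu segmentation
#'   on image read.
#' @return a config list consumed by [extractFeatures()].
#' @export
featureConfig <- function(gabor = list(), lbp = list(), mask = list()) {
  g <- utils::modifyList(list(nScales = 5, nOrientations = 8, fMax = 0.25,
                              kernelSize = 31, sigmaRatio = 0.56,
                              gamma = 0.5), gabor)
  l <- utils::modifyList(list(radius = 1, points = 8), lbp)
  if (l$radius != 1 || l$points != 8)
    stop("only the radius-1, 8-point LBP geometry is implemented")
  m <- utils::modifyList(list(enabled = TRUE), mask)
  list(gabor = g, lbp = l, mask = m)
}

#' Names of the 113 fused features, in order
#'
#' @param config feature configuration (sets the Gabor bank size).
#' @return character vector: 14 color moments, 59 LBP bins, Gabor energies.
#' @export
featureNames <- function(config = featureConfig()) {
  cm <- paste0(rep(c("color_mu_", "color_sd_"), times = 7),
               rep(c("R", "G", "B", "H", "S", "a", "b"), each = 2))
  lb <- sprintf("lbp_u2_%02d", 1:59)
  gb <- as.vector(vapply(0:(config$gabor$nScales - 1), function(u)
    sprintf("gabor_e_%d_%d", u, 0:(config$gabor$nOrientations - 1)),
    character(config$gabor$nOrientations)))
  c(cm, lb, gb)
}

#' @describeIn extractFeatures fused descriptor of a single slice image:
#'   14 color moments, 59-bin uniform LBP histogram and 40 Gabor energies
#'   concatenated in that fixed order. Deterministic in (pixels, mask,
#'   config).
#' @export
setMethod("extractFeatures", "SliceImage", function(x, config = featureConfig(), ...) {
  bank <- do.call(gaborBank, config$gabor)
  out <- c(colorMoments(x), lbpHistogram(x),
           gaborEnergy(x, bank = bank, config = config))
  stopifnot(!anyDuplicated(names(out)))
  out
})

#' @describeIn extractFeatures extract from a list of slice images into a
#'   feature matrix (rows = images). The Gabor bank is built once.
#' @export
setMethod("extractFeatures", "list", function(x, config = featureConfig(), ...) {
  bank <- do.call(gaborBank, config$gabor)
  rows <- lapply(x, function(img)
    c(colorMoments(img), lbpHistogram(img),
      gaborEnergy(img, bank = bank, config = config)))
  X <- do.call(rbind, rows)
  rownames(X) <- names(x)
  X
})

#' Read a slice image from PNG, JPEG or TIFF
#'
#' Channel values are normalized to `[0, 1]` from the native bit depth by
#' the reader; grayscale files are replicated across the three channels.
#'
#' @param path image file path.
#' @param config feature configuration; `config$mask$enabled` controls
#'   Otsu foreground segmentation.
#' @return a [SliceImage-class].
#' @export
readSliceImage <- function(path, config = featureConfig()) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  a <- as.array(img)
  px <- if (length(d) == 2L) {
    array(rep(a, 3), dim = c(d[1], d[2], 3))
  } else {
    array(a[, , 1:3], dim = c(d[1], d[2], 3))  # drop alpha if present
  }
  px <- pmin(pmax(px, 0), 1)
  si <- SliceImage(px)
  SliceImage(px, mask = foregroundMask(si, enabled = config$mask$enabled))
}

#' Write / read a feature table as CSV
#'
#' First column `sample_id`, remaining columns the feature names; values
#' round-trip to at least 12 significant digits.
#'
#' @param X numeric feature matrix with feature names as colnames and
#'   sample ids as rownames.
#' @param path CSV file path.
#' @return `readFeatures` returns the matrix with ids as rownames.
#' @export
writeFeatures <- function(X, path) {
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  df <- data.frame(sample_id = ids, signif(X, 15), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatures
#' @export
readFeatures <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "sample_id")
    stop("feature CSV is missing the 'sample_id' column")
  X <- as.matrix(df[, -1, drop = FALSE])
  rownames(X) <- df$sample_id
  X
}
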