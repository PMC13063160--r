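#' @include AllGenerics.R
NULL

#' SliceImage: an RGB slice cross-section raster with a foreground mask
#'
#' Pixel values are stored in `[0, 1]` (native bit depth is normalized on
#' read). The mask marks slice foreground; background pixels are excluded
#' from all feature statistics.
#'
#' @slot pixels numeric H x W x 3 array, values in `[0, 1]`.
#' @slot mask logical H x W matrix, `TRUE` = foreground.
#'
#' @aliases pixels sliceMask
#' @export
setClass("SliceImage",
  representation(pixels = "array", mask = "matrix"))

setValidity("SliceImage", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L)
    return("pixels must be an H x W x 3 array")
  if (d[1] < 3L || d[2] < 3L)
    return("image must be at least 3 x 3")
  if (!all(is.finite(object@pixels)))
    return("pixel values must be finite")
  if (min(object@pixels) < 0 || max(object@pixels) > 1)
    return("pixel values must lie in [0, 1]")
  if (!is.logical(object@mask))
    return("mask must be logical")
  if (!identical(dim(object@mask), d[1:2]))
    return("mask shape must equal the pixel-plane shape")
  TRUE
})

#' Construct a SliceImage
#'
#' @param pixels H x W x 3 numeric array with values in `[0, 1]`.
#' @param mask optional logical H x W matrix; defaults to all-foreground.
#' @return a [SliceImage-class] object.
#' @export
SliceImage <- function(pixels, mask = NULL) {
  if (is.null(mask))
    mask <- matrix(TRUE, nrow = dim(pixels)[1], ncol = dim(pixels)[2])
  new("SliceImage", pixels = pixels, mask = mask)
}

#' @rdname SliceImage-class
setMethod("pixels", "SliceImage", function(x) x@pixels)

#' @rdname SliceImage-class
setMethod("sliceMask", "SliceImage", function(x) x@mask)

setMethod("show", "SliceImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("SliceImage %d x %d, foreground %d/%d px (%.1f%%)\n",
              d[1], d[2], sum(object@mask), length(object@mask),
              100 * mean(object@mask)))
})

#' GradeTable: contiguous saponin-content intervals mapping mg/g to grades
#'
#' Rows are ordered by content; grade 1 is the lowest band. Intervals are
#' lower-closed and upper-open, except the top interval which is closed.
#'
#' @slot scheme integer grade count (3, 5 or 6 in the shipped standards).
#' @slot rows data.frame with columns `grade`, `lo`, `hi` (mg/g).
#'
#' @aliases gradeRows gradeScheme
#' @export
setClass("GradeTable",
  representation(scheme = "integer", rows = "data.frame"))

setValidity("GradeTable", function(object) {
  r <- object@rows
  if (!all(c("grade", "lo", "hi") %in% names(r)))
    return("rows must have columns grade, lo, hi")
  if (nrow(r) != object@scheme)
    return("row count must equal the scheme's grade count")
  if (!identical(as.integer(r$grade), seq_len(nrow(r))))
    return("grades must be 1..K in order")
  if (any(r$hi <= r$lo))
    return("bounds must be strictly increasing within rows")
  if (nrow(r) > 1L && any(abs(r$lo[-1] - r$hi[-nrow(r)]) > 1e-9))
    return("rows must be contiguous (row g's upper = row g+1's lower)")
  TRUE
})

#' Construct a GradeTable
#'
#' @param scheme number of grades.
#' @param rows data.frame with columns `grade`, `lo`, `hi`.
#' @return a [GradeTable-class] object.
#' @export
GradeTable <- function(scheme, rows) {
  new("GradeTable", scheme = as.integer(scheme),
      rows = as.data.frame(rows))
}

#' @rdname GradeTable-class
setMethod("gradeRows", "GradeTable", function(x) x@rows)

#' @rdname GradeTable-class
setMethod("gradeScheme", "GradeTable", function(x) x@scheme)

setMethod("show", "GradeTable", function(object) {
  cat(sprintf("GradeTable (%d-grade standard, mg/g)\n", object@scheme))
  r <- object@rows
  for (i in seq_len(nrow(r)))
    cat(sprintf("  grade %d: [%g, %g%s\n", r$grade[i], r$lo[i], r$hi[i],
                if (i == nrow(r)) "]" else ")"))
})

#' LabeledDataset: a feature matrix with grade labels and row provenance
#'
#' @slot X numeric n x p matrix; column names are feature identifiers.
#' @slot y factor of grade labels, aligned with rows of `X`.
#' @slot provenance character vector in `{"original", "synthetic"}`;
#'   synthetic rows are SMOTE interpolants and must never reach a test
#'   partition.
#'
#' @aliases features grades provenance
#' @export
setClass("LabeledDataset",
  representation(X = "matrix", y = "factor", provenance = "character"))

setValidity("LabeledDataset", function(object) {
  if (nrow(object@X) != length(object@y))
    return("X and y must have aligned rows")
  if (length(object@provenance) != nrow(object@X))
    return("provenance must have one flag per row")
  if (!all(object@provenance %in% c("original", "synthetic")))
    return("provenance flags must be 'original' or 'synthetic'")
  if (anyNA(object@X) || !all(is.finite(object@X)))
    return("X must be finite with no missing values")
  if (is.null(colnames(object@X)))
    return("X must carry feature names as column names")
  TRUE
})

#' Construct a LabeledDataset
#'
#' @param X numeric matrix with feature names as column names.
#' @param y grade labels (coerced to factor).
#' @param provenance per-row flags, default all `"original"`.
#' @return a [LabeledDataset-class] object.
#' @export
LabeledDataset <- function(X, y, provenance = NULL) {
  if (is.null(provenance)) provenance <- rep("original", nrow(X))
  new("LabeledDataset", X = X, y = as.factor(y), provenance = provenance)
}

#' @rdname LabeledDataset-class
setMethod("features", "LabeledDataset", function(x) x@X)

#' @rdname LabeledDataset-class
setMethod("grades", "LabeledDataset", function(x) x@y)

#' @rdname LabeledDataset-class
setMethod("provenance", "LabeledDataset", function(x) x@provenance)

setMethod("show", "LabeledDataset", function(object) {
  cat(sprintf("LabeledDataset: %d samples x %d features (%d synthetic)\n",
              nrow(object@X), ncol(object@X),
              sum(object@provenance == "synthetic")))
  print(table(grade = object@y))
})

#' @rdname LabeledDataset-class
#' @param object a `LabeledDataset`.
#' @export
setMethod("nrow", "LabeledDataset", function(x) nrow(x@X))

#' FeatureSelection: importance scores and the selected prefix
#'
#' @slot method one of ALL, RFI, COR, MI, RFE, XGB.
#' @slot importances named numeric scores, normalized to sum 1.
#' @slot selected integer indices of the kept features (importance order).
#' @slot threshold cumulative-importance fraction used for the cut.
#' @export
setClass("FeatureSelection",
  representation(method = "character", importances = "numeric",
                 selected = "integer", threshold = "numeric"))

setMethod("show", "FeatureSelection", function(object) {
  cat(sprintf("FeatureSelection[%s]: %d/%d features at threshold %.2f\n",
              object@method, length(object@selected),
              length(object@importances), object@threshold))
})

#' EvalReport: confusion matrix and the metric suite
#'
#' @slot confusion C x C count matrix (rows = true, cols = predicted).
#' @slot accuracy,precision,recall,f1,mAP fractions in `[0, 1]`
#'   (precision/recall/F1 macro-averaged one-vs-rest).
#' @slot perClass data.frame of per-class precision, recall, F1 and AP.
#' @export
setClass("EvalReport",
  representation(confusion = "matrix", accuracy = "numeric",
                 precision = "numeric", recall = "numeric", f1 = "numeric",
                 mAP = "numeric", perClass = "data.frame"))

setMethod("show", "EvalReport", function(object) {
  cat(sprintf(
    "EvalReport: accuracy %.3f, macro-F1 %.3f, mAP %.3f (%d classes)\n",
    object@accuracy, object@f1, object@mAP, nrow(object@confusion)))
})

#' ModelSpec: a registry key plus hyperparameters and a seed
#'
#' @slot algorithm key into [algorithmRegistry()].
#' @slot params named list of hyperparameters (registry names:
#'   `learning_rate`, `depth`, `iterations`, `l2_leaf_reg`).
#' @slot seed integer seed controlling the fit.
#' @export
setClass("ModelSpec",
  representation(algorithm = "character", params = "list", seed = "numeric"))

setValidity("ModelSpec", function(object) {
  reg <- algorithmRegistry()
  if (!object@algorithm %in% names(reg))
    return(sprintf("unknown algorithm '%s'; registered: %s",
                   object@algorithm, paste(names(reg), collapse = ", ")))
  TRUE
})

#' Construct a ModelSpec
#'
#' @param algorithm registry key (see [algorithmRegistry()]).
#' @param params hyperparameter overrides; registry defaults fill the rest.
#' @param seed integer seed.
#' @return a [ModelSpec-class] object.
#' @export
modelSpec <- function(algorithm, params = list(), seed = 1L) {
  new("ModelSpec", algorithm = algorithm, params = params, seed = seed)
}

setMethod("show", "ModelSpec", function(object) {
  p <- resolveParams(object)
  cat(sprintf("ModelSpec[%s] seed=%d: %s\n", object@algorithm,
              as.integer(object@seed),
              paste(names(p), unlist(p), sep = "=", collapse = ", ")))
})

#' PNSModel: a fitted classifier handle
#'
#' @slot spec the [ModelSpec-class] that produced the fit.
#' @slot fit backend fit object (ranger or xgboost).
#' @slot classes class levels seen in training.
#' @slot featureNames feature order expected at prediction time.
#' @export
setClass("PNSModel",
  representation(spec = "ModelSpec", fit = "ANY", classes = "character",
                 featureNames = "character"))

setMethod("show", "PNSModel", function(object) {
  cat(sprintf("PNSModel[%s]: %d classes, %d features\n",
              object@spec@algorithm, length(object@classes),
              length(object@featureNames)))
})
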