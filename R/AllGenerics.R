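#' Extract the fused image descriptor
#'
#' @param x an object holding slice pixel data.
#' @param config feature configuration, see [featureConfig()].
#' @param ... passed to methods.
#' @return a named numeric vector of length 113.
#' @export
setGeneric("extractFeatures", function(x, config = featureConfig(), ...)
  standardGeneric("extractFeatures"))

#' Map assay values to grade labels
#'
#' @param pns numeric vector of total saponin contents (mg/g).
#' @param table a [GradeTable-class] object.
#' @return integer grade labels (1 = lowest content band).
#' @export
setGeneric("assignGrade", function(pns, table) standardGeneric("assignGrade"))

#' @rdname SliceImage-class
#' @param x a `SliceImage`.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname SliceImage-class
#' @export
setGeneric("sliceMask", function(x) standardGeneric("sliceMask"))

#' @rdname GradeTable-class
#' @param x a `GradeTable`.
#' @export
setGeneric("gradeRows", function(x) standardGeneric("gradeRows"))

#' @rdname GradeTable-class
#' @export
setGeneric("gradeScheme", function(x) standardGeneric("gradeScheme"))

#' @rdname LabeledDataset-class
#' @param x a `LabeledDataset`.
#' @export
setGeneric("features", function(x) standardGeneric("features"))

#' @rdname LabeledDataset-class
#' @export
setGeneric("grades", function(x) standardGeneric("grades"))

#' @rdname LabeledDataset-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
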