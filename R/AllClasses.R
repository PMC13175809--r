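#' @import methods
NULL

VIEW_NAMES <- c("sagittal", "coronal", "axial")
LABEL_NAMES <- c("abnormal", "acl", "meniscus")

#' ExamTensor: one preprocessed three-view knee MRI study
#'
#' Container for a single exam after preprocessing: three equally shaped
#' slice stacks (one per acquisition plane), the per-study normalization
#' record, and the three exam-level binary labels.
#'
#' @slot examId character scalar study identifier.
#' @slot views named list of three rank-3 arrays (slices x rows x cols) in
#'   fixed order sagittal, coronal, axial.
#' @slot normMean,normSd numeric scalars: the per-study intensity mean and
#'   standard deviation used for z-scoring (recorded for provenance).
#' @slot degenerate logical: `TRUE` when the study was constant-valued and
#'   was mapped to all zeros.
#' @slot labels named integer vector (abnormal, acl, meniscus) in {0,1},
#'   possibly `NA` for unlabeled studies.
#' @export
setClass("ExamTensor",
  representation(examId = "character", views = "list",
                 normMean = "numeric", normSd = "numeric",
                 degenerate = "logical", labels = "integer"),
  prototype(degenerate = FALSE,
            labels = stats::setNames(rep(NA_integer_, 3L),
                                     c("abnormal", "acl", "meniscus"))))

setValidity("ExamTensor", function(object) {
  msgs <- character()
  if (length(object@examId) != 1L) msgs <- c(msgs, "examId must be scalar")
  if (!identical(names(object@views), VIEW_NAMES))
    msgs <- c(msgs, "views must be named sagittal, coronal, axial (in order)")
  dims <- lapply(object@views, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    msgs <- c(msgs, "each view must be a rank-3 array")
  else if (length(unique(lapply(dims, identity))) != 1L)
    msgs <- c(msgs, "all views must share one shape")
  if (!all(vapply(object@views, function(v) all(is.finite(v)), TRUE)))
    msgs <- c(msgs, "views must contain only finite values")
  if (!identical(names(object@labels), LABEL_NAMES))
    msgs <- c(msgs, "labels must be named abnormal, acl, meniscus")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn ExamTensor study identifier accessor
#' @param object an `ExamTensor`.
#' @export
setGeneric("examId", function(object) standardGeneric("examId"))
#' @export
setMethod("examId", "ExamTensor", function(object) object@examId)

#' @describeIn ExamTensor one view's slice stack
#' @param view one of `"sagittal"`, `"coronal"`, `"axial"`.
#' @export
setGeneric("viewArray", function(object, view) standardGeneric("viewArray"))
#' @export
setMethod("viewArray", "ExamTensor", function(object, view) {
  view <- match.arg(view, VIEW_NAMES)
  object@views[[view]]
})

#' @describeIn ExamTensor labels accessor
#' @export
setGeneric("examLabels", function(object) standardGeneric("examLabels"))
#' @export
setMethod("examLabels", "ExamTensor", function(object) object@labels)

setMethod("show", "ExamTensor", function(object) {
  d <- dim(object@views[[1]])
  cat(sprintf("ExamTensor '%s': 3 views x %d slices x %dx%d px", object@examId,
              d[1], d[2], d[3]),
      if (object@degenerate) "(degenerate)" else "", "\n")
  lb <- object@labels
  cat("  labels:", paste(names(lb), lb, sep = "=", collapse = " "), "\n")
  cat(sprintf("  normalization: mean=%.4g sd=%.4g\n",
              object@normMean, object@normSd))
})

#' MILModel: a multiple-instance-learning exam classifier
#'
#' Holds the parameter set and architecture configuration of one model:
#' a shared convolutional slice encoder, a per-view slice aggregator
#' (multi-scale attention, or a mean/max/gated-attention baseline), and the
#' concatenation + MLP view-fusion classifier with three sigmoid outputs.
#'
#' @slot params named list of numeric parameter arrays.
#' @slot config the [modelConfig()] list the model was built from.
#' @export
setClass("MILModel", representation(params = "list", config = "list"))

setMethod("show", "MILModel", function(object) {
  np <- sum(vapply(object@params, length, 1L))
  cf <- object@config
  cat(sprintf("MILModel (%s aggregator): D=%d E=%d heads=%d layers=%d kernels={%s}\n",
              cf$aggregator, cf$encoder_dim, cf$embed_dim, cf$heads,
              cf$attn_layers, paste(cf$pool_kernels, collapse = ",")))
  cat(sprintf("  %d parameter tensors, %d trainable values\n",
              length(object@params), np))
})

#' @describeIn MILModel named list of parameter arrays
#' @param object a `MILModel`.
#' @export
setGeneric("modelParams", function(object) standardGeneric("modelParams"))
#' @export
setMethod("modelParams", "MILModel", function(object) object@params)

#' @describeIn MILModel architecture configuration
#' @export
setGeneric("modelConfigOf", function(object) standardGeneric("modelConfigOf"))
#' @export
setMethod("modelConfigOf", "MILModel", function(object) object@config)

#' MetricReport: per-label and macro evaluation metrics for one run
#'
#' @slot perLabel numeric matrix, metrics (auroc, auprc, f1, brier) by label
#'   (abnormal, acl, meniscus).
#' @slot macro named numeric vector: unweighted mean of each metric over the
#'   three labels.
#' @slot threshold decision threshold used for F1.
#' @slot nExams number of exams evaluated.
#' @export
setClass("MetricReport",
  representation(perLabel = "matrix", macro = "numeric",
                 threshold = "numeric", nExams = "integer"))

setValidity("MetricReport", function(object) {
  ok <- identical(rownames(object@perLabel), c("auroc", "auprc", "f1", "brier")) &&
    identical(colnames(object@perLabel), LABEL_NAMES)
  if (!ok) return("perLabel must be metrics x labels (auroc/auprc/f1/brier x abnormal/acl/meniscus)")
  macro <- rowMeans(object@perLabel)
  if (any(abs(macro - object@macro) > 1e-12, na.rm = TRUE))
    return("macro must equal the unweighted per-label mean")
  TRUE
})

setMethod("show", "MetricReport", function(object) {
  cat(sprintf("MetricReport on %d exams (F1 threshold %.2f)\n",
              object@nExams, object@threshold))
  print(round(cbind(object@perLabel, macro = object@macro), 4))
})

#' @describeIn MetricReport macro (label-averaged) metric vector
#' @param object a `MetricReport`.
#' @export
setGeneric("macroMetrics", function(object) standardGeneric("macroMetrics"))
#' @export
setMethod("macroMetrics", "MetricReport", function(object) object@macro)

#' @describeIn MetricReport metrics-by-label matrix
#' @export
setGeneric("perLabelMetrics", function(object) standardGeneric("perLabelMetrics"))
#' @export
setMethod("perLabelMetrics", "MetricReport", function(object) object@perLabel)
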