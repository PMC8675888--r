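#' @import methods
NULL

#' ChannelSet: a named set of electrode labels
#'
#' @slot name single string.
#' @slot members character vector of canonical channel labels, non-empty,
#'   unique.
#' @seealso \code{\link{ChannelSet}}, \code{\link{channelSets}}
#' @exportClass ChannelSet
setClass("ChannelSet",
  representation(name = "character", members = "character"))

setValidity("ChannelSet", function(object) {
  if (length(object@name) != 1L) return("'name' must be a single string")
  if (!length(object@members)) return("'members' must be non-empty")
  if (anyDuplicated(object@members)) return("'members' must be unique")
  TRUE
})

#' ICComponent: one EEG independent component
#'
#' An independent component is represented by its topomap (one mixing weight
#' per scalp channel, arbitrary scale and sign), its source time series
#' (epochs x samples; a continuous recording is a single epoch), and the
#' sampling rate.
#'
#' @slot componentId single string, unique within a dataset.
#' @slot subjectId single string.
#' @slot channels character vector of canonical channel labels.
#' @slot weights numeric vector, one finite weight per channel.
#' @slot signal numeric matrix, epochs x samples, all finite.
#' @slot samplingRate positive number, Hz.
#' @seealso \code{\link{ICComponent}}, \code{\link{epochView}}
#' @exportClass ICComponent
setClass("ICComponent",
  representation(componentId = "character", subjectId = "character",
                 channels = "character", weights = "numeric",
                 signal = "matrix", samplingRate = "numeric"))

setValidity("ICComponent", function(object) {
  msg <- character()
  if (length(object@componentId) != 1L || !nzchar(object@componentId))
    msg <- c(msg, "'componentId' must be a single non-empty string")
  if (length(object@subjectId) != 1L)
    msg <- c(msg, "'subjectId' must be a single string")
  if (length(object@weights) != length(object@channels))
    msg <- c(msg, sprintf("%d weights for %d channels",
                          length(object@weights), length(object@channels)))
  if (anyDuplicated(object@channels))
    msg <- c(msg, "channel labels must be unique")
  if (!all(is.finite(object@weights)))
    msg <- c(msg, "weights must all be finite")
  if (!is.numeric(object@signal) || nrow(object@signal) < 1L ||
      ncol(object@signal) < 2L)
    msg <- c(msg, "signal must have >= 1 epoch and >= 2 samples")
  else if (!all(is.finite(object@signal)))
    msg <- c(msg, "signal must be all finite")
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' ICDataset: a collection of independent components
#'
#' All components in one dataset share an identical channel ordering so that
#' spatial features are comparable across components.
#'
#' @slot components list of \linkS4class{ICComponent}, unique ids.
#' @slot metadata named list of free-form strings (cohort, montage name...).
#' @seealso \code{\link{ICDataset}}, \code{\link{loadDataset}}
#' @exportClass ICDataset
setClass("ICDataset",
  representation(components = "list", metadata = "list"),
  prototype(components = list(), metadata = list()))

setValidity("ICDataset", function(object) {
  if (!all(vapply(object@components, is, logical(1), "ICComponent")))
    return("all components must be ICComponent objects")
  ids <- vapply(object@components, function(x) x@componentId, character(1))
  if (anyDuplicated(ids))
    return(sprintf("duplicated component ids: %s",
                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (length(object@components) > 1L) {
    ref <- object@components[[1L]]@channels
    same <- vapply(object@components,
                   function(x) identical(x@channels, ref), logical(1))
    if (!all(same))
      return(sprintf("components %s differ in channel ordering from '%s'",
                     paste(ids[!same], collapse = ", "), ids[1L]))
  }
  TRUE
})

#' LabelMatrix: binary expert votes per component and class
#'
#' Three-way array of \{0, 1, NA\} votes: \code{votes[c, e, k]} is 1 when
#' expert \code{e} listed class \code{k} for component \code{c}, and NA
#' across all classes when that expert never annotated that component.
#'
#' @slot votes 3-d array component x expert x class with dimnames.
#' @seealso \code{\link{buildLabelMatrix}}
#' @exportClass LabelMatrix
setClass("LabelMatrix", representation(votes = "array"))

setValidity("LabelMatrix", function(object) {
  v <- object@votes
  if (length(dim(v)) != 3L) return("'votes' must be a 3-d array")
  if (is.null(dimnames(v)) || any(vapply(dimnames(v), is.null, logical(1))))
    return("'votes' needs complete dimnames (components, experts, classes)")
  if (!all(v %in% c(0, 1, NA)))
    return("votes must be 0, 1 or NA")
  for (ci in seq_len(dim(v)[1L])) for (ei in seq_len(dim(v)[2L])) {
    slice <- v[ci, ei, ]
    if (all(is.na(slice))) next
    if (anyNA(slice))
      return("a (component, expert) slice must be all-missing or complete")
    if (sum(slice) < 1)
      return("a non-missing (component, expert) slice needs >= 1 positive")
  }
  TRUE
})

#' AggregatedLabels: per-component class targets after vote aggregation
#'
#' @slot probabilities numeric matrix component x class in [0, 1]
#'   (weighted probabilities).
#' @slot targets logical matrix, same shape; TRUE iff the probability
#'   strictly exceeds the class threshold.
#' @slot strategy named character: "majority" or "probabilistic" per class.
#' @slot threshold named numeric threshold per class.
#' @seealso \code{\link{aggregateAnnotations}}
#' @exportClass AggregatedLabels
setClass("AggregatedLabels",
  representation(probabilities = "matrix", targets = "matrix",
                 strategy = "character", threshold = "numeric"))

setValidity("AggregatedLabels", function(object) {
  p <- object@probabilities
  if (!identical(dim(p), dim(object@targets)))
    return("probabilities and targets must have identical shape")
  if (any(p < -1e-12 | p > 1 + 1e-12, na.rm = TRUE))
    return("probabilities must lie in [0, 1]")
  cls <- colnames(p)
  if (!all(names(object@strategy) %in% cls) ||
      !identical(names(object@strategy), names(object@threshold)))
    return("strategy/threshold must be named consistently with classes")
  if (!all(object@strategy %in% c("majority", "probabilistic")))
    return("strategy must be 'majority' or 'probabilistic'")
  TRUE
})

#' ValidationReport: repeated-split validation results
#'
#' @slot metrics data.frame with one row per class x model x split:
#'   columns class, model, split, roc_auc, pr_auc, f1.
#' @slot summary data.frame of per class x model means and sds.
#' @slot curves named list: per class x model, aggregated ROC and PR curves
#'   on fixed grids with pointwise mean and 95\% percentile bands.
#' @slot selected data.frame with the selected model family per class and
#'   the rule applied.
#' @slot config list echoing split fraction, repeat count and seed.
#' @seealso \code{\link{repeatedSplitValidate}}, \code{\link{selectModel}}
#' @exportClass ValidationReport
setClass("ValidationReport",
  representation(metrics = "data.frame", summary = "data.frame",
                 curves = "list", selected = "data.frame", config = "list"))

setValidity("ValidationReport", function(object) {
  m <- object@metrics
  need <- c("class", "model", "split", "roc_auc", "pr_auc", "f1")
  if (!all(need %in% names(m)))
    return(sprintf("metrics must have columns %s", paste(need, collapse = ", ")))
  num <- m[, c("roc_auc", "pr_auc", "f1")]
  if (any(num < -1e-9 | num > 1 + 1e-9, na.rm = TRUE))
    return("roc_auc, pr_auc and f1 must lie in [0, 1]")
  TRUE
})

#' ICClassifier: a fitted, exportable per-class model
#'
#' Wraps one one-vs-rest classifier with everything needed to validate input
#' at prediction time and to re-create the model from a plain-text export:
#' feature schema, train-set standardisation parameters, and a portable
#' parameter payload (coefficients for the linear families, the JSON dump of
#' the boosted-tree ensemble).
#'
#' @slot className target class name.
#' @slot family "logreg", "svm" or "xgb".
#' @slot featureNames character vector, order fixed at fit time.
#' @slot center,scale numeric standardisation vectors (all zero / one for
#'   the tree family, which takes raw features).
#' @slot params list: intercept + coefficients (linear) or model JSON (xgb).
#' @slot hyper list of the fixed hyperparameters used.
#' @seealso \code{\link{fitFinal}}, \code{\link{predictComponents}},
#'   \code{\link{exportModel}}
#' @exportClass ICClassifier
setClass("ICClassifier",
  representation(className = "character", family = "character",
                 featureNames = "character", center = "numeric",
                 scale = "numeric", params = "list", hyper = "list"))

setValidity("ICClassifier", function(object) {
  if (!object@family %in% c("logreg", "svm", "xgb"))
    return("family must be one of logreg, svm, xgb")
  if (length(object@center) != length(object@featureNames) ||
      length(object@scale) != length(object@featureNames))
    return("center/scale must match featureNames")
  TRUE
})
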