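#' @include AllClasses.R montage.R
NULL

#' Construct an independent component
#'
#' @param componentId,subjectId identifier strings.
#' @param channels character vector of channel labels; normalised to
#'   canonical modern 10-10 names (see \code{\link{canonicalChannels}}).
#' @param weights numeric topomap weight vector, one per channel.
#' @param signal numeric matrix (epochs x samples) or vector (continuous,
#'   treated as one epoch).
#' @param samplingRate sampling rate in Hz.
#' @return an \linkS4class{ICComponent}.
#' @examples
#' ic <- ICComponent("ic1", "s1", c("Fp1", "Oz"), c(0.2, -1),
#'                   matrix(rnorm(500), 2, 250), 250)
#' nEpochs(ic)
#' @export
ICComponent <- function(componentId, subjectId, channels, weights, signal,
                        samplingRate) {
  if (is.vector(signal)) signal <- matrix(signal, nrow = 1L)
  new("ICComponent",
      componentId = as.character(componentId),
      subjectId = as.character(subjectId),
      channels = canonicalChannels(channels),
      weights = as.numeric(weights),
      signal = signal,
      samplingRate = as.numeric(samplingRate))
}

#' Construct a dataset of independent components
#'
#' @param components list of \linkS4class{ICComponent} objects sharing one
#'   channel ordering.
#' @param metadata named list of strings.
#' @return an \linkS4class{ICDataset}.
#' @export
ICDataset <- function(components = list(), metadata = list()) {
  new("ICDataset", components = components, metadata = metadata)
}

#' @rdname ICAnnotate-accessors
#' @export
setGeneric("componentIds", function(x) standardGeneric("componentIds"))
#' @rdname ICAnnotate-accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))
#' @rdname ICAnnotate-accessors
#' @export
setGeneric("topoWeights", function(x) standardGeneric("topoWeights"))
#' @rdname ICAnnotate-accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname ICAnnotate-accessors
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))
#' @rdname ICAnnotate-accessors
#' @export
setGeneric("epochView", function(x) standardGeneric("epochView"))
#' @rdname ICAnnotate-accessors
#' @export
setGeneric("components", function(x) standardGeneric("components"))

#' Accessors for IC objects
#'
#' \code{componentIds} returns component identifiers; \code{channelLabels}
#' the channel ordering; \code{topoWeights} the named topomap weight vector;
#' \code{samplingRate} the sampling rate in Hz; \code{nEpochs} the epoch
#' count; \code{epochView} the signal as an epochs x samples matrix (a
#' continuous recording comes back as 1 x samples); \code{components} the
#' component list of a dataset.
#'
#' @param x an \linkS4class{ICComponent} or \linkS4class{ICDataset}.
#' @return see details above.
#' @name ICAnnotate-accessors
NULL

#' @rdname ICAnnotate-accessors
#' @export
setMethod("componentIds", "ICComponent", function(x) x@componentId)
#' @rdname ICAnnotate-accessors
#' @export
setMethod("componentIds", "ICDataset", function(x)
  vapply(x@components, function(c) c@componentId, character(1)))
#' @rdname ICAnnotate-accessors
#' @export
setMethod("channelLabels", "ICComponent", function(x) x@channels)
#' @rdname ICAnnotate-accessors
#' @export
setMethod("channelLabels", "ICDataset", function(x) {
  if (!length(x@components)) character() else x@components[[1L]]@channels
})
#' @rdname ICAnnotate-accessors
#' @export
setMethod("topoWeights", "ICComponent", function(x)
  stats::setNames(x@weights, x@channels))
#' @rdname ICAnnotate-accessors
#' @export
setMethod("samplingRate", "ICComponent", function(x) x@samplingRate)
#' @rdname ICAnnotate-accessors
#' @export
setMethod("nEpochs", "ICComponent", function(x) nrow(x@signal))
#' @rdname ICAnnotate-accessors
#' @export
setMethod("epochView", "ICComponent", function(x) x@signal)
#' @rdname ICAnnotate-accessors
#' @export
setMethod("components", "ICDataset", function(x) x@components)

#' @export
setMethod("length", "ICDataset", function(x) length(x@components))

#' @export
setMethod("[[", "ICDataset", function(x, i) {
  if (is.character(i)) i <- match(i, componentIds(x))
  x@components[[i]]
})

setMethod("show", "ICComponent", function(object) {
  cat(sprintf("ICComponent '%s' (subject %s): %d channels, %d epoch(s) x %d samples @ %g Hz\n",
              object@componentId, object@subjectId, length(object@channels),
              nrow(object@signal), ncol(object@signal), object@samplingRate))
})

setMethod("show", "ICDataset", function(object) {
  cat(sprintf("ICDataset: %d component(s), %d channels\n",
              length(object@components), length(channelLabels(object))))
  if (length(object@metadata))
    cat("metadata:", paste(names(object@metadata), unlist(object@metadata),
                           sep = "=", collapse = ", "), "\n")
})
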