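#' @include AllClasses.R
NULL

#' Annotation vocabulary and aggregated class set
#'
#' \code{annotationVocabulary} returns the fixed set of labels an expert may
#' assign to an independent component. \code{aggregationClasses} returns the
#' class set that remains after \code{\link{mergeClasses}} (eye-movement
#' subtypes merged into Eyes, Line noise dropped), in canonical order.
#'
#' @return character vector.
#' @export
annotationVocabulary <- function() {
  c("Eyes", "Horizontal eye movements", "Vertical eye movements",
    "Line noise", "Channel noise", "Brain", "Alpha", "Mu", "Muscle",
    "Heart", "Other", "Uncertain")
}

#' @rdname annotationVocabulary
#' @export
aggregationClasses <- function() {
  c("Brain", "Alpha", "Mu", "Eyes", "Muscle", "Heart", "Channel noise",
    "Other", "Uncertain")
}

.checkAnnotations <- function(ann) {
  need <- c("component_id", "expert_id", "labels")
  if (!is.data.frame(ann) || !all(need %in% names(ann)))
    stop("annotations must be a data.frame with columns ",
         paste(need, collapse = ", "))
  if (anyDuplicated(ann[c("component_id", "expert_id")]))
    stop("duplicate (component_id, expert_id) annotation rows")
  labs <- unlist(ann$labels)
  bad <- setdiff(labs, annotationVocabulary())
  if (length(bad))
    stop("labels outside the vocabulary: ", paste(unique(bad), collapse = ", "))
  if (any(!vapply(ann$labels, length, integer(1))))
    stop("every annotation needs a non-empty label set")
  invisible(ann)
}

#' Merge annotation classes prior to aggregation
#'
#' Applies the class-merging rules used before label aggregation:
#' \itemize{
#'   \item Horizontal and vertical eye-movement labels are replaced by the
#'     single \code{Eyes} class (deduplicated);
#'   \item \code{Line noise} labels are dropped; an annotation left with an
#'     empty label set becomes \code{Uncertain} so the row (and agreement
#'     denominators) survive;
#'   \item any annotation containing \code{Alpha} or \code{Mu} is ensured to
#'     also carry \code{Brain};
#'   \item \code{Other} and \code{Uncertain} pass through unchanged.
#' }
#'
#' @param ann annotation data.frame (component_id, expert_id, labels
#'   list-column, optional comment).
#' @return annotation data.frame with merged label sets.
#' @examples
#' ann <- data.frame(component_id = "c1", expert_id = "e1")
#' ann$labels <- list(c("Horizontal eye movements", "Brain"))
#' mergeClasses(ann)$labels[[1]]
#' @export
mergeClasses <- function(ann) {
  .checkAnnotations(ann)
  ann$labels <- lapply(ann$labels, function(l) {
    l[l %in% c("Horizontal eye movements", "Vertical eye movements")] <- "Eyes"
    l <- setdiff(unique(l), "Line noise")
    if (any(l %in% c("Alpha", "Mu"))) l <- union(l, "Brain")
    if (!length(l)) l <- "Uncertain"
    l
  })
  ann
}

#' Build the binary vote matrix from merged annotations
#'
#' @param ann merged annotation data.frame (see \code{\link{mergeClasses}}).
#' @param classes ordered class names for the third dimension; defaults to
#'   \code{\link{aggregationClasses}} so every label an expert cast keeps
#'   its share of the vote under the probabilistic strategy.
#' @return a \linkS4class{LabelMatrix}: votes[component, expert, class]
#'   in \{0, 1\}, NA across classes where an expert never annotated a
#'   component.
#' @export
buildLabelMatrix <- function(ann, classes = aggregationClasses()) {
  .checkAnnotations(ann)
  comps <- unique(ann$component_id)
  experts <- unique(ann$expert_id)
  v <- array(NA_real_, dim = c(length(comps), length(experts), length(classes)),
             dimnames = list(comps, experts, classes))
  for (i in seq_len(nrow(ann))) {
    l <- ann$labels[[i]]
    extra <- setdiff(l, classes)
    if (length(extra))
      stop("labels not covered by the class set: ",
           paste(extra, collapse = ", "))
    v[ann$component_id[i], ann$expert_id[i], ] <- as.numeric(classes %in% l)
  }
  new("LabelMatrix", votes = v)
}

## Shared thresholding: strict ">" after rounding probabilities to 12
## decimals, so a one-of-three vote (0.333...) beats the default 0.33
## threshold unambiguously.
.threshold <- function(prob, threshold) round(prob, 12) > threshold

.voteCore <- function(m, threshold, strategy) {
  stopifnot(is(m, "LabelMatrix"), threshold > 0, threshold < 1)
  v <- m@votes
  nc <- dim(v)[1L]; ne <- dim(v)[2L]
  ## per-expert contribution: raw vote (majority) or vote split equally
  ## over the k classes that expert chose (probabilistic)
  contrib <- v
  if (strategy == "probabilistic") {
    for (ei in seq_len(ne)) {
      k <- rowSums(v[, ei, , drop = FALSE], dims = 1)
      contrib[, ei, ] <- v[, ei, ] / ifelse(k > 0, k, 1)
    }
  }
  ## mean over experts who actually annotated the component
  prob <- apply(contrib, c(1L, 3L), function(x) mean(x, na.rm = TRUE))
  annotated <- apply(v, 1L, function(x) any(!is.na(x)))
  if (!all(annotated))
    stop("components with zero annotators: ",
         paste(dimnames(v)[[1L]][!annotated], collapse = ", "))
  classes <- dimnames(v)[[3L]]
  new("AggregatedLabels",
      probabilities = prob,
      targets = .threshold(prob, threshold),
      strategy = stats::setNames(rep(strategy, length(classes)), classes),
      threshold = stats::setNames(rep(threshold, length(classes)), classes))
}

#' Vote-aggregation strategies
#'
#' \code{majorityVote} averages the experts' binary votes per class
#' (Strategy 1): the weighted probability for a class is the fraction of
#' annotating experts who listed it. \code{probabilisticVote} (Strategy 2)
#' first splits each expert's single vote equally over the k classes they
#' chose (1/k each), then averages. Under both, the boolean target is 1 iff
#' the weighted probability strictly exceeds the threshold. Experts who did
#' not annotate a component are excluded from its denominator.
#'
#' @param m a \linkS4class{LabelMatrix}.
#' @param threshold vote threshold in (0, 1); default 0.33.
#' @return an \linkS4class{AggregatedLabels}.
#' @examples
#' ann <- data.frame(component_id = "c1", expert_id = "e1")
#' ann$labels <- list(c("Eyes", "Muscle", "Heart"))
#' p <- probabilisticVote(buildLabelMatrix(ann))
#' probabilities(p)[, c("Eyes", "Muscle", "Heart")]  # 1/3 each
#' @export
majorityVote <- function(m, threshold = 0.33)
  .voteCore(m, threshold, "majority")

#' @rdname majorityVote
#' @export
probabilisticVote <- function(m, threshold = 0.33)
  .voteCore(m, threshold, "probabilistic")

#' Default per-class aggregation plan
#'
#' The per-class strategy assignment used for the reference annotation
#' corpus: the probabilistic vote for the well-represented classes (Brain,
#' Eyes, Muscle, Channel noise) and the majority vote for the sparse ones
#' (Alpha, Mu, Heart), all at threshold 0.33. Other/Uncertain are
#' annotation-quality flags, not targets, and carry no strategy.
#'
#' @return data.frame with columns class, strategy, threshold.
#' @export
defaultAggregationPlan <- function() {
  data.frame(
    class = c("Brain", "Alpha", "Mu", "Eyes", "Muscle", "Heart",
              "Channel noise"),
    strategy = c("probabilistic", "majority", "majority", "probabilistic",
                 "probabilistic", "majority", "probabilistic"),
    threshold = 0.33,
    stringsAsFactors = FALSE)
}

#' Aggregate a multi-expert annotation table into per-class targets
#'
#' Runs the full aggregation pipeline: \code{\link{mergeClasses}}, then
#' \code{\link{buildLabelMatrix}}, then the per-class strategy given by
#' \code{plan}.
#'
#' @param ann annotation data.frame.
#' @param plan data.frame with columns class, strategy
#'   ("majority"/"probabilistic") and threshold;
#'   default \code{\link{defaultAggregationPlan}}.
#' @return an \linkS4class{AggregatedLabels} restricted to the plan's
#'   classes.
#' @export
aggregateAnnotations <- function(ann, plan = defaultAggregationPlan()) {
  stopifnot(is.data.frame(plan),
            all(c("class", "strategy", "threshold") %in% names(plan)))
  if (anyDuplicated(plan$class)) stop("plan lists a class twice")
  bad <- setdiff(plan$strategy, c("majority", "probabilistic"))
  if (length(bad)) stop("unknown strategy: ", paste(bad, collapse = ", "))
  merged <- mergeClasses(ann)
  m <- buildLabelMatrix(merged)
  missingCls <- setdiff(plan$class, dimnames(m@votes)[[3L]])
  if (length(missingCls))
    stop("plan covers classes absent from the matrix: ",
         paste(missingCls, collapse = ", "))
  prob <- matrix(NA_real_, nrow = dim(m@votes)[1L], ncol = nrow(plan),
                 dimnames = list(dimnames(m@votes)[[1L]], plan$class))
  tgt <- matrix(NA, nrow = nrow(prob), ncol = ncol(prob),
                dimnames = dimnames(prob))
  for (i in seq_len(nrow(plan))) {
    agg <- .voteCore(m, plan$threshold[i], plan$strategy[i])
    prob[, i] <- agg@probabilities[, plan$class[i]]
    tgt[, i] <- agg@targets[, plan$class[i]]
  }
  new("AggregatedLabels", probabilities = prob, targets = tgt,
      strategy = stats::setNames(plan$strategy, plan$class),
      threshold = stats::setNames(plan$threshold, plan$class))
}

#' @rdname AggregatedLabels-accessors
#' @export
setGeneric("probabilities", function(x) standardGeneric("probabilities"))
#' @rdname AggregatedLabels-accessors
#' @export
setGeneric("targets", function(x) standardGeneric("targets"))

#' Accessors for aggregated labels
#'
#' \code{probabilities} returns the component x class weighted-probability
#' matrix; \code{targets} the boolean target matrix.
#'
#' @param x an \linkS4class{AggregatedLabels}.
#' @return a matrix with component rows and class columns.
#' @name AggregatedLabels-accessors
NULL

#' @rdname AggregatedLabels-accessors
#' @export
setMethod("probabilities", "AggregatedLabels", function(x) x@probabilities)
#' @rdname AggregatedLabels-accessors
#' @export
setMethod("targets", "AggregatedLabels", function(x) x@targets)

setMethod("show", "AggregatedLabels", function(object) {
  cat(sprintf("AggregatedLabels: %d component(s) x %d class(es)\n",
              nrow(object@probabilities), ncol(object@probabilities)))
  cat("positives per class:",
      paste(colnames(object@targets),
            colSums(object@targets), sep = "=", collapse = ", "), "\n")
})

setMethod("show", "LabelMatrix", function(object) {
  d <- dim(object@votes)
  cat(sprintf("LabelMatrix: %d component(s) x %d expert(s) x %d class(es)\n",
              d[1L], d[2L], d[3L]))
})

#' Write aggregated labels as a delimited table
#'
#' One row per component: \code{component_id}, a \code{prob_<class>} and a
#' \code{target_<class>} column per class. The plan (strategy and threshold
#' per class) is written alongside as a JSON sidecar.
#'
#' @param agg an \linkS4class{AggregatedLabels}.
#' @param path output CSV path (the sidecar gets suffix \code{.plan.json}).
#' @return \code{path}, invisibly.
#' @export
writeAggregatedLabels <- function(agg, path) {
  stopifnot(is(agg, "AggregatedLabels"))
  p <- agg@probabilities; t <- agg@targets
  out <- data.frame(component_id = rownames(p), stringsAsFactors = FALSE)
  for (cls in colnames(p)) {
    out[[paste0("prob_", cls)]] <- p[, cls]
    out[[paste0("target_", cls)]] <- as.integer(t[, cls])
  }
  names(out) <- gsub(" ", "_", names(out))
  utils::write.csv(out, path, row.names = FALSE)
  jsonlite::write_json(
    list(strategy = as.list(agg@strategy), threshold = as.list(agg@threshold)),
    paste0(path, ".plan.json"), auto_unbox = TRUE)
  invisible(path)
}
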