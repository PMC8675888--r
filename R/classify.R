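#' @include models.R aggregation.R
NULL

#' Ranking metrics for binary classifiers
#'
#' \code{rocAuc} is the area under the ROC curve computed from the rank
#' statistic (equivalent to the Wilcoxon/Mann-Whitney estimator, handling
#' ties by mid-ranks). \code{prAuc} is the average-precision summary of the
#' precision-recall curve: the sum over distinct score thresholds of the
#' recall increment times the precision at that threshold. \code{f1Score}
#' is the harmonic mean of precision and recall for a hard decision vector.
#'
#' @param scores numeric scores, higher = more positive.
#' @param y binary labels (0/1 or logical), both classes present.
#' @return a number in [0, 1].
#' @export
rocAuc <- function(scores, y) {
  y <- as.numeric(y)
  np <- sum(y == 1); nn <- sum(y == 0)
  stopifnot(np > 0, nn > 0, length(scores) == length(y))
  r <- rank(scores)
  (sum(r[y == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' @rdname rocAuc
#' @export
prAuc <- function(scores, y) {
  y <- as.numeric(y)
  np <- sum(y == 1)
  stopifnot(np > 0, length(scores) == length(y))
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; ss <- scores[o]
  tp <- cumsum(ys); fp <- cumsum(1 - ys)
  last <- !duplicated(ss, fromLast = TRUE)  # last index of each threshold
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / np
  sum(diff(c(0, rec)) * prec)
}

#' @rdname rocAuc
#' @param decisions logical/0-1 hard decisions (for \code{f1Score}).
#' @export
f1Score <- function(decisions, y) {
  y <- as.numeric(y); d <- as.numeric(decisions)
  tp <- sum(d == 1 & y == 1)
  if (tp == 0) return(0)
  prec <- tp / sum(d == 1)
  rec <- tp / sum(y == 1)
  2 * prec * rec / (prec + rec)
}

## ROC curve interpolated onto an FPR grid (step, right-continuous) and
## PR curve onto a recall grid.
.rocOnGrid <- function(scores, y, grid) {
  y <- as.numeric(y)
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; ss <- scores[o]
  tp <- cumsum(ys); fp <- cumsum(1 - ys)
  last <- !duplicated(ss, fromLast = TRUE)
  tpr <- c(0, tp[last] / sum(y)); fpr <- c(0, fp[last] / sum(1 - y))
  stats::approx(fpr, tpr, grid, method = "linear", ties = max,
                yleft = 0, yright = 1)$y
}

.prOnGrid <- function(scores, y, grid) {
  y <- as.numeric(y)
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; ss <- scores[o]
  tp <- cumsum(ys); fp <- cumsum(1 - ys)
  last <- !duplicated(ss, fromLast = TRUE)
  prec <- tp[last] / (tp[last] + fp[last])
  rec <- tp[last] / sum(y)
  ## precision at recall 0 taken as the precision of the top-scored bin
  stats::approx(c(0, rec), c(prec[1L], prec), grid, method = "constant",
                f = 1, ties = list("ordered", max), rule = 2)$y
}

## Stratified train/test split of indices; deterministic given the RNG
## state.
.stratifiedSplit <- function(y, fraction) {
  idx <- seq_along(y)
  train <- unlist(lapply(split(idx, y), function(g) {
    sample(g, round(length(g) * fraction))
  }), use.names = FALSE)
  sort(train)
}

#' Repeated train/test split validation of per-class classifiers
#'
#' For each requested class (one-vs-rest) and each model family, performs
#' \code{nRepeats} stratified splits at \code{splitFraction} (default 70/30),
#' fits on the training part with the fixed hyperparameters, scores the
#' test part, and records ROC-AUC, PR-AUC (average precision) and F1 at the
#' default decision point (probability 0.5 / margin 0). Features are
#' standardised with training-set statistics for the linear families; the
#' boosted trees take raw features. ROC and PR curves are interpolated onto
#' fixed 101-point grids and aggregated as pointwise means with 95\%
#' percentile bands over the repeats.
#'
#' Classes with fewer than 2 positives or 2 negatives are skipped with a
#' warning. A split whose test set turns out single-class is redrawn with
#' an incremented sub-seed.
#'
#' @param ft feature data.frame from \code{\link{extractFeatures}}.
#' @param labels an \linkS4class{AggregatedLabels}, or a logical/0-1 matrix
#'   with component rows and class columns aligned to \code{ft}.
#' @param classes classes to validate; default all columns of
#'   \code{labels}.
#' @param families model families; default all three.
#' @param splitFraction training fraction, default 0.7.
#' @param nRepeats number of repeated splits, default 50.
#' @param seed integer seed controlling every split.
#' @param features feature columns; default \code{\link{featureNames}}.
#' @return a \linkS4class{ValidationReport}.
#' @export
repeatedSplitValidate <- function(ft, labels, classes = NULL,
                                  families = c("logreg", "xgb", "svm"),
                                  splitFraction = 0.7, nRepeats = 50,
                                  seed = 1, features = featureNames()) {
  stopifnot(splitFraction > 0, splitFraction < 1, nRepeats >= 1)
  tg <- if (is(labels, "AggregatedLabels")) targets(labels) else labels
  tg <- as.matrix(tg) * 1
  if (is.null(classes)) classes <- colnames(tg)
  families <- match.arg(families, .FAMILIES, several.ok = TRUE)
  if (nrow(tg) != nrow(ft))
    stop("labels and feature table disagree on component count")
  if (!is.null(rownames(tg)) &&
      !identical(rownames(tg), ft$component_id))
    tg <- tg[match(ft$component_id, rownames(tg)), , drop = FALSE]
  X <- .featureMatrix(ft, features)
  if (nrow(X) < 10L) stop("need >= 10 components for validation")
  grid <- seq(0, 1, length.out = 101L)
  rows <- list(); curves <- list(); posFrac <- c()
  for (cls in classes) {
    y <- tg[, cls]
    if (sum(y) < 2 || sum(1 - y) < 2) {
      warning("class '", cls, "' has < 2 positives or < 2 negatives; skipped",
              call. = FALSE)
      next
    }
    posFrac[cls] <- mean(y)
    acc <- list()
    for (fam in families)
      acc[[fam]] <- list(roc = matrix(NA_real_, nRepeats, length(grid)),
                         pr = matrix(NA_real_, nRepeats, length(grid)))
    for (r in seq_len(nRepeats)) {
      sub <- 0L
      repeat {
        set.seed(seed + 1000L * sub + r)
        train <- .stratifiedSplit(y, splitFraction)
        test <- setdiff(seq_along(y), train)
        if (length(unique(y[test])) == 2L && length(unique(y[train])) == 2L)
          break
        sub <- sub + 1L
        if (sub > 100L) stop("could not draw a two-class split for ", cls)
      }
      for (fam in families) {
        std <- .standardizer(X[train, , drop = FALSE], use = fam != "xgb")
        set.seed(seed + r)  # family fits see identical RNG state
        params <- .fitFamily(fam, .applyStd(X[train, , drop = FALSE], std),
                             y[train])
        s <- .scoreFamily(fam, params, .applyStd(X[test, , drop = FALSE], std))
        rows[[length(rows) + 1L]] <- data.frame(
          class = cls, model = fam, split = r,
          roc_auc = rocAuc(s, y[test]),
          pr_auc = prAuc(s, y[test]),
          f1 = f1Score(.flagFamily(fam, s, 0.5), y[test]),
          stringsAsFactors = FALSE)
        acc[[fam]]$roc[r, ] <- .rocOnGrid(s, y[test], grid)
        acc[[fam]]$pr[r, ] <- .prOnGrid(s, y[test], grid)
      }
    }
    for (fam in families) {
      band <- function(m) list(
        grid = grid, mean = colMeans(m),
        lower = apply(m, 2L, stats::quantile, 0.025),
        upper = apply(m, 2L, stats::quantile, 0.975))
      curves[[paste(cls, fam, sep = "|")]] <-
        list(roc = band(acc[[fam]]$roc), pr = band(acc[[fam]]$pr))
    }
  }
  metrics <- do.call(rbind, rows)
  if (is.null(metrics)) stop("no class was eligible for validation")
  agg <- stats::aggregate(metrics[c("roc_auc", "pr_auc", "f1")],
                          by = metrics[c("class", "model")],
                          function(v) c(mean = mean(v), sd = stats::sd(v)))
  summ <- data.frame(class = agg$class, model = agg$model,
                     roc_auc_mean = agg$roc_auc[, "mean"],
                     roc_auc_sd = agg$roc_auc[, "sd"],
                     pr_auc_mean = agg$pr_auc[, "mean"],
                     pr_auc_sd = agg$pr_auc[, "sd"],
                     f1_mean = agg$f1[, "mean"], f1_sd = agg$f1[, "sd"],
                     stringsAsFactors = FALSE)
  rep <- new("ValidationReport", metrics = metrics, summary = summ,
             curves = curves, selected = data.frame(),
             config = list(splitFraction = splitFraction,
                           nRepeats = nRepeats, seed = seed,
                           families = families,
                           positiveFraction = posFrac))
  rep@selected <- selectModel(rep)
  rep
}

#' Balance-aware model selection
#'
#' Chooses one model family per class: by mean ROC-AUC when the class is
#' relatively balanced, by mean PR-AUC when it is unbalanced (positive
#' fraction below \code{balanceThreshold}, default 0.25). Exact ties are
#' broken by the other metric, then by the fixed family order (logistic
#' regression, boosted trees, SVM).
#'
#' @param report a \linkS4class{ValidationReport}.
#' @param balanceThreshold positive-fraction cutoff below which a class is
#'   deemed unbalanced.
#' @return data.frame: class, model, rule ("roc_auc" or "pr_auc"),
#'   positive_fraction.
#' @export
selectModel <- function(report, balanceThreshold = 0.25) {
  stopifnot(is(report, "ValidationReport"))
  summ <- report@summary
  if (!nrow(summ)) stop("empty validation report")
  posFrac <- report@config$positiveFraction
  famOrder <- c("logreg", "xgb", "svm")
  do.call(rbind, lapply(unique(summ$class), function(cls) {
    s <- summ[summ$class == cls, ]
    pf <- posFrac[[cls]]
    rule <- if (!is.null(pf) && pf < balanceThreshold) "pr_auc" else "roc_auc"
    other <- if (rule == "pr_auc") "roc_auc" else "pr_auc"
    key <- s[[paste0(rule, "_mean")]]
    tie <- s[[paste0(other, "_mean")]]
    ord <- order(-key, -tie, match(s$model, famOrder))
    data.frame(class = cls, model = s$model[ord[1L]], rule = rule,
               positive_fraction = if (is.null(pf)) NA_real_ else pf,
               stringsAsFactors = FALSE)
  }))
}

#' @rdname ValidationReport-accessors
#' @export
setGeneric("validationMetrics", function(x) standardGeneric("validationMetrics"))
#' @rdname ValidationReport-accessors
#' @export
setGeneric("validationSummary", function(x) standardGeneric("validationSummary"))
#' @rdname ValidationReport-accessors
#' @export
setGeneric("selectedModels", function(x) standardGeneric("selectedModels"))
#' @rdname ValidationReport-accessors
#' @export
setGeneric("validationCurves", function(x) standardGeneric("validationCurves"))

#' Accessors for validation reports
#'
#' \code{validationMetrics} returns the per-split metric rows;
#' \code{validationSummary} the per class x model means and standard
#' deviations; \code{selectedModels} the balance-aware selection;
#' \code{validationCurves} the aggregated ROC/PR curves (fixed grid,
#' pointwise mean and 95\% band).
#'
#' @param x a \linkS4class{ValidationReport}.
#' @return data.frame or list; see above.
#' @name ValidationReport-accessors
NULL

#' @rdname ValidationReport-accessors
#' @export
setMethod("validationMetrics", "ValidationReport", function(x) x@metrics)
#' @rdname ValidationReport-accessors
#' @export
setMethod("validationSummary", "ValidationReport", function(x) x@summary)
#' @rdname ValidationReport-accessors
#' @export
setMethod("selectedModels", "ValidationReport", function(x) x@selected)
#' @rdname ValidationReport-accessors
#' @export
setMethod("validationCurves", "ValidationReport", function(x) x@curves)

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf("ValidationReport: %d class(es) x %d model(s), %d split(s)\n",
              length(unique(object@summary$class)),
              length(unique(object@summary$model)),
              object@config$nRepeats))
  s <- object@summary
  cat(sprintf("  %-14s %-7s roc %.3f+/-%.3f  pr %.3f+/-%.3f  f1 %.3f\n",
              s$class, s$model, s$roc_auc_mean, s$roc_auc_sd,
              s$pr_auc_mean, s$pr_auc_sd, s$f1_mean), sep = "")
  if (nrow(object@selected)) {
    cat("selected:\n")
    cat(sprintf("  %-14s -> %-7s (%s)\n", object@selected$class,
                object@selected$model, object@selected$rule), sep = "")
  }
})

#' Write a validation report to a directory of delimited tables
#'
#' Writes \code{metrics.csv} (per-split rows), \code{summary.csv},
#' \code{selected.csv} and one \code{curve_<class>_<model>.csv} per
#' class/model pair (grid, ROC mean/band, PR mean/band), plus a JSON echo
#' of the run configuration.
#'
#' @param report a \linkS4class{ValidationReport}.
#' @param dir output directory, created if needed.
#' @return \code{dir}, invisibly.
#' @export
writeValidationReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report@metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(report@summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(report@selected, file.path(dir, "selected.csv"),
                   row.names = FALSE)
  for (key in names(report@curves)) {
    cv <- report@curves[[key]]
    df <- data.frame(grid = cv$roc$grid,
                     roc_mean = cv$roc$mean, roc_lower = cv$roc$lower,
                     roc_upper = cv$roc$upper,
                     pr_mean = cv$pr$mean, pr_lower = cv$pr$lower,
                     pr_upper = cv$pr$upper)
    safe <- gsub("[^A-Za-z0-9._-]", "_", key)
    utils::write.csv(df, file.path(dir, paste0("curve_", safe, ".csv")),
                     row.names = FALSE)
  }
  cfg <- report@config
  cfg$positiveFraction <- as.list(cfg$positiveFraction)
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE)
  invisible(dir)
}
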