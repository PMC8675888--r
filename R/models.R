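#' @include AllClasses.R features.R
NULL

## Fixed hyperparameters for the three model families. C is the inverse
## regularisation strength of the linear families; the boosted trees use
## 30 estimators of depth 4.
.FAMILIES <- c("logreg", "xgb", "svm")

.hyperFor <- function(family) {
  switch(family,
    logreg = list(C = 1.0, penalty = "l2"),
    svm = list(C = 1.0, kernel = "linear"),
    xgb = list(nrounds = 30L, max_depth = 4L, eta = 0.3),
    stop("unknown model family: ", family))
}

## Fit one family on an already-standardised (linear) or raw (xgb) matrix.
## Returns portable parameters: linear families reduce to intercept +
## coefficients, the tree family to its JSON dump, so prediction never
## needs the fitting object.
.fitFamily <- function(family, X, y, hyper = .hyperFor(family)) {
  if (family == "logreg") {
    fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                          lambda = 1 / (hyper$C * length(y)),
                          standardize = FALSE, thresh = 1e-10)
    cf <- as.numeric(stats::coef(fit))
    list(intercept = cf[1L], coef = cf[-1L])
  } else if (family == "svm") {
    fit <- e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "linear",
                      cost = hyper$C, scale = FALSE)
    ## libsvm orients decision values toward the class of the first
    ## training row, so the positive-class margin may need a sign flip
    w <- as.numeric(t(fit$coefs) %*% fit$SV)
    b <- -fit$rho
    if (fit$levels[fit$labels[1L]] != "1") { w <- -w; b <- -b }
    list(intercept = b, coef = w)
  } else {
    d <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
    bst <- xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = hyper$max_depth, eta = hyper$eta,
                    nthread = 1),
      data = d, nrounds = hyper$nrounds)
    list(modelJSON = rawToChar(xgboost::xgb.save.raw(bst,
                                                     raw_format = "json")))
  }
}

## Continuous score on new data: probability for logreg/xgb, signed margin
## for svm.
.scoreFamily <- function(family, params, X) {
  if (family == "xgb") {
    bst <- xgboost::xgb.load.raw(charToRaw(params$modelJSON))
    as.numeric(stats::predict(bst, xgboost::xgb.DMatrix(X, nthread = 1)))
  } else {
    eta <- as.numeric(X %*% params$coef) + params$intercept
    if (family == "logreg") stats::plogis(eta) else eta
  }
}

## Decision flag at a probability-scale threshold: svm margins are mapped
## through the logistic so one threshold semantics covers all families
## (threshold 0.5 == margin 0).
.flagFamily <- function(family, score, threshold) {
  if (family == "svm") stats::plogis(score) > threshold else score > threshold
}

## Feature standardisation (linear families only; trees take raw values).
.standardizer <- function(X, use = TRUE) {
  if (!use)
    return(list(center = rep(0, ncol(X)), scale = rep(1, ncol(X))))
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl)
}

.applyStd <- function(X, std) {
  sweep(sweep(X, 2L, std$center), 2L, std$scale, "/")
}

## Feature matrix from a feature table, schema-checked.
.featureMatrix <- function(ft, featNames) {
  miss <- setdiff(featNames, names(ft))
  if (length(miss))
    stop("feature table is missing columns: ", paste(miss, collapse = ", "))
  X <- as.matrix(ft[featNames])
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("feature matrix contains missing values")
  X
}

#' Fit a final exportable classifier for one class
#'
#' Fits the chosen model family on all supplied data with the fixed
#' hyperparameters (logistic regression: L2 penalty, C = 1; linear SVM:
#' C = 1; gradient boosting: 30 trees of depth 4) and wraps it with the
#' feature schema and standardisation parameters so that prediction can
#' validate its input.
#'
#' @param ft feature data.frame from \code{\link{extractFeatures}}.
#' @param y binary target vector (0/1 or logical), one per row of
#'   \code{ft}, with >= 2 positives.
#' @param class name of the target class (metadata).
#' @param family "logreg", "svm" or "xgb".
#' @param features feature columns to use; default \code{\link{featureNames}}.
#' @return an \linkS4class{ICClassifier}.
#' @seealso \code{\link{predictComponents}}, \code{\link{exportModel}}
#' @export
fitFinal <- function(ft, y, class, family = c("logreg", "xgb", "svm"),
                     features = featureNames()) {
  family <- match.arg(family)
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(ft), all(y %in% c(0, 1)))
  if (sum(y) < 2) stop("class '", class, "' has fewer than 2 positives")
  X <- .featureMatrix(ft, features)
  std <- .standardizer(X, use = family != "xgb")
  params <- .fitFamily(family, .applyStd(X, std), y)
  new("ICClassifier", className = as.character(class), family = family,
      featureNames = features, center = std$center, scale = std$scale,
      params = params, hyper = .hyperFor(family))
}

#' Score components with fitted per-class models
#'
#' Applies each model to the feature table and returns, per component and
#' class, the continuous score (probability for logistic regression and
#' boosted trees, signed margin for the SVM) and a boolean flag comparing
#' the score with \code{threshold} on the probability scale (SVM margins
#' are mapped through the logistic, so threshold 0.5 corresponds to margin
#' 0). Classes are independent: a component may carry several flags or
#' none.
#'
#' @param models a single \linkS4class{ICClassifier} or a list of them.
#' @param ft feature data.frame; must contain every model's feature
#'   columns.
#' @param threshold decision threshold on the probability scale, default
#'   0.5.
#' @return data.frame: component_id, then \code{score_<class>} and
#'   \code{flag_<class>} per model.
#' @export
predictComponents <- function(models, ft, threshold = 0.5) {
  if (is(models, "ICClassifier")) models <- list(models)
  out <- data.frame(component_id = ft$component_id,
                    stringsAsFactors = FALSE)
  for (m in models) {
    X <- .featureMatrix(ft, m@featureNames)
    s <- .scoreFamily(m@family, m@params,
                      .applyStd(X, list(center = m@center, scale = m@scale)))
    out[[paste0("score_", m@className)]] <- s
    out[[paste0("flag_", m@className)]] <- .flagFamily(m@family, s, threshold)
  }
  out
}

#' Export / import a fitted classifier as self-describing JSON
#'
#' The export carries the model family, its fixed hyperparameters, the
#' feature schema, the standardisation parameters and the fitted
#' coefficients (linear families) or tree-ensemble dump (boosted trees), so
#' an imported model reproduces predictions exactly without any opaque
#' binary state.
#'
#' @param model an \linkS4class{ICClassifier}.
#' @param path output JSON path.
#' @return \code{exportModel}: \code{path}, invisibly;
#'   \code{importModel}: an \linkS4class{ICClassifier}.
#' @export
exportModel <- function(model, path) {
  stopifnot(is(model, "ICClassifier"))
  payload <- list(
    format = "ICAnnotate-classifier", version = 1L,
    className = model@className, family = model@family,
    featureNames = model@featureNames,
    center = model@center, scale = model@scale,
    hyper = model@hyper, params = model@params)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname exportModel
#' @export
importModel <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "ICAnnotate-classifier"))
    stop("not an exported classifier: ", path)
  params <- p$params
  if (!is.null(params$coef)) params$coef <- as.numeric(params$coef)
  new("ICClassifier", className = p$className, family = p$family,
      featureNames = p$featureNames, center = as.numeric(p$center),
      scale = as.numeric(p$scale), params = params, hyper = as.list(p$hyper))
}

setMethod("show", "ICClassifier", function(object) {
  cat(sprintf("ICClassifier for class '%s': family %s, %d features\n",
              object@className, object@family, length(object@featureNames)))
})
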