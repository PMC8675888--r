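#' @include aggregation.R
NULL

#' Cohen's kappa for two binary raters
#'
#' Chance-corrected agreement kappa = (p0 - pe) / (1 - pe), with p0 the
#' observed fraction of positions where the raters agree and pe the chance
#' agreement implied by the marginal frequencies,
#' pe = P(a=1)P(b=1) + P(a=0)P(b=0).
#'
#' When both raters are constant with identical marginals (pe = 1) the
#' statistic is undefined; the conventional value 1 (if agreement is
#' perfect) or 0 is returned with a warning.
#'
#' @param a,b binary vectors (0/1 or logical) of equal length >= 1.
#' @return kappa in [-1, 1].
#' @examples
#' cohensKappa(c(1, 0, 1, 0), c(1, 0, 0, 1))  # 0
#' @export
cohensKappa <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) == length(b), length(a) >= 1L,
            all(a %in% c(0, 1)), all(b %in% c(0, 1)))
  p0 <- mean(a == b)
  pe <- mean(a) * mean(b) + (1 - mean(a)) * (1 - mean(b))
  if (abs(1 - pe) < .Machine$double.eps * 4) {
    warning("degenerate marginals (pe = 1); returning conventional value",
            call. = FALSE)
    return(if (p0 == 1) 1 else 0)
  }
  (p0 - pe) / (1 - pe)
}

#' Fleiss' kappa for multiple raters
#'
#' Standard Fleiss' kappa on an items x categories count matrix where every
#' item is rated by exactly \code{nRaters} raters: per-item agreement
#' P_i = (sum_k n_ik^2 - n) / (n (n - 1)), p0 = mean of P_i, and chance
#' agreement pe = sum_k p_k^2 with p_k the pooled category proportions.
#'
#' @param counts numeric matrix, items x categories, of rater counts; every
#'   row must sum to \code{nRaters}.
#' @param nRaters number of raters per item, >= 2.
#' @return kappa in [-1, 1].
#' @examples
#' counts <- rbind(c(3, 0), c(0, 3), c(3, 0))
#' fleissKappa(counts, 3)  # 1: unanimity
#' @export
fleissKappa <- function(counts, nRaters) {
  counts <- as.matrix(counts)
  stopifnot(nRaters >= 2)
  if (!all(rowSums(counts) == nRaters))
    stop("every item must be rated by exactly ", nRaters,
         " raters (ragged counts; subsample first)")
  n <- nRaters
  Pi <- (rowSums(counts^2) - n) / (n * (n - 1))
  p0 <- mean(Pi)
  pk <- colSums(counts) / sum(counts)
  pe <- sum(pk^2)
  if (abs(1 - pe) < .Machine$double.eps * 4) {
    warning("degenerate marginals (pe = 1); returning conventional value",
            call. = FALSE)
    return(if (p0 == 1) 1 else 0)
  }
  (p0 - pe) / (1 - pe)
}

#' Inter-expert correlation between two annotators
#'
#' For each component annotated by both experts, the Pearson correlation
#' between the two experts' binary per-component label vectors (one entry
#' per class) is computed; the statistic is the mean over components.
#' Components where either vector is constant (correlation undefined) are
#' skipped; their number is returned as attribute \code{nSkipped} along
#' with \code{nUsed}.
#'
#' @param m a \linkS4class{LabelMatrix}.
#' @param expert1,expert2 expert ids (column names of the matrix).
#' @return mean correlation in [-1, 1], with attributes \code{nUsed} and
#'   \code{nSkipped}.
#' @export
interExpertCorrelation <- function(m, expert1, expert2) {
  stopifnot(is(m, "LabelMatrix"))
  v <- m@votes
  experts <- dimnames(v)[[2L]]
  if (!all(c(expert1, expert2) %in% experts))
    stop("unknown expert id(s)")
  v1 <- v[, expert1, , drop = FALSE][, 1L, ]
  v2 <- v[, expert2, , drop = FALSE][, 1L, ]
  if (dim(v)[1L] == 1L) { v1 <- matrix(v1, 1L); v2 <- matrix(v2, 1L) }
  joint <- which(rowSums(is.na(v1)) == 0 & rowSums(is.na(v2)) == 0)
  if (!length(joint))
    stop("no components annotated by both experts")
  rs <- vapply(joint, function(ci) {
    x <- v1[ci, ]; y <- v2[ci, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
  used <- !is.na(rs)
  out <- mean(rs[used])
  attr(out, "nUsed") <- sum(used)
  attr(out, "nSkipped") <- sum(!used)
  out
}

#' Per-class inter-expert agreement report
#'
#' Computes per-class agreement over the components jointly annotated by the
#' experts — Cohen's kappa for two experts, Fleiss' kappa for three or more
#' (restricted to components annotated by all experts) — plus the
#' inter-expert correlation for every expert pair and its mean. Agreement is
#' computed after \code{\link{mergeClasses}}, on the merged class set.
#'
#' @param ann annotation data.frame.
#' @param classes classes to report on; default the aggregated target
#'   classes (Other/Uncertain excluded).
#' @return list with \code{perClass} (data.frame: class, statistic, value,
#'   n) and \code{iec} (data.frame: expert1, expert2, value, nUsed,
#'   nSkipped) and \code{meanIEC}.
#' @export
agreementReport <- function(ann, classes = defaultAggregationPlan()$class) {
  merged <- mergeClasses(ann)
  m <- buildLabelMatrix(merged)
  v <- m@votes
  experts <- dimnames(v)[[2L]]
  nExp <- length(experts)
  if (nExp < 2L) stop("agreement needs >= 2 experts")
  perClass <- do.call(rbind, lapply(classes, function(cls) {
    if (nExp == 2L) {
      sl <- v[, , cls, drop = FALSE][, , 1L]
      if (dim(v)[1L] == 1L) sl <- matrix(sl, 1L)
      joint <- stats::complete.cases(sl)
      val <- if (sum(joint) >= 1L)
        suppressWarnings(cohensKappa(sl[joint, 1L], sl[joint, 2L]))
      else NA_real_
      data.frame(class = cls, statistic = "cohens_kappa", value = val,
                 n = sum(joint), stringsAsFactors = FALSE)
    } else {
      full <- apply(v, 1L, function(x) !anyNA(x))
      sl <- v[full, , cls, drop = FALSE][, , 1L, drop = FALSE]
      pos <- rowSums(sl, dims = 1)
      counts <- cbind(pos, nExp - pos)
      val <- if (nrow(counts) >= 1L)
        suppressWarnings(fleissKappa(counts, nExp)) else NA_real_
      data.frame(class = cls, statistic = "fleiss_kappa", value = val,
                 n = sum(full), stringsAsFactors = FALSE)
    }
  }))
  pairs <- utils::combn(experts, 2L)
  iec <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    r <- interExpertCorrelation(m, pairs[1L, j], pairs[2L, j])
    data.frame(expert1 = pairs[1L, j], expert2 = pairs[2L, j],
               value = as.numeric(r), nUsed = attr(r, "nUsed"),
               nSkipped = attr(r, "nSkipped"), stringsAsFactors = FALSE)
  }))
  list(perClass = perClass, iec = iec, meanIEC = mean(iec$value))
}

#' Write an agreement report as a delimited table
#'
#' @param report list returned by \code{\link{agreementReport}}.
#' @param path output CSV path (class, statistic, value, n rows followed by
#'   IEC rows).
#' @return \code{path}, invisibly.
#' @export
writeAgreementReport <- function(report, path) {
  a <- report$perClass
  b <- data.frame(class = paste(report$iec$expert1, report$iec$expert2,
                                sep = ":"),
                  statistic = "inter_expert_correlation",
                  value = report$iec$value, n = report$iec$nUsed,
                  stringsAsFactors = FALSE)
  c <- data.frame(class = "all", statistic = "mean_inter_expert_correlation",
                  value = report$meanIEC, n = sum(report$iec$nUsed),
                  stringsAsFactors = FALSE)
  utils::write.csv(rbind(a, b, c), path, row.names = FALSE)
  invisible(path)
}
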