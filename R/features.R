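#' @include spectral.R montage.R
NULL

#' Normalise topomap weights
#'
#' ICA topomap weights have arbitrary scale and sign; all spatial features
#' are computed on weights scaled to unit sum of absolute values, with sign
#' preserved (the signed convention matters for the eye-difference feature).
#'
#' @param c an \linkS4class{ICComponent} (or a named numeric weight vector).
#' @return named numeric vector, \code{sum(abs(.)) == 1}.
#' @export
normalizeWeights <- function(c) {
  w <- if (is(c, "ICComponent")) topoWeights(c) else c
  s <- sum(abs(w))
  if (s == 0) stop("all-zero weight vector cannot be normalised")
  w / s
}

#' Temporal-moment features
#'
#' \code{kurtosisFeature} is the fourth standardised moment (Pearson,
#' non-excess, population moments) of the source time series, computed per
#' epoch and averaged over epochs; a Gaussian signal gives ~3, a pure
#' sinusoid exactly 1.5. Zero-variance epochs are skipped with a warning.
#' Set \code{excess = TRUE} to subtract 3.
#'
#' \code{maxEpochVariance} is the ratio between the maximum and the mean of
#' the per-epoch signal variances after discarding the top
#' \code{ceiling(0.01 n)} variances for robustness; it is large for sparse
#' high-amplitude events such as blinks.
#'
#' @param c an \linkS4class{ICComponent}.
#' @param excess subtract 3 from the kurtosis? Default FALSE.
#' @return a single number.
#' @export
kurtosisFeature <- function(c, excess = FALSE) {
  x <- epochView(c)
  if (ncol(x) < 4L) stop("kurtosis needs >= 4 samples per epoch")
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  ok <- v > 0
  if (!any(ok)) stop("all epochs have zero variance")
  if (!all(ok))
    warning(sum(!ok), " zero-variance epoch(s) skipped", call. = FALSE)
  k <- rowMeans(xc[ok, , drop = FALSE]^4) / v[ok]^2
  mean(k) - if (excess) 3 else 0
}

#' @rdname kurtosisFeature
#' @export
maxEpochVariance <- function(c) {
  x <- epochView(c)
  n <- nrow(x)
  if (n < 2L) stop("maxEpochVariance needs >= 2 epochs")
  v <- apply(x, 1L, stats::var)
  drop <- ceiling(0.01 * n)
  keep <- sort(v)[seq_len(n - drop)]
  if (length(keep) < 2L) stop("fewer than 2 epochs remain after trimming")
  max(keep) / mean(keep)
}

#' Topographic contrast features (SAD, SVD, SED)
#'
#' Computed on normalised weights (\code{\link{normalizeWeights}}):
#' \describe{
#'   \item{SAD}{spatial average difference — mean absolute weight over the
#'     frontal set minus mean absolute weight over the posterior set; large
#'     for vertical eye movements and blinks.}
#'   \item{SVD}{spatial variance difference — variance of absolute weights,
#'     frontal minus posterior.}
#'   \item{SED}{spatial eye difference — with the default
#'     \code{sedConvention = "absdiff_of_means"}, the absolute value of the
#'     mean signed weight over the left-eye set minus the absolute value of
#'     the mean over the right-eye set. The alternative
#'     \code{"diff_of_means"} returns |mean(left) - mean(right)|, which is
#'     large for the antisymmetric dipolar topography of horizontal
#'     saccades even when the two sides have equal magnitude.}
#' }
#' Sets are intersected with the montage; members absent from the montage
#' are dropped with a warning, an empty intersection is an error.
#'
#' @param c an \linkS4class{ICComponent}.
#' @param sets named list of \linkS4class{ChannelSet}s with entries
#'   frontal, posterior, leftEye, rightEye; default \code{\link{channelSets}}.
#' @param sedConvention "absdiff_of_means" (default) or "diff_of_means".
#' @return named numeric vector (SAD, SVD, SED).
#' @export
spatialFeatures <- function(c, sets = channelSets(),
                            sedConvention = c("absdiff_of_means",
                                              "diff_of_means")) {
  sedConvention <- match.arg(sedConvention)
  w <- normalizeWeights(c)
  mont <- names(w)
  fr <- abs(w[.applySet(sets$frontal, mont)])
  po <- abs(w[.applySet(sets$posterior, mont)])
  le <- w[.applySet(sets$leftEye, mont)]
  ri <- w[.applySet(sets$rightEye, mont)]
  sed <- if (sedConvention == "absdiff_of_means")
    abs(mean(le)) - abs(mean(ri))
  else
    abs(mean(le) - mean(ri))
  c(SAD = mean(fr) - mean(po),
    SVD = stats::var(fr) - stats::var(po),
    SED = sed)
}

#' Band-ratio spectral features
#'
#' \code{mif} (myogenic identification feature) is the relative spectral
#' strength in the 20-100 Hz band: integrated Welch PSD over
#' [20, min(100, Nyquist)] divided by the integrated PSD over
#' (0, Nyquist]; in [0, 1], high for muscle components.
#'
#' \code{amalb} is the ratio between average spectral amplitude (square
#' root of the Welch PSD) inside the 6-12 Hz alpha band and the summed
#' amplitude at all other estimated frequencies up to Nyquist. The band is
#' widened down to 6 Hz because the alpha peak sits lower in children.
#'
#' @param c an \linkS4class{ICComponent}.
#' @return a single number.
#' @export
mif <- function(c) {
  fs <- samplingRate(c)
  if (fs <= 40) stop("mif needs sampling rate > 40 Hz")
  p <- welchPSD(c)
  num <- p$freq >= 20 & p$freq <= min(100, fs / 2)
  den <- p$freq > 0
  sum(p$psd[num]) / sum(p$psd[den])
}

#' @rdname mif
#' @export
amalb <- function(c) {
  fs <- samplingRate(c)
  p <- welchPSD(c)
  if (!any(p$freq >= 6 & p$freq <= 12))
    stop("the 6-12 Hz band is not resolvable at this sampling rate")
  amp <- sqrt(p$psd)
  inBand <- p$freq >= 6 & p$freq <= 12
  if (!any(!inBand)) stop("empty denominator band")
  sum(amp[inBand]) / sum(amp[!inBand])
}

#' Default signal-pattern template bank
#'
#' Unit-amplitude stereotypes correlated against each epoch:
#' \code{blink} is a smooth centred positive hump (Gaussian, sd = 10\% of
#' the epoch length); \code{saccade} is a smoothed step (logistic rise at
#' mid-epoch, rise time ~5\% of the epoch). Templates are z-scored before
#' correlation, so only their shape matters.
#'
#' @param nSamples epoch length in samples.
#' @return named list of numeric vectors of length \code{nSamples}.
#' @export
patternTemplates <- function(nSamples) {
  t <- seq_len(nSamples)
  mid <- (nSamples + 1) / 2
  list(
    blink = exp(-0.5 * ((t - mid) / (0.10 * nSamples))^2),
    saccade = stats::plogis((t - mid) / (0.05 * nSamples))
  )
}

#' Correlations with stereotyped signal patterns
#'
#' For each template, each epoch is correlated (Pearson) with the template
#' resampled to the epoch length; the feature is the maximum absolute
#' correlation over epochs, signed by the correlation at the maximising
#' epoch. Constant epochs (undefined correlation) are skipped.
#'
#' @param c an \linkS4class{ICComponent}.
#' @param templates named list of template vectors; default
#'   \code{\link{patternTemplates}} at the component's epoch length.
#' @return named numeric vector, one value per template, in [-1, 1].
#' @export
patternCorrelations <- function(c, templates = NULL) {
  x <- epochView(c)
  n <- ncol(x)
  if (is.null(templates)) templates <- patternTemplates(n)
  sds <- apply(x, 1L, stats::sd)
  ok <- which(sds > 0)
  if (!length(ok)) stop("all epochs constant; correlations undefined")
  vapply(templates, function(tp) {
    if (length(tp) != n)
      tp <- stats::approx(seq(0, 1, length.out = length(tp)), tp,
                          seq(0, 1, length.out = n))$y
    tp <- (tp - mean(tp)) / stats::sd(tp)
    r <- as.numeric(stats::cor(t(x[ok, , drop = FALSE]), tp))
    r[which.max(abs(r))]
  }, numeric(1))
}

## Electrode-set topography contrast on normalised absolute weights:
## sum inside the set minus sum outside it.
.setContrast <- function(c, set) {
  w <- abs(normalizeWeights(c))
  keep <- .applySet(set, names(w))
  sum(w[keep]) - sum(w[!names(w) %in% keep])
}

#' Mu and alpha topography features
#'
#' \code{muTopography} (MT) is the sum of normalised absolute weights over
#' the fronto-central mu electrode set minus the sum over all remaining
#' channels; \code{alphaTopography} (AT) is the same contrast for the
#' centro-parieto-occipital alpha set (see \code{\link{channelSets}}; the
#' central channels C3/Cz/C4 belong to both sets). MT is high for mu-rhythm
#' components, AT for alpha-rhythm components.
#'
#' @param c an \linkS4class{ICComponent}.
#' @param set override the electrode set (a \linkS4class{ChannelSet}).
#' @return a single number in [-1, 1].
#' @export
muTopography <- function(c, set = channelSets()$mu) .setContrast(c, set)

#' @rdname muTopography
#' @export
alphaTopography <- function(c, set = channelSets()$alpha) .setContrast(c, set)

#' Names of the per-component features
#'
#' @return character vector of the feature columns produced by
#'   \code{\link{extractFeatures}}.
#' @export
featureNames <- function() {
  c("kurtosis", "max_epoch_variance", "SAD", "SVD", "SED", "MIF",
    "pattern_corr_blink", "pattern_corr_saccade", "MT", "AT", "AMALB")
}

#' Extract the full feature vector for every component
#'
#' Computes, per component: temporal moments (kurtosis,
#' max_epoch_variance), topographic contrasts (SAD, SVD, SED, MT, AT),
#' band-ratio spectra (MIF, AMALB) and template correlations
#' (pattern_corr_blink, pattern_corr_saccade). A feature whose
#' preconditions fail (e.g. max_epoch_variance on a single-epoch
#' recording) is recorded as NA and the failure logged in the
#' \code{"errors"} attribute; such components are flagged in the
#' \code{flagged} column.
#'
#' @param ds an \linkS4class{ICDataset} (or a single
#'   \linkS4class{ICComponent}).
#' @param sets electrode sets, default \code{\link{channelSets}}.
#' @param sedConvention see \code{\link{spatialFeatures}}.
#' @return data.frame: component_id, one column per
#'   \code{\link{featureNames}}, logical \code{flagged}; attribute
#'   \code{"errors"} holds per-component error messages.
#' @export
extractFeatures <- function(ds, sets = channelSets(),
                            sedConvention = "absdiff_of_means") {
  if (is(ds, "ICComponent")) ds <- ICDataset(list(ds))
  stopifnot(is(ds, "ICDataset"))
  errors <- list()
  rows <- lapply(components(ds), function(c) {
    out <- stats::setNames(rep(NA_real_, length(featureNames())),
                           featureNames())
    grab <- function(name, expr) {
      val <- tryCatch(expr, error = function(e) {
        errors[[c@componentId]] <<- c(errors[[c@componentId]],
                                      paste0(name, ": ", conditionMessage(e)))
        NA_real_
      })
      out[name] <<- as.numeric(val[1L])
      if (name == "SAD" && length(val) == 3L) out[c("SVD", "SED")] <<- val[2:3]
    }
    grab("kurtosis", suppressWarnings(kurtosisFeature(c)))
    grab("max_epoch_variance", maxEpochVariance(c))
    grab("SAD", suppressWarnings(
      spatialFeatures(c, sets, sedConvention)))
    grab("MIF", mif(c))
    pc <- tryCatch(patternCorrelations(c), error = function(e) {
      errors[[c@componentId]] <<- c(errors[[c@componentId]],
                                    paste0("pattern: ", conditionMessage(e)))
      c(blink = NA_real_, saccade = NA_real_)
    })
    out["pattern_corr_blink"] <- pc[["blink"]]
    out["pattern_corr_saccade"] <- pc[["saccade"]]
    grab("MT", suppressWarnings(muTopography(c, sets$mu)))
    grab("AT", suppressWarnings(alphaTopography(c, sets$alpha)))
    grab("AMALB", amalb(c))
    out
  })
  ft <- as.data.frame(do.call(rbind, rows))
  ft <- cbind(data.frame(component_id = componentIds(ds),
                         stringsAsFactors = FALSE), ft)
  ft$flagged <- apply(is.na(ft[featureNames()]), 1L, any)
  rownames(ft) <- NULL
  attr(ft, "errors") <- errors
  ft
}

#' Write a feature table as delimited text
#'
#' @param ft feature data.frame from \code{\link{extractFeatures}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeFeatureTable <- function(ft, path) {
  utils::write.csv(ft, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(component_id = "character"))
}
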