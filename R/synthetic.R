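#' @include ic-model.R aggregation.R montage.R
NULL

.SYNTH_CLASSES <- c("brain", "alpha", "mu", "eyes_blink", "eyes_horizontal",
                    "muscle", "heart", "channel_noise")

#' Configuration for the synthetic IC generator
#'
#' Defaults describe the emulated recording setup: the 31-channel 10-10
#' montage, 250 Hz sampling, 100 one-second epochs per component, and 200
#' components per class. Per-class signal parameters (band edges, event
#' rates, amplitudes relative to a unit-variance 1/f background) live in
#' \code{params} and are documented in the package vignette.
#'
#' @param montage channel labels; default \code{\link{defaultMontage}}.
#' @param samplingRate Hz, must exceed 40.
#' @param nEpochs,nSamples epoch grid per component.
#' @param counts named integer vector of per-class component counts over
#'   \code{brain, alpha, mu, eyes_blink, eyes_horizontal, muscle, heart,
#'   channel_noise}.
#' @param mixedFraction fraction of components built as convex mixtures of
#'   two class recipes (both ground-truth labels kept); default 0.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return a list of class \code{"GeneratorConfig"}.
#' @export
generatorConfig <- function(montage = defaultMontage(), samplingRate = 250,
                            nEpochs = 100, nSamples = 250,
                            counts = NULL, mixedFraction = 0, seed = 1) {
  if (is.null(counts))
    counts <- stats::setNames(rep(200L, length(.SYNTH_CLASSES)),
                              .SYNTH_CLASSES)
  stopifnot(samplingRate > 40, nEpochs >= 1, nSamples >= 2,
            all(counts >= 0), mixedFraction >= 0, mixedFraction <= 1)
  bad <- setdiff(names(counts), .SYNTH_CLASSES)
  if (length(bad)) stop("unknown class(es) in counts: ",
                        paste(bad, collapse = ", "))
  structure(list(montage = canonicalChannels(montage),
                 samplingRate = samplingRate, nEpochs = nEpochs,
                 nSamples = nSamples, counts = counts,
                 mixedFraction = mixedFraction, seed = as.integer(seed)),
            class = "GeneratorConfig")
}

#' Expert profile for the annotation simulator
#'
#' Two observed annotator styles are modelled: a \code{purist} reports only
#' the dominant activity of a component (and misses it entirely, falling
#' back to Uncertain, with probability 1 - sensitivity); a \code{splitter}
#' reports every activity truly present and adds spurious labels at the
#' false-label rate.
#'
#' @param expertId identifier string.
#' @param style "purist" or "splitter".
#' @param sensitivity probability of reporting a true label, in [0, 1].
#' @param falseRate per-class probability of adding a spurious label
#'   (splitters only), in [0, 1].
#' @return a list of class \code{"ExpertProfile"}.
#' @export
expertProfile <- function(expertId, style = c("purist", "splitter"),
                          sensitivity = 0.9, falseRate = 0.1) {
  style <- match.arg(style)
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            falseRate >= 0, falseRate <= 1)
  structure(list(expertId = as.character(expertId), style = style,
                 sensitivity = sensitivity, falseRate = falseRate),
            class = "ExpertProfile")
}

## --- signal primitives (all return unit-scale vectors of length n) -----

.pinkNoise <- function(n, fs) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(1e-3, seq_len(n - 1)) * fs / n  # avoid DC blowup
  f <- pmin(f, fs - f)                   # fold at Nyquist
  X <- X / sqrt(pmax(f, 0.5))
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  (y - mean(y)) / stats::sd(y)
}

.bandNoise <- function(n, fs, lo, hi) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- seq(0, n - 1) * fs / n
  f <- pmin(f, fs - f)
  X[f < lo | f > hi] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  (y - mean(y)) / stats::sd(y)
}

.oscillation <- function(n, fs, freq, harmonic = 0, modDepth = 0.5) {
  t <- seq_len(n) / fs
  ph <- stats::runif(1, 0, 2 * pi)
  x <- sin(2 * pi * freq * t + ph)
  if (harmonic > 0)
    x <- x + harmonic * sin(2 * pi * 2 * freq * t + 2 * ph + pi / 4)
  ## slow random amplitude modulation (waxing/waning)
  env <- 1 + modDepth * sin(2 * pi * stats::runif(1, 0.05, 0.3) * t +
                            stats::runif(1, 0, 2 * pi))
  x * env / stats::sd(x * env)
}

## sparse events: returns length-n vector with `shape` stamped at Poisson
## event times (rate per second)
.eventTrain <- function(n, fs, rate, shape) {
  y <- numeric(n)
  nEv <- stats::rpois(1, rate * n / fs)
  if (nEv > 0) {
    centers <- sort(sample.int(n, min(nEv, n)))
    half <- (length(shape) - 1) %/% 2
    for (cc in centers) {
      i <- (cc - half):(cc - half + length(shape) - 1)
      ok <- i >= 1 & i <= n
      y[i[ok]] <- y[i[ok]] + shape[ok]
    }
  }
  y
}

.blinkShape <- function(fs) {
  t <- seq(-0.15, 0.15, by = 1 / fs)
  exp(-0.5 * (t / 0.05)^2)
}

.qrsShape <- function(fs) {
  t <- seq(-0.05, 0.05, by = 1 / fs)
  ## biphasic spike-and-wave
  exp(-0.5 * (t / 0.01)^2) - 0.4 * exp(-0.5 * ((t - 0.025) / 0.015)^2)
}

## --- topography primitives ---------------------------------------------

.gaussTopo <- function(montage, cx, cy, spread) {
  xy <- .CHANNEL_XY[montage, , drop = FALSE]
  w <- exp(-((xy[, "x"] - cx)^2 + (xy[, "y"] - cy)^2) / (2 * spread^2))
  stats::setNames(w, montage)
}

.unitScale <- function(w) w / sqrt(sum(w^2))

## --- class recipes -------------------------------------------------------

.makeTopo <- function(class, montage) {
  switch(class,
    brain = {
      ## broad dipole at a random scalp location
      ang <- stats::runif(1, 0, 2 * pi)
      cx <- 0.4 * cos(ang); cy <- 0.4 * sin(ang)
      w <- .gaussTopo(montage, cx, cy, 0.8) -
        0.6 * .gaussTopo(montage, -cx, -cy, 0.9)
      w
    },
    alpha = .gaussTopo(montage, stats::runif(1, -0.15, 0.15), -0.9, 0.45),
    mu = {
      side <- sample(c(-0.58, 0.58), 1)
      .gaussTopo(montage, side, stats::runif(1, -0.1, 0.1), 0.38)
    },
    eyes_blink = .gaussTopo(montage, stats::runif(1, -0.1, 0.1), 1.0, 0.35),
    eyes_horizontal =
      .gaussTopo(montage, -0.81, 0.59, 0.3) -
        .gaussTopo(montage, 0.81, 0.59, 0.3),
    muscle = {
      edge <- sample(c("FT7", "FT8", "T7", "T8", "TP7", "TP8"), 1)
      if (!edge %in% montage) edge <- montage[which.max(
        abs(.CHANNEL_XY[montage, "x"]))]
      xy <- .CHANNEL_XY[edge, ]
      .gaussTopo(montage, xy["x"], xy["y"], 0.25)
    },
    heart = {
      ## near-uniform gradient across the cap: low spatial contrast
      xy <- .CHANNEL_XY[montage, , drop = FALSE]
      ang <- stats::runif(1, 0, 2 * pi)
      w <- 1 + 0.3 * (cos(ang) * xy[, "x"] + sin(ang) * xy[, "y"])
      stats::setNames(w, montage)
    },
    channel_noise = {
      w <- stats::setNames(abs(stats::rnorm(length(montage), 0, 0.01)),
                           montage)
      w[sample(seq_along(montage), 1)] <- 1
      ## cap the off-channel mass so the dominant channel keeps >= 80%
      k <- which.max(w)
      rest <- sum(abs(w[-k]))
      if (rest > 0.25 * w[k]) w[-k] <- w[-k] * 0.2 * w[k] / rest
      w
    },
    stop("unknown synthetic class: ", class))
}

.makeSignal <- function(class, n, fs) {
  ## per-component amplitude draws keep class feature distributions
  ## overlapping (weak exemplars exist for every class), as in real ICs
  x <- switch(class,
    brain = .pinkNoise(n, fs) +
      stats::runif(1, 0.3, 1.0) * .oscillation(n, fs,
                                               stats::runif(1, 4, 8)),
    alpha = stats::runif(1, 0.7, 1.3) * .pinkNoise(n, fs) +
      stats::runif(1, 0.4, 3.0) *
        .oscillation(n, fs, stats::runif(1, 8, 12), modDepth = 0.7),
    mu = stats::runif(1, 0.7, 1.3) * .pinkNoise(n, fs) +
      stats::runif(1, 0.4, 3.0) *
        .oscillation(n, fs, stats::runif(1, 9, 11), harmonic = 0.4,
                     modDepth = 0.7),
    eyes_blink = stats::runif(1, 0.5, 1.1) * .pinkNoise(n, fs) +
      stats::runif(1, 1.2, 9) *
        .eventTrain(n, fs, stats::runif(1, 0.2, 0.5), .blinkShape(fs)),
    eyes_horizontal = {
      ## step-like gaze shifts: integrate a sparse impulse train
      steps <- .eventTrain(n, fs, 0.4, c(rep(0, 9), 1))
      lvl <- cumsum(steps * sample(c(-1, 1), n, replace = TRUE))
      sm <- stats::filter(lvl, rep(1 / 15, 15), sides = 2)
      sm[is.na(sm)] <- 0
      stats::runif(1, 0.5, 1.1) * .pinkNoise(n, fs) +
        stats::runif(1, 1, 6) * as.numeric(sm) / max(stats::sd(sm), 0.1)
    },
    muscle = {
      base <- .bandNoise(n, fs, 20, min(100, fs / 2 - 1))
      burst <- 1 + 2 * (stats::runif(ceiling(n / fs)) > 0.5)
      env <- rep(burst, each = fs)[seq_len(n)]
      stats::runif(1, 0.3, 0.9) * .pinkNoise(n, fs) +
        stats::runif(1, 0.35, 2.0) * base * env
    },
    heart = stats::runif(1, 0.6, 1.1) * .pinkNoise(n, fs) +
      stats::runif(1, 0.8, 5) * .heartTrain(n, fs, stats::runif(1, 1.0, 1.5)),
    channel_noise = stats::rnorm(n),
    stop("unknown synthetic class: ", class))
  ## broadband sensor/residual-unmixing noise on every source
  x + stats::runif(1, 0.15, 0.4) * stats::rnorm(n)
}

## strictly periodic spike train (QRS-like), continuous phase across epochs
.heartTrain <- function(n, fs, rate) {
  period <- round(fs / rate)
  centers <- seq(sample.int(period, 1), n, by = period)
  y <- numeric(n)
  shape <- .qrsShape(fs)
  half <- (length(shape) - 1) %/% 2
  for (cc in centers) {
    i <- (cc - half):(cc - half + length(shape) - 1)
    ok <- i >= 1 & i <= n
    y[i[ok]] <- y[i[ok]] + shape[ok]
  }
  y
}

.trueLabelsFor <- function(class) {
  switch(class,
    brain = "Brain",
    alpha = c("Alpha", "Brain"),
    mu = c("Mu", "Brain"),
    eyes_blink = "Eyes",
    eyes_horizontal = "Eyes",
    muscle = "Muscle",
    heart = "Heart",
    channel_noise = "Channel noise")
}

#' Generate one synthetic independent component
#'
#' Builds a component with the class-specific topography and source signal
#' recipe (occipital 8-12 Hz for alpha, central arch wave with a 2f
#' harmonic for mu, frontal-polar sparse humps for blinks, antisymmetric
#' periocular steps for horizontal eye movements, edge-channel broadband
#' >20 Hz bursts for muscle, low-contrast topography with periodic
#' QRS-like spikes for heart, single-channel white noise for channel
#' noise, and a broad dipole over 1/f noise for generic brain activity).
#' Deterministic given \code{seed}.
#'
#' @param class one of \code{brain, alpha, mu, eyes_blink,
#'   eyes_horizontal, muscle, heart, channel_noise}.
#' @param cfg a \code{\link{generatorConfig}}.
#' @param seed integer seed for this component.
#' @param id,subject identifier strings.
#' @return list with \code{component} (an \linkS4class{ICComponent}) and
#'   \code{labels} (ground-truth label set; alpha/mu components also carry
#'   Brain).
#' @export
generateComponent <- function(class, cfg = generatorConfig(), seed = 1,
                              id = paste0(class, "_", seed),
                              subject = "sim") {
  if (!class %in% .SYNTH_CLASSES)
    stop("unknown synthetic class: ", class)
  set.seed(seed)
  n <- cfg$nEpochs * cfg$nSamples
  w <- .unitScale(.makeTopo(class, cfg$montage))
  if (class != "channel_noise") {
    ## imperfect unmixing: spatial leakage noise on the topomap
    w <- .unitScale(w + stats::rnorm(length(w), 0,
                                     stats::runif(1, 0.05, 0.18) *
                                       max(abs(w))))
  }
  sig <- .makeSignal(class, n, cfg$samplingRate)
  m <- matrix(sig, nrow = cfg$nEpochs, ncol = cfg$nSamples, byrow = TRUE)
  list(component = ICComponent(id, subject, cfg$montage, as.numeric(w),
                               m, cfg$samplingRate),
       labels = .trueLabelsFor(class))
}

#' Generate a synthetic IC dataset with ground-truth labels
#'
#' Honours the per-class counts in \code{cfg$counts}; optionally a fraction
#' of components are convex mixtures of two class recipes (signal and
#' topography mixed, both ground-truth label sets kept), emulating the
#' mixed-nature components that motivate the probabilistic vote.
#' Deterministic given \code{cfg$seed}.
#'
#' @param cfg a \code{\link{generatorConfig}}.
#' @return list with \code{dataset} (an \linkS4class{ICDataset}),
#'   \code{labels} (logical component x class matrix over the aggregated
#'   target classes) and \code{labelSets} (per-component character label
#'   sets, dominant class first).
#' @export
generateDataset <- function(cfg = generatorConfig()) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  classes <- rep(names(cfg$counts), times = cfg$counts)
  comps <- vector("list", length(classes))
  labelSets <- vector("list", length(classes))
  set.seed(cfg$seed)
  mixed <- if (length(classes))
    stats::runif(length(classes)) < cfg$mixedFraction else logical()
  partners <- vapply(seq_along(classes), function(i)
    sample(setdiff(.SYNTH_CLASSES, classes[i]), 1), character(1))
  lambdas <- stats::runif(length(classes), 0.35, 0.65)
  for (i in seq_along(classes)) {
    seedI <- cfg$seed + i
    g <- generateComponent(classes[i], cfg, seed = seedI,
                           id = sprintf("%s_%04d", classes[i], i))
    if (mixed[i]) {
      g2 <- generateComponent(partners[i], cfg, seed = seedI + 500000L,
                              id = "tmp")
      lam <- lambdas[i]
      w <- .unitScale(lam * topoWeights(g$component) +
                        (1 - lam) * topoWeights(g2$component))
      sig <- lam * epochView(g$component) + (1 - lam) * epochView(g2$component)
      g$component <- ICComponent(sprintf("mixed_%s_%s_%04d", classes[i],
                                         partners[i], i),
                                 "sim", cfg$montage, as.numeric(w), sig,
                                 cfg$samplingRate)
      g$labels <- unique(c(g$labels, .trueLabelsFor(partners[i])))
    }
    comps[[i]] <- g$component
    labelSets[[i]] <- g$labels
  }
  ds <- ICDataset(comps, list(origin = "synthetic",
                              montage = "10-10 31-channel"))
  cls <- setdiff(aggregationClasses(), c("Other", "Uncertain"))
  lab <- t(vapply(labelSets, function(l) cls %in% l,
                  logical(length(cls))))
  dimnames(lab) <- list(componentIds(ds), cls)
  names(labelSets) <- componentIds(ds)
  list(dataset = ds, labels = lab, labelSets = labelSets)
}

#' Simulate multi-expert annotations of known components
#'
#' Given per-component ground-truth label sets (dominant class first) and a
#' list of \code{\link{expertProfile}}s, produces an annotation table with
#' controlled disagreement: purists report the dominant label only and
#' fall back to Uncertain when they miss it (probability 1 - sensitivity);
#' splitters report each true label with probability \code{sensitivity}
#' and add each absent class with probability \code{falseRate}.
#' Deterministic given \code{seed}.
#'
#' @param labelSets named list of character label sets (as returned by
#'   \code{\link{generateDataset}}).
#' @param experts list of \code{\link{expertProfile}}s (>= 1).
#' @param seed integer seed.
#' @return annotation data.frame (component_id, expert_id, labels
#'   list-column, comment).
#' @export
generateAnnotations <- function(labelSets, experts, seed = 1) {
  stopifnot(length(experts) >= 1,
            all(vapply(experts, inherits, logical(1), "ExpertProfile")))
  set.seed(seed)
  spurious <- setdiff(aggregationClasses(), c("Other", "Uncertain"))
  rows <- list()
  for (e in experts) {
    for (ci in seq_along(labelSets)) {
      truth <- labelSets[[ci]]
      if (e$style == "purist") {
        lab <- if (stats::runif(1) <= e$sensitivity) truth[1L] else "Uncertain"
      } else {
        keep <- truth[stats::runif(length(truth)) <= e$sensitivity]
        extra <- setdiff(spurious, truth)
        extra <- extra[stats::runif(length(extra)) < e$falseRate]
        lab <- unique(c(keep, extra))
        if (!length(lab)) lab <- "Uncertain"
      }
      rows[[length(rows) + 1L]] <- list(component_id = names(labelSets)[ci],
                                        expert_id = e$expertId, labels = lab)
    }
  }
  ann <- data.frame(
    component_id = vapply(rows, `[[`, character(1), "component_id"),
    expert_id = vapply(rows, `[[`, character(1), "expert_id"),
    stringsAsFactors = FALSE)
  ann$labels <- lapply(rows, `[[`, "labels")
  ann$comment <- ""
  ann
}
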