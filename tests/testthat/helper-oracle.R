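# Independent hand-rule oracles and small fixture builders. These
# deliberately re-derive results with plain loops so they share no code
# path with the package implementations they check.

# Annotation data.frame builder: rows = list of list(c, e, labels)
makeAnn <- function(rows) {
  ann <- data.frame(
    component_id = vapply(rows, function(r) r[[1L]], character(1)),
    expert_id = vapply(rows, function(r) r[[2L]], character(1)),
    stringsAsFactors = FALSE)
  ann$labels <- lapply(rows, function(r) r[[3L]])
  ann
}

# Literal per-component voting oracle over a fixed class set (no merging).
oracleVote <- function(ann, classes, strategy, threshold = 0.33) {
  comps <- unique(ann$component_id)
  experts <- unique(ann$expert_id)
  prob <- matrix(NA_real_, length(comps), length(classes),
                 dimnames = list(comps, classes))
  for (comp in comps) {
    sub <- ann[ann$component_id == comp, ]
    for (cls in classes) {
      contribs <- c()
      for (i in seq_len(nrow(sub))) {
        labs <- sub$labels[[i]]
        v <- as.numeric(cls %in% labs)
        if (strategy == "probabilistic") v <- v / length(labs)
        contribs <- c(contribs, v)
      }
      prob[comp, cls] <- mean(contribs)
    }
  }
  list(prob = prob, target = round(prob, 12) > threshold)
}

# Contingency-table Cohen's kappa oracle
oracleCohen <- function(a, b) {
  n <- length(a)
  n11 <- sum(a == 1 & b == 1); n00 <- sum(a == 0 & b == 0)
  n10 <- sum(a == 1 & b == 0); n01 <- sum(a == 0 & b == 1)
  p0 <- (n11 + n00) / n
  pA1 <- (n11 + n10) / n; pB1 <- (n11 + n01) / n
  pe <- pA1 * pB1 + (1 - pA1) * (1 - pB1)
  if (abs(1 - pe) < 1e-12) return(if (p0 == 1) 1 else 0)
  (p0 - pe) / (1 - pe)
}

# Random annotation table over a class set; every component is annotated
# by at least one expert and every cast annotation is non-empty.
randomAnnTable <- function(nComp, nExp, classes) {
  rows <- list()
  for (ci in seq_len(nComp)) {
    annotated <- FALSE
    for (ei in seq_len(nExp)) {
      if (runif(1) < 0.3 && !(ei == nExp && !annotated)) next
      annotated <- TRUE
      k <- sample(length(classes), 1)
      rows[[length(rows) + 1L]] <- list(paste0("c", ci), paste0("e", ei),
                                        sample(classes, k))
    }
  }
  makeAnn(rows)
}

# Tiny component builders
sineComponent <- function(freq, fs = 250, nEpochs = 1, nSamples = fs,
                          id = "sine") {
  t <- seq_len(nEpochs * nSamples) / fs
  sig <- matrix(sin(2 * pi * freq * t), nEpochs, nSamples, byrow = TRUE)
  ICComponent(id, "s", c("Cz", "Fp1", "Oz"), c(1, 0.5, 0.2), sig, fs)
}

noiseComponent <- function(fs = 250, nEpochs = 10, nSamples = fs,
                           id = "noise") {
  sig <- matrix(rnorm(nEpochs * nSamples), nEpochs, nSamples)
  ICComponent(id, "s", c("Cz", "Fp1", "Oz"), c(1, 0.5, 0.2), sig, fs)
}

randomDataset <- function(nComp = 3, nChan = 5, nEpochs = 4, nSamples = 50,
                          fs = 200) {
  chans <- defaultMontage()[seq_len(nChan)]
  comps <- lapply(seq_len(nComp), function(i)
    ICComponent(sprintf("ic%02d", i), sprintf("s%d", (i %% 2) + 1),
                chans, rnorm(nChan),
                matrix(rnorm(nEpochs * nSamples), nEpochs, nSamples), fs))
  ICDataset(comps, list(cohort = "unit-test"))
}
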