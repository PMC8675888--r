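# small separable/noisy fixtures reused across blocks
.toyFeatures <- function(n, sep = 10, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c(0, 1), each = n / 2)
    ft <- data.frame(component_id = sprintf("c%03d", seq_len(n)),
                     stringsAsFactors = FALSE)
    for (f in featureNames()) ft[[f]] <- rnorm(n)
    ft$MIF <- ft$MIF + sep * y
  })
  lab <- matrix(y == 1, ncol = 1, dimnames = list(ft$component_id, "Muscle"))
  list(ft = ft, lab = lab, y = y)
}

test_that("ROC-AUC agrees with an independent implementation", {
  withr::with_seed(2, {
    for (i in 1:5) {
      y <- rbinom(60, 1, 0.4)
      if (length(unique(y)) < 2) next
      s <- rnorm(60) + y
      ref <- as.numeric(suppressMessages(pROC::auc(y, s,
                                                   direction = "<")))
      expect_equal(rocAuc(s, y), ref, tolerance = 1e-12)
    }
  })
})

test_that("PR-AUC and F1 match hand-computed small cases", {
  # scores order the four items as 1,0,1,0 from the top
  y <- c(1, 0, 1, 0); s <- c(4, 3, 2, 1)
  # AP = 0.5 * 1 + 0.5 * 2/3
  expect_equal(prAuc(s, y), 0.5 + 0.5 * 2 / 3)
  expect_equal(prAuc(c(2, 1, 4, 3), c(1, 0, 1, 0)), 0.5 + 0.5 * 2 / 3)
  expect_equal(prAuc(s, c(1, 1, 0, 0)), 1)
  expect_equal(f1Score(c(1, 1, 0, 0), y), 2 * 0.5 * 0.5 / (0.5 + 0.5))
  expect_equal(f1Score(c(0, 0, 0, 0), y), 0)
})

test_that("ROC-AUC is invariant under monotone score transforms", {
  withr::with_seed(4, {
    y <- rbinom(80, 1, 0.5); s <- rnorm(80) + 0.8 * y
  })
  expect_equal(rocAuc(plogis(s), y), rocAuc(s, y))
  expect_equal(rocAuc(3 * s - 7, y), rocAuc(s, y))
})

test_that("perfectly separable features score 1.0 for every model", {
  # positives at +10, negatives at -10 on a single feature
  y <- rep(c(0, 1), each = 30)
  ft <- data.frame(component_id = sprintf("c%03d", 1:60),
                   stringsAsFactors = FALSE)
  for (f in featureNames()) ft[[f]] <- 0
  ft$MIF <- ifelse(y == 1, 10, -10)
  lab <- matrix(y == 1, ncol = 1, dimnames = list(ft$component_id, "Muscle"))
  rep <- repeatedSplitValidate(ft, lab, nRepeats = 5, seed = 2)
  s <- validationSummary(rep)
  expect_identical(nrow(s), 3L)
  expect_true(all(s$roc_auc_mean == 1))
  expect_true(all(s$pr_auc_mean == 1))
})

test_that("permuted labels give chance-level ROC-AUC", {
  toy <- .toyFeatures(80, sep = 0, seed = 5)  # labels independent of X
  rep <- repeatedSplitValidate(toy$ft, toy$lab, families = "logreg",
                               nRepeats = 50, seed = 6)
  m <- validationSummary(rep)$roc_auc_mean
  expect_lt(abs(m - 0.5), 0.1)
})

test_that("validation is reproducible bit-for-bit under a fixed seed", {
  toy <- .toyFeatures(40, sep = 2)
  r1 <- repeatedSplitValidate(toy$ft, toy$lab, nRepeats = 4, seed = 9)
  r2 <- repeatedSplitValidate(toy$ft, toy$lab, nRepeats = 4, seed = 9)
  expect_identical(validationMetrics(r1), validationMetrics(r2))
  expect_identical(validationCurves(r1), validationCurves(r2))
  r3 <- repeatedSplitValidate(toy$ft, toy$lab, nRepeats = 4, seed = 10)
  expect_false(identical(validationMetrics(r1), validationMetrics(r3)))
})

test_that("summary means equal recomputation from per-split rows", {
  toy <- .toyFeatures(50, sep = 1.5)
  rep <- repeatedSplitValidate(toy$ft, toy$lab, nRepeats = 6, seed = 3)
  m <- validationMetrics(rep)
  s <- validationSummary(rep)
  for (i in seq_len(nrow(s))) {
    sub <- m[m$class == s$class[i] & m$model == s$model[i], ]
    expect_identical(nrow(sub), 6L)
    expect_equal(mean(sub$roc_auc), s$roc_auc_mean[i])
    expect_equal(sd(sub$pr_auc), s$pr_auc_sd[i])
  }
})

test_that("model selection follows the balance rule with tie-breaks", {
  mkReport <- function(summ, posFrac) {
    new("ValidationReport",
        metrics = data.frame(class = summ$class, model = summ$model,
                             split = 1, roc_auc = summ$roc_auc_mean,
                             pr_auc = summ$pr_auc_mean, f1 = 0.5),
        summary = summ, curves = list(), selected = data.frame(),
        config = list(positiveFraction = posFrac, nRepeats = 1))
  }
  summ <- data.frame(
    class = "Brain", model = c("logreg", "xgb"),
    roc_auc_mean = c(0.93, 0.91), roc_auc_sd = 0,
    pr_auc_mean = c(0.80, 0.95), pr_auc_sd = 0,
    f1_mean = 0.5, f1_sd = 0, stringsAsFactors = FALSE)
  # balanced: ROC governs despite better PR elsewhere
  sel <- selectModel(mkReport(summ, c(Brain = 0.5)))
  expect_identical(sel$model, "logreg")
  expect_identical(sel$rule, "roc_auc")
  # unbalanced: PR governs
  summ2 <- summ; summ2$class <- "Eyes"
  summ2$roc_auc_mean <- c(0.95, 0.90); summ2$pr_auc_mean <- c(0.40, 0.55)
  sel2 <- selectModel(mkReport(summ2, c(Eyes = 0.1)))
  expect_identical(sel2$model, "xgb")
  expect_identical(sel2$rule, "pr_auc")
  # exact tie on both metrics: fixed family order logreg, xgb, svm
  summ3 <- summ; summ3$model <- c("svm", "xgb")
  summ3$roc_auc_mean <- 0.9; summ3$pr_auc_mean <- 0.9
  sel3 <- selectModel(mkReport(summ3, c(Brain = 0.5)))
  expect_identical(sel3$model, "xgb")
})

test_that("final fits recover separable training data and check schema", {
  toy <- .toyFeatures(40)
  for (fam in c("logreg", "xgb", "svm")) {
    mdl <- fitFinal(toy$ft, toy$y, "Muscle", fam)
    pred <- predictComponents(mdl, toy$ft)
    expect_identical(unname(pred$flag_Muscle), toy$y == 1)
  }
  mdl <- fitFinal(toy$ft, toy$y, "Muscle", "logreg")
  broken <- toy$ft[setdiff(names(toy$ft), "MIF")]
  expect_error(predictComponents(mdl, broken), "MIF")
  expect_error(fitFinal(toy$ft, rep(0, 40), "Muscle", "logreg"),
               "positives")
})

test_that("exported models reproduce predictions after import", {
  toy <- .toyFeatures(40, sep = 2)
  dir <- withr::local_tempdir()
  for (fam in c("logreg", "xgb", "svm")) {
    mdl <- fitFinal(toy$ft, toy$y, "Muscle", fam)
    path <- file.path(dir, paste0(fam, ".json"))
    exportModel(mdl, path)
    back <- importModel(path)
    expect_equal(predictComponents(back, toy$ft)$score_Muscle,
                 predictComponents(mdl, toy$ft)$score_Muscle,
                 tolerance = 1e-12)
  }
  expect_error(importModel(file.path(dir, "nope.json")), "missing")
})

test_that("raising the decision threshold never adds a flag", {
  toy <- .toyFeatures(60, sep = 1, seed = 8)
  for (fam in c("logreg", "svm")) {
    mdl <- fitFinal(toy$ft, toy$y, "Muscle", fam)
    prev <- rep(TRUE, 60)
    for (thr in c(0.1, 0.3, 0.5, 0.7, 0.9, 1.0)) {
      fl <- predictComponents(mdl, toy$ft, threshold = thr)$flag_Muscle
      expect_true(all(fl <= prev))
      prev <- fl
    }
    expect_false(any(predictComponents(mdl, toy$ft, 1.0)$flag_Muscle))
  }
})

test_that("classes without enough positives are skipped with a warning", {
  toy <- .toyFeatures(40)
  lab <- cbind(toy$lab, Rare = c(TRUE, rep(FALSE, 39)))
  expect_warning(
    rep <- repeatedSplitValidate(toy$ft, lab, nRepeats = 2, seed = 1),
    "Rare")
  expect_false("Rare" %in% validationSummary(rep)$class)
})

test_that("validation reports serialise to a directory of tables", {
  toy <- .toyFeatures(40, sep = 2)
  rep <- repeatedSplitValidate(toy$ft, toy$lab, nRepeats = 3, seed = 2)
  dir <- withr::local_tempdir()
  writeValidationReport(rep, dir)
  expect_true(file.exists(file.path(dir, "metrics.csv")))
  summ <- read.csv(file.path(dir, "summary.csv"))
  expect_identical(nrow(summ), 3L)
  curves <- list.files(dir, pattern = "^curve_")
  expect_length(curves, 3L)
  cfg <- jsonlite::read_json(file.path(dir, "config.json"))
  expect_identical(cfg$nRepeats, 3L)
})
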