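test_that("weight normalisation scales to unit absolute mass", {
  ic <- ICComponent("a", "s", c("Cz", "Pz"), c(2, -2),
                    matrix(rnorm(100), 1), 250)
  expect_equal(unname(normalizeWeights(ic)), c(0.5, -0.5))
  ic0 <- ICComponent("b", "s", c("Cz", "Pz"), c(0, 0),
                     matrix(rnorm(100), 1), 250)
  expect_error(normalizeWeights(ic0), "zero")
})

test_that("kurtosis matches closed forms for sinusoid and Gaussian", {
  # full integer number of cycles -> population moments are exact
  expect_equal(kurtosisFeature(sineComponent(10)), 1.5, tolerance = 1e-10)
  withr::with_seed(5, {
    g <- ICComponent("g", "s", "Cz", 1, matrix(rnorm(1e5), 100, 1000), 250)
  })
  expect_lt(abs(kurtosisFeature(g) - 3), 0.1)
  expect_equal(kurtosisFeature(g, excess = TRUE), kurtosisFeature(g) - 3)
})

test_that("zero-variance epochs are skipped, all-constant errors", {
  sig <- rbind(rep(1, 100), sin(2 * pi * 10 * seq_len(100) / 250))
  ic <- ICComponent("a", "s", "Cz", 1, sig, 250)
  expect_warning(k <- kurtosisFeature(ic), "skipped")
  expect_equal(k, 1.5, tolerance = 1e-2)
  flat <- ICComponent("b", "s", "Cz", 1, matrix(1, 3, 100), 250)
  expect_error(suppressWarnings(kurtosisFeature(flat)), "zero variance")
})

test_that("max epoch variance trims the top percent before the ratio", {
  base <- sin(2 * pi * 5 * seq_len(250) / 250)  # fixed epoch shape
  mk <- function(scales) {
    ICComponent("a", "s", "Cz", 1, t(vapply(scales, function(s) s * base,
                                            numeric(250))), 250)
  }
  # 100 epochs: the single large epoch is exactly the trimmed 1%
  expect_equal(maxEpochVariance(mk(c(rep(1, 99), 10))), 1)
  # 200 epochs, 3 outliers at sd 50: ceil(2) trimmed, one survives
  v <- var(base) * c(rep(1, 197), rep(2500, 3))
  keep <- sort(v)[1:198]
  expect_equal(maxEpochVariance(mk(c(rep(1, 197), rep(50, 3)))),
               max(keep) / mean(keep))
  expect_error(maxEpochVariance(mk(1)), "epochs")
})

test_that("spatial contrasts follow the stated conventions", {
  mont <- defaultMontage()
  w <- setNames(rep(0, 31), mont)
  w[c("Fp1", "Fpz", "Fp2", "F3", "Fz", "F4", "F7", "F8")] <- 1
  ic <- ICComponent("f", "s", mont, w, matrix(rnorm(100), 1), 250)
  sf <- spatialFeatures(ic)
  expect_equal(unname(sf["SAD"]), 1 / 8)  # frontal mean of normalised 1/8s
  expect_equal(unname(sf["SVD"]), 0)
  # symmetric equal-sign eye weights cancel under both conventions
  w2 <- setNames(rep(0.01, 31), mont)
  w2[c("Fp1", "F7")] <- 0.8; w2[c("Fp2", "F8")] <- 0.8
  ic2 <- ICComponent("e", "s", mont, w2, matrix(rnorm(100), 1), 250)
  expect_equal(unname(spatialFeatures(ic2)["SED"]), 0)
  # antisymmetric dipole: invisible to the literal convention, strong
  # under the signed-difference alternative
  w3 <- setNames(rep(0, 31), mont)
  w3[c("Fp1", "F7")] <- 0.8; w3[c("Fp2", "F8")] <- -0.8
  ic3 <- ICComponent("d", "s", mont, w3, matrix(rnorm(100), 1), 250)
  expect_equal(unname(spatialFeatures(ic3)["SED"]), 0)
  expect_equal(unname(spatialFeatures(ic3,
                                      sedConvention = "diff_of_means")["SED"]),
               0.5)
})

test_that("MIF isolates high-frequency spectral mass", {
  expect_gt(mif(sineComponent(50, nEpochs = 10)), 0.95)
  expect_lt(mif(sineComponent(5, nEpochs = 10)), 0.05)
  withr::with_seed(6, n <- noiseComponent(nEpochs = 60))
  expect_lt(abs(mif(n) - 0.64), 0.05)
  slow <- ICComponent("s", "s", "Cz", 1, matrix(rnorm(80), 1), 30)
  expect_error(mif(slow), "40")
})

test_that("AMALB contrasts the 6-12 Hz band against the rest", {
  expect_gt(amalb(sineComponent(10, nEpochs = 10)), 5)
  expect_lt(amalb(sineComponent(30, nEpochs = 10)), 0.2)
  withr::with_seed(7, n <- noiseComponent(nEpochs = 60))
  # flat amplitude spectrum: ~7 of 126 one-hertz bins lie in [6, 12]
  expect_gt(amalb(n), 6 / 119 / 2)
  expect_lt(amalb(n), 6 / 119 * 2)
})

test_that("integrated Welch PSD approximates the variance (Parseval)", {
  withr::with_seed(8, n <- noiseComponent(nEpochs = 80))
  p <- welchPSD(n)
  df <- p$freq[2] - p$freq[1]
  expect_lt(abs(sum(p$psd) * df / mean(apply(epochView(n), 1, var)) - 1),
            0.05)
})

test_that("pattern correlations recover planted templates", {
  tpl <- patternTemplates(250)
  sig <- rbind(tpl$blink, rnorm(250))
  ic <- ICComponent("a", "s", "Cz", 1, sig, 250)
  pc <- patternCorrelations(ic)
  expect_equal(unname(pc["blink"]), 1)
  icneg <- ICComponent("b", "s", "Cz", 1, -sig[1, , drop = FALSE], 250)
  expect_equal(unname(patternCorrelations(icneg)["blink"]), -1)
  withr::with_seed(9, {
    noise <- ICComponent("n", "s", "Cz", 1, matrix(rnorm(100 * 1000),
                                                   100, 1000), 250)
  })
  x <- epochView(noise)
  tplb <- patternTemplates(1000)$blink
  rs <- abs(as.numeric(cor(t(x), (tplb - mean(tplb)) / sd(tplb))))
  expect_gte(mean(rs < 0.2), 0.99)
})

test_that("mu/alpha topography contrasts match hand arithmetic", {
  mont <- defaultMontage()
  w <- setNames(rep(0, 31), mont); w["Cz"] <- 1
  ic <- ICComponent("a", "s", mont, w, matrix(rnorm(100), 1), 250)
  expect_equal(muTopography(ic), 1)
  expect_equal(alphaTopography(ic), 1)  # Cz is in both sets
  wu <- setNames(rep(1, 31), mont)
  icu <- ICComponent("b", "s", mont, wu, matrix(rnorm(100), 1), 250)
  expect_equal(muTopography(icu), -7 / 31)
  expect_equal(alphaTopography(icu), -7 / 31)
  wo <- setNames(rep(0, 31), mont); wo["Oz"] <- 1
  ico <- ICComponent("c", "s", mont, wo, matrix(rnorm(100), 1), 250)
  expect_equal(alphaTopography(ico), 1)
  expect_equal(muTopography(ico), -1)
  wf <- setNames(rep(0, 31), mont); wf["Fp1"] <- 1
  icf <- ICComponent("d", "s", mont, wf, matrix(rnorm(100), 1), 250)
  expect_equal(alphaTopography(icf), -1)
  expect_gt(muTopography(icf), 0)
})

test_that("set members missing from the montage are dropped with warning", {
  ic <- ICComponent("a", "s", c("Cz", "Pz"), c(1, 1),
                    matrix(rnorm(100), 1), 250)
  expect_warning(v <- muTopography(ic), "dropping")
  expect_equal(v, 0)  # Cz in, Pz out, equal mass
  icq <- ICComponent("b", "s", c("P9", "P10"), c(1, 1),
                     matrix(rnorm(100), 1), 250)
  expect_error(suppressWarnings(muTopography(icq)), "no members")
})

test_that("features are invariant to scaling and sign flips", {
  withr::with_seed(10, {
    cfg <- generatorConfig(counts = c(alpha = 1, muscle = 1), nEpochs = 20,
                           seed = 10)
    g <- generateDataset(cfg)
  })
  ds <- g$dataset
  ft <- extractFeatures(ds)
  scaled <- ICDataset(lapply(components(ds), function(c)
    ICComponent(c@componentId, c@subjectId, c@channels, 10 * c@weights,
                10 * c@signal, c@samplingRate)))
  expect_equal(extractFeatures(scaled)[featureNames()], ft[featureNames()],
               tolerance = 1e-9)
  flipped <- ICDataset(lapply(components(ds), function(c)
    ICComponent(c@componentId, c@subjectId, c@channels, -c@weights,
                -c@signal, c@samplingRate)))
  ftf <- extractFeatures(flipped)
  absFeatures <- c("kurtosis", "max_epoch_variance", "SAD", "SVD", "MIF",
                   "MT", "AT", "AMALB")
  expect_equal(ftf[absFeatures], ft[absFeatures], tolerance = 1e-9)
})

test_that("feature extraction flags failed features instead of dying", {
  cont <- ICComponent("cont", "s", defaultMontage(),
                      rnorm(31), rnorm(2000), 250)
  ft <- extractFeatures(cont)
  expect_identical(nrow(ft), 1L)
  expect_true(is.na(ft$max_epoch_variance))  # single epoch
  expect_true(ft$flagged)
  expect_match(attr(ft, "errors")[["cont"]][1], "epochs")
  expect_false(is.na(ft$kurtosis))
})
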