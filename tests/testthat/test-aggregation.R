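test_that("class merging applies the eye/line-noise/alpha-mu rules", {
  ann <- makeAnn(list(
    list("c1", "e1", c("Horizontal eye movements", "Brain")),
    list("c2", "e1", "Alpha"),
    list("c3", "e1", "Line noise"),
    list("c4", "e1", c("Vertical eye movements",
                       "Horizontal eye movements")),
    list("c5", "e1", c("Mu", "Other"))))
  m <- mergeClasses(ann)
  expect_setequal(m$labels[[1]], c("Eyes", "Brain"))
  expect_setequal(m$labels[[2]], c("Alpha", "Brain"))
  expect_identical(m$labels[[3]], "Uncertain")
  expect_identical(m$labels[[4]], "Eyes")
  expect_setequal(m$labels[[5]], c("Mu", "Other", "Brain"))
  bad <- makeAnn(list(list("c1", "e1", "Blink")))
  expect_error(mergeClasses(bad), "vocabulary")
})

test_that("the label matrix records votes and missing experts", {
  ann <- makeAnn(list(
    list("c1", "e1", "Brain"),
    list("c1", "e2", c("Brain", "Mu")),
    list("c2", "e1", "Eyes")))
  m <- buildLabelMatrix(ann)
  expect_identical(m@votes["c1", "e1", "Brain"], 1)
  expect_identical(m@votes["c1", "e2", "Mu"], 1)
  expect_identical(m@votes["c1", "e1", "Mu"], 0)
  expect_true(all(is.na(m@votes["c2", "e2", ])))
  # row sums equal label-set sizes
  expect_identical(sum(m@votes["c1", "e2", ]), 2)
  dup <- makeAnn(list(list("c1", "e1", "Brain"), list("c1", "e1", "Mu")))
  expect_error(buildLabelMatrix(dup), "duplicate")
})

test_that("majority vote averages binary votes with a strict threshold", {
  ann <- makeAnn(list(
    list("c1", "e1", "Brain"), list("c1", "e2", "Brain"),
    list("c1", "e3", "Eyes")))
  agg <- majorityVote(buildLabelMatrix(ann), 0.33)
  expect_equal(probabilities(agg)["c1", "Brain"], 2 / 3)
  expect_true(targets(agg)["c1", "Brain"])
  # a one-of-three vote (1/3 = 0.333...) strictly exceeds 0.33
  expect_equal(probabilities(agg)["c1", "Eyes"], 1 / 3)
  expect_true(targets(agg)["c1", "Eyes"])
  expect_equal(probabilities(agg)["c1", "Muscle"], 0)
  expect_false(targets(agg)["c1", "Muscle"])
  # but it does not exceed a 1/3-as-exact threshold
  agg3 <- majorityVote(buildLabelMatrix(ann), 1 / 3)
  expect_false(targets(agg3)["c1", "Eyes"])
})

test_that("probabilistic vote splits each expert's vote over their labels", {
  ann <- makeAnn(list(list("c1", "e1", c("Eyes", "Muscle", "Heart"))))
  agg <- probabilisticVote(buildLabelMatrix(ann), 0.33)
  expect_equal(unname(probabilities(agg)["c1", c("Eyes", "Muscle", "Heart")]),
               rep(1 / 3, 3))
  expect_equal(round(probabilities(agg)["c1", "Eyes"], 2), 0.33)
  single <- makeAnn(list(list("c1", "e1", "Brain")))
  expect_equal(
    probabilities(probabilisticVote(buildLabelMatrix(single)))["c1", "Brain"],
    1)
  two <- makeAnn(list(list("c1", "e1", "Brain"),
                      list("c1", "e2", c("Brain", "Alpha"))))
  agg2 <- probabilisticVote(buildLabelMatrix(two), 0.33)
  expect_equal(probabilities(agg2)["c1", "Brain"], 0.75)
  expect_equal(probabilities(agg2)["c1", "Alpha"], 0.25)
  expect_true(targets(agg2)["c1", "Brain"])
  expect_false(targets(agg2)["c1", "Alpha"])
})

test_that("components with zero annotators raise a named error", {
  ann <- makeAnn(list(list("c1", "e1", "Brain")))
  m <- buildLabelMatrix(ann)
  m@votes["c1", "e1", ] <- NA
  expect_error(majorityVote(m), "c1")
})

test_that("mixed-nature components separate the two strategies", {
  # one expert splits a mixed component into many labels, the other
  # reports only the clear pattern
  ann <- makeAnn(list(
    list("c1", "e1", c("Eyes", "Muscle", "Heart", "Brain")),
    list("c1", "e2", "Brain")))
  m <- buildLabelMatrix(ann)
  pv <- probabilisticVote(m, 0.33)
  mv <- majorityVote(m, 0.33)
  expect_equal(probabilities(pv)["c1", "Brain"], (0.25 + 1) / 2)
  expect_identical(colnames(targets(pv))[targets(pv)["c1", ]], "Brain")
  expect_setequal(colnames(targets(mv))[targets(mv)["c1", ]],
                  c("Eyes", "Muscle", "Heart", "Brain"))
})

test_that("strategies coincide on singleton label sets", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      ann <- randomAnnTable(4, 3, c("Brain", "Eyes", "Muscle"))
      ann$labels <- lapply(ann$labels, function(l) l[1])
      m <- buildLabelMatrix(ann, c("Brain", "Eyes", "Muscle"))
      expect_equal(probabilities(majorityVote(m)),
                   probabilities(probabilisticVote(m)))
    }
  })
})

test_that("probabilistic probabilities never exceed majority probabilities", {
  withr::with_seed(12, {
    for (rep in 1:10) {
      ann <- randomAnnTable(5, 3, c("Brain", "Eyes", "Muscle", "Heart"))
      m <- buildLabelMatrix(ann, c("Brain", "Eyes", "Muscle", "Heart"))
      pm <- probabilities(majorityVote(m))
      pp <- probabilities(probabilisticVote(m))
      expect_true(all(pp <= pm + 1e-12))
    }
  })
})

test_that("each expert's probabilistic contributions sum to one vote", {
  withr::with_seed(13, {
    ann <- randomAnnTable(6, 3, c("Brain", "Eyes", "Muscle", "Heart"))
    m <- buildLabelMatrix(ann, c("Brain", "Eyes", "Muscle", "Heart"))
    v <- m@votes
    for (ci in dimnames(v)[[1]]) for (ei in dimnames(v)[[2]]) {
      sl <- v[ci, ei, ]
      if (anyNA(sl)) next
      expect_equal(sum(sl / sum(sl)), 1)
    }
  })
})

test_that("aggregation is invariant to expert and component order", {
  withr::with_seed(14, {
    ann <- randomAnnTable(6, 3, c("Brain", "Eyes", "Muscle"))
    perm <- ann[sample(nrow(ann)), ]
    a1 <- aggregateAnnotations(ann)
    a2 <- aggregateAnnotations(perm)
    ids <- rownames(probabilities(a1))
    expect_equal(probabilities(a2)[ids, ], probabilities(a1))
    expect_equal(targets(a2)[ids, ], targets(a1))
  })
})

test_that("the default plan follows the per-class strategy table", {
  plan <- defaultAggregationPlan()
  expect_setequal(plan$class[plan$strategy == "probabilistic"],
                  c("Brain", "Eyes", "Muscle", "Channel noise"))
  expect_setequal(plan$class[plan$strategy == "majority"],
                  c("Alpha", "Mu", "Heart"))
  expect_true(all(plan$threshold == 0.33))
  # Other/Uncertain are carried in the matrix but not aggregated
  ann <- makeAnn(list(list("c1", "e1", c("Brain", "Other"))))
  agg <- aggregateAnnotations(ann)
  expect_false("Other" %in% colnames(probabilities(agg)))
  expect_equal(probabilities(agg)["c1", "Brain"], 0.5)
})

test_that("aggregation errors on a plan naming an unknown strategy", {
  ann <- makeAnn(list(list("c1", "e1", "Brain")))
  plan <- data.frame(class = "Brain", strategy = "median", threshold = 0.33)
  expect_error(aggregateAnnotations(ann, plan), "median")
})
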