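test_that("stratified splits hit exact per-class 20% where divisible", {
  labels <- rep(c("A", "B"), c(10, 5))
  plan <- stratifiedShuffleSplits(labels, folds = 1, runs = 1, baseSeed = 3)
  sp <- plan@splits[[1]]
  expect_length(sp$test, 3L)
  expect_equal(sum(labels[sp$test] == "A"), 2L)
  expect_equal(sum(labels[sp$test] == "B"), 1L)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  expect_length(intersect(sp$train, sp$test), 0L)
})

test_that("the study cohort allocates 35 test samples by largest remainder", {
  cfg <- defaultStudyConfig()
  labels <- rep(names(cfg@perSpeciesCounts), cfg@perSpeciesCounts)
  plan <- stratifiedShuffleSplits(labels, folds = 2, runs = 2, baseSeed = 1)
  for (sp in plan@splits) expect_length(sp$test, 35L)
})

test_that("splits are deterministic in the base seed and vary across folds", {
  labels <- rep(letters[1:3], c(12, 9, 7))
  p1 <- stratifiedShuffleSplits(labels, folds = 3, runs = 2, baseSeed = 42)
  p2 <- stratifiedShuffleSplits(labels, folds = 3, runs = 2, baseSeed = 42)
  expect_identical(p1@splits, p2@splits)
  expect_false(identical(p1@splits[[1]]$test, p1@splits[[2]]$test))
})

test_that("per-class test proportions stay within one sample of the target over random label mixes", {
  set.seed(14)
  for (i in 1:8) {
    k <- sample(2:6, 1)
    counts <- sample(3:40, k, replace = TRUE)
    labels <- rep(paste0("c", seq_len(k)), counts)
    plan <- stratifiedShuffleSplits(labels, folds = 2, runs = 2,
                                    baseSeed = 100 + i)
    for (sp in plan@splits) {
      tt <- table(factor(labels[sp$test], levels = paste0("c", seq_len(k))))
      expect_true(all(abs(as.vector(tt) - counts * 0.2) < 1),
                  info = paste(counts, collapse = ","))
    }
  }
  expect_error(stratifiedShuffleSplits(c("a", "a", "b")),
               class = "beakid_class_too_small")
})

test_that("confusion matrices count true/predicted pairs and conserve totals", {
  cm <- confusionMatrix(c("A", "A", "B"), c("A", "B", "B"), c("A", "B"))
  expect_equal(unname(cm), matrix(c(1L, 0L, 1L, 1L), 2, 2))
  expect_equal(sum(cm), 3L)
  perfect <- confusionMatrix(c("A", "B", "C"), c("A", "B", "C"), c("A", "B", "C"))
  expect_true(all(perfect[upper.tri(perfect) | lower.tri(perfect)] == 0))
  expect_error(confusionMatrix("A", "Z", c("A", "B")), "outside")
})

test_that("accuracy is trace over total, matching the binary TP/TN formula", {
  cm <- matrix(c(3L, 2L, 1L, 4L), 2, 2)  # TP=3, FN=1, FP=2, TN=4
  expect_equal(accuracyFromConfusion(cm), 0.7)
  expect_equal(accuracyFromConfusion(diag(5L)), 1)
  expect_equal(accuracyFromConfusion(matrix(c(0L, 3L, 2L, 0L), 2, 2)), 0)
  expect_error(accuracyFromConfusion(matrix(0L, 2, 2)), "zero total")
})

test_that("precision and recall follow the one-vs-rest TP ratios with degenerate flags", {
  cm <- matrix(c(3L, 1L, 1L, 5L), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  pr <- precisionRecall(cm, "A")
  expect_equal(pr$precision, 0.75)
  expect_equal(pr$recall, 0.75)
  expect_false(pr$degenerate)
  cm0 <- matrix(c(4L, 0L, 0L, 0L), 2, 2,
                dimnames = list(c("A", "B"), c("A", "B")))
  pr0 <- precisionRecall(cm0, "B")
  expect_equal(pr0$precision, 0)
  expect_equal(pr0$recall, 0)
  expect_true(pr0$degenerate)
})

test_that("PR-AUC is 1 for perfect ranking and tracks prevalence for random scores", {
  expect_equal(prCurveAuc(c(TRUE, TRUE, FALSE, FALSE), c(9, 8, 2, 1))$auc, 1)
  set.seed(77)
  n <- 10000
  y <- runif(n) < 0.25
  auc <- prCurveAuc(y, runif(n))$auc
  expect_lt(abs(auc - 0.25), 0.05)
  # reversed perfect scores: worse than prevalence-free 0.5 at low prevalence
  rev <- prCurveAuc(c(TRUE, FALSE, FALSE, FALSE), c(1, 2, 3, 4))$auc
  expect_lt(rev, 0.5)
  expect_error(prCurveAuc(c(FALSE, FALSE), c(1, 2)), "positive")
})

test_that("experiments aggregate folds deterministically and ace separable data", {
  set.seed(8)
  X <- rbind(matrix(rnorm(60, 0), 20, 3), matrix(rnorm(60, 6), 20, 3))
  y <- rep(c("a", "b"), each = 20)
  plan <- stratifiedShuffleSplits(y, folds = 5, runs = 2, baseSeed = 9)
  rep1 <- runExperiment(X, classifierSpec("ANN", seed = 4), plan, labels = y)
  expect_length(foldAccuracies(rep1), 10L)
  expect_equal(meanAccuracy(rep1), 1)
  expect_equal(macroAuc(rep1), 1)
  expect_equal(sum(rep1@confusion), 10 * length(plan@splits[[1]]$test))
  rep2 <- runExperiment(X, classifierSpec("ANN", seed = 4), plan, labels = y)
  expect_identical(writeReportJson(rep1), writeReportJson(rep2))
})

test_that("report JSON carries the documented schema", {
  set.seed(8)
  X <- rbind(matrix(rnorm(40, 0), 10, 4), matrix(rnorm(40, 5), 10, 4))
  y <- rep(c("a", "b"), each = 10)
  plan <- stratifiedShuffleSplits(y, folds = 2, runs = 1, baseSeed = 2)
  rep <- runExperiment(X, classifierSpec("LDA"), plan, labels = y,
                       descriptor = "msd", view = "lower")
  js <- jsonlite::fromJSON(writeReportJson(rep))
  expect_equal(js$classifier, "LDA")
  expect_equal(js$descriptor, "msd")
  expect_equal(js$view, "lower")
  expect_length(js$folds, 2L)
  expect_named(js$per_class, c("a", "b"))
  expect_true(all(c("precision", "recall", "auc") %in% names(js$per_class$a)))
  expect_equal(js$mean_accuracy, mean(js$folds), tolerance = 1e-12)
})
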