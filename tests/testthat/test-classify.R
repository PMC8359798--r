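blobs <- function(n = 20, k = 3, p = 5, sep = 5, seed = 2) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(k) - 1, function(c0)
    matrix(rnorm(n * p, mean = c0 * sep), n, p)))
  colnames(X) <- sprintf("f_%d", seq_len(p) - 1L)
  list(x = X, y = factor(rep(letters[seq_len(k)], each = n)))
}

test_that("classifier specs carry the benchmark hyperparameters and reject unknowns", {
  expect_equal(classifierSpec("kNN")@params$k, 8L)
  expect_equal(classifierSpec("kNN")@params$weights, "uniform")
  expect_equal(classifierSpec("RF")@params$nTrees, 100L)
  expect_equal(classifierSpec("ANN")@params$hiddenUnits, 30L)
  expect_equal(classifierSpec("SVM")@params$C, 30)
  expect_equal(classifierSpec("DT")@params$maxDepth, 2L)
  expect_equal(classifierSpec("LR")@params$C, 0.15)
  expect_equal(classifierSpec("GNB")@params$varSmoothing, 1e-9)
  expect_error(classifierSpec("XGB"), class = "beakid_unknown_classifier")
  expect_error(classifierSpec("RF", list(trees = 10)),
               class = "beakid_invalid_hyperparameter")
  expect_warning(spec <- classifierSpec("LDA", list(C = 0.15)), "ignored")
  expect_false("C" %in% names(spec@params))
})

test_that("an ANN separates linearly separable blobs perfectly in training", {
  d <- blobs()
  model <- fitModel("ANN", d$x, d$y)
  pred <- predictScores(model, d$x)
  expect_equal(mean(pred$labels == d$y), 1.0)
})

test_that("fits are deterministic under a fixed seed and reject degenerate input", {
  d <- blobs()
  train <- c(1:15, 21:35, 41:55)
  test <- setdiff(seq_along(d$y), train)
  for (nm in c("ANN", "RF")) {
    m1 <- fitModel(buildClassifier(classifierSpec(nm, seed = 9)), d$x, d$y, train)
    m2 <- fitModel(buildClassifier(classifierSpec(nm, seed = 9)), d$x, d$y, train)
    p1 <- predictScores(m1, d$x[test, ])
    p2 <- predictScores(m2, d$x[test, ])
    expect_identical(p1$labels, p2$labels)
    expect_equal(p1$scores, p2$scores)
  }
  expect_error(fitModel("ANN", d$x, d$y, trainIndex = 1:10),
               class = "beakid_single_class")
  xx <- d$x; xx[1, 1] <- NA
  expect_error(fitModel("ANN", xx, d$y), "non-finite")
})

test_that("probability scores sum to one and argmax ties break by class order", {
  d <- blobs()
  for (nm in c("ANN", "RF", "DT", "kNN", "LR", "LDA", "GNB")) {
    m <- fitModel(nm, d$x, d$y)
    sc <- predictScores(m, d$x[c(1, 25, 45), ])$scores
    expect_equal(unname(rowSums(sc)), rep(1, 3), tolerance = 1e-9,
                 info = nm)
    expect_equal(colnames(sc), levels(d$y), info = nm)
  }
  # SVM emits one-vs-one vote shares in [0, 1], not probabilities
  msvm <- fitModel("SVM", d$x, d$y)
  scv <- predictScores(msvm, d$x[1:5, ])$scores
  expect_true(all(scv >= 0 & scv <= 1))
  # tie on equal scores resolves to the lowest class index
  expect_equal(which.max(c(0.4, 0.4, 0.2)), 1L)
})

test_that("kNN follows the 8-neighbour majority against a brute-force oracle", {
  set.seed(6)
  x <- matrix(rnorm(40 * 2), 40, 2)
  y <- factor(rep(c("a", "b"), each = 20))
  m <- fitModel(buildClassifier(classifierSpec("kNN"), scale = FALSE), x, y)
  q <- matrix(c(0.2, -0.1, 1.5, 0.3), 2, 2, byrow = TRUE)
  pred <- predictScores(m, q)
  for (i in 1:2) {
    d2 <- colSums((t(x) - q[i, ])^2)
    nn <- order(d2)[1:8]
    counts <- table(y[nn])
    expect_equal(as.character(pred$labels[i]),
                 names(counts)[which.max(counts)])
    expect_equal(unname(pred$scores[i, ]), unname(as.vector(counts) / 8),
                 tolerance = 1e-9)
  }
})

test_that("order-insensitive learners ignore training row permutations", {
  d <- blobs()
  set.seed(3)
  perm <- sample(length(d$y))
  for (nm in c("kNN", "GNB", "LDA", "DT")) {
    m1 <- fitModel(nm, d$x, d$y)
    m2 <- fitModel(nm, d$x[perm, ], d$y[perm])
    p1 <- predictScores(m1, d$x[1:10, ])
    p2 <- predictScores(m2, d$x[1:10, ])
    expect_identical(p1$labels, p2$labels, info = nm)
    expect_equal(p1$scores, p2$scores, tolerance = 1e-9, info = nm)
  }
})

test_that("prediction rejects a feature-width mismatch", {
  d <- blobs()
  m <- fitModel("LDA", d$x, d$y)
  expect_error(predictScores(m, d$x[, 1:3]), "width")
})
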