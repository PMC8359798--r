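# The eight benchmark classifiers behind one build/fit/score contract.
# Hyperparameter schemas mirror the study's tuning table; every other
# backend setting stays at the documented default.

.classifierSchemas <- list(
  ANN = list(hiddenUnits = 30L, learningRate = 1e-3, maxIter = 200L),
  SVM = list(C = 30, kernel = "sigmoid", decisionShape = "one-vs-one"),
  RF  = list(nTrees = 100L, split = "gini", maxFeatures = "sqrt"),
  DT  = list(split = "information", maxDepth = 2L),
  kNN = list(k = 8L, metric = "euclidean", weights = "uniform"),
  LR  = list(C = 0.15, multiClass = "multinomial", solver = "newton-cg"),
  LDA = list(solver = "svd", tol = 1e-4),
  GNB = list(varSmoothing = 1e-9)
)

#' Construct a classifier specification
#'
#' Defaults are the study's tuned values: ANN with one hidden layer of 30
#' neurons and at most 200 iterations; SVM with C = 30, sigmoid kernel and
#' one-vs-one decisions; RF with 100 Gini trees and sqrt(p) features per
#' split; DT split on information gain at depth 2; kNN with k = 8 Euclidean
#' uniform-weight neighbours; multinomial LR with C = 0.15; LDA with the
#' SVD solver and tolerance 1e-4; GNB with variance smoothing 1e-9.
#' Unknown classifier names and unknown hyperparameter keys are rejected.
#'
#' @param name one of `"ANN"`, `"SVM"`, `"RF"`, `"DT"`, `"kNN"`, `"LR"`,
#'   `"LDA"`, `"GNB"`.
#' @param params named list overriding schema defaults.
#' @param seed integer seed for the stochastic learners.
#' @return a [ClassifierSpec].
#' @export
classifierSpec <- function(name, params = list(), seed = 1L) {
  if (!(is.character(name) && length(name) == 1L && name %in% .classifierNames))
    stop(structure(class = c("beakid_unknown_classifier", "error", "condition"),
                   list(message = sprintf(
                     "unknown classifier '%s'; must be one of: %s",
                     paste(name, collapse = ","),
                     paste(.classifierNames, collapse = ", ")),
                     call = sys.call())))
  schema <- .classifierSchemas[[name]]
  if (name == "LDA" && "C" %in% names(params)) {
    warning("LDA has no regularization parameter C; the value is ignored")
    params$C <- NULL
  }
  bad <- setdiff(names(params), names(schema))
  if (length(bad))
    stop(structure(class = c("beakid_invalid_hyperparameter", "error", "condition"),
                   list(message = sprintf(
                     "invalid hyperparameter%s for %s: %s (allowed: %s)",
                     if (length(bad) > 1) "s" else "", name,
                     paste(bad, collapse = ", "),
                     paste(names(schema), collapse = ", ")),
                     call = sys.call())))
  schema[names(params)] <- params
  new("ClassifierSpec", name = name, params = schema, seed = as.integer(seed))
}

setMethod("show", "ClassifierSpec", function(object) {
  p <- object@params
  cat(sprintf("ClassifierSpec %s (seed %d): %s\n", object@name, object@seed,
              paste(sprintf("%s=%s", names(p),
                            vapply(p, function(v) paste(format(v), collapse = "/"),
                                   character(1))),
                    collapse = ", ")))
})

#' Build an untrained classifier from a specification
#'
#' @param spec a [ClassifierSpec] (or a classifier name, which is promoted
#'   with schema defaults).
#' @param scale z-score standardization fitted on the training rows only
#'   (recommended for the scale-sensitive ANN/SVM/kNN learners).
#' @return a [BeakClassifier].
#' @export
buildClassifier <- function(spec, scale = TRUE) {
  if (is.character(spec)) spec <- classifierSpec(spec)
  stopifnot(is(spec, "ClassifierSpec"))
  new("BeakClassifier", spec = spec, scale = scale)
}

#' Fit a classifier on the training rows of a feature table
#'
#' Deterministic given `spec@seed`. Optional z-score scaling statistics are
#' learned from the training rows only and stored in the model.
#'
#' @param classifier a [BeakClassifier] (or [ClassifierSpec] / name).
#' @param features samples x features numeric matrix or a [BeakFeatureSet].
#' @param labels sample labels (ignored when `features` is a
#'   [BeakFeatureSet]).
#' @param trainIndex integer indices of the training rows (default: all).
#' @return a [TrainedBeakModel].
#' @export
fitModel <- function(classifier, features, labels = NULL, trainIndex = NULL) {
  if (!is(classifier, "BeakClassifier")) classifier <- buildClassifier(classifier)
  if (is(features, "BeakFeatureSet")) {
    labels <- sampleLabels(features)
    features <- featureMatrix(features)
  }
  features <- as.matrix(features)
  labels <- factor(labels)
  if (is.null(trainIndex)) trainIndex <- seq_len(nrow(features))
  x <- features[trainIndex, , drop = FALSE]
  y <- droplevels(labels[trainIndex])
  if (!all(is.finite(x))) stop("non-finite feature values in the training rows")
  if (nlevels(y) < 2L)
    stop(structure(class = c("beakid_single_class", "error", "condition"),
                   list(message = "training rows contain a single class; >= 2 required",
                        call = sys.call())))
  if (is.null(colnames(x))) colnames(x) <- sprintf("f_%d", seq_len(ncol(x)) - 1L)

  center <- numeric(0); scaling <- numeric(0)
  if (classifier@scale) {
    center <- colMeans(x)
    scaling <- apply(x, 2, sd)
    scaling[!is.finite(scaling) | scaling == 0] <- 1
    x <- sweep(sweep(x, 2, center), 2, scaling, "/")
  }

  spec <- classifier@spec
  p <- spec@params
  oldseed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, envir = globalenv()))
  set.seed(spec@seed)
  df <- data.frame(x, check.names = FALSE)
  fit <- switch(spec@name,
    ANN = nnet::nnet(x, nnet::class.ind(y), size = p$hiddenUnits,
                     maxit = p$maxIter, softmax = TRUE, trace = FALSE,
                     MaxNWts = 1000000L),
    SVM = e1071::svm(x, y, cost = p$C, kernel = p$kernel, scale = FALSE),
    RF  = randomForest::randomForest(x, y, ntree = p$nTrees,
                                     mtry = max(1L, floor(sqrt(ncol(x))))),
    DT  = rpart::rpart(.beak_label ~ ., data = cbind(df, .beak_label = y),
                       method = "class",
                       parms = list(split = p$split),
                       control = rpart::rpart.control(maxdepth = p$maxDepth,
                                                      minsplit = 4L,
                                                      minbucket = 2L, cp = 0,
                                                      xval = 0L)),
    kNN = caret::knn3(x, y, k = p$k),
    LR  = nnet::multinom(.beak_label ~ ., data = cbind(df, .beak_label = y),
                         decay = 1 / p$C, maxit = 200, trace = FALSE,
                         MaxNWts = 1000000L),
    LDA = .fitLda(x, y, p$tol),
    GNB = .fitGnb(x, y, p$varSmoothing)
  )
  new("TrainedBeakModel", spec = spec, fit = fit,
      classes = levels(y), center = center, scaling = scaling,
      featureNames = colnames(x))
}

# LDA via MASS, discarding features with (near-)zero pooled within-group
# variance first -- discriminant axes are undefined along them and lda()
# rejects such input (e.g. the identically-1 rectangularity descriptor).
.fitLda <- function(x, y, tol) {
  withinSd <- vapply(seq_len(ncol(x)), function(j) {
    sqrt(mean(tapply(x[, j], y, function(v) stats::var(v)), na.rm = TRUE))
  }, numeric(1))
  keep <- which(is.finite(withinSd) & withinSd > tol)
  if (length(keep) < 1L) stop("no usable features for LDA: all within-group constant")
  fit <- withCallingHandlers(
    MASS::lda(x[, keep, drop = FALSE], grouping = y, tol = tol),
    # collinear blocks are expected for block-normalized HOG features; the
    # SVD solver truncates the rank-deficient directions
    warning = function(w) {
      if (grepl("collinear", conditionMessage(w))) invokeRestart("muffleWarning")
    })
  list(lda = fit, keep = keep)
}

# Gaussian naive Bayes via e1071, with the variance floor
# varSmoothing * max(feature variance) added for numerical stability.
.fitGnb <- function(x, y, varSmoothing) {
  nb <- e1071::naiveBayes(x, y)
  floorVar <- varSmoothing * max(apply(x, 2, function(v) stats::var(v)), 1e-12)
  nb$tables <- lapply(nb$tables, function(tab) {
    tab[, 2] <- sqrt(tab[, 2]^2 + floorVar)
    tab
  })
  nb
}

#' Score samples with a trained model
#'
#' Scores are class probabilities where the classifier defines them (ANN,
#' RF, DT, kNN, LR, LDA, GNB) and one-vs-one vote shares in [0, 1] for the
#' SVM. The hard label is the row argmax, ties broken by class order.
#'
#' @param model a [TrainedBeakModel].
#' @param features samples x features matrix or [BeakFeatureSet]; width must
#'   equal the training width.
#' @return list with `scores` (samples x classes matrix) and `labels`
#'   (factor of hard labels).
#' @export
predictScores <- function(model, features) {
  stopifnot(is(model, "TrainedBeakModel"))
  if (is(features, "BeakFeatureSet")) features <- featureMatrix(features)
  features <- as.matrix(features)
  if (ncol(features) != length(model@featureNames))
    stop(sprintf("feature width %d does not match training width %d",
                 ncol(features), length(model@featureNames)))
  colnames(features) <- model@featureNames
  if (length(model@center))
    features <- sweep(sweep(features, 2, model@center), 2, model@scaling, "/")
  classes <- model@classes
  K <- length(classes)
  df <- data.frame(features, check.names = FALSE)
  scores <- switch(model@spec@name,
    ANN = predict(model@fit, features),
    SVM = .svmVoteShares(model@fit, features, classes),
    RF  = predict(model@fit, features, type = "prob"),
    DT  = predict(model@fit, df, type = "prob"),
    kNN = predict(model@fit, features, type = "prob"),
    LR  = .multinomProbs(model@fit, df, classes),
    LDA = predict(model@fit$lda,
                  features[, model@fit$keep, drop = FALSE])$posterior,
    GNB = predict(model@fit, features, type = "raw")
  )
  scores <- as.matrix(scores)
  scores <- scores[, classes, drop = FALSE]
  hard <- apply(scores, 1, which.max)     # which.max: first (lowest) index wins ties
  list(scores = scores,
       labels = factor(classes[hard], levels = classes))
}

.multinomProbs <- function(fit, df, classes) {
  pr <- predict(fit, newdata = df, type = "probs")
  if (is.null(dim(pr))) {                  # two-class: vector of P(class 2)
    pr <- cbind(1 - pr, pr)
    colnames(pr) <- classes
  }
  pr
}

.svmVoteShares <- function(fit, x, classes) {
  pred <- predict(fit, x, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  K <- length(classes)
  votes <- matrix(0, nrow(x), K, dimnames = list(NULL, classes))
  for (j in seq_len(ncol(dv))) {
    pair <- strsplit(colnames(dv)[j], "/", fixed = TRUE)[[1]]
    win <- ifelse(dv[, j] > 0, pair[1], pair[2])
    for (cl in pair) votes[, cl] <- votes[, cl] + (win == cl)
  }
  votes / max(1L, K - 1L)                  # vote shares in [0, 1]
}
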