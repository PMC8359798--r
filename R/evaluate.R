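#' Build a repeated stratified shuffle-split plan
#'
#' Per run, `folds` independent stratified train/test shuffle splits at
#' `1 - testFraction` / `testFraction`; repeated `runs` times (the study
#' protocol: 5 splits x 10 runs at 80/20). Per-class test counts follow the
#' largest-remainder rounding of `classCount * testFraction` (the overall
#' test size is `round(n * testFraction)`); remainder ties are broken by
#' class order. Fold f of run r draws with seed `baseSeed + r * 1000 + f`.
#'
#' @param labels sample labels (factor or character); every class needs at
#'   least 2 samples.
#' @param folds splits per run.
#' @param runs number of repetitions.
#' @param testFraction held-out fraction in (0, 1).
#' @param baseSeed integer base seed.
#' @return a [SplitPlan] with `runs * folds` splits in run-major order.
#' @export
stratifiedShuffleSplits <- function(labels, folds = 5L, runs = 10L,
                                    testFraction = 0.2, baseSeed = 1L) {
  labels <- factor(labels)
  counts <- table(labels)
  if (any(counts < 2L)) {
    bad <- names(counts)[counts < 2L]
    stop(structure(class = c("beakid_class_too_small", "error", "condition"),
                   list(message = sprintf(
                     "class%s with fewer than 2 samples: %s",
                     if (length(bad) > 1) "es" else "",
                     paste(bad, collapse = ", ")),
                     call = sys.call())))
  }
  testCounts <- .largestRemainder(as.integer(counts), testFraction)
  names(testCounts) <- names(counts)
  # keep at least one training sample per class
  testCounts <- pmin(testCounts, as.integer(counts) - 1L)
  byClass <- split(seq_along(labels), labels)
  splits <- vector("list", runs * folds)
  k <- 0L
  oldseed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, envir = globalenv()))
  for (r in seq_len(runs)) {
    for (f in seq_len(folds)) {
      set.seed(as.integer(baseSeed + r * 1000 + f))
      test <- integer(0)
      for (cl in names(byClass)) {
        idx <- byClass[[cl]]
        test <- c(test, sort(sample(idx, testCounts[[cl]])))
      }
      test <- sort(test)
      k <- k + 1L
      splits[[k]] <- list(train = setdiff(seq_along(labels), test), test = test)
    }
  }
  new("SplitPlan", labels = labels, folds = as.integer(folds),
      runs = as.integer(runs), testFraction = testFraction,
      baseSeed = as.integer(baseSeed), splits = splits)
}

# Largest-remainder allocation of round(sum(n * frac)) test slots over
# classes; ties by class order.
.largestRemainder <- function(counts, frac) {
  q <- counts * frac
  base <- floor(q)
  total <- floor(sum(q) + 0.5)
  extra <- total - sum(base)
  rem <- q - base
  add <- integer(length(counts))
  if (extra > 0) {
    ord <- order(-rem, seq_along(counts))
    add[ord[seq_len(extra)]] <- 1L
  }
  as.integer(base + add)
}

setMethod("show", "SplitPlan", function(object) {
  cat(sprintf("SplitPlan: %d runs x %d folds at %.0f/%.0f over %d samples (%d classes), base seed %d\n",
              object@runs, object@folds, 100 * (1 - object@testFraction),
              100 * object@testFraction, length(object@labels),
              nlevels(object@labels), object@baseSeed))
})

#' Confusion matrix
#'
#' @param yTrue,yPred equal-length label vectors drawn from `classOrder`.
#' @param classOrder class labels fixing the row/column order.
#' @return K x K integer matrix, entry (i, j) = samples with true class i
#'   predicted as class j.
#' @export
confusionMatrix <- function(yTrue, yPred, classOrder) {
  yTrue <- as.character(yTrue); yPred <- as.character(yPred)
  if (length(yTrue) != length(yPred))
    stop("yTrue and yPred must have equal length")
  unknown <- setdiff(unique(c(yTrue, yPred)), classOrder)
  if (length(unknown))
    stop("labels outside classOrder: ", paste(unknown, collapse = ", "))
  tab <- table(factor(yTrue, levels = classOrder),
               factor(yPred, levels = classOrder))
  m <- matrix(as.integer(tab), nrow = length(classOrder),
              dimnames = list(true = classOrder, predicted = classOrder))
  m
}

#' Accuracy from a confusion matrix
#'
#' Multiclass generalization trace/total of the TP+TN over TP+TN+FP+FN
#' testing-accuracy formula (they coincide for two classes).
#'
#' @param confusion K x K matrix.
#' @return fraction in [0, 1].
#' @export
accuracyFromConfusion <- function(confusion) {
  total <- sum(confusion)
  if (total == 0) stop("empty confusion matrix: zero total")
  sum(diag(confusion)) / total
}

#' One-vs-rest precision and recall for one class
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)` from the
#' confusion matrix. Division-by-zero cases return 0 with
#' `degenerate = TRUE`.
#'
#' @param confusion K x K matrix.
#' @param class class name or index.
#' @return list with `precision`, `recall`, `degenerate`.
#' @export
precisionRecall <- function(confusion, class) {
  if (is.character(class)) class <- match(class, rownames(confusion))
  if (is.na(class) || class < 1 || class > nrow(confusion))
    stop("invalid class")
  tp <- confusion[class, class]
  fp <- sum(confusion[, class]) - tp
  fn <- sum(confusion[class, ]) - tp
  degenerate <- (tp + fp) == 0 || (tp + fn) == 0
  list(precision = if (tp + fp > 0) tp / (tp + fp) else 0,
       recall = if (tp + fn > 0) tp / (tp + fn) else 0,
       degenerate = degenerate)
}

#' Precision-recall curve and AUC (average precision)
#'
#' Precision-recall pairs at every distinct score threshold in descending
#' order; the AUC is the step-wise average-precision summation
#' `sum((R_i - R_{i-1}) * P_i)` with no linear interpolation.
#'
#' @param yTrue logical (or 0/1) one-vs-rest truth; at least one positive.
#' @param scores finite numeric scores, larger = more positive.
#' @return list with `curve` (data.frame recall/precision/threshold) and
#'   `auc`.
#' @export
prCurveAuc <- function(yTrue, scores) {
  yTrue <- as.logical(yTrue)
  if (!any(yTrue)) stop("no positive samples")
  if (!all(is.finite(scores))) stop("scores must be finite")
  ord <- order(scores, decreasing = TRUE)
  y <- yTrue[ord]; s <- scores[ord]
  tp <- cumsum(y); fp <- cumsum(!y)
  # collapse tied scores: metrics at the last element of each tie group
  last <- which(diff(s) != 0)
  last <- c(last, length(s))
  tp <- tp[last]; fp <- fp[last]
  nPos <- sum(yTrue)
  recall <- tp / nPos
  precision <- tp / (tp + fp)
  auc <- sum(diff(c(0, recall)) * precision)
  list(curve = data.frame(recall = recall, precision = precision,
                          threshold = s[last]),
       auc = auc)
}

#' Run one classifier over a full split plan
#'
#' Fits the classifier on every split's training rows, scores the test rows,
#' and aggregates: accuracy mean and standard deviation over all
#' `runs * folds` splits, a pooled confusion matrix, per-class one-vs-rest
#' precision/recall (pooled) and precision-recall AUC computed from the
#' test scores pooled over all splits, plus their macro average.
#'
#' @param features a [BeakFeatureSet] or samples x features matrix.
#' @param spec a [ClassifierSpec] (or name).
#' @param plan a [SplitPlan] built on the same samples.
#' @param labels labels when `features` is a bare matrix.
#' @param scale z-score standardization per fold (training rows only).
#' @param descriptor,view identifying strings stored in the report.
#' @return a [BeakEvalReport].
#' @export
runExperiment <- function(features, spec, plan, labels = NULL, scale = TRUE,
                          descriptor = "unknown", view = "unknown") {
  if (is.character(spec)) spec <- classifierSpec(spec)
  if (is(features, "BeakFeatureSet")) {
    if (descriptor == "unknown")
      descriptor <- metadata(features)$descriptor %||% "unknown"
    labels <- sampleLabels(features)
    features <- featureMatrix(features)
  }
  labels <- factor(labels)
  stopifnot(nrow(features) == length(labels),
            length(labels) == length(plan@labels))
  classes <- levels(labels)
  K <- length(classes)
  nSplit <- length(plan@splits)
  foldAcc <- numeric(nSplit)
  foldConf <- vector("list", nSplit)
  pooledScores <- vector("list", nSplit)
  pooledTruth <- vector("list", nSplit)
  for (i in seq_len(nSplit)) {
    sp <- plan@splits[[i]]
    fitSpec <- classifierSpec(spec@name, spec@params,
                              seed = spec@seed + i)
    model <- fitModel(buildClassifier(fitSpec, scale = scale),
                      features, labels, sp$train)
    pred <- predictScores(model, features[sp$test, , drop = FALSE])
    conf <- confusionMatrix(labels[sp$test], pred$labels, classes)
    foldConf[[i]] <- conf
    foldAcc[i] <- accuracyFromConfusion(conf)
    # widen the per-fold score matrix to the full class set
    sc <- matrix(0, length(sp$test), K, dimnames = list(NULL, classes))
    sc[, colnames(pred$scores)] <- pred$scores
    pooledScores[[i]] <- sc
    pooledTruth[[i]] <- as.character(labels[sp$test])
  }
  confusion <- Reduce(`+`, foldConf)
  scores <- do.call(rbind, pooledScores)
  truth <- unlist(pooledTruth)
  perClass <- data.frame(class = classes, precision = NA_real_,
                         recall = NA_real_, prAuc = NA_real_,
                         stringsAsFactors = FALSE)
  prCurves <- setNames(vector("list", K), classes)
  for (k in seq_len(K)) {
    pr <- precisionRecall(confusion, k)
    perClass$precision[k] <- pr$precision
    perClass$recall[k] <- pr$recall
    pos <- truth == classes[k]
    if (any(pos)) {
      cur <- prCurveAuc(pos, scores[, k])
      perClass$prAuc[k] <- cur$auc
      prCurves[[k]] <- cur$curve
    }
  }
  new("BeakEvalReport",
      classifier = spec@name, descriptor = descriptor, view = view,
      classes = classes, foldAccuracy = foldAcc, confusion = confusion,
      foldConfusion = foldConf, perClass = perClass, prCurves = prCurves,
      macroAuc = mean(perClass$prAuc, na.rm = TRUE),
      meanAccuracy = mean(foldAcc), sdAccuracy = sd(foldAcc))
}

setMethod("show", "BeakEvalReport", function(object) {
  cat(sprintf("BeakEvalReport: %s on %s (%s beak)\n", object@classifier,
              object@descriptor, object@view))
  cat(sprintf("  mean accuracy %.2f%% (sd %.2f%%, proportions %.4f +/- %.4f) over %d folds\n",
              100 * object@meanAccuracy, 100 * object@sdAccuracy,
              object@meanAccuracy, object@sdAccuracy,
              length(object@foldAccuracy)))
  cat(sprintf("  macro PR-AUC %.4f over %d classes\n", object@macroAuc,
              length(object@classes)))
})

#' Accessors for evaluation reports
#' @param x a [BeakEvalReport].
#' @return `meanAccuracy`/`sdAccuracy`: accuracy moments over folds (as
#'   proportions); `foldAccuracies`: per-fold vector; `macroAuc`: the
#'   macro-averaged precision-recall AUC.
#' @export
meanAccuracy <- function(x) x@meanAccuracy

#' @rdname meanAccuracy
#' @export
sdAccuracy <- function(x) x@sdAccuracy

#' @rdname meanAccuracy
#' @export
foldAccuracies <- function(x) x@foldAccuracy

#' @rdname meanAccuracy
#' @export
macroAuc <- function(x) x@macroAuc

#' Serialize an evaluation report to JSON
#'
#' Schema: `{classifier, descriptor, view, folds: [...], mean_accuracy,
#' sd_accuracy, per_class: {label: {precision, recall, auc}}, macro_auc}`.
#' Accuracies are proportions in [0, 1]; the standard deviation is over all
#' runs x folds.
#'
#' @param report a [BeakEvalReport].
#' @param path output path (optional; when `NULL` the JSON string is
#'   returned).
#' @return the JSON string, invisibly when written to a file.
#' @export
writeReportJson <- function(report, path = NULL) {
  perClass <- setNames(lapply(seq_along(report@classes), function(k) {
    list(precision = report@perClass$precision[k],
         recall = report@perClass$recall[k],
         auc = report@perClass$prAuc[k])
  }), report@classes)
  obj <- list(classifier = report@classifier,
              descriptor = report@descriptor,
              view = report@view,
              folds = report@foldAccuracy,
              mean_accuracy = report@meanAccuracy,
              sd_accuracy = report@sdAccuracy,
              per_class = perClass,
              macro_auc = report@macroAuc)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}
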