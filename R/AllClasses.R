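#' Species-specific beak shape parameters
#'
#' Parameters of the stylized left-lateral beak silhouette for one species:
#' a hooked-crescent body (hood lobe plus posterior wing lobe joined at the
#' rostrum) with a species-specific pigmentation gradient. The silhouette is
#' always darker than the lightbox background so that threshold segmentation
#' is exact by construction.
#'
#' @slot speciesId single character label.
#' @slot rostrumCurvature dimensionless > 0; larger values carve a deeper
#'   hook at the rostrum.
#' @slot hoodToWingRatio dimensionless > 0; ratio of hood (dorsal lobe)
#'   height to wing extension. Drives the bounding-box aspect ratio.
#' @slot wingLengthFrac fraction of body length in (0, 1] taken up by the
#'   posterior wing lobe.
#' @slot baseDarkness grey level (0--255, must be < 200) at the rostrum tip,
#'   the darkest, most heavily tanned part of the beak.
#' @slot darknessGradient grey-level increase per unit normalized distance
#'   from the rostrum (pigmentation fades away from the tip).
#' @slot sizeRange numeric length-2, nominal beak length range in mm
#'   (min < max).
#' @export
setClass("SpeciesShape",
  representation(
    speciesId = "character",
    rostrumCurvature = "numeric",
    hoodToWingRatio = "numeric",
    wingLengthFrac = "numeric",
    baseDarkness = "numeric",
    darknessGradient = "numeric",
    sizeRange = "numeric"
  )
)

setValidity("SpeciesShape", function(object) {
  msg <- character()
  num <- c(object@rostrumCurvature, object@hoodToWingRatio,
           object@wingLengthFrac, object@baseDarkness,
           object@darknessGradient, object@sizeRange)
  if (length(object@speciesId) != 1L || !nzchar(object@speciesId))
    msg <- c(msg, "speciesId must be a single non-empty label")
  if (!all(is.finite(num))) {
    msg <- c(msg, "all shape parameters must be finite")
    return(msg)
  }
  if (object@rostrumCurvature <= 0 || object@hoodToWingRatio <= 0)
    msg <- c(msg, "rostrumCurvature and hoodToWingRatio must be positive")
  if (object@wingLengthFrac <= 0 || object@wingLengthFrac > 1)
    msg <- c(msg, "wingLengthFrac must lie in (0, 1]")
  if (object@baseDarkness < 0 || object@baseDarkness >= 200)
    msg <- c(msg, "baseDarkness must lie in [0, 200) so the beak is darker than the lightbox")
  if (length(object@sizeRange) != 2L || object@sizeRange[1] >= object@sizeRange[2])
    msg <- c(msg, "sizeRange must be (min, max) with min < max")
  if (length(msg)) msg else TRUE
})

#' Configuration of a synthetic beak dataset
#'
#' @slot species list of [SpeciesShape] objects, one per species.
#' @slot perSpeciesCounts named integer vector, images per species; names
#'   must match the species ids.
#' @slot imageSize integer length-2 `(width, height)` in pixels.
#' @slot backgroundRange numeric length-2, grey-level range of the lightbox
#'   background; must be a subset of [240, 255].
#' @slot noiseSd grey levels, standard deviation of additive pixel noise.
#' @slot view `"upper"` or `"lower"` beak view.
#' @slot seed integer master seed; the same seed yields a byte-identical
#'   dataset.
#' @export
setClass("BeakDatasetConfig",
  representation(
    species = "list",
    perSpeciesCounts = "integer",
    imageSize = "integer",
    backgroundRange = "numeric",
    noiseSd = "numeric",
    view = "character",
    seed = "integer"
  )
)

setValidity("BeakDatasetConfig", function(object) {
  msg <- character()
  ids <- vapply(object@species, function(s) s@speciesId, character(1))
  if (length(object@species) == 0L)
    msg <- c(msg, "species set must not be empty")
  if (!all(vapply(object@species, function(s) is(s, "SpeciesShape"), logical(1))))
    msg <- c(msg, "species must be a list of SpeciesShape objects")
  if (is.null(names(object@perSpeciesCounts)) ||
      !setequal(names(object@perSpeciesCounts), ids))
    msg <- c(msg, "perSpeciesCounts names must match species ids")
  if (any(object@perSpeciesCounts < 1L))
    msg <- c(msg, "perSpeciesCounts must be >= 1 for every included species")
  if (length(object@imageSize) != 2L || any(object@imageSize < 16L))
    msg <- c(msg, "imageSize must be (width, height), each >= 16 px")
  if (length(object@backgroundRange) != 2L ||
      object@backgroundRange[1] < 240 || object@backgroundRange[2] > 255 ||
      object@backgroundRange[1] > object@backgroundRange[2])
    msg <- c(msg, "backgroundRange must be an ordered subset of [240, 255]")
  if (!(object@view %in% c("upper", "lower")))
    msg <- c(msg, "view must be 'upper' or 'lower'")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Histogram-of-oriented-gradients geometry
#'
#' @slot cellSize cell side in pixels (default 128).
#' @slot bins number of unsigned orientation bins over 180 degrees
#'   (default 9, bin centres 0, 20, ..., 160).
#' @slot blockSize block side in cells (default 2, i.e. 2x2 cells).
#' @slot blockStride block stride in cells (default 1).
#' @slot asPrinted logical; if `TRUE` the gradient orientation uses the
#'   arctan(Gx/Gy) ratio instead of the standard arctan(Gy/Gx).
#' @slot interpolation `"linear"` (magnitude split between the two nearest
#'   bin centres, circular over 180 degrees) or `"hard"` (nearest bin).
#' @export
setClass("HogParams",
  representation(
    cellSize = "integer",
    bins = "integer",
    blockSize = "integer",
    blockStride = "integer",
    asPrinted = "logical",
    interpolation = "character"
  )
)

setValidity("HogParams", function(object) {
  msg <- character()
  if (object@cellSize < 1L) msg <- c(msg, "cellSize must be >= 1")
  if (object@bins < 1L) msg <- c(msg, "bins must be >= 1")
  if (180 %% object@bins != 0)
    msg <- c(msg, "bins must divide 180 (unsigned orientation)")
  if (object@blockSize < 1L || object@blockStride < 1L)
    msg <- c(msg, "blockSize and blockStride must be >= 1")
  if (!(object@interpolation %in% c("linear", "hard")))
    msg <- c(msg, "interpolation must be 'linear' or 'hard'")
  if (length(msg)) msg else TRUE
})

#' Deep-feature backbone description
#'
#' Fixed (name, input size, feature dimension) table of the three supported
#' transfer-learning backbones, plus the weight mode. Only seeded random
#' weights can be instantiated offline; requesting pretrained weights raises
#' a "backbone unavailable" error at extraction time.
#'
#' @slot name one of `"vgg19"`, `"inceptionv3"`, `"resnet50"`.
#' @slot inputSize square input side in pixels (224, 299, 224).
#' @slot featureDim length of the emitted feature vector (4096, 2048, 2048).
#' @slot weights `"random"` or `"pretrained"`.
#' @slot tapPoint `"fc2"` (second fully connected layer, vgg19) or `"gap"`
#'   (global average pool, inceptionv3/resnet50).
#' @slot meanRgb per-channel means subtracted during preprocessing.
#' @slot weightsSeed integer seed for random-weight instantiation.
#' @export
setClass("BackboneSpec",
  representation(
    name = "character",
    inputSize = "integer",
    featureDim = "integer",
    weights = "character",
    tapPoint = "character",
    meanRgb = "numeric",
    weightsSeed = "integer"
  )
)

.backboneTable <- data.frame(
  name = c("vgg19", "inceptionv3", "resnet50"),
  inputSize = c(224L, 299L, 224L),
  featureDim = c(4096L, 2048L, 2048L),
  tapPoint = c("fc2", "gap", "gap"),
  stringsAsFactors = FALSE
)

setValidity("BackboneSpec", function(object) {
  row <- .backboneTable[.backboneTable$name == object@name, ]
  if (nrow(row) != 1L)
    return(sprintf("unknown backbone '%s'", object@name))
  if (object@inputSize != row$inputSize || object@featureDim != row$featureDim ||
      object@tapPoint != row$tapPoint)
    return("(name, inputSize, featureDim, tapPoint) must match the fixed backbone table")
  if (!(object@weights %in% c("random", "pretrained")))
    return("weights must be 'random' or 'pretrained'")
  if (length(object@meanRgb) != 3L)
    return("meanRgb must have 3 components")
  TRUE
})

#' Classifier specification (one of the eight benchmark classifiers)
#'
#' @slot name one of `"ANN"`, `"SVM"`, `"RF"`, `"DT"`, `"kNN"`, `"LR"`,
#'   `"LDA"`, `"GNB"`.
#' @slot params named list of hyperparameters, validated against a fixed
#'   per-classifier schema.
#' @slot seed integer seed controlling the stochastic learners.
#' @export
setClass("ClassifierSpec",
  representation(name = "character", params = "list", seed = "integer")
)

#' A built (untrained) classifier
#' @slot spec the validated [ClassifierSpec].
#' @slot scale logical; z-score standardization fitted on the training rows.
#' @export
setClass("BeakClassifier",
  representation(spec = "ClassifierSpec", scale = "logical")
)

#' A trained classifier
#' @slot spec the [ClassifierSpec] used.
#' @slot fit opaque fitted backend object.
#' @slot classes class labels in fixed order.
#' @slot center,scaling feature scaling statistics learned from the training
#'   rows only (length 0 when scaling is off).
#' @slot featureNames training feature names (width contract for prediction).
#' @export
setClass("TrainedBeakModel",
  representation(
    spec = "ClassifierSpec",
    fit = "ANY",
    classes = "character",
    center = "numeric",
    scaling = "numeric",
    featureNames = "character"
  )
)

#' Repeated stratified shuffle-split plan
#'
#' The evaluation protocol: per run, `folds` independent stratified 80/20
#' shuffle splits; repeated `runs` times. Per-class test counts are the
#' largest-remainder rounding of `classCount * testFraction` (ties broken by
#' class order), so every fold's per-class test proportion is within one
#' sample of the target fraction.
#'
#' @slot labels factor of sample labels the plan was built for.
#' @slot folds splits per run.
#' @slot runs number of repetitions.
#' @slot testFraction fraction of samples held out per split.
#' @slot baseSeed integer; fold f of run r is seeded `baseSeed + r*1000 + f`.
#' @slot splits list of `list(train=, test=)` integer index pairs, length
#'   `runs * folds`, run-major order.
#' @export
setClass("SplitPlan",
  representation(
    labels = "factor",
    folds = "integer",
    runs = "integer",
    testFraction = "numeric",
    baseSeed = "integer",
    splits = "list"
  )
)

#' Evaluation report
#'
#' @slot classifier,descriptor,view identifying strings.
#' @slot classes class labels (confusion matrix order).
#' @slot foldAccuracy accuracy of every fold (length runs x folds).
#' @slot confusion summed confusion matrix over all folds (rows = true,
#'   columns = predicted).
#' @slot foldConfusion list of per-fold confusion matrices.
#' @slot perClass data.frame with per-class precision, recall, prAuc
#'   (pooled over folds).
#' @slot prCurves list of per-class precision-recall curve data.frames.
#' @slot macroAuc macro-averaged precision-recall AUC.
#' @slot meanAccuracy,sdAccuracy accuracy mean and standard deviation over
#'   all folds x runs (proportions in [0, 1]).
#' @export
setClass("BeakEvalReport",
  representation(
    classifier = "character",
    descriptor = "character",
    view = "character",
    classes = "character",
    foldAccuracy = "numeric",
    confusion = "matrix",
    foldConfusion = "list",
    perClass = "data.frame",
    prCurves = "list",
    macroAuc = "numeric",
    meanAccuracy = "numeric",
    sdAccuracy = "numeric"
  )
)

#' Samples-by-features container
#'
#' A [SummarizedExperiment] with one assay `"features"` (rows = features,
#' columns = samples) and `label`, `view`, `path` columns in `colData`.
#' @export
setClass("BeakFeatureSet", contains = "SummarizedExperiment")

setValidity("BeakFeatureSet", function(object) {
  cd <- colData(object)
  if (!all(c("label", "view") %in% colnames(cd)))
    return("colData must contain 'label' and 'view'")
  if (!("features" %in% SummarizedExperiment::assayNames(object)))
    return("assay 'features' is required")
  TRUE
})

#' One pipeline run configuration
#'
#' @slot dataset a [BeakDatasetConfig] (synthetic source) or a single
#'   character path to a manifest CSV.
#' @slot view `"upper"` or `"lower"`; one view per run.
#' @slot descriptor one of `"gray_hog"`, `"colour_hog"`, `"msd"`,
#'   `"gray_hog+msd"`, `"colour_hog+msd"`, `"vgg19"`, `"inceptionv3"`,
#'   `"resnet50"`.
#' @slot classifier classifier name (see [ClassifierSpec]).
#' @slot runs,folds,testFraction evaluation protocol parameters.
#' @slot seed global seed fanned out to the generation, training and
#'   splitting stages by fixed offsets.
#' @slot outDir output directory for artifacts.
#' @export
setClass("BeakRunConfig",
  representation(
    dataset = "ANY",
    view = "character",
    descriptor = "character",
    classifier = "character",
    runs = "integer",
    folds = "integer",
    testFraction = "numeric",
    seed = "integer",
    outDir = "character"
  )
)

.descriptorNames <- c("gray_hog", "colour_hog", "msd",
                      "gray_hog+msd", "colour_hog+msd",
                      "vgg19", "inceptionv3", "resnet50")
.classifierNames <- c("ANN", "SVM", "RF", "DT", "kNN", "LR", "LDA", "GNB")

setValidity("BeakRunConfig", function(object) {
  msg <- character()
  if (!(is(object@dataset, "BeakDatasetConfig") ||
        (is.character(object@dataset) && length(object@dataset) == 1L)))
    msg <- c(msg, "dataset must be a BeakDatasetConfig or a manifest path")
  if (!(object@view %in% c("upper", "lower")))
    msg <- c(msg, "view must be 'upper' or 'lower'")
  if (!(object@descriptor %in% .descriptorNames))
    msg <- c(msg, sprintf("descriptor must be one of: %s",
                          paste(.descriptorNames, collapse = ", ")))
  if (!(object@classifier %in% .classifierNames))
    msg <- c(msg, sprintf("classifier must be one of: %s",
                          paste(.classifierNames, collapse = ", ")))
  if (object@testFraction <= 0 || object@testFraction >= 1)
    msg <- c(msg, "testFraction must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})
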