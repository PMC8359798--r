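#' Construct a backbone specification
#'
#' The (input size, feature dimension, tap point) triple is fixed per
#' backbone: vgg19 takes 224 x 224 inputs and emits the 4096-unit second
#' fully connected layer; inceptionv3 takes 299 x 299 and resnet50
#' 224 x 224, both emitting the 2048-unit global average pool. Pretrained
#' weights require an external download and cannot be instantiated offline;
#' only seeded random weights are available, which fix the dimensionality
#' and determinism contracts.
#'
#' @param name `"vgg19"`, `"inceptionv3"` or `"resnet50"`.
#' @param weights `"random"` (default) or `"pretrained"`.
#' @param weightsSeed integer seed for random-weight instantiation.
#' @return a [BackboneSpec].
#' @export
backboneSpec <- function(name, weights = c("random", "pretrained"),
                         weightsSeed = 1L) {
  weights <- match.arg(weights)
  row <- .backboneTable[.backboneTable$name == name, ]
  if (nrow(row) != 1L)
    stop(structure(class = c("beakid_unknown_backbone", "error", "condition"),
                   list(message = sprintf("unknown backbone '%s'", name),
                        call = sys.call())))
  means <- if (name == "inceptionv3") c(127.5, 127.5, 127.5)
           else c(123.68, 116.779, 103.939)   # ImageNet channel means (R, G, B)
  new("BackboneSpec", name = row$name, inputSize = row$inputSize,
      featureDim = row$featureDim, weights = weights, tapPoint = row$tapPoint,
      meanRgb = means, weightsSeed = as.integer(weightsSeed))
}

setMethod("show", "BackboneSpec", function(object) {
  cat(sprintf("BackboneSpec '%s': input %dx%d, %d features (tap %s), %s weights\n",
              object@name, object@inputSize, object@inputSize,
              object@featureDim, object@tapPoint, object@weights))
})

#' Preprocess an image for a backbone
#'
#' Bilinear resize to the backbone's square input size, then per-channel
#' mean-RGB subtraction (channel order R, G, B).
#'
#' @param img RGB array (package convention, 0--255).
#' @param spec a [BackboneSpec].
#' @return `inputSize x inputSize x 3` float array, mean-centred.
#' @export
backbonePreprocess <- function(img, spec) {
  stopifnot(is(spec, "BackboneSpec"))
  validObject(spec)
  s <- spec@inputSize
  d <- dim(img)
  if (d[1] != s || d[2] != s) {
    eb <- EBImage::Image(aperm(img, c(2, 1, 3)) / 255, colormode = "Color")
    out <- EBImage::resize(eb, w = s, h = s, filter = "bilinear")
    img <- aperm(EBImage::imageData(out), c(2, 1, 3)) * 255
  }
  for (ch in 1:3) img[, , ch] <- img[, , ch] - spec@meanRgb[ch]
  img
}

# strided valid convolution via patch extraction; x is (H, W, Cin),
# w is (k*k*Cin, Cout); returns (Ho, Wo, Cout)
.convStride <- function(x, w, k, stride) {
  H <- dim(x)[1]; W <- dim(x)[2]; cin <- dim(x)[3]
  ho <- (H - k) %/% stride + 1L
  wo <- (W - k) %/% stride + 1L
  oy <- (seq_len(ho) - 1L) * stride
  ox <- (seq_len(wo) - 1L) * stride
  cols <- matrix(0, ho * wo, k * k * cin)
  j <- 0L
  for (ch in seq_len(cin)) {
    for (ky in seq_len(k)) {
      for (kx in seq_len(k)) {
        j <- j + 1L
        cols[, j] <- as.vector(x[oy + ky, ox + kx, ch])
      }
    }
  }
  out <- cols %*% w
  array(out, c(ho, wo, ncol(w)))
}

.randomBackboneWeights <- function(spec) {
  oldseed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, envir = globalenv()))
  set.seed(spec@weightsSeed + match(spec@name, .backboneTable$name) * 131L)
  c1 <- 32L; c2 <- 64L
  list(
    w1 = matrix(rnorm(7 * 7 * 3 * c1, sd = sqrt(2 / (7 * 7 * 3))), 7 * 7 * 3, c1),
    w2 = matrix(rnorm(3 * 3 * c1 * c2, sd = sqrt(2 / (3 * 3 * c1))), 3 * 3 * c1, c2),
    wd = matrix(rnorm(c2 * spec@featureDim, sd = sqrt(1 / c2)), c2, spec@featureDim)
  )
}

.backboneForward <- function(prep, weights) {
  a1 <- .convStride(prep / 255, weights$w1, 7L, 4L)
  a1[a1 < 0] <- 0
  a2 <- .convStride(a1, weights$w2, 3L, 2L)
  a2[a2 < 0] <- 0
  gap <- apply(a2, 3, mean)
  as.vector(gap %*% weights$wd)
}

#' Extract deep features for every image in a manifest
#'
#' Runs each image through the backbone adapter (resize, mean subtraction,
#' seeded random convolutional stack, global average pool, dense projection
#' to the backbone's feature dimension). Rows follow manifest order; missing
#' image files are collected as per-record errors (attribute `errors`) and
#' the run continues.
#'
#' @param manifest data.frame with `path`, `label`, `view` columns.
#' @param spec a [BackboneSpec] with `weights = "random"`; requesting
#'   pretrained weights raises a "backbone unavailable" error.
#' @return a [BeakFeatureSet] with `featureDim` features per sample.
#' @export
extractDeepFeatures <- function(manifest, spec) {
  stopifnot(is(spec, "BackboneSpec"))
  validObject(spec)
  if (spec@weights == "pretrained")
    stop(structure(class = c("beakid_backbone_unavailable", "error", "condition"),
                   list(message = paste0("backbone unavailable: pretrained '",
                                         spec@name,
                                         "' weights require an external download; ",
                                         "use weights = 'random'"),
                        call = sys.call())))
  weights <- .randomBackboneWeights(spec)
  n <- nrow(manifest)
  feats <- matrix(NA_real_, n, spec@featureDim)
  errors <- list()
  for (i in seq_len(n)) {
    res <- tryCatch({
      img <- readBeakImage(manifest$path[i])
      prep <- backbonePreprocess(img, spec)
      .backboneForward(prep, weights)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[manifest$path[i]]] <- conditionMessage(res)
    } else {
      feats[i, ] <- res
    }
  }
  colnames(feats) <- sprintf("deep_%d", seq_len(spec@featureDim) - 1L)
  fs <- beakFeatureSet(feats, labels = manifest$label, view = manifest$view,
                       path = manifest$path, descriptor = spec@name)
  if (length(errors)) metadata(fs)$errors <- errors
  fs
}
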