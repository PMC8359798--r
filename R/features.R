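#' Construct a BeakFeatureSet
#'
#' @param features samples x features numeric matrix (column names used as
#'   feature names).
#' @param labels character/factor sample labels.
#' @param view beak view per sample (recycled if length 1).
#' @param path image path per sample (optional).
#' @param descriptor descriptor name stored in the metadata.
#' @return a [BeakFeatureSet] (features x samples assay).
#' @export
beakFeatureSet <- function(features, labels, view = "lower", path = NA_character_,
                           descriptor = "unknown") {
  features <- as.matrix(features)
  n <- nrow(features)
  if (is.null(colnames(features)))
    colnames(features) <- sprintf("f_%d", seq_len(ncol(features)) - 1L)
  cd <- DataFrame(label = as.character(labels),
                  view = rep_len(as.character(view), n),
                  path = rep_len(as.character(path), n))
  se <- SummarizedExperiment(assays = list(features = t(features)),
                             colData = cd)
  out <- new("BeakFeatureSet", se)
  metadata(out)$descriptor <- descriptor
  out
}

#' @describeIn beakFeatureSet samples x features matrix accessor.
#' @param x a [BeakFeatureSet].
#' @export
featureMatrix <- function(x) t(assay(x, "features"))

#' @describeIn beakFeatureSet sample label accessor (factor).
#' @export
sampleLabels <- function(x) factor(colData(x)$label)

setMethod("show", "BeakFeatureSet", function(object) {
  cat(sprintf("BeakFeatureSet: %d samples x %d features (descriptor '%s')\n",
              ncol(object), nrow(object),
              metadata(object)$descriptor %||% "unknown"))
  tab <- table(colData(object)$label)
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Segment the beak ROI contour from an image
#'
#' The preprocessing chain of the study protocol: optional rescale, Gaussian
#' smoothing, luma greyscale conversion, threshold segmentation and
#' largest-contour ROI selection.
#'
#' @param img RGB array.
#' @param rescaleFactor scale fraction (1 keeps the input resolution; 0.1
#'   is the protocol value for full-resolution camera originals).
#' @param sigma Gaussian smoothing standard deviation in pixels.
#' @param threshold segmentation grey level.
#' @param polarity `"dark"` (beak darker than lightbox) or `"bright"`.
#' @param minArea minimum ROI contour area in px^2.
#' @return list with `image` (preprocessed RGB), `gray`, `mask`, `contour`.
#' @export
segmentBeak <- function(img, rescaleFactor = 1, sigma = 1, threshold = 240,
                        polarity = "dark", minArea = 100) {
  if (rescaleFactor < 1) img <- rescaleImage(img, rescaleFactor)
  sm <- gaussianSmooth(img, sigma)
  gray <- rgbToGray(sm)
  mask <- binarize(gray, threshold, polarity)
  contour <- selectRoi(extractContours(mask), minArea)
  list(image = sm, gray = gray, mask = mask, contour = contour)
}

#' Extract a feature set for every image in a manifest
#'
#' Dispatches on the descriptor vocabulary: `"gray_hog"`, `"colour_hog"`,
#' `"msd"`, the hybrids `"gray_hog+msd"` / `"colour_hog+msd"`, and the deep
#' backbones `"vgg19"`, `"inceptionv3"`, `"resnet50"`.
#'
#' @param manifest data.frame with `path`, `label`, `view` columns.
#' @param descriptor descriptor name.
#' @param params a [HogParams] for the HOG-based descriptors.
#' @param rescaleFactor,sigma,threshold,polarity,minArea see [segmentBeak()].
#' @param standardMsd use the square-root equivalent-diameter form.
#' @param weightsSeed seed for random backbone weights.
#' @return a [BeakFeatureSet].
#' @export
extractFeatureSet <- function(manifest, descriptor, params = hogParams(),
                              rescaleFactor = 1, sigma = 1, threshold = 240,
                              polarity = "dark", minArea = 100,
                              standardMsd = FALSE, weightsSeed = 1L) {
  if (!(descriptor %in% .descriptorNames))
    stop(sprintf("unknown descriptor '%s'; must be one of: %s", descriptor,
                 paste(.descriptorNames, collapse = ", ")))
  if (descriptor %in% c("vgg19", "inceptionv3", "resnet50"))
    return(extractDeepFeatures(manifest,
                               backboneSpec(descriptor, weightsSeed = weightsSeed)))
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    img <- readBeakImage(manifest$path[i])
    seg <- segmentBeak(img, rescaleFactor, sigma, threshold, polarity, minArea)
    rows[[i]] <- switch(descriptor,
      "gray_hog" = {
        v <- hogDescriptor(seg$gray, params)
        setNames(v, sprintf("hog_%d", seq_along(v) - 1L))
      },
      "colour_hog" = {
        v <- colourHogDescriptor(seg$image, params)
        setNames(v, sprintf("hog_%d", seq_along(v) - 1L))
      },
      "msd" = msdFeatures(seg$contour, standard = standardMsd),
      "gray_hog+msd" = hybridConcat(hogDescriptor(seg$gray, params),
                                    msdFeatures(seg$contour, standard = standardMsd)),
      "colour_hog+msd" = hybridConcat(colourHogDescriptor(seg$image, params),
                                      msdFeatures(seg$contour, standard = standardMsd))
    )
  }
  feats <- do.call(rbind, rows)
  beakFeatureSet(feats, labels = manifest$label, view = manifest$view,
                 path = manifest$path, descriptor = descriptor)
}

#' Write a feature set as CSV (one row per image, label last)
#'
#' @param fs a [BeakFeatureSet].
#' @param path output CSV path.
#' @export
writeFeatureCsv <- function(fs, path) {
  df <- as.data.frame(featureMatrix(fs))
  df$label <- as.character(sampleLabels(fs))
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a feature CSV written by [writeFeatureCsv()]
#' @param path CSV path.
#' @param descriptor descriptor name stored in the metadata.
#' @return a [BeakFeatureSet].
#' @export
readFeatureCsv <- function(path, descriptor = "unknown") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  stopifnot("label" %in% colnames(df))
  labels <- df$label
  df$label <- NULL
  beakFeatureSet(as.matrix(df), labels = labels, descriptor = descriptor)
}
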