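#' Read an 8-bit RGB image (PNG or JPEG)
#'
#' Returns the package raster convention: a `height x width x 3` numeric
#' array on the 0--255 scale. Greyscale files are expanded to three equal
#' channels; an alpha channel, if present, is dropped.
#'
#' @param path image file path.
#' @return numeric array `height x width x 3`, values in [0, 255].
#' @export
readBeakImage <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  a <- if (ext %in% c("png")) {
    png::readPNG(path)
  } else {
    # EBImage handles JPEG; its Image is (x, y, c) in [0, 1]
    eb <- EBImage::readImage(path)
    d <- EBImage::imageData(eb)
    if (length(dim(d)) == 2L) t(d) else aperm(d, c(2, 1, 3))
  }
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  if (dim(a)[3] == 1L) a <- array(rep(a, 3), c(dim(a)[1:2], 3L))
  a * 255
}

#' Write an RGB image as PNG
#' @param img `height x width x 3` array, 0--255.
#' @param path output path.
#' @export
writeBeakImage <- function(img, path) {
  png::writePNG(pmin(pmax(img / 255, 0), 1), path)
}

.roundHalfUp <- function(x) floor(x + 0.5)

#' Rescale an image by a fraction
#'
#' Bilinear interpolation; each output dimension is
#' `round-half-up(dimension * factor)`, minimum 1 pixel. The study protocol
#' downscales 5312 x 2988 camera originals to 10% (approximately 531 x 299).
#'
#' @param img grey matrix or RGB array (package convention).
#' @param factor scale fraction in (0, 1].
#' @return rescaled image of the same kind.
#' @export
rescaleImage <- function(img, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0 || factor > 1)
    stop("factor must be a single value in (0, 1]")
  d <- dim(img)
  H <- d[1]; W <- d[2]
  nH <- max(1L, as.integer(.roundHalfUp(H * factor)))
  nW <- max(1L, as.integer(.roundHalfUp(W * factor)))
  if (nH == H && nW == W) return(img)
  if (length(d) == 2L) {
    eb <- EBImage::Image(t(img) / 255)
    out <- EBImage::resize(eb, w = nW, h = nH, filter = "bilinear")
    t(EBImage::imageData(out)) * 255
  } else {
    eb <- EBImage::Image(aperm(img, c(2, 1, 3)) / 255, colormode = "Color")
    out <- EBImage::resize(eb, w = nW, h = nH, filter = "bilinear")
    aperm(EBImage::imageData(out), c(2, 1, 3)) * 255
  }
}

.gaussKernel1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

.padReplicate <- function(m, r) {
  H <- nrow(m); W <- ncol(m)
  m <- m[c(rep(1L, r), seq_len(H), rep(H, r)), , drop = FALSE]
  m[, c(rep(1L, r), seq_len(W), rep(W, r)), drop = FALSE]
}

.convSep <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  p <- .padReplicate(m, r)
  # horizontal pass
  acc <- matrix(0, H + 2L * r, W)
  for (i in seq_along(k))
    acc <- acc + k[i] * p[, i:(i + W - 1L), drop = FALSE]
  # vertical pass
  out <- matrix(0, H, W)
  for (i in seq_along(k))
    out <- out + k[i] * acc[i:(i + H - 1L), , drop = FALSE]
  out
}

#' Gaussian smoothing
#'
#' Separable convolution with a normalized Gaussian kernel of radius
#' `ceiling(3 * sigma)`, replicate borders. `sigma = 0` returns the input
#' unchanged; constants are preserved exactly up to the kernel normalization.
#'
#' @param img grey matrix or RGB array.
#' @param sigma kernel standard deviation in pixels (>= 0).
#' @return smoothed image of the same kind and dimensions.
#' @export
gaussianSmooth <- function(img, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("sigma must be a single value >= 0")
  if (sigma == 0) return(img)
  k <- .gaussKernel1d(sigma)
  if (length(dim(img)) == 2L || is.null(dim(img))) {
    .convSep(as.matrix(img), k)
  } else {
    out <- img
    for (ch in seq_len(dim(img)[3])) out[, , ch] <- .convSep(img[, , ch], k)
    out
  }
}

#' Convert RGB to grey by the luma transform
#'
#' `Y = 0.299 R + 0.587 G + 0.114 B`, computed in floating point and not
#' re-quantized.
#'
#' @param img `height x width x 3` RGB array, 0--255.
#' @return `height x width` grey matrix with fractional values in [0, 255].
#' @export
rgbToGray <- function(img) {
  if (length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("img must be a height x width x 3 RGB array")
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Threshold a grey image into a binary mask
#'
#' With `polarity = "bright"` (the rule as printed in the study protocol)
#' pixels with `Y >= threshold` form the object and 0--(threshold-1) the
#' background. With `polarity = "dark"` (a dark beak on a white lightbox,
#' the default for real and synthetic photographs) the object is
#' `Y < threshold`.
#'
#' @param gray grey matrix, values in [0, 255].
#' @param threshold grey level in [0, 255]; default 240.
#' @param polarity `"dark"` or `"bright"`.
#' @return logical `height x width` mask, `TRUE` = object.
#' @export
binarize <- function(gray, threshold = 240, polarity = c("dark", "bright")) {
  polarity <- match.arg(polarity)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 255)
    stop("threshold must be a single grey level in [0, 255]")
  if (polarity == "bright") gray >= threshold else gray < threshold
}
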