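#' Convex hull of a contour
#'
#' @param contour `n x 2` matrix of (x, y) points.
#' @return `m x 2` matrix of hull vertices in order (a convex polygon
#'   containing all input points). Collinear input raises a degenerate-hull
#'   error.
#' @export
convexHull <- function(contour) {
  if (nrow(contour) < 3L)
    stop("convex hull requires at least 3 points")
  idx <- grDevices::chull(contour[, 1], contour[, 2])
  if (length(idx) < 3L)
    stop(structure(class = c("beakid_degenerate_hull", "error", "condition"),
                   list(message = "degenerate hull: input points are collinear",
                        call = sys.call())))
  contour[idx, , drop = FALSE]
}

.msdNames <- c("area", "perimeter", "aspect_ratio", "extent", "solidity",
               "equivalent_diameter", "circularity", "rectangularity",
               "form_factor", "narrow_factor")

#' Ten morphological shape descriptors of the beak contour
#'
#' Computed on the contour polygon (sub-pixel geometry, shoelace area,
#' polygon arc-length perimeter, axis-aligned bounding box):
#' \describe{
#'   \item{area}{beak size, shoelace area in px^2.}
#'   \item{perimeter}{closed contour arc length in px.}
#'   \item{aspect_ratio}{bounding-box width / height.}
#'   \item{extent}{area / bounding-box area.}
#'   \item{solidity}{area / convex-hull area.}
#'   \item{equivalent_diameter}{`(4 * area) / pi` — the protocol's printed
#'     form, which carries px^2 units; `standard = TRUE` switches to the
#'     conventional `sqrt((4 * area) / pi)`.}
#'   \item{circularity}{`(4 * pi * area) / convexPerimeter^2`.}
#'   \item{rectangularity}{`(w * h) / boundingBoxArea` (identically 1 for
#'     the axis-aligned box; kept for fidelity to the descriptor table).}
#'   \item{form_factor}{`(4 * pi * area) / perimeter^2`; 1 for a circle.}
#'   \item{narrow_factor}{equivalent_diameter / bounding-box height.}
#' }
#'
#' @param contour `n x 2` matrix of (x, y) vertices of the beak ROI.
#' @param standard use the square-root equivalent-diameter form (affects
#'   `narrow_factor` too).
#' @return named numeric vector of length 10.
#' @export
msdFeatures <- function(contour, standard = FALSE) {
  if (!is.matrix(contour) || ncol(contour) != 2L || nrow(contour) < 3L)
    stop("contour must be an n x 2 matrix with n >= 3")
  area <- contourArea(contour)
  if (area <= 0) stop("degenerate contour: zero area")
  perim <- contourPerimeter(contour)
  w <- max(contour[, 1]) - min(contour[, 1])
  h <- max(contour[, 2]) - min(contour[, 2])
  if (w <= 0 || h <= 0) stop("degenerate contour: zero-extent bounding box")
  bboxArea <- w * h
  hull <- convexHull(contour)
  hullArea <- contourArea(hull)
  hullPerim <- contourPerimeter(hull)
  eqd <- (4 * area) / pi
  if (standard) eqd <- sqrt(eqd)
  setNames(c(
    area,
    perim,
    w / h,
    area / bboxArea,
    area / hullArea,
    eqd,
    (4 * pi * area) / hullPerim^2,
    (w * h) / bboxArea,
    (4 * pi * area) / perim^2,
    eqd / h
  ), .msdNames)
}

#' Concatenate a HOG descriptor with the MSD vector
#'
#' Order is HOG block first, then the ten shape descriptors; at the study
#' geometry the hybrid vector has 108 + 10 = 118 features.
#'
#' @param hog numeric HOG descriptor.
#' @param msd named MSD vector from [msdFeatures()].
#' @return numeric vector of length `length(hog) + 10`.
#' @export
hybridConcat <- function(hog, msd) {
  stopifnot(length(msd) == 10L)
  out <- c(hog, msd)
  names(out) <- c(sprintf("hog_%d", seq_along(hog) - 1L), .msdNames)
  out
}
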