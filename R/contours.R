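# Connected components (8-connected object pixels), Moore boundary tracing
# and scanline fill. Object pixels are 8-connected and background pixels
# 4-connected, the standard pairing for contour tracing.

#' Label 8-connected components of a binary mask
#'
#' @param mask logical matrix, `TRUE` = object.
#' @return integer matrix of the same dimensions; 0 = background, components
#'   numbered 1..n.
#' @export
labelComponents <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  lab <- EBImage::imageData(EBImage::bwlabel(mask * 1L))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  # bwlabel is 4-connected; merge labels touching diagonally (union-find)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  H <- nrow(lab); W <- ncol(lab)
  a1 <- lab[-H, -W]; b1 <- lab[-1, -1]     # \ diagonal
  a2 <- lab[-H, -1]; b2 <- lab[-1, -W]     # / diagonal
  pairs <- rbind(cbind(a1[a1 > 0 & b1 > 0 & a1 != b1], b1[a1 > 0 & b1 > 0 & a1 != b1]),
                 cbind(a2[a2 > 0 & b2 > 0 & a2 != b2], b2[a2 > 0 & b2 > 0 & a2 != b2]))
  if (nrow(pairs)) {
    for (i in seq_len(nrow(pairs))) {
      ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  lab[lab > 0] <- relab[lab[lab > 0]]
  lab
}

# Moore-neighbour tracing with Jacob's stopping criterion.
# Returns an n x 2 matrix of 0-based (x, y) boundary pixel centres,
# ordered clockwise in image coordinates (x right, y down); the first and
# last points are 8-adjacent (closed contour, endpoint not repeated).
.traceBoundary <- function(member) {
  H <- nrow(member); W <- ncol(member)
  # pad by 1 so neighbour lookups never leave the matrix
  m <- matrix(FALSE, H + 2L, W + 2L)
  m[2:(H + 1L), 2:(W + 1L)] <- member
  # start: topmost then leftmost object pixel (row-major scan in y, then x)
  idx <- which(t(m))                       # t(): scan rows (y) outer, x inner
  if (!length(idx)) return(matrix(numeric(0), 0, 2))
  first <- idx[1]
  sy <- (first - 1L) %/% (W + 2L) + 1L
  sx <- (first - 1L) %% (W + 2L) + 1L
  # clockwise Moore neighbourhood in image coords, starting west
  dx <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  dy <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  if (sum(m) == 1L) return(cbind(sx - 2L, sy - 2L))
  pts <- matrix(0L, 4L * (H * W), 2L)
  np <- 0L
  cxp <- sx; cyp <- sy
  dir <- 1L                                # backtrack points west initially
  startDir <- NA_integer_
  repeat {
    found <- FALSE
    for (i in 0:7) {
      d <- ((dir - 1L + i) %% 8L) + 1L
      nx <- cxp + dx[d]; ny <- cyp + dy[d]
      if (m[ny, nx]) {
        np <- np + 1L
        pts[np, ] <- c(cxp, cyp)
        # terminate on re-entering the start pixel in the starting direction
        if (np > 1L && cxp == sx && cyp == sy && d == startDir) {
          np <- np - 1L
          return(cbind(pts[seq_len(np), 1] - 2L, pts[seq_len(np), 2] - 2L))
        }
        if (np == 1L) startDir <- d
        cxp <- nx; cyp <- ny
        dir <- ((d - 1L + 6L) %% 8L) + 1L  # new search start: backtrack + 1
        found <- TRUE
        break
      }
    }
    if (!found) {                          # isolated pixel
      return(cbind(sx - 2L, sy - 2L))
    }
    if (np >= nrow(pts)) stop("boundary tracing failed to terminate")
  }
}

#' Extract closed outer contours from a binary mask
#'
#' One clockwise (image coordinates: x right, y down) closed outer contour
#' per 8-connected component of object pixels. Coordinates are 0-based
#' pixel centres; the first and last points are adjacent.
#'
#' @param mask logical matrix, `TRUE` = object.
#' @return list of `n x 2` matrices `(x, y)`; an empty mask yields an empty
#'   list.
#' @export
extractContours <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  lab <- labelComponents(mask)
  n <- max(lab)
  if (n == 0L) return(list())
  out <- vector("list", n)
  for (comp in seq_len(n)) {
    pts <- .traceBoundary(lab == comp)
    # normalize orientation to clockwise in image coords (positive shoelace
    # sum with y downward)
    if (nrow(pts) >= 3L && .signedArea(pts) < 0) pts <- pts[rev(seq_len(nrow(pts))), ]
    out[[comp]] <- pts
  }
  out
}

.signedArea <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

#' Polygon area by the shoelace formula
#' @param contour `n x 2` matrix of (x, y) vertices (closed implicitly).
#' @return non-negative area in px^2.
#' @export
contourArea <- function(contour) abs(.signedArea(contour))

#' Polygon perimeter (closed arc length)
#' @param contour `n x 2` matrix of (x, y) vertices.
#' @return total edge length including the closing edge.
#' @export
contourPerimeter <- function(contour) {
  x <- contour[, 1]; y <- contour[, 2]
  sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
}

#' Select the beak region of interest among contours
#'
#' Returns the largest-area contour (shoelace area) among those with area
#' at least `minArea`; raises a "no ROI found" condition when none passes.
#'
#' @param contours list of contours from [extractContours()].
#' @param minArea minimum area in px^2.
#' @return the selected contour matrix.
#' @export
selectRoi <- function(contours, minArea = 100) {
  areas <- vapply(contours, function(ct)
    if (nrow(ct) >= 3L) contourArea(ct) else 0, numeric(1))
  keep <- which(areas >= minArea)
  if (!length(keep))
    stop(structure(class = c("beakid_no_roi", "error", "condition"),
                   list(message = sprintf(
                     "no ROI found: no contour with area >= %g (largest was %g)",
                     minArea, if (length(areas)) max(areas) else 0),
                     call = sys.call())))
  contours[[keep[which.max(areas[keep])]]]
}

#' Fill a closed contour back into a pixel mask
#'
#' Scanline even-odd fill over pixel centres, united with the contour pixels
#' themselves. On a contour traced from a simply-connected component this
#' reproduces the component exactly.
#'
#' @param contour `n x 2` matrix of 0-based (x, y) boundary pixel centres.
#' @param dim `c(height, width)` of the target mask.
#' @return logical matrix.
#' @export
fillContour <- function(contour, dim) {
  H <- dim[1]; W <- dim[2]
  mask <- matrix(FALSE, H, W)
  n <- nrow(contour)
  if (n == 0L) return(mask)
  mask[cbind(contour[, 2] + 1L, contour[, 1] + 1L)] <- TRUE
  if (n < 3L) return(mask)
  x <- contour[, 1]; y <- contour[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  for (row in min(y):max(y)) {
    crosses <- (y > row) != (y2 > row)
    if (!any(crosses)) next
    xi <- x[crosses] + (row - y[crosses]) * (x2[crosses] - x[crosses]) /
      (y2[crosses] - y[crosses])
    xi <- sort(xi)
    for (i in seq(1, length(xi) - 1, by = 2)) {
      a <- ceiling(xi[i]); b <- floor(xi[i + 1])
      if (b >= a) mask[row + 1L, (a:b) + 1L] <- TRUE
    }
  }
  mask
}
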