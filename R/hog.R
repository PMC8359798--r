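#' Construct HOG geometry parameters
#'
#' Defaults follow the study geometry: 128 x 128 px cells, nine unsigned
#' orientation bins with centres 0, 20, ..., 160 degrees, 2 x 2-cell blocks
#' sliding with stride one cell. On a 532 x 299 image this yields a 4 x 2
#' cell grid, 3 blocks and a 108-feature descriptor.
#'
#' @param cellSize cell side in pixels.
#' @param bins number of orientation bins over 180 degrees.
#' @param blockSize block side in cells.
#' @param blockStride block stride in cells.
#' @param asPrinted use the arctan(Gx/Gy) orientation ratio instead of the
#'   standard arctan(Gy/Gx).
#' @param interpolation `"linear"` or `"hard"` vote assignment.
#' @return a [HogParams] object.
#' @export
hogParams <- function(cellSize = 128L, bins = 9L, blockSize = 2L,
                      blockStride = 1L, asPrinted = FALSE,
                      interpolation = c("linear", "hard")) {
  interpolation <- match.arg(interpolation)
  new("HogParams", cellSize = as.integer(cellSize), bins = as.integer(bins),
      blockSize = as.integer(blockSize), blockStride = as.integer(blockStride),
      asPrinted = asPrinted, interpolation = interpolation)
}

setMethod("show", "HogParams", function(object) {
  cat(sprintf("HogParams: cell %d px, %d bins over 180deg, %dx%d-cell blocks, stride %d%s\n",
              object@cellSize, object@bins, object@blockSize, object@blockSize,
              object@blockStride,
              if (object@asPrinted) " (as-printed orientation)" else ""))
})

#' Image gradients, magnitude and unsigned orientation
#'
#' Centred differences with kernel (-1, 0, 1) horizontally for `Gx` and
#' vertically for `Gy`, replicate borders. Magnitude is
#' `sqrt(Gx^2 + Gy^2)`; orientation is the unsigned angle of the gradient
#' vector folded to [0, 180) degrees (standard `atan2(Gy, Gx)` by default;
#' `asPrinted = TRUE` uses the transposed `atan2(Gx, Gy)` ratio). Zero
#' gradients are assigned orientation 0.
#'
#' @param gray grey matrix, at least 3 x 3.
#' @param asPrinted orientation ratio convention (see above).
#' @return list with matrices `gx`, `gy`, `magnitude`, `orientation`
#'   (degrees in [0, 180)).
#' @export
imageGradients <- function(gray, asPrinted = FALSE) {
  gray <- as.matrix(gray)
  H <- nrow(gray); W <- ncol(gray)
  if (H < 3L || W < 3L) stop("image must be at least 3 x 3 pixels")
  right <- gray[, c(2:W, W)]; left <- gray[, c(1, 1:(W - 1))]
  down <- gray[c(2:H, H), ]; up <- gray[c(1, 1:(H - 1)), ]
  gx <- right - left
  gy <- down - up
  mag <- sqrt(gx^2 + gy^2)
  theta <- if (asPrinted) atan2(gx, gy) else atan2(gy, gx)
  theta <- (theta * 180 / pi) %% 180
  theta[mag == 0] <- 0
  list(gx = gx, gy = gy, magnitude = mag, orientation = theta)
}

#' Per-cell orientation histograms
#'
#' The image is partitioned into `floor(W/cell) x floor(H/cell)` full cells
#' (partial edge cells are dropped). Every pixel votes its gradient
#' magnitude, split linearly between the two nearest bin centres (circular
#' over 180 degrees), or assigned to the nearest bin when
#' `interpolation = "hard"`.
#'
#' @param field gradient field from [imageGradients()].
#' @param params a [HogParams].
#' @return array of dimension `c(cellsY, cellsX, bins)`.
#' @export
cellHistograms <- function(field, params = hogParams()) {
  validObject(params)
  mag <- field$magnitude; theta <- field$orientation
  H <- nrow(mag); W <- ncol(mag)
  cs <- params@cellSize; nb <- params@bins
  nx <- W %/% cs; ny <- H %/% cs
  if (nx < 1L || ny < 1L)
    stop("image smaller than one cell (", cs, " px)")
  keepY <- seq_len(ny * cs); keepX <- seq_len(nx * cs)
  mag <- mag[keepY, keepX]; theta <- theta[keepY, keepX]
  cellY <- (row(mag) - 1L) %/% cs          # 0-based cell row
  cellX <- (col(mag) - 1L) %/% cs
  cellIdx <- cellY + ny * cellX            # 0-based cell id, column-major
  binW <- 180 / nb
  t <- theta / binW
  b0 <- floor(t) %% nb
  frac <- t - floor(t)
  hist <- numeric(ny * nx * nb)
  if (params@interpolation == "linear") {
    idx0 <- cellIdx * nb + b0 + 1
    idx1 <- cellIdx * nb + ((b0 + 1) %% nb) + 1
    acc <- rowsum(c(as.vector((1 - frac) * mag), as.vector(frac * mag)),
                  group = c(as.vector(idx0), as.vector(idx1)))
    hist[as.integer(rownames(acc))] <- acc[, 1]
  } else {
    bn <- round(t) %% nb
    idx <- cellIdx * nb + bn + 1
    acc <- rowsum(as.vector(mag), group = as.vector(idx))
    hist[as.integer(rownames(acc))] <- acc[, 1]
  }
  # hist is laid out bins-fastest, then cellY, then cellX
  aperm(array(hist, c(nb, ny, nx)), c(2, 3, 1))
}

#' Number of cells and blocks for a given image size
#'
#' @param width,height image dimensions in pixels.
#' @param params a [HogParams].
#' @return list with `cells` (`c(x, y)` counts), `blocks` (`c(x, y)`
#'   positions), `nBlocks` and `length` (descriptor length).
#' @export
hogGeometry <- function(width, height, params = hogParams()) {
  nx <- width %/% params@cellSize; ny <- height %/% params@cellSize
  bs <- params@blockSize; st <- params@blockStride
  bx <- if (nx >= bs) (nx - bs) %/% st + 1L else 0L
  by <- if (ny >= bs) (ny - bs) %/% st + 1L else 0L
  list(cells = c(x = nx, y = ny), blocks = c(x = bx, y = by),
       nBlocks = bx * by, length = bx * by * bs * bs * params@bins)
}

#' Grey HOG descriptor
#'
#' Blocks of `blockSize x blockSize` cells slide with `blockStride`; each
#' block's concatenated cell histograms are L2-normalized (all-zero blocks
#' pass through as zeros). Concatenation is row-major over blocks (block
#' rows, then columns), then cells within the block (row-major), then bins.
#' At the study geometry (532 x 299 image, 128-px cells, 9 bins) the
#' descriptor has 3 blocks x 36 = 108 features.
#'
#' @param gray grey matrix.
#' @param params a [HogParams].
#' @return numeric descriptor vector.
#' @export
hogDescriptor <- function(gray, params = hogParams()) {
  field <- imageGradients(gray, asPrinted = params@asPrinted)
  hists <- cellHistograms(field, params)
  .blocksFromCells(hists, params)
}

.blocksFromCells <- function(hists, params) {
  ny <- dim(hists)[1]; nx <- dim(hists)[2]; nb <- dim(hists)[3]
  bs <- params@blockSize; st <- params@blockStride
  if (nx < bs || ny < bs)
    stop("cell grid (", nx, " x ", ny, ") smaller than a block (", bs, " cells)")
  out <- numeric(0)
  blocks <- vector("list", ((ny - bs) %/% st + 1L) * ((nx - bs) %/% st + 1L))
  k <- 0L
  for (by in seq(1L, ny - bs + 1L, by = st)) {
    for (bx in seq(1L, nx - bs + 1L, by = st)) {
      v <- numeric(bs * bs * nb)
      j <- 0L
      for (cy in by:(by + bs - 1L)) {
        for (cx in bx:(bx + bs - 1L)) {
          v[j + seq_len(nb)] <- hists[cy, cx, ]
          j <- j + nb
        }
      }
      nrm <- sqrt(sum(v^2))
      if (nrm > 0) v <- v / nrm
      k <- k + 1L
      blocks[[k]] <- v
    }
  }
  unlist(blocks, use.names = FALSE)
}

#' Colour HOG descriptor
#'
#' Gradients are computed per RGB channel; at each pixel the channel with
#' the largest gradient magnitude supplies the (magnitude, orientation)
#' pair. Geometry and normalization are identical to [hogDescriptor()], so
#' the descriptor length equals the grey HOG length (108 at the study
#' geometry).
#'
#' @param img RGB array.
#' @param params a [HogParams].
#' @return numeric descriptor vector.
#' @export
colourHogDescriptor <- function(img, params = hogParams()) {
  if (length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("img must be a height x width x 3 RGB array")
  f1 <- imageGradients(img[, , 1], asPrinted = params@asPrinted)
  f2 <- imageGradients(img[, , 2], asPrinted = params@asPrinted)
  f3 <- imageGradients(img[, , 3], asPrinted = params@asPrinted)
  mag <- pmax(f1$magnitude, f2$magnitude, f3$magnitude)
  theta <- f1$orientation
  pick2 <- f2$magnitude >= f1$magnitude & f2$magnitude >= f3$magnitude
  theta[pick2] <- f2$orientation[pick2]
  pick3 <- f3$magnitude >= f1$magnitude & f3$magnitude >= f2$magnitude & !pick2
  theta[pick3] <- f3$orientation[pick3]
  hists <- cellHistograms(list(magnitude = mag, orientation = theta), params)
  .blocksFromCells(hists, params)
}
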