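test_that("gradient magnitude and orientation follow the centred-difference definition", {
  # 3-4-5 triangle at one pixel: ramp with slope 1.5 in x and 2 in y gives
  # Gx = 3, Gy = 4 under the (-1, 0, 1) kernel
  img <- outer(seq_len(5) * 2, seq_len(5) * 1.5, `+`)
  f <- imageGradients(img)
  expect_equal(f$gx[3, 3], 3)
  expect_equal(f$gy[3, 3], 4)
  expect_equal(f$magnitude[3, 3], 5)
  # constant image: all magnitudes 0, orientation forced to 0
  fc <- imageGradients(matrix(4, 6, 6))
  expect_true(all(fc$magnitude == 0))
  expect_true(all(fc$orientation == 0))
  # vertical step edge: purely horizontal gradient, orientation 0
  step <- cbind(matrix(0, 6, 3), matrix(100, 6, 3))
  fs <- imageGradients(step)
  edge <- fs$magnitude[, 3] > 0
  expect_true(all(fs$orientation[, 3][edge] == 0))
  expect_error(imageGradients(matrix(0, 2, 5)), "3 x 3")
})

test_that("the as-printed orientation convention swaps the gradient ratio", {
  img <- matrix(runif(100, 0, 255), 10, 10)
  std <- imageGradients(img, asPrinted = FALSE)
  prt <- imageGradients(img, asPrinted = TRUE)
  i <- which(std$magnitude > 1e-6 & std$gy != 0 & std$gx != 0)[1]
  expect_equal(prt$orientation[i],
               (atan2(std$gx[i], std$gy[i]) * 180 / pi) %% 180)
  expect_false(isTRUE(all.equal(std$orientation[i], prt$orientation[i])))
})

test_that("cell partition drops partial cells and votes split linearly between bins", {
  p <- hogParams()
  g <- hogGeometry(532, 299, p)
  expect_equal(unname(g$cells), c(4L, 2L))
  # all gradients at a bin centre: no interpolation leakage
  field <- list(magnitude = matrix(2, 16, 16),
                orientation = matrix(40, 16, 16))
  h <- cellHistograms(field, hogParams(cellSize = 16L))
  expect_equal(h[1, 1, 3], 2 * 256)
  expect_true(all(h[1, 1, -3] == 0))
  # orientation 30 with magnitude 10: 5 to bin 20 and 5 to bin 40
  field1 <- list(magnitude = matrix(c(10, rep(0, 15)), 4, 4),
                 orientation = matrix(c(30, rep(0, 15)), 4, 4))
  h1 <- cellHistograms(field1, hogParams(cellSize = 4L))
  expect_equal(h1[1, 1, 2], 5)
  expect_equal(h1[1, 1, 3], 5)
  expect_equal(sum(h1[1, 1, ]), 10)
  expect_error(cellHistograms(field, hogParams(cellSize = 64L)), "smaller")
})

test_that("vote splitting conserves total gradient mass within retained cells", {
  set.seed(4)
  img <- matrix(runif(48 * 80, 0, 255), 48, 80)
  f <- imageGradients(img)
  p <- hogParams(cellSize = 16L)
  h <- cellHistograms(f, p)
  keep <- f$magnitude[1:48, 1:80]
  expect_equal(sum(h), sum(keep))
})

test_that("descriptor length follows the block-count formula", {
  expect_length(hogDescriptor(matrix(runif(299 * 532, 0, 255), 299, 532)), 108L)
  expect_length(hogDescriptor(matrix(runif(256 * 640, 0, 255), 256, 640)), 144L)
  # property over random sizes: len = (floor(W/c)-1)(floor(H/c)-1) * 36
  set.seed(7)
  for (i in 1:5) {
    c0 <- sample(8:16, 1)
    W <- sample((2 * c0):(5 * c0), 1); H <- sample((2 * c0):(5 * c0), 1)
    v <- hogDescriptor(matrix(runif(H * W, 0, 255), H, W),
                       hogParams(cellSize = c0))
    expect_length(v, (W %/% c0 - 1) * (H %/% c0 - 1) * 36)
  }
  # constant image: zero-norm blocks pass through as zeros
  expect_identical(hogDescriptor(matrix(3, 299, 532)), rep(0, 108))
})

test_that("block sub-vectors are L2-normalized or all-zero, never negative", {
  set.seed(5)
  v <- hogDescriptor(matrix(runif(64 * 64, 0, 255), 64, 64),
                     hogParams(cellSize = 16L))
  expect_true(all(v >= 0))
  for (b in seq_len(length(v) / 36)) {
    nrm <- sqrt(sum(v[(b - 1) * 36 + 1:36]^2))
    expect_true(abs(nrm - 1) < 1e-9 || nrm == 0)
  }
})

test_that("the vectorized descriptor matches a naive per-pixel oracle", {
  set.seed(12)
  for (i in 1:3) {
    H <- sample(40:64, 1); W <- sample(40:64, 1)
    img <- matrix(runif(H * W, 0, 255), H, W)
    fast <- hogDescriptor(img, hogParams(cellSize = 16L))
    slow <- naiveHog(img, cell = 16L)
    expect_equal(fast, slow, tolerance = 1e-9)
  }
})

test_that("colour HOG reduces to grey HOG on achromatic images and keeps the grey length", {
  set.seed(9)
  ch <- matrix(runif(299 * 532, 0, 255), 299, 532)
  img <- array(rep(ch, 3), c(299, 532, 3))
  expect_equal(colourHogDescriptor(img), hogDescriptor(ch))
  expect_length(colourHogDescriptor(img), 108L)
  const <- array(120, c(299, 532, 3))
  expect_identical(colourHogDescriptor(const), rep(0, 108))
})

test_that("unsigned orientation histograms are invariant under 180-degree rotation of a centred disc", {
  n <- 65L
  xs <- matrix(rep(0:(n - 1), each = n), n, n)
  ys <- matrix(rep(0:(n - 1), times = n), n, n)
  disc <- 255 * ((xs - 32)^2 + (ys - 32)^2 <= 20^2)
  rot <- disc[n:1, n:1]
  p <- hogParams(cellSize = 16L)
  h1 <- cellHistograms(imageGradients(disc), p)
  h2 <- cellHistograms(imageGradients(rot), p)
  expect_equal(apply(h1, 3, sum), apply(h2, 3, sum), tolerance = 1e-9)
})
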