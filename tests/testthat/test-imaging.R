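test_that("rescale rounds target dimensions half-up and is identity at factor 1", {
  img <- array(runif(60 * 40 * 3, 0, 255), c(40, 60, 3))
  expect_identical(dim(rescaleImage(img, 1)), dim(img))
  small <- rescaleImage(img, 0.1)
  expect_equal(dim(small)[1:2], c(4L, 6L))
  # the study's camera resolution: 2988 -> 299, 5312 -> 531 (round(531.2))
  tall <- matrix(0, 2988, 4)
  expect_equal(nrow(rescaleImage(tall, 0.1)), 299L)
  wide <- matrix(0, 4, 5312)
  expect_equal(ncol(rescaleImage(wide, 0.1)), 531L)
  expect_error(rescaleImage(img, 0), "factor")
  expect_error(rescaleImage(img, -0.5), "factor")
})

test_that("gaussian smoothing preserves constants, is identity at sigma 0, and matches the kernel centre weight", {
  const <- matrix(7.5, 20, 30)
  expect_equal(gaussianSmooth(const, 2), const)
  img <- matrix(runif(200, 0, 255), 10, 20)
  expect_identical(gaussianSmooth(img, 0), img)
  expect_error(gaussianSmooth(img, -1), "sigma")
  # single bright pixel: centre response = centre weight^2 (separable kernel)
  sigma <- 1
  imp <- matrix(0, 21, 21); imp[11, 11] <- 100
  k <- dnorm(seq(-3, 3), sd = sigma); k <- k / sum(k)
  expect_equal(gaussianSmooth(imp, sigma)[11, 11], 100 * k[4]^2)
})

test_that("the luma transform matches its coefficients and is channel-order sensitive", {
  px <- function(r, g, b) array(c(r, g, b), c(1, 1, 3))
  expect_equal(as.numeric(rgbToGray(px(255, 255, 255))), 255)
  expect_equal(as.numeric(rgbToGray(px(0, 0, 0))), 0)
  expect_equal(as.numeric(rgbToGray(px(100, 150, 200))), 140.75)
  # swapping R and B changes Y unless R = B
  expect_false(as.numeric(rgbToGray(px(200, 150, 100))) ==
                 as.numeric(rgbToGray(px(100, 150, 200))))
})

test_that("binarize follows the printed threshold rule in both polarities", {
  gray <- matrix(c(0, 239, 240, 255), 2, 2)
  bright <- binarize(gray, 240, "bright")
  expect_identical(as.vector(bright), c(FALSE, FALSE, TRUE, TRUE))
  dark <- binarize(gray, 240, "dark")
  expect_identical(as.vector(dark), c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(binarize(matrix(0, 3, 3), 240, "bright"),
                   matrix(FALSE, 3, 3))
  expect_error(binarize(gray, 300), "threshold")
})

test_that("threshold-240 segmentation recovers synthetic ground truth exactly", {
  for (s in twoSpecies()) {
    g <- generateBeakImage(s, "lower", seed = 5, imageSize = c(180L, 130L))
    mask <- binarize(rgbToGray(g$image), 240, "dark")
    expect_identical(mask, g$mask)
  }
})

test_that("contour extraction finds one closed clockwise contour per component", {
  m <- matrix(FALSE, 20, 30)
  m[5:10, 5:12] <- TRUE
  m[14:17, 20:26] <- TRUE
  cts <- extractContours(m)
  expect_length(cts, 2L)
  for (ct in cts) {
    # closed: first and last points 8-adjacent
    d <- abs(ct[1, ] - ct[nrow(ct), ])
    expect_true(all(d <= 1))
    # clockwise in image coordinates: positive shoelace sum with y down
    x <- ct[, 1]; y <- ct[, 2]
    expect_gt(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2, 0)
  }
  expect_identical(extractContours(matrix(FALSE, 5, 5)), list())
})

test_that("contour areas match component pixel counts within the boundary convention", {
  m <- matrix(FALSE, 40, 40)
  m[10:29, 5:34] <- TRUE            # 20 x 30 block = 600 px
  ct <- extractContours(m)[[1]]
  # pixel-centre polygon of a w x h block has shoelace area (w-1)(h-1)
  expect_equal(contourArea(ct), 19 * 29)
  expect_equal(contourPerimeter(ct), 2 * (19 + 29))
})

test_that("filling a traced contour reproduces the component", {
  for (s in twoSpecies()) {
    g <- generateBeakImage(s, "lower", seed = 13, imageSize = c(150L, 110L))
    ct <- selectRoi(extractContours(g$mask), 50)
    expect_identical(fillContour(ct, dim(g$mask)), g$mask)
  }
})

test_that("selectRoi keeps the largest contour above the area floor", {
  m <- matrix(FALSE, 120, 120)
  m[10:80, 10:80] <- TRUE           # area ~ 70^2
  m[100:106, 100:106] <- TRUE       # area ~ 36
  cts <- extractContours(m)
  roi <- selectRoi(cts, 100)
  expect_equal(contourArea(roi), max(vapply(cts, contourArea, numeric(1))))
  expect_identical(selectRoi(cts[1], 100), cts[[1]])
  expect_error(selectRoi(cts, 1e6), class = "beakid_no_roi")
})

test_that("8-connected labelling merges diagonal touches", {
  m <- matrix(FALSE, 8, 8)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE; m[4, 4] <- TRUE
  expect_equal(max(labelComponents(m)), 1L)
  m2 <- matrix(FALSE, 8, 8)
  m2[2, 2] <- TRUE; m2[2, 4] <- TRUE
  expect_equal(max(labelComponents(m2)), 2L)
})
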