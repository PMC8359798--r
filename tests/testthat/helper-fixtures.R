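# Shared fixtures: tiny species parameter sets, polygon builders and an
# independent per-pixel HOG oracle used to cross-check the vectorized
# implementation.

twoSpecies <- function() {
  list(
    speciesShape("sp_tall", rostrumCurvature = 1.2, hoodToWingRatio = 1.6,
                 wingLengthFrac = 0.35, baseDarkness = 50,
                 darknessGradient = 70, sizeRange = c(18, 24)),
    speciesShape("sp_long", rostrumCurvature = 0.9, hoodToWingRatio = 0.8,
                 wingLengthFrac = 0.7, baseDarkness = 90,
                 darknessGradient = 50, sizeRange = c(22, 30))
  )
}

smallConfig <- function(counts = c(sp_tall = 3L, sp_long = 2L), seed = 11L,
                        imageSize = c(200L, 140L)) {
  sp <- twoSpecies()
  names(sp) <- vapply(sp, function(s) s@speciesId, character(1))
  beakDatasetConfig(species = sp[names(counts)], perSpeciesCounts = counts,
                    imageSize = imageSize, seed = seed)
}

rectContour <- function(w, h, x0 = 0, y0 = 0) {
  cbind(c(x0, x0 + w, x0 + w, x0), c(y0, y0, y0 + h, y0 + h))
}

discContour <- function(r, n = 512, cx = 0, cy = 0) {
  a <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + r * cos(a), cy + r * sin(a))
}

# Independent HOG oracle: explicit per-pixel double loops over gradients,
# cell votes and blocks, written directly from the descriptor definition.
naiveHog <- function(gray, cell = 16L, bins = 9L) {
  H <- nrow(gray); W <- ncol(gray)
  binW <- 180 / bins
  nx <- W %/% cell; ny <- H %/% cell
  hists <- array(0, c(ny, nx, bins))
  for (yy in seq_len(ny * cell)) {
    for (xx in seq_len(nx * cell)) {
      xr <- min(xx + 1L, W); xl <- max(xx - 1L, 1L)
      yd <- min(yy + 1L, H); yu <- max(yy - 1L, 1L)
      gx <- gray[yy, xr] - gray[yy, xl]
      gy <- gray[yd, xx] - gray[yu, xx]
      mag <- sqrt(gx^2 + gy^2)
      if (mag == 0) { theta <- 0 } else {
        theta <- (atan2(gy, gx) * 180 / pi) %% 180
      }
      cy <- (yy - 1L) %/% cell + 1L
      cx <- (xx - 1L) %/% cell + 1L
      t <- theta / binW
      b0 <- floor(t) %% bins
      frac <- t - floor(t)
      hists[cy, cx, b0 + 1L] <- hists[cy, cx, b0 + 1L] + (1 - frac) * mag
      hists[cy, cx, (b0 + 1L) %% bins + 1L] <-
        hists[cy, cx, (b0 + 1L) %% bins + 1L] + frac * mag
    }
  }
  out <- numeric(0)
  for (by in seq_len(ny - 1L)) {
    for (bx in seq_len(nx - 1L)) {
      v <- c(hists[by, bx, ], hists[by, bx + 1L, ],
             hists[by + 1L, bx, ], hists[by + 1L, bx + 1L, ])
      nrm <- sqrt(sum(v^2))
      if (nrm > 0) v <- v / nrm
      out <- c(out, v)
    }
  }
  out
}
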