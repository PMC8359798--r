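#' Construct species shape parameters
#'
#' @param speciesId single character label.
#' @param rostrumCurvature hook depth at the rostrum (> 0).
#' @param hoodToWingRatio hood height relative to wing extension (> 0).
#' @param wingLengthFrac wing lobe length as a fraction of body length.
#' @param baseDarkness grey level at the rostrum tip (< 200).
#' @param darknessGradient grey-level increase per unit normalized distance
#'   from the rostrum.
#' @param sizeRange nominal beak length range in mm, `c(min, max)`.
#' @return a [SpeciesShape] object.
#' @export
speciesShape <- function(speciesId, rostrumCurvature = 1, hoodToWingRatio = 1,
                         wingLengthFrac = 0.5, baseDarkness = 60,
                         darknessGradient = 80, sizeRange = c(18, 28)) {
  new("SpeciesShape", speciesId = speciesId,
      rostrumCurvature = as.numeric(rostrumCurvature),
      hoodToWingRatio = as.numeric(hoodToWingRatio),
      wingLengthFrac = as.numeric(wingLengthFrac),
      baseDarkness = as.numeric(baseDarkness),
      darknessGradient = as.numeric(darknessGradient),
      sizeRange = as.numeric(sizeRange))
}

setMethod("show", "SpeciesShape", function(object) {
  cat(sprintf("SpeciesShape '%s': curvature %.2f, hood/wing %.2f, wing frac %.2f,\n",
              object@speciesId, object@rostrumCurvature,
              object@hoodToWingRatio, object@wingLengthFrac))
  cat(sprintf("  base darkness %g, gradient %g, size %g-%g mm\n",
              object@baseDarkness, object@darknessGradient,
              object@sizeRange[1], object@sizeRange[2]))
})

#' Default shape parameters for the seven study species
#'
#' Four squid, two cuttlefish and one octopus species, with shape and
#' pigmentation parameters spaced so that species differing in hood-to-wing
#' ratio by 20% or more separate in mean bounding-box aspect ratio.
#'
#' @return a named list of seven [SpeciesShape] objects.
#' @export
defaultSpeciesTable <- function() {
  tab <- list(
    speciesShape("Sepioteuthis lessoniana", 1.00, 1.00, 0.55,  60,  80, c(20, 30)),
    speciesShape("Loliolus uyii",           1.30, 1.35, 0.45,  90,  60, c(12, 18)),
    speciesShape("Uroteuthis chinensis",    0.80, 0.80, 0.70,  50, 100, c(25, 35)),
    speciesShape("Uroteuthis edulis",       1.10, 1.12, 0.62,  75,  70, c(22, 32)),
    speciesShape("Sepia aculeata",          1.50, 1.60, 0.40,  40,  50, c(18, 26)),
    speciesShape("Sepia esculenta",         0.90, 0.95, 0.50, 110,  40, c(16, 24)),
    speciesShape("Amphioctopus aegina",     1.60, 1.90, 0.30,  30,  90, c(14, 20))
  )
  names(tab) <- vapply(tab, function(s) s@speciesId, character(1))
  tab
}

#' Construct a synthetic dataset configuration
#'
#' @param species list of [SpeciesShape]; default [defaultSpeciesTable()].
#' @param perSpeciesCounts named integer vector of images per species.
#' @param imageSize `(width, height)` in pixels; default `c(532, 299)`, the
#'   working resolution at which the descriptor geometry (128-px HOG cells,
#'   threshold 240) is defined.
#' @param backgroundRange lightbox grey-level range, subset of [240, 255].
#' @param noiseSd additive pixel noise standard deviation (grey levels).
#' @param view `"upper"` or `"lower"` beak view.
#' @param seed integer master seed.
#' @return a [BeakDatasetConfig].
#' @export
beakDatasetConfig <- function(species = defaultSpeciesTable(),
                              perSpeciesCounts,
                              imageSize = c(532L, 299L),
                              backgroundRange = c(245, 254),
                              noiseSd = 2, view = "lower", seed = 1L) {
  new("BeakDatasetConfig", species = species,
      perSpeciesCounts = setNames(as.integer(perSpeciesCounts),
                                  names(perSpeciesCounts)),
      imageSize = as.integer(imageSize),
      backgroundRange = as.numeric(backgroundRange),
      noiseSd = as.numeric(noiseSd), view = view, seed = as.integer(seed))
}

#' The default study configuration: 174 samples of 7 species
#'
#' Cohort structure of the study collection: four squid species (96 samples),
#' two cuttlefish species (49) and one octopus (29), 174 in total. Per-species
#' counts split each taxon total evenly: 24 x 4 squid, 25 + 24 cuttlefish,
#' 29 octopus.
#'
#' @param seed integer master seed.
#' @param view `"upper"` or `"lower"`.
#' @return a [BeakDatasetConfig] with 7 species and 174 records.
#' @export
defaultStudyConfig <- function(seed = 1L, view = "lower") {
  counts <- c("Sepioteuthis lessoniana" = 24L,
              "Loliolus uyii"           = 24L,
              "Uroteuthis chinensis"    = 24L,
              "Uroteuthis edulis"       = 24L,
              "Sepia aculeata"          = 25L,
              "Sepia esculenta"         = 24L,
              "Amphioctopus aegina"     = 29L)
  beakDatasetConfig(perSpeciesCounts = counts, seed = seed, view = view)
}

#' Generate one synthetic beak image with its ground-truth mask
#'
#' Renders a single dark hooked-crescent beak silhouette (hood lobe, wing
#' lobe and a carved rostral hook) on a near-white lightbox background.
#' Pigmentation is darkest at the rostrum and fades along the body per the
#' species' darkness gradient. All object grey levels are kept below 240 and
#' all background levels within the configured range, so threshold-240
#' segmentation recovers the emitted mask exactly.
#'
#' @param params a [SpeciesShape].
#' @param view `"upper"` or `"lower"`.
#' @param seed integer seed; the same (params, view, seed) triple yields a
#'   pixel-identical image.
#' @param imageSize `(width, height)` in pixels.
#' @param backgroundRange background grey-level range, subset of [240, 255].
#' @param noiseSd additive noise standard deviation (grey levels).
#' @return list with `image` (height x width x 3 array, 0--255) and `mask`
#'   (height x width logical, `TRUE` on silhouette pixels).
#' @export
generateBeakImage <- function(params, view, seed = 1L,
                              imageSize = c(532L, 299L),
                              backgroundRange = c(245, 254),
                              noiseSd = 2) {
  stopifnot(is(params, "SpeciesShape"))
  validObject(params)
  if (!(is.character(view) && length(view) == 1L && view %in% c("upper", "lower")))
    stop(structure(class = c("beakid_invalid_view", "error", "condition"),
                   list(message = sprintf("invalid beak view '%s'; must be 'upper' or 'lower'",
                                          paste(view, collapse = ",")),
                        call = sys.call())))
  W <- as.integer(imageSize[1]); H <- as.integer(imageSize[2])
  oldseed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, envir = globalenv()))
  set.seed(as.integer(seed))

  # nominal length in mm -> pixels; keep the beak inside the frame
  lenMm <- runif(1, params@sizeRange[1], params@sizeRange[2])
  pxPerMm <- 0.55 * min(W, H) / mean(params@sizeRange)
  L <- lenMm * pxPerMm
  cx <- W / 2 + runif(1, -0.04, 0.04) * W
  cy <- H / 2 + runif(1, -0.04, 0.04) * H
  rot <- runif(1, -6, 6) * pi / 180

  # pixel-centre grid in rotated body coordinates
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), times = W), H, W)
  xr <- cos(rot) * (xs - cx) + sin(rot) * (ys - cy)
  yr <- -sin(rot) * (xs - cx) + cos(rot) * (ys - cy)

  ax <- L / 2                                   # body semi-length
  ay <- ax * 0.55 * params@hoodToWingRatio      # hood height
  flip <- if (view == "upper") -1 else 1        # hook down (lower) / up (upper)
  yb <- flip * yr

  # hood/body ellipse
  body <- (xr / ax)^2 + (yb / ay)^2 <= 1
  # posterior wing lobe (elongates the silhouette)
  wf <- params@wingLengthFrac * if (view == "upper") 0.85 else 1
  wx <- 0.45 * wf * L
  wing <- ((xr - wx) / (0.5 * wf * L))^2 + ((yb - 0.15 * ay) / (0.45 * ay))^2 <= 1
  # rostral hook lobe at the anterior tip
  hookR <- 0.22 * ay * params@rostrumCurvature
  hook <- (xr + 0.92 * ax)^2 + (yb + 0.35 * ay)^2 <= hookR^2
  # carve a notch under the hook to form the hooked profile
  notch <- (xr + 0.80 * ax)^2 + (yb - 0.45 * ay)^2 <= (0.30 * ay)^2
  mask <- (body | wing | hook) & !notch

  # pigmentation: darkest at the rostrum tip, fading along the body
  dRost <- sqrt((xr + ax)^2 + yb^2) / L
  grey <- params@baseDarkness + params@darknessGradient * dRost
  grey <- grey + rnorm(H * W, 0, noiseSd)
  grey <- pmin(pmax(grey, 0), 235)

  bg <- runif(1, backgroundRange[1], backgroundRange[2])
  bgPix <- bg + rnorm(H * W, 0, noiseSd)
  bgPix <- pmin(pmax(bgPix, backgroundRange[1]), backgroundRange[2])

  img <- array(0, c(H, W, 3))
  tint <- c(1.12, 0.90, 0.72)                   # tanned chitin: reddish brown
  for (ch in 1:3) {
    plane <- matrix(bgPix, H, W)
    obj <- pmin(pmax(grey * tint[ch], 0), 235)
    plane[mask] <- obj[mask]
    img[, , ch] <- plane
  }
  list(image = img, mask = mask)
}

#' Generate a labelled synthetic beak dataset on disk
#'
#' Writes `perSpeciesCounts` PNG images per species plus ground-truth mask
#' PNGs and a manifest CSV (`path,label,view,mask_path`, UTF-8, header).
#' Identical configurations (including the seed) yield byte-identical
#' images and manifest.
#'
#' @param config a [BeakDatasetConfig].
#' @param dir output directory (created if missing).
#' @return the manifest as a data.frame (invisibly written to
#'   `file.path(dir, "manifest.csv")`).
#' @export
generateBeakDataset <- function(config, dir) {
  stopifnot(is(config, "BeakDatasetConfig"))
  validObject(config)
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2) != 0)
    stop("output directory is not writable: ", dir)
  dir.create(file.path(dir, "images"), showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)

  ids <- vapply(config@species, function(s) s@speciesId, character(1))
  rows <- list(); k <- 0L
  for (sp in names(config@perSpeciesCounts)) {
    shp <- config@species[[match(sp, ids)]]
    for (i in seq_len(config@perSpeciesCounts[[sp]])) {
      k <- k + 1L
      imgSeed <- (config@seed + 7919L * k) %% .Machine$integer.max
      gen <- generateBeakImage(shp, config@view, seed = imgSeed,
                               imageSize = config@imageSize,
                               backgroundRange = config@backgroundRange,
                               noiseSd = config@noiseSd)
      slug <- gsub("[^A-Za-z0-9]+", "_", sp)
      ipath <- file.path(dir, "images",
                         sprintf("%s_%s_%03d.png", slug, config@view, i))
      mpath <- file.path(dir, "masks",
                         sprintf("%s_%s_%03d_mask.png", slug, config@view, i))
      writeBeakImage(gen$image, ipath)
      png::writePNG(matrix(as.numeric(gen$mask), nrow(gen$mask)), mpath)
      rows[[k]] <- data.frame(path = ipath, label = sp, view = config@view,
                              mask_path = mpath, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  manifest
}

#' Read a dataset manifest CSV
#'
#' Columns `path,label,view` (header required), optional `mask_path`.
#' @param path manifest CSV path.
#' @return data.frame with at least path/label/view columns.
#' @export
readManifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("path", "label", "view")
  if (!all(need %in% colnames(m)))
    stop("manifest must contain columns: ", paste(need, collapse = ", "))
  m
}
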