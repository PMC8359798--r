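test_that("generated beaks are dark objects on a bright lightbox, separable at 240", {
  sp <- twoSpecies()[[1]]
  sp@baseDarkness <- 80
  g <- generateBeakImage(sp, "lower", seed = 3, imageSize = c(200L, 140L),
                         backgroundRange = c(250, 255))
  gray <- rgbToGray(g$image)
  expect_true(all(gray[!g$mask] >= 250))
  expect_true(all(gray[g$mask] < 240))
  expect_true(sum(g$mask) > 0)
})

test_that("same parameters and seed reproduce pixel-identical images", {
  sp <- twoSpecies()[[2]]
  g1 <- generateBeakImage(sp, "upper", seed = 9, imageSize = c(120L, 90L))
  g2 <- generateBeakImage(sp, "upper", seed = 9, imageSize = c(120L, 90L))
  expect_identical(g1$image, g2$image)
  expect_identical(g1$mask, g2$mask)
  g3 <- generateBeakImage(sp, "upper", seed = 10, imageSize = c(120L, 90L))
  expect_false(identical(g1$image, g3$image))
})

test_that("the silhouette is a single connected component for every species and view", {
  for (sp in defaultSpeciesTable()) {
    for (view in c("upper", "lower")) {
      g <- generateBeakImage(sp, view, seed = 21)
      expect_equal(max(labelComponents(g$mask)), 1L,
                   info = paste(sp@speciesId, view))
    }
  }
})

test_that("invalid views and degenerate shape parameters are rejected", {
  sp <- twoSpecies()[[1]]
  expect_error(generateBeakImage(sp, "dorsal", seed = 1),
               class = "beakid_invalid_view")
  bad <- sp
  bad@rostrumCurvature <- NaN
  expect_error(generateBeakImage(bad, "lower", seed = 1), "finite")
})

test_that("generateBeakDataset writes the configured class counts and a valid manifest", {
  dir <- withr::local_tempdir()
  cfg <- smallConfig(counts = c(sp_tall = 3L, sp_long = 2L))
  man <- generateBeakDataset(cfg, dir)
  expect_equal(nrow(man), 5L)
  expect_equal(as.vector(table(man$label)[c("sp_tall", "sp_long")]), c(3L, 2L))
  expect_true(all(file.exists(man$path)))
  expect_true(all(file.exists(man$mask_path)))
  onDisk <- readManifest(file.path(dir, "manifest.csv"))
  expect_equal(onDisk$label, man$label)
})

test_that("identical configs yield byte-identical datasets", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- smallConfig(seed = 31L)
  generateBeakDataset(cfg, d1)
  generateBeakDataset(cfg, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  imgs <- grep("images/", f1, value = TRUE)
  for (f in imgs)
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  # manifests identical modulo the directory prefix
  m1 <- gsub(d1, "", readLines(file.path(d1, "manifest.csv")), fixed = TRUE)
  m2 <- gsub(d2, "", readLines(file.path(d2, "manifest.csv")), fixed = TRUE)
  expect_identical(m1, m2)
})

test_that("the default study configuration reproduces the 174-sample cohort", {
  cfg <- defaultStudyConfig()
  expect_equal(sum(cfg@perSpeciesCounts), 174L)
  expect_equal(length(cfg@species), 7L)
  squid <- c("Sepioteuthis lessoniana", "Loliolus uyii",
             "Uroteuthis chinensis", "Uroteuthis edulis")
  cuttle <- c("Sepia aculeata", "Sepia esculenta")
  expect_equal(unname(cfg@perSpeciesCounts[squid]), rep(24L, 4))
  expect_equal(sum(cfg@perSpeciesCounts[squid]), 96L)
  expect_equal(sum(cfg@perSpeciesCounts[cuttle]), 49L)
  expect_equal(unname(cfg@perSpeciesCounts["Amphioctopus aegina"]), 29L)
})

test_that("species differing in hood-to-wing ratio separate in mean aspect ratio", {
  sp <- twoSpecies()   # ratios 1.6 vs 0.8 (100% apart)
  aspect <- function(s) {
    vapply(1:12, function(i) {
      g <- generateBeakImage(s, "lower", seed = 100 + i,
                             imageSize = c(200L, 160L))
      ct <- selectRoi(extractContours(g$mask), 50)
      msdFeatures(ct)[["aspect_ratio"]]
    }, numeric(1))
  }
  aTall <- aspect(sp[[1]]); aLong <- aspect(sp[[2]])
  expect_lt(mean(aTall), mean(aLong))
  expect_lt(stats::t.test(aTall, aLong)$p.value, 0.01)
})
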