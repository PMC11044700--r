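test_that("flow frames put the rendered interface where the ground truth says", {
  # boundary case: single-phase appearance at f = 0
  fr0 <- renderFlowFrame(0, nCells = 0, noiseSd = 0, seed = 1)
  expect_s4_class(fr0, "FlowFrame")
  expect_equal(trueFraction(fr0), 0)
  expect_false(any(cellMask(fr0)))

  # brute-force column scan oracle: position of the largest adjacent
  # column-mean difference
  scanOracle <- function(px) {
    m <- colMeans(px)
    which.max(abs(m[-1] - m[-length(m)]))
  }
  fr <- renderFlowFrame(0.5, nCells = 0, noiseSd = 0, seed = 1)
  expect_lte(abs(scanOracle(framePixels(fr)) - 60), 1)
  expect_equal(maxGradientColumn(fr), scanOracle(framePixels(fr)))

  # localizability across the full fraction grid
  for (f in seq(0, 1, by = 0.05)) {
    frg <- renderFlowFrame(f, nCells = 0, noiseSd = 0, seed = 2)
    expect_lte(abs(scanOracle(framePixels(frg)) - round(f * 120)), 1)
  }

  # determinism and input validation
  a <- renderFlowFrame(0.3, nCells = 4, noiseSd = 6, illumGradient = 0.1, seed = 9)
  b <- renderFlowFrame(0.3, nCells = 4, noiseSd = 6, illumGradient = 0.1, seed = 9)
  expect_identical(framePixels(a), framePixels(b))
  expect_identical(cellMask(a), cellMask(b))
  expect_error(renderFlowFrame(1.2), "fHigh")
  expect_error(renderFlowFrame(-0.1), "fHigh")

  # 8-bit intensity and dimension invariants
  expect_true(all(framePixels(a) >= 0 & framePixels(a) <= 255))
  expect_identical(dim(framePixels(a)), c(120L, 120L))
})

test_that("classifier datasets respect class bands, counts and the stratified split", {
  ds <- makeClassifierDataset(300, seed = 5)
  expect_length(ds, 600L)
  expect_equal(as.vector(table(frameLabels(ds))), c(300L, 300L))

  # exhaustive band membership scan of the stored ground truth
  f <- frameFractions(ds)
  lab <- frameLabels(ds)
  expect_true(all(f[lab == "LOW_VF"] >= 0 & f[lab == "LOW_VF"] < 0.2))
  expect_true(all(f[lab == "HIGH_VF"] >= 0.8 & f[lab == "HIGH_VF"] <= 1))

  # stratified 70/30 within each class
  for (cl in levels(lab)) {
    expect_equal(sum(frameSplit(ds) == "train" & lab == cl), 210L)
  }

  tiny <- makeClassifierDataset(1, seed = 2)
  expect_length(tiny, 2L)
  expect_equal(sort(as.character(frameLabels(tiny))), c("HIGH_VF", "LOW_VF"))

  expect_error(makeClassifierDataset(5, lowBand = c(0, 0.5), highBand = c(0.4, 1)),
               "disjoint")

  # concatenation grows the training pool by the added train fraction
  extra <- makeClassifierDataset(300, seed = 6)
  both <- combineFrameSets(ds, extra)
  expect_equal(sum(frameSplit(both) == "train"),
               sum(frameSplit(ds) == "train") + 420L)
})

test_that("bead populations follow the droplet-size distribution and composition rule", {
  pop <- sampleBeadPopulation(10000, fHighTrace = c(0.3, 0.5, 0.7), seed = 3)
  expect_lt(abs(mean(pop$diameter_um) - 106), 1)
  expect_true(all(pop$diameter_um > 0))

  fixed <- sampleBeadPopulation(50, diamSd = 0, fHighTrace = 0.5, seed = 1)
  expect_true(all(fixed$diameter_um == 106))

  pure <- sampleBeadPopulation(20, fHighTrace = 1.0, seed = 1)
  expect_true(all(pure$fitc_nM == 625))
  expect_true(all(!pure$crosslinked))

  expect_error(sampleBeadPopulation(10, fHighTrace = numeric(0)), "non-empty")
  expect_error(sampleBeadPopulation(0, fHighTrace = 0.5), "n must be")
})

test_that("bead fields render discs with the configured intensity and complete annotations", {
  one <- sampleBeadPopulation(1, diamSd = 0, fHighTrace = 1.0, seed = 1)
  bf <- renderBeadField(one, background = 0, snrRange = NULL, gain = 0.2,
                        brightnessJitterSd = 0, seed = 2)
  ann <- bf$annotations
  expect_equal(nrow(ann), 1L)
  # pixel average inside the ground-truth disc equals gain x fitc
  rows <- seq_len(nrow(bf$image)); cols <- seq_len(ncol(bf$image))
  inside <- outer((rows - 0.5 - ann$center_y)^2,
                  (cols - 0.5 - ann$center_x)^2, "+") <= (ann$w / 2)^2
  expect_equal(mean(bf$image[inside]), 0.2 * 625, tolerance = 1e-8)

  # zero beads: background plus noise only, empty annotations
  none <- renderBeadField(one[0, ], background = 12, snrRange = NULL, seed = 3)
  expect_equal(nrow(none$annotations), 0L)
  expect_true(all(none$image == 12L))

  # determinism
  pop <- sampleBeadPopulation(15, fHighTrace = c(0.2, 0.8), seed = 4)
  f1 <- renderBeadField(pop, seed = 11)
  f2 <- renderBeadField(pop, seed = 11)
  expect_identical(f1$image, f2$image)
  expect_identical(f1$annotations, f2$annotations)

  # ground-truth completeness: every bright disc has an annotation and
  # every annotation a bright disc
  f3 <- renderBeadField(pop, background = 10, snrRange = NULL,
                        brightnessJitterSd = 0, seed = 12)
  lit <- f3$image > 30
  for (i in seq_len(nrow(f3$annotations))) {
    a <- f3$annotations[i, ]
    expect_true(lit[round(a$center_y), round(a$center_x)])
    lit[max(1, floor(a$y)):min(nrow(lit), ceiling(a$y + a$h)),
        max(1, floor(a$x)):min(ncol(lit), ceiling(a$x + a$w))] <- FALSE
  }
  expect_false(any(lit))
})

test_that("spheroid fields emit boxes matching the ellipse axes", {
  sph <- data.frame(a_um = 25, b_um = 25, bead_index = 1L)
  sf <- renderSpheroidField(sph, pxPerUm = 1, noiseSd = 0, seed = 1)
  expect_equal(sf$annotations$w, 50)
  expect_equal(sf$annotations$h, 50)
  expect_equal(sf$annotations$h / sf$annotations$w, 1.0)

  elong <- data.frame(a_um = 32.5, b_um = 25, bead_index = 1L)
  se <- renderSpheroidField(elong, pxPerUm = 1, seed = 2)
  # box ratio sits exactly on the shape-filter boundary
  expect_equal(se$annotations$w / se$annotations$h, 1.3)

  empty <- renderSpheroidField(sph[0, ], noiseSd = 0, seed = 3)
  expect_equal(nrow(empty$annotations), 0L)
  expect_true(all(empty$image == 205L))

  s1 <- renderSpheroidField(elong, seed = 5)
  s2 <- renderSpheroidField(elong, seed = 5)
  expect_identical(s1$image, s2$image)
})

test_that("images and annotations round-trip through the documented file formats", {
  dir <- withr::local_tempdir()
  fr <- renderFlowFrame(0.4, nCells = 2, noiseSd = 3, seed = 8)
  for (ext in c("tif", "png")) {
    p <- file.path(dir, paste0("frame.", ext))
    writeGrayImage(framePixels(fr), p)
    expect_identical(readGrayImage(p), framePixels(fr))
  }
  pop <- sampleBeadPopulation(5, fHighTrace = 0.5, seed = 1)
  bf <- renderBeadField(pop, seed = 2)
  csv <- file.path(dir, "ann.csv")
  writeAnnotations(bf$annotations, "beads_01.tif", csv)
  back <- read.csv(csv)
  expect_identical(names(back),
                   c("image", "object_class", "x", "y", "w", "h",
                     "alginate_pct", "fitc_nM", "f_high"))
  expect_equal(nrow(back), nrow(bf$annotations))
})
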