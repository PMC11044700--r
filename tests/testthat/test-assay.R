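mkCal <- function() {
  cal <- new("CalibrationModel", slope = 0.02, intercept = 0.5,
             anchorsI = c(I5 = 10, I95 = 115),
             anchorsPct = c(low = 0.7, high = 2.8),
             stiffCoef = numeric(0), stiffRange = numeric(0))
  fitStiffnessModel(model = cal)
}

test_that("spheroid measurement converts boxes, filters shape and maps stiffness", {
  cal <- mkCal()
  beads <- data.frame(x = c(0, 100), y = c(0, 100), w = 60, h = 60)
  fluor <- c(50, 100)

  sph <- data.frame(x = c(5, 110), y = c(5, 108), w = c(50, 10), h = c(50, 14))
  m <- measureSpheroids(sph, beads, fluor, cal, pxPerUm = 1)
  # the 50x50 box at 1 px/um: diameter 50 um, AR 1.0, retained;
  # the 10x14 box: AR 1.4, dropped by the shape filter
  expect_equal(nrow(m), 1L)
  expect_equal(m$diameter_um, 50)
  expect_equal(m$aspect_ratio, 1.0)
  expect_equal(m$bead_fluor, 50)
  expect_equal(m$alginate_pct, 0.5 + 0.02 * 50)
  expect_equal(m$stiffness_Pa,
               stiffnessFromConcentration(cal, m$alginate_pct))
  expect_equal(unname(attr(m, "dropped")["aspect_ratio"]), 1)

  # a spheroid whose centre is outside every bead box is dropped
  lost <- data.frame(x = 300, y = 300, w = 40, h = 40)
  m2 <- measureSpheroids(lost, beads, fluor, cal, pxPerUm = 1)
  expect_equal(nrow(m2), 0L)
  expect_equal(unname(attr(m2, "dropped")["unassigned"]), 1)

  # exhaustive filter oracle over random boxes
  rb <- withr::with_seed(9, data.frame(
    x = runif(200, 0, 60), y = runif(200, 0, 60),
    w = runif(200, 10, 50), h = runif(200, 10, 50)))
  bigBead <- data.frame(x = -50, y = -50, w = 300, h = 300)
  mAll <- measureSpheroids(rb, bigBead, 75, cal, pxPerUm = 1)
  keepOracle <- rb$h / rb$w >= 0.7 & rb$h / rb$w <= 1.3
  expect_equal(nrow(mAll), sum(keepOracle))
  expect_equal(sort(mAll$aspect_ratio), sort((rb$h / rb$w)[keepOracle]))
})

test_that("stiffness binning summarises, flags and tests medians", {
  meas <- withr::with_seed(3, data.frame(
    diameter_um = rnorm(800, 40, 8),
    stiffness_Pa = runif(800, 50, 1000)))
  res <- binAndTest(meas, nBins = 8, minPerBin = 65)
  expect_equal(nrow(res$bins), 8L)
  expect_equal(sum(res$bins$n), 800L)
  expect_s3_class(res$test, "htest")
  expect_true(all(c("median", "q25", "q75", "flagged") %in% names(res$bins)))

  # identical diameters everywhere: degenerate H = 0, p = 1
  flat <- data.frame(diameter_um = rep(40, 400),
                     stiffness_Pa = runif(400, 50, 1000))
  r0 <- binAndTest(flat, nBins = 4, minPerBin = 10)
  expect_equal(unname(r0$test$statistic), 0)
  expect_equal(r0$test$p.value, 1)
  expect_false(r0$significant)

  # too few qualifying bins
  expect_error(binAndTest(meas, nBins = 8, minPerBin = 500),
               "fewer than 2 bins")
})

test_that("a shifted bin is detected with high power", {
  hits <- vapply(1:100, function(s) {
    meas <- withr::with_seed(1000 + s, {
      d <- rnorm(800, 40, 8)
      st <- rep(seq(100, 900, length.out = 8), each = 100) +
        runif(800, -40, 40)
      d[st > 800] <- d[st > 800] + 20     # one bin shifted by +20 um
      data.frame(diameter_um = d, stiffness_Pa = st)
    })
    binAndTest(meas, nBins = 8, minPerBin = 65)$test$p.value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the full assay recovers a stiffness histogram spanning the soft-gel range", {
  # controller-run droplet trace -> bead fields -> detection, intensity,
  # calibration: the assigned stiffness values must reach below 60 Pa and
  # above 900 Pa, reflecting the soft-to-stiff breadth of the gradient
  run <- fixtureLoopRun()
  trace <- run$droplets$f_high[run$droplets$crosslinked]
  beads <- sampleBeadPopulation(2000, fHighTrace = trace, seed = 701)
  seeds <- fanOutSeeds(702, 100)
  fields <- lapply(seq_len(100), function(i)
    renderBeadField(beads[((i - 1) * 20 + 1):(i * 20), ], seed = seeds[i]))
  det <- trainGridDetector(fields[1:40], "bead", seed = 703)
  ints <- unlist(lapply(fields, function(f)
    beadIntensity(f$image, detectObjects(det$model, f$image, 0.4))))
  cal <- fitStiffnessModel(model = fitIntensityCalibration(ints))
  st <- stiffnessFromConcentration(cal, concentrationFromIntensity(cal, ints))
  expect_gt(length(st), 1500)
  expect_lte(min(st), 60)
  expect_gte(max(st), 900)
})
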