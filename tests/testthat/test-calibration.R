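test_that("the two-point stiffness quadratic passes exactly through both anchors", {
  m <- fitStiffnessModel()
  # 2x2 solve of {0.49 a + 0.7 b = 50, 7.84 a + 2.8 b = 1000}
  expect_equal(m@stiffCoef[["a"]], 800 / 5.88, tolerance = 1e-9)
  expect_equal(m@stiffCoef[["b"]], (50 - 0.49 * 800 / 5.88) / 0.7,
               tolerance = 1e-9)
  expect_equal(stiffnessFromConcentration(m, 0.7), 50, tolerance = 1e-9)
  expect_equal(stiffnessFromConcentration(m, 2.8), 1000, tolerance = 1e-9)
  expect_equal(stiffnessFromConcentration(m, 1.75), 375, tolerance = 1e-9)

  # strictly increasing over the anchored range
  g <- stiffnessFromConcentration(m, seq(0.7, 2.8, by = 0.01))
  expect_true(all(diff(g) > 0))

  # least-squares path recovers a known quadratic from >2 points
  cc <- seq(0.7, 2.8, length.out = 9)
  pts <- data.frame(concentration_pct = cc,
                    G_prime_Pa = 120 * cc^2 + 10 * cc + 5)
  m2 <- fitStiffnessModel(pts)
  expect_equal(unname(m2@stiffCoef), c(120, 10, 5), tolerance = 1e-6)

  # a decreasing relationship is rejected with diagnostics
  bad <- data.frame(concentration_pct = c(0.7, 2.8),
                    G_prime_Pa = c(1000, 50))
  expect_error(fitStiffnessModel(bad), "non-monotone")
  expect_error(fitStiffnessModel(data.frame(concentration_pct = 1,
                                            G_prime_Pa = 50)), "at least 2")
})

test_that("fluorescence calibration anchors the fitted Gaussian percentiles", {
  ints <- withr::with_seed(11, rnorm(5000, 1000, 100))
  cal <- fitIntensityCalibration(ints)
  # normal-quantile oracle: mu +/- 1.6449 sigma
  expect_equal(cal@anchorsI[["I5"]], 1000 - qnorm(0.95) * 100, tolerance = 0.01)
  expect_equal(cal@anchorsI[["I95"]], 1000 + qnorm(0.95) * 100, tolerance = 0.01)
  expect_equal(concentrationFromIntensity(cal, cal@anchorsI[["I95"]]), 2.8,
               tolerance = 1e-9)
  expect_equal(concentrationFromIntensity(cal, cal@anchorsI[["I5"]]), 0.7,
               tolerance = 1e-9)
  # midpoint of the linear map
  expect_equal(concentrationFromIntensity(cal, mean(cal@anchorsI)), 1.75,
               tolerance = 1e-9)
  expect_gt(cal@slope, 0)

  expect_error(fitIntensityCalibration(rnorm(10)), "at least 50")
  expect_error(fitIntensityCalibration(rep(5, 100)), "degenerate")
})

test_that("rheology tables read from CSV and drive the stiffness fit", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "rheo.csv")
  write.csv(data.frame(concentration_pct = c(0.7, 2.8),
                       G_prime_Pa = c(50, 1000),
                       G_loss_Pa = c(2, 45)), p, row.names = FALSE)
  rheo <- readRheology(p)
  m <- fitStiffnessModel(rheo)
  expect_equal(stiffnessFromConcentration(m, 0.7), 50, tolerance = 1e-9)
  write.csv(data.frame(a = 1), p, row.names = FALSE)
  expect_error(readRheology(p), "must contain")
})

test_that("detected beads recover their alginate concentration within 0.15 % w/v", {
  # controlled condition: per-bead brightness variation off, so the error
  # reflects the detection + intensity + Gaussian-percentile calibration
  # chain alone
  f <- withr::with_seed(601, rnorm(20000, 0.444, 0.2837))
  f <- f[f >= 0.1 & f <= 0.9]
  beads <- sampleBeadPopulation(600, fHighTrace = f, seed = 602)
  seeds <- fanOutSeeds(603, 30)
  fields <- lapply(seq_len(30), function(i)
    renderBeadField(beads[((i - 1) * 20 + 1):(i * 20), ],
                    brightnessJitterSd = 0, dimFraction = 0,
                    seed = seeds[i]))
  det <- trainGridDetector(fields, "bead", seed = 604)
  allInt <- c(); allTrue <- c()
  for (i in seq_len(30)) {
    d <- detectObjects(det$model, fields[[i]]$image, confThresh = 0.5)
    ii <- beadIntensity(fields[[i]]$image, d)
    gt <- fields[[i]]$annotations
    for (k in seq_len(nrow(d))) {
      j <- which.min((gt$center_x - (d$x[k] + d$w[k] / 2))^2 +
                       (gt$center_y - (d$y[k] + d$h[k] / 2))^2)
      allInt <- c(allInt, ii[k])
      allTrue <- c(allTrue, gt$alginate_pct[j])
    }
  }
  cal <- fitIntensityCalibration(allInt)
  pred <- concentrationFromIntensity(cal, allInt)
  expect_gt(length(pred), 400)
  expect_lt(mean(abs(pred - allTrue)), 0.15)
})
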