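test_that("the classifier has the fixed 3-conv topology and normalised softmax", {
  m <- buildInterfaceClassifier(seed = 1)
  expect_s4_class(m, "InterfaceClassifier")
  expect_error(buildInterfaceClassifier(filters = c(8, 16)), "3 convolutional")

  p <- predictInterface(m, matrix(0L, 120, 120))
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_identical(colnames(p), c("LOW_VF", "HIGH_VF"))

  m2 <- buildInterfaceClassifier(seed = 1)
  expect_identical(m@weights, m2@weights)
  m3 <- buildInterfaceClassifier(seed = 2)
  expect_false(identical(m@weights$W1, m3@weights$W1))

  expect_error(predictInterface(m, matrix(0L, 100, 100)), "120x120")
})

test_that("training separates the volume-fraction classes on held-out frames", {
  fit <- fixtureClassifier()
  expect_gte(fit$heldOutAccuracy, 0.99)

  # clean frames deep inside each band classify correctly
  expect_equal(as.character(classifyFrames(fit$model,
                                           renderFlowFrame(0.95, seed = 3))),
               "HIGH_VF")
  expect_equal(as.character(classifyFrames(fit$model,
                                           renderFlowFrame(0.05, seed = 3))),
               "LOW_VF")

  # epochs = 0 leaves the weights untouched
  m0 <- buildInterfaceClassifier(seed = 5)
  same <- trainInterfaceClassifier(m0, fixtureDataset(), epochs = 0)
  expect_identical(same$model@weights, m0@weights)

  # a dataset with a single class present is rejected
  ds <- makeClassifierDataset(3, seed = 1)
  lowIdx <- which(frameLabels(ds) == "LOW_VF")
  oneClass <- new("FrameSet",
                  frames = frameList(ds)[lowIdx],
                  labels = factor(rep("LOW_VF", 3),
                                  levels = c("LOW_VF", "HIGH_VF")),
                  split = factor(c("train", "train", "test"),
                                 levels = c("train", "test")))
  expect_error(trainInterfaceClassifier(m0, oneClass, epochs = 1),
               "both classes")
})

test_that("predictions are invariant to affine intensity rescaling", {
  fit <- fixtureClassifier()
  frames <- lapply(fanOutSeeds(77, 50), function(s)
    renderFlowFrame(withr::with_seed(s, runif(1)), nCells = 1, noiseSd = 4,
                    seed = s))
  base <- classifyFrames(fit$model, frames)
  for (scale in c(0.9, 1.1)) {
    scaled <- lapply(frames, function(f) {
      m <- framePixels(f)
      matrix(as.integer(round(pmin(255, m * scale))), 120, 120)
    })
    expect_gte(mean(classifyFrames(fit$model, scaled) == base), 0.98)
  }
})

test_that("window estimates match a brute-force mean/std oracle", {
  # fifty 1s and a balanced window
  w1 <- windowEstimate(rep(1, 50))
  expect_equal(w1$mean, 1); expect_equal(w1$std, 0)
  wb <- windowEstimate(rep(c(1, 0), each = 25))
  expect_equal(wb$mean, 0.5); expect_equal(wb$std, 0.5)

  # oracle equivalence on random binary sequences
  for (s in 1:25) {
    x <- withr::with_seed(s, rbinom(50, 1, runif(1)))
    w <- windowEstimate(x)
    expect_equal(w$mean, sum(x) / 50, tolerance = 1e-12)
    expect_equal(w$std, sqrt(sum((x - sum(x) / 50)^2) / 50), tolerance = 1e-12)
  }

  # std > 0.4 exactly when the mean is strictly between 0.2 and 0.8
  for (k in 0:50) {
    w <- windowEstimate(c(rep(1, k), rep(0, 50 - k)))
    expect_identical(w$std > 0.4, w$mean > 0.2 && w$mean < 0.8)
  }

  expect_error(windowEstimate(rep(1, 49)), "exactly 50")
  expect_error(windowEstimate(rep(2, 50)), "binary")
})

test_that("the Canny baseline finds clean interfaces and fails on hard frames", {
  est <- cannyInterface(renderFlowFrame(0.5, nCells = 0, noiseSd = 0, seed = 1))
  expect_true(est$ok)
  expect_lt(abs(est$fHigh - 0.5), 0.05)

  expect_false(cannyInterface(matrix(100L, 120, 120))$ok)

  # frames with cells sitting on the laminar boundary, strong noise and
  # sub-optimal lighting: the baseline fails or errs by > 0.1 in a
  # substantial fraction of a 100-frame batch
  seeds <- fanOutSeeds(88, 100)
  f <- withr::with_seed(89, runif(100, 0.2, 0.8))
  bad <- vapply(seq_len(100), function(i) {
    fr <- renderFlowFrame(f[i], nCells = 6, noiseSd = 14, cellSpread = 5,
                          contrast = 0.3, seed = seeds[i])
    r <- cannyInterface(fr)
    !r$ok || abs(r$fHigh - f[i]) > 0.1
  }, logical(1))
  expect_gte(mean(bad), 0.2)
})

test_that("the trained classifier beats the Canny baseline on occluded frames", {
  occ <- fixtureOccludedSet()
  fit <- fixtureClassifier()
  cnnAcc <- mean(as.character(classifyFrames(fit$model, occ$frames)) ==
                   occ$labels)
  cannyPred <- vapply(occ$frames, function(fr) {
    r <- cannyInterface(fr)
    if (!r$ok) return(NA_character_)
    if (r$fHigh >= 0.5) "HIGH_VF" else "LOW_VF"
  }, character(1))
  cannyAcc <- mean(!is.na(cannyPred) & cannyPred == occ$labels)
  expect_gte(cnnAcc, cannyAcc)
})
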