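mkWindow <- function(mean, std = 0) list(mean = mean, std = std, windowSize = 50L)

test_that("pump limits are enforced, including the oil-ratio sum bound", {
  cfg <- defaultControllerConfig()
  expect_equal(enforceLimits(c(low = 14, high = 2), cfg)[["low"]], 13)
  clipped <- enforceLimits(c(low = 13, high = 6), cfg, lastIncremented = "high")
  expect_equal(clipped[["high"]], 2)
  expect_equal(sum(clipped), cfg$qOil / 2)
  ok <- c(low = 4, high = 3)
  expect_equal(enforceLimits(ok, cfg), ok)
})

test_that("the decision state machine seeks, overshoots, and flips targets", {
  cfg <- defaultControllerConfig()
  cs <- controllerInit(cfg)
  expect_equal(cs$targetClass, "HIGH_VF")
  expect_equal(cs$phase, "SEEKING")

  # seeking steps the pumps in opposite directions (+1 high / -1 low)
  cs1 <- decideControl(cs, mkWindow(0.1), cfg)
  expect_equal(cs1$command[["high"]], cs$command[["high"]] + 1)
  expect_equal(cs1$command[["low"]], cs$command[["low"]] - 1)
  expect_equal(cs1$phase, "SEEKING")

  # 95% window confidence toward the target triggers the overshoot
  cs2 <- decideControl(cs, mkWindow(0.96), cfg)
  expect_equal(cs2$phase, "OVERSHOOT")

  # overshoot ends when the window std exceeds 40%
  cs3 <- decideControl(cs2, mkWindow(0.7, std = 0.45), cfg)
  expect_equal(cs3$phase, "SEEKING")
  expect_equal(cs3$targetClass, "LOW_VF")

  # ... or by the 10 s timeout with a perfectly steady window
  csT <- cs2
  for (i in 1:9) {
    csT <- decideControl(csT, mkWindow(1, std = 0), cfg)
    expect_equal(csT$phase, "OVERSHOOT")
  }
  csT <- decideControl(csT, mkWindow(1, std = 0), cfg)
  expect_equal(csT$phase, "SEEKING")
  expect_equal(csT$targetClass, "LOW_VF")

  # reducing the viscous high-concentration pump uses the 3 uL/min step
  csL <- csT
  csL$command <- c(low = 5, high = 6)
  csL2 <- decideControl(csL, mkWindow(0.5), cfg)
  expect_equal(csL2$command[["high"]], 3)
  expect_equal(csL2$command[["low"]], 6)

  # a completed LOW/HIGH/LOW alternation increments the gradient counter
  expect_equal(csT$flipCount, 1L)
  expect_equal(csT$gradientsCompleted, 0L)

  # purity: identical inputs give identical outputs
  expect_identical(decideControl(cs, mkWindow(0.3), cfg),
                   decideControl(cs, mkWindow(0.3), cfg))
})

test_that("the oracle-driven loop sweeps past both class bands every gradient", {
  p <- defaultPlantParams()
  p$tauLow <- 0; p$tauHigh <- 0; p$flowNoiseFrac <- 0
  run <- runGradientLoop(NULL, nGradients = 3, oracle = TRUE,
                         plantParams = p, seed = 21)
  expect_equal(run$framesPerUpdate, 50L)
  expect_equal(run$state$gradientsCompleted, 3L)
  for (cy in unique(run$log$cycle)) {
    f <- run$log$f_high[run$log$cycle == cy]
    expect_lt(min(f), 0.2)
    expect_gt(max(f), 0.8)
  }
})

test_that("closed-loop logs obey cadence, flow limits and phase grammar", {
  run <- fixtureLoopRun()
  log <- run$log
  cfg <- defaultControllerConfig()

  # one decision per simulated second over disjoint 50-frame windows
  expect_equal(run$framesPerUpdate, 50L)
  expect_equal(diff(log$t), rep(1, nrow(log) - 1))

  # flow limits at every tick
  expect_true(all(log$q_high_cmd <= cfg$qHighMax))
  expect_true(all(log$q_low_cmd <= cfg$qLowMax))
  expect_true(all(log$q_low_cmd + log$q_high_cmd <= cfg$qOil / 2 + 1e-9))
  expect_true(all(log$q_low_cmd >= cfg$qMin & log$q_high_cmd >= cfg$qMin))

  # phase grammar: runs of SEEKING followed by OVERSHOOT; the target
  # flips exactly when OVERSHOOT returns to SEEKING
  ph <- log$phase
  tg <- log$target
  for (i in seq_len(nrow(log) - 1)) {
    expect_true(ph[i + 1] %in%
                  if (ph[i] == "SEEKING") c("SEEKING", "OVERSHOOT")
                  else c("OVERSHOOT", "SEEKING"))
    if (tg[i + 1] != tg[i]) {
      expect_equal(ph[i], "OVERSHOOT")
      expect_equal(ph[i + 1], "SEEKING")
    }
  }

  # two completed gradients, counted once per LOW/HIGH alternation pair
  expect_equal(run$state$gradientsCompleted, 2L)
  expect_equal(run$state$flipCount %/% 2L, 2L)

  # droplet bookkeeping matches the tick count exactly
  expect_equal(nrow(run$droplets), nrow(log) * 50L * round(200 * 0.02))
})

test_that("gradient runs serialise to the documented CSV logs", {
  run <- fixtureLoopRun()
  dir <- withr::local_tempdir()
  writeGradientRun(run, dir)
  log <- read.csv(file.path(dir, "gradient_log.csv"))
  expect_equal(nrow(log), nrow(run$log))
  drops <- read.csv(file.path(dir, "droplets.csv"))
  expect_true(all(c("t", "volume_nL", "f_high", "alginate_pct", "fitc_nM",
                    "ca_mM", "zn_mM", "n_cells", "crosslinked") %in%
                    names(drops)))
})
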