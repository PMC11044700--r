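#' @include plant.R interfaceClassifier.R
NULL

#' Default controller configuration
#'
#' Stepping, limit and threshold constants of the closed loop: 1 uL/min
#' steps (3 uL/min when reducing the viscous high-concentration pump),
#' upper limits of 6 and 13 uL/min for the high- and low-concentration
#' pumps, a constant 30 uL/min oil phase with the dispersed:continuous
#' ratio kept below 1:2, the 95% window-confidence criterion for reaching
#' a target class, and an overshoot phase ending after 10 s or when the
#' window standard deviation exceeds 0.4.
#'
#' @return Named list of controller parameters.
#' @export
defaultControllerConfig <- function() {
  list(stepUp = 1, stepDownLow = 1, stepDownHigh = 3,
       qHighMax = 6, qLowMax = 13, qMin = 0.5, qOil = 30,
       confThreshold = 0.95, stdThreshold = 0.4, overshootMaxS = 10,
       windowSize = 50L, frameRateHz = 50L,
       initTarget = "HIGH_VF", initQLow = 3, initQHigh = 2,
       maxSimTimeS = 600)
}

#' Initialise the controller state
#'
#' @param config Controller configuration (see
#'   [defaultControllerConfig()]).
#' @return Controller-state list: `targetClass`, `phase`
#'   (`SEEKING`/`OVERSHOOT`), `overshootClock` (s), `gradientsCompleted`,
#'   `flipCount`, `command` (`c(low=, high=)`, uL/min),
#'   `lastIncremented`.
#' @export
controllerInit <- function(config = defaultControllerConfig()) {
  config <- modifyList(defaultControllerConfig(), config)
  list(targetClass = config$initTarget, phase = "SEEKING",
       overshootClock = 0, gradientsCompleted = 0L, flipCount = 0L,
       command = c(low = config$initQLow, high = config$initQHigh),
       lastIncremented = "high")
}

#' Clip a pump command to the configured limits
#'
#' The high- and low-concentration pumps are clipped to
#' `[qMin, qHighMax]` and `[qMin, qLowMax]`; if the dispersed-phase sum
#' then still exceeds half the oil flow (the monodispersity bound), the
#' pump that was last incremented is reduced until the sum constraint
#' holds (but never below `qMin`).
#'
#' @param command Named numeric `c(low=, high=)`, uL/min.
#' @param config Controller configuration.
#' @param lastIncremented `"low"` or `"high"`: the pump stepped up most
#'   recently.
#' @return The clipped command.
#' @export
enforceLimits <- function(command, config = defaultControllerConfig(),
                          lastIncremented = "high") {
  command[["high"]] <- clamp(command[["high"]], config$qMin, config$qHighMax)
  command[["low"]] <- clamp(command[["low"]], config$qMin, config$qLowMax)
  lim <- config$qOil / 2
  if (sum(command) > lim) {
    other <- setdiff(c("low", "high"), lastIncremented)
    command[[lastIncremented]] <-
      max(config$qMin, lim - command[[other]])
  }
  command
}

#' One controller decision from a window estimate
#'
#' Pure transition function of the gradient state machine. While SEEKING,
#' the pump driving toward the target class steps up by `stepUp` and the
#' opposing pump steps down (3 uL/min when the viscous high-concentration
#' pump is being reduced, else 1); the phase switches to OVERSHOOT once
#' the window mean toward the target reaches `confThreshold`. During
#' OVERSHOOT the same-direction stepping continues until 10 s have
#' elapsed or the window standard deviation exceeds `stdThreshold`
#' (the interface appearance no longer resembling either trained class),
#' whereupon the target class flips, a completed LOW/HIGH alternation
#' pair increments `gradientsCompleted`, and SEEKING resumes toward the
#' new target. Every command passes through [enforceLimits()].
#'
#' @param cs Controller state from [controllerInit()].
#' @param w Window estimate from [windowEstimate()].
#' @param config Controller configuration.
#' @return The updated controller state (its `command` is the new pump
#'   command).
#' @export
decideControl <- function(cs, w, config = defaultControllerConfig()) {
  if (cs$phase == "OVERSHOOT") {
    cs$overshootClock <- cs$overshootClock + 1
    if (cs$overshootClock >= config$overshootMaxS ||
        w$std > config$stdThreshold) {
      cs$targetClass <- if (cs$targetClass == "HIGH_VF") "LOW_VF" else "HIGH_VF"
      cs$phase <- "SEEKING"
      cs$overshootClock <- 0
      cs$flipCount <- cs$flipCount + 1L
      cs$gradientsCompleted <- cs$flipCount %/% 2L
    }
  }
  cmd <- cs$command
  if (cs$targetClass == "HIGH_VF") {
    cmd[["high"]] <- cmd[["high"]] + config$stepUp
    cmd[["low"]] <- cmd[["low"]] - config$stepDownLow
    cs$lastIncremented <- "high"
  } else {
    cmd[["low"]] <- cmd[["low"]] + config$stepUp
    cmd[["high"]] <- cmd[["high"]] - config$stepDownHigh
    cs$lastIncremented <- "low"
  }
  cs$command <- enforceLimits(cmd, config, cs$lastIncremented)
  if (cs$phase == "SEEKING") {
    toward <- if (cs$targetClass == "HIGH_VF") w$mean else 1 - w$mean
    if (toward >= config$confThreshold) {
      cs$phase <- "OVERSHOOT"
      cs$overshootClock <- 0
    }
  }
  cs
}

#' Perfect-knowledge oracle classifier
#'
#' Binary class from the true volume fraction: HIGH_VF at or above 0.8,
#' LOW_VF at or below 0.2, nearest class in between. Used to exercise the
#' controller and plant without a trained model.
#'
#' @param fHigh Numeric vector of true volume fractions.
#' @return Integer vector (1 = HIGH_VF).
#' @export
oracleClass <- function(fHigh) {
  as.integer(ifelse(fHigh >= 0.8, 1L,
                    ifelse(fHigh <= 0.2, 0L, as.integer(fHigh >= 0.5))))
}

#' Run the closed-loop gradient generation
#'
#' Simulates the full loop: frames are rendered from the plant's realised
#' interface fraction at 50 Hz, classified (shallow CNN or oracle),
#' aggregated into 50-frame windows, and one [decideControl()] call per
#' simulated second updates the pump commands; the plant is stepped at
#' dt = 20 ms and droplets accumulate at the droplet rate throughout. The
#' loop starts from 3/2 uL/min (low/high) with 30 uL/min oil and stops
#' after `nGradients` completed LOW/HIGH alternation cycles, or aborts
#' with a diagnostic at the simulated-time cap.
#'
#' @param classifier An [InterfaceClassifier-class], or `NULL` with
#'   `oracle = TRUE`.
#' @param nGradients Number of completed gradients to run.
#' @param config Controller configuration.
#' @param plantParams Plant parameter overrides (see
#'   [defaultPlantParams()]).
#' @param stocks Stock pair.
#' @param oracle Use the perfect oracle instead of the classifier.
#' @param renderNoiseSd,renderCellLambda Frame rendering conditions during
#'   the run.
#' @param cellDensityPerML Cell density for droplet encapsulation.
#' @param seed Integer seed covering the entire run.
#' @return List: `log` (one row per control tick: `t`, `window_mean`,
#'   `window_std`, `phase`, `target`, `q_low_cmd`, `q_high_cmd`,
#'   `q_low_actual`, `q_high_actual`, `f_high`, `gradients_completed`,
#'   `cycle`), `droplets` (per-droplet records with their `cycle`),
#'   `framesPerUpdate`, `state` (final controller state).
#' @export
runGradientLoop <- function(classifier = NULL, nGradients = 1L,
                            config = defaultControllerConfig(),
                            plantParams = list(), stocks = defaultStocks(),
                            oracle = is.null(classifier),
                            renderNoiseSd = 4, renderCellLambda = 1.5,
                            cellDensityPerML = 6e6, seed = 1L) {
  if (nGradients < 1L) stop("nGradients must be >= 1")
  if (!oracle && (is.null(classifier) || !classifier@trained))
    stop("classifier must be trained (or use oracle = TRUE)")
  config <- modifyList(defaultControllerConfig(), config)
  dt <- 1 / config$frameRateHz
  cs <- controllerInit(config)
  plant <- plantInit(config$initQLow, config$initQHigh, stocks,
                     modifyList(defaultPlantParams(), plantParams))

  logRows <- list()
  dropletChunks <- list()
  withSeed(seed, {
    tSec <- 0L
    repeat {
      fs <- numeric(config$windowSize)
      frames <- if (!oracle) vector("list", config$windowSize)
      for (k in seq_len(config$windowSize)) {
        plant <- plantStep(plant, cs$command, dt)
        fs[k] <- realizedFraction(plant)
        if (!oracle) {
          frames[[k]] <- renderFlowFrame(
            fs[k], nCells = rpois(1, renderCellLambda),
            noiseSd = renderNoiseSd,
            seed = sample.int(.Machine$integer.max - 1L, 1L))
        }
        drops <- generateDroplets(plant, dt, cellDensityPerML)
        drops$cycle <- cs$gradientsCompleted + 1L
        dropletChunks[[length(dropletChunks) + 1L]] <- drops
      }
      preds <- if (oracle) oracleClass(fs) else
        as.integer(classifyFrames(classifier, frames) == "HIGH_VF")
      w <- windowEstimate(preds, config$windowSize)
      cs <- decideControl(cs, w, config)
      tSec <- tSec + 1L
      logRows[[tSec]] <- data.frame(
        t = tSec, window_mean = w$mean, window_std = w$std,
        phase = cs$phase, target = cs$targetClass,
        q_low_cmd = cs$command[["low"]], q_high_cmd = cs$command[["high"]],
        q_low_actual = actualFlows(plant)[["low"]],
        q_high_actual = actualFlows(plant)[["high"]],
        f_high = realizedFraction(plant),
        gradients_completed = cs$gradientsCompleted,
        cycle = min(cs$gradientsCompleted + 1L, nGradients))
      if (cs$gradientsCompleted >= nGradients) break
      if (tSec >= config$maxSimTimeS)
        stop("gradient loop did not complete ", nGradients,
             " cycles within ", config$maxSimTimeS,
             " simulated seconds (completed ", cs$gradientsCompleted,
             "; phase ", cs$phase, ", target ", cs$targetClass, ")")
    }
  })
  list(log = do.call(rbind, logRows),
       droplets = as.data.frame(data.table::rbindlist(dropletChunks)),
       framesPerUpdate = config$windowSize, state = cs)
}

#' Write a gradient run to CSV files
#'
#' @param run Result of [runGradientLoop()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeGradientRun <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(run$log, file.path(dir, "gradient_log.csv"))
  data.table::fwrite(run$droplets, file.path(dir, "droplets.csv"))
  invisible(dir)
}
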