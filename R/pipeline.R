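#' @include controller.R assay.R synthfix.R
NULL

#' Default end-to-end run configuration
#'
#' Desk-scale defaults for the full demonstration pipeline: classifier
#' dataset size and epochs, number of gradients, bead-field geometry,
#' detector split and the binned statistics. All controller/plant
#' constants come from [defaultControllerConfig()] /
#' [defaultPlantParams()] unless overridden here.
#'
#' @return Named list.
#' @export
defaultRunConfig <- function() {
  list(nPerClass = 120L, epochs = 6L,            # classifier stage
       oracle = FALSE,                           # use the perfect oracle
       nGradients = 2L,
       renderNoiseSd = 4, renderCellLambda = 1.5,
       cellDensityPerML = 6e6,
       pxPerUm = 0.4,
       beadsPerField = 22L, nBeadFields = 18L,
       beadDiamMeanUm = 106, beadDiamSdUm = 24,
       snrRange = c(4, 10),
       spheroidMeanDiamUm = 35, spheroidSdDiamUm = 8,
       detectorTrainFrac = 0.7,
       confThresh = 0.5, nmsIoU = 0.5,
       nBins = 4L, minPerBin = 10L,
       controller = list(), plant = list())
}

#' Write / read a run configuration as YAML
#'
#' @param config Configuration list.
#' @param path YAML file.
#' @return `path` (write) or the configuration list (read).
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  yaml::read_yaml(path)
}

#' Run the full gradient-to-assay pipeline
#'
#' Executes fixture generation, classifier training, the closed gradient
#' loop, bead/spheroid field rendering from the droplet log, detector
#' training, and the stiffness-binned growth analysis, writing all
#' artifacts plus a manifest (seeds, versions, file hashes) and a summary
#' into `outDir`. Stage seeds fan out deterministically from `seed`, so a
#' repeated run with the same configuration and seed reproduces every
#' artifact bit for bit. Any stage failure aborts with a stage-tagged
#' diagnostic.
#'
#' @param config Overrides of [defaultRunConfig()].
#' @param outDir Output directory.
#' @param seed Master seed.
#' @return Invisibly, a list with the summary, manifest and key objects.
#' @export
runEndToEnd <- function(config = list(), outDir, seed = 1L) {
  cfg <- modifyList(defaultRunConfig(), config)
  seeds <- fanOutSeeds(seed, 10L)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    res
  }
  writeRunConfig(cfg, file.path(outDir, "config.yaml"))

  classifier <- NULL
  heldOutAccuracy <- NA_real_
  if (!cfg$oracle) {
    classifier <- stage("train-classifier", {
      ds <- makeClassifierDataset(cfg$nPerClass, seed = seeds[1],
                                  noiseSd = cfg$renderNoiseSd,
                                  cellLambda = cfg$renderCellLambda)
      fit <- trainInterfaceClassifier(buildInterfaceClassifier(seed = seeds[2]),
                                      ds, epochs = cfg$epochs, seed = seeds[2])
      heldOutAccuracy <- fit$heldOutAccuracy
      fit$model
    })
  }

  run <- stage("run-loop", {
    r <- runGradientLoop(classifier, nGradients = cfg$nGradients,
                         config = cfg$controller, plantParams = cfg$plant,
                         oracle = cfg$oracle,
                         renderNoiseSd = cfg$renderNoiseSd,
                         renderCellLambda = cfg$renderCellLambda,
                         cellDensityPerML = cfg$cellDensityPerML,
                         seed = seeds[3])
    writeGradientRun(r, outDir)
    r
  })

  fields <- stage("render-fields", {
    trace <- run$droplets$f_high[run$droplets$crosslinked]
    beads <- sampleBeadPopulation(cfg$beadsPerField * cfg$nBeadFields,
                                  diamMean = cfg$beadDiamMeanUm,
                                  diamSd = cfg$beadDiamSdUm,
                                  fHighTrace = trace, seed = seeds[4])
    fseeds <- fanOutSeeds(seeds[5], cfg$nBeadFields * 2L)
    annPath <- file.path(outDir, "annotations.csv")
    if (file.exists(annPath)) unlink(annPath)
    lapply(seq_len(cfg$nBeadFields), function(i) {
      chunk <- beads[((i - 1) * cfg$beadsPerField + 1):(i * cfg$beadsPerField), ]
      bf <- renderBeadField(chunk, pxPerUm = cfg$pxPerUm,
                            snrRange = cfg$snrRange, seed = fseeds[i])
      sph <- sampleSpheroids(
        data.frame(diameter_um = bf$annotations$diameter_um),
        meanDiamUm = cfg$spheroidMeanDiamUm,
        sdDiamUm = cfg$spheroidSdDiamUm,
        seed = fseeds[cfg$nBeadFields + i])
      sf <- renderSpheroidField(sph, beadAnnotations = bf$annotations,
                                pxPerUm = cfg$pxPerUm,
                                seed = fseeds[cfg$nBeadFields + i])
      writeGrayImage(bf$image, file.path(outDir, sprintf("beads_%02d.tif", i)))
      writeGrayImage(sf$image, file.path(outDir, sprintf("spheroids_%02d.tif", i)))
      writeAnnotations(bf$annotations, sprintf("beads_%02d.tif", i), annPath)
      writeAnnotations(sf$annotations, sprintf("spheroids_%02d.tif", i), annPath)
      list(bead = bf, spheroid = sf)
    })
  })

  detectors <- stage("train-detectors", {
    list(bead = trainGridDetector(lapply(fields, `[[`, "bead"),
                                  "bead", trainFrac = cfg$detectorTrainFrac,
                                  seed = seeds[6]),
         spheroid = trainGridDetector(lapply(fields, `[[`, "spheroid"),
                                      "spheroid",
                                      trainFrac = cfg$detectorTrainFrac,
                                      seed = seeds[6]))
  })

  analysis <- stage("analyze", {
    evalIdx <- which(detectors$bead$split == "test")
    if (!length(evalIdx)) evalIdx <- seq_along(fields)
    dets <- list(); meas <- list(); intens <- list()
    calibSamples <- numeric(0)
    for (i in evalIdx) {
      bd <- detectObjects(detectors$bead$model, fields[[i]]$bead$image,
                          cfg$confThresh, cfg$nmsIoU)
      calibSamples <- c(calibSamples,
                        beadIntensity(fields[[i]]$bead$image, bd))
    }
    calib <- fitIntensityCalibration(calibSamples)
    calib <- fitStiffnessModel(model = calib)
    for (i in evalIdx) {
      bd <- detectObjects(detectors$bead$model, fields[[i]]$bead$image,
                          cfg$confThresh, cfg$nmsIoU)
      sdets <- detectObjects(detectors$spheroid$model,
                             fields[[i]]$spheroid$image,
                             cfg$confThresh, cfg$nmsIoU)
      bi <- beadIntensity(fields[[i]]$bead$image, bd)
      m <- measureSpheroids(sdets, bd, bi, calib, pxPerUm = cfg$pxPerUm)
      if (nrow(bd)) { bd$image <- sprintf("beads_%02d.tif", i) }
      if (nrow(sdets)) { sdets$image <- sprintf("spheroids_%02d.tif", i) }
      dets[[length(dets) + 1L]] <- rbind(bd, sdets)
      meas[[length(meas) + 1L]] <- m
      intens[[length(intens) + 1L]] <- bi
    }
    detections <- do.call(rbind, dets)
    measurements <- do.call(rbind, meas)
    binres <- tryCatch(
      binAndTest(measurements, nBins = cfg$nBins, minPerBin = cfg$minPerBin),
      error = function(e) e$message)
    list(calibration = calib, detections = detections,
         measurements = measurements, bins = binres)
  })

  stage("write-outputs", {
    data.table::fwrite(
      analysis$detections[, c("image", "object_class", "x", "y", "w", "h", "score")],
      file.path(outDir, "detections.csv"))
    data.table::fwrite(analysis$measurements, file.path(outDir, "measurements.csv"))
    if (!is.character(analysis$bins)) {
      data.table::fwrite(analysis$bins$bins, file.path(outDir, "bins.csv"))
      jsonlite::write_json(analysis$bins$violin,
                           file.path(outDir, "violin.json"), digits = NA)
    }
    summary <- list(
      n_gradients = cfg$nGradients,
      gradients_completed = run$state$gradientsCompleted,
      droplet_count = nrow(run$droplets),
      droplet_rate_bookkeeping = {
        pp <- modifyList(defaultPlantParams(), cfg$plant)
        ctl <- modifyList(defaultControllerConfig(), cfg$controller)
        nrow(run$log) * ctl$windowSize * round(pp$dropletRate / ctl$frameRateHz)
      },
      classifier_held_out_accuracy = heldOutAccuracy,
      bead_test_ap = detectors$bead$testAP,
      spheroid_test_ap = detectors$spheroid$testAP,
      n_detections = nrow(analysis$detections),
      n_measurements = nrow(analysis$measurements),
      stiffness_range_Pa = if (nrow(analysis$measurements))
        range(analysis$measurements$stiffness_Pa) else NULL,
      kruskal_p = if (!is.character(analysis$bins))
        analysis$bins$test$p.value else analysis$bins)
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    TRUE
  })

  files <- setdiff(list.files(outDir), "manifest.json")
  manifest <- list(
    package = "stiffgrad",
    version = as.character(utils::packageVersion("stiffgrad")),
    seed = seed, stage_seeds = seeds,
    hashes = as.list(tools::md5sum(file.path(outDir, sort(files)))),
    timings_s = timings)
  names(manifest$hashes) <- sort(files)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(summary = jsonlite::read_json(file.path(outDir, "summary.json")),
                 manifest = manifest, run = run, detectors = detectors,
                 analysis = analysis))
}
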