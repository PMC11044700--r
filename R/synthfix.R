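#' @include AllClasses.R
NULL

# Rendering constants for the junction frames. The high-concentration
# stream (left of the interface) images slightly darker than the
# low-concentration stream; the refractive-index boundary adds a narrow
# bright line. Values are in 8-bit intensity units.
.flowRender <- list(
  levelHigh = 118,   # mean intensity of the high-concentration stream
  levelLow = 142,    # mean intensity of the low-concentration stream
  stepWidth = 1.2,   # sigmoidal transition width, px
  lineAmp = 70,      # amplitude of the bright refraction line
  lineSigma = 0.8    # Gaussian width of the refraction line, px
)

#' Render one synthetic flow-junction frame
#'
#' Draws a 120x120 bright-field view of two co-flowing alginate streams.
#' The high-concentration stream occupies the leftmost `fHigh` fraction of
#' the channel width; the laminar boundary is rendered as a smooth
#' sigmoidal intensity step (width ~1 px) topped by a narrow bright
#' refraction line, so the edge is localisable but not a hard step. Cells
#' are dark ellipses (8-15 px across) that may straddle the interface.
#'
#' @param fHigh Fraction of the channel width occupied by the
#'   high-concentration stream, in \[0, 1\].
#' @param nCells Number of occluding cells to render.
#' @param noiseSd Additive Gaussian noise sd, intensity units.
#' @param illumGradient Relative left-to-right illumination change
#'   (e.g. 0.2 means +/-10% across the frame).
#' @param cellSpread When finite, cell x positions are drawn from a normal
#'   centred on the interface column with this sd (px), concentrating the
#'   occlusions on the laminar boundary; `Inf` (default) places cells
#'   uniformly.
#' @param contrast Scaling of the interface contrast (step and refraction
#'   line) about the mid grey level; values below 1 emulate sub-optimal
#'   lighting.
#' @param seed Integer seed; identical arguments give bit-identical frames.
#' @return A [FlowFrame-class] object.
#' @examples
#' fr <- renderFlowFrame(0.5, nCells = 2, noiseSd = 4, seed = 1)
#' trueFraction(fr)
#' @export
renderFlowFrame <- function(fHigh, nCells = 0L, noiseSd = 0,
                            illumGradient = 0, cellSpread = Inf,
                            contrast = 1, seed = 1L) {
  if (length(fHigh) != 1L || is.na(fHigh) || fHigh < 0 || fHigh > 1)
    stop("fHigh must be a single value in [0, 1]")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  n <- 120L
  p <- .flowRender
  c0 <- fHigh * n
  xc <- seq_len(n) - 0.5                     # pixel-centre x coordinates
  profile <- p$levelHigh +
    (p$levelLow - p$levelHigh) * stats::plogis((xc - c0) / p$stepWidth) +
    p$lineAmp * exp(-(xc - c0)^2 / (2 * p$lineSigma^2))
  mid <- (p$levelHigh + p$levelLow) / 2
  profile <- mid + contrast * (profile - mid)
  img <- matrix(profile, nrow = n, ncol = n, byrow = TRUE)
  mask <- matrix(FALSE, n, n)

  withSeed(seed, {
    if (nCells > 0) {
      yc <- seq_len(n) - 0.5
      for (i in seq_len(nCells)) {
        cx <- if (is.finite(cellSpread))
          clamp(rnorm(1, c0, cellSpread), 4, n - 4)
        else runif(1, 4, n - 4)
        cy <- runif(1, 4, n - 4)
        ra <- runif(1, 4, 7.5)               # semi-axes, px
        rb <- runif(1, 4, 7.5)
        th <- runif(1, 0, pi)
        dark <- runif(1, 0.40, 0.65)
        dx <- outer(yc - cy, xc - cx, function(y, x) x)  # cols = x
        dy <- outer(yc - cy, xc - cx, function(y, x) y)
        u <- dx * cos(th) + dy * sin(th)
        v <- -dx * sin(th) + dy * cos(th)
        inside <- (u / ra)^2 + (v / rb)^2 <= 1
        img[inside] <- img[inside] * dark
        mask <- mask | inside
      }
    }
    if (illumGradient != 0)
      img <- sweep(img, 2, 1 + illumGradient * (xc / n - 0.5), "*")
    if (noiseSd > 0)
      img <- img + matrix(rnorm(n * n, sd = noiseSd), n, n)
  })

  new("FlowFrame", pixels = quantise8(img), fHigh = fHigh,
      cellMask = mask, seed = as.integer(seed))
}

#' Locate the interface by brute-force column gradient scan
#'
#' Utility used as the independent localisation oracle: returns the column
#' boundary (in pixel units, 0..120) with the largest absolute difference of
#' adjacent column means. For clean frames this sits within 1 px of
#' `fHigh * 120`.
#'
#' @param pixels 120x120 intensity matrix (or a [FlowFrame-class]).
#' @return Boundary position in pixels.
#' @export
maxGradientColumn <- function(pixels) {
  if (is(pixels, "FlowFrame")) pixels <- framePixels(pixels)
  m <- colMeans(pixels)
  which.max(abs(diff(m)))
}

#' Generate a labelled classifier dataset of junction frames
#'
#' Draws `nPerClass` frames per class with the true volume fraction sampled
#' uniformly inside each class band: `LOW_VF` when the high-concentration
#' stream makes up less than 20% of the channel width, `HIGH_VF` when it
#' makes up at least 80% (default bands). A stratified 70/30 train/test
#' split is attached.
#'
#' @param nPerClass Frames per class (600 total at the default 300).
#' @param lowBand,highBand Volume-fraction intervals for the two classes;
#'   must be disjoint.
#' @param noiseSd Additive noise sd passed to [renderFlowFrame()].
#' @param cellLambda Poisson mean of the per-frame occluding-cell count.
#' @param illumRange Range of the per-frame illumination gradient.
#' @param trainFrac Training fraction of the stratified split.
#' @param seed Integer seed.
#' @return A [FrameSet-class].
#' @export
makeClassifierDataset <- function(nPerClass, lowBand = c(0, 0.2),
                                  highBand = c(0.8, 1), seed = 1L,
                                  noiseSd = 4, cellLambda = 1.5,
                                  illumRange = c(-0.15, 0.15),
                                  trainFrac = 0.7) {
  if (max(lowBand) > min(highBand) &&
      max(highBand) > min(lowBand))
    stop("class bands must be disjoint")
  n <- as.integer(nPerClass)
  if (n < 1L) stop("nPerClass must be >= 1")

  withSeed(seed, {
    fLow <- runif(n, lowBand[1], min(lowBand[2], 1) - 1e-9)
    fHigh <- runif(n, highBand[1], highBand[2])
    cells <- rpois(2L * n, cellLambda)
    illum <- runif(2L * n, illumRange[1], illumRange[2])
    seeds <- sample.int(.Machine$integer.max - 1L, 2L * n)
    splitIdx <- c(sample(rep(c("train", "test"),
                             c(round(trainFrac * n), n - round(trainFrac * n)))),
                  sample(rep(c("train", "test"),
                             c(round(trainFrac * n), n - round(trainFrac * n)))))
  })

  fAll <- c(fLow, fHigh)
  frames <- lapply(seq_len(2L * n), function(i) {
    renderFlowFrame(fAll[i], nCells = cells[i], noiseSd = noiseSd,
                    illumGradient = illum[i], seed = seeds[i])
  })
  labels <- factor(rep(c("LOW_VF", "HIGH_VF"), each = n),
                   levels = c("LOW_VF", "HIGH_VF"))
  new("FrameSet", frames = frames, labels = labels,
      split = factor(splitIdx, levels = c("train", "test")))
}

#' Concatenate two frame sets (incremental retraining)
#'
#' @param a,b [FrameSet-class] objects.
#' @return The combined [FrameSet-class].
#' @export
combineFrameSets <- function(a, b) {
  new("FrameSet", frames = c(a@frames, b@frames),
      labels = factor(c(as.character(a@labels), as.character(b@labels)),
                      levels = c("LOW_VF", "HIGH_VF")),
      split = factor(c(as.character(a@split), as.character(b@split)),
                     levels = c("train", "test")))
}

#' Sample a synthetic bead population from a volume-fraction trace
#'
#' Bead diameters are drawn from a normal distribution (default 106 +/- 24
#' um, the typical gel bead size for an 80 um flow-focusing junction)
#' truncated at zero; each bead inherits its composition from a volume
#' fraction sampled uniformly from `fHighTrace` through the linear mixing
#' rule of [composeDroplet()], including the crosslinking viability flag.
#'
#' @param n Number of beads.
#' @param diamMean,diamSd Diameter distribution, um.
#' @param fHighTrace Numeric vector of volume fractions (e.g. the realized
#'   `f_high` column of a gradient run's droplet log).
#' @param stocks List with `low`/`high` [StockSpec-class] entries.
#' @param seed Integer seed.
#' @return A `data.frame` with columns `diameter_um`, `f_high`,
#'   `alginate_pct`, `fitc_nM`, `ca_mM`, `zn_mM`, `crosslinked`.
#' @export
sampleBeadPopulation <- function(n, diamMean = 106, diamSd = 24, fHighTrace,
                                 stocks = defaultStocks(), seed = 1L) {
  if (n <= 0) stop("n must be > 0")
  if (diamSd < 0) stop("diamSd must be >= 0")
  if (missing(fHighTrace) || length(fHighTrace) == 0L)
    stop("fHighTrace must be non-empty")
  withSeed(seed, {
    d <- rnorm(n, diamMean, diamSd)
    while (any(bad <- d <= 0)) d[bad] <- rnorm(sum(bad), diamMean, diamSd)
    f <- fHighTrace[sample.int(length(fHighTrace), n, replace = TRUE)]
  })
  comp <- composeMix(f, stocks)
  data.frame(diameter_um = d, f_high = f, comp)
}

#' Render a fluorescence bead field with ground-truth annotations
#'
#' Beads are drawn as hard-edged filled discs whose intensity above
#' background is `gain * fitc_nM`, emulating the FITC-dextran concentration
#' encoding. Per-image Gaussian noise is scaled so the mean bead
#' signal-to-noise ratio falls inside `snrRange` (low values emulate faint,
#' partially crosslinked beads). Placement is rejection-sampled so discs do
#' not overlap beyond `overlapTol`.
#'
#' @param beads Bead population `data.frame` from [sampleBeadPopulation()];
#'   only rows that fit in the field are used.
#' @param pxPerUm Pixel size, px/um.
#' @param background Background intensity, 8-bit units.
#' @param snrRange Interval for the per-image SNR draw, or `NULL` for a
#'   noise-free render.
#' @param gain Intensity units per nM of FITC-dextran.
#' @param imageSize `c(height, width)` in px.
#' @param overlapTol Fraction of the summed radii below which two centres
#'   may not approach each other.
#' @param brightnessJitterSd SD of the per-bead log-normal brightness
#'   factor, emulating bead-to-bead variation in dye retention and
#'   crosslinking completeness.
#' @param dimFraction Fraction of beads rendered with strongly reduced
#'   brightness — the incompletely crosslinked / dye-leaking beads whose
#'   low signal-to-background ratio defeats classical segmentation.
#' @param dimRetention Range of the brightness retention factor for dim
#'   beads.
#' @param seed Integer seed.
#' @return List with `image` (integer matrix) and `annotations`
#'   (`data.frame`: `object_class`, `x`, `y`, `w`, `h` half-open pixel
#'   boxes, plus `center_x`, `center_y`, `diameter_um`, `alginate_pct`,
#'   `fitc_nM`, `f_high`).
#' @export
renderBeadField <- function(beads, pxPerUm = 0.4, background = 12,
                            snrRange = c(3, 10), gain = 0.25,
                            imageSize = c(480L, 480L), overlapTol = 1.02,
                            brightnessJitterSd = 0.10, dimFraction = 0.08,
                            dimRetention = c(0.3, 1), seed = 1L) {
  H <- imageSize[1]; W <- imageSize[2]
  img <- matrix(as.numeric(background), H, W)
  ann <- list()
  withSeed(seed, {
    placed <- matrix(numeric(0), ncol = 3)  # cx, cy, r
    for (i in seq_len(nrow(beads))) {
      r <- beads$diameter_um[i] * pxPerUm / 2
      ok <- FALSE
      for (try in 1:200) {
        cx <- runif(1, r + 1, W - r - 1)
        cy <- runif(1, r + 1, H - r - 1)
        if (nrow(placed) == 0 ||
            all(sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2) >=
                overlapTol * (placed[, 3] + r))) {
          ok <- TRUE
          break
        }
      }
      if (!ok) next  # field full; remaining beads are simply not placed
      placed <- rbind(placed, c(cx, cy, r))
      amp <- gain * beads$fitc_nM[i] *
        (if (brightnessJitterSd > 0) exp(rnorm(1, 0, brightnessJitterSd)) else 1)
      if (dimFraction > 0 && runif(1) < dimFraction)
        amp <- amp * runif(1, dimRetention[1], dimRetention[2])
      rows <- max(1L, floor(cy - r)):min(H, ceiling(cy + r + 1))
      cols <- max(1L, floor(cx - r)):min(W, ceiling(cx + r + 1))
      dy2 <- (rows - 0.5 - cy)^2
      dx2 <- (cols - 0.5 - cx)^2
      inside <- outer(dy2, dx2, "+") <= r^2
      img[rows, cols][inside] <- background + amp
      ann[[length(ann) + 1L]] <- data.frame(
        object_class = "bead", x = cx - r, y = cy - r, w = 2 * r, h = 2 * r,
        center_x = cx, center_y = cy,
        diameter_um = beads$diameter_um[i],
        alginate_pct = beads$alginate_pct[i],
        fitc_nM = beads$fitc_nM[i], f_high = beads$f_high[i])
    }
    if (!is.null(snrRange) && length(ann)) {
      snr <- runif(1, snrRange[1], snrRange[2])
      noiseSd <- mean(gain * beads$fitc_nM) / snr
      img <- img + matrix(rnorm(H * W, sd = noiseSd), H, W)
    } else if (!is.null(snrRange)) {
      img <- img + matrix(rnorm(H * W, sd = background / mean(snrRange)), H, W)
    }
  })
  annotations <- if (length(ann)) do.call(rbind, ann) else
    data.frame(object_class = character(), x = numeric(), y = numeric(),
               w = numeric(), h = numeric(), center_x = numeric(),
               center_y = numeric(), diameter_um = numeric(),
               alginate_pct = numeric(), fitc_nM = numeric(),
               f_high = numeric())
  list(image = quantise8(img), annotations = annotations)
}

#' Grow synthetic spheroids inside a bead population
#'
#' Convenience generator pairing each (crosslinked) bead with one spheroid:
#' spheroid mean diameter is drawn around `meanDiamUm` and the two
#' semi-axes receive independent log-normal aspect jitter, so a tail of
#' elongated (fused-looking) spheroids falls outside the 0.7-1.3
#' aspect-ratio band.
#'
#' @param beads Bead population `data.frame`.
#' @param meanDiamUm,sdDiamUm Spheroid diameter distribution, um.
#' @param arSdLog SD of the log aspect jitter applied to each semi-axis.
#' @param seed Integer seed.
#' @return `data.frame` with `a_um`, `b_um` (semi-axes), `bead_index`.
#' @export
sampleSpheroids <- function(beads, meanDiamUm = 35, sdDiamUm = 8,
                            arSdLog = 0.08, seed = 1L) {
  n <- nrow(beads)
  withSeed(seed, {
    d <- rnorm(n, meanDiamUm, sdDiamUm)
    while (any(bad <- d <= 5)) d[bad] <- rnorm(sum(bad), meanDiamUm, sdDiamUm)
    ja <- exp(rnorm(n, 0, arSdLog))
    jb <- exp(rnorm(n, 0, arSdLog))
  })
  data.frame(a_um = d / 2 * ja, b_um = d / 2 * jb, bead_index = seq_len(n))
}

#' Render a bright-field spheroid field with ground-truth annotations
#'
#' Spheroids are textured dark ellipses on a bright background with
#' per-object contrast jitter. When `beadAnnotations` is supplied, each
#' spheroid is centred (with jitter) on its host bead so bead and spheroid
#' channels are spatially registered; otherwise positions are sampled
#' uniformly.
#'
#' @param spheroids `data.frame` from [sampleSpheroids()] (`a_um`, `b_um`,
#'   `bead_index`).
#' @param beadAnnotations Optional bead annotation `data.frame` from
#'   [renderBeadField()]; spheroids whose host bead was not placed are
#'   skipped.
#' @param pxPerUm Pixel size, px/um.
#' @param background Background intensity.
#' @param noiseSd Background noise sd.
#' @param imageSize `c(height, width)` px (ignored when registered to a
#'   bead field).
#' @param seed Integer seed.
#' @return List with `image` and `annotations` (`object_class`, half-open
#'   box `x`, `y`, `w`, `h`, `center_x`, `center_y`, `a_um`, `b_um`,
#'   `bead_index`).
#' @export
renderSpheroidField <- function(spheroids, beadAnnotations = NULL,
                                pxPerUm = 0.4, background = 205,
                                noiseSd = 4, imageSize = c(480L, 480L),
                                seed = 1L) {
  H <- imageSize[1]; W <- imageSize[2]
  img <- matrix(as.numeric(background), H, W)
  ann <- list()
  withSeed(seed, {
    for (i in seq_len(NROW(spheroids))) {
      ra <- spheroids$a_um[i] * pxPerUm   # horizontal semi-axis, px
      rb <- spheroids$b_um[i] * pxPerUm
      if (!is.null(beadAnnotations)) {
        j <- match(spheroids$bead_index[i],
                   seq_len(nrow(beadAnnotations)))
        if (is.na(j) || spheroids$bead_index[i] > nrow(beadAnnotations)) next
        jit <- beadAnnotations$w[spheroids$bead_index[i]] / 2 - max(ra, rb)
        jit <- max(0, jit)
        cx <- beadAnnotations$center_x[spheroids$bead_index[i]] +
          runif(1, -jit, jit) * 0.5
        cy <- beadAnnotations$center_y[spheroids$bead_index[i]] +
          runif(1, -jit, jit) * 0.5
      } else {
        cx <- runif(1, ra + 1, W - ra - 1)
        cy <- runif(1, rb + 1, H - rb - 1)
      }
      contrast <- runif(1, 0.35, 0.65)
      rows <- max(1L, floor(cy - rb)):min(H, ceiling(cy + rb + 1))
      cols <- max(1L, floor(cx - ra)):min(W, ceiling(cx + ra + 1))
      dy <- (rows - 0.5 - cy) / rb
      dx <- (cols - 0.5 - cx) / ra
      inside <- outer(dy^2, dx^2, "+") <= 1
      sub <- img[rows, cols]
      texture <- matrix(rnorm(length(sub), 0, 8), nrow(sub), ncol(sub))
      sub[inside] <- background * contrast + texture[inside]
      img[rows, cols] <- sub
      ann[[length(ann) + 1L]] <- data.frame(
        object_class = "spheroid",
        x = cx - ra, y = cy - rb, w = 2 * ra, h = 2 * rb,
        center_x = cx, center_y = cy,
        a_um = spheroids$a_um[i], b_um = spheroids$b_um[i],
        bead_index = spheroids$bead_index[i])
    }
    if (noiseSd > 0)
      img <- img + matrix(rnorm(H * W, sd = noiseSd), H, W)
  })
  annotations <- if (length(ann)) do.call(rbind, ann) else
    data.frame(object_class = character(), x = numeric(), y = numeric(),
               w = numeric(), h = numeric(), center_x = numeric(),
               center_y = numeric(), a_um = numeric(), b_um = numeric(),
               bead_index = integer())
  list(image = quantise8(img), annotations = annotations)
}

#' Write annotations in the package's CSV dialect
#'
#' Columns: `image`, `object_class`, `x`, `y`, `w`, `h`, `alginate_pct`,
#' `fitc_nM`, `f_high` (missing fields filled with `NA`).
#'
#' @param annotations Annotation `data.frame`.
#' @param image Image file name to record.
#' @param path Output CSV; appended to if it exists.
#' @return `path`, invisibly.
#' @export
writeAnnotations <- function(annotations, image, path) {
  cols <- c("object_class", "x", "y", "w", "h", "alginate_pct", "fitc_nM",
            "f_high")
  for (cl in setdiff(cols, names(annotations))) annotations[[cl]] <- NA
  out <- cbind(image = image, annotations[, cols, drop = FALSE])
  data.table::fwrite(out, path, append = file.exists(path))
  invisible(path)
}
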