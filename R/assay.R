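#' @include detector.R calibration.R
NULL

#' Measure spheroids and assign bead-encoded stiffness
#'
#' Converts spheroid detections into physical measurements: diameter is
#' the mean of box width and height divided by the pixel size, aspect
#' ratio is height/width, and only detections with aspect ratio inside
#' `arBand` (inclusive) are retained — irregular or fused spheroids fall
#' outside it. Each retained spheroid is associated with the bead whose
#' centre is nearest to its own; the spheroid centre must fall inside
#' that bead's box, otherwise the spheroid is dropped (counted in the
#' `dropped` attribute). The host bead's fluorescence is converted to
#' alginate concentration and stiffness through `calibration`.
#'
#' @param spheroidDetections Detection `data.frame` for spheroids.
#' @param beadDetections Detection `data.frame` for beads.
#' @param beadIntensities Background-subtracted intensities, one per bead
#'   detection (see [beadIntensity()]).
#' @param calibration A [CalibrationModel-class] with both parts fitted.
#' @param arBand Inclusive aspect-ratio band.
#' @param pxPerUm Pixel size, px/um.
#' @param day Imaging day recorded with each measurement.
#' @return `data.frame`: `diameter_um`, `aspect_ratio`, `bead_fluor`,
#'   `alginate_pct`, `stiffness_Pa`, `day`; attribute `dropped` holds the
#'   counts of AR-filtered and unassigned spheroids.
#' @export
measureSpheroids <- function(spheroidDetections, beadDetections,
                             beadIntensities, calibration,
                             arBand = c(0.7, 1.3), pxPerUm = 0.4,
                             day = NA_integer_) {
  sph <- spheroidDetections
  empty <- data.frame(diameter_um = numeric(), aspect_ratio = numeric(),
                      bead_fluor = numeric(), alginate_pct = numeric(),
                      stiffness_Pa = numeric(), day = integer())
  if (nrow(sph) == 0L) return(empty)
  stopifnot(nrow(beadDetections) == length(beadIntensities))

  ar <- sph$h / sph$w
  keep <- ar >= arBand[1] & ar <= arBand[2]
  nAR <- sum(!keep)
  sph <- sph[keep, , drop = FALSE]
  ar <- ar[keep]
  if (nrow(sph) == 0L || nrow(beadDetections) == 0L) {
    out <- empty
    attr(out, "dropped") <- c(aspect_ratio = nAR, unassigned = nrow(sph))
    return(out)
  }

  bcx <- beadDetections$x + beadDetections$w / 2
  bcy <- beadDetections$y + beadDetections$h / 2
  scx <- sph$x + sph$w / 2
  scy <- sph$y + sph$h / 2
  nearest <- vapply(seq_len(nrow(sph)), function(i) {
    which.min((bcx - scx[i])^2 + (bcy - scy[i])^2)
  }, integer(1))
  contained <- scx >= beadDetections$x[nearest] &
    scx < beadDetections$x[nearest] + beadDetections$w[nearest] &
    scy >= beadDetections$y[nearest] &
    scy < beadDetections$y[nearest] + beadDetections$h[nearest]
  nUnassigned <- sum(!contained)

  sph <- sph[contained, , drop = FALSE]
  ar <- ar[contained]
  nearest <- nearest[contained]
  fluor <- beadIntensities[nearest]
  pct <- concentrationFromIntensity(calibration, fluor)
  out <- data.frame(
    diameter_um = (sph$w + sph$h) / 2 / pxPerUm,
    aspect_ratio = ar,
    bead_fluor = fluor,
    alginate_pct = pct,
    stiffness_Pa = stiffnessFromConcentration(calibration, pct),
    day = rep(day, nrow(sph)))
  attr(out, "dropped") <- c(aspect_ratio = nAR, unassigned = nUnassigned)
  out
}

#' Bin measurements by stiffness and test the medians
#'
#' Splits the observed stiffness range into `nBins` equal-width bins
#' (equal-count on request), summarises each bin (n, median, quartiles),
#' flags bins below `minPerBin` spheroids, and runs a Kruskal-Wallis
#' omnibus test of the diameters across the qualifying bins at
#' `alpha = 0.05`. Degenerate input with identical diameters everywhere
#' yields H = 0, p = 1.
#'
#' @param measurements `data.frame` from [measureSpheroids()].
#' @param nBins Number of stiffness bins.
#' @param minPerBin Minimum spheroids for a bin to enter the test.
#' @param equalCount Use equal-count (quantile) bins instead of
#'   equal-width.
#' @param value,by Column names for the tested value and the binning axis.
#' @param alpha Test level.
#' @return List: `bins` (per-bin summaries with `flagged`), `test`
#'   (`htest` from [stats::kruskal.test()], or the degenerate H = 0
#'   result), `significant`, `alpha`, `violin` (per-bin value vectors for
#'   plotting).
#' @export
binAndTest <- function(measurements, nBins = 8L, minPerBin = 65L,
                       equalCount = FALSE, value = "diameter_um",
                       by = "stiffness_Pa", alpha = 0.05) {
  v <- measurements[[value]]
  b <- measurements[[by]]
  if (length(v) == 0L) stop("no measurements")
  if (diff(range(b)) <= 0) stop("measurements do not span a range of ", by)
  breaks <- if (equalCount) {
    unique(quantile(b, probs = seq(0, 1, length.out = nBins + 1)))
  } else {
    seq(min(b), max(b), length.out = nBins + 1)
  }
  bin <- cut(b, breaks = breaks, include.lowest = TRUE)
  bins <- do.call(rbind, lapply(levels(bin), function(lv) {
    x <- v[bin == lv]
    data.frame(bin = lv,
               lower = breaks[match(lv, levels(bin))],
               upper = breaks[match(lv, levels(bin)) + 1],
               n = length(x),
               median = if (length(x)) median(x) else NA_real_,
               q25 = if (length(x)) unname(quantile(x, 0.25)) else NA_real_,
               q75 = if (length(x)) unname(quantile(x, 0.75)) else NA_real_)
  }))
  bins$flagged <- bins$n < minPerBin
  ok <- !bins$flagged & bins$n > 0
  if (sum(ok) < 2L)
    stop("fewer than 2 bins reach the minimum of ", minPerBin, " spheroids")
  qual <- bin %in% bins$bin[ok]
  if (length(unique(v[qual])) == 1L) {
    test <- structure(list(statistic = c(`Kruskal-Wallis chi-squared` = 0),
                           parameter = c(df = sum(ok) - 1),
                           p.value = 1,
                           method = "Kruskal-Wallis rank sum test (degenerate: all values identical)",
                           data.name = value),
                      class = "htest")
  } else {
    test <- kruskal.test(v[qual], droplevels(bin[qual]))
  }
  list(bins = bins, test = test,
       significant = test$p.value < alpha, alpha = alpha,
       violin = split(v[qual], droplevels(bin[qual])))
}
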