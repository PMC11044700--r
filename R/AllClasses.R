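#' @include utils.R
NULL

# ---------------------------------------------------------------------------
# FlowFrame: one synthetic flow-junction image with its ground truth.
# ---------------------------------------------------------------------------

#' FlowFrame: a synthetic flow-junction frame with ground truth
#'
#' Holds one 120x120 8-bit grayscale image of the laminar co-flow junction,
#' the true fraction of the channel width occupied by the high-concentration
#' stream, and the binary mask of occluding cells.
#'
#' @slot pixels Integer matrix (120x120) of intensities in \[0, 255\].
#' @slot fHigh True volume fraction of the high-concentration stream, in
#'   \[0, 1\].
#' @slot cellMask Logical matrix marking pixels covered by rendered cells.
#' @slot seed Integer seed the frame was generated with.
#'
#' @aliases FlowFrame
#' @exportClass FlowFrame
setClass("FlowFrame",
  representation(pixels = "matrix", fHigh = "numeric",
                 cellMask = "matrix", seed = "integer"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@pixels)
    if (!identical(d, c(120L, 120L)))
      msg <- c(msg, "pixels must be 120x120")
    if (any(object@pixels < 0L) || any(object@pixels > 255L))
      msg <- c(msg, "pixel values must lie in [0, 255]")
    if (length(object@fHigh) != 1L || object@fHigh < 0 || object@fHigh > 1)
      msg <- c(msg, "fHigh must be a single value in [0, 1]")
    if (!identical(dim(object@cellMask), d))
      msg <- c(msg, "cellMask must match pixel dimensions")
    if (length(msg)) msg else TRUE
  })

#' @describeIn FlowFrame-class Pixel matrix accessor.
#' @param object,x A `FlowFrame`.
#' @export
framePixels <- function(x) x@pixels

#' @describeIn FlowFrame-class True interface fraction accessor.
#' @export
trueFraction <- function(x) x@fHigh

#' @describeIn FlowFrame-class Cell occlusion mask accessor.
#' @export
cellMask <- function(x) x@cellMask

setMethod("show", "FlowFrame", function(object) {
  cat("FlowFrame: 120x120 8-bit junction image\n",
      "  f_high (true): ", format(object@fHigh, digits = 4),
      " | interface column ~", round(object@fHigh * 120),
      " | occluded px: ", sum(object@cellMask), "\n", sep = "")
})

# ---------------------------------------------------------------------------
# FrameSet: a labelled classifier dataset of FlowFrames.
# ---------------------------------------------------------------------------

#' FrameSet: a labelled set of flow frames with a stratified split
#'
#' @slot frames List of [FlowFrame-class] objects.
#' @slot labels Factor with levels `LOW_VF`, `HIGH_VF` (low/high volume
#'   fraction of the high-concentration stream).
#' @slot split Factor with levels `train`, `test` (stratified 70/30).
#'
#' @aliases FrameSet
#' @exportClass FrameSet
setClass("FrameSet",
  representation(frames = "list", labels = "factor", split = "factor"),
  validity = function(object) {
    msg <- character()
    n <- length(object@frames)
    if (length(object@labels) != n || length(object@split) != n)
      msg <- c(msg, "labels and split must match the number of frames")
    if (!identical(levels(object@labels), c("LOW_VF", "HIGH_VF")))
      msg <- c(msg, "labels must have levels LOW_VF, HIGH_VF")
    if (!all(levels(object@split) %in% c("train", "test")))
      msg <- c(msg, "split levels must be train/test")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "FrameSet", function(object) {
  cat("FrameSet:", length(object@frames), "frames |",
      paste(sprintf("%s=%d", levels(object@labels), table(object@labels)),
            collapse = " "),
      "|", sum(object@split == "train"), "train /",
      sum(object@split == "test"), "test\n")
})

setMethod("length", "FrameSet", function(x) length(x@frames))

#' @describeIn FrameSet-class Extract the frames as a list.
#' @param x A `FrameSet`.
#' @export
frameList <- function(x) x@frames

#' @describeIn FrameSet-class Class labels accessor.
#' @export
frameLabels <- function(x) x@labels

#' @describeIn FrameSet-class Train/test split accessor.
#' @export
frameSplit <- function(x) x@split

#' @describeIn FrameSet-class True interface fractions for all frames.
#' @export
frameFractions <- function(x) vapply(x@frames, trueFraction, numeric(1))

# ---------------------------------------------------------------------------
# InterfaceClassifier: shallow CNN for LOW_VF / HIGH_VF frames.
# ---------------------------------------------------------------------------

#' InterfaceClassifier: shallow convolutional interface classifier
#'
#' A fixed-topology shallow CNN: three 3x3 convolution + 2x2 max-pooling
#' stages, one dense ReLU stage and a two-way softmax. Weights are plain
#' numeric arrays, portable across platforms.
#'
#' @slot topology List with elements `filters` (three conv widths), `dense`
#'   (dense width), `inputShape` (c(120, 120, 1)).
#' @slot weights Named list of weight matrices/vectors (W1..W5, b1..b5).
#' @slot classOrder Character vector `c("LOW_VF", "HIGH_VF")`; softmax
#'   column order.
#' @slot trained Logical flag.
#' @slot seed Integer initialisation seed.
#'
#' @aliases InterfaceClassifier
#' @exportClass InterfaceClassifier
setClass("InterfaceClassifier",
  representation(topology = "list", weights = "list",
                 classOrder = "character", trained = "logical",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@topology$filters) != 3L)
      msg <- c(msg, "exactly 3 convolutional stages required")
    if (!identical(object@classOrder, c("LOW_VF", "HIGH_VF")))
      msg <- c(msg, "classOrder must be c('LOW_VF', 'HIGH_VF')")
    need <- c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4", "W5", "b5")
    if (!all(need %in% names(object@weights)))
      msg <- c(msg, "weights must contain W1..W5/b1..b5")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "InterfaceClassifier", function(object) {
  np <- sum(vapply(object@weights, length, numeric(1)))
  cat("InterfaceClassifier: 3-conv shallow CNN (",
      paste(object@topology$filters, collapse = "/"), " filters, dense ",
      object@topology$dense, ")\n  input ",
      paste(object@topology$inputShape, collapse = "x"), " | ",
      format(np, big.mark = ","), " parameters | ",
      if (object@trained) "trained" else "untrained", "\n", sep = "")
})

# ---------------------------------------------------------------------------
# StockSpec: one alginate stock solution.
# ---------------------------------------------------------------------------

#' StockSpec: composition of one alginate stock solution
#'
#' @slot alginatePct Alginate concentration, % w/v.
#' @slot fitcNM FITC-dextran concentration, nM.
#' @slot caMM Ca2+ (as Ca-EDTA) concentration, mM.
#' @slot znMM Zn2+ (as Zn-EDDA) concentration, mM.
#' @slot viscosityCP Apparent viscosity, cP.
#'
#' @aliases StockSpec
#' @exportClass StockSpec
setClass("StockSpec",
  representation(alginatePct = "numeric", fitcNM = "numeric",
                 caMM = "numeric", znMM = "numeric", viscosityCP = "numeric"),
  validity = function(object) {
    v <- c(object@alginatePct, object@fitcNM, object@caMM, object@znMM,
           object@viscosityCP)
    if (any(v < 0)) "all concentrations/viscosities must be >= 0" else TRUE
  })

#' Construct a StockSpec
#'
#' @param alginatePct Alginate % w/v.
#' @param fitcNM FITC-dextran, nM.
#' @param caMM Ca2+, mM.
#' @param znMM Zn2+, mM.
#' @param viscosityCP Apparent viscosity, cP.
#' @return A [StockSpec-class] object.
#' @export
StockSpec <- function(alginatePct, fitcNM, caMM = 0, znMM = 0,
                      viscosityCP = 100) {
  new("StockSpec", alginatePct = alginatePct, fitcNM = fitcNM,
      caMM = caMM, znMM = znMM, viscosityCP = viscosityCP)
}

setMethod("show", "StockSpec", function(object) {
  cat(sprintf(
    "StockSpec: %.2f%% w/v alginate | %.0f nM FITC | Ca %.0f mM | Zn %.0f mM | %.0f cP\n",
    object@alginatePct, object@fitcNM, object@caMM, object@znMM,
    object@viscosityCP))
})

# ---------------------------------------------------------------------------
# PlantState: the simulated fluidic plant at one instant.
# ---------------------------------------------------------------------------

#' PlantState: state of the simulated co-flow plant
#'
#' @slot t Simulated time, s.
#' @slot qActual Named numeric `c(low=, high=)`: delivered flows, uL/min.
#' @slot fHigh Realised interface fraction in \[0, 1\].
#' @slot dropletRate Droplet generation rate, Hz.
#' @slot stocks List with elements `low`, `high` ([StockSpec-class]).
#' @slot params List of plant parameters (lags, noise, droplet geometry).
#'
#' @aliases PlantState
#' @exportClass PlantState
setClass("PlantState",
  representation(t = "numeric", qActual = "numeric", fHigh = "numeric",
                 dropletRate = "numeric", stocks = "list", params = "list"),
  validity = function(object) {
    msg <- character()
    if (object@fHigh < 0 || object@fHigh > 1)
      msg <- c(msg, "fHigh must lie in [0, 1]")
    if (any(object@qActual < 0))
      msg <- c(msg, "actual flows must be >= 0")
    if (!all(c("low", "high") %in% names(object@stocks)))
      msg <- c(msg, "stocks must have elements low and high")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "PlantState", function(object) {
  cat(sprintf(
    "PlantState @ t=%.2f s: Q = (%.2f, %.2f) uL/min | f_high = %.3f | %.0f Hz\n",
    object@t, object@qActual[["low"]], object@qActual[["high"]],
    object@fHigh, object@dropletRate))
})

#' @describeIn PlantState-class Realised interface fraction accessor.
#' @param x A `PlantState`.
#' @export
realizedFraction <- function(x) x@fHigh

#' @describeIn PlantState-class Delivered flow rates (uL/min) accessor.
#' @export
actualFlows <- function(x) x@qActual

# ---------------------------------------------------------------------------
# CalibrationModel: fluorescence -> concentration -> stiffness.
# ---------------------------------------------------------------------------

#' CalibrationModel: fluorescence-to-concentration-to-stiffness maps
#'
#' The linear part maps mean bead fluorescence to alginate concentration by
#' anchoring the 5th/95th percentiles of a Gaussian fitted to the intensity
#' histogram at 0.7 and 2.8 % w/v. The quadratic part maps concentration c
#' (% w/v) to storage modulus G'(c) = a c^2 + b c (+ c0 when fitted to more
#' than two rheology points).
#'
#' @slot slope Linear slope, % per intensity unit (> 0).
#' @slot intercept Linear intercept, % w/v.
#' @slot anchorsI Numeric `c(I5=, I95=)`: intensity anchors.
#' @slot anchorsPct Numeric `c(low=, high=)`: concentration anchors, % w/v.
#' @slot stiffCoef Numeric `c(a=, b=, c0=)`: quadratic coefficients, Pa.
#' @slot stiffRange Concentration range (% w/v) over which monotonicity of
#'   G' was verified.
#'
#' @aliases CalibrationModel
#' @exportClass CalibrationModel
setClass("CalibrationModel",
  representation(slope = "numeric", intercept = "numeric",
                 anchorsI = "numeric", anchorsPct = "numeric",
                 stiffCoef = "numeric", stiffRange = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@slope) && object@slope <= 0)
      msg <- c(msg, "slope must be > 0")
    if (length(object@stiffCoef) == 3L && length(object@stiffRange) == 2L) {
      cc <- seq(object@stiffRange[1], object@stiffRange[2], length.out = 64)
      g <- object@stiffCoef[1] * cc^2 + object@stiffCoef[2] * cc
      if (any(diff(g) <= 0))
        msg <- c(msg, "G' must be strictly increasing over stiffRange")
    }
    if (length(msg)) msg else TRUE
  })

setMethod("show", "CalibrationModel", function(object) {
  if (length(object@slope))
    cat(sprintf(
      "CalibrationModel: c(I) = %.4g + %.4g I  (anchors I5=%.1f -> %.2f%%, I95=%.1f -> %.2f%%)\n",
      object@intercept, object@slope, object@anchorsI[["I5"]],
      object@anchorsPct[["low"]], object@anchorsI[["I95"]],
      object@anchorsPct[["high"]]))
  if (length(object@stiffCoef))
    cat(sprintf("  G'(c) = %.4g c^2 + %.4g c + %.4g Pa on [%.2f, %.2f] %% w/v\n",
                object@stiffCoef[1], object@stiffCoef[2], object@stiffCoef[3],
                object@stiffRange[1], object@stiffRange[2]))
})

# ---------------------------------------------------------------------------
# GridDetector: single-stage grid object detector.
# ---------------------------------------------------------------------------

#' GridDetector: lightweight single-stage grid object detector
#'
#' Anchor-free detector operating on a regular grid of candidate centres:
#' per-cell pooled patch features feed a logistic objectness score and ridge
#' regressors for the centre offset and box size. One class per model.
#'
#' @slot objectClass `"bead"` or `"spheroid"`.
#' @slot wObj Numeric objectness weights (incl. intercept).
#' @slot wBox Numeric matrix of box regression weights, columns
#'   `dx`, `dy`, `w`, `h`.
#' @slot featMean,featSd Feature standardisation vectors.
#' @slot params List: `cellSize`, `patch`, `block`, `profBins`, `profStep`,
#'   `profBand`.
#'
#' @aliases GridDetector
#' @exportClass GridDetector
setClass("GridDetector",
  representation(objectClass = "character", wObj = "numeric",
                 wBox = "matrix", featMean = "numeric", featSd = "numeric",
                 params = "list"),
  validity = function(object) {
    msg <- character()
    if (!object@objectClass %in% c("bead", "spheroid"))
      msg <- c(msg, "objectClass must be 'bead' or 'spheroid'")
    if (ncol(object@wBox) && !identical(colnames(object@wBox),
                                        c("dx", "dy", "w", "h")))
      msg <- c(msg, "wBox columns must be dx, dy, w, h")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "GridDetector", function(object) {
  cat("GridDetector (", object@objectClass, "): cell ",
      object@params$cellSize, " px, patch ", object@params$patch,
      " px, ", length(object@wObj) - 1L, " features\n", sep = "")
})
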