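#' @include AllClasses.R synthfix.R
NULL

#' Build an untrained shallow interface classifier
#'
#' Fixed topology: three 3x3 convolution stages (ReLU, 2x2 max-pool) of
#' widths `filters`, one dense ReLU stage of width `dense`, and a two-way
#' softmax over (LOW_VF, HIGH_VF). Fewer than three convolution stages do
#' not produce reliable interface models, so the stage count is not
#' configurable. He-initialised deterministically from `seed`.
#'
#' @param filters Integer vector of exactly three convolution widths.
#' @param dense Dense layer width.
#' @param seed Initialisation seed.
#' @return An [InterfaceClassifier-class].
#' @export
buildInterfaceClassifier <- function(filters = c(8L, 16L, 32L), dense = 64L,
                                     seed = 1L) {
  if (length(filters) != 3L)
    stop("exactly 3 convolutional stages are required")
  f <- as.integer(filters)
  d <- as.integer(dense)
  nflat <- f[3] * 15L * 15L   # 120 -> 60 -> 30 -> 15 after three pools
  he <- function(nr, nc) matrix(rnorm(nr * nc, sd = sqrt(2 / nc)), nr, nc)
  w <- withSeed(seed, list(
    W1 = he(f[1], 9L), b1 = numeric(f[1]),
    W2 = he(f[2], 9L * f[1]), b2 = numeric(f[2]),
    W3 = he(f[3], 9L * f[2]), b3 = numeric(f[3]),
    W4 = he(d, nflat), b4 = numeric(d),
    W5 = he(2L, d), b5 = numeric(2L)))
  new("InterfaceClassifier",
      topology = list(filters = f, dense = d, inputShape = c(120L, 120L, 1L)),
      weights = w, classOrder = c("LOW_VF", "HIGH_VF"),
      trained = FALSE, seed = as.integer(seed))
}

# Stack frames into the H x W x N cube the C++ kernels expect.
framesToCube <- function(frames) {
  if (is(frames, "FrameSet")) frames <- frameList(frames)
  if (is(frames, "FlowFrame")) frames <- list(frames)
  if (is.matrix(frames)) frames <- list(frames)
  mats <- lapply(frames, function(f) {
    m <- if (is(f, "FlowFrame")) framePixels(f) else f
    if (!identical(dim(m), c(120L, 120L)))
      stop("frames must be 120x120")
    m
  })
  array(unlist(mats), dim = c(120L, 120L, length(mats)))
}

#' Train (or retrain) the interface classifier
#'
#' Mini-batch Adam on softmax cross-entropy over the `train` portion of the
#' stratified split; accuracy is reported on the 30% held-out `test`
#' portion. Incremental retraining is dataset concatenation: combine the
#' old and new frames with [combineFrameSets()] and call this again.
#' `epochs = 0` returns the model unchanged.
#'
#' @param model An [InterfaceClassifier-class].
#' @param dataset A [FrameSet-class]; both classes must be present.
#' @param epochs Training epochs.
#' @param seed Shuffling seed.
#' @param lr Adam learning rate.
#' @param batchSize Mini-batch size.
#' @return List: `model` (trained classifier), `heldOutAccuracy`,
#'   `epochLoss` (mean training loss per epoch).
#' @export
trainInterfaceClassifier <- function(model, dataset, epochs = 8L, seed = 1L,
                                     lr = 1e-3, batchSize = 32L) {
  labs <- frameLabels(dataset)
  if (nlevels(droplevels(labs)) < 2L)
    stop("dataset must contain both classes")
  tr <- which(frameSplit(dataset) == "train")
  te <- which(frameSplit(dataset) == "test")
  if (epochs > 0) {
    cube <- framesToCube(frameList(dataset)[tr])
    y <- as.integer(labs[tr] == "HIGH_VF")   # 0 = LOW_VF, 1 = HIGH_VF
    order <- withSeed(seed, vapply(seq_len(epochs),
                                   function(e) sample.int(length(tr)),
                                   integer(length(tr))))
    fit <- .cnn_train(model@weights, cube, y, matrix(order, ncol = epochs),
                      as.integer(batchSize), lr)
    model@weights <- fit$weights
    model@trained <- TRUE
    epochLoss <- drop(fit$epoch_loss)
  } else {
    epochLoss <- numeric(0)
  }
  acc <- if (length(te)) {
    p <- predictInterface(model, frameList(dataset)[te])
    mean(classifyFromProbs(p) == as.character(labs[te]))
  } else NA_real_
  list(model = model, heldOutAccuracy = acc, epochLoss = epochLoss)
}

#' Class probabilities for flow frames
#'
#' Runs the forward pass; each image is internally standardised, so the
#' output is invariant to affine intensity rescaling. Single-frame latency
#' on one CPU is a few milliseconds, well inside the 20 ms frame budget.
#'
#' @param model An [InterfaceClassifier-class].
#' @param frames A [FlowFrame-class], list of them, [FrameSet-class], or a
#'   120x120 matrix.
#' @return Numeric matrix (n x 2) with columns `LOW_VF`, `HIGH_VF`; rows
#'   sum to 1.
#' @export
predictInterface <- function(model, frames) {
  cube <- framesToCube(frames)
  p <- .cnn_forward(model@weights, cube)
  colnames(p) <- model@classOrder
  p
}

# argmax with deterministic tie-break toward LOW_VF
classifyFromProbs <- function(p) {
  ifelse(p[, "HIGH_VF"] > p[, "LOW_VF"], "HIGH_VF", "LOW_VF")
}

#' Hard class labels for flow frames
#'
#' @inheritParams predictInterface
#' @return Factor with levels `LOW_VF`, `HIGH_VF` (ties break to `LOW_VF`).
#' @export
classifyFrames <- function(model, frames) {
  factor(classifyFromProbs(predictInterface(model, frames)),
         levels = c("LOW_VF", "HIGH_VF"))
}

#' Windowed class estimate
#'
#' Mean and population standard deviation of a window of binary class
#' predictions (1 = HIGH_VF). At the 50 Hz frame rate a 50-frame window
#' yields one flow-rate update per second. The population sd is used
#' because the window length is fixed; it is bounded by 0.5 and exceeds
#' 0.4 exactly when the window mean lies strictly between 0.2 and 0.8.
#'
#' @param predictions Binary vector (0/1, logical, or a factor with levels
#'   `LOW_VF`/`HIGH_VF`) of length exactly `windowSize`.
#' @param windowSize Required window length.
#' @return List with `mean`, `std`, `windowSize`.
#' @export
windowEstimate <- function(predictions, windowSize = 50L) {
  if (is.factor(predictions)) predictions <- predictions == "HIGH_VF"
  x <- as.numeric(predictions)
  if (length(x) != windowSize)
    stop("need exactly ", windowSize, " predictions")
  if (!all(x %in% c(0, 1))) stop("predictions must be binary")
  m <- mean(x)
  list(mean = m, std = sqrt(mean((x - m)^2)), windowSize = windowSize)
}
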