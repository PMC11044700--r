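#' @include AllClasses.R
NULL

#' Default grid-detector parameters
#'
#' @param objectClass `"bead"` or `"spheroid"`.
#' @return Named list: `cellSize` (grid stride, px), `patch` (feature patch
#'   side, px), `block` (pooling block, px), `profBins`, `profStep`,
#'   `profBand` (extent-profile geometry, px).
#' @export
defaultDetectorParams <- function(objectClass = "bead") {
  list(cellSize = 16L, patch = 96L, block = 12L,
       profBins = 16L, profStep = 3, profBand = 8L)
}

# Feature matrix for a set of candidate centres (adds nothing to the C++
# pooled features beyond the intercept handled by the caller).
gridFeatures <- function(image, cx, cy, params) {
  .grid_features(matrix(as.numeric(image), nrow(image), ncol(image)),
                 as.numeric(cx), as.numeric(cy),
                 params$patch, params$block,
                 params$profBins, params$profStep, params$profBand)
}

gridCentres <- function(dimHW, cellSize) {
  cy <- seq(cellSize / 2, dimHW[1] - cellSize / 2, by = cellSize)
  cx <- seq(cellSize / 2, dimHW[2] - cellSize / 2, by = cellSize)
  list(cx = rep(cx, times = length(cy)), cy = rep(cy, each = length(cx)))
}

# Ridge-regularised logistic regression by IRLS; deterministic.
ridgeLogistic <- function(X, y, lambda = 1, iters = 20L) {
  w <- numeric(ncol(X))
  for (i in seq_len(iters)) {
    p <- stats::plogis(drop(X %*% w))
    p <- clamp(p, 1e-9, 1 - 1e-9)
    wt <- p * (1 - p)
    H <- crossprod(X, X * wt) + diag(lambda, ncol(X))
    g <- crossprod(X, p - y) + lambda * w
    step <- solve(H, g)
    w <- w - drop(step)
    if (max(abs(step)) < 1e-8) break
  }
  w
}

#' Train a single-stage grid detector
#'
#' Lightweight stand-in for a full convolutional detector with the same
#' analytical role: candidate centres on a regular grid, pooled patch and
#' extent-profile features (extracted in C++), logistic objectness and
#' ridge regression of centre offsets and box sizes. One object class per
#' model. Images are split stratified 70/30 into train and test sets and
#' the held-out average precision at IoU 0.5 is reported.
#'
#' @param fields List of rendered fields, each a list with `image` and
#'   `annotations` (the [renderBeadField()] / [renderSpheroidField()]
#'   output format).
#' @param objectClass `"bead"` or `"spheroid"`.
#' @param params Detector parameters ([defaultDetectorParams()]).
#' @param trainFrac Training fraction of the image split.
#' @param lambda Ridge penalty.
#' @param seed Split seed.
#' @return List: `model` ([GridDetector-class]), `split` (factor per
#'   field), `testAP` (held-out AP at IoU 0.5).
#' @export
trainGridDetector <- function(fields, objectClass = "bead",
                              params = defaultDetectorParams(objectClass),
                              trainFrac = 0.7, lambda = 1, seed = 1L) {
  if (!length(fields)) stop("no training fields supplied")
  nAnn <- vapply(fields, function(f) nrow(f$annotations), integer(1))
  if (sum(nAnn) == 0L) stop("annotations are empty")
  nF <- length(fields)
  nTrain <- max(1L, round(trainFrac * nF))
  # stratified by annotation density: fields ordered by object count are
  # dealt into the two splits so dense and sparse fields land in both
  split <- withSeed(seed, {
    ord <- order(nAnn, runif(nF))
    nTest <- nF - nTrain
    testPick <- if (nTest > 0) ord[ceiling(seq_len(nTest) * nF / nTest)]
                else integer(0)
    s <- rep("train", nF)
    if (nTrain < nF) s[testPick] <- "test"
    factor(s, levels = c("train", "test"))
  })

  featList <- list(); labList <- list(); boxList <- list()
  ctrFeatList <- list(); ctrSizeList <- list()
  jitterSeeds <- fanOutSeeds(seed + 2L, length(fields))
  for (i in which(split == "train")) {
    img <- fields[[i]]$image
    ann <- fields[[i]]$annotations
    g <- gridCentres(dim(img), params$cellSize)
    X <- gridFeatures(img, g$cx, g$cy, params)
    y <- numeric(length(g$cx))
    use <- rep(TRUE, length(g$cx))   # cells inside an object but not its
                                     # centre cell are ambiguous: ignored
    B <- matrix(NA_real_, length(g$cx), 4,
                dimnames = list(NULL, c("dx", "dy", "w", "h")))
    if (nrow(ann)) {
      gcx <- ann$x + ann$w / 2
      gcy <- ann$y + ann$h / 2
      for (j in seq_len(nrow(ann))) {
        dx <- gcx[j] - g$cx; dy <- gcy[j] - g$cy
        d2 <- dx^2 + dy^2
        # the 8 cells adjacent to the centre cell are ambiguous; cells
        # deeper inside the object stay as clear negatives
        use[abs(dx) <= params$cellSize & abs(dy) <= params$cellSize] <- FALSE
        hit <- which(abs(dx) <= params$cellSize / 2 &
                     abs(dy) <= params$cellSize / 2)
        if (length(hit)) {
          hit <- hit[which.min(d2[hit])]
          y[hit] <- 1
          use[hit] <- TRUE
          B[hit, ] <- c(dx[hit], dy[hit], ann$w[j], ann$h[j])
        }
      }
    }
    featList[[length(featList) + 1L]] <- X[use, , drop = FALSE]
    labList[[length(labList) + 1L]] <- y[use]
    boxList[[length(boxList) + 1L]] <- B[use, , drop = FALSE]
    if (nrow(ann)) {
      # size regression is trained on (nearly) object-centred patches,
      # matching the refinement pass applied at inference
      jit <- withSeed(jitterSeeds[i],
                      matrix(runif(2L * nrow(ann), -2, 2), ncol = 2))
      ctrFeatList[[length(ctrFeatList) + 1L]] <-
        gridFeatures(img, ann$x + ann$w / 2 + jit[, 1],
                     ann$y + ann$h / 2 + jit[, 2], params)
      ctrSizeList[[length(ctrSizeList) + 1L]] <-
        cbind(w = ann$w, h = ann$h)
    }
  }
  X <- do.call(rbind, featList)
  y <- unlist(labList)
  B <- do.call(rbind, boxList)

  fm <- colMeans(X)
  fs <- apply(X, 2, sd)
  fs[fs < 1e-9] <- 1
  Xs <- cbind(1, sweep(sweep(X, 2, fm), 2, fs, "/"))
  wObj <- ridgeLogistic(Xs, y, lambda = lambda)

  pos <- which(y == 1)
  Xp <- Xs[pos, , drop = FALSE]
  wOff <- solve(crossprod(Xp) + diag(lambda, ncol(Xp)),
                crossprod(Xp, B[pos, c("dx", "dy"), drop = FALSE]))
  Xc <- do.call(rbind, ctrFeatList)
  Xc <- cbind(1, sweep(sweep(Xc, 2, fm), 2, fs, "/"))
  Yc <- do.call(rbind, ctrSizeList)
  wSize <- solve(crossprod(Xc) + diag(lambda, ncol(Xc)),
                 crossprod(Xc, Yc))
  wBox <- cbind(wOff, wSize)
  colnames(wBox) <- c("dx", "dy", "w", "h")

  model <- new("GridDetector", objectClass = objectClass, wObj = drop(wObj),
               wBox = wBox, featMean = fm, featSd = fs, params = params)

  testAP <- NA_real_
  teIdx <- which(split == "test")
  if (length(teIdx)) {
    dets <- list(); gts <- list()
    for (i in teIdx) {
      d <- detectObjects(model, fields[[i]]$image, confThresh = 0.25)
      if (nrow(d)) d$image <- i
      dets[[length(dets) + 1L]] <- d
      gt <- fields[[i]]$annotations
      if (nrow(gt)) gt$image <- i
      gts[[length(gts) + 1L]] <- gt
    }
    dets <- do.call(rbind, dets)
    gts <- do.call(rbind, gts)
    if (nrow(gts)) testAP <- evaluateAP(dets, gts, iouThresh = 0.5)
  }
  list(model = model, split = split, testAP = testAP)
}

#' Detect objects in an image
#'
#' Scores every grid cell, decodes centre offsets and box sizes for cells
#' above `confThresh`, and removes duplicates by greedy non-maximum
#' suppression. Per-image latency on one CPU is well below 1 s.
#'
#' @param model A [GridDetector-class].
#' @param image Intensity matrix.
#' @param confThresh Objectness threshold in \[0, 1\].
#' @param nmsIoU IoU threshold for suppression.
#' @return `data.frame`: `x`, `y`, `w`, `h` (half-open pixel box),
#'   `score`, `object_class`.
#' @export
detectObjects <- function(model, image, confThresh = 0.5, nmsIoU = 0.5) {
  p <- model@params
  g <- gridCentres(dim(image), p$cellSize)
  X <- gridFeatures(image, g$cx, g$cy, p)
  Xs <- cbind(1, sweep(sweep(X, 2, model@featMean), 2, model@featSd, "/"))
  score <- stats::plogis(drop(Xs %*% model@wObj))
  keep <- which(score >= confThresh)
  if (!length(keep))
    return(data.frame(x = numeric(), y = numeric(), w = numeric(),
                      h = numeric(), score = numeric(),
                      object_class = character()))
  reg <- Xs[keep, , drop = FALSE] %*% model@wBox
  # one refinement pass: re-extract features at the predicted centre so the
  # size regression sees a (nearly) centred patch
  rcx <- g$cx[keep] + reg[, "dx"]
  rcy <- g$cy[keep] + reg[, "dy"]
  Xr <- gridFeatures(image, rcx, rcy, p)
  Xr <- cbind(1, sweep(sweep(Xr, 2, model@featMean), 2, model@featSd, "/"))
  reg2 <- Xr %*% model@wBox
  w <- pmax(reg2[, "w"], 2)
  h <- pmax(reg2[, "h"], 2)
  x1 <- clamp(rcx + reg2[, "dx"] - w / 2, 0, ncol(image) - 2)
  y1 <- clamp(rcy + reg2[, "dy"] - h / 2, 0, nrow(image) - 2)
  det <- data.frame(x = x1, y = y1,
                    w = pmin(w, ncol(image) - x1),
                    h = pmin(h, nrow(image) - y1),
                    score = score[keep],
                    object_class = model@objectClass)
  det <- nmsBoxes(det, nmsIoU)
  # objects of one class cannot be concentric: additionally suppress any
  # lower-scoring box whose centre falls inside a kept box
  keepC <- rep(TRUE, nrow(det))
  cx <- det$x + det$w / 2
  cy <- det$y + det$h / 2
  for (i in seq_len(nrow(det))) {
    if (!keepC[i]) next
    if (i < nrow(det)) {
      rest <- (i + 1):nrow(det)
      inside <- cx[rest] >= det$x[i] & cx[rest] < det$x[i] + det$w[i] &
        cy[rest] >= det$y[i] & cy[rest] < det$y[i] + det$h[i]
      keepC[rest][inside] <- FALSE
    }
  }
  det[keepC, , drop = FALSE]
}

# IoU between two sets of half-open boxes (vectorised over the first).
boxIoU <- function(a, b) {
  ix <- pmax(0, pmin(a$x + a$w, b$x + b$w) - pmax(a$x, b$x))
  iy <- pmax(0, pmin(a$y + a$h, b$y + b$h) - pmax(a$y, b$y))
  inter <- ix * iy
  inter / (a$w * a$h + b$w * b$h - inter)
}

#' Greedy non-maximum suppression
#'
#' @param det Detection `data.frame` with `x`, `y`, `w`, `h`, `score`.
#' @param nmsIoU Boxes overlapping a kept higher-scoring box beyond this
#'   IoU are removed.
#' @return The surviving detections, ordered by decreasing score.
#' @export
nmsBoxes <- function(det, nmsIoU = 0.5) {
  det <- det[order(-det$score), , drop = FALSE]
  keep <- logical(nrow(det))
  alive <- rep(TRUE, nrow(det))
  for (i in seq_len(nrow(det))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    if (i < nrow(det)) {
      rest <- (i + 1):nrow(det)
      iou <- boxIoU(det[rest, , drop = FALSE], det[i, , drop = FALSE])
      alive[rest][iou > nmsIoU] <- FALSE
    }
  }
  det[keep, , drop = FALSE]
}

#' All-point interpolated average precision
#'
#' Detections are taken in decreasing score order; each is greedily matched
#' to the unmatched ground-truth box of highest IoU at or above
#' `iouThresh` (within the same `image` when both tables carry that
#' column). AP is the area under the precision envelope of the resulting
#' precision-recall curve.
#'
#' @param detections `data.frame` with `x`, `y`, `w`, `h`, `score` (and
#'   optionally `image`).
#' @param groundTruth `data.frame` with `x`, `y`, `w`, `h` (and optionally
#'   `image`).
#' @param iouThresh Matching threshold.
#' @return AP in \[0, 1\].
#' @export
evaluateAP <- function(detections, groundTruth, iouThresh = 0.5) {
  if (is.null(groundTruth) || nrow(groundTruth) == 0L)
    stop("average precision is undefined without ground truth")
  nGT <- nrow(groundTruth)
  if (is.null(detections) || nrow(detections) == 0L) return(0)
  byImage <- "image" %in% names(detections) && "image" %in% names(groundTruth)
  det <- detections[order(-detections$score), , drop = FALSE]
  matched <- logical(nGT)
  tp <- numeric(nrow(det))
  for (i in seq_len(nrow(det))) {
    cand <- if (byImage) which(!matched & groundTruth$image == det$image[i])
            else which(!matched)
    if (!length(cand)) next
    iou <- boxIoU(groundTruth[cand, , drop = FALSE], det[i, , drop = FALSE])
    j <- which.max(iou)
    if (iou[j] >= iouThresh) {
      matched[cand[j]] <- TRUE
      tp[i] <- 1
    }
  }
  cumTP <- cumsum(tp)
  precision <- cumTP / seq_along(tp)
  recall <- cumTP / nGT
  # precision envelope, integrated over all recall change points
  penv <- rev(cummax(rev(precision)))
  sum(diff(c(0, recall)) * penv)
}

#' Background-subtracted mean bead intensity
#'
#' For each detection, the mean intensity over the disc inscribed in its
#' box minus the image background (median of all pixels outside every
#' detection box), clamped at zero — dimmer-than-background beads read 0.
#' The sampling disc is eroded by `1 - shrink` relative to the inscribed
#' disc: the FITC-dextran distribution inside a bead is uniform, so
#' interior sampling is unbiased while being robust to small box
#' regression errors that would otherwise mix background into the mean.
#'
#' @param image Intensity matrix.
#' @param detections Detection `data.frame` (`x`, `y`, `w`, `h`); every
#'   box must lie inside the image.
#' @param shrink Sampling-disc radius as a fraction of the inscribed
#'   radius.
#' @return Numeric vector of intensities, one per detection.
#' @export
beadIntensity <- function(image, detections, shrink = 0.8) {
  H <- nrow(image); W <- ncol(image)
  if (nrow(detections) == 0L) return(numeric(0))
  if (any(detections$x < 0 | detections$y < 0 |
          detections$x + detections$w > W |
          detections$y + detections$h > H))
    stop("detection box outside image")
  inBox <- matrix(FALSE, H, W)
  for (i in seq_len(nrow(detections))) {
    rows <- (floor(detections$y[i]) + 1L):ceiling(detections$y[i] + detections$h[i])
    cols <- (floor(detections$x[i]) + 1L):ceiling(detections$x[i] + detections$w[i])
    inBox[rows, cols] <- TRUE
  }
  bg <- median(image[!inBox])
  vapply(seq_len(nrow(detections)), function(i) {
    cx <- detections$x[i] + detections$w[i] / 2
    cy <- detections$y[i] + detections$h[i] / 2
    r <- shrink * min(detections$w[i], detections$h[i]) / 2
    rows <- max(1L, floor(cy - r)):min(H, ceiling(cy + r + 1))
    cols <- max(1L, floor(cx - r)):min(W, ceiling(cx + r + 1))
    inside <- outer((rows - 0.5 - cy)^2, (cols - 0.5 - cx)^2, "+") <= r^2
    max(0, mean(image[rows, cols][inside]) - bg)
  }, numeric(1))
}
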