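#' @include AllClasses.R
NULL

# Edge-replicating 2D shift: move the matrix by (dr, dc), filling exposed
# borders with the nearest row/column.
shiftMat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- clamp(seq_len(nr) - dr, 1L, nr)
  ci <- clamp(seq_len(nc) - dc, 1L, nc)
  m[ri, ci, drop = FALSE]
}

# Separable Gaussian blur with replicated edges.
gaussBlur <- function(m, sigma) {
  h <- ceiling(3 * sigma)
  k <- exp(-(-h:h)^2 / (2 * sigma^2))
  k <- k / sum(k)
  padConv <- function(x) {
    # x: matrix, convolve along rows (dimension 1)
    out <- matrix(0, nrow(x), ncol(x))
    for (j in seq_along(k))
      out <- out + k[j] * shiftMat(x, (j - h - 1L), 0L)
    out
  }
  t(padConv(t(padConv(m))))
}

# Internal Canny edge map: blur, Sobel, non-maximum suppression along the
# quantised gradient direction, hysteresis at lowFrac/highFrac of the
# gradient-magnitude dynamic range.
cannyEdges <- function(img, sigma = 1.5, lowFrac = 0.1, highFrac = 0.3) {
  g <- gaussBlur(img, sigma)
  sx <- shiftMat(g, 0, -1) - shiftMat(g, 0, 1) +
    0.5 * (shiftMat(g, -1, -1) - shiftMat(g, -1, 1)) +
    0.5 * (shiftMat(g, 1, -1) - shiftMat(g, 1, 1))
  sy <- shiftMat(g, -1, 0) - shiftMat(g, 1, 0) +
    0.5 * (shiftMat(g, -1, -1) - shiftMat(g, 1, -1)) +
    0.5 * (shiftMat(g, -1, 1) - shiftMat(g, 1, 1))
  mag <- sqrt(sx^2 + sy^2)
  mmax <- max(mag)
  if (mmax <= 0) return(matrix(FALSE, nrow(img), ncol(img)))

  # quantise gradient direction into 4 sectors and suppress non-maxima
  ang <- atan2(sy, sx)
  sector <- (round(ang / (pi / 4)) %% 4)     # 0:E/W 1:NE/SW 2:N/S 3:NW/SE
  n1 <- mag; n2 <- mag
  pick <- function(cond, dr, dc, which) {
    sh <- shiftMat(mag, dr, dc)
    if (which == 1L) n1[cond] <<- sh[cond] else n2[cond] <<- sh[cond]
  }
  pick(sector == 0, 0, 1, 1);  pick(sector == 0, 0, -1, 2)
  pick(sector == 1, -1, 1, 1); pick(sector == 1, 1, -1, 2)
  pick(sector == 2, -1, 0, 1); pick(sector == 2, 1, 0, 2)
  pick(sector == 3, -1, -1, 1); pick(sector == 3, 1, 1, 2)
  nms <- mag >= n1 & mag >= n2

  hi <- highFrac * mmax
  lo <- lowFrac * mmax
  strong <- nms & mag >= hi
  weak <- nms & mag >= lo
  # hysteresis: grow strong edges into connected weak pixels
  repeat {
    nb <- strong
    for (dr in -1:1) for (dc in -1:1)
      if (dr || dc) nb <- nb | shiftMat(strong, dr, dc)
    grown <- weak & nb
    if (all(grown == strong)) break
    strong <- grown
  }
  strong
}

#' Canny edge-detection baseline for interface localisation
#'
#' Classical alternative to the learned classifier: Canny edges
#' (Gaussian sigma 1.5, hysteresis thresholds at 0.1/0.3 of the gradient
#' dynamic range) followed by dominant-vertical-edge voting over the
#' column histogram of edge pixels. Fails explicitly when no dominant edge
#' exists or when two well-separated columns collect comparable votes —
#' the regimes (uniform frames, poor lighting, cells sitting on the
#' interface) where the learned model is expected to win.
#'
#' @param frame A [FlowFrame-class] or 120x120 intensity matrix.
#' @param sigma Gaussian blur width, px.
#' @param lowFrac,highFrac Hysteresis thresholds as fractions of the
#'   gradient-magnitude maximum.
#' @param minVotes Minimum edge pixels in the winning column window for a
#'   confident estimate.
#' @param conflictRatio A second peak at least this fraction of the winner
#'   (and > 10 px away) flags a conflict.
#' @return List: `fHigh` (estimated interface fraction, `NA` on failure),
#'   `ok` (logical), `votes`, `reason`.
#' @export
cannyInterface <- function(frame, sigma = 1.5, lowFrac = 0.1,
                           highFrac = 0.3, minVotes = 30,
                           conflictRatio = 0.6) {
  img <- if (is(frame, "FlowFrame")) framePixels(frame) else frame
  img <- matrix(as.numeric(img), nrow(img), ncol(img))
  edges <- cannyEdges(img, sigma, lowFrac, highFrac)
  if (!any(edges))
    return(list(fHigh = NA_real_, ok = FALSE, votes = 0, reason = "no edges"))
  counts <- colSums(edges)
  # pool votes over a 5-column window so the two flanks of the bright
  # refraction line reinforce one peak
  sm <- stats::filter(counts, rep(1, 5), sides = 2)
  sm[is.na(sm)] <- 0
  peak <- which.max(sm)
  votes <- sm[peak]
  if (votes < minVotes)
    return(list(fHigh = NA_real_, ok = FALSE, votes = votes,
                reason = "no dominant edge"))
  far <- abs(seq_along(sm) - peak) > 10
  if (any(far) && max(sm[far]) >= conflictRatio * votes)
    return(list(fHigh = NA_real_, ok = FALSE, votes = votes,
                reason = "conflicting edges"))
  # centre-of-mass of the winning window for sub-column precision
  win <- max(1, peak - 2):min(ncol(img), peak + 2)
  pos <- sum(win * counts[win]) / sum(counts[win])
  list(fHigh = unname(pos / ncol(img)), ok = TRUE, votes = votes,
       reason = "ok")
}
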