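# Independent average-precision oracle: explicit per-box IoU geometry,
# greedy score-ordered matching, and direct all-point interpolation by
# scanning recall levels. Deliberately written as plain loops, independent
# of the package's vectorised implementation.
apOracle <- function(det, gt, iouThresh = 0.5) {
  iou1 <- function(a, b) {
    ix <- max(0, min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1]))
    iy <- max(0, min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2]))
    inter <- ix * iy
    inter / (a[3] * a[4] + b[3] * b[4] - inter)
  }
  det <- det[order(-det$score), , drop = FALSE]
  used <- rep(FALSE, nrow(gt))
  tp <- logical(nrow(det))
  for (i in seq_len(nrow(det))) {
    best <- 0; bj <- 0
    for (j in seq_len(nrow(gt))) {
      if (used[j]) next
      v <- iou1(as.numeric(det[i, c("x", "y", "w", "h")]),
                as.numeric(gt[j, c("x", "y", "w", "h")]))
      if (v > best) { best <- v; bj <- j }
    }
    if (bj > 0 && best >= iouThresh) { used[bj] <- TRUE; tp[i] <- TRUE }
  }
  prec <- cumsum(tp) / seq_along(tp)
  rec <- cumsum(tp) / nrow(gt)
  ap <- 0; prev <- 0
  for (r in sort(unique(rec))) {
    ap <- ap + (r - prev) * max(prec[rec >= r])
    prev <- r
  }
  ap
}
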