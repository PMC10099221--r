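# Independent oracles used across the suite. These deliberately re-derive
# results by brute force rather than calling the implementation under test.

# rasterize an axis-aligned box on an integer pixel grid and count pixels
pixelCountIou <- function(a, b, canvas = 64L) {
  grid <- function(bx) {
    m <- matrix(FALSE, canvas, canvas)
    xs <- seq_len(canvas) - 0.5; ys <- seq_len(canvas) - 0.5
    inX <- xs > bx[1] & xs < bx[3]
    inY <- ys > bx[2] & ys < bx[4]
    outer(inY, inX, "&")
  }
  A <- grid(a); B <- grid(b)
  un <- sum(A | B)
  if (un == 0) 0 else sum(A & B) / un
}

# O(n^2) reference NMS, written independently of nmsKeep
bruteNms <- function(boxes, scores, thr) {
  n <- length(scores)
  ord <- order(-scores, seq_len(n))
  kept <- integer()
  for (i in ord) {
    ok <- TRUE
    for (k in kept) {
      ix <- max(0, min(boxes[i, 3], boxes[k, 3]) - max(boxes[i, 1], boxes[k, 1]))
      iy <- max(0, min(boxes[i, 4], boxes[k, 4]) - max(boxes[i, 2], boxes[k, 2]))
      inter <- ix * iy
      ai <- (boxes[i, 3] - boxes[i, 1]) * (boxes[i, 4] - boxes[i, 2])
      ak <- (boxes[k, 3] - boxes[k, 1]) * (boxes[k, 4] - boxes[k, 2])
      if (inter / (ai + ak - inter) > thr) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  kept
}

# reference greedy matcher over box IoU, independent of matchDetections
bruteMatch <- function(predBoxes, predCls, predScores, gtBoxes, gtCls, thr) {
  used <- rep(FALSE, NROW(gtBoxes))
  tp <- logical(length(predScores))
  for (i in order(-predScores, seq_along(predScores))) {
    bestJ <- NA; bestV <- 0
    for (j in seq_len(NROW(gtBoxes))) {
      if (used[j] || gtCls[j] != predCls[i]) next
      ix <- max(0, min(predBoxes[i, 3], gtBoxes[j, 3]) -
                  max(predBoxes[i, 1], gtBoxes[j, 1]))
      iy <- max(0, min(predBoxes[i, 4], gtBoxes[j, 4]) -
                  max(predBoxes[i, 2], gtBoxes[j, 2]))
      inter <- ix * iy
      ai <- (predBoxes[i, 3] - predBoxes[i, 1]) * (predBoxes[i, 4] - predBoxes[i, 2])
      aj <- (gtBoxes[j, 3] - gtBoxes[j, 1]) * (gtBoxes[j, 4] - gtBoxes[j, 2])
      v <- inter / (ai + aj - inter)
      if (v > bestV) { bestV <- v; bestJ <- j }
    }
    if (!is.na(bestJ) && bestV >= thr) { tp[i] <- TRUE; used[bestJ] <- TRUE }
  }
  list(tp = tp, fn = sum(!used))
}

# exhaustive threshold-sweep AP oracle (trapezoid-free envelope area)
sweepAp <- function(scores, isTp, nGt) {
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- t(vapply(thr, function(t) {
    sel <- scores >= t
    c(rec = sum(isTp[sel]) / nGt,
      prec = sum(isTp[sel]) / max(1, sum(sel)))
  }, numeric(2)))
  pts <- pts[order(pts[, 1]), , drop = FALSE]
  env <- rev(cummax(rev(pts[, 2])))
  sum(diff(c(0, pts[, 1])) * env)
}

# brute-force rasterized ellipse area under the pixel-center-inside rule
ellipseArea <- function(center, axes, rotation, h, w) {
  cnt <- 0L
  for (i in seq_len(h)) for (j in seq_len(w)) {
    dx <- j - 0.5 - center[1]; dy <- i - 0.5 - center[2]
    u <- dx * cos(rotation) + dy * sin(rotation)
    v <- -dx * sin(rotation) + dy * cos(rotation)
    if ((u / axes[1])^2 + (v / axes[2])^2 <= 1) cnt <- cnt + 1L
  }
  cnt
}

tinyScene <- function(n = 3, seed = 7, size = c(128L, 128L), adhesion = 0.1) {
  renderScene(randomSceneSpec(n, size, adhesionLevel = adhesion, seed = seed,
                              axisRange = c(10, 14)))
}

# tight half-open box of a logical mask, recomputed independently
maskBboxOf <- function(mask) {
  cs <- which(colSums(mask) > 0); rs <- which(rowSums(mask) > 0)
  c(min(cs) - 1, min(rs) - 1, max(cs), max(rs))
}
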