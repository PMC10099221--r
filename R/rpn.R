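# Region-proposal stage: anchor generation over the pyramid levels, IoU,
# greedy NMS, the 0.7/0.3 foreground/background assignment with the
# best-anchor-per-target rescue rule, and proposal decoding.

#' Anchor configuration
#'
#' Six anchor scales spread across the pyramid levels (one per level, two on
#' the finest) with three aspect ratios per location. An anchor of scale a
#' and ratio r covers area a^2 with height/width ratio r.
#'
#' @param scales Anchor scales (box side at ratio 1) in input pixels.
#' @param ratios Aspect ratios height/width.
#' @param levelAssignment Named list mapping pyramid level index ("2".."6")
#'   to the scales placed there. Default: 8 and 16 on level 2, then one scale
#'   per level. Every scale must be assigned exactly once.
#' @return A list of class \code{anchorConfig}.
#' @export
anchorConfig <- function(scales = c(8, 16, 32, 64, 128, 256),
                         ratios = c(0.5, 1, 2),
                         levelAssignment = NULL) {
  if (is.null(levelAssignment))
    levelAssignment <- list(`2` = scales[seq_len(max(1, length(scales) - 4))],
                            `3` = scales[length(scales) - 3],
                            `4` = scales[length(scales) - 2],
                            `5` = scales[length(scales) - 1],
                            `6` = scales[length(scales)])
  if (!length(levelAssignment)) stop("empty level assignment")
  assigned <- sort(unname(unlist(levelAssignment)))
  if (!isTRUE(all.equal(assigned, sort(scales))))
    stop("every scale must be assigned to exactly one level")
  structure(list(scales = scales, ratios = ratios,
                 levelAssignment = levelAssignment),
            class = "anchorConfig")
}

#' Assignment and NMS configuration for the proposal stage
#'
#' @param fgIou Foreground threshold: max IoU strictly above it is positive.
#' @param bgIou Background threshold: max IoU strictly below it is negative;
#'   anchors in between are discarded.
#' @param nmsIou Proposal NMS threshold (reduced to 0.5 so adjacent adherent
#'   kernels are not merged into one target).
#' @param preNmsTopk Per-level candidates kept before NMS.
#' @param postNmsTopk Overall survivors after NMS.
#' @return A list of class \code{assignmentConfig}.
#' @export
assignmentConfig <- function(fgIou = 0.7, bgIou = 0.3, nmsIou = 0.5,
                             preNmsTopk = 1000L, postNmsTopk = 500L) {
  stopifnot(bgIou >= 0, bgIou < fgIou, fgIou <= 1, nmsIou > 0, nmsIou < 1)
  structure(list(fgIou = fgIou, bgIou = bgIou, nmsIou = nmsIou,
                 preNmsTopk = as.integer(preNmsTopk),
                 postNmsTopk = as.integer(postNmsTopk)),
            class = "assignmentConfig")
}

anchorDims <- function(scale, ratio) {
  w <- scale / sqrt(ratio)
  c(w = w, h = scale * sqrt(ratio))
}

#' Generate anchors for the configured pyramid levels
#'
#' For a level with h x w cells and s assigned scales, produces exactly
#' h*w*s*length(ratios) anchors centred at the cell centres in input
#' coordinates; anchor order matches the column-major flattening of an
#' (h, w, anchorsPerCell) map, so head outputs align one-to-one.
#'
#' @param levelDims Named list (\code{"2".."6"}) of c(h, w) cell grids.
#' @param config An \code{\link{anchorConfig}}.
#' @return A list with \code{boxes} (n x 4 matrix, unclipped), \code{level}
#'   (integer vector), and \code{perLevel} bookkeeping (dims, stride,
#'   anchors per cell, row ranges).
#' @export
generateAnchors <- function(levelDims, config = anchorConfig()) {
  boxes <- list(); levels <- list(); perLevel <- list()
  row0 <- 0L
  for (lv in names(levelDims)) {
    scalesHere <- config$levelAssignment[[lv]]
    if (is.null(scalesHere)) next
    d <- levelDims[[lv]]
    h <- d[1]; w <- d[2]
    stride <- 2^as.integer(lv)
    cx <- (rep(seq_len(w), each = h) - 0.5) * stride
    cy <- (rep(seq_len(h), times = w) - 0.5) * stride
    bl <- list()
    for (s in scalesHere)
      for (r in config$ratios) {
        a <- anchorDims(s, r)
        bl[[length(bl) + 1L]] <- cbind(cx - a["w"] / 2, cy - a["h"] / 2,
                                       cx + a["w"] / 2, cy + a["h"] / 2)
      }
    b <- do.call(rbind, bl)
    boxes[[lv]] <- b
    levels[[lv]] <- rep(as.integer(lv), nrow(b))
    perLevel[[lv]] <- list(dims = d, stride = stride,
                           anchorsPerCell = length(scalesHere) * length(config$ratios),
                           rows = row0 + seq_len(nrow(b)))
    row0 <- row0 + nrow(b)
  }
  if (!length(boxes)) stop("no level received any anchors")
  list(boxes = do.call(rbind, boxes), level = unlist(levels, use.names = FALSE),
       perLevel = perLevel)
}

#' Intersection-over-union of axis-aligned boxes
#'
#' @param a,b Matrices (n x 4) / (m x 4) of half-open (x1, y1, x2, y2) boxes;
#'   single boxes may be given as length-4 vectors.
#' @return An n x m matrix of IoU values in [0, 1]. Degenerate (zero-area)
#'   boxes get IoU 0 with a warning.
#' @export
boxIou <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, 1)
  if (is.null(dim(b))) b <- matrix(b, 1)
  areaA <- pmax(0, a[, 3] - a[, 1]) * pmax(0, a[, 4] - a[, 2])
  areaB <- pmax(0, b[, 3] - b[, 1]) * pmax(0, b[, 4] - b[, 2])
  if (any(areaA == 0) || any(areaB == 0))
    warning("degenerate zero-area box; IoU defined as 0")
  ix <- pmax(0, outer(a[, 3], b[, 3], pmin) - outer(a[, 1], b[, 1], pmax))
  iy <- pmax(0, outer(a[, 4], b[, 4], pmin) - outer(a[, 2], b[, 2], pmax))
  inter <- ix * iy
  un <- outer(areaA, areaB, "+") - inter
  out <- ifelse(un > 0, inter / un, 0)
  out
}

#' Greedy non-maximum suppression
#'
#' Boxes are visited in descending score order (ties by lower original
#' index); a box is suppressed iff its IoU with an already kept box exceeds
#' \code{iouThr}.
#'
#' @param boxes n x 4 matrix.
#' @param scores Numeric vector of length n.
#' @param iouThr Suppression threshold.
#' @return Integer vector of kept indices, in keep order.
#' @export
nmsKeep <- function(boxes, scores, iouThr) {
  n <- length(scores)
  if (n == 0) return(integer())
  if (is.null(dim(boxes))) boxes <- matrix(boxes, ncol = 4)
  stopifnot(nrow(boxes) == n)
  ord <- order(-scores, seq_len(n))
  keep <- integer()
  alive <- rep(TRUE, n)
  for (i in ord) {
    if (!alive[i]) next
    keep <- c(keep, i)
    if (length(ord) > 1) {
      iou <- suppressWarnings(boxIou(boxes[i, , drop = FALSE], boxes))
      alive <- alive & (drop(iou) <= iouThr)
      alive[i] <- FALSE
    }
  }
  keep
}

#' Foreground/background assignment of anchors
#'
#' Labels every anchor by its maximum IoU over ground-truth boxes:
#' strictly above \code{fgIou} is foreground, strictly below \code{bgIou}
#' background, anything between is discarded. In addition the highest-IoU
#' anchor of every ground truth is rescued as foreground so no target is
#' left without a positive anchor.
#'
#' @param anchorBoxes n x 4 matrix of anchors.
#' @param gtBoxes m x 4 matrix of ground-truth boxes (may have zero rows:
#'   everything becomes background).
#' @param config An \code{\link{assignmentConfig}}.
#' @return A list with \code{labels} (integer: 1 foreground, 0 background,
#'   -1 discard), \code{maxIou}, and \code{gtIndex} (best ground truth per
#'   anchor, NA where background).
#' @export
assignFgBg <- function(anchorBoxes, gtBoxes, config = assignmentConfig()) {
  n <- nrow(anchorBoxes)
  if (is.null(gtBoxes) || NROW(gtBoxes) == 0)
    return(list(labels = rep(0L, n), maxIou = numeric(n),
                gtIndex = rep(NA_integer_, n)))
  iou <- boxIou(anchorBoxes, gtBoxes)
  gtIndex <- max.col(iou, ties.method = "first")
  maxIou <- iou[cbind(seq_len(n), gtIndex)]
  labels <- rep(-1L, n)
  labels[maxIou > config$fgIou] <- 1L
  labels[maxIou < config$bgIou] <- 0L
  for (g in seq_len(ncol(iou))) {           # rescue rule
    best <- which.max(iou[, g])
    if (iou[best, g] > 0) { labels[best] <- 1L; gtIndex[best] <- g }
  }
  gtIndex[labels == 0L] <- NA_integer_
  list(labels = labels, maxIou = maxIou, gtIndex = gtIndex)
}

# standard (dx, dy, log dw, log dh) box parameterization
encodeDeltas <- function(anchors, gt) {
  aw <- anchors[, 3] - anchors[, 1]; ah <- anchors[, 4] - anchors[, 2]
  ax <- (anchors[, 1] + anchors[, 3]) / 2; ay <- (anchors[, 2] + anchors[, 4]) / 2
  gw <- gt[, 3] - gt[, 1]; gh <- gt[, 4] - gt[, 2]
  gx <- (gt[, 1] + gt[, 3]) / 2; gy <- (gt[, 2] + gt[, 4]) / 2
  cbind((gx - ax) / aw, (gy - ay) / ah, log(gw / aw), log(gh / ah))
}

#' Decode box deltas against anchors
#'
#' @param anchors n x 4 anchor boxes.
#' @param deltas n x 4 matrix of (dx, dy, log dw, log dh) offsets; zero
#'   deltas reproduce the anchors exactly.
#' @return n x 4 matrix of decoded boxes.
#' @export
decodeDeltas <- function(anchors, deltas) {
  aw <- anchors[, 3] - anchors[, 1]; ah <- anchors[, 4] - anchors[, 2]
  ax <- (anchors[, 1] + anchors[, 3]) / 2; ay <- (anchors[, 2] + anchors[, 4]) / 2
  cx <- ax + deltas[, 1] * aw; cy <- ay + deltas[, 2] * ah
  w <- aw * exp(pmin(deltas[, 3], 8)); h <- ah * exp(pmin(deltas[, 4], 8))
  cbind(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
}

# reshape per-level head maps into anchor-aligned vectors / matrices
flattenObjMap <- function(arr) as.numeric(arr)

flattenDeltaMap <- function(arr) {
  d <- dim(arr)
  A <- d[3] %/% 4L
  m <- matrix(arr, d[1] * d[2], d[3])
  do.call(rbind, lapply(seq_len(A), function(a)
    m[, (a - 1L) * 4L + 1:4, drop = FALSE]))
}

#' Decode, filter and suppress proposals
#'
#' Applies the standard delta decoding to every anchor, clips to the image,
#' drops degenerate boxes, keeps the top-k per level by objectness, runs NMS
#' at \code{config$nmsIou} and returns the overall top-k survivors sorted by
#' descending score.
#'
#' @param objMaps Named list (per level) of (h, w, A) objectness logit maps.
#' @param deltaMaps Named list of (h, w, 4A) delta maps.
#' @param anchors Output of \code{\link{generateAnchors}} for the same dims.
#' @param config An \code{\link{assignmentConfig}}.
#' @param imageSize Integer (height, width) for clipping.
#' @return A list with \code{boxes}, \code{scores} (sigmoid objectness),
#'   \code{level}.
#' @export
proposeRegions <- function(objMaps, deltaMaps, anchors,
                           config = assignmentConfig(),
                           imageSize) {
  h <- imageSize[1]; w <- imageSize[2]
  allBoxes <- list(); allScores <- list(); allLev <- list()
  for (lv in names(anchors$perLevel)) {
    info <- anchors$perLevel[[lv]]
    obj <- objMaps[[lv]]; del <- deltaMaps[[lv]]
    if (is.null(obj) || is.null(del))
      stop("missing head maps for level ", lv)
    d <- dim(obj)
    if (d[1] != info$dims[1] || d[2] != info$dims[2] ||
        d[3] != info$anchorsPerCell ||
        !all(dim(del) == c(d[1], d[2], 4L * d[3])))
      stop("head map shape mismatch on level ", lv)
    scores <- 1 / (1 + exp(-flattenObjMap(obj)))
    boxes <- decodeDeltas(anchors$boxes[info$rows, , drop = FALSE],
                          flattenDeltaMap(del))
    boxes[, c(1, 3)] <- clamp(boxes[, c(1, 3)], 0, w)
    boxes[, c(2, 4)] <- clamp(boxes[, c(2, 4)], 0, h)
    ok <- is.finite(rowSums(boxes)) & is.finite(scores) &
      boxes[, 3] - boxes[, 1] > 1e-3 & boxes[, 4] - boxes[, 2] > 1e-3
    boxes <- boxes[ok, , drop = FALSE]; scores <- scores[ok]
    if (nrow(boxes) > config$preNmsTopk) {
      top <- order(-scores)[seq_len(config$preNmsTopk)]
      boxes <- boxes[top, , drop = FALSE]; scores <- scores[top]
    }
    allBoxes[[lv]] <- boxes; allScores[[lv]] <- scores
    allLev[[lv]] <- rep(as.integer(lv), length(scores))
  }
  boxes <- do.call(rbind, allBoxes)
  scores <- unlist(allScores, use.names = FALSE)
  lev <- unlist(allLev, use.names = FALSE)
  keep <- nmsKeep(boxes, scores, config$nmsIou)
  keep <- keep[seq_len(min(length(keep), config$postNmsTopk))]
  list(boxes = boxes[keep, , drop = FALSE], scores = scores[keep],
       level = lev[keep])
}
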