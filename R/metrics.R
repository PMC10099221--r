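# Evaluation: confusion counts, precision/recall, mask IoU, greedy
# prediction-to-truth matching, AP (area under the precision-recall curve,
# all-point interpolation), mAP, AR and mIoU.

#' Confusion counts
#'
#' @param TP,FP,FN,TN Non-negative integers. TN is unused for detection but
#'   kept for completeness.
#' @return A list of class \code{confusionCounts}.
#' @export
confusionCounts <- function(TP = 0L, FP = 0L, FN = 0L, TN = 0L) {
  v <- c(TP, FP, FN, TN)
  if (any(v < 0)) stop("confusion counts must be non-negative")
  structure(list(TP = TP, FP = FP, FN = FN, TN = TN),
            class = "confusionCounts")
}

#' Precision: TP / (TP + FP)
#'
#' @param counts A \code{\link{confusionCounts}} (or list with TP/FP/FN).
#' @return Precision in [0, 1]; 0 with a warning when TP + FP = 0.
#' @examples
#' precisionScore(confusionCounts(TP = 86, FP = 14))  # 0.86
#' @export
precisionScore <- function(counts) {
  if (counts$TP < 0 || counts$FP < 0) stop("negative counts")
  d <- counts$TP + counts$FP
  if (d == 0) { warning("TP + FP = 0; precision defined as 0"); return(0) }
  counts$TP / d
}

#' Recall: TP / (TP + FN)
#'
#' @param counts A \code{\link{confusionCounts}}.
#' @return Recall in [0, 1]; 0 with a warning when TP + FN = 0.
#' @examples
#' recallScore(confusionCounts(TP = 91, FN = 9))  # 0.91
#' @export
recallScore <- function(counts) {
  if (counts$TP < 0 || counts$FN < 0) stop("negative counts")
  d <- counts$TP + counts$FN
  if (d == 0) { warning("TP + FN = 0; recall defined as 0"); return(0) }
  counts$TP / d
}

#' Mask intersection-over-union
#'
#' @param maskA,maskB Logical matrices of identical dimensions.
#' @return |A intersect B| / |A union B|; 0 with a warning when both masks
#'   are empty.
#' @export
maskIou <- function(maskA, maskB) {
  if (!all(dim(maskA) == dim(maskB))) stop("mask dimensions differ")
  un <- sum(maskA | maskB)
  if (un == 0) { warning("both masks empty; IoU defined as 0"); return(0) }
  sum(maskA & maskB) / un
}

#' Matching specification
#'
#' @param iouThreshold Match threshold in (0, 1); default 0.5.
#' @param kind \code{"mask"} (default) or \code{"box"} IoU.
#' @param interpolation AP interpolation: \code{"all"} (precision envelope
#'   over every point) or \code{"coco101"} (101 recall points).
#' @return A list of class \code{matchSpec}.
#' @export
matchSpec <- function(iouThreshold = 0.5, kind = c("mask", "box"),
                      interpolation = c("all", "coco101")) {
  stopifnot(iouThreshold > 0, iouThreshold < 1)
  structure(list(iouThreshold = iouThreshold, kind = match.arg(kind),
                 interpolation = match.arg(interpolation)),
            class = "matchSpec")
}

predAsList <- function(pred) {
  if (is(pred, "DetectionResult"))
    list(boxes = pred@boxes, labels = pred@labels, scores = pred@scores,
         masks = pred@masks)
  else pred
}

#' Match predictions to ground truth in one image
#'
#' Greedy over predictions in descending score order: a prediction is a true
#' positive iff its best same-class IoU over the still-unmatched ground
#' truths reaches the threshold; every ground truth is matched at most once.
#'
#' @param pred A \code{DetectionResult} or a list with \code{boxes},
#'   \code{labels}, \code{scores}, \code{masks}.
#' @param gt List of ground-truth annotations (categoryId, bbox, mask).
#' @param spec A \code{\link{matchSpec}}.
#' @return A data.frame (one row per prediction, descending score) with
#'   \code{score}, \code{label}, \code{tp}, \code{iou}, \code{gtIndex};
#'   attribute \code{fnPerClass} counts unmatched ground truths by class.
#' @export
matchDetections <- function(pred, gt, spec = matchSpec()) {
  pred <- predAsList(pred)
  n <- length(pred$scores)
  gtCls <- vapply(gt, `[[`, integer(1), "categoryId")
  used <- rep(FALSE, length(gt))
  ord <- order(-pred$scores, seq_len(n))
  out <- data.frame(score = numeric(n), label = integer(n), tp = logical(n),
                    iou = numeric(n), gtIndex = rep(NA_integer_, n))
  row <- 0L
  for (i in ord) {
    row <- row + 1L
    out$score[row] <- pred$scores[i]
    out$label[row] <- pred$labels[i]
    cand <- which(!used & gtCls == pred$labels[i])
    bestIou <- 0; bestJ <- NA_integer_
    for (j in cand) {
      v <- if (spec$kind == "mask")
        suppressWarnings(maskIou(pred$masks[[i]], gt[[j]]$mask))
      else drop(suppressWarnings(boxIou(pred$boxes[i, ], gt[[j]]$bbox)))
      if (v > bestIou) { bestIou <- v; bestJ <- j }
    }
    if (!is.na(bestJ) && bestIou >= spec$iouThreshold) {
      out$tp[row] <- TRUE
      out$iou[row] <- bestIou
      out$gtIndex[row] <- bestJ
      used[bestJ] <- TRUE
    }
  }
  fn <- table(factor(gtCls[!used], levels = 1:6))
  attr(out, "fnPerClass") <- as.integer(fn)
  out
}

#' Average precision from scored match flags
#'
#' Area under the precision-recall curve obtained by sweeping the score
#' threshold over every prediction, with the precision envelope (all-point
#' interpolation) or the 101-point COCO grid.
#'
#' @param scores Prediction scores.
#' @param isTp Logical true-positive flags aligned with \code{scores}.
#' @param nGt Number of ground truths of this class (>= 1; 0 gives NA with a
#'   warning).
#' @param interpolation \code{"all"} or \code{"coco101"}.
#' @return AP in [0, 1].
#' @export
averagePrecision <- function(scores, isTp, nGt, interpolation = "all") {
  if (nGt == 0) { warning("no ground truths; AP undefined"); return(NA_real_) }
  if (!length(scores)) return(0)
  ord <- order(-scores, seq_along(scores))
  s <- scores[ord]
  tp <- cumsum(isTp[ord])
  fp <- cumsum(!isTp[ord])
  # tied scores enter together: evaluate at the last index of each group,
  # matching the threshold-sweep definition exactly
  keep <- c(s[-length(s)] != s[-1], TRUE)
  tp <- tp[keep]; fp <- fp[keep]
  rec <- tp / nGt
  prec <- tp / (tp + fp)
  env <- rev(cummax(rev(prec)))
  if (interpolation == "coco101") {
    grid <- seq(0, 1, by = 0.01)
    pr <- vapply(grid, function(r) {
      ok <- which(rec >= r)
      if (length(ok)) env[ok[1]] else 0
    }, numeric(1))
    return(mean(pr))
  }
  sum(diff(c(0, rec)) * env)
}

#' Mean average precision
#'
#' @param perClassAP Numeric vector of per-class APs; NA entries (classes
#'   without ground truth) are excluded.
#' @return Unweighted mean.
#' @examples
#' meanAveragePrecision(c(0.60, 0.99, 0.82, 0.89, 0.89, 0.98))
#' @export
meanAveragePrecision <- function(perClassAP) mean(perClassAP, na.rm = TRUE)

#' Mean of per-class recalls
#' @param perClassRecall Numeric vector; NA excluded.
#' @export
averageRecall <- function(perClassRecall) mean(perClassRecall, na.rm = TRUE)

#' Mean of per-class IoUs
#' @param perClassIoU Numeric vector; NA excluded.
#' @export
meanIou <- function(perClassIoU) mean(perClassIoU, na.rm = TRUE)

#' Evaluate predictions over a set of images
#'
#' Matches every image, pools per-class scored flags, and assembles the full
#' report: per-class AP and mAP, per-class recall and AR, per-class matched
#' IoU and mIoU, and overall point precision/recall at the operating
#' threshold. Classes absent from the ground truth are excluded from the
#' means with a warning.
#'
#' @param preds List of \code{DetectionResult}s (or equivalent lists).
#' @param gts List (parallel to \code{preds}) of annotation lists.
#' @param spec A \code{\link{matchSpec}}.
#' @return A \code{\link[=MetricReport-class]{MetricReport}}.
#' @export
evaluateDetections <- function(preds, gts, spec = matchSpec()) {
  stopifnot(length(preds) == length(gts))
  cats <- kernelCategories()
  rows <- list(); fn <- integer(6)
  for (i in seq_along(preds)) {
    m <- matchDetections(preds[[i]], gts[[i]], spec)
    fn <- fn + attr(m, "fnPerClass")
    rows[[i]] <- m
  }
  all <- do.call(rbind, rows)
  nGt <- integer(6)
  for (g in unlist(lapply(gts, function(x)
    vapply(x, `[[`, integer(1), "categoryId"))))
    nGt[g] <- nGt[g] + 1L
  perAP <- perRec <- perIou <- stats::setNames(rep(NA_real_, 6), cats$name)
  for (k in 1:6) {
    sel <- all$label == k
    if (nGt[k] == 0) {
      if (any(sel)) warning("predictions for class without ground truth: ",
                            cats$name[k])
      next
    }
    perAP[k] <- averagePrecision(all$score[sel], all$tp[sel], nGt[k],
                                 spec$interpolation)
    perRec[k] <- sum(all$tp[sel]) / nGt[k]
    ious <- all$iou[sel & all$tp]
    perIou[k] <- if (length(ious)) mean(ious) else 0
  }
  if (any(nGt == 0))
    warning("classes without ground truth excluded from means: ",
            paste(cats$name[nGt == 0], collapse = ", "))
  TP <- sum(all$tp); FP <- sum(!all$tp); FN <- sum(nGt) - TP
  cc <- confusionCounts(TP = TP, FP = FP, FN = FN)
  new("MetricReport",
      perClassAP = perAP, mAP = meanAveragePrecision(perAP),
      perClassRecall = perRec, AR = averageRecall(perRec),
      perClassIoU = perIou, mIoU = meanIou(perIou),
      precision = suppressWarnings(precisionScore(cc)),
      recall = suppressWarnings(recallScore(cc)),
      counts = list(TP = TP, FP = FP, FN = FN),
      nParameters = NA_real_, timePerImage = NA_real_)
}
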