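# Training and inference. One train step: full forward to the RPN head
# maps, RPN losses on a sampled anchor minibatch, exact backprop through
# pyramid/attention/backbone, then ROI box/mask head updates on detached
# ROI-aligned features. Inference decodes proposals, refines and classifies
# them, applies per-class NMS and pastes ROI masks to image resolution.

smoothL1 <- function(d) ifelse(abs(d) < 1, 0.5 * d^2, abs(d) - 0.5)
smoothL1Grad <- function(d) ifelse(abs(d) < 1, d, sign(d))

gtFromAnnotations <- function(annotations, minSide = 0) {
  if (!length(annotations))
    return(list(boxes = matrix(numeric(), 0, 4), classes = integer(),
                masks = list()))
  out <- list(boxes = do.call(rbind, lapply(annotations, `[[`, "bbox")),
              classes = vapply(annotations, `[[`, integer(1), "categoryId"),
              masks = lapply(annotations, `[[`, "mask"))
  if (minSide > 0) {
    keep <- (out$boxes[, 3] - out$boxes[, 1]) >= minSide &
      (out$boxes[, 4] - out$boxes[, 2]) >= minSide
    out$boxes <- out$boxes[keep, , drop = FALSE]
    out$classes <- out$classes[keep]
    out$masks <- out$masks[keep]
  }
  out
}

mergePg <- function(a, b) {
  for (pname in names(b))
    for (comp in names(b[[pname]]))
      a <- pgAdd(a, pname, comp, b[[pname]][[comp]])
  a
}

# scatter anchor-row gradients back into per-level (h, w, A) / (h, w, 4A) maps
scatterRpnGrads <- function(anchors, objDims, idx, dz, fgIdx, dd) {
  seeds <- list()
  for (lv in names(anchors$perLevel)) {
    info <- anchors$perLevel[[lv]]
    hw <- info$dims[1] * info$dims[2]
    A <- info$anchorsPerCell
    lo <- info$rows[1]; hi <- info$rows[length(info$rows)]
    gobj <- numeric(hw * A)
    here <- which(idx >= lo & idx <= hi)
    if (length(here)) gobj[idx[here] - lo + 1L] <- dz[here]
    gdel <- matrix(0, hw, 4L * A)
    hereF <- which(fgIdx >= lo & fgIdx <= hi)
    if (length(hereF)) {
      loc <- fgIdx[hereF] - lo + 1L
      a <- (loc - 1L) %/% hw + 1L
      cell <- (loc - 1L) %% hw + 1L
      for (t in 1:4)
        gdel[cbind(cell, (a - 1L) * 4L + t)] <- dd[hereF, t]
    }
    seeds[[lv]] <- list(
      obj = array(gobj, c(info$dims[1], info$dims[2], A)),
      del = array(gdel, c(info$dims[1], info$dims[2], 4L * A)))
  }
  seeds
}

jitterBox <- function(box, imageSize) {
  w <- box[3] - box[1]; h <- box[4] - box[2]
  b <- box + rnorm(4) * 0.08 * c(w, h, w, h)
  b[c(1, 3)] <- clamp(b[c(1, 3)], 0, imageSize[2])
  b[c(2, 4)] <- clamp(b[c(2, 4)], 0, imageSize[1])
  if (b[3] - b[1] < 2 || b[4] - b[2] < 2) box else b
}

sampleRois <- function(gt, imageSize, nMax) {
  rois <- list()
  for (g in seq_len(nrow(gt$boxes))) {
    rois[[length(rois) + 1L]] <- gt$boxes[g, ]
    rois[[length(rois) + 1L]] <- jitterBox(gt$boxes[g, ], imageSize)
    rois[[length(rois) + 1L]] <- jitterBox(gt$boxes[g, ], imageSize)
  }
  sz <- mean(gt$boxes[, 3] - gt$boxes[, 1])
  tries <- 0L
  while (length(rois) < nMax && tries < 40L) {
    tries <- tries + 1L
    cx <- runif(1, sz, imageSize[2] - sz)
    cy <- runif(1, sz, imageSize[1] - sz)
    cand <- c(cx - sz / 2, cy - sz / 2, cx + sz / 2, cy + sz / 2)
    if (max(suppressWarnings(boxIou(cand, gt$boxes))) < 0.3)
      rois[[length(rois) + 1L]] <- cand
  }
  do.call(rbind, rois[seq_len(min(length(rois), nMax))])
}

softmaxRows <- function(l) {
  e <- exp(l - apply(l, 1, max))
  e / rowSums(e)
}

maskTarget <- function(mask, box, size) {
  cube <- array(as.numeric(mask), c(dim(mask), 1L))
  cpp_roi_align(cube, box, size, size)[, , 1] >= 0.5
}

#' One optimisation step
#'
#' Runs the full forward pass on each image of the batch, computes the five
#' loss components (RPN objectness and box regression, ROI classification
#' and regression, mask), backpropagates and applies an SGD-with-momentum
#' update (linear learning-rate warm-up). Images without annotations
#' contribute RPN losses only.
#'
#' @param model A \code{GrainModel}.
#' @param batch List of scenes, each a list with \code{image} and
#'   \code{annotations} (as produced by \code{\link{renderScene}}).
#' @return A list with the updated \code{model} and named \code{losses}
#'   (rpn_cls, rpn_reg, box_cls, box_reg, mask, total).
#' @export
trainStep <- function(model, batch) {
  cfg <- model@config
  step <- model@state$step
  pgTotal <- list()
  L <- c(rpn_cls = 0, rpn_reg = 0, box_cls = 0, box_reg = 0, mask = 0)
  for (scene in batch) {
    fw <- forwardBase(model, scene$image)
    anchors <- anchorsFor(fw$levelDims, cfg$anchor)
    # nearly hidden kernels leave sliver boxes whose regression targets are
    # extreme; they are excluded from supervision (evaluation still counts
    # every visible instance)
    gt <- gtFromAnnotations(scene$annotations, minSide = 6)
    asg <- assignFgBg(anchors$boxes, gt$boxes, cfg$assign)
    nA <- nrow(anchors$boxes)
    zAll <- numeric(nA)
    for (lv in names(anchors$perLevel))
      zAll[anchors$perLevel[[lv]]$rows] <-
        flattenObjMap(tpVal(fw$tp, fw$objIds[[lv]]))
    fgPool <- which(asg$labels == 1L)
    bgPool <- which(asg$labels == 0L)
    sampled <- withSeed(deriveSeed(cfg$seed, 100L + step), {
      nFg <- min(32L, length(fgPool))
      fgS <- if (nFg) sample(fgPool, nFg) else integer()
      nBg <- min(64L - nFg, length(bgPool))
      bgS <- if (nBg) sample(bgPool, nBg) else integer()
      list(fg = fgS, bg = bgS)
    })
    idx <- c(sampled$fg, sampled$bg)
    y <- c(rep(1, length(sampled$fg)), rep(0, length(sampled$bg)))
    # class-balanced objectness loss: with the strict 0.7 threshold the
    # positives are few (often just the rescue anchors), so foreground and
    # background each carry half the loss mass
    wv <- numeric(length(idx))
    if (length(sampled$fg) && length(sampled$bg)) {
      wv[y == 1] <- 0.5 / length(sampled$fg)
      wv[y == 0] <- 0.5 / length(sampled$bg)
    } else wv[] <- 1 / length(idx)
    sig <- 1 / (1 + exp(-zAll[idx]))
    eps <- 1e-7
    L[["rpn_cls"]] <- L[["rpn_cls"]] +
      sum(-wv * (y * log(sig + eps) + (1 - y) * log(1 - sig + eps)))
    dz <- wv * (sig - y)
    fgS <- sampled$fg
    dd <- matrix(numeric(), 0, 4)
    if (length(fgS)) {
      predD <- matrix(0, nA, 4)
      for (lv in names(anchors$perLevel))
        predD[anchors$perLevel[[lv]]$rows, ] <-
          flattenDeltaMap(tpVal(fw$tp, fw$delIds[[lv]]))
      target <- encodeDeltas(anchors$boxes[fgS, , drop = FALSE],
                             gt$boxes[asg$gtIndex[fgS], , drop = FALSE])
      diff <- predD[fgS, , drop = FALSE] - target
      L[["rpn_reg"]] <- L[["rpn_reg"]] + sum(smoothL1(diff)) / (4 * length(fgS))
      dd <- smoothL1Grad(diff) / (4 * length(fgS))
    }
    seedMaps <- scatterRpnGrads(anchors, NULL, idx, dz, fgS, dd)
    seeds <- list()
    for (lv in names(seedMaps)) {
      seeds[[length(seeds) + 1L]] <- list(id = fw$objIds[[lv]],
                                          grad = seedMaps[[lv]]$obj)
      seeds[[length(seeds) + 1L]] <- list(id = fw$delIds[[lv]],
                                          grad = seedMaps[[lv]]$del)
    }

    # ROI box/mask heads run on the same tape, so their losses shape the
    # pyramid and backbone too (keeping class information in the features)
    if (nrow(gt$boxes) > 0) {
      tp <- fw$tp
      rois <- withSeed(deriveSeed(cfg$seed, 200L + step),
                       sampleRois(gt, cfg$inputSize, cfg$roi$roisPerImage))
      iou <- suppressWarnings(boxIou(rois, gt$boxes))
      best <- max.col(iou, ties.method = "first")
      maxIou <- iou[cbind(seq_len(nrow(rois)), best)]
      roiCls <- ifelse(maxIou >= 0.5, gt$classes[best], 0L)
      n <- nrow(rois)
      fgR <- which(roiCls > 0L)
      mRois <- head(fgR, 16L)
      ms <- cfg$roi$maskSize
      clsIds <- integer(n); regIds <- integer(n)
      for (i in seq_len(n)) {
        fid <- tpFlatten(tp, roiFeatureNode(fw, rois[i, ], cfg$roi$boxSize))
        f1 <- tpRelu(tp, tpDense(tp, fid, "box.fc1"))
        clsIds[i] <- tpDense(tp, f1, "box.cls")
        regIds[i] <- tpDense(tp, f1, "box.reg")
      }
      logits <- t(vapply(clsIds, function(id) tpVal(tp, id),
                         numeric(cfg$numClasses + 1L)))
      p <- softmaxRows(logits)
      onehot <- matrix(0, n, cfg$numClasses + 1L)
      onehot[cbind(seq_len(n), roiCls + 1L)] <- 1
      L[["box_cls"]] <- L[["box_cls"]] +
        mean(-log(p[cbind(seq_len(n), roiCls + 1L)] + 1e-7))
      dcls <- (p - onehot) / n
      for (i in seq_len(n))
        seeds[[length(seeds) + 1L]] <- list(id = clsIds[i], grad = dcls[i, ])
      if (length(fgR)) {
        targetR <- encodeDeltas(rois[fgR, , drop = FALSE],
                                gt$boxes[best[fgR], , drop = FALSE])
        predR <- t(vapply(regIds[fgR], function(id) tpVal(tp, id),
                          numeric(4)))
        diffR <- predR - targetR
        L[["box_reg"]] <- L[["box_reg"]] +
          sum(smoothL1(diffR)) / (4 * length(fgR))
        dregR <- smoothL1Grad(diffR) / (4 * length(fgR))
        for (j in seq_along(fgR))
          seeds[[length(seeds) + 1L]] <- list(id = regIds[fgR[j]],
                                              grad = dregR[j, ])
      }
      for (i in mRois) {
        mid <- tpConv(tp, tpRelu(tp, tpConv(tp, roiFeatureNode(fw, rois[i, ],
                                                               ms),
                                            "mask.c1", 3L)),
                      "mask.c2", 1L)
        logitsM <- tpVal(tp, mid)
        cls <- roiCls[i]
        yM <- maskTarget(gt$masks[[best[i]]], rois[i, ], ms)
        sg <- 1 / (1 + exp(-logitsM[, , cls]))
        L[["mask"]] <- L[["mask"]] +
          mean(-(yM * log(sg + 1e-7) + (1 - yM) * log(1 - sg + 1e-7))) /
          length(mRois)
        gM <- array(0, dim(logitsM))
        gM[, , cls] <- (sg - yM) / (ms * ms * length(mRois))
        seeds[[length(seeds) + 1L]] <- list(id = mid, grad = gM)
      }
    }
    bk <- tapeBackward(fw$tp, seeds)
    pgTotal <- mergePg(pgTotal, bk$pgrads)
  }
  nb <- length(batch)
  L <- L / nb
  # global-norm gradient clipping keeps the small model stable at the
  # relatively large desk-scale learning rate
  gn2 <- 0
  for (pn in names(pgTotal))
    for (comp in names(pgTotal[[pn]]))
      gn2 <- gn2 + sum(pgTotal[[pn]][[comp]]^2)
  gn <- sqrt(gn2)
  clipAt <- if (is.null(cfg$train$clip)) 5 else cfg$train$clip
  if (is.finite(gn) && gn > clipAt) {
    sc <- clipAt / gn
    for (pn in names(pgTotal))
      for (comp in names(pgTotal[[pn]]))
        pgTotal[[pn]][[comp]] <- pgTotal[[pn]][[comp]] * sc
  }
  # the mask head sees the fewest supervised pixels per step, so its
  # parameters get a faster schedule
  hm <- if (is.null(cfg$train$headLrMult)) 4 else cfg$train$headLrMult
  for (pn in grep("^mask\\.", names(pgTotal), value = TRUE))
    for (comp in names(pgTotal[[pn]]))
      pgTotal[[pn]][[comp]] <- pgTotal[[pn]][[comp]] * hm
  lr <- cfg$train$lr * min(1, (step + 1) / max(1L, cfg$train$warmup))
  method <- if (is.null(cfg$train$optimizer)) "adam" else cfg$train$optimizer
  upd <- optimUpdate(model@params, model@state, pgTotal, lr / nb,
                     method = method)
  model@params <- upd$params
  model@state <- upd$state
  model@state$step <- step + 1L
  losses <- c(L, total = sum(L))
  list(model = model, losses = losses)
}

emptyDetection <- function(imageSize) {
  new("DetectionResult", boxes = matrix(numeric(), 0, 4),
      labels = integer(), scores = numeric(), masks = list(),
      imageSize = as.integer(imageSize))
}

pasteMask <- function(m14, box, imageSize) {
  h <- imageSize[1]; w <- imageSize[2]
  x1i <- max(0L, as.integer(floor(box[1]))); x2i <- min(w, as.integer(ceiling(box[3])))
  y1i <- max(0L, as.integer(floor(box[2]))); y2i <- min(h, as.integer(ceiling(box[4])))
  out <- matrix(FALSE, h, w)
  bw <- x2i - x1i; bh <- y2i - y1i
  if (bw < 1 || bh < 1) return(out)
  s <- dim(m14)[1]
  rel <- c((x1i - box[1]) / (box[3] - box[1]) * s,
           (y1i - box[2]) / (box[4] - box[2]) * s,
           (x2i - box[1]) / (box[3] - box[1]) * s,
           (y2i - box[2]) / (box[4] - box[2]) * s)
  res <- cpp_roi_align(array(m14, c(s, s, 1L)), rel, bh, bw)[, , 1]
  out[(y1i + 1L):y2i, (x1i + 1L):x2i] <- res >= 0.5
  out
}

#' Detect and segment kernels in one image
#'
#' Deterministic in evaluation: same weights and image give identical
#' output. Proposals are decoded from the RPN heads, refined and classified
#' by the box head, reduced by per-class NMS, and each survivor above the
#' confidence threshold receives a pasted binary mask from the mask head.
#'
#' @param model A trained (or freshly built) \code{GrainModel}.
#' @param image RGB array (h, w, 3), values in [0, 1]; h and w must be
#'   multiples of 64.
#' @param confidence Score threshold (default from the config; the standard
#'   operating point is 0.3).
#' @param maxDetections Cap on returned instances.
#' @return A \code{\link[=DetectionResult-class]{DetectionResult}}.
#' @export
predictKernels <- function(model, image, confidence = model@config$confidence,
                           maxDetections = 100L) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("input must be an RGB (h, w, 3) array")
  imageSize <- dim(image)[1:2]
  if (any(imageSize %% 64L != 0L))
    stop("image height and width must be multiples of 64")
  cfg <- model@config
  fw <- forwardBase(model, image)
  anchors <- anchorsFor(fw$levelDims, cfg$anchor)
  objMaps <- lapply(fw$objIds, function(id) tpVal(fw$tp, id))
  delMaps <- lapply(fw$delIds, function(id) tpVal(fw$tp, id))
  prop <- proposeRegions(objMaps, delMaps, anchors, cfg$assign, imageSize)
  if (!nrow(prop$boxes)) return(emptyDetection(imageSize))
  W <- cfg$pyramid$width
  X <- t(vapply(seq_len(nrow(prop$boxes)), function(i)
    as.numeric(roiFeature(fw, prop$boxes[i, ], cfg$roi$boxSize)),
    numeric(cfg$roi$boxSize^2 * W)))
  p <- model@params
  f1 <- pmax(sweep(X %*% p$box.fc1$W, 2, p$box.fc1$b, "+"), 0)
  probs <- softmaxRows(sweep(f1 %*% p$box.cls$W, 2, p$box.cls$b, "+"))
  reg <- sweep(f1 %*% p$box.reg$W, 2, p$box.reg$b, "+")
  refined <- decodeDeltas(prop$boxes, reg)
  refined[, c(1, 3)] <- clamp(refined[, c(1, 3)], 0, imageSize[2])
  refined[, c(2, 4)] <- clamp(refined[, c(2, 4)], 0, imageSize[1])
  # suppression (per-class, then optionally across classes) runs before the
  # confidence cut, so lowering the threshold can only add detections
  keepB <- list(); keepS <- list(); keepL <- list()
  for (cls in seq_len(cfg$numClasses)) {
    sc <- probs[, cls + 1L]
    ok <- which(refined[, 3] - refined[, 1] > 1 &
                refined[, 4] - refined[, 2] > 1)
    if (!length(ok)) next
    kept <- ok[nmsKeep(refined[ok, , drop = FALSE], sc[ok], cfg$detNmsIou)]
    if (!length(kept)) next
    keepB[[cls]] <- refined[kept, , drop = FALSE]
    keepS[[cls]] <- sc[kept]
    keepL[[cls]] <- rep(cls, length(kept))
  }
  if (!length(keepB)) return(emptyDetection(imageSize))
  boxes <- do.call(rbind, keepB)
  scores <- unlist(keepS); labels <- unlist(keepL)
  if (isTRUE(cfg$crossClassNms)) {
    keep <- nmsKeep(boxes, scores, cfg$detNmsIou)
    boxes <- boxes[keep, , drop = FALSE]
    scores <- scores[keep]; labels <- labels[keep]
  }
  pass <- scores >= confidence
  boxes <- boxes[pass, , drop = FALSE]
  scores <- scores[pass]; labels <- labels[pass]
  if (!length(scores)) return(emptyDetection(imageSize))
  ord <- order(-scores)
  ord <- ord[seq_len(min(length(ord), maxDetections))]
  boxes <- boxes[ord, , drop = FALSE]
  scores <- scores[ord]; labels <- as.integer(labels[ord])
  masks <- vector("list", nrow(boxes))
  for (i in seq_len(nrow(boxes))) {
    feat <- roiFeature(fw, boxes[i, ], cfg$roi$maskSize)
    h1 <- cpp_conv2d_fwd(feat, p$mask.c1$W, p$mask.c1$b, 3L, 1L, 1L)$out
    h1 <- pmax(h1, 0)
    lg <- cpp_conv2d_fwd(h1, p$mask.c2$W, p$mask.c2$b, 1L, 1L, 0L)$out
    m14 <- 1 / (1 + exp(-lg[, , labels[i]]))
    masks[[i]] <- pasteMask(m14, boxes[i, ], imageSize)
  }
  new("DetectionResult", boxes = boxes, labels = labels, scores = scores,
      masks = masks, imageSize = as.integer(imageSize))
}

#' @rdname predictKernels
#' @param object A \code{GrainModel} (S4 dispatch for \code{predict}).
#' @param ... Passed to \code{predictKernels}.
#' @export
setMethod("predict", "GrainModel", function(object, ...)
  predictKernels(object, ...))

#' Train a model on a set of scenes
#'
#' Cycles through the scenes in order with the configured batch size,
#' optionally evaluating validation mAP along the way. Deterministic given
#' the model seed and scene list.
#'
#' @param model A \code{GrainModel}.
#' @param scenes List of rendered scenes (image + annotations).
#' @param iterations Number of optimisation steps.
#' @param valScenes Optional validation scenes.
#' @param evalEvery Evaluate validation mAP every this many steps (0 = only
#'   at the end when \code{valScenes} are given).
#' @param verbose Print progress lines.
#' @return A list with the trained \code{model} and a \code{log} data.frame
#'   of per-step losses (plus \code{valMAP} where evaluated).
#' @export
trainModel <- function(model, scenes, iterations, valScenes = NULL,
                       evalEvery = 0L, verbose = FALSE) {
  nb <- model@config$train$batch
  logRows <- vector("list", iterations)
  ptr <- 1L
  for (it in seq_len(iterations)) {
    take <- ((ptr - 1L + seq_len(nb) - 1L) %% length(scenes)) + 1L
    ptr <- ptr + nb
    st <- trainStep(model, scenes[take])
    model <- st$model
    row <- as.list(st$losses)
    row$iter <- it
    row$valMAP <- NA_real_
    if (evalEvery > 0 && !is.null(valScenes) && it %% evalEvery == 0)
      row$valMAP <- evaluateModel(model, valScenes)@mAP
    logRows[[it]] <- row
    if (verbose && it %% 10 == 0)
      message(sprintf("iter %d: total loss %.4f", it, st$losses[["total"]]))
  }
  log <- do.call(rbind, lapply(logRows, as.data.frame))
  if (!is.null(valScenes) && (evalEvery == 0 || iterations %% evalEvery != 0))
    log$valMAP[iterations] <- evaluateModel(model, valScenes)@mAP
  list(model = model, log = log)
}

#' Evaluate a model on scenes with ground truth
#'
#' @param model A \code{GrainModel}.
#' @param scenes List of scenes with annotations.
#' @param confidence Detection threshold used during prediction. The default
#'   is a low cutoff (0.05) because AP sweeps the score threshold itself;
#'   deployment-style reporting at the 0.3 operating point is obtained by
#'   passing \code{confidence = 0.3}.
#' @param spec A \code{\link{matchSpec}}.
#' @return A \code{\link[=MetricReport-class]{MetricReport}}.
#' @export
evaluateModel <- function(model, scenes, confidence = 0.05,
                          spec = matchSpec()) {
  t0 <- proc.time()[["elapsed"]]
  preds <- lapply(scenes, function(s) predictKernels(model, s$image,
                                                     confidence))
  dt <- (proc.time()[["elapsed"]] - t0) / max(1L, length(scenes))
  gts <- lapply(scenes, `[[`, "annotations")
  rep <- evaluateDetections(preds, gts, spec)
  rep@nParameters <- as.numeric(countParameters(model))
  rep@timePerImage <- dt
  rep
}
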