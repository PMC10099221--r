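# Detector assembly: residual backbone with optional channel attention on
# the four stage outputs, feature pyramid (top-down or with the bottom-up
# fusion path), RPN heads, and ROI box/mask heads.

variantKinds <- function(variant) {
  switch(variant,
    baseline = c(attention = "none", pyramid = "fpn"),
    am       = c(attention = "eca",  pyramid = "fpn"),
    fpn      = c(attention = "none", pyramid = "bottom_up"),
    am_fpn   = c(attention = "eca",  pyramid = "bottom_up"),
    custom   = NULL,
    stop("unknown variant: ", variant))
}

#' Model configuration
#'
#' The four named variants wire attention and pyramid kinds together:
#' \code{baseline} (no attention, top-down pyramid), \code{am} (ECA added),
#' \code{fpn} (bottom-up fusion path added) and \code{am_fpn} (both, the
#' improved model). \code{variant = "custom"} frees both axes for ablations
#' (e.g. SE or CBAM attention with the recursive pyramid).
#'
#' @param variant One of \code{baseline}, \code{am}, \code{fpn},
#'   \code{am_fpn}, \code{custom}.
#' @param inputSize Integer (height, width) the model ingests.
#' @param backboneChannels Channel widths of stages C2..C5.
#' @param blocksPerStage Residual blocks per backbone stage.
#' @param pyramidWidth Uniform pyramid channel width.
#' @param attentionKind,pyramidKind Used when \code{variant = "custom"}.
#' @param anchor An \code{\link{anchorConfig}}.
#' @param assign An \code{\link{assignmentConfig}} (training thresholds).
#' @param lr,batch,epochs,warmup Training schedule: base learning rate,
#'   images per step, passes over the data, linear warm-up steps.
#' @param optimizer \code{"adam"} (default) or \code{"sgd"} (momentum 0.9).
#' @param confidence Detection score threshold at inference.
#' @param detNmsIou Per-class NMS threshold at the detection stage.
#' @param crossClassNms Also suppress overlapping detections across classes
#'   (adherent kernels never overlap deeply, so a same-spot detection of a
#'   second class is almost surely a duplicate). Default TRUE.
#' @param seed Weight-initialisation seed.
#' @return A list of class \code{modelConfig}.
#' @export
modelConfig <- function(variant = c("baseline", "am", "fpn", "am_fpn",
                                    "custom"),
                        inputSize = c(512L, 512L),
                        backboneChannels = c(32L, 64L, 128L, 256L),
                        blocksPerStage = 1L,
                        pyramidWidth = 64L,
                        attentionKind = "none", pyramidKind = "fpn",
                        anchor = anchorConfig(),
                        assign = assignmentConfig(),
                        lr = 0.00125, batch = 4L, epochs = 50L,
                        warmup = 500L, optimizer = c("adam", "sgd"),
                        confidence = 0.3, detNmsIou = 0.5,
                        crossClassNms = TRUE, seed = 1L) {
  variant <- match.arg(variant)
  optimizer <- match.arg(optimizer)
  kinds <- variantKinds(variant)
  if (!is.null(kinds)) {
    attentionKind <- kinds[["attention"]]
    pyramidKind <- kinds[["pyramid"]]
  }
  structure(list(
    variant = variant,
    inputSize = as.integer(inputSize),
    backboneChannels = as.integer(backboneChannels),
    blocksPerStage = as.integer(blocksPerStage),
    attention = attentionConfig(attentionKind),
    pyramid = pyramidConfig(pyramidKind, pyramidWidth),
    anchor = anchor, assign = assign,
    train = list(lr = lr, batch = as.integer(batch),
                 epochs = as.integer(epochs), warmup = as.integer(warmup),
                 optimizer = optimizer),
    roi = list(boxSize = 7L, maskSize = 14L, fcWidth = 128L,
               roisPerImage = 24L),
    numClasses = 6L,
    confidence = confidence, detNmsIou = detNmsIou,
    crossClassNms = crossClassNms,
    seed = as.integer(seed)), class = c("modelConfig", "list"))
}

#' Desk-scale model configuration
#'
#' A small preset that trains in minutes on one CPU: 256 px input, a narrow
#' backbone (8/16/32/64), pyramid width 16, reduced proposal budgets and a
#' learning rate suited to the small parameter count. Used by the package's
#' examples and tests.
#'
#' @param variant Model variant, as in \code{\link{modelConfig}}.
#' @param lr,batch,inputSize Desk-scale schedule and input size defaults.
#' @param ... Further overrides passed to \code{\link{modelConfig}}.
#' @return A \code{modelConfig}.
#' @export
tinyModelConfig <- function(variant = "am_fpn", lr = 0.01, batch = 2L,
                            inputSize = c(256L, 256L), ...) {
  modelConfig(variant = variant,
              inputSize = inputSize,
              backboneChannels = c(8L, 16L, 32L, 64L),
              blocksPerStage = 1L,
              pyramidWidth = 16L,
              assign = assignmentConfig(preNmsTopk = 500L,
                                        postNmsTopk = 100L),
              lr = lr, batch = batch, warmup = 30L, optimizer = "sgd", ...)
}

# anchors-per-cell for each pyramid level under an anchor config
levelAnchorCounts <- function(anchor) {
  vapply(anchor$levelAssignment, function(s) length(s) * length(anchor$ratios),
         integer(1))
}

makeDetectorParams <- function(cfg) {
  ch <- cfg$backboneChannels
  W <- cfg$pyramid$width
  p <- list()
  p[["bb.stem"]] <- initConv(3L, ch[1], 3L)
  cin <- ch[1]
  for (s in 1:4) {
    p[[sprintf("bb.s%d.conv", s)]] <- initConv(cin, ch[s], 3L)
    for (bl in seq_len(cfg$blocksPerStage)) {
      p[[sprintf("bb.s%d.b%d.c1", s, bl)]] <- initConv(ch[s], ch[s], 3L)
      p[[sprintf("bb.s%d.b%d.c2", s, bl)]] <- initConv(ch[s], ch[s], 3L)
    }
    cin <- ch[s]
  }
  if (cfg$attention$kind != "none") {
    for (s in 1:4) {
      blk <- makeAttentionParams(cfg$attention$kind, ch[s], cfg$attention)
      for (nm in names(blk)) p[[sprintf("att%d.%s", s + 1, nm)]] <- blk[[nm]]
    }
  }
  pyr <- makePyramidParams(ch, cfg$pyramid)
  for (nm in names(pyr)) p[[paste0("pyr.", nm)]] <- pyr[[nm]]
  p[["rpn.trunk"]] <- initConv(W, W, 3L)
  # output layers start near zero (the usual detection-head practice): the
  # initial losses are then well-scaled and the ReLU trunk cannot die from
  # violent first updates
  for (A in unique(levelAnchorCounts(cfg$anchor))) {
    p[[sprintf("rpn.obj%d", A)]] <- initConv(W, A, 1L, sd = 0.01)
    p[[sprintf("rpn.del%d", A)]] <- initConv(W, 4L * A, 1L, sd = 0.01)
  }
  p[["box.fc1"]] <- initDense(cfg$roi$boxSize^2 * W, cfg$roi$fcWidth)
  p[["box.cls"]] <- initDense(cfg$roi$fcWidth, cfg$numClasses + 1L, sd = 0.01)
  p[["box.reg"]] <- initDense(cfg$roi$fcWidth, 4L, sd = 0.01)
  p[["mask.c1"]] <- initConv(W, W, 3L)
  p[["mask.c2"]] <- initConv(W, cfg$numClasses, 1L, sd = 0.01)
  p
}

#' Build a kernel-segmentation model
#'
#' Initialises all weights from the configuration seed; the four named
#' variants differ only in their attention and pyramid subgraphs, so
#' parameter-count differences audit those modules exactly.
#'
#' @param config A \code{\link{modelConfig}}.
#' @param seed Optional override of the config's weight seed.
#' @return A \code{\link[=GrainModel-class]{GrainModel}}.
#' @examples
#' m <- buildModel(tinyModelConfig("baseline"))
#' countParameters(m)
#' @export
buildModel <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "modelConfig"))
  params <- withSeed(deriveSeed(seed, 7L), makeDetectorParams(config))
  new("GrainModel", config = config, params = params,
      state = list(step = 0L, velocity = list()))
}

#' Count trainable parameters
#'
#' @param model A \code{GrainModel}, or a bare list of parameter blocks.
#' @return Integer count of trainable scalars; an empty model counts 0.
#' @export
countParameters <- function(model) {
  params <- if (is(model, "GrainModel")) model@params else model
  as.integer(numParams(params))
}

#' Add (or replace) the attention stage of a model
#'
#' Gates each backbone stage output C2..C5 with one attention block before
#' the pyramid laterals. \code{kind = "none"} returns the model unchanged;
#' any other kind strictly increases the parameter count.
#'
#' @param model A \code{GrainModel}.
#' @param config An \code{\link{attentionConfig}} or a kind string.
#' @return The modified \code{GrainModel}.
#' @export
attachAttention <- function(model, config) {
  if (is.character(config)) config <- attentionConfig(config)
  stopifnot(inherits(config, "attentionConfig"))
  if (config$kind == "none") return(model)
  params <- model@params
  params <- params[!grepl("^att[0-9]+\\.", names(params))]
  ch <- model@config$backboneChannels
  newBlocks <- withSeed(deriveSeed(model@config$seed, 8L), {
    out <- list()
    for (s in 1:4) {
      blk <- makeAttentionParams(config$kind, ch[s], config)
      for (nm in names(blk)) out[[sprintf("att%d.%s", s + 1, nm)]] <- blk[[nm]]
    }
    out
  })
  model@params <- c(params, newBlocks)
  model@config$attention <- config
  if (model@config$variant != "custom") model@config$variant <- "custom"
  model
}

# ---- forward graph -------------------------------------------------------

# every backbone conv is followed by a parameter-free per-channel RMS norm
# (the single-image stand-in for batch normalisation), then ReLU
backboneGraph <- function(tp, xid, cfg) {
  cnr <- function(id, pname, stride = 1L)
    tpRelu(tp, tpChanRmsNorm(tp, tpConv(tp, id, pname, 3L, stride = stride,
                                        pad = 1L)))
  x <- cnr(xid, "bb.stem", stride = 2L)
  x <- tpPool(tp, x)
  out <- list()
  for (s in 1:4) {
    if (s > 1) x <- tpPool(tp, x)
    x <- cnr(x, sprintf("bb.s%d.conv", s))
    for (bl in seq_len(cfg$blocksPerStage)) {
      y <- cnr(x, sprintf("bb.s%d.b%d.c1", s, bl))
      y <- tpChanRmsNorm(tp, tpConv(tp, y, sprintf("bb.s%d.b%d.c2", s, bl),
                                    3L))
      x <- tpRelu(tp, tpAdd(tp, x, y))
    }
    out[[paste0("C", s + 1)]] <- x
  }
  out
}

# full forward pass to RPN head maps; returns tape plus node bookkeeping
forwardBase <- function(model, image) {
  cfg <- model@config
  tp <- tapeNew(model@params)
  xid <- tpInput(tp, image)
  cIds <- backboneGraph(tp, xid, cfg)
  if (cfg$attention$kind != "none") {
    for (s in 1:4) {
      nm <- paste0("C", s + 1)
      cIds[[nm]] <- attentionGraph(tp, cIds[[nm]], cfg$attention$kind,
                                   cfg$attention, sprintf("att%d", s + 1))
    }
  }
  lvIds <- pyramidGraph(tp, cIds, cfg$pyramid, "pyr")
  names(lvIds) <- sub("^[PN]", "", names(lvIds))
  counts <- levelAnchorCounts(cfg$anchor)
  objIds <- list(); delIds <- list(); levelDims <- list()
  for (lv in names(lvIds)) {
    A <- counts[[lv]]
    if (is.null(A) || is.na(A)) next
    t <- tpRelu(tp, tpConv(tp, lvIds[[lv]], "rpn.trunk", 3L))
    objIds[[lv]] <- tpConv(tp, t, sprintf("rpn.obj%d", A), 1L)
    delIds[[lv]] <- tpConv(tp, t, sprintf("rpn.del%d", A), 1L)
    levelDims[[lv]] <- dim(tpVal(tp, lvIds[[lv]]))[1:2]
  }
  list(tp = tp, cIds = cIds, lvIds = lvIds, objIds = objIds,
       delIds = delIds, levelDims = levelDims)
}

# memoized anchors (keyed by dims and anchor config)
.anchorCache <- new.env(parent = emptyenv())

anchorsFor <- function(levelDims, anchor) {
  key <- paste(unlist(levelDims), unlist(anchor$levelAssignment),
               paste(anchor$ratios, collapse = ","), collapse = "|")
  got <- .anchorCache[[key]]
  if (!is.null(got)) return(got)
  a <- generateAnchors(levelDims, anchor)
  .anchorCache[[key]] <- a
  a
}

# feature level for an ROI: kernels (~32 px) map to the stride-4 level
roiLevel <- function(box) {
  area <- max(box[3] - box[1], 1e-6) * max(box[4] - box[2], 1e-6)
  clamp(2L + as.integer(floor(log2(sqrt(area) / 32))), 2L, 5L)
}

# inference-time ROI feature: bilinear alignment from the level matching the
# box size, RMS-normalised (identical math to the tape path used in training)
roiFeature <- function(fw, box, size) {
  lv <- as.character(roiLevel(box))
  feat <- tpVal(fw$tp, fw$lvIds[[lv]])
  stride <- 2^as.integer(lv)
  out <- cpp_roi_align(feat, box / stride, size, size)
  out / sqrt(mean(out^2) + 1e-8)
}

# tape node for the same ROI feature (training path, gradients flow through)
roiFeatureNode <- function(fw, box, size) {
  lv <- as.character(roiLevel(box))
  stride <- 2^as.integer(lv)
  tpRmsNorm(fw$tp, tpRoiAlign(fw$tp, fw$lvIds[[lv]], box / stride,
                              size, size))
}
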