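# Channel attention blocks: ECA (default), SE and CBAM for the ablation.
# Each block gates the (h, w, C) stage output without changing its shape;
# gates are logistic, hence strictly inside (0, 1).

#' Attention configuration
#'
#' @param kind One of \code{"eca"}, \code{"se"}, \code{"cbam"}, \code{"none"}.
#' @param ecaGamma,ecaB Integers of the adaptive ECA kernel-size rule
#'   \code{k = |log2(C)/gamma + b/gamma|} rounded to the nearest odd integer.
#' @param seReduction Squeeze-excite bottleneck reduction (bottleneck width
#'   is \code{max(1, floor(C / seReduction))}).
#' @param cbamSpatialKernel Spatial-gate convolution size (odd).
#' @return A list of class \code{attentionConfig}.
#' @export
attentionConfig <- function(kind = c("eca", "se", "cbam", "none"),
                            ecaGamma = 2L, ecaB = 1L, seReduction = 16L,
                            cbamSpatialKernel = 7L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, ecaGamma = as.integer(ecaGamma),
                 ecaB = as.integer(ecaB), seReduction = as.integer(seReduction),
                 cbamSpatialKernel = as.integer(cbamSpatialKernel)),
            class = "attentionConfig")
}

#' Adaptive ECA kernel size
#'
#' Cross-channel 1-D convolution width \code{k} grows with the channel count:
#' \code{k} is \code{log2(C)/gamma + b/gamma} rounded to the nearest odd
#' integer (ties round up), never below 1.
#'
#' @param channels Number of channels (>= 1).
#' @param gamma,b Rule coefficients.
#' @return An odd integer >= 1.
#' @examples
#' ecaKernelSize(256)  # 5
#' @export
ecaKernelSize <- function(channels, gamma = 2L, b = 1L) {
  stopifnot(channels >= 1)
  k0 <- abs(log2(channels) / gamma + b / gamma)
  lower <- 2 * floor((k0 - 1) / 2) + 1
  upper <- lower + 2
  k <- if (k0 - lower < upper - k0) lower else upper
  max(1L, as.integer(k))
}

# fresh parameter blocks for one attention module (caller seeds the RNG)
makeAttentionParams <- function(kind, channels, cfg) {
  switch(kind,
    none = list(),
    eca = list(conv = initConv1d(ecaKernelSize(channels, cfg$ecaGamma,
                                               cfg$ecaB))),
    se = {
      cb <- max(1L, channels %/% cfg$seReduction)
      list(fc1 = initDense(channels, cb), fc2 = initDense(cb, channels))
    },
    cbam = {
      cb <- max(1L, channels %/% cfg$seReduction)
      list(fc1 = initDense(channels, cb), fc2 = initDense(cb, channels),
           sconv = initConv(2L, 1L, cfg$cbamSpatialKernel))
    },
    stop("unknown attention kind: '", kind, "'"))
}

# tape subgraph; params registered under paste0(prefix, ".", name)
attentionGraph <- function(tp, xid, kind, cfg, prefix) {
  pn <- function(nm) paste0(prefix, ".", nm)
  if (kind == "none") return(xid)
  if (kind == "eca") {
    g <- tpSigmoid(tp, tpConv1d(tp, tpGap(tp, xid), pn("conv")))
    return(tpScaleChan(tp, xid, g))
  }
  if (kind == "se") {
    g <- tpSigmoid(tp, tpDense(tp, tpRelu(tp, tpDense(tp, tpGap(tp, xid),
                                                      pn("fc1"))), pn("fc2")))
    return(tpScaleChan(tp, xid, g))
  }
  if (kind == "cbam") {
    mlp <- function(sid) tpDense(tp, tpRelu(tp, tpDense(tp, sid, pn("fc1"))),
                                 pn("fc2"))
    gch <- tpSigmoid(tp, tpAdd(tp, mlp(tpGap(tp, xid)), mlp(tpGmp(tp, xid))))
    x1 <- tpScaleChan(tp, xid, gch)
    sin <- tpConcatC(tp, tpChanMean(tp, x1), tpChanMax(tp, x1))
    gsp <- tpSigmoid(tp, tpConv(tp, sin, pn("sconv"), cfg$cbamSpatialKernel))
    return(tpScaleSpace(tp, x1, gsp))
  }
  stop("unknown attention kind: '", kind, "'")
}

#' Create a standalone attention block
#'
#' @param kind Attention kind (\code{eca}, \code{se}, \code{cbam}).
#' @param channels Channel count of the feature map the block will gate.
#' @param config An \code{\link{attentionConfig}}.
#' @param seed Seed for weight initialisation.
#' @return A list of class \code{attentionBlock} holding the parameters.
#' @export
attentionBlock <- function(kind, channels, config = attentionConfig(kind),
                           seed = 1L) {
  params <- withSeed(deriveSeed(seed, 31L),
                     makeAttentionParams(kind, channels, config))
  structure(list(kind = kind, channels = as.integer(channels),
                 config = config, params = params),
            class = "attentionBlock")
}

#' Apply an attention block to a feature map
#'
#' @param block An \code{\link{attentionBlock}}.
#' @param x Numeric array (h, w, channels); must be finite.
#' @return The gated feature map, same shape as \code{x}.
#' @export
attentionApply <- function(block, x) {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("x must be an (h, w, c) array")
  if (dim(x)[3] != block$channels)
    stop("channel mismatch: block expects ", block$channels)
  if (any(!is.finite(x))) stop("non-finite values in input feature map")
  params <- list()
  for (nm in names(block$params)) params[[paste0("att.", nm)]] <- block$params[[nm]]
  tp <- tapeNew(params)
  out <- attentionGraph(tp, tpInput(tp, x), block$kind, block$config, "att")
  tpVal(tp, out)
}

#' @describeIn attentionApply ECA forward pass with fresh (seeded) weights.
#' @param config An \code{\link{attentionConfig}}.
#' @param seed Weight seed.
#' @export
ecaForward <- function(x, config = attentionConfig("eca"), seed = 1L) {
  attentionApply(attentionBlock("eca", dim(x)[3], config, seed), x)
}

#' @describeIn attentionApply SE forward pass with fresh (seeded) weights.
#' @export
seForward <- function(x, config = attentionConfig("se"), seed = 1L) {
  attentionApply(attentionBlock("se", dim(x)[3], config, seed), x)
}

#' @describeIn attentionApply CBAM forward pass with fresh (seeded) weights.
#' @export
cbamForward <- function(x, config = attentionConfig("cbam"), seed = 1L) {
  attentionApply(attentionBlock("cbam", dim(x)[3], config, seed), x)
}
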