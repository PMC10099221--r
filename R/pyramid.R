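# Feature pyramids: the standard top-down path (P-levels), the bottom-up
# fusion path producing the prediction levels (N-levels), and a recursive
# variant that feeds the fused maps back into the backbone levels for a
# second top-down pass.
#
# Smoothing convention for kind = "bottom_up": the final 3x3 output conv of
# the top-down path (the P2 one) is removed and N2 is the raw P2; P3..P5 keep
# their 3x3 convs and the three bottom-up fusion convs are added, a net gain
# of two 3x3 convolutions over the plain pyramid.

#' Pyramid configuration
#'
#' @param kind \code{"fpn"} (top-down only), \code{"bottom_up"} (adds the
#'   low-to-high fusion path; the default of the improved model) or
#'   \code{"rfpn"} (recursive variant).
#' @param width Uniform channel width of all pyramid levels.
#' @param downsample How the bottom-up path halves resolution:
#'   \code{"maxpool2"} (default) or \code{"strided_conv"}.
#' @return A list of class \code{pyramidConfig}.
#' @export
pyramidConfig <- function(kind = c("fpn", "bottom_up", "rfpn"), width = 256L,
                          downsample = c("maxpool2", "strided_conv")) {
  kind <- match.arg(kind)
  downsample <- match.arg(downsample)
  stopifnot(width > 0)
  structure(list(kind = kind, width = as.integer(width),
                 downsample = downsample),
            class = "pyramidConfig")
}

# parameter blocks for a pyramid over backbone channels cChannels (C2..C5)
makePyramidParams <- function(cChannels, cfg) {
  W <- cfg$width
  p <- list()
  for (k in 2:5) p[[paste0("lat", k)]] <- initConv(cChannels[[k - 1]], W, 1L)
  smoothLevels <- if (cfg$kind == "bottom_up") 3:5 else 2:5
  for (k in smoothLevels) p[[paste0("smooth", k)]] <- initConv(W, W, 3L)
  if (cfg$kind == "bottom_up") {
    for (k in 3:5) p[[paste0("fuse", k)]] <- initConv(W, W, 3L)
    if (cfg$downsample == "strided_conv")
      for (k in 3:5) p[[paste0("down", k)]] <- initConv(W, W, 3L)
  }
  if (cfg$kind == "rfpn")
    for (k in 2:5) p[[paste0("proj", k)]] <- initConv(W, cChannels[[k - 1]], 1L)
  p
}

# top-down pass over backbone node ids; smoothing = "all" or "upper" (P3..P5)
topDownGraph <- function(tp, cIds, cfg, prefix, smoothing = "all") {
  pn <- function(nm) paste0(prefix, ".", nm)
  lat <- lapply(2:5, function(k) tpConv(tp, cIds[[paste0("C", k)]],
                                        pn(paste0("lat", k)), 1L))
  names(lat) <- paste0("L", 2:5)
  raw <- list(P5 = lat$L5)
  for (k in 4:2)
    raw[[paste0("P", k)]] <- tpAdd(tp, lat[[paste0("L", k)]],
                                   tpUp(tp, raw[[paste0("P", k + 1)]]))
  out <- list()
  for (k in 2:5) {
    nm <- paste0("P", k)
    out[[nm]] <- if (smoothing == "all" || k >= 3)
      tpConv(tp, raw[[nm]], pn(paste0("smooth", k)), 3L)
    else raw[[nm]]
  }
  out
}

# bottom-up fusion over P-level node ids -> N2..N6
bottomUpGraph <- function(tp, pIds, cfg, prefix) {
  pn <- function(nm) paste0(prefix, ".", nm)
  down <- function(id, k) {
    if (cfg$downsample == "strided_conv")
      tpConv(tp, id, pn(paste0("down", k)), 3L, stride = 2L, pad = 1L)
    else tpPool(tp, id)
  }
  out <- list(N2 = pIds$P2)
  for (k in 3:5) {
    fused <- tpAdd(tp, down(out[[paste0("N", k - 1)]], k),
                   pIds[[paste0("P", k)]])
    out[[paste0("N", k)]] <- tpConv(tp, fused, pn(paste0("fuse", k)), 3L)
  }
  out$N6 <- tpPool(tp, out$N5)
  out
}

# full pyramid subgraph; returns named list of prediction-level node ids
pyramidGraph <- function(tp, cIds, cfg, prefix = "pyr") {
  if (cfg$kind == "fpn") {
    p <- topDownGraph(tp, cIds, cfg, prefix, smoothing = "all")
    p$P6 <- tpPool(tp, p$P5)
    return(p)
  }
  if (cfg$kind == "bottom_up") {
    p <- topDownGraph(tp, cIds, cfg, prefix, smoothing = "upper")
    return(bottomUpGraph(tp, p, cfg, prefix))
  }
  if (cfg$kind == "rfpn") {
    p1 <- topDownGraph(tp, cIds, cfg, prefix, smoothing = "all")
    c2 <- list()
    for (k in 2:5) {
      nm <- paste0("C", k)
      back <- tpConv(tp, p1[[paste0("P", k)]],
                     paste0(prefix, ".proj", k), 1L)
      c2[[nm]] <- tpAdd(tp, cIds[[nm]], back)
    }
    p2 <- topDownGraph(tp, c2, cfg, prefix, smoothing = "all")
    p2$P6 <- tpPool(tp, p2$P5)
    return(p2)
  }
  stop("unknown pyramid kind: ", cfg$kind)
}

checkCLevels <- function(cLevels) {
  stopifnot(all(paste0("C", 2:5) %in% names(cLevels)))
  for (k in 2:4) {
    da <- dim(cLevels[[paste0("C", k)]]); db <- dim(cLevels[[paste0("C", k + 1)]])
    if (!(da[1] == 2 * db[1] && da[2] == 2 * db[2]))
      stop("spatial dims must halve between C", k, " and C", k + 1)
  }
}

runPyramid <- function(cLevels, config, params, seed, builder) {
  if (is.null(params))
    params <- withSeed(deriveSeed(seed, 41L),
                       makePyramidParams(vapply(cLevels, function(x) dim(x)[3],
                                                numeric(1)), config))
  full <- list()
  for (nm in names(params)) full[[paste0("pyr.", nm)]] <- params[[nm]]
  tp <- tapeNew(full)
  ids <- lapply(cLevels, function(x) tpInput(tp, x))
  outIds <- builder(tp, ids)
  list(levels = lapply(outIds, function(id) tpVal(tp, id)), params = params)
}

#' Top-down feature pyramid
#'
#' Projects backbone stages C2..C5 to a uniform width with 1x1 laterals,
#' fuses them top-down with nearest-neighbour upsampling, smooths with 3x3
#' convolutions per the configured kind, and appends a stride-2 pooled top
#' level for proposal generation.
#'
#' @param cLevels Named list of arrays \code{C2..C5}; spatial dims must halve
#'   per level.
#' @param config A \code{\link{pyramidConfig}}.
#' @param params Optional pyramid parameters (as produced internally);
#'   freshly initialised from \code{seed} when \code{NULL}.
#' @param seed Weight seed.
#' @return List with \code{levels} (named arrays \code{P2..P6}) and
#'   \code{params}.
#' @export
topDownFpn <- function(cLevels, config = pyramidConfig("fpn"), params = NULL,
                       seed = 1L) {
  checkCLevels(cLevels)
  runPyramid(cLevels, config, params, seed, function(tp, ids) {
    p <- topDownGraph(tp, ids, config, "pyr",
                      smoothing = if (config$kind == "bottom_up") "upper"
                                  else "all")
    p$P6 <- tpPool(tp, p$P5)
    p
  })
}

#' Bottom-up fusion path
#'
#' Builds the prediction levels from the P-levels: \code{N2 = P2}, then
#' \code{N(k+1) = conv3x3(downsample(Nk) + P(k+1))}, plus a pooled \code{N6}.
#' All levels keep the pyramid width.
#'
#' @param pLevels Named list of arrays \code{P2..P5} of equal channel width.
#' @param config A \code{\link{pyramidConfig}} (kind \code{"bottom_up"}).
#' @param params Optional fusion parameters; fresh when \code{NULL}.
#' @param seed Weight seed.
#' @return List with \code{levels} (named arrays \code{N2..N6}) and
#'   \code{params}.
#' @export
bottomUpFuse <- function(pLevels, config = pyramidConfig("bottom_up"),
                         params = NULL, seed = 1L) {
  stopifnot(all(paste0("P", 2:5) %in% names(pLevels)))
  ws <- vapply(pLevels, function(x) dim(x)[3], numeric(1))
  if (length(unique(ws)) != 1L)
    stop("all P-levels must share one channel width")
  if (is.null(params)) {
    cfg <- config
    params <- withSeed(deriveSeed(seed, 42L), {
      p <- list()
      for (k in 3:5) p[[paste0("fuse", k)]] <- initConv(ws[[1]], ws[[1]], 3L)
      if (cfg$downsample == "strided_conv")
        for (k in 3:5) p[[paste0("down", k)]] <- initConv(ws[[1]], ws[[1]], 3L)
      p
    })
  }
  full <- list()
  for (nm in names(params)) full[[paste0("pyr.", nm)]] <- params[[nm]]
  tp <- tapeNew(full)
  ids <- lapply(pLevels, function(x) tpInput(tp, x))
  outIds <- bottomUpGraph(tp, ids, config, "pyr")
  list(levels = lapply(outIds, function(id) tpVal(tp, id)), params = params)
}

#' Recursive pyramid pass
#'
#' Projects a completed set of P-levels back onto the matching backbone
#' levels (1x1 convolution, then addition) and runs a second top-down pass
#' with the same lateral and smoothing weights, yielding refreshed levels of
#' identical shapes. No atrous pooling block is used.
#'
#' @param cLevels Named list of backbone arrays \code{C2..C5}.
#' @param pLevels Named list of arrays \code{P2..P5} from a prior pass.
#' @param config A \code{\link{pyramidConfig}} (kind \code{"rfpn"}).
#' @param params Optional parameters; fresh when \code{NULL}.
#' @param seed Weight seed.
#' @return List with \code{levels} (named arrays \code{P2..P6}) and
#'   \code{params}.
#' @export
recursiveFpn <- function(cLevels, pLevels, config = pyramidConfig("rfpn"),
                         params = NULL, seed = 1L) {
  checkCLevels(cLevels)
  if (is.null(params))
    params <- withSeed(deriveSeed(seed, 43L),
                       makePyramidParams(vapply(cLevels, function(x) dim(x)[3],
                                                numeric(1)), config))
  full <- list()
  for (nm in names(params)) full[[paste0("pyr.", nm)]] <- params[[nm]]
  tp <- tapeNew(full)
  cIds <- lapply(cLevels, function(x) tpInput(tp, x))
  c2 <- list()
  for (k in 2:5) {
    nm <- paste0("C", k)
    back <- tpConv(tp, tpInput(tp, pLevels[[paste0("P", k)]]),
                   paste0("pyr.proj", k), 1L)
    c2[[nm]] <- tpAdd(tp, cIds[[nm]], back)
  }
  p2 <- topDownGraph(tp, c2, config, "pyr", smoothing = "all")
  p2$P6 <- tpPool(tp, p2$P5)
  list(levels = lapply(p2, function(id) tpVal(tp, id)), params = params)
}
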