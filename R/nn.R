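# A compact define-by-run engine for the detector. A "tape" records every
# operation applied to (h, w, c) feature arrays so that one reverse sweep
# yields exact gradients for all parameters. Convolution, pooling and
# upsampling run in C++ (src/kernels.cpp); vector-sized ops stay in R.
# Parameters live in a flat named list: conv -> list(W, b), dense ->
# list(W, b), conv1d -> list(w).

tapeNew <- function(params) {
  e <- new.env(parent = emptyenv())
  e$nodes <- list()
  e$params <- params
  e
}

tpEmit <- function(tp, node) {
  # force the node first: building it may create child nodes on the tape,
  # and the id must be assigned after them
  force(node)
  id <- length(tp$nodes) + 1L
  tp$nodes[[id]] <- node
  id
}

# force id before touching tp$nodes: arguments are often node-creating
# calls that mutate the tape environment
tpVal <- function(tp, id) {
  force(id)
  tp$nodes[[id]]$val
}

tpInput <- function(tp, x) tpEmit(tp, list(op = "input", ins = integer(), val = x))

tpConv <- function(tp, in_, pname, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  p <- tp$params[[pname]]
  if (is.null(p)) stop("no such parameter block: ", pname)
  x <- tpVal(tp, in_)
  r <- cpp_conv2d_fwd(x, p$W, p$b, k, stride, pad)
  val <- r$out
  tpEmit(tp, list(op = "conv", ins = in_, pname = pname, k = k,
                  stride = stride, pad = pad, dimin = dim(x),
                  val = val, cache = r$cols))
}

tpRelu <- function(tp, in_) {
  x <- tpVal(tp, in_)
  tpEmit(tp, list(op = "relu", ins = in_, val = pmax(x, 0)))
}

tpSigmoid <- function(tp, in_) {
  x <- tpVal(tp, in_)
  tpEmit(tp, list(op = "sigmoid", ins = in_, val = 1 / (1 + exp(-x))))
}

tpAdd <- function(tp, a, b) {
  tpEmit(tp, list(op = "add", ins = c(a, b), val = tpVal(tp, a) + tpVal(tp, b)))
}

tpPool <- function(tp, in_) {
  x <- tpVal(tp, in_)
  r <- cpp_maxpool2_fwd(x)
  tpEmit(tp, list(op = "pool", ins = in_, dimin = dim(x), val = r$out,
                  cache = r$idx))
}

tpUp <- function(tp, in_) {
  tpEmit(tp, list(op = "up", ins = in_, val = cpp_upsample2_fwd(tpVal(tp, in_))))
}

tpGap <- function(tp, in_) {
  x <- tpVal(tp, in_)
  d <- dim(x)
  tpEmit(tp, list(op = "gap", ins = in_, dimin = d,
                  val = colMeans(matrix(x, d[1] * d[2], d[3]))))
}

tpGmp <- function(tp, in_) {
  x <- tpVal(tp, in_)
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3])
  idx <- vapply(seq_len(d[3]), function(c) which.max(m[, c]), integer(1))
  tpEmit(tp, list(op = "gmp", ins = in_, dimin = d, cache = idx,
                  val = m[cbind(idx, seq_len(d[3]))]))
}

# same-size 1-D convolution across the channel vector with edge-replicate
# padding (keeps the gate symmetric when every channel is identical)
conv1dSame <- function(x, w) {
  k <- length(w)
  c0 <- (k + 1L) %/% 2L
  n <- length(x)
  z <- numeric(n)
  for (j in seq_len(k)) {
    src <- pmin(pmax(seq_len(n) + j - c0, 1L), n)
    z <- z + w[j] * x[src]
  }
  z
}

tpConv1d <- function(tp, in_, pname) {
  p <- tp$params[[pname]]
  x <- tpVal(tp, in_)
  tpEmit(tp, list(op = "conv1d", ins = in_, pname = pname,
                  val = conv1dSame(x, p$w)))
}

tpDense <- function(tp, in_, pname) {
  p <- tp$params[[pname]]
  x <- tpVal(tp, in_)
  val <- if (is.matrix(x)) sweep(x %*% p$W, 2, p$b, "+")
         else drop(x %*% p$W) + p$b
  tpEmit(tp, list(op = "dense", ins = in_, pname = pname, val = val))
}

# x (h, w, C) scaled per channel by gate vector g (length C)
tpScaleChan <- function(tp, xin, gin) {
  x <- tpVal(tp, xin); g <- tpVal(tp, gin)
  d <- dim(x)
  tpEmit(tp, list(op = "scalechan", ins = c(xin, gin), dimin = d,
                  val = x * array(rep(g, each = d[1] * d[2]), d)))
}

tpChanMean <- function(tp, in_) {
  x <- tpVal(tp, in_)
  d <- dim(x)
  tpEmit(tp, list(op = "chanmean", ins = in_, dimin = d,
                  val = array(rowMeans(matrix(x, d[1] * d[2], d[3])),
                              c(d[1], d[2], 1L))))
}

tpChanMax <- function(tp, in_) {
  x <- tpVal(tp, in_)
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3])
  which <- max.col(m, ties.method = "first")
  tpEmit(tp, list(op = "chanmax", ins = in_, dimin = d, cache = which,
                  val = array(m[cbind(seq_len(nrow(m)), which)],
                              c(d[1], d[2], 1L))))
}

tpConcatC <- function(tp, a, b) {
  xa <- tpVal(tp, a); xb <- tpVal(tp, b)
  da <- dim(xa); db <- dim(xb)
  tpEmit(tp, list(op = "concatc", ins = c(a, b), ca = da[3],
                  val = array(c(xa, xb), c(da[1], da[2], da[3] + db[3]))))
}

# x (h, w, C) scaled per pixel by map s (h, w, 1)
tpScaleSpace <- function(tp, xin, sin) {
  x <- tpVal(tp, xin); s <- tpVal(tp, sin)
  tpEmit(tp, list(op = "scalespace", ins = c(xin, sin), dimin = dim(x),
                  val = x * as.vector(s)))
}

tpRoiAlign <- function(tp, in_, box, outH, outW) {
  x <- tpVal(tp, in_)
  tpEmit(tp, list(op = "roialign", ins = in_, box = box, dimin = dim(x),
                  val = cpp_roi_align(x, box, outH, outW)))
}

tpFlatten <- function(tp, in_) {
  x <- tpVal(tp, in_)
  tpEmit(tp, list(op = "flatten", ins = in_, dimin = dim(x),
                  val = as.numeric(x)))
}

# x / sqrt(mean(x^2) + eps): keeps ROI features at unit scale for the heads
tpRmsNorm <- function(tp, in_) {
  x <- tpVal(tp, in_)
  r <- sqrt(mean(x^2) + 1e-8)
  tpEmit(tp, list(op = "rmsnorm", ins = in_, r = r, val = x / r))
}

# per-channel RMS normalisation (parameter-free): the single-image analogue
# of the normalisation layers detection backbones rely on; keeps every
# channel at unit scale regardless of initialisation
tpChanRmsNorm <- function(tp, in_) {
  x <- tpVal(tp, in_)
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3])
  r <- sqrt(colMeans(m^2) + 1e-8)
  tpEmit(tp, list(op = "chanrms", ins = in_, r = r, dimin = d,
                  val = array(sweep(m, 2, r, "/"), d)))
}

pgAdd <- function(pg, pname, comp, g) {
  if (is.null(pg[[pname]])) pg[[pname]] <- list()
  cur <- pg[[pname]][[comp]]
  pg[[pname]][[comp]] <- if (is.null(cur)) g else cur + g
  pg
}

# seeds: list of list(id = node id, grad = array) — multiple loss heads allowed
tapeBackward <- function(tp, seeds) {
  n <- length(tp$nodes)
  grads <- vector("list", n)
  pg <- list()
  addg <- function(id, g) {
    grads[[id]] <<- if (is.null(grads[[id]])) g else grads[[id]] + g
  }
  for (s in seeds) addg(s$id, s$grad)
  for (id in rev(seq_len(n))) {
    g <- grads[[id]]
    if (is.null(g)) next
    nd <- tp$nodes[[id]]
    switch(nd$op,
      input = NULL,
      conv = {
        if (!is.array(g)) g <- array(g, dim(nd$val))
        r <- cpp_conv2d_bwd(nd$cache, tp$params[[nd$pname]]$W, g,
                            nd$dimin[1], nd$dimin[2], nd$dimin[3],
                            nd$k, nd$stride, nd$pad)
        pg <- pgAdd(pg, nd$pname, "W", r$gW)
        pg <- pgAdd(pg, nd$pname, "b", r$gb)
        addg(nd$ins, r$gx)
      },
      relu = addg(nd$ins, g * (nd$val > 0)),
      sigmoid = addg(nd$ins, g * nd$val * (1 - nd$val)),
      add = { addg(nd$ins[1], g); addg(nd$ins[2], g) },
      pool = addg(nd$ins, cpp_maxpool2_bwd(g, nd$cache,
                                           nd$dimin[1], nd$dimin[2])),
      up = addg(nd$ins, cpp_upsample2_bwd(g)),
      gap = {
        hw <- nd$dimin[1] * nd$dimin[2]
        addg(nd$ins, array(rep(g / hw, each = hw), nd$dimin))
      },
      gmp = {
        gx <- array(0, nd$dimin)
        m <- matrix(gx, nd$dimin[1] * nd$dimin[2], nd$dimin[3])
        m[cbind(nd$cache, seq_len(nd$dimin[3]))] <- g
        addg(nd$ins, array(m, nd$dimin))
      },
      conv1d = {
        w <- tp$params[[nd$pname]]$w
        k <- length(w); c0 <- (k + 1L) %/% 2L
        x <- tpVal(tp, nd$ins)
        nlen <- length(x)
        gx <- numeric(nlen); gw <- numeric(k)
        for (j in seq_len(k)) {
          src <- pmin(pmax(seq_len(nlen) + j - c0, 1L), nlen)
          for (i in seq_len(nlen)) gx[src[i]] <- gx[src[i]] + w[j] * g[i]
          gw[j] <- sum(g * x[src])
        }
        pg <- pgAdd(pg, nd$pname, "w", gw)
        addg(nd$ins, gx)
      },
      dense = {
        p <- tp$params[[nd$pname]]
        x <- tpVal(tp, nd$ins)
        if (is.matrix(x)) {
          if (!is.matrix(g)) g <- matrix(g, nrow(x), ncol(p$W))
          pg <- pgAdd(pg, nd$pname, "W", crossprod(x, g))
          pg <- pgAdd(pg, nd$pname, "b", colSums(g))
          addg(nd$ins, g %*% t(p$W))
        } else {
          pg <- pgAdd(pg, nd$pname, "W", outer(x, as.numeric(g)))
          pg <- pgAdd(pg, nd$pname, "b", as.numeric(g))
          addg(nd$ins, drop(p$W %*% as.numeric(g)))
        }
      },
      scalechan = {
        x <- tpVal(tp, nd$ins[1]); gv <- tpVal(tp, nd$ins[2])
        d <- nd$dimin; hw <- d[1] * d[2]
        addg(nd$ins[1], g * array(rep(gv, each = hw), d))
        addg(nd$ins[2], colSums(matrix(g * x, hw, d[3])))
      },
      chanmean = {
        d <- nd$dimin
        addg(nd$ins, array(rep(as.vector(g) / d[3], d[3]), d))
      },
      chanmax = {
        d <- nd$dimin
        m <- matrix(0, d[1] * d[2], d[3])
        m[cbind(seq_len(nrow(m)), nd$cache)] <- as.vector(g)
        addg(nd$ins, array(m, d))
      },
      concatc = {
        da <- dim(tpVal(tp, nd$ins[1]))
        addg(nd$ins[1], array(g[, , seq_len(nd$ca), drop = FALSE], da))
        rest <- array(g[, , -seq_len(nd$ca), drop = FALSE],
                      dim(tpVal(tp, nd$ins[2])))
        addg(nd$ins[2], rest)
      },
      roialign = {
        if (!is.array(g)) g <- array(g, dim(nd$val))
        addg(nd$ins, cpp_roi_align_bwd(g, nd$box, nd$dimin[1], nd$dimin[2]))
      },
      flatten = addg(nd$ins, array(g, nd$dimin)),
      chanrms = {
        x <- tpVal(tp, nd$ins)
        d <- nd$dimin; hw <- d[1] * d[2]
        gm <- matrix(g, hw, d[3]); xm <- matrix(x, hw, d[3])
        dot <- colSums(gm * xm)
        gx <- sweep(gm, 2, nd$r, "/") -
          sweep(xm, 2, dot / (hw * nd$r^3), "*")
        addg(nd$ins, array(gx, d))
      },
      rmsnorm = {
        x <- tpVal(tp, nd$ins)
        n <- length(x)
        addg(nd$ins, g / nd$r - x * (sum(g * x) / (n * nd$r^3)))
      },
      scalespace = {
        x <- tpVal(tp, nd$ins[1]); s <- tpVal(tp, nd$ins[2])
        d <- nd$dimin
        addg(nd$ins[1], g * as.vector(s))
        addg(nd$ins[2], array(rowSums(matrix(g * x, d[1] * d[2], d[3])),
                              c(d[1], d[2], 1L)))
      },
      stop("unknown op in backward: ", nd$op)
    )
  }
  list(pgrads = pg, grads = grads)
}

# ---- parameter initialisation (He) ---------------------------------------

initConv <- function(cin, cout, k, sd = sqrt(2 / (k * k * cin))) {
  list(W = matrix(rnorm(k * k * cin * cout, 0, sd), k * k * cin, cout),
       b = numeric(cout))
}

initDense <- function(nin, nout, sd = sqrt(2 / nin)) {
  list(W = matrix(rnorm(nin * nout, 0, sd), nin, nout),
       b = numeric(nout))
}

initConv1d <- function(k) list(w = rnorm(k, 0, 0.1))

numParams <- function(params) {
  sum(vapply(params, function(p)
    sum(vapply(p, length, numeric(1))), numeric(1)))
}

# optimiser step: Adam (default; fastest to converge at small step budgets)
# or plain SGD with momentum. State mirrors the parameter structure.
optimUpdate <- function(params, state, pgrads, lr, method = "adam",
                        momentum = 0.9, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  if (method == "sgd") {
    if (is.null(state$velocity)) state$velocity <- list()
    for (pname in names(pgrads)) {
      for (comp in names(pgrads[[pname]])) {
        g <- pgrads[[pname]][[comp]]
        key <- paste0(pname, ".", comp)
        v <- state$velocity[[key]]
        if (is.null(v)) v <- g * 0
        v <- momentum * v + g
        state$velocity[[key]] <- v
        params[[pname]][[comp]] <- params[[pname]][[comp]] - lr * v
      }
    }
    return(list(params = params, state = state))
  }
  if (is.null(state$adam)) state$adam <- list(m = list(), v = list(), t = 0L)
  state$adam$t <- state$adam$t + 1L
  t <- state$adam$t
  for (pname in names(pgrads)) {
    for (comp in names(pgrads[[pname]])) {
      g <- pgrads[[pname]][[comp]]
      key <- paste0(pname, ".", comp)
      m <- state$adam$m[[key]]; v <- state$adam$v[[key]]
      if (is.null(m)) { m <- g * 0; v <- g * 0 }
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      state$adam$m[[key]] <- m
      state$adam$v[[key]] <- v
      mh <- m / (1 - beta1^t)
      vh <- v / (1 - beta2^t)
      params[[pname]][[comp]] <- params[[pname]][[comp]] -
        lr * mh / (sqrt(vh) + eps)
    }
  }
  list(params = params, state = state)
}
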