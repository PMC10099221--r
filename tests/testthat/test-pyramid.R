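cMaker <- function(sizes = c(32, 16, 8, 4), channels = c(4, 8, 16, 32),
                   fill = rnorm) {
  out <- list()
  for (k in 1:4)
    out[[paste0("C", k + 1)]] <- array(fill(sizes[k]^2 * channels[k]),
                                       c(sizes[k], sizes[k], channels[k]))
  out
}

test_that("top-down pyramid has uniform width and halving shapes", {
  set.seed(31)
  cl <- cMaker()
  r <- topDownFpn(cl, pyramidConfig("fpn", width = 8), seed = 1)
  expect_setequal(names(r$levels), paste0("P", 2:6))
  for (k in 2:5) {
    d <- dim(r$levels[[paste0("P", k)]])
    expect_equal(d, c(64 / 2^k * 2, 64 / 2^k * 2, 8))
  }
  expect_equal(dim(r$levels$P6), c(2, 2, 8))
})

test_that("zero backbone features give zero pyramid levels (linearity)", {
  cl <- cMaker(fill = function(n) numeric(n))
  r <- topDownFpn(cl, pyramidConfig("fpn", width = 8), seed = 2)
  for (lv in r$levels) expect_true(all(lv == 0))
  rb <- bottomUpFuse(r$levels[paste0("P", 2:5)],
                     pyramidConfig("bottom_up", width = 8), seed = 3)
  for (lv in rb$levels) expect_true(all(lv == 0))
})

test_that("a pure top-level signal reaches P2 as its triple upsampling", {
  # identical channel counts allow identity laterals; identity smoothing
  # convs turn the top-down pass into pure upsample-and-add
  cl <- cMaker(channels = c(3, 3, 3, 3), fill = function(n) numeric(n))
  set.seed(32)
  cl$C5 <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  idConv1 <- function(C) {
    W <- matrix(0, C, C); diag(W) <- 1
    list(W = W, b = numeric(C))
  }
  idConv3 <- function(C) {
    W <- matrix(0, 9 * C, C)
    for (c in seq_len(C)) W[(c - 1) * 9 + 5, c] <- 1   # centre tap
    list(W = W, b = numeric(C))
  }
  params <- list(lat2 = idConv1(3), lat3 = idConv1(3), lat4 = idConv1(3),
                 lat5 = idConv1(3), smooth2 = idConv3(3), smooth3 = idConv3(3),
                 smooth4 = idConv3(3), smooth5 = idConv3(3))
  r <- topDownFpn(cl, pyramidConfig("fpn", width = 3), params = params)
  up <- grainseg:::cpp_upsample2_fwd
  expect_equal(r$levels$P2, up(up(up(cl$C5))))
  expect_equal(r$levels$P5, cl$C5)
})

test_that("bottom-up fusion: N2 is P2 bit-exactly and shapes are conserved", {
  set.seed(33)
  pl <- list()
  for (k in 2:5)
    pl[[paste0("P", k)]] <- array(rnorm((64 / 2^k * 2)^2 * 8),
                                  c(64 / 2^k * 2, 64 / 2^k * 2, 8))
  r <- bottomUpFuse(pl, pyramidConfig("bottom_up", width = 8), seed = 4)
  expect_identical(r$levels$N2, pl$P2)
  for (k in 2:5)
    expect_equal(dim(r$levels[[paste0("N", k)]]), dim(pl[[paste0("P", k)]]))
  expect_equal(dim(r$levels$N6), c(2, 2, 8))
  expect_error(bottomUpFuse(list(P2 = pl$P2, P3 = pl$P3, P4 = pl$P4,
                                 P5 = array(0, c(4, 4, 4)))), "width")
})

test_that("low-level signal reaches the top prediction level in three fused steps", {
  pl <- list(P2 = array(0, c(32, 32, 2)), P3 = array(0, c(16, 16, 2)),
             P4 = array(0, c(8, 8, 2)), P5 = array(0, c(4, 4, 2)))
  set.seed(34)
  pl$P2 <- array(rnorm(32 * 32 * 2), c(32, 32, 2))
  idConv3 <- function(C) {
    W <- matrix(0, 9 * C, C)
    for (c in seq_len(C)) W[(c - 1) * 9 + 5, c] <- 1
    list(W = W, b = numeric(C))
  }
  params <- list(fuse3 = idConv3(2), fuse4 = idConv3(2), fuse5 = idConv3(2))
  r <- bottomUpFuse(pl, pyramidConfig("bottom_up", width = 2), params = params)
  pool <- function(x) grainseg:::cpp_maxpool2_fwd(x)$out
  expect_equal(r$levels$N5, pool(pool(pool(pl$P2))))
})

test_that("recursive pass with zero P-levels equals a plain second pass", {
  set.seed(35)
  cl <- cMaker(channels = c(4, 4, 4, 4))
  cfgR <- pyramidConfig("rfpn", width = 4)
  params <- grainseg:::withSeed(99, grainseg:::makePyramidParams(
    c(4, 4, 4, 4), cfgR))
  zeroP <- list(P2 = array(0, c(32, 32, 4)), P3 = array(0, c(16, 16, 4)),
                P4 = array(0, c(8, 8, 4)), P5 = array(0, c(4, 4, 4)))
  r1 <- recursiveFpn(cl, zeroP, cfgR, params = params)
  plain <- topDownFpn(cl, pyramidConfig("fpn", width = 4),
                      params = params[!grepl("^proj", names(params))])
  for (lv in names(plain$levels))
    expect_equal(r1$levels[[lv]], plain$levels[[lv]], tolerance = 1e-12)
  # shape preservation under recursion with non-zero P-levels
  r2 <- recursiveFpn(cl, plain$levels[paste0("P", 2:5)], cfgR, params = params)
  for (lv in names(plain$levels))
    expect_equal(dim(r2$levels[[lv]]), dim(plain$levels[[lv]]))
})

test_that("recursive pass matches a hand-composed scalar trace", {
  # one channel, centre-tap-only convs with known scalar weights: every
  # operation reduces to scalar multiply-add that we can compose by hand
  sizes <- c(16, 8, 4, 2)
  cl <- list()
  vals <- c(2, 3, 5, 7)
  for (k in 1:4)
    cl[[paste0("C", k + 1)]] <- array(vals[k], c(sizes[k], sizes[k], 1))
  sc1 <- function(w) list(W = matrix(w, 1, 1), b = 0)
  sc3 <- function(w) { W <- matrix(0, 9, 1); W[5, 1] <- w; list(W = W, b = 0) }
  params <- list(lat2 = sc1(1), lat3 = sc1(1), lat4 = sc1(1), lat5 = sc1(1),
                 smooth2 = sc3(2), smooth3 = sc3(2), smooth4 = sc3(2),
                 smooth5 = sc3(2),
                 proj2 = sc1(0.5), proj3 = sc1(0.5), proj4 = sc1(0.5),
                 proj5 = sc1(0.5))
  # first pass raw values (constant fields, so upsampling preserves them,
  # but 3x3 centre-tap convs act per pixel; border effects vanish because
  # only the centre tap is non-zero)
  raw5 <- 7; raw4 <- 5 + raw5; raw3 <- 3 + raw4; raw2 <- 2 + raw3
  p1 <- c(P2 = 2 * raw2, P3 = 2 * raw3, P4 = 2 * raw4, P5 = 2 * raw5)
  pl <- list()
  for (k in 2:5)
    pl[[paste0("P", k)]] <- array(p1[[paste0("P", k)]],
                                  c(sizes[k - 1], sizes[k - 1], 1))
  r <- recursiveFpn(cl, pl, pyramidConfig("rfpn", width = 1), params = params)
  c2 <- vals + 0.5 * p1          # C'_k = C_k + 0.5 * P_k
  raw5b <- c2[4]; raw4b <- c2[3] + raw5b; raw3b <- c2[2] + raw4b
  raw2b <- c2[1] + raw3b
  expect_equal(r$levels$P5[1, 1, 1], unname(2 * raw5b))
  expect_equal(r$levels$P2[4, 4, 1], unname(2 * raw2b))
})

test_that("bottom-up path adds exactly two 3x3 convolutions of parameters", {
  W <- 8
  pf <- grainseg:::withSeed(1, grainseg:::makePyramidParams(
    c(4, 8, 16, 32), pyramidConfig("fpn", width = W)))
  pb <- grainseg:::withSeed(1, grainseg:::makePyramidParams(
    c(4, 8, 16, 32), pyramidConfig("bottom_up", width = W)))
  nP <- function(p) sum(vapply(p, function(b) length(b$W) + length(b$b),
                               numeric(1)))
  expect_equal(nP(pb) - nP(pf), 2 * (9 * W * W + W))
})

test_that("mismatched spatial ratios are rejected", {
  cl <- cMaker()
  cl$C3 <- array(0, c(20, 20, 8))
  expect_error(topDownFpn(cl, pyramidConfig("fpn", width = 8)), "halve")
})
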