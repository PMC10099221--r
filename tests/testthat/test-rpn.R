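test_that("anchor geometry: area a^2 with height/width ratio r", {
  d1 <- grainseg:::anchorDims(8, 1)
  expect_equal(unname(d1), c(8, 8))
  d2 <- grainseg:::anchorDims(8, 2)
  expect_equal(unname(d2["w"]), 8 / sqrt(2))
  expect_equal(unname(d2["h"]), 8 * sqrt(2))
  expect_equal(unname(d2["w"] * d2["h"]), 64)
})

test_that("anchor counts follow h*w*scales*ratios exactly per level", {
  cfg <- anchorConfig(scales = 8, ratios = c(0.5, 1, 2),
                      levelAssignment = list(`2` = 8))
  a <- generateAnchors(list(`2` = c(4, 4)), cfg)
  expect_equal(nrow(a$boxes), 48)
  full <- generateAnchors(list(`2` = c(64, 64), `3` = c(32, 32),
                               `4` = c(16, 16), `5` = c(8, 8),
                               `6` = c(4, 4)), anchorConfig())
  want <- 64 * 64 * 2 * 3 + 32 * 32 * 3 + 16 * 16 * 3 + 8 * 8 * 3 + 4 * 4 * 3
  expect_equal(nrow(full$boxes), want)
  for (lv in names(full$perLevel)) {
    info <- full$perLevel[[lv]]
    expect_equal(length(info$rows),
                 prod(info$dims) * info$anchorsPerCell)
  }
  # anchors are centred on cell centres in input coordinates
  first <- full$boxes[full$perLevel[["3"]]$rows[1], ]
  expect_equal((first[1] + first[3]) / 2, 0.5 * 8)  # stride 8, first cell
})

test_that("anchor config validation", {
  expect_error(anchorConfig(levelAssignment = list()), "empty")
  expect_error(anchorConfig(scales = c(8, 16),
                            levelAssignment = list(`2` = 8)), "exactly one")
})

test_that("box IoU matches closed forms and a pixel-count oracle", {
  expect_equal(drop(boxIou(c(0, 0, 10, 10), c(0, 0, 10, 10))), 1)
  expect_equal(drop(boxIou(c(0, 0, 10, 10), c(20, 20, 30, 30))), 0)
  expect_equal(drop(boxIou(c(0, 0, 10, 10), c(5, 0, 15, 10))), 1 / 3)
  expect_warning(v <- boxIou(c(0, 0, 0, 10), c(0, 0, 10, 10)))
  expect_equal(drop(v), 0)
  # 1,000 random integer box pairs against brute-force rasterized counting
  set.seed(77)
  for (i in 1:1000) {
    a <- sort(sample(0:40, 2)); b <- sort(sample(0:40, 2))
    c1 <- c(a[1], b[1], a[2] + 1, b[2] + 1)
    a <- sort(sample(0:40, 2)); b <- sort(sample(0:40, 2))
    c2 <- c(a[1], b[1], a[2] + 1, b[2] + 1)
    expect_equal(drop(boxIou(c1, c2)), pixelCountIou(c1, c2), tolerance = 1e-6)
  }
})

test_that("NMS matches its worked examples", {
  boxes <- rbind(c(0, 0, 10, 10), c(1, 1, 11, 11), c(20, 20, 30, 30))
  keep <- nmsKeep(boxes, c(0.9, 0.8, 0.7), 0.5)
  expect_equal(sort(keep), c(1, 3))
  expect_equal(nmsKeep(matrix(c(0, 0, 5, 5), 1), 0.3, 0.5), 1L)
  two <- rbind(c(0, 0, 5, 5), c(10, 10, 15, 15))
  expect_equal(sort(nmsKeep(two, c(0.2, 0.9), 0.01)), c(1, 2))
  expect_equal(nmsKeep(matrix(numeric(), 0, 4), numeric(), 0.5), integer())
})

test_that("NMS equals the brute-force reference on 1,000 random instances", {
  set.seed(88)
  for (i in 1:1000) {
    n <- sample(1:50, 1)
    cx <- runif(n, 0, 60); cy <- runif(n, 0, 60)
    wd <- runif(n, 2, 20); ht <- runif(n, 2, 20)
    boxes <- cbind(cx - wd / 2, cy - ht / 2, cx + wd / 2, cy + ht / 2)
    scores <- runif(n)
    thr <- runif(1, 0.2, 0.8)
    expect_identical(nmsKeep(boxes, scores, thr), bruteNms(boxes, scores, thr))
  }
})

test_that("lowering the NMS threshold never increases the kept count", {
  set.seed(89)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    cx <- runif(n, 0, 50); cy <- runif(n, 0, 50)
    boxes <- cbind(cx - 6, cy - 6, cx + 6, cy + 6)
    scores <- runif(n)
    thrs <- sort(runif(4))
    counts <- vapply(thrs, function(t) length(nmsKeep(boxes, scores, t)),
                     numeric(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("foreground/background assignment follows the 0.7/0.3 rule", {
  gt <- matrix(c(0, 0, 10, 10), 1)
  anchors <- rbind(
    c(0, 0, 10, 7.5),    # IoU 0.75 -> foreground
    c(0, 0, 10, 2),      # IoU 0.20 -> background
    c(0, 0, 10, 5),      # IoU 0.50 -> in-between, discarded
    c(0, 0, 10, 9.5))    # IoU 0.95 -> foreground (absorbs the rescue rule)
  asg <- assignFgBg(anchors, gt)
  expect_equal(asg$labels, c(1L, 0L, -1L, 1L))
  # rescue: when no anchor clears 0.7 the best one still becomes foreground
  asg2 <- assignFgBg(rbind(c(0, 0, 10, 5), c(0, 0, 10, 2)), gt)
  expect_equal(asg2$labels[1], 1L)
  # no ground truth: everything is background
  asg3 <- assignFgBg(anchors, matrix(numeric(), 0, 4))
  expect_true(all(asg3$labels == 0L))
})

test_that("assignment labels partition all anchors", {
  set.seed(90)
  for (i in 1:20) {
    n <- 200
    cx <- runif(n, 0, 100); cy <- runif(n, 0, 100)
    anchors <- cbind(cx - 8, cy - 8, cx + 8, cy + 8)
    gt <- cbind(c(20, 60), c(20, 60), c(40, 80), c(40, 80))
    asg <- assignFgBg(anchors, gt)
    expect_equal(length(asg$labels), n)
    expect_true(all(asg$labels %in% c(-1L, 0L, 1L)))
    # every ground truth has at least one foreground anchor (rescue)
    expect_true(all(table(asg$gtIndex[asg$labels == 1L]) >= 1))
  }
})

test_that("delta decoding: identity at zero, exact width doubling at log 2", {
  anchors <- rbind(c(10, 10, 20, 30), c(0, 0, 8, 8))
  expect_equal(decodeDeltas(anchors, matrix(0, 2, 4)), anchors)
  d <- matrix(0, 2, 4); d[1, 3] <- log(2)
  out <- decodeDeltas(anchors, d)
  expect_equal(out[1, 3] - out[1, 1], 20)
  expect_equal(out[1, 4] - out[1, 2], 20)
  # encode/decode round-trip
  set.seed(91)
  gt <- rbind(c(12, 8, 25, 33), c(1, 2, 6, 9))
  expect_equal(decodeDeltas(anchors, grainseg:::encodeDeltas(anchors, gt)), gt)
})

test_that("proposal decoding recovers anchors at zero deltas and honours top-k", {
  cfg <- anchorConfig(scales = 16, ratios = 1, levelAssignment = list(`3` = 16))
  anchors <- generateAnchors(list(`3` = c(4, 4)), cfg)
  objMap <- array(seq(0.1, 1.6, length.out = 16), c(4, 4, 1))
  delMap <- array(0, c(4, 4, 4))
  prop <- proposeRegions(list(`3` = objMap), list(`3` = delMap), anchors,
                         assignmentConfig(nmsIou = 0.2, postNmsTopk = 100L),
                         imageSize = c(64, 64))
  # zero deltas: every surviving box is a clipped anchor
  raw <- anchors$boxes
  raw[, c(1, 3)] <- pmin(pmax(raw[, c(1, 3)], 0), 64)
  raw[, c(2, 4)] <- pmin(pmax(raw[, c(2, 4)], 0), 64)
  for (i in seq_len(nrow(prop$boxes)))
    expect_true(any(apply(raw, 1, function(r)
      all(abs(r - prop$boxes[i, ]) < 1e-9))))
  expect_true(!is.unsorted(rev(prop$scores)))
  one <- proposeRegions(list(`3` = objMap), list(`3` = delMap), anchors,
                        assignmentConfig(postNmsTopk = 1L),
                        imageSize = c(64, 64))
  expect_equal(nrow(one$boxes), 1)
  expect_equal(one$scores, max(1 / (1 + exp(-objMap))))
  expect_error(proposeRegions(list(`3` = objMap),
                              list(`3` = array(0, c(4, 4, 8))), anchors,
                              assignmentConfig(), c(64, 64)), "shape")
})

test_that("assignment config validates its thresholds", {
  expect_error(assignmentConfig(fgIou = 0.3, bgIou = 0.7))
  expect_error(assignmentConfig(nmsIou = 0))
})
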