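test_that("precision and recall reproduce their closed forms", {
  expect_equal(precisionScore(confusionCounts(TP = 86, FP = 14)), 0.86)
  expect_equal(recallScore(confusionCounts(TP = 91, FN = 9)), 0.91)
  expect_warning(p0 <- precisionScore(confusionCounts()), "precision")
  expect_equal(p0, 0)
  expect_equal(recallScore(confusionCounts(TP = 0, FN = 5)), 0)
  expect_warning(r0 <- recallScore(confusionCounts()), "recall")
  expect_equal(r0, 0)
  expect_error(confusionCounts(TP = -1), "non-negative")
})

test_that("mask IoU counts pixels", {
  a <- matrix(FALSE, 20, 20); a[1:10, 1:10] <- TRUE      # 100 px
  b <- matrix(FALSE, 20, 20); b[1:10, 1:5] <- TRUE       # 50 px subset
  expect_equal(maskIou(a, a), 1)
  expect_equal(maskIou(a, b), 0.5)
  d <- matrix(FALSE, 20, 20); d[15:20, 15:20] <- TRUE
  expect_equal(maskIou(a, d), 0)
  expect_warning(z <- maskIou(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)))
  expect_equal(z, 0)
  expect_error(maskIou(a, matrix(FALSE, 5, 5)), "dimensions")
})

boxPred <- function(boxes, labels, scores, size = c(40, 40)) {
  masks <- lapply(seq_len(NROW(boxes)), function(i) {
    m <- matrix(FALSE, size[1], size[2])
    b <- round(boxes[i, ])
    m[(b[2] + 1):b[4], (b[1] + 1):b[3]] <- TRUE
    m
  })
  list(boxes = boxes, labels = as.integer(labels), scores = scores,
       masks = masks)
}

boxGt <- function(boxes, labels, size = c(40, 40)) {
  lapply(seq_len(NROW(boxes)), function(i) {
    m <- matrix(FALSE, size[1], size[2])
    b <- round(boxes[i, ])
    m[(b[2] + 1):b[4], (b[1] + 1):b[3]] <- TRUE
    structure(list(categoryId = as.integer(labels[i]), bbox = boxes[i, ],
                   mask = m, area = sum(m)), class = "instanceAnnotation")
  })
}

test_that("matching handles the canonical cases", {
  gt <- boxGt(matrix(c(5, 5, 15, 15), 1), 3)
  exact <- boxPred(matrix(c(5, 5, 15, 15), 1), 3, 0.9)
  m <- matchDetections(exact, gt)
  expect_equal(sum(m$tp), 1)
  expect_equal(sum(attr(m, "fnPerClass")), 0)
  # two predictions on one ground truth: one TP, one FP
  dup <- boxPred(rbind(c(5, 5, 15, 15), c(6, 6, 16, 16)), c(3, 3),
                 c(0.9, 0.8))
  m2 <- matchDetections(dup, gt)
  expect_equal(sum(m2$tp), 1)
  expect_equal(sum(!m2$tp), 1)
  expect_true(m2$tp[1])                 # higher score matched first
  # class mismatch on perfect overlap: FP plus FN
  wrong <- boxPred(matrix(c(5, 5, 15, 15), 1), 2, 0.9)
  m3 <- matchDetections(wrong, gt)
  expect_equal(sum(m3$tp), 0)
  expect_equal(sum(attr(m3, "fnPerClass")), 1)
})

test_that("matching agrees with an independent reference on random instances", {
  set.seed(55)
  for (rep in 1:200) {
    nP <- sample(0:5, 1); nG <- sample(1:5, 1)
    mk <- function(n) {
      cx <- runif(n, 8, 32); cy <- runif(n, 8, 32)
      cbind(cx - 5, cy - 5, cx + 5, cy + 5)
    }
    pb <- mk(nP); gb <- mk(nG)
    pc <- sample(1:3, nP, replace = TRUE); gc <- sample(1:3, nG, replace = TRUE)
    sc <- runif(nP)
    got <- matchDetections(list(boxes = pb, labels = pc, scores = sc,
                                masks = vector("list", nP)),
                           boxGt(gb, gc),
                           matchSpec(kind = "box"))
    ref <- bruteMatch(pb, pc, sc, gb, gc, 0.5)
    expect_equal(sum(got$tp), sum(ref$tp))
    expect_equal(sum(attr(got, "fnPerClass")), ref$fn)
  }
})

test_that("average precision reproduces worked examples and the sweep oracle", {
  expect_equal(averagePrecision(0.9, TRUE, 1), 1)
  # two detections (TP at 0.9, FP at 0.8) against 2 ground truths -> 0.5
  expect_equal(averagePrecision(c(0.9, 0.8), c(TRUE, FALSE), 2), 0.5)
  expect_equal(sweepAp(c(0.9, 0.8), c(TRUE, FALSE), 2), 0.5)
  set.seed(56)
  for (rep in 1:100) {
    n <- sample(1:12, 1)
    scores <- round(runif(n), 3)
    isTp <- runif(n) > 0.4
    nGt <- sum(isTp) + sample(0:3, 1)
    if (nGt == 0) next
    expect_equal(averagePrecision(scores, isTp, nGt),
                 sweepAp(scores, isTp, nGt), tolerance = 1e-12)
  }
  expect_warning(na <- averagePrecision(0.5, TRUE, 0))
  expect_true(is.na(na))
})

test_that("AP never increases when a confident false positive is inserted", {
  set.seed(57)
  for (rep in 1:50) {
    n <- sample(2:10, 1)
    scores <- runif(n); isTp <- runif(n) > 0.3
    nGt <- max(1, sum(isTp))
    base <- averagePrecision(scores, isTp, nGt)
    worse <- averagePrecision(c(scores, max(scores) + 0.1), c(isTp, FALSE),
                              nGt)
    expect_lte(worse, base + 1e-12)
  }
})

test_that("mAP is the exact arithmetic mean of per-class APs", {
  aps <- c(0.60, 0.99, 0.82, 0.89, 0.89, 0.98)
  expect_equal(meanAveragePrecision(aps), mean(aps), tolerance = 1e-12)
  expect_equal(round(meanAveragePrecision(aps), 2), 0.86)
  expect_equal(averageRecall(c(0.5, 0.7, NA)), 0.6)
  expect_equal(meanIou(c(0.2, 0.4)), 0.3)
})

test_that("evaluateDetections on perfect predictions scores 1 everywhere", {
  sc <- tinyScene(4, seed = 30)
  perfect <- list(
    boxes = do.call(rbind, lapply(sc$annotations, `[[`, "bbox")),
    labels = vapply(sc$annotations, `[[`, integer(1), "categoryId"),
    scores = rep(0.99, length(sc$annotations)),
    masks = lapply(sc$annotations, `[[`, "mask"))
  rep1 <- suppressWarnings(evaluateDetections(list(perfect),
                                              list(sc$annotations)))
  expect_equal(rep1@precision, 1)
  expect_equal(rep1@recall, 1)
  expect_equal(rep1@mAP, 1)
  expect_equal(rep1@mIoU, 1)
  rep2 <- suppressWarnings(evaluateDetections(list(perfect),
                                              list(sc$annotations)))
  expect_identical(grainseg:::reportAsList(rep1),
                   grainseg:::reportAsList(rep2))
})
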