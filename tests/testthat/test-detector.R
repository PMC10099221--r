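test_that("the four variants build and their parameter audit is exact", {
  counts <- vapply(c("baseline", "am", "fpn", "am_fpn"), function(v)
    countParameters(buildModel(tinyModelConfig(v))), numeric(1))
  # the bottom-up path and the attention stage both add parameters
  expect_true(counts[["baseline"]] < counts[["am"]])
  expect_true(counts[["baseline"]] < counts[["fpn"]])
  expect_true(counts[["fpn"]] < counts[["am_fpn"]])
  expect_true(counts[["am"]] < counts[["am_fpn"]])
  # am_fpn minus fpn equals exactly what attachAttention alone adds
  mf <- buildModel(tinyModelConfig("fpn"))
  expect_equal(counts[["am_fpn"]] - counts[["fpn"]],
               countParameters(attachAttention(mf, "eca")) -
                 countParameters(mf))
})

test_that("countParameters: empty model, closed-form conv, forward invariance", {
  expect_equal(countParameters(list()), 0L)
  p <- grainseg:::withSeed(1, grainseg:::initConv(256, 256, 3))
  expect_equal(countParameters(list(conv = p)), 3 * 3 * 256 * 256 + 256)
  m <- buildModel(tinyModelConfig("baseline"))
  before <- countParameters(m)
  invisible(predictKernels(m, array(0.5, c(128, 128, 3))))
  expect_identical(countParameters(m), before)
})

test_that("forward prediction is shape-consistent on a blank image", {
  m <- buildModel(tinyModelConfig("baseline"))
  d <- predictKernels(m, array(0.5, c(128, 128, 3)))
  expect_s4_class(d, "DetectionResult")
  expect_equal(length(d@labels), nrow(d@boxes))
  expect_equal(length(d@scores), nrow(d@boxes))
  expect_equal(length(d@masks), nrow(d@boxes))
  if (nrow(d@boxes)) {
    expect_true(all(d@scores >= 0.3))
    expect_true(all(d@labels %in% 1:6))
    for (msk in d@masks) expect_equal(dim(msk), c(128L, 128L))
  }
})

test_that("prediction validates inputs and the confidence bound", {
  m <- buildModel(tinyModelConfig("baseline"))
  expect_error(predictKernels(m, matrix(0, 64, 64)), "RGB")
  expect_error(predictKernels(m, array(0, c(100, 100, 3))), "64")
  d <- predictKernels(m, array(0.5, c(128, 128, 3)), confidence = 1.01)
  expect_equal(nrow(d@boxes), 0)
})

test_that("evaluation-mode prediction is bit-deterministic", {
  sc <- renderScene(randomSceneSpec(3, c(128, 128), seed = 61,
                                    axisRange = c(10, 14)))
  m <- buildModel(tinyModelConfig("am_fpn"))
  d1 <- predictKernels(m, sc$image)
  d2 <- predictKernels(m, sc$image)
  expect_identical(d1@boxes, d2@boxes)
  expect_identical(d1@scores, d2@scores)
  expect_identical(d1@masks, d2@masks)
})

test_that("lowering the confidence never reduces the detection count", {
  sc <- renderScene(randomSceneSpec(4, c(128, 128), seed = 62,
                                    axisRange = c(10, 14)))
  m <- buildModel(tinyModelConfig("am_fpn"))
  st <- trainStep(m, list(sc))            # move off the symmetric init
  counts <- vapply(c(0.9, 0.5, 0.3, 0.1, 0.01), function(cf)
    nrow(predictKernels(st$model, sc$image, confidence = cf)@boxes),
    numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("initial losses are finite for all four variants", {
  sc <- renderScene(randomSceneSpec(3, c(128, 128), seed = 63,
                                    axisRange = c(10, 14)))
  for (v in c("baseline", "am", "fpn", "am_fpn")) {
    m <- buildModel(tinyModelConfig(v, inputSize = c(128L, 128L)))
    st <- trainStep(m, list(sc))
    expect_true(all(is.finite(st$losses)))
    expect_true(all(st$losses >= 0))
  }
})

test_that("images without annotations contribute RPN losses only", {
  empty <- renderScene(sceneSpec(c(128, 128), seed = 2))
  m <- buildModel(tinyModelConfig("am_fpn", inputSize = c(128L, 128L)))
  st <- trainStep(m, list(empty))
  expect_equal(unname(st$losses[["box_cls"]]), 0)
  expect_equal(unname(st$losses[["box_reg"]]), 0)
  expect_equal(unname(st$losses[["mask"]]), 0)
  expect_true(is.finite(st$losses[["rpn_cls"]]))
})

test_that("a repeated single-scene batch is overfit within 50 steps", {
  sc <- renderScene(randomSceneSpec(3, c(128, 128), seed = 64,
                                    axisRange = c(10, 14)))
  m <- buildModel(tinyModelConfig("am_fpn", inputSize = c(128L, 128L),
                                  batch = 1L))
  first <- NULL
  for (i in 1:50) {
    st <- trainStep(m, list(sc))
    m <- st$model
    if (i == 1) first <- st$losses[["total"]]
  }
  expect_lt(st$losses[["total"]], first)
})

test_that("training is reproducible given the model seed and scenes", {
  sc <- makeScenes(2, c(128, 128), c(2, 3), 0.1, seed = 65)
  f1 <- trainModel(buildModel(tinyModelConfig("baseline",
                                              inputSize = c(128L, 128L))),
                   sc, 3)
  f2 <- trainModel(buildModel(tinyModelConfig("baseline",
                                              inputSize = c(128L, 128L))),
                   sc, 3)
  expect_equal(f1$log$total, f2$log$total, tolerance = 1e-12)
})
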