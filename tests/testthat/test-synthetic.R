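test_that("rendering is deterministic and masks are disjoint visible regions", {
  sp <- randomSceneSpec(4, c(128, 128), adhesionLevel = 0.2, seed = 3,
                        axisRange = c(10, 14))
  s1 <- renderScene(sp)
  s2 <- renderScene(sp)
  expect_identical(s1, s2)
  expect_gt(length(s1$annotations), 0)
  ms <- lapply(s1$annotations, `[[`, "mask")
  if (length(ms) > 1)
    for (i in seq_len(length(ms) - 1))
      for (j in seq(i + 1, length(ms)))
        expect_equal(sum(ms[[i]] & ms[[j]]), 0)
  for (ann in s1$annotations) {
    expect_equal(ann$area, sum(ann$mask))
    expect_equal(ann$bbox, maskBboxOf(ann$mask))
  }
})

test_that("a single unoccluded kernel's mask equals the rasterized ellipse", {
  inst <- kernelInstance("perfect", center = c(40, 35), axes = c(14, 9),
                         rotation = 0.4, zOrder = 1L)
  sc <- renderScene(sceneSpec(c(80, 80), list(inst), 0, seed = 5))
  expect_length(sc$annotations, 1)
  expect_equal(sc$annotations[[1]]$area,
               ellipseArea(c(40, 35), c(14, 9), 0.4, 80, 80))
})

test_that("total occlusion drops the hidden instance", {
  a <- kernelInstance("perfect", c(40, 40), c(12, 8), 0, zOrder = 1L)
  b <- kernelInstance("moldy", c(40, 40), c(12, 8), 0, zOrder = 2L)
  sc <- renderScene(sceneSpec(c(80, 80), list(a, b), 1, seed = 1))
  expect_length(sc$annotations, 1)
  expect_equal(sc$annotations[[1]]$categoryId, 2L)
})

test_that("partial occlusion yields disjoint masks whose union covers both footprints", {
  a <- kernelInstance("perfect", c(35, 40), c(12, 8), 0, zOrder = 1L)
  b <- kernelInstance("injured", c(50, 40), c(12, 8), 0, zOrder = 2L)
  sc <- renderScene(sceneSpec(c(80, 80), list(a, b), 1, seed = 2))
  expect_length(sc$annotations, 2)
  m1 <- sc$annotations[[1]]$mask; m2 <- sc$annotations[[2]]$mask
  expect_equal(sum(m1 & m2), 0)
  # union equals the union of the two independently rasterized footprints
  footA <- outer(seq_len(80) - 0.5 - 40, seq_len(80) - 0.5 - 35,
                 function(dy, dx) (dx / 12)^2 + (dy / 8)^2 <= 1)
  footB <- outer(seq_len(80) - 0.5 - 40, seq_len(80) - 0.5 - 50,
                 function(dy, dx) (dx / 12)^2 + (dy / 8)^2 <= 1)
  expect_identical(m1 | m2, footA | footB)
  # occluder (higher z) keeps its full footprint
  expect_identical(m2, footB)
})

test_that("renderScene validates image size and empty scenes", {
  expect_error(renderScene(sceneSpec(c(32, 32))), "64x64")
  sc <- renderScene(sceneSpec(c(64, 64)))
  expect_length(sc$annotations, 0)
  expect_equal(dim(sc$image), c(64, 64, 3))
})

test_that("photometric augmentations keep annotations bit-identical", {
  sc <- tinyScene(3, seed = 9)
  for (m in c("brightness", "noise", "points")) {
    out <- augmentScene(sc$image, sc$annotations, m, seed = 4)
    expect_identical(out$annotations, sc$annotations)
    expect_false(identical(out$image, sc$image))
  }
})

test_that("horizontal flip is an involution on image and annotations", {
  sc <- tinyScene(3, seed = 10)
  once <- augmentScene(sc$image, sc$annotations, "flip")
  twice <- augmentScene(once$image, once$annotations, "flip")
  expect_identical(twice$image, sc$image)
  expect_equal(twice$annotations, sc$annotations, tolerance = 1e-12)
  # flipped boxes are the tight boxes of the flipped masks
  for (ann in once$annotations)
    expect_equal(ann$bbox, maskBboxOf(ann$mask))
})

test_that("translation shifts boxes consistently with shifted masks", {
  sc <- tinyScene(3, seed = 11)
  out <- augmentScene(sc$image, sc$annotations, "translate", seed = 21)
  for (ann in out$annotations)
    expect_equal(ann$bbox, maskBboxOf(ann$mask))
  # interior instances shift rigidly; recover the offset from one of them
  if (length(out$annotations) && length(sc$annotations)) {
    d1 <- out$annotations[[1]]$bbox - sc$annotations[[1]]$bbox
    if (all(abs(d1[1:2] - d1[3:4]) < 1e-9))
      expect_equal(out$annotations[[1]]$area, sc$annotations[[1]]$area)
  }
})

test_that("unknown augmentation method is rejected by name", {
  sc <- tinyScene(1, seed = 12)
  expect_error(augmentScene(sc$image, sc$annotations, "rotate"), "rotate")
})

test_that("default dataset recipe reproduces the 780-image 8:1:1 design", {
  m <- buildDataset(5, 100, seed = 1, imageSize = c(96, 96),
                    kernelsPerScene = c(3, 4), axisRange = c(8, 12))
  tb <- table(splitTable(m)$split)
  expect_equal(length(m), 780L)
  expect_equal(unname(tb[c("train", "val", "test")]), c(624L, 78L, 78L),
               ignore_attr = TRUE)
  rec <- splitTable(m)
  mix <- rec[rec$composition == "mixture", ]
  expect_equal(sum(mix$split == "train"), 480L)
  expect_equal(sum(mix$split == "val"), 60L)
  for (cls in kernelCategories()$name) {
    sub <- rec[rec$composition == cls, ]
    expect_equal(unname(table(sub$split)[c("train", "val", "test")]),
                 c(24L, 3L, 3L), ignore_attr = TRUE)
  }
  # every base image appears with all six versions
  expect_true(all(table(rec$baseIndex) == 6L))
  expect_setequal(unique(rec$provenance),
                  c("original", "brightness", "noise", "points",
                    "translate", "flip"))
})

test_that("dataset size follows the generation arithmetic for other recipes", {
  m <- buildDataset(1, 0, seed = 2, imageSize = c(96, 96),
                    kernelsPerScene = c(2, 2), axisRange = c(8, 12))
  expect_equal(length(m), 36L)
  m2 <- buildDataset(2, 3, seed = 3, imageSize = c(96, 96),
                     kernelsPerScene = c(2, 2), axisRange = c(8, 12))
  expect_equal(length(m2), 6 * 6 * 2 + 6 * 3)
  # split sizes sum to the manifest size; per-stratum ratio within 1 of 8:1:1
  rec <- splitTable(m2)
  expect_equal(sum(table(rec$split)), nrow(rec))
  for (cp in unique(rec$composition)) {
    sub <- rec[rec$composition == cp, ]
    n <- nrow(sub)
    expect_lte(abs(sum(sub$split == "train") - 0.8 * n), 1)
  }
})

test_that("manifests and their rendered records are reproducible", {
  m1 <- buildDataset(1, 1, seed = 7, imageSize = c(96, 96),
                     kernelsPerScene = c(2, 2), axisRange = c(8, 12))
  m2 <- buildDataset(1, 1, seed = 7, imageSize = c(96, 96),
                     kernelsPerScene = c(2, 2), axisRange = c(8, 12))
  expect_identical(splitTable(m1), splitTable(m2))
  expect_identical(renderRecord(m1, 5), renderRecord(m2, 5))
})
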