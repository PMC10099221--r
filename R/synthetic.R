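# Synthetic kernel scenes: seeded rendering of dense, partially adherent
# wheat kernels with visible-region instance masks, the five augmentations,
# and stratified dataset assembly.

# Per-category paint. Base hues are deliberately well separated so that the
# six classes remain learnable by a small model; motifs echo how the real
# damage types look (gray mold patches, dark embryo-end blotch, bored holes,
# a sprout bump at one pole, a truncated broken outline).
categoryPaint <- function(id) {
  base <- list(
    c(0.85, 0.72, 0.45),  # perfect: warm tan
    c(0.55, 0.57, 0.50),  # moldy: gray-green
    c(0.62, 0.45, 0.30),  # injured: brown
    c(0.45, 0.32, 0.22),  # spotted: dark brown
    c(0.72, 0.78, 0.45),  # sprouted: green-yellow
    c(0.93, 0.88, 0.72))  # broken: pale
  base[[id]]
}

# local ellipse coordinates of every pixel centre; x = col - 0.5, y = row - 0.5
localCoords <- function(h, w, center, rotation) {
  xs <- seq_len(w) - 0.5 - center[1]
  ys <- seq_len(h) - 0.5 - center[2]
  dx <- matrix(xs, h, w, byrow = TRUE)
  dy <- matrix(ys, h, w)
  ct <- cos(rotation); st <- sin(rotation)
  list(u = dx * ct + dy * st, v = -dx * st + dy * ct)
}

# footprint of one instance (pixel-center-inside rule) plus appearance fields
instanceFootprint <- function(inst, h, w, app) {
  lc <- localCoords(h, w, inst$center, inst$rotation)
  a <- inst$axes[1]; b <- inst$axes[2]
  rr <- (lc$u / a)^2 + (lc$v / b)^2
  foot <- rr <= 1
  if (inst$category == 6L) {                       # broken: truncated outline
    foot <- foot & (lc$u <= app$cutFrac * a)
  } else if (inst$category == 5L) {                # sprouted: bump at one pole
    db <- (lc$u - 0.95 * a)^2 + lc$v^2
    foot <- foot | (db <= (0.35 * b)^2)
  }
  list(foot = foot, u = lc$u, v = lc$v, rr = rr)
}

# appearance parameters are drawn once per instance from the scene RNG stream
drawAppearance <- function(inst) {
  switch(inst$category,
    list(),                                                        # perfect
    list(patch = matrix(c(runif(3, -0.5, 0.5), runif(3, -0.5, 0.5),
                          runif(3, 0.22, 0.35)), 3, 3)),           # moldy
    list(hole = c(runif(1, -0.4, 0.4), runif(1, -0.4, 0.4),
                  runif(1, 0.15, 0.22))),                          # injured
    list(blotch = c(runif(1, 0.45, 0.65), runif(1, -0.2, 0.2),
                    runif(1, 0.35, 0.5))),                         # spotted
    list(),                                                        # sprouted
    list(cutFrac = runif(1, -0.1, 0.4)))                           # broken
}

paintInstance <- function(img, fp, inst, app) {
  sel <- which(fp$foot)
  if (!length(sel)) return(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  a <- inst$axes[1]; b <- inst$axes[2]
  base <- categoryPaint(inst$category)
  shade <- 1 - 0.3 * pmin(fp$rr[sel], 1)
  cols <- cbind(base[1] * shade, base[2] * shade, base[3] * shade)
  u <- fp$u[sel]; v <- fp$v[sel]
  mix <- function(cols, where, target, wgt) {
    for (ch in 1:3) cols[where, ch] <- (1 - wgt) * cols[where, ch] + wgt * target[ch]
    cols
  }
  if (inst$category == 2L) {                       # moldy patches
    for (p in seq_len(nrow(app$patch))) {
      pc <- app$patch[p, ]
      inpatch <- ((u - pc[1] * a)^2 + (v - pc[2] * b)^2) <= (pc[3] * b)^2
      cols <- mix(cols, inpatch, c(0.72, 0.72, 0.68), 0.75)
    }
  } else if (inst$category == 3L) {                # injured: bored hole
    hh <- app$hole
    inh <- ((u - hh[1] * a)^2 + (v - hh[2] * b)^2) <= (hh[3] * b)^2
    cols <- mix(cols, inh, c(0.16, 0.11, 0.08), 0.9)
  } else if (inst$category == 4L) {                # spotted: embryo-end blotch
    bl <- app$blotch
    inb <- ((u - bl[1] * a)^2 + (v - bl[2] * b)^2) <= (bl[3] * b)^2
    cols <- mix(cols, inb, c(0.13, 0.09, 0.07), 0.85)
  } else if (inst$category == 5L) {                # sprout tip highlight
    inb <- ((u - 0.95 * a)^2 + v^2) <= (0.35 * b)^2
    cols <- mix(cols, inb, c(0.80, 0.90, 0.55), 0.8)
  } else if (inst$category == 6L) {                # broken: pale cut face
    inc <- u > (app$cutFrac - 0.25) * a
    cols <- mix(cols, inc, c(0.97, 0.94, 0.82), 0.6)
  }
  cols <- cols + matrix(rnorm(length(sel) * 3, 0, 0.015), ncol = 3)
  cols <- clamp(cols, 0, 1)
  for (ch in 1:3) {
    pl <- img[, , ch]
    pl[sel] <- cols[, ch]
    img[, , ch] <- pl
  }
  img
}

maskBbox <- function(mask) {
  cs <- which(colSums(mask) > 0)
  rs <- which(rowSums(mask) > 0)
  if (!length(cs)) return(NULL)
  c(min(cs) - 1, min(rs) - 1, max(cs), max(rs))   # half-open, origin top-left
}

newAnnotation <- function(categoryId, mask) {
  bb <- maskBbox(mask)
  if (is.null(bb)) return(NULL)
  structure(list(categoryId = as.integer(categoryId), bbox = as.numeric(bb),
                 mask = mask, area = sum(mask)),
            class = "instanceAnnotation")
}

#' Render a synthetic kernel scene
#'
#' Rasterizes every kernel instance of a \code{\link{sceneSpec}} (pixel-center
#' inside rule), resolves occlusion by z-order (higher rank owns contested
#' pixels), and returns the RGB image together with one visible-region
#' annotation per instance. Instances whose visible mask is empty are
#' dropped. Output is bit-reproducible given the spec.
#'
#' @param spec A \code{SceneSpec}.
#' @return A list with \code{image} (h x w x 3 array in [0, 1]) and
#'   \code{annotations} (list; each has \code{categoryId}, \code{bbox} as
#'   half-open (x1, y1, x2, y2), logical \code{mask} of visible pixels, and
#'   \code{area}).
#' @examples
#' sp <- randomSceneSpec(3, imageSize = c(96, 96), seed = 7)
#' sc <- renderScene(sp)
#' length(sc$annotations)
#' @export
renderScene <- function(spec) {
  stopifnot(is(spec, "SceneSpec"))
  h <- spec@imageSize[1]; w <- spec@imageSize[2]
  if (h < 64 || w < 64) stop("image size must be at least 64x64")
  insts <- spec@instances
  nI <- length(insts)
  ord <- order(vapply(insts, function(i) i$zOrder, numeric(1)), seq_len(nI))
  withSeed(spec@seed, {
    img <- array(0, c(h, w, 3))
    bg <- c(0.36, 0.34, 0.31)
    for (ch in 1:3)
      img[, , ch] <- clamp(bg[ch] + matrix(rnorm(h * w, 0, 0.012), h, w), 0, 1)
    own <- matrix(0L, h, w)
    for (i in ord) {
      inst <- insts[[i]]
      app <- drawAppearance(inst)
      fp <- instanceFootprint(inst, h, w, app)
      own[fp$foot] <- i
      img <- paintInstance(img, fp, inst, app)
    }
    anns <- list()
    for (i in seq_len(nI)) {
      ann <- newAnnotation(insts[[i]]$category, own == i)
      if (!is.null(ann)) anns[[length(anns) + 1L]] <- ann
    }
    list(image = img, annotations = anns)
  })
}

# effective collision radius (sprout bump can poke beyond the ellipse)
effectiveRadius <- function(category, a, b) {
  if (category == 5L) max(a, 0.95 * a + 0.35 * b) else a
}

#' Draw a random scene recipe
#'
#' Places kernels sequentially with rejection sampling so that pairwise
#' centre distances respect the adhesion level: at \code{adhesionLevel = 0}
#' footprints are guaranteed disjoint; larger values allow progressively
#' deeper overlap (occlusion resolved by placement order).
#'
#' @param nInstances Number of kernels to place.
#' @param imageSize Integer (height, width), at least 64 each.
#' @param categories Category ids to sample from (or a single id for a
#'   single-class scene).
#' @param adhesionLevel Allowed overlap fraction in [0, 1].
#' @param seed Integer seed; the recipe and its rendering are reproducible.
#' @param axisRange Range of the semi-major axis in pixels.
#' @return A \code{SceneSpec}.
#' @export
randomSceneSpec <- function(nInstances, imageSize = c(256L, 256L),
                            categories = 1:6, adhesionLevel = 0.1,
                            seed = 1L, axisRange = c(16, 24)) {
  h <- imageSize[1]; w <- imageSize[2]
  withSeed(deriveSeed(seed, 1L), {
    placed <- list()
    for (i in seq_len(nInstances)) {
      cat_i <- if (length(categories) == 1L) categories else
        sample(categories, 1L)
      a <- runif(1, axisRange[1], axisRange[2])
      b <- a / runif(1, 1.25, 2.4)
      rot <- runif(1, 0, pi)
      rEff <- effectiveRadius(cat_i, a, b)
      done <- FALSE
      for (try in seq_len(400)) {
        cx <- runif(1, rEff + 2, w - rEff - 2)
        cy <- runif(1, rEff + 2, h - rEff - 2)
        ok <- TRUE
        for (pj in placed) {
          dmin <- (1 - adhesionLevel) * (rEff + pj$rEff) +
            if (adhesionLevel == 0) 1 else 0
          if (sqrt((cx - pj$cx)^2 + (cy - pj$cy)^2) < dmin) { ok <- FALSE; break }
        }
        if (ok) {
          placed[[i]] <- list(cx = cx, cy = cy, rEff = rEff,
                              inst = kernelInstance(cat_i, c(cx, cy), c(a, b),
                                                    rot, zOrder = i))
          done <- TRUE
          break
        }
      }
      if (!done)
        stop("could not place instance ", i,
             "; reduce nInstances or raise adhesionLevel")
    }
    sceneSpec(imageSize, lapply(placed, `[[`, "inst"), adhesionLevel,
              seed = deriveSeed(seed, 2L))
  })
}

shiftMatrix <- function(m, dx, dy, fill) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  srcc <- seq_len(w) - dx; srcr <- seq_len(h) - dy
  okc <- srcc >= 1 & srcc <= w; okr <- srcr >= 1 & srcr <= h
  out[okr, okc] <- m[srcr[okr], srcc[okc]]
  out
}

#' Apply one of the five dataset augmentations
#'
#' Photometric methods (\code{brightness}, \code{noise}, \code{points}) leave
#' the annotations untouched; geometric methods (\code{translate},
#' \code{flip}) transform masks and boxes consistently with the pixels, and
#' instances translated fully outside the frame are dropped.
#'
#' @param image h x w x 3 array in [0, 1].
#' @param annotations List of annotations as produced by
#'   \code{\link{renderScene}}.
#' @param method One of \code{"brightness"}, \code{"noise"}, \code{"points"},
#'   \code{"translate"}, \code{"flip"}.
#' @param seed Integer seed for the stochastic methods.
#' @param params Optional overrides: \code{brightnessFactor} (default 0.6),
#'   \code{noiseSd} (default 10/255), \code{nPoints} (default 50),
#'   \code{maxShiftFrac} (default 0.15).
#' @return A list with transformed \code{image} and \code{annotations}.
#' @export
augmentScene <- function(image, annotations, method, seed = 1L,
                         params = list()) {
  p <- modifyList(list(brightnessFactor = 0.6, noiseSd = 10 / 255,
                       nPoints = 50L, maxShiftFrac = 0.15), params)
  h <- dim(image)[1]; w <- dim(image)[2]
  switch(method,
    brightness = list(image = clamp(image * p$brightnessFactor, 0, 1),
                      annotations = annotations),
    noise = withSeed(deriveSeed(seed, 11L), list(
      image = clamp(image + array(rnorm(length(image), 0, p$noiseSd),
                                  dim(image)), 0, 1),
      annotations = annotations)),
    points = withSeed(deriveSeed(seed, 12L), {
      rows <- sample.int(h, p$nPoints, replace = TRUE)
      cols <- sample.int(w, p$nPoints, replace = TRUE)
      for (ch in 1:3) {
        pl <- image[, , ch]
        pl[cbind(rows, cols)] <- 1
        image[, , ch] <- pl
      }
      list(image = image, annotations = annotations)
    }),
    translate = withSeed(deriveSeed(seed, 13L), {
      mx <- floor(p$maxShiftFrac * w); my <- floor(p$maxShiftFrac * h)
      dx <- sample(seq(-mx, mx), 1L); dy <- sample(seq(-my, my), 1L)
      fill <- apply(image[c(1, h), c(1, w), , drop = FALSE], 3, stats::median)
      for (ch in 1:3)
        image[, , ch] <- shiftMatrix(image[, , ch], dx, dy, fill[ch])
      anns <- list()
      for (ann in annotations) {
        m <- shiftMatrix(ann$mask, dx, dy, FALSE)
        a2 <- newAnnotation(ann$categoryId, m)
        if (!is.null(a2)) anns[[length(anns) + 1L]] <- a2
      }
      list(image = image, annotations = anns)
    }),
    flip = {
      image <- image[, w:1, , drop = FALSE]
      anns <- lapply(annotations, function(ann) {
        m <- ann$mask[, ncol(ann$mask):1, drop = FALSE]
        structure(list(categoryId = ann$categoryId,
                       bbox = c(w - ann$bbox[3], ann$bbox[2],
                                w - ann$bbox[1], ann$bbox[4]),
                       mask = m, area = ann$area),
                  class = "instanceAnnotation")
      })
      list(image = image, annotations = anns)
    },
    stop("unknown augmentation method: '", method,
         "' (expected brightness, noise, points, translate or flip)")
  )
}

provenanceTags <- function() c("original", "brightness", "noise", "points",
                               "translate", "flip")

# largest-remainder 8:1:1 allocation; remainder ties resolved train, val, test
allocate811 <- function(n) {
  q <- n * c(8, 1, 1) / 10
  fl <- floor(q)
  left <- n - sum(fl)
  add <- integer(3)
  if (left > 0) {
    o <- order(-(q - fl), seq_len(3))
    add[o[seq_len(left)]] <- 1L
  }
  stats::setNames(as.integer(fl + add), c("train", "val", "test"))
}

#' Assemble a stratified synthetic dataset manifest
#'
#' Builds the dataset recipe: \code{nSinglePerClass} base scenes for each of
#' the six categories plus \code{nMixture} mixed scenes, each accompanied by
#' its five augmented versions, for a total of
#' \code{6 * 6 * nSinglePerClass + 6 * nMixture} images. Within every
#' composition stratum images are split 8:1:1 into train/val/test
#' (largest-remainder rounding), keeping each base scene's versions together
#' wherever the quota allows so augmented copies do not straddle splits. The
#' defaults (5 per class, 100 mixture) yield 780 images split 624/78/78 with
#' the mixture stratum at 480/60/60.
#'
#' @param nSinglePerClass Base single-class scenes per category (>= 1).
#' @param nMixture Mixed-category base scenes (>= 0).
#' @param seed Master seed; every scene and augmentation derives from it.
#' @param imageSize Scene size in pixels.
#' @param kernelsPerScene Kernels per single-class / mixture scene (length-2).
#' @param adhesionLevel Allowed adhesion during placement.
#' @param axisRange Kernel semi-major axis range in pixels.
#' @return A \code{DatasetManifest}.
#' @examples
#' m <- buildDataset(1, 0, seed = 1, imageSize = c(96, 96),
#'                   kernelsPerScene = c(2, 3))
#' length(m)
#' @export
buildDataset <- function(nSinglePerClass = 5L, nMixture = 100L, seed = 1L,
                         imageSize = c(512L, 512L),
                         kernelsPerScene = c(12L, 20L),
                         adhesionLevel = 0.3, axisRange = c(16, 24)) {
  stopifnot(nSinglePerClass >= 1L, nMixture >= 0L)
  cats <- kernelCategories()
  baseSpecs <- list()
  comp <- character()
  for (k in cats$id) {
    for (j in seq_len(nSinglePerClass)) {
      baseSpecs[[length(baseSpecs) + 1L]] <- randomSceneSpec(
        kernelsPerScene[1], imageSize, categories = k,
        adhesionLevel = adhesionLevel, axisRange = axisRange,
        seed = deriveSeed(seed, k, j))
      comp <- c(comp, cats$name[k])
    }
  }
  for (j in seq_len(nMixture)) {
    baseSpecs[[length(baseSpecs) + 1L]] <- randomSceneSpec(
      kernelsPerScene[2], imageSize, categories = cats$id,
      adhesionLevel = adhesionLevel, axisRange = axisRange,
      seed = deriveSeed(seed, 99L, j))
    comp <- c(comp, "mixture")
  }
  prov <- provenanceTags()
  rec <- expand.grid(provenance = prov, baseIndex = seq_along(baseSpecs),
                     stringsAsFactors = FALSE)
  rec <- rec[order(rec$baseIndex), c("baseIndex", "provenance")]
  rec$composition <- comp[rec$baseIndex]
  rec$id <- seq_len(nrow(rec))
  rec$augSeed <- mapply(function(b, pv) deriveSeed(seed, 500L + b,
                                                   match(pv, prov)),
                        rec$baseIndex, rec$provenance)
  rec$split <- NA_character_
  for (cp in unique(rec$composition)) {
    idx <- which(rec$composition == cp)      # already ordered base-major
    cnt <- allocate811(length(idx))
    rec$split[idx] <- rep(c("train", "val", "test"), times = cnt)
  }
  rownames(rec) <- NULL
  new("DatasetManifest",
      records = rec[, c("id", "baseIndex", "composition", "provenance",
                        "split", "augSeed")],
      baseSpecs = baseSpecs, seed = as.integer(seed))
}

#' Render one manifest record (base scene plus its augmentation)
#'
#' @param manifest A \code{DatasetManifest}.
#' @param i Record index (row of \code{splitTable(manifest)}).
#' @return A list with \code{image} and \code{annotations}.
#' @export
renderRecord <- function(manifest, i) {
  r <- manifest@records[i, ]
  sc <- renderScene(manifest@baseSpecs[[r$baseIndex]])
  if (r$provenance == "original") return(sc)
  augmentScene(sc$image, sc$annotations, r$provenance, seed = r$augSeed)
}

#' Record table of a dataset manifest
#'
#' @param manifest A \code{DatasetManifest}.
#' @return The records data.frame (id, baseIndex, composition, provenance,
#'   split, augSeed).
#' @export
splitTable <- function(manifest) manifest@records
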