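#' Kernel category table
#'
#' The six-class taxonomy used throughout the package: one undamaged class
#' (\code{perfect}) and five kinds of unsound kernels. Ids are a fixed
#' bijection onto the names; \code{color} is the display colour used for
#' prediction overlays (orange perfect, yellow moldy, green injured, blue
#' spotted, purple sprouted, red broken).
#'
#' @return A data.frame with columns \code{id}, \code{name}, \code{color}.
#' @examples
#' kernelCategories()
#' @export
kernelCategories <- function() {
  data.frame(
    id = 1:6,
    name = c("perfect", "moldy", "injured", "spotted", "sprouted", "broken"),
    color = c("#FFA500", "#FFD700", "#00A550", "#1E90FF", "#A020F0", "#FF2020"),
    stringsAsFactors = FALSE
  )
}

categoryIdOf <- function(name) {
  cats <- kernelCategories()
  id <- cats$id[match(name, cats$name)]
  if (anyNA(id)) stop("unknown kernel category: ",
                      paste(name[is.na(id)], collapse = ", "))
  id
}

#' A single kernel instance in a scene recipe
#'
#' @param category Category id (1..6) or name.
#' @param center Numeric (x, y) centre in pixels.
#' @param axes Numeric (a, b) semi-axes in pixels, \code{a >= b > 0}. The
#'   ellipse aspect \code{a/b} must lie in [1.2, 2.5] except for broken
#'   kernels, whose truncated outline may violate ellipticity.
#' @param rotation Rotation in radians.
#' @param zOrder Integer occlusion rank; higher values occlude lower ones.
#' @return A list of class \code{kernelInstance}.
#' @export
kernelInstance <- function(category, center, axes, rotation = 0, zOrder = 1L) {
  if (is.character(category)) category <- categoryIdOf(category)
  category <- as.integer(category)
  stopifnot(length(category) == 1L, category >= 1L, category <= 6L,
            length(center) == 2L, length(axes) == 2L)
  if (!(axes[1] >= axes[2] && axes[2] > 0))
    stop("axes must satisfy a >= b > 0")
  ratio <- axes[1] / axes[2]
  if (category != 6L && (ratio < 1.2 - 1e-9 || ratio > 2.5 + 1e-9))
    stop("aspect ratio a/b must lie in [1.2, 2.5] for non-broken kernels")
  structure(list(category = category, center = as.numeric(center),
                 axes = as.numeric(axes), rotation = as.numeric(rotation),
                 zOrder = as.integer(zOrder)),
            class = "kernelInstance")
}

#' @title SceneSpec: a synthetic kernel-scene recipe
#' @description Fully determines one rendered scene: image size, the kernel
#'   instances (category, pose, occlusion rank), the permitted adhesion level
#'   and the seed for all appearance noise. Rendering is bit-reproducible
#'   given the spec.
#' @slot imageSize integer (height, width) in pixels.
#' @slot instances list of \code{kernelInstance}.
#' @slot adhesionLevel numeric in [0, 1]; 0 means footprints never touch.
#' @slot seed integer seed controlling textures and background noise.
#' @exportClass SceneSpec
setClass("SceneSpec", representation(
  imageSize = "integer", instances = "list",
  adhesionLevel = "numeric", seed = "integer"))

setValidity("SceneSpec", function(object) {
  msg <- character()
  if (length(object@imageSize) != 2L || any(object@imageSize < 1L))
    msg <- c(msg, "imageSize must be two positive integers (h, w)")
  if (object@adhesionLevel < 0 || object@adhesionLevel > 1)
    msg <- c(msg, "adhesionLevel must lie in [0, 1]")
  ok <- vapply(object@instances, inherits, logical(1), "kernelInstance")
  if (!all(ok)) msg <- c(msg, "instances must all be kernelInstance objects")
  if (length(msg)) msg else TRUE
})

#' Construct a SceneSpec
#' @param imageSize Integer (height, width).
#' @param instances List of \code{\link{kernelInstance}}.
#' @param adhesionLevel Allowed pairwise adhesion in [0, 1].
#' @param seed Integer appearance seed.
#' @return A \code{SceneSpec} object.
#' @export
sceneSpec <- function(imageSize = c(256L, 256L), instances = list(),
                      adhesionLevel = 0, seed = 1L) {
  new("SceneSpec", imageSize = as.integer(imageSize), instances = instances,
      adhesionLevel = as.numeric(adhesionLevel), seed = as.integer(seed))
}

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf("SceneSpec: %dx%d, %d instance(s), adhesion %.2f, seed %d\n",
              object@imageSize[1], object@imageSize[2],
              length(object@instances), object@adhesionLevel, object@seed))
})

#' @title DatasetManifest: a synthetic dataset recipe with split tags
#' @description Records every image of a generated dataset: which base scene
#'   it renders, which augmentation produced it, its composition stratum and
#'   its train/val/test assignment. Images are rendered lazily from the
#'   recipe, so the manifest itself is light.
#' @slot records data.frame with columns id, baseIndex, composition,
#'   provenance, split, augSeed.
#' @slot baseSpecs list of \code{SceneSpec}, one per base image.
#' @slot seed integer master seed.
#' @exportClass DatasetManifest
setClass("DatasetManifest", representation(
  records = "data.frame", baseSpecs = "list", seed = "integer"))

setValidity("DatasetManifest", function(object) {
  need <- c("id", "baseIndex", "composition", "provenance", "split", "augSeed")
  if (!all(need %in% names(object@records)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (!all(object@records$split %in% c("train", "val", "test")))
    return("split tags must be train/val/test")
  if (!all(object@records$baseIndex >= 1L &
           object@records$baseIndex <= length(object@baseSpecs)))
    return("baseIndex out of range")
  TRUE
})

setMethod("show", "DatasetManifest", function(object) {
  s <- table(object@records$split)
  cat(sprintf("DatasetManifest: %d images (%d base scenes); train/val/test = %d/%d/%d\n",
              nrow(object@records), length(object@baseSpecs),
              s[["train"]], s[["val"]], s[["test"]]))
})

#' Number of images in a manifest
#' @param x A DatasetManifest.
#' @export
setMethod("length", "DatasetManifest", function(x) nrow(x@records))

#' @title DetectionResult: per-instance detector output for one image
#' @slot boxes numeric matrix n x 4, (x1, y1, x2, y2) half-open pixel coords.
#' @slot labels integer category ids (1..6).
#' @slot scores numeric confidences in [0, 1].
#' @slot masks list of logical full-image rasters, one per instance.
#' @slot imageSize integer (height, width).
#' @exportClass DetectionResult
setClass("DetectionResult", representation(
  boxes = "matrix", labels = "integer", scores = "numeric",
  masks = "list", imageSize = "integer"))

setValidity("DetectionResult", function(object) {
  n <- nrow(object@boxes)
  if (length(object@labels) != n || length(object@scores) != n ||
      length(object@masks) != n)
    return("boxes, labels, scores and masks must have equal length")
  if (n > 0 && (any(object@scores < 0) || any(object@scores > 1)))
    return("scores must lie in [0, 1]")
  TRUE
})

setMethod("show", "DetectionResult", function(object) {
  cat(sprintf("DetectionResult: %d instance(s) on %dx%d image\n",
              nrow(object@boxes), object@imageSize[1], object@imageSize[2]))
  if (nrow(object@boxes) > 0) {
    nm <- kernelCategories()$name[object@labels]
    for (i in seq_len(min(5, nrow(object@boxes))))
      cat(sprintf("  %-9s score %.3f box (%.1f, %.1f, %.1f, %.1f)\n",
                  nm[i], object@scores[i], object@boxes[i, 1],
                  object@boxes[i, 2], object@boxes[i, 3], object@boxes[i, 4]))
    if (nrow(object@boxes) > 5) cat("  ...\n")
  }
})

#' @title MetricReport: COCO-style evaluation summary
#' @slot perClassAP named numeric, average precision per category.
#' @slot mAP numeric, unweighted mean of per-class APs.
#' @slot perClassRecall named numeric.
#' @slot AR numeric, mean of per-class recalls.
#' @slot perClassIoU named numeric, mean matched-pair IoU per category.
#' @slot mIoU numeric.
#' @slot precision numeric overall point precision.
#' @slot recall numeric overall point recall.
#' @slot counts list with TP, FP, FN totals.
#' @slot nParameters numeric model size (NA when not applicable).
#' @slot timePerImage numeric inference seconds per image (NA if unmeasured).
#' @exportClass MetricReport
setClass("MetricReport", representation(
  perClassAP = "numeric", mAP = "numeric", perClassRecall = "numeric",
  AR = "numeric", perClassIoU = "numeric", mIoU = "numeric",
  precision = "numeric", recall = "numeric", counts = "list",
  nParameters = "numeric", timePerImage = "numeric"))

setMethod("show", "MetricReport", function(object) {
  cat("MetricReport\n")
  cat(sprintf("  precision %.3f  recall %.3f  mAP %.3f  AR %.3f  mIoU %.3f\n",
              object@precision, object@recall, object@mAP, object@AR,
              object@mIoU))
  cat("  per-class AP:\n")
  for (nm in names(object@perClassAP))
    cat(sprintf("    %-9s %.3f\n", nm, object@perClassAP[[nm]]))
  cat(sprintf("  TP %d  FP %d  FN %d\n", object@counts$TP, object@counts$FP,
              object@counts$FN))
})

setOldClass(c("modelConfig", "list"))

#' @title GrainModel: a configured kernel-segmentation model
#' @description Holds the resolved configuration, all trainable parameters
#'   (a flat named list of arrays) and optimiser state. Models are value
#'   objects: training returns an updated copy.
#' @slot config list, resolved model configuration (see
#'   \code{\link{modelConfig}}).
#' @slot params list of named parameter arrays.
#' @slot state list with optimiser state (step counter, momenta).
#' @exportClass GrainModel
setClass("GrainModel", representation(
  config = "list", params = "list", state = "list"))

setMethod("show", "GrainModel", function(object) {
  cat(sprintf("GrainModel: variant '%s' (attention %s, pyramid %s)\n",
              object@config$variant, object@config$attention$kind,
              object@config$pyramid$kind))
  cat(sprintf("  %d trainable parameters, %d training step(s) taken\n",
              countParameters(object), object@state$step))
})
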