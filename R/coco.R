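# COCO instance-annotation JSON and labelme JSON interchange. Masks travel
# as uncompressed column-major RLE (counts start with the zero run, the COCO
# convention); boxes as [x, y, w, h] in continuous pixel coordinates.

rleEncode <- function(mask) {
  r <- rle(as.integer(mask))
  counts <- r$lengths
  if (length(r$values) && r$values[1] == 1L) counts <- c(0L, counts)
  list(size = dim(mask), counts = as.integer(counts))
}

rleDecode <- function(size, counts) {
  counts <- as.integer(counts)
  vals <- rep(c(0L, 1L), length.out = length(counts))
  v <- inverse.rle(list(lengths = counts, values = vals))
  matrix(as.logical(v), size[1], size[2])
}

annToCoco <- function(ann, annId, imageId) {
  rle <- rleEncode(ann$mask)
  list(id = annId, image_id = imageId, category_id = ann$categoryId,
       bbox = c(ann$bbox[1], ann$bbox[2],
                ann$bbox[3] - ann$bbox[1], ann$bbox[4] - ann$bbox[2]),
       area = ann$area, iscrowd = 0L,
       segmentation = list(size = as.integer(rle$size), counts = rle$counts))
}

#' Write a manifest as a COCO dataset on disk
#'
#' Renders every record of the manifest, writes the images as PNG under
#' \code{dir/images}, a COCO instance-annotation file
#' (\code{annotations.json}: images / annotations / categories, RLE masks)
#' and a \code{manifest.json} with the split, provenance and seed of every
#' record.
#'
#' @param manifest A \code{\link{buildDataset}} manifest.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the path to \code{annotations.json}.
#' @export
writeCoco <- function(manifest, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  rec <- manifest@records
  images <- vector("list", nrow(rec))
  anns <- list()
  annId <- 0L
  for (i in seq_len(nrow(rec))) {
    sc <- renderRecord(manifest, i)
    fn <- sprintf("img_%04d.png", rec$id[i])
    png::writePNG(sc$image, file.path(dir, "images", fn))
    d <- dim(sc$image)
    images[[i]] <- list(id = rec$id[i], file_name = file.path("images", fn),
                        height = d[1], width = d[2])
    for (ann in sc$annotations) {
      annId <- annId + 1L
      anns[[annId]] <- annToCoco(ann, annId, rec$id[i])
    }
  }
  cats <- kernelCategories()
  coco <- list(
    images = images,
    annotations = anns,
    categories = lapply(seq_len(nrow(cats)), function(k)
      list(id = cats$id[k], name = cats$name[k])))
  out <- file.path(dir, "annotations.json")
  jsonlite::write_json(coco, out, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(seed = manifest@seed, records = rec),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' Read a COCO instance-annotation file
#'
#' Validates the category map against the six-class taxonomy and decodes RLE
#' masks back to logical rasters.
#'
#' @param path Path to a COCO JSON file.
#' @return A list of class \code{cocoDataset} with \code{images} (metadata
#'   rows) and \code{annotations} (per image id, a list of annotations in the
#'   same form \code{\link{renderScene}} produces).
#' @export
readCoco <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(js$categories)) stop("malformed COCO file: missing category map")
  known <- kernelCategories()
  for (ct in js$categories) {
    if (!(ct$name %in% known$name))
      stop("COCO category not in the six-class map: '", ct$name, "'")
    if (known$id[match(ct$name, known$name)] != ct$id)
      stop("COCO category id mismatch for '", ct$name, "'")
  }
  images <- lapply(js$images, function(im)
    list(id = im$id, file_name = im$file_name,
         height = im$height, width = im$width))
  annotations <- list()
  for (an in js$annotations) {
    seg <- an$segmentation
    mask <- rleDecode(unlist(seg$size), unlist(seg$counts))
    bb <- as.numeric(unlist(an$bbox))
    ann <- structure(list(categoryId = as.integer(an$category_id),
                          bbox = c(bb[1], bb[2], bb[1] + bb[3], bb[2] + bb[4]),
                          mask = mask, area = sum(mask)),
                     class = "instanceAnnotation")
    key <- as.character(an$image_id)
    annotations[[key]] <- c(annotations[[key]], list(ann))
  }
  structure(list(images = images, annotations = annotations),
            class = "cocoDataset")
}

# even-odd polygon fill under the pixel-center-inside rule
polygonMask <- function(points, h, w) {
  n <- nrow(points)
  mask <- matrix(FALSE, h, w)
  px <- points[, 1]; py <- points[, 2]
  nx <- c(px[-1], px[1]); ny <- c(py[-1], py[1])
  for (i in seq_len(h)) {
    y <- i - 0.5
    cross <- (py <= y) != (ny <= y)
    if (!any(cross)) next
    xs <- sort(px[cross] + (y - py[cross]) * (nx[cross] - px[cross]) /
                 (ny[cross] - py[cross]))
    for (k in seq(1, length(xs) - 1, by = 2)) {
      j1 <- floor(xs[k] + 0.5) + 1L
      j2 <- ceiling(xs[k + 1] + 0.5) - 1L
      if (j2 >= j1) mask[i, max(1L, j1):min(w, j2)] <- TRUE
    }
  }
  mask
}

#' Read a labelme annotation file
#'
#' Rasterizes every polygon shape to a visible-region mask using the
#' pixel-center-inside rule and maps labels through the six-class taxonomy.
#'
#' @param path Path to a labelme JSON file.
#' @return A list of annotations (categoryId, bbox, mask, area).
#' @export
readLabelme <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  h <- js$imageHeight; w <- js$imageWidth
  if (is.null(h) || is.null(w))
    stop("malformed labelme file: missing imageHeight/imageWidth")
  anns <- list()
  for (sh in js$shapes) {
    pts <- do.call(rbind, lapply(sh$points, function(p) as.numeric(unlist(p))))
    if (is.null(pts) || nrow(pts) < 3)
      stop("labelme polygon must have at least 3 vertices (label '",
           sh$label, "')")
    cid <- categoryIdOf(sh$label)
    ann <- newAnnotation(cid, polygonMask(pts, h, w))
    if (!is.null(ann)) anns[[length(anns) + 1L]] <- ann
  }
  anns
}
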