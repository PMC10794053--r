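# I/O for every external format the pipeline touches, plus crop extraction.
#
# Coordinate convention: 0-based pixels, boxes half-open [xmin, xmax) x
# [ymin, ymax).  Pascal-VOC XML stores 1-based *inclusive* pixel indices, so
# (xmin, ymin, xmax, ymax)_voc maps to (xmin - 1, ymin - 1, xmax, ymax) here
# and back on write.

#' Read Pascal-VOC bounding boxes (LabelImg dialect)
#'
#' Parses an `<annotation>` XML file with `<object><bndbox>` entries and
#' converts the VOC 1-based inclusive indices to the toolkit's 0-based
#' half-open convention. A `<score>` or `<confidence>` element inside an
#' object, if present, is read as the prediction confidence.
#'
#' @param path path to the XML file.
#' @return A [BoxAnnotation-class].
#' @examples
#' f <- tempfile(fileext = ".xml")
#' writeVocBoxes(boxAnnotation("img", data.frame(
#'   xmin = 0, ymin = 0, xmax = 11, ymax = 11, label = "tree")), f)
#' readVocBoxes(f)
#' @export
readVocBoxes <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed XML in ", path, ": ",
                                           conditionMessage(e)))
  fname <- xml2::xml_find_first(doc, "./filename")
  imageId <- if (inherits(fname, "xml_missing"))
    sub("\\.xml$", "", basename(path)) else xml2::xml_text(fname)
  objs <- xml2::xml_find_all(doc, "./object")
  if (length(objs) == 0L) return(boxAnnotation(imageId))
  rows <- lapply(seq_along(objs), function(i) {
    obj <- objs[[i]]
    bb <- xml2::xml_find_first(obj, "./bndbox")
    if (inherits(bb, "xml_missing"))
      stop("format error in ", path, ": object ", i, " has no <bndbox>")
    val <- function(tag) {
      node <- xml2::xml_find_first(bb, paste0("./", tag))
      if (inherits(node, "xml_missing"))
        stop("format error in ", path, ": object ", i,
             " is missing <bndbox>/<", tag, ">")
      v <- suppressWarnings(as.numeric(xml2::xml_text(node)))
      if (is.na(v))
        stop("format error in ", path, ": object ", i,
             " has non-numeric <", tag, ">")
      v
    }
    lab <- xml2::xml_find_first(obj, "./name")
    conf <- xml2::xml_find_first(obj, "./score | ./confidence")
    data.frame(
      xmin = val("xmin") - 1, ymin = val("ymin") - 1,
      xmax = val("xmax"), ymax = val("ymax"),
      label = if (inherits(lab, "xml_missing")) "object" else xml2::xml_text(lab),
      confidence = if (inherits(conf, "xml_missing")) NA_real_
                   else as.numeric(xml2::xml_text(conf)))
  })
  boxAnnotation(imageId, do.call(rbind, rows))
}

#' Write bounding boxes as Pascal-VOC XML
#'
#' Inverse of [readVocBoxes()]: the toolkit's 0-based half-open boxes are
#' written back as VOC 1-based inclusive indices, so a read/write round trip
#' reproduces coordinates exactly.
#'
#' @param boxes a [BoxAnnotation-class].
#' @param path output path.
#' @param width,height optional image dimensions for the `<size>` element.
#' @return `path`, invisibly.
#' @export
writeVocBoxes <- function(boxes, path, width = NA, height = NA) {
  stopifnot(is(boxes, "BoxAnnotation"))
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", imageId(boxes))
  if (!is.na(width) && !is.na(height)) {
    sz <- xml2::xml_add_child(doc, "size")
    xml2::xml_add_child(sz, "width", format(width))
    xml2::xml_add_child(sz, "height", format(height))
    xml2::xml_add_child(sz, "depth", "3")
  }
  b <- boxTable(boxes)
  for (i in seq_len(nrow(b))) {
    obj <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(obj, "name", b$label[i])
    if (!is.na(b$confidence[i]))
      xml2::xml_add_child(obj, "score", format(b$confidence[i], digits = 10))
    bb <- xml2::xml_add_child(obj, "bndbox")
    xml2::xml_add_child(bb, "xmin", format(b$xmin[i] + 1, digits = 10))
    xml2::xml_add_child(bb, "ymin", format(b$ymin[i] + 1, digits = 10))
    xml2::xml_add_child(bb, "xmax", format(b$xmax[i], digits = 10))
    xml2::xml_add_child(bb, "ymax", format(b$ymax[i], digits = 10))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read shoot point annotations (CSV or JSON)
#'
#' The CSV dialect carries the image metadata in a two-line header followed
#' by an `x,y` table:
#' \preformatted{
#' image_id,width,height
#' scene_0001,256,256
#' x,y
#' 12.5,30.25
#' ...
#' }
#' The JSON dialect is an object with fields `image_id`, `width`, `height`
#' and `points` (an array of `[x, y]` pairs). Points outside
#' `[0, width) x [0, height)` are rejected with the offending row number.
#'
#' @param path path to a `.csv` or `.json` file.
#' @return A [PointAnnotation-class].
#' @export
readPoints <- function(path) {
  if (!file.exists(path)) stop("point file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::fromJSON(path)
    pts <- obj$points
    if (is.null(pts) || length(pts) == 0L) pts <- matrix(numeric(), 0L, 2L)
    pts <- matrix(as.numeric(as.matrix(pts)), ncol = 2L)
    meta <- list(image_id = obj$image_id, width = obj$width, height = obj$height)
  } else {
    lines <- readLines(path)
    if (length(lines) < 3L) stop("point CSV must have metadata header and x,y header: ", path)
    meta <- utils::read.csv(text = paste(lines[1:2], collapse = "\n"))
    if (!all(c("image_id", "width", "height") %in% names(meta)))
      stop("point CSV metadata header must carry image_id,width,height: ", path)
    tab <- utils::read.csv(text = paste(lines[-(1:2)], collapse = "\n"))
    if (!all(c("x", "y") %in% names(tab)))
      stop("point CSV must have x,y columns: ", path)
    pts <- as.matrix(tab[, c("x", "y")])
    meta <- list(image_id = meta$image_id, width = meta$width, height = meta$height)
  }
  if (nrow(pts) && (!is.numeric(pts) || anyNA(pts)))
    stop("non-numeric point coordinates in ", path)
  w <- as.numeric(meta$width); h <- as.numeric(meta$height)
  if (nrow(pts)) {
    bad <- which(pts[, 1] < 0 | pts[, 1] >= w | pts[, 2] < 0 | pts[, 2] >= h)
    if (length(bad))
      stop("point out of bounds in ", path, " at row ", bad[1],
           sprintf(": (%g, %g) not inside [0,%g) x [0,%g)",
                   pts[bad[1], 1], pts[bad[1], 2], w, h))
  }
  pointAnnotation(meta$image_id, w, h, pts)
}

#' Write shoot point annotations
#'
#' Inverse of [readPoints()]; the format is chosen from the file extension.
#'
#' @param ann a [PointAnnotation-class].
#' @param path output path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
writePoints <- function(ann, path) {
  stopifnot(is(ann, "PointAnnotation"))
  sz <- imageSize(ann)
  p <- shootPoints(ann)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- list(image_id = imageId(ann), width = unname(sz["width"]),
                height = unname(sz["height"]),
                points = unname(apply(p, 1, c, simplify = FALSE)))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("image_id,width,height",
                 sprintf("%s,%s,%s", imageId(ann), format(sz["width"]),
                         format(sz["height"])),
                 "x,y"), con)
    if (nrow(p))
      writeLines(sprintf("%s,%s", formatC(p[, 1], format = "fg", digits = 10),
                         formatC(p[, 2], format = "fg", digits = 10)), con)
  }
  invisible(path)
}

#' Extract per-crown crops from an image
#'
#' Implements the plant-extraction stage: each detected crown box, expanded by
#' `pad` pixels on every side and clamped to the image bounds, is cut out of
#' the image. Offsets are returned so crop-local coordinates can be mapped
#' back to the parent image (`parent = crop + offset`).
#'
#' @param image numeric array `H x W x C` (or `H x W` matrix) with values in
#'   `[0, 1]`.
#' @param boxes a [BoxAnnotation-class]; boxes are snapped to integer pixel
#'   bounds with `floor`/`ceiling` before cropping.
#' @param pad non-negative padding in pixels added to each side.
#' @return A list with one element per box, each a list with `image` (the
#'   crop), `offset` (`c(x, y)` of the crop's origin in parent coordinates)
#'   and `box` (the realised integer crop box, half-open).
#' @examples
#' img <- array(0, c(100, 100, 3))
#' ba <- boxAnnotation("img", data.frame(xmin = 10, ymin = 10,
#'                                       xmax = 50, ymax = 50))
#' cr <- cropSingleTrees(img, ba, pad = 20)
#' dim(cr[[1]]$image)  # 70 x 70 x 3 after clamping at the origin
#' @export
cropSingleTrees <- function(image, boxes, pad = 0) {
  stopifnot(is(boxes, "BoxAnnotation"), pad >= 0)
  d <- dim(image)
  H <- d[1]; W <- d[2]
  b <- boxTable(boxes)
  lapply(seq_len(nrow(b)), function(i) {
    x0 <- max(0L, as.integer(floor(b$xmin[i] - pad)))
    y0 <- max(0L, as.integer(floor(b$ymin[i] - pad)))
    x1 <- min(W, as.integer(ceiling(b$xmax[i] + pad)))
    y1 <- min(H, as.integer(ceiling(b$ymax[i] + pad)))
    if (x1 <= x0 || y1 <= y0)
      stop("box ", i, " lies outside the image after clamping")
    crop <- if (length(d) == 3L) image[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE]
            else image[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
    list(image = crop, offset = c(x = x0, y = y0),
         box = c(xmin = x0, ymin = y0, xmax = x1, ymax = y1))
  })
}

#' Remap points between parent and crop coordinates
#'
#' @param ann a [PointAnnotation-class] in parent coordinates.
#' @param offset `c(x, y)` origin of the crop (from [cropSingleTrees()]).
#' @param size `c(width, height)` of the crop; points falling outside the
#'   crop are dropped.
#' @return A [PointAnnotation-class] in crop-local coordinates.
#' @export
pointsToCrop <- function(ann, offset, size) {
  p <- shootPoints(ann)
  q <- cbind(p[, 1] - offset[1], p[, 2] - offset[2])
  keep <- q[, 1] >= 0 & q[, 1] < size[1] & q[, 2] >= 0 & q[, 2] < size[2]
  pointAnnotation(imageId(ann), size[1], size[2], q[keep, , drop = FALSE])
}

#' @rdname pointsToCrop
#' @param parentSize `c(width, height)` of the parent image.
#' @export
pointsToParent <- function(ann, offset, parentSize) {
  p <- shootPoints(ann)
  q <- cbind(p[, 1] + offset[1], p[, 2] + offset[2])
  pointAnnotation(imageId(ann), parentSize[1], parentSize[2], q)
}

#' Read an RGB image file
#'
#' PNG files are read with the png package; JPEG and TIFF images are read via
#' EBImage when it is installed. Returns an `H x W x 3` array in `[0, 1]`
#' (grayscale images are replicated across channels).
#'
#' @param path image path.
#' @return numeric array `H x W x 3`.
#' @export
readImageFile <- function(path) {
  if (!file.exists(path)) stop("image not found: ", path)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
  } else if (requireNamespace("EBImage", quietly = TRUE)) {
    img <- EBImage::imageData(EBImage::readImage(path))
    img <- if (length(dim(img)) == 2L) t(img) else aperm(img, c(2, 1, 3))
  } else {
    stop("only PNG is supported without EBImage: ", path)
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Persist a density map as 32-bit TIFF plus a JSON sidecar
#'
#' The grid is stored in a single-channel TIFF scaled to `[0, 1]`; the JSON
#' sidecar (`<path>.json`) carries the scale factor, the count (grid sum),
#' the stride and the source id, so [readDensityMap()] restores the map
#' exactly up to 32-bit float precision.
#'
#' @param d a [DensityMap-class].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
writeDensityMap <- function(d, path) {
  stopifnot(is(d, "DensityMap"))
  g <- densityGrid(d)
  scale <- max(g, 1e-12)
  tiff::writeTIFF(g / scale, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(scale = scale, count = sum(g), stride = mapStride(d),
         source_id = d@sourceId),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeDensityMap
#' @return For `readDensityMap`, the restored [DensityMap-class].
#' @export
readDensityMap <- function(path) {
  if (!file.exists(path)) stop("density map not found: ", path)
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("density map sidecar not found: ", side)
  meta <- jsonlite::fromJSON(side)
  g <- tiff::readTIFF(path)
  if (length(dim(g)) == 3L) g <- g[, , 1]
  densityMap(g * meta$scale, stride = meta$stride, sourceId = meta$source_id)
}
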