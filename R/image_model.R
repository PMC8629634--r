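#' Core raster types
#'
#' Lightweight S3 wrappers over base matrices/arrays with validated
#' invariants. A `gray_image` is an H x W integer matrix with values in
#' `[0, 255]`; a `color_image` is an H x W x 3 array with the same bounds
#' per channel; a `binary_mask` is an H x W matrix of 0/1; a `label_map`
#' is an H x W matrix of non-negative integer region labels with label 0
#' reserved for background.
#'
#' @param pixels numeric matrix (or H x W x 3 array for `color_image`).
#' @return An object of the corresponding class, storing integer pixels.
#' @name rasters
NULL

#' @rdname rasters
#' @export
gray_image <- function(pixels) {
  if (!is.matrix(pixels) || nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("gray_image: pixels must be a non-empty matrix")
  p <- as.vector(pixels)
  if (anyNA(p) || any(p < 0 | p > 255))
    stop("gray_image: intensities must lie in [0, 255]")
  if (any(p != round(p)))
    stop("gray_image: intensities must be integers")
  structure(matrix(as.integer(pixels), nrow(pixels), ncol(pixels)),
            class = c("gray_image", "matrix"))
}

#' @rdname rasters
#' @export
color_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("color_image: pixels must be an H x W x 3 array")
  p <- as.vector(pixels)
  if (anyNA(p) || any(p < 0 | p > 255) || any(p != round(p)))
    stop("color_image: channel values must be integers in [0, 255]")
  structure(array(as.integer(pixels), dim(pixels)),
            class = c("color_image", "array"))
}

#' @rdname rasters
#' @export
binary_mask <- function(pixels) {
  if (!is.matrix(pixels)) stop("binary_mask: pixels must be a matrix")
  p <- as.vector(pixels)
  if (anyNA(p) || !all(p %in% c(0, 1)))
    stop("binary_mask: values must be strictly 0/1")
  structure(matrix(as.integer(pixels), nrow(pixels), ncol(pixels)),
            class = c("binary_mask", "matrix"))
}

#' @rdname rasters
#' @export
label_map <- function(pixels) {
  if (!is.matrix(pixels)) stop("label_map: pixels must be a matrix")
  p <- as.vector(pixels)
  if (anyNA(p) || any(p < 0) || any(p != round(p)))
    stop("label_map: labels must be non-negative integers")
  structure(matrix(as.integer(pixels), nrow(pixels), ncol(pixels)),
            class = c("label_map", "matrix"))
}

# Strip the S3 class, returning the bare integer matrix/array.
px <- function(x) {
  if (is.matrix(x)) matrix(as.integer(x), nrow(x), ncol(x)) else unclass(x)
}

#' Relabel a label map so the nonzero labels are contiguous 1..L
#'
#' Empty labels are dropped; ordering of first appearance by numeric label
#' value is preserved. Label 0 (background) is kept as is.
#'
#' @param map a `label_map` (or plain matrix of labels).
#' @return a `label_map` with contiguous labels.
#' @export
compact_labels <- function(map) {
  m <- px(map)
  lv <- sort(unique(m[m > 0L]))
  out <- m
  if (length(lv)) out[m > 0L] <- match(m[m > 0L], lv)
  label_map(out)
}

#' Read an 8-bit PNG or TIFF image
#'
#' Grayscale inputs become a [gray_image]; RGB inputs become a
#' [color_image] (an alpha channel, if present, is dropped). Inputs with a
#' bit depth other than 8 are rejected rather than silently rescaled.
#'
#' @param path path to a PNG or TIFF file.
#' @return a `gray_image` or `color_image`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("read_image: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    x <- png::readPNG(path, info = TRUE)
    depth <- attr(x, "info")$bit.depth
  } else if (ext %in% c("tif", "tiff")) {
    x <- tiff::readTIFF(path, info = TRUE)
    depth <- attr(x, "bits.per.sample")
  } else {
    stop("read_image: unsupported format '", ext, "' (PNG or TIFF only)")
  }
  if (!is.null(depth) && !identical(as.integer(depth), 8L))
    stop("read_image: unsupported bit depth (", depth, "); 8-bit required")
  v <- round(unclass(x) * 255)
  if (length(dim(v)) == 3L) {
    if (dim(v)[3] >= 3L) return(color_image(v[, , 1:3, drop = FALSE]))
    v <- v[, , 1L]
  }
  gray_image(v)
}

#' Write an 8-bit grayscale or RGB image as PNG
#'
#' @param image a [gray_image] or [color_image].
#' @param path output path (PNG).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  png::writePNG(unclass(image) / 255, path)
  invisible(path)
}

#' Convert a color image to gray
#'
#' Uses the ITU-R BT.601 luminance combination
#' `0.299 R + 0.587 G + 0.114 B`, rounded to the nearest integer and
#' clipped to `[0, 255]`. Channel-identical inputs are left unchanged.
#'
#' @param image a [color_image] (a `gray_image` passes through).
#' @return a [gray_image].
#' @export
to_gray <- function(image) {
  if (inherits(image, "gray_image")) return(image)
  if (!inherits(image, "color_image")) stop("to_gray: expected a color_image")
  a <- unclass(image)
  y <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
  gray_image(pmin(pmax(round(y), 0), 255))
}

#' Label map round-trip as 16-bit single-channel TIFF
#'
#' The on-disk format is a 16-bit grayscale TIFF whose sample values are
#' the labels; the round-trip is bit-exact. Maps with more than 65535
#' labels cannot be represented and are rejected.
#'
#' @param map a [label_map].
#' @param path file path (`.tif`/`.tiff`).
#' @return `write_labelmap` returns `path` invisibly; `read_labelmap`
#'   returns a [label_map].
#' @export
write_labelmap <- function(map, path) {
  m <- px(map)
  if (max(m) > 65535L) stop("write_labelmap: more than 65535 labels")
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_labelmap
#' @export
read_labelmap <- function(path) {
  x <- tiff::readTIFF(path, info = TRUE)
  if (!identical(as.integer(attr(x, "bits.per.sample")), 16L))
    stop("read_labelmap: expected a 16-bit TIFF")
  label_map(round(unclass(x) * 65535))
}

#' A single segmented cell: cytoplasm mask, nucleus mask, centroid
#'
#' The nucleus mask must be contained in the cytoplasm mask (the cytoplasm
#' mask covers the whole cell footprint), both must be nonempty, and the
#' centroid must fall inside the cytoplasm bounding box. If `centroid` is
#' `NULL` the cytoplasm centroid is used.
#'
#' @param cytoplasm,nucleus [binary_mask]s of identical shape.
#' @param centroid optional `(row, col)` pair.
#' @return an object of class `cell_instance`.
#' @export
cell_instance <- function(cytoplasm, nucleus, centroid = NULL) {
  cyt <- px(binary_mask(cytoplasm)); nuc <- px(binary_mask(nucleus))
  if (!identical(dim(cyt), dim(nuc)))
    stop("cell_instance: cytoplasm and nucleus shapes differ")
  if (sum(cyt) == 0L || sum(nuc) == 0L)
    stop("cell_instance: masks must be nonempty")
  if (any(nuc > cyt))
    stop("cell_instance: nucleus must be contained in cytoplasm")
  if (is.null(centroid)) centroid <- mask_centroid(cyt)
  bb <- mask_bbox(cyt)
  if (centroid[1] < bb[1] || centroid[1] > bb[2] ||
      centroid[2] < bb[3] || centroid[2] > bb[4])
    stop("cell_instance: centroid outside cytoplasm bounding box")
  structure(list(cytoplasm = binary_mask(cyt), nucleus = binary_mask(nuc),
                 centroid = as.numeric(centroid)),
            class = "cell_instance")
}

mask_centroid <- function(m) {
  idx <- which(m == 1L, arr.ind = TRUE)
  c(mean(idx[, 1]), mean(idx[, 2]))
}

mask_bbox <- function(m) {
  idx <- which(m == 1L, arr.ind = TRUE)
  c(min(idx[, 1]), max(idx[, 1]), min(idx[, 2]), max(idx[, 2]))
}

#' A segmented multicell scene
#'
#' Holds an ordered list of [cell_instance]s plus a background mask.
#' Cytoplasm masks of different cells may overlap each other (overlapping
#' cells are the point), but the background must be disjoint from every
#' cytoplasm mask. With `background = NULL` the complement of the cytoplasm
#' union is used. An empty scene (no cells) is valid and requires an
#' explicit background mask.
#'
#' @param cells list of [cell_instance]s (possibly empty).
#' @param background optional [binary_mask].
#' @return an object of class `scene_segmentation`.
#' @export
scene_segmentation <- function(cells, background = NULL) {
  stopifnot(is.list(cells))
  for (cl in cells) {
    if (!inherits(cl, "cell_instance"))
      stop("scene_segmentation: cells must be cell_instance objects")
  }
  if (length(cells) == 0L) {
    if (is.null(background))
      stop("scene_segmentation: empty scene needs an explicit background")
    bg <- binary_mask(background)
  } else {
    u <- cytoplasm_union(cells)
    if (is.null(background)) {
      bg <- binary_mask(1L - u)
    } else {
      bg <- binary_mask(background)
      if (any(px(bg) == 1L & u == 1L))
        stop("scene_segmentation: background intersects a cytoplasm mask")
    }
  }
  structure(list(cells = cells, background = bg), class = "scene_segmentation")
}

#' Union of the cytoplasm masks of a scene (or cell list)
#'
#' @param x a `scene_segmentation` or list of `cell_instance`s.
#' @return a plain 0/1 integer matrix.
#' @export
cytoplasm_union <- function(x) {
  cells <- if (inherits(x, "scene_segmentation")) x$cells else x
  if (length(cells) == 0L) {
    if (inherits(x, "scene_segmentation")) return(0L * px(x$background))
    stop("cytoplasm_union: no cells and no shape information")
  }
  u <- 0L * px(cells[[1]]$cytoplasm)
  for (cl in cells) u <- pmax(u, px(cl$cytoplasm))
  u
}

#' @export
print.cell_instance <- function(x, ...) {
  cat(sprintf("<cell_instance> cytoplasm %d px, nucleus %d px, centroid (%.1f, %.1f)\n",
              sum(px(x$cytoplasm)), sum(px(x$nucleus)),
              x$centroid[1], x$centroid[2]))
  invisible(x)
}

#' @export
print.scene_segmentation <- function(x, ...) {
  d <- dim(px(x$background))
  cat(sprintf("<scene_segmentation> %d cells, %d x %d\n",
              length(x$cells), d[1], d[2]))
  invisible(x)
}

#' Write / read a scene as a directory of per-cell mask PNGs + manifest
#'
#' Each cell contributes two 8-bit binary PNGs (`cell_<id>_cyto.png`,
#' `cell_<id>_nuc.png`); `manifest.json` records the image size, cell ids,
#' file names and centroids. One mask file per cell is used (rather than a
#' single label map) because overlapping cytoplasm regions cannot share a
#' label plane.
#'
#' @param scene a [scene_segmentation].
#' @param dir output directory (created if needed).
#' @return `write_scene` returns `dir` invisibly; `read_scene` returns a
#'   [scene_segmentation].
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- vector("list", length(scene$cells))
  for (i in seq_along(scene$cells)) {
    cl <- scene$cells[[i]]
    fc <- sprintf("cell_%03d_cyto.png", i)
    fn <- sprintf("cell_%03d_nuc.png", i)
    png::writePNG(px(cl$cytoplasm) * 1.0, file.path(dir, fc))
    png::writePNG(px(cl$nucleus) * 1.0, file.path(dir, fn))
    entries[[i]] <- list(id = i, cytoplasm = fc, nucleus = fn,
                         centroid = round(cl$centroid, 3))
  }
  man <- list(image_size = dim(px(scene$background)),
              n_cells = length(scene$cells), cells = entries)
  writeLines(jsonlite::toJSON(man, auto_unbox = TRUE, digits = NA),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' @rdname write_scene
#' @export
read_scene <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("read_scene: no manifest.json in ", dir)
  man <- jsonlite::fromJSON(mf, simplifyVector = FALSE)
  cells <- lapply(man$cells, function(e) {
    cyt <- round(png::readPNG(file.path(dir, e$cytoplasm)))
    nuc <- round(png::readPNG(file.path(dir, e$nucleus)))
    cell_instance(cyt, nuc, unlist(e$centroid))
  })
  sz <- unlist(man$image_size)
  if (length(cells) == 0L)
    return(scene_segmentation(list(), binary_mask(matrix(1L, sz[1], sz[2]))))
  scene_segmentation(cells)
}
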