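# File formats: multi-page TIFF stacks with JSON geometry sidecars,
# 16-bit label TIFFs, polygon/label-image ROIs, CSV tables.

#' Write / read a 3D stack as multi-page TIFF with a JSON sidecar
#'
#' Intensities are stored as 32-bit float pages normalized to the stack
#' maximum; the sidecar records the voxel pitches and the intensity scale so
#' the round trip is lossless up to float precision.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path; the sidecar is written at
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  a <- stack$data
  off <- min(a)
  sc <- max(max(a) - off, 1e-12)
  pages <- lapply(seq_len(dim(a)[3]), function(k) (a[, , k] - off) / sc)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(voxel_xy = stack$voxel_xy,
                            voxel_z = stack$voxel_z,
                            intensity_scale = sc, intensity_offset = off,
                            shape_xyz = dim(a)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @param path TIFF path written by [write_stack()] (sidecar expected at
#'   `paste0(path, ".json")`, else pitches must be given).
#' @param voxel_xy,voxel_z geometry overrides when no sidecar exists.
#' @return an [image_stack()].
#' @export
read_stack <- function(path, voxel_xy = NULL, voxel_z = NULL) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      stop(sprintf("cannot read TIFF '%s': %s", path,
                                   conditionMessage(e)), call. = FALSE))
  side <- paste0(path, ".json")
  sc <- 1; off <- 0
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    voxel_xy <- meta$voxel_xy; voxel_z <- meta$voxel_z
    sc <- meta$intensity_scale
    if (!is.null(meta$intensity_offset)) off <- meta$intensity_offset
  }
  if (is.null(voxel_xy) || is.null(voxel_z))
    stop(sprintf("no sidecar '%s': voxel_xy and voxel_z must be supplied",
                 side), call. = FALSE)
  a <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) a[, , k] <- pages[[k]] * sc + off
  image_stack(a, voxel_xy, voxel_z)
}

#' Write / read an integer label image (2D or 3D) as 16-bit TIFF
#'
#' Labels up to 65535 survive the round trip exactly.
#'
#' @param labels integer matrix or 3D array of labels (0 = background).
#' @param path TIFF path.
#' @return `path` invisibly; `read_labels()` returns the integer array.
#' @export
write_labels <- function(labels, path) {
  if (max(labels) > 65535L)
    bad_arg("labels", "more than 65535 labels cannot be stored in 16 bits")
  if (min(labels) < 0L) bad_arg("labels", "labels must be >= 0")
  if (is.matrix(labels)) {
    tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  } else {
    pages <- lapply(seq_len(dim(labels)[3]), function(k) labels[, , k] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  }
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      stop(sprintf("cannot read TIFF '%s': %s", path,
                                   conditionMessage(e)), call. = FALSE))
  to_int <- function(m) { m <- round(m * 65535); storage.mode(m) <- "integer"; m }
  if (length(pages) == 1L) return(to_int(pages[[1]]))
  a <- array(0L, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) a[, , k] <- to_int(pages[[k]])
  a
}

#' Write / read an RGB slide image as TIFF
#'
#' @param slide list with `image` (array `x * y * 3`, 0-1) and `mpp`;
#'   `mpp` is stored in a JSON sidecar.
#' @param path TIFF path.
#' @export
write_slide <- function(slide, path) {
  tiff::writeTIFF(slide$image, path, bits.per.sample = 8L)
  jsonlite::write_json(list(mpp = slide$mpp), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_slide
#' @param mpp um/pixel override when no sidecar exists.
#' @export
read_slide <- function(path, mpp = NULL) {
  img <- tryCatch(tiff::readTIFF(path),
                  error = function(e)
                    stop(sprintf("cannot read TIFF '%s': %s", path,
                                 conditionMessage(e)), call. = FALSE))
  side <- paste0(path, ".json")
  if (file.exists(side))
    mpp <- jsonlite::read_json(side, simplifyVector = TRUE)$mpp
  if (is.null(mpp))
    stop(sprintf("no sidecar '%s': mpp must be supplied", side),
         call. = FALSE)
  list(image = img, mpp = mpp)
}

# point-in-polygon by even-odd ray casting, vectorized over query points
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Read ROIs from polygon JSON or a label-image TIFF
#'
#' Polygon JSON is a list of objects with `name` and vertex arrays `x`, `y`
#' in pixel coordinates; polygons are rasterized by pixel-center inclusion.
#' A label TIFF yields one ROI per label, named `roi_<label>` unless a
#' `names` vector is given.
#'
#' @param path `.json` polygon file or label TIFF.
#' @param shape_xy pixel counts of the target image (JSON only).
#' @param mpp um/pixel.
#' @param names optional ROI names for label images.
#' @return list of [roi_region()]s.
#' @export
read_roi <- function(path, shape_xy = NULL, mpp, names = NULL) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (is.null(shape_xy))
      bad_arg("shape_xy", "required to rasterize polygon ROIs")
    polys <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
    lapply(polys, function(p) {
      if (is.null(p$name) || is.null(p$x) || is.null(p$y))
        stop(sprintf("ROI file '%s': each polygon needs fields name, x, y",
                     path), call. = FALSE)
      grid <- expand.grid(x = seq_len(shape_xy[1]), y = seq_len(shape_xy[2]))
      inside <- point_in_polygon(grid$x, grid$y,
                                 as.numeric(p$x), as.numeric(p$y))
      roi_region(p$name, matrix(inside, shape_xy[1], shape_xy[2]), mpp)
    })
  } else {
    lab <- read_labels(path)
    if (!is.matrix(lab))
      bad_arg("path", "label-image ROIs must be single-page (2D)")
    ids <- sort(setdiff(unique(as.vector(lab)), 0L))
    lapply(seq_along(ids), function(i) {
      nm <- if (!is.null(names)) names[i] else sprintf("roi_%d", ids[i])
      roi_region(nm, lab == ids[i], mpp)
    })
  }
}

#' Write / read a results table as CSV
#'
#' Plain CSV with a header, no row names; types and column order round-trip.
#'
#' @param x data frame.
#' @param path CSV path.
#' @export
write_table_csv <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  if (!file.exists(path))
    stop(sprintf("no such table: '%s'", path), call. = FALSE)
  read.csv(path, stringsAsFactors = FALSE)
}
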