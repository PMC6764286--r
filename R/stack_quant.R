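#' Preprocess a 3D stack: background subtraction and smoothing
#'
#' Subtracts a per-slice grayscale-opening background estimate (the
#' rolling-ball idea realized as an opening with a disc structuring element
#' of the given physical radius) and then applies 3D Gaussian smoothing.
#' Sigmas and radii are given in um and converted per axis, which matters
#' because axial pitch typically exceeds in-plane pitch (1.5 vs 0.592 um).
#' With `smoothing_sigma = 0` and `background_radius = 0` the function is
#' the identity.
#'
#' @param stack an [image_stack()].
#' @param smoothing_sigma Gaussian sigma, um (default 1).
#' @param background_radius opening disc radius, um (default 20); 0 disables
#'   background subtraction.
#' @return an [image_stack()] with the same geometry.
#' @export
preprocess_stack <- function(stack, smoothing_sigma = 1, background_radius = 20) {
  stopifnot(inherits(stack, "image_stack"))
  if (smoothing_sigma < 0) bad_arg("smoothing_sigma", "must be >= 0")
  if (background_radius < 0) bad_arg("background_radius", "must be >= 0")
  a <- stack$data
  if (any(!is.finite(a)))
    bad_arg("stack", "voxel intensities must all be finite")
  if (background_radius > 0) {
    r_px <- max(1L, round(background_radius / stack$voxel_xy))
    brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
    # opening removes structures smaller than the disc; what remains is the
    # slowly-varying background (per slice, since z-pitch is coarse)
    rng <- range(a)
    scaled <- if (diff(rng) > 0) (a - rng[1]) / diff(rng) else a * 0
    bg <- EBImage::imageData(EBImage::opening(EBImage::Image(scaled), brush))
    a <- (scaled - bg) * diff(rng)  # back on the original intensity scale
    a[a < 0] <- 0
  }
  if (smoothing_sigma > 0) {
    a <- gauss_smooth_3d(a, c(smoothing_sigma / stack$voxel_xy,
                              smoothing_sigma / stack$voxel_xy,
                              smoothing_sigma / stack$voxel_z))
  }
  image_stack(a, stack$voxel_xy, stack$voxel_z)
}

#' Detect individual cells in a 3D stack
#'
#' Segments bright cells from a (preferably preprocessed) stack: global
#' threshold (Otsu by default), 26-connected component labelling, optional
#' watershed splitting of touching cells seeded at intensity maxima that are
#' separated by at least an h-maxima depth, and a minimum-volume filter.
#'
#' @param stack an [image_stack()], typically from [preprocess_stack()].
#' @param threshold_method `"otsu"` (global Otsu on the intensity
#'   histogram) or `"fixed"` (use `threshold`).
#' @param threshold fixed intensity threshold when
#'   `threshold_method = "fixed"`.
#' @param min_volume minimum cell volume, um^3; smaller objects are
#'   discarded (default 150).
#' @param split_touching when `TRUE` (default), connected foreground
#'   components containing k intensity maxima separated by depth `h_frac`
#'   times the foreground dynamic range are split into k cells by seeded
#'   watershed.
#' @param h_frac h-maxima depth as a fraction of the foreground dynamic
#'   range (default 0.10).
#' @param connectivity 26 (default) or 6, for component labelling.
#' @return an object of class `cell_set`: list with `cells`, a data frame of
#'   per-cell records (`label`, centroid `x_um`/`y_um`/`z_um`, `n_voxels`,
#'   `size_um3`, `on_border`), the integer `labels` array, and the geometry.
#'   A constant (unthresholdable) stack yields zero cells, not an error.
#' @export
detect_cells_3d <- function(stack, threshold_method = c("otsu", "fixed"),
                            threshold = NULL, min_volume = 150,
                            split_touching = TRUE, h_frac = 0.10,
                            connectivity = 26L) {
  stopifnot(inherits(stack, "image_stack"))
  threshold_method <- match.arg(threshold_method)
  if (min_volume <= 0) bad_arg("min_volume", "must be > 0")
  a <- stack$data
  if (length(a) == 0) bad_arg("stack", "empty stack")
  if (any(!is.finite(a))) bad_arg("stack", "voxel intensities must be finite")

  thr <- if (threshold_method == "fixed") {
    if (is.null(threshold)) bad_arg("threshold", "required for method 'fixed'")
    threshold
  } else {
    th <- otsu_threshold(a)
    # signal-presence guard: on a noise-only image Otsu merely splits the
    # noise distribution; require the threshold to clear the bulk of the
    # intensity distribution by a robust margin before calling anything
    # foreground
    if (!is.na(th) && th <= stats::median(a) + 3 * stats::mad(a)) NA_real_
    else th
  }
  d <- dim(a)
  empty <- function() {
    structure(list(
      cells = data.frame(label = integer(0), x_um = numeric(0),
                         y_um = numeric(0), z_um = numeric(0),
                         n_voxels = integer(0), size_um3 = numeric(0),
                         on_border = logical(0)),
      labels = array(0L, d), voxel_xy = stack$voxel_xy,
      voxel_z = stack$voxel_z), class = "cell_set")
  }
  if (is.na(thr)) return(empty())  # constant image: nothing to segment
  mask <- a > thr
  if (!any(mask)) return(empty())

  lab <- .cc_label_3d(as.logical(mask), dims = d,
                      connectivity = as.integer(connectivity))
  if (split_touching && max(lab) > 0L) {
    fg <- a[mask]
    h <- h_frac * (max(fg) - min(fg))
    lab <- split_components_3d(a, lab, h)
  }

  nlab <- max(lab)
  if (nlab == 0L) return(empty())
  vox_vol <- voxel_volume_um3(stack)
  counts <- tabulate(lab[lab > 0L], nlab)
  keep <- which(counts * vox_vol >= min_volume)
  if (length(keep) == 0L) return(empty())

  # relabel kept cells 1..k and gather per-cell geometry
  remap <- integer(nlab); remap[keep] <- seq_along(keep)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  idx <- which(lab > 0L)
  lv <- lab[idx]
  ai <- arrayInd(idx, d)
  x_um <- voxel_to_um(ai[, 1], stack$voxel_xy)
  y_um <- voxel_to_um(ai[, 2], stack$voxel_xy)
  z_um <- voxel_to_um(ai[, 3], stack$voxel_z)
  n_vox <- tabulate(lv, length(keep))
  border <- ai[, 1] == 1L | ai[, 1] == d[1] | ai[, 2] == 1L |
    ai[, 2] == d[2] | ai[, 3] == 1L | ai[, 3] == d[3]
  cells <- data.frame(
    label = seq_along(keep),
    x_um = as.numeric(tapply(x_um, lv, mean)),
    y_um = as.numeric(tapply(y_um, lv, mean)),
    z_um = as.numeric(tapply(z_um, lv, mean)),
    n_voxels = n_vox,
    size_um3 = n_vox * vox_vol,
    on_border = as.logical(tapply(border, lv, any)))
  structure(list(cells = cells, labels = lab, voxel_xy = stack$voxel_xy,
                 voxel_z = stack$voxel_z), class = "cell_set")
}

#' @export
print.cell_set <- function(x, ...) {
  cat(sprintf("<cell_set> %d cells; %d on border; median size %.0f um^3\n",
              nrow(x$cells), sum(x$cells$on_border),
              if (nrow(x$cells)) stats::median(x$cells$size_um3) else NA))
  invisible(x)
}

# Split connected 3D components that contain several intensity maxima
# separated by at least depth h (h-maxima), via seeded region growing from
# the maxima in decreasing-intensity order. Components with a single
# dominant maximum are left whole. Returns a relabelled integer array.
split_components_3d <- function(a, lab, h) {
  d <- dim(a)
  ncomp <- max(lab)
  idx_all <- which(lab > 0L)
  by_comp <- split(idx_all, lab[idx_all])
  out <- array(0L, d)
  next_lab <- 0L

  # 26-neighbour shifts of a local 3D array, -Inf padded
  shifts <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  shifts <- shifts[!(shifts$dx == 0 & shifts$dy == 0 & shifts$dz == 0), ]
  shift3 <- function(m, dl, dx, dy, dz, fill = -Inf) {
    outm <- array(fill, dl)
    sx <- max(1, 1 + dx):min(dl[1], dl[1] + dx)
    sy <- max(1, 1 + dy):min(dl[2], dl[2] + dy)
    sz <- max(1, 1 + dz):min(dl[3], dl[3] + dz)
    outm[sx, sy, sz] <- m[sx - dx, sy - dy, sz - dz]
    outm
  }
  nbr_max <- function(m, dl) {
    acc <- array(-Inf, dl)
    for (s in seq_len(nrow(shifts)))
      acc <- pmax(acc, shift3(m, dl, shifts$dx[s], shifts$dy[s],
                              shifts$dz[s]))
    acc
  }

  for (ci in seq_along(by_comp)) {
    idx <- by_comp[[ci]]
    ai <- arrayInd(idx, d)
    lo <- pmax(apply(ai, 2, min) - 1L, 1L)
    hi <- pmin(apply(ai, 2, max) + 1L, d)
    dl <- hi - lo + 1L
    vals <- array(-Inf, dl)
    loc <- cbind(ai[, 1] - lo[1] + 1L, ai[, 2] - lo[2] + 1L,
                 ai[, 3] - lo[3] + 1L)
    lin_loc <- loc[, 1] + dl[1] * (loc[, 2] - 1L) +
      dl[1] * dl[2] * (loc[, 3] - 1L)
    vals[lin_loc] <- a[idx]
    comp_mask <- array(FALSE, dl); comp_mask[lin_loc] <- TRUE

    # morphological reconstruction of (vals - h) under vals
    rec <- vals - h
    repeat {
      rec2 <- pmin(vals, pmax(rec, nbr_max(rec, dl)))
      if (max(abs(rec2[lin_loc] - rec[lin_loc])) < 1e-9) break
      rec <- rec2
    }
    rmax <- (rec >= nbr_max(rec, dl) - 1e-9) & comp_mask
    seeds <- .cc_label_3d(as.logical(rmax), dims = dl, connectivity = 26L)
    k <- max(seeds)

    if (k <= 1L) {
      out[idx] <- next_lab + 1L
      next_lab <- next_lab + 1L
      next
    }
    # grow seed labels over the component, highest-intensity neighbour first
    labs <- seeds
    labs[!comp_mask] <- 0L
    while (any(labs[lin_loc] == 0L)) {
      best_val <- array(-Inf, dl)
      best_lab <- array(0L, dl)
      for (s in seq_len(nrow(shifts))) {
        nl <- shift3(labs, dl, shifts$dx[s], shifts$dy[s], shifts$dz[s],
                     fill = 0L)
        nv <- shift3(vals, dl, shifts$dx[s], shifts$dy[s], shifts$dz[s])
        take <- nl > 0L & nv > best_val
        best_val[take] <- nv[take]
        best_lab[take] <- nl[take]
      }
      newly <- comp_mask & labs == 0L & best_lab > 0L
      if (!any(newly)) break  # unreachable voxels (shouldn't happen)
      labs[newly] <- best_lab[newly]
    }
    out[idx] <- ifelse(labs[lin_loc] > 0L, next_lab + labs[lin_loc],
                       next_lab + 1L)
    next_lab <- next_lab + k
  }
  out
}

#' Volumetric cell density of a stack
#'
#' Density is the total number of cells divided by the image volume, where
#' the volume is the product of axis extents (voxel count times physical
#' pitch per axis).
#'
#' @param n_cells cell count (>= 0).
#' @param stack an [image_stack()] supplying the geometry.
#' @param animal_id,region optional identifiers carried into the record.
#' @return one-row data frame: `animal_id`, `region`, `n_cells`,
#'   `volume_mm3`, `density_per_mm3`.
#' @examples
#' st <- image_stack(array(0, c(1024, 1024, 100)), 0.592, 1.5)
#' compute_density(100, st)$density_per_mm3  # about 1814 cells/mm^3
#' @export
compute_density <- function(n_cells, stack, animal_id = NA_character_,
                            region = NA_character_) {
  if (n_cells < 0) bad_arg("n_cells", "must be >= 0")
  v <- stack_volume_mm3(stack)
  data.frame(animal_id = animal_id, region = region, n_cells = n_cells,
             volume_mm3 = v, density_per_mm3 = n_cells / v)
}

#' Areal cell density of a single-plane image
#'
#' 2D variant for spinal-cord sections: the total number of cells divided by
#' the image area.
#'
#' @param n_cells cell count (>= 0).
#' @param shape_xy pixel counts, length-2.
#' @param mpp pixel pitch, um/pixel.
#' @param animal_id,region optional identifiers.
#' @return one-row data frame: `animal_id`, `region`, `n_cells`, `area_mm2`,
#'   `density_per_mm2`.
#' @examples
#' compute_density_2d(200, c(1024, 1024), 2.3649)$density_per_mm2
#' @export
compute_density_2d <- function(n_cells, shape_xy, mpp,
                               animal_id = NA_character_,
                               region = NA_character_) {
  if (n_cells < 0) bad_arg("n_cells", "must be >= 0")
  if (length(shape_xy) != 2L || any(shape_xy < 1))
    bad_arg("shape_xy", "must be two pixel counts >= 1")
  if (mpp <= 0) bad_arg("mpp", "must be > 0")
  area_mm2 <- (shape_xy[1] * mpp) * (shape_xy[2] * mpp) / 1e6
  if (area_mm2 <= 0) bad_arg("shape_xy", "zero image area")
  data.frame(animal_id = animal_id, region = region, n_cells = n_cells,
             area_mm2 = area_mm2, density_per_mm2 = n_cells / area_mm2)
}

#' Physical size of a detected cell
#'
#' Cell size is the voxel count of the cell mask (soma plus processes)
#' times the single-voxel volume `voxel_xy^2 * voxel_z`, in um^3.
#'
#' @param cell either a logical 3D mask array, or an integer voxel count.
#' @param voxel_xy in-plane pitch, um/pixel.
#' @param voxel_z axial pitch, um/slice.
#' @return size in um^3.
#' @examples
#' measure_cell_size(1L, 0.592, 1.5)  # single voxel: 0.592^2 * 1.5
#' @export
measure_cell_size <- function(cell, voxel_xy, voxel_z) {
  if (voxel_xy <= 0 || voxel_z <= 0)
    bad_arg("voxel_xy/voxel_z", "pitches must be > 0")
  n <- if (is.array(cell)) sum(cell != 0) else as.numeric(cell)
  if (length(n) != 1L || is.na(n) || n <= 0)
    bad_arg("cell", "voxel set must be non-empty")
  n * voxel_xy^2 * voxel_z
}
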