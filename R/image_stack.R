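#' 3D image stack with physical voxel geometry
#'
#' Container for a 3D grayscale voxel grid plus its physical voxel pitches,
#' the carrier for two-photon microscopy data. Intensities are arbitrary
#' units; geometry is in-plane pitch `voxel_xy` (um/pixel, equal along x and
#' y) and axial pitch `voxel_z` (um/slice).
#'
#' @param data numeric 3D array indexed `[x, y, z]`.
#' @param voxel_xy in-plane voxel pitch, um/pixel (> 0).
#' @param voxel_z axial voxel pitch, um/slice (> 0).
#' @return an object of class `image_stack`: a list with elements `data`,
#'   `voxel_xy`, `voxel_z`.
#' @examples
#' st <- image_stack(array(0, c(8, 8, 4)), voxel_xy = 0.592, voxel_z = 1.5)
#' stack_volume_mm3(st)
#' @export
image_stack <- function(data, voxel_xy, voxel_z) {
  if (!is.array(data) || length(dim(data)) != 3L)
    bad_arg("data", "must be a 3D array")
  if (any(dim(data) < 1L)) bad_arg("data", "all dimensions must be >= 1")
  if (!is.numeric(voxel_xy) || length(voxel_xy) != 1L || voxel_xy <= 0)
    bad_arg("voxel_xy", "must be a single positive number (um/pixel)")
  if (!is.numeric(voxel_z) || length(voxel_z) != 1L || voxel_z <= 0)
    bad_arg("voxel_z", "must be a single positive number (um/slice)")
  structure(list(data = data, voxel_xy = voxel_xy, voxel_z = voxel_z),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d x %d x %d voxels @ %.4g um/px, %.4g um/slice\n",
              d[1], d[2], d[3], x$voxel_xy, x$voxel_z))
  cat(sprintf("  extent: %.1f x %.1f x %.1f um; intensity range [%.3g, %.3g]\n",
              d[1] * x$voxel_xy, d[2] * x$voxel_xy, d[3] * x$voxel_z,
              min(x$data), max(x$data)))
  invisible(x)
}

#' Physical volume of a stack
#'
#' Image volume as the product of axis extents (voxel count times pitch per
#' axis), the denominator of volumetric cell density.
#'
#' @param stack an [image_stack()].
#' @return volume in mm^3.
#' @export
stack_volume_mm3 <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  v_um3 <- (d[1] * stack$voxel_xy) * (d[2] * stack$voxel_xy) * (d[3] * stack$voxel_z)
  if (v_um3 <= 0) bad_arg("stack", "zero physical volume")
  v_um3 / 1e9
}

# physical coordinate (um) of a 1-based voxel index: voxel centers sit at
# (i - 1) * pitch + pitch / 2
voxel_to_um <- function(i, pitch) (i - 0.5) * pitch
um_to_voxel <- function(u, pitch) pmax(1L, as.integer(round(u / pitch + 0.5)))

# per-voxel volume in um^3
voxel_volume_um3 <- function(stack) stack$voxel_xy^2 * stack$voxel_z
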