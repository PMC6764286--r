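#' Specification for a synthetic two-photon stack
#'
#' Describes a 3D fluorescence stack of sparse, bright soma-plus-process
#' cells over a noisy constant background, mimicking in vivo/ex vivo imaging
#' of GFP-labelled microglia. Defaults use the acquisition geometry of
#' two-photon microglia imaging (0.592 um/pixel in plane, 1.5 um z-step)
#' at a desk-scale field of view, with a signal-to-noise ratio
#' (`foreground_intensity / noise_sd`) of 5.
#'
#' @param shape_xyz integer triple, voxel counts per axis.
#' @param voxel_xy in-plane pitch, um/pixel.
#' @param voxel_z axial pitch, um/slice.
#' @param n_cells number of cells to place (>= 0).
#' @param soma_radius_range um pair; soma radii drawn uniformly in range.
#' @param n_processes_range integer pair, processes per cell.
#' @param process_length_range um pair, process length.
#' @param process_radius um, process thickness (single value).
#' @param min_separation um, minimum pairwise centroid distance. Must
#'   exceed twice the maximum soma radius when `n_cells > 1`.
#' @param foreground_intensity soma peak intensity, arbitrary units.
#' @param background_level constant background, arbitrary units.
#' @param noise_sd additive Gaussian noise SD, arbitrary units.
#' @return a `stack_spec` list.
#' @seealso [generate_stack()]
#' @export
stack_spec <- function(shape_xyz = c(384L, 384L, 64L),
                       voxel_xy = 0.592,
                       voxel_z = 1.5,
                       n_cells = 50L,
                       soma_radius_range = c(3.5, 5),
                       n_processes_range = c(2L, 6L),
                       process_length_range = c(8, 15),
                       process_radius = 0.5,
                       min_separation = 30,
                       foreground_intensity = 100,
                       background_level = 10,
                       noise_sd = 20) {
  spec <- list(shape_xyz = as.integer(shape_xyz), voxel_xy = voxel_xy,
               voxel_z = voxel_z, n_cells = as.integer(n_cells),
               soma_radius_range = as.numeric(soma_radius_range),
               n_processes_range = as.integer(n_processes_range),
               process_length_range = as.numeric(process_length_range),
               process_radius = process_radius,
               min_separation = min_separation,
               foreground_intensity = foreground_intensity,
               background_level = background_level, noise_sd = noise_sd)
  validate_stack_spec(spec)
  structure(spec, class = "stack_spec")
}

validate_stack_spec <- function(spec) {
  if (length(spec$shape_xyz) != 3L || any(spec$shape_xyz < 1L))
    bad_arg("shape_xyz", "must be three voxel counts >= 1")
  if (spec$voxel_xy <= 0 || spec$voxel_z <= 0)
    bad_arg("voxel_xy/voxel_z", "voxel pitches must be > 0")
  if (spec$n_cells < 0L) bad_arg("n_cells", "must be >= 0")
  if (any(spec$soma_radius_range <= 0) || diff(spec$soma_radius_range) < 0)
    bad_arg("soma_radius_range", "must be increasing positive um pair")
  if (spec$n_cells > 1L && spec$min_separation <= 2 * max(spec$soma_radius_range))
    bad_arg("min_separation",
            "must exceed twice the maximum soma radius when n_cells > 1")
  if (any(spec$n_processes_range < 0L) || diff(spec$n_processes_range) < 0)
    bad_arg("n_processes_range", "must be a non-decreasing count pair")
  if (any(spec$process_length_range <= 0) || diff(spec$process_length_range) < 0)
    bad_arg("process_length_range", "must be increasing positive um pair")
  if (spec$process_radius <= 0) bad_arg("process_radius", "must be > 0")
  if (spec$noise_sd < 0) bad_arg("noise_sd", "must be >= 0")
  if (spec$foreground_intensity <= 0)
    bad_arg("foreground_intensity", "must be > 0")
  invisible(spec)
}

# Draw n points uniformly in a box [lo, hi]^3 (um) with pairwise distance
# >= min_sep, by rejection sampling with a hard attempt cap.
place_centroids <- function(n, lo, hi, min_sep, max_attempts = 10000L) {
  pts <- matrix(numeric(0), ncol = 3)
  attempts <- 0L
  while (nrow(pts) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop(sprintf(paste0("could not place %d centroids at min_separation ",
                          "%.3g um within %d attempts; spec is infeasible"),
                   n, min_sep, max_attempts), call. = FALSE)
    p <- lo + runif(3) * (hi - lo)
    if (nrow(pts) == 0 ||
        min(sqrt(colSums((t(pts) - p)^2))) >= min_sep)
      pts <- rbind(pts, p)
  }
  pts
}

# Linear indices of the voxels of a solid ball (um coordinates) by
# pixel-center inclusion. The caller assigns into its own array so no large
# copies are triggered.
ball_indices <- function(d, center_um, radius_um, voxel_xy, voxel_z) {
  ix <- max(1L, floor((center_um[1] - radius_um) / voxel_xy)):
        min(d[1], ceiling((center_um[1] + radius_um) / voxel_xy) + 1L)
  iy <- max(1L, floor((center_um[2] - radius_um) / voxel_xy)):
        min(d[2], ceiling((center_um[2] + radius_um) / voxel_xy) + 1L)
  iz <- max(1L, floor((center_um[3] - radius_um) / voxel_z)):
        min(d[3], ceiling((center_um[3] + radius_um) / voxel_z) + 1L)
  dx2 <- (voxel_to_um(ix, voxel_xy) - center_um[1])^2
  dy2 <- (voxel_to_um(iy, voxel_xy) - center_um[2])^2
  dz2 <- (voxel_to_um(iz, voxel_z) - center_um[3])^2
  inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= radius_um^2
  lin <- outer(outer(ix, (iy - 1L) * d[1], `+`),
               (iz - 1L) * d[1] * d[2], `+`)
  lin[inside]
}

#' Generate a synthetic 3D stack with known cell ground truth
#'
#' Renders `n_cells` cells — a soma ball plus thin radiating processes —
#' at rejection-sampled positions respecting `min_separation`, applies a
#' light Gaussian blur so objects have smooth intensity profiles, then adds
#' constant background and Gaussian noise. The generator is a pure function
#' of `(spec, seed)`.
#'
#' @param spec a [stack_spec()].
#' @param seed integer seed; identical `(spec, seed)` give bit-identical
#'   output.
#' @return list with `stack` (an [image_stack()]) and `truth`, a data frame
#'   with one row per rendered cell: `cell_id`, centroid `x_um`, `y_um`,
#'   `z_um`, `soma_radius_um`, `n_processes`, and the analytic
#'   `true_volume_um3` (soma ball plus process cylinders).
#' @examples
#' sp <- stack_spec(shape_xyz = c(64, 64, 16), n_cells = 3, min_separation = 15)
#' g <- generate_stack(sp, seed = 1)
#' nrow(g$truth)
#' @export
generate_stack <- function(spec, seed) {
  validate_stack_spec(spec)
  with_seed(seed, {
    d <- spec$shape_xyz
    ext <- c(d[1] * spec$voxel_xy, d[2] * spec$voxel_xy, d[3] * spec$voxel_z)
    a <- array(0, d)
    truth <- data.frame(cell_id = integer(0), x_um = numeric(0),
                        y_um = numeric(0), z_um = numeric(0),
                        soma_radius_um = numeric(0), n_processes = integer(0),
                        true_volume_um3 = numeric(0))
    if (spec$n_cells > 0L) {
      margin <- max(spec$soma_radius_range)
      if (any(ext <= 2 * margin))
        stop("stack too small to contain a soma; spec is infeasible",
             call. = FALSE)
      cen <- place_centroids(spec$n_cells, lo = rep(margin, 3),
                             hi = ext - margin,
                             min_sep = spec$min_separation)
      radii <- runif(spec$n_cells, spec$soma_radius_range[1],
                     spec$soma_radius_range[2])
      n_proc <- if (diff(spec$n_processes_range) == 0L)
        rep(spec$n_processes_range[1], spec$n_cells)
      else sample(spec$n_processes_range[1]:spec$n_processes_range[2],
                  spec$n_cells, replace = TRUE)
      vols <- numeric(spec$n_cells)
      for (i in seq_len(spec$n_cells)) {
        soma_idx <- ball_indices(d, cen[i, ], radii[i],
                                 spec$voxel_xy, spec$voxel_z)
        a[soma_idx] <- spec$foreground_intensity
        proc_len <- 0
        proc_idx <- vector("list", n_proc[i])
        for (j in seq_len(n_proc[i])) {
          # isotropic random direction
          v <- rnorm(3); v <- v / sqrt(sum(v^2))
          len <- runif(1, spec$process_length_range[1],
                       spec$process_length_range[2])
          proc_len <- proc_len + len
          ts <- seq(0.8 * radii[i], radii[i] + len, by = 0.3)
          seg <- vector("list", length(ts))
          for (k in seq_along(ts)) {
            p <- cen[i, ] + ts[k] * v
            if (any(p < 0) || any(p > ext)) break
            seg[[k]] <- ball_indices(d, p, spec$process_radius,
                                     spec$voxel_xy, spec$voxel_z)
          }
          proc_idx[[j]] <- unlist(seg)
        }
        proc_idx <- setdiff(unique(unlist(proc_idx)), soma_idx)
        a[proc_idx] <- pmax(a[proc_idx], 0.6 * spec$foreground_intensity)
        vols[i] <- 4 / 3 * pi * radii[i]^3 +
          pi * spec$process_radius^2 * proc_len
      }
      truth <- data.frame(cell_id = seq_len(spec$n_cells),
                          x_um = cen[, 1], y_um = cen[, 2], z_um = cen[, 3],
                          soma_radius_um = radii, n_processes = n_proc,
                          true_volume_um3 = vols)
      # soft render blur so somas have smooth unimodal profiles
      a <- gauss_smooth_3d(a, c(0.4 / spec$voxel_xy, 0.4 / spec$voxel_xy,
                                0.4 / spec$voxel_z))
    }
    a <- a + spec$background_level
    if (spec$noise_sd > 0)
      a <- a + array(rnorm(length(a), 0, spec$noise_sd), d)
    list(stack = image_stack(a, spec$voxel_xy, spec$voxel_z), truth = truth)
  })
}
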