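# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All generators route their randomness through this so that identical
# (spec, seed) pairs are bit-identical and callers' RNG streams are untouched.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# Global Otsu threshold from a 256-bin histogram of `x` (any numeric range).
# Returns the threshold on the original intensity scale. For a constant
# image there is no inter-class variance to maximize; returns NA.
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) <= 0) return(NA_real_)
  h <- tabulate(pmin(n_bins, floor((x - r[1]) / diff(r) * n_bins) + 1L), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- r[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(r)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b2 <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  k <- which.max(sigma_b2)
  r[1] + k / n_bins * diff(r)
}

# Otsu inter-class variance at the optimal split; used as a scalar measure
# of foreground/background separability.
otsu_separation <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) <= 0) return(0)
  h <- tabulate(pmin(n_bins, floor((x - r[1]) / diff(r) * n_bins) + 1L), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- r[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(r)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b2 <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  # normalize by total variance so the measure is scale-free
  v <- sum(p * (mids - mu_t)^2)
  if (v <= 0) return(0)
  max(sigma_b2) / v
}

# Separable 3D Gaussian smoothing with per-axis sigma in voxels
# (replicate boundary); the convolution runs in compiled code.
gauss_smooth_3d <- function(a, sigma_vox) {
  stopifnot(length(dim(a)) == 3L, length(sigma_vox) == 3L)
  if (all(sigma_vox <= 0)) return(a)
  .gauss_smooth_3d(as.numeric(a), dim(a), as.numeric(sigma_vox))
}

# Rasterize a solid ball of radius `radius_um` on a voxel grid with pitches
# (voxel_xy, voxel_xy, voxel_z) um. A voxel belongs to the ball when its
# center lies within the radius. Returns a logical 3D array just covering
# the ball. Used for resolution-convergence checks of size measurement.
#' Rasterize a ball on an anisotropic voxel grid
#'
#' Builds a logical 3D mask of a solid sphere using pixel-center inclusion,
#' the same convention the detector uses for voxel sets. Mainly useful for
#' validating volume measurement against the analytic sphere volume
#' \eqn{4/3 \pi r^3}.
#'
#' @param radius_um ball radius, um.
#' @param voxel_xy in-plane voxel pitch, um/pixel.
#' @param voxel_z axial pitch, um/slice (defaults to `voxel_xy`).
#' @return logical 3D array; `sum()` times the single-voxel volume
#'   approximates the analytic ball volume.
#' @examples
#' m <- rasterize_ball(10, 0.5)
#' sum(m) * 0.5^3 / (4 / 3 * pi * 1000)  # close to 1
#' @export
rasterize_ball <- function(radius_um, voxel_xy, voxel_z = voxel_xy) {
  stopifnot(radius_um > 0, voxel_xy > 0, voxel_z > 0)
  nx <- 2L * ceiling(radius_um / voxel_xy) + 3L
  nz <- 2L * ceiling(radius_um / voxel_z) + 3L
  cx <- (nx + 1) / 2; cz <- (nz + 1) / 2
  x <- ((seq_len(nx)) - cx) * voxel_xy
  z <- ((seq_len(nz)) - cz) * voxel_z
  d2 <- outer(outer(x^2, x^2, `+`), z^2, `+`)
  array(d2 <= radius_um^2, c(nx, nx, nz))
}

# stop() with a consistent prefix naming the offending field
bad_arg <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}
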