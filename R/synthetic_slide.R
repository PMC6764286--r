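# Synthetic brightfield IHC slides: DAB-brown positive cell bodies over
# hematoxylin-tinted tissue on a white background, with a configurable
# fraction of cells placed as touching pairs whose intensity landscape
# keeps two local minima (so minima-controlled watershed can split them).

#' Specification for a synthetic chromogenic IHC slide
#'
#' @param shape_xy pixel counts, length-2.
#' @param mpp um/pixel (default 0.46, a 200x whole-slide scan).
#' @param tissue_fraction fraction of the image covered by tissue, in (0, 1].
#' @param n_positive_cells number of stained cells (>= 0).
#' @param cell_radius_range um pair, visible cell-body radius.
#' @param touching_pair_fraction fraction of cells placed as touching pairs,
#'   in `[0, 1]`; pairs overlap in the stain mask but retain two intensity
#'   minima.
#' @param stain_color RGB triple in `[0, 1]`, the positive (DAB brown) stain.
#' @param counterstain_color RGB triple, the tissue counterstain
#'   (hematoxylin).
#' @param noise_sd per-channel Gaussian noise SD on the 0-1 scale.
#' @return a `slide_spec` list.
#' @seealso [generate_ihc_slide()]
#' @export
slide_spec <- function(shape_xy = c(1024L, 1024L),
                       mpp = 0.46,
                       tissue_fraction = 0.6,
                       n_positive_cells = 100L,
                       cell_radius_range = c(4, 6.5),
                       touching_pair_fraction = 0.2,
                       stain_color = c(0.45, 0.24, 0.10),
                       counterstain_color = c(0.62, 0.60, 0.78),
                       noise_sd = 0.015) {
  spec <- list(shape_xy = as.integer(shape_xy), mpp = mpp,
               tissue_fraction = tissue_fraction,
               n_positive_cells = as.integer(n_positive_cells),
               cell_radius_range = as.numeric(cell_radius_range),
               touching_pair_fraction = touching_pair_fraction,
               stain_color = stain_color,
               counterstain_color = counterstain_color,
               noise_sd = noise_sd)
  validate_slide_spec(spec)
  structure(spec, class = "slide_spec")
}

validate_slide_spec <- function(spec) {
  if (length(spec$shape_xy) != 2L || any(spec$shape_xy < 8L))
    bad_arg("shape_xy", "must be two pixel counts >= 8")
  if (spec$mpp <= 0) bad_arg("mpp", "must be > 0")
  if (spec$tissue_fraction <= 0 || spec$tissue_fraction > 1)
    bad_arg("tissue_fraction", "must be in (0, 1]")
  if (spec$n_positive_cells < 0L) bad_arg("n_positive_cells", "must be >= 0")
  if (spec$touching_pair_fraction < 0 || spec$touching_pair_fraction > 1)
    bad_arg("touching_pair_fraction", "must be in [0, 1]")
  if (any(spec$cell_radius_range <= 0) || diff(spec$cell_radius_range) < 0)
    bad_arg("cell_radius_range", "must be increasing positive um pair")
  if (length(spec$stain_color) != 3L || any(spec$stain_color < 0) ||
      any(spec$stain_color > 1) || all(spec$stain_color > 0.98))
    bad_arg("stain_color", "must be a non-white RGB triple in [0, 1]")
  invisible(spec)
}

# Organic tissue mask: threshold a smoothed random field at the quantile
# that yields the requested coverage fraction.
random_tissue_mask <- function(shape_xy, fraction) {
  if (fraction >= 1) return(matrix(TRUE, shape_xy[1], shape_xy[2]))
  coarse <- matrix(rnorm(144), 12, 12)
  f <- EBImage::imageData(EBImage::resize(EBImage::Image(coarse),
                                          w = shape_xy[1], h = shape_xy[2]))
  f >= quantile(f, 1 - fraction)
}

# stamp max(weight) of a radial profile w(d) = 1 - (d/r)^2 onto W
stamp_profile <- function(W, cx, cy, r_px) {
  d <- dim(W)
  ix <- max(1L, floor(cx - r_px)):min(d[1], ceiling(cx + r_px))
  iy <- max(1L, floor(cy - r_px)):min(d[2], ceiling(cy + r_px))
  w <- outer((ix - cx)^2, (iy - cy)^2, `+`) / r_px^2
  w <- pmax(0, 1 - w)
  W[ix, iy] <- pmax(W[ix, iy], w)
  W
}

#' Generate a synthetic IHC slide with known positive-cell ground truth
#'
#' Renders tissue as a counterstain-tinted organic region on a white
#' background and positive cells as radially shaded stain-coloured bodies
#' (darkest at the center, so each cell is one intensity minimum). A
#' `touching_pair_fraction` of cells are placed as pairs at 1.3 cell radii
#' separation: their stain masks merge into one connected component while
#' the intensity landscape keeps two minima basins. Pure function of
#' `(spec, seed)`.
#'
#' @param spec a [slide_spec()].
#' @param seed integer seed.
#' @return list with `image` (numeric array `x * y * 3`, RGB in 0-1),
#'   `mpp`, `truth` (data frame: `cell_id`, `x_px`, `y_px`, `x_um`, `y_um`,
#'   `radius_um`, `pair_id` — 0 for singletons), `tissue_mask` (logical),
#'   and `stain_mask` (logical; pixels where the stain contributes at least
#'   half the blend).
#' @export
generate_ihc_slide <- function(spec, seed) {
  validate_slide_spec(spec)
  with_seed(seed, {
    d <- spec$shape_xy
    tissue <- random_tissue_mask(d, spec$tissue_fraction)
    n <- spec$n_positive_cells
    n_pairs <- floor(round(spec$touching_pair_fraction * n) / 2)
    n_single <- n - 2L * n_pairs

    r_max_px <- spec$cell_radius_range[2] / spec$mpp
    # placement sites: tissue pixels away from the image border
    ok <- tissue
    b <- ceiling(2 * r_max_px)
    ok[c(seq_len(min(b, d[1])), max(1, d[1] - b + 1):d[1]), ] <- FALSE
    ok[, c(seq_len(min(b, d[2])), max(1, d[2] - b + 1):d[2])] <- FALSE
    sites <- which(ok)
    if (n > 0L && length(sites) == 0L)
      stop("no tissue area available to place cells; spec is infeasible",
           call. = FALSE)

    centers <- matrix(numeric(0), ncol = 2)
    radii <- numeric(0)
    pair_id <- integer(0)
    # place pair anchors then singles, all mutually well separated so only
    # deliberate pairs ever touch
    place <- function(k, is_pair) {
      attempts <- 0L
      placed <- 0L
      while (placed < k) {
        attempts <- attempts + 1L
        if (attempts > 10000L)
          stop("could not place cells without accidental contact; ",
               "spec is infeasible", call. = FALSE)
        s <- sites[sample.int(length(sites), 1L)]
        cx <- ((s - 1L) %% d[1]) + 1L
        cy <- ((s - 1L) %/% d[1]) + 1L
        r_um <- runif(1, spec$cell_radius_range[1], spec$cell_radius_range[2])
        r_px <- r_um / spec$mpp
        if (is_pair) {
          ang <- runif(1, 0, 2 * pi)
          off <- 1.3 * r_px * c(cos(ang), sin(ang))
          new <- rbind(c(cx, cy), c(cx + off[1], cy + off[2]))
        } else new <- matrix(c(cx, cy), ncol = 2)
        clear <- TRUE
        if (nrow(centers) > 0) {
          for (i in seq_len(nrow(new))) {
            dist <- sqrt((centers[, 1] - new[i, 1])^2 +
                         (centers[, 2] - new[i, 2])^2)
            if (min(dist) < 2.8 * r_max_px) { clear <- FALSE; break }
          }
        }
        if (!clear) next
        centers <<- rbind(centers, new)
        radii <<- c(radii, rep(r_um, nrow(new)))
        pair_id <<- c(pair_id,
                      if (is_pair) rep(placed + 1L, 2L) else 0L)
        placed <- placed + 1L
      }
    }
    if (n_pairs > 0L) place(n_pairs, TRUE)
    if (n_single > 0L) place(n_single, FALSE)

    # stain blend weight field (max over cells)
    W <- matrix(0, d[1], d[2])
    if (n > 0L) for (i in seq_len(nrow(centers)))
      W <- stamp_profile(W, centers[i, 1], centers[i, 2],
                         radii[i] / spec$mpp)
    stain_mask <- W >= 0.5

    img <- array(0, c(d[1], d[2], 3L))
    mottle <- EBImage::imageData(EBImage::resize(
      EBImage::Image(matrix(rnorm(32 * 32, 0, 0.03), 32, 32)),
      w = d[1], h = d[2]))
    for (ch in 1:3) {
      base <- matrix(1, d[1], d[2])              # white background
      base[tissue] <- spec$counterstain_color[ch] + mottle[tissue]
      img[, , ch] <- base * (1 - W) + spec$stain_color[ch] * W
    }
    if (spec$noise_sd > 0)
      img <- img + array(rnorm(length(img), 0, spec$noise_sd), dim(img))
    img[img < 0] <- 0; img[img > 1] <- 1

    truth <- if (n > 0L)
      data.frame(cell_id = seq_len(nrow(centers)),
                 x_px = centers[, 1], y_px = centers[, 2],
                 x_um = (centers[, 1] - 0.5) * spec$mpp,
                 y_um = (centers[, 2] - 0.5) * spec$mpp,
                 radius_um = radii, pair_id = pair_id)
    else data.frame(cell_id = integer(0), x_px = numeric(0),
                    y_px = numeric(0), x_um = numeric(0), y_um = numeric(0),
                    radius_um = numeric(0), pair_id = integer(0))
    list(image = img, mpp = spec$mpp, truth = truth,
         tissue_mask = tissue, stain_mask = stain_mask)
  })
}
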