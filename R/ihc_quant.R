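# Quantification of chromogenic IHC slides: tissue and stain segmentation,
# minima-controlled watershed cell counting, ROI-normalized density, and
# binned 8-bit staining-intensity histograms.

#' Named region of interest with physical area
#'
#' @param name region label (e.g. "cortex", "dentate gyrus", "fimbria",
#'   or "tissue" for the whole section).
#' @param mask logical matrix, same shape as the slide.
#' @param mpp um/pixel.
#' @return a `roi_region`: list with `name`, `mask`, `mpp`, `area_mm2`
#'   (true-pixel count times `mpp^2`).
#' @export
roi_region <- function(name, mask, mpp) {
  if (!is.matrix(mask) || !is.logical(mask))
    bad_arg("mask", "must be a logical matrix")
  if (mpp <= 0) bad_arg("mpp", "must be > 0")
  structure(list(name = name, mask = mask, mpp = mpp,
                 area_mm2 = sum(mask) * mpp^2 / 1e6),
            class = "roi_region")
}

#' @export
print.roi_region <- function(x, ...) {
  cat(sprintf("<roi_region> '%s': %d px, %.4g mm^2\n",
              x$name, sum(x$mask), x$area_mm2))
  invisible(x)
}

# luminance (Rec. 709) of an RGB array [x, y, 3] in 0-1
rgb_luminance <- function(img) {
  0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
}

# brightness-insensitive chromaticity coordinates: each channel divided by
# the channel sum, so uniform intensity scaling cancels exactly
rgb_chromaticity <- function(img) {
  s <- img[, , 1] + img[, , 2] + img[, , 3]
  s[s <= 0] <- 1
  ch <- img
  for (k in 1:3) ch[, , k] <- img[, , k] / s
  ch
}

#' Segment the tissue region of a brightfield slide
#'
#' Tissue is everything darker than the white slide background: intensity
#' threshold on luminance, then morphological opening (removes isolated
#' noise pixels), closing, and hole filling. An all-background slide yields
#' an empty mask, not an error.
#'
#' @param slide list with `image` (RGB array `x * y * 3` in 0-1) and `mpp`,
#'   as produced by [generate_ihc_slide()] or [read_slide()].
#' @param white_threshold luminance above which a pixel is background
#'   (default 0.92).
#' @param clean_radius radius (pixels) of the opening/closing brush
#'   (default 2).
#' @return a [roi_region()] named `"tissue"`.
#' @export
segment_tissue <- function(slide, white_threshold = 0.92, clean_radius = 2L) {
  lum <- rgb_luminance(slide$image)
  mask <- lum < white_threshold
  if (any(mask) && clean_radius > 0) {
    brush <- EBImage::makeBrush(2L * clean_radius + 1L, shape = "disc")
    m <- EBImage::Image(mask * 1)
    m <- EBImage::closing(EBImage::opening(m, brush), brush)
    m <- EBImage::fillHull(m)
    mask <- EBImage::imageData(m) > 0.5
  }
  roi_region("tissue", mask, slide$mpp)
}

#' Segment positively stained pixels by color distance
#'
#' Classifies pixels whose chromaticity (brightness-normalized RGB) lies
#' within `threshold` of the stain reference color. Chromaticity makes the
#' mask invariant to uniform brightness scaling. An optional
#' stain-separation mode projects optical densities onto the stain vector
#' (color deconvolution) and thresholds that instead.
#'
#' @param slide list with `image` and `mpp`.
#' @param stain_color RGB reference of the positive stain (non-white).
#' @param threshold chromaticity distance cutoff (default 0.26, roughly the
#'   half-blend point between a DAB-brown stain and a hematoxylin
#'   counterstain), or optical
#'   density cutoff in deconvolution mode (default 0.25).
#' @param space `"chromaticity"` (default) or `"deconvolution"`.
#' @return logical stain mask, same shape as the slide.
#' @export
segment_stain <- function(slide, stain_color = c(0.45, 0.24, 0.10),
                          threshold = NULL,
                          space = c("chromaticity", "deconvolution")) {
  space <- match.arg(space)
  if (all(stain_color > 0.98))
    bad_arg("stain_color", "reference color must be non-white")
  img <- slide$image
  if (space == "chromaticity") {
    if (is.null(threshold)) threshold <- 0.26
    ch <- rgb_chromaticity(img)
    ref <- stain_color / sum(stain_color)
    d2 <- (ch[, , 1] - ref[1])^2 + (ch[, , 2] - ref[2])^2 +
      (ch[, , 3] - ref[3])^2
    # chromaticity alone cannot distinguish white from gray; require the
    # pixel to actually be stained (darker than background) as well
    d2 <= threshold^2 & rgb_luminance(img) < 0.92
  } else {
    if (is.null(threshold)) threshold <- 0.25
    od <- -log10(pmax(img, 1 / 255))        # optical density per channel
    v <- -log10(pmax(stain_color, 1 / 255))
    v <- v / sqrt(sum(v^2))
    proj <- od[, , 1] * v[1] + od[, , 2] * v[2] + od[, , 3] * v[3]
    proj >= threshold
  }
}

#' Count positive cells in an ROI with minima-controlled watershed
#'
#' Connected stained regions are split by a watershed seeded at the h-minima
#' of the intensity landscape (staining is dark, so the inverted luminance
#' is flooded): touching cells whose profiles retain two minima basins
#' separated by depth `h_depth` are counted separately. Objects smaller than
#' `min_area` are discarded and counting is restricted to the ROI.
#'
#' @param stain_mask logical matrix from [segment_stain()].
#' @param intensity grayscale matrix in 0-1 (e.g. luminance of the slide).
#' @param roi a [roi_region()]; must be non-empty.
#' @param min_area minimum object area, um^2 (default 20).
#' @param h_depth minima depth on the 0-1 intensity scale (default 0.10,
#'   i.e. 10 percent of the 8-bit range).
#' @param split_touching disable to count plain connected components.
#' @param smooth_sigma Gaussian sigma in pixels applied to the landscape
#'   before flooding (default 1; suppresses single-pixel noise minima).
#' @return one-row data frame: `roi`, `n_positive`, `area_mm2`,
#'   `density_per_mm2`, plus the label matrix as attribute `"labels"`.
#' @export
count_positive_cells <- function(stain_mask, intensity, roi,
                                 min_area = 20, h_depth = 0.10,
                                 split_touching = TRUE, smooth_sigma = 1) {
  stopifnot(inherits(roi, "roi_region"))
  if (!any(roi$mask)) bad_arg("roi", "empty region of interest")
  if (!identical(dim(stain_mask), dim(roi$mask)))
    bad_arg("stain_mask", "shape differs from roi mask")
  mask <- stain_mask & roi$mask
  mpp <- roi$mpp
  min_px <- min_area / mpp^2
  if (!any(mask)) {
    res <- data.frame(roi = roi$name, n_positive = 0L,
                      area_mm2 = roi$area_mm2, density_per_mm2 = 0)
    attr(res, "labels") <- matrix(0L, nrow(stain_mask), ncol(stain_mask))
    return(res)
  }
  if (split_touching) {
    land <- (1 - intensity)
    if (smooth_sigma > 0)
      land <- EBImage::imageData(EBImage::gblur(EBImage::Image(land),
                                                sigma = smooth_sigma))
    land[!mask] <- 0
    lab <- EBImage::imageData(EBImage::watershed(EBImage::Image(land),
                                                 tolerance = h_depth,
                                                 ext = 1))
  } else {
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  }
  storage.mode(lab) <- "integer"
  nlab <- max(lab)
  if (nlab > 0L) {
    counts <- tabulate(lab[lab > 0L], nlab)
    keep <- which(counts >= min_px)
    remap <- integer(nlab); remap[keep] <- seq_along(keep)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
    n <- length(keep)
  } else n <- 0L
  res <- data.frame(roi = roi$name, n_positive = n,
                    area_mm2 = roi$area_mm2,
                    density_per_mm2 = n / roi$area_mm2)
  attr(res, "labels") <- lab
  res
}

#' Binned per-cell staining-intensity histogram
#'
#' Measures each labelled cell's mean intensity in 8-bit grayscale
#' (0 = darkest, 255 = lightest) and bins the per-cell means in 5-unit
#' bins covering 0-255; the terminal bin `[250, 255]` absorbs 255.
#'
#' @param labels integer label matrix (e.g. attribute `"labels"` of
#'   [count_positive_cells()]).
#' @param intensity grayscale matrix in 0-1.
#' @return an `intensity_histogram`: list with `bin_edges` (0, 5, ..., 255)
#'   and `counts` (one per bin; sums to the number of cells).
#' @export
intensity_histogram <- function(labels, intensity) {
  if (!identical(dim(labels), dim(intensity)))
    bad_arg("labels", "shape differs from intensity image")
  edges <- seq(0, 255, by = 5)
  nlab <- max(labels)
  counts <- integer(length(edges) - 1L)
  if (nlab > 0L) {
    idx <- labels > 0L
    means <- tapply(intensity[idx] * 255, labels[idx], mean)
    bin <- pmin(length(counts), floor(means / 5) + 1L)
    tab <- tabulate(bin, length(counts))
    counts <- tab
  }
  structure(list(bin_edges = edges, counts = counts),
            class = "intensity_histogram")
}

#' @export
print.intensity_histogram <- function(x, ...) {
  cat(sprintf("<intensity_histogram> %d cells in %d five-unit bins\n",
              sum(x$counts), length(x$counts)))
  invisible(x)
}
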