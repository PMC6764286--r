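# Quantification of FISH channels: puncta detection and percent of tissue
# area stained within an ROI.

#' Detect fluorescent puncta in a FISH channel
#'
#' Band-pass filters the channel at the dot scale (difference of Gaussians
#' with sigmas `spot_sigma` and `2 * spot_sigma`), finds local maxima above a
#' threshold, and refines each to sub-pixel precision by the intensity
#' centroid of its 3x3 neighbourhood.
#'
#' @param channel intensity matrix (finite, non-negative).
#' @param mpp um/pixel.
#' @param spot_sigma dot scale, um (default 0.5).
#' @param threshold response cutoff on the band-pass image; `NULL` (default)
#'   uses Otsu on the positive responses.
#' @return data frame with one punctum per row: `x_px`, `y_px` (sub-pixel),
#'   `x_um`, `y_um`, `response`. Empty image yields zero rows.
#' @export
detect_puncta <- function(channel, mpp, spot_sigma = 0.5, threshold = NULL) {
  if (spot_sigma <= 0) bad_arg("spot_sigma", "must be > 0")
  if (mpp <= 0) bad_arg("mpp", "must be > 0")
  if (any(!is.finite(channel)) || any(channel < 0))
    bad_arg("channel", "intensities must be finite and non-negative")
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      x_um = numeric(0), y_um = numeric(0),
                      response = numeric(0))
  if (max(channel) <= min(channel)) return(empty)
  s1 <- max(spot_sigma / mpp, 0.5)
  g1 <- EBImage::imageData(EBImage::gblur(EBImage::Image(channel), sigma = s1))
  g2 <- EBImage::imageData(EBImage::gblur(EBImage::Image(channel),
                                          sigma = 2 * s1))
  dog <- g1 - g2
  if (is.null(threshold)) {
    pos <- dog[dog > 0]
    if (length(pos) < 10) return(empty)
    threshold <- otsu_threshold(pos)
    if (is.na(threshold)) return(empty)
  }
  d <- dim(dog)
  # strict local maxima over the 8-neighbourhood, away from the 1-px border
  shift <- function(m, dx, dy) {
    out <- matrix(-Inf, d[1], d[2])
    xs <- seq_len(d[1]) + dx; ys <- seq_len(d[2]) + dy
    okx <- xs >= 1 & xs <= d[1]; oky <- ys >= 1 & ys <= d[2]
    out[okx, oky] <- m[xs[okx], ys[oky]]
    out
  }
  is_max <- dog > threshold
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    is_max <- is_max & (dog >= shift(dog, dx, dy))
  }
  is_max[c(1L, d[1]), ] <- FALSE
  is_max[, c(1L, d[2])] <- FALSE
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)
  # sub-pixel centroid of the 3x3 band-pass response around each maximum
  sub <- t(apply(idx, 1, function(p) {
    w <- dog[(p[1] - 1):(p[1] + 1), (p[2] - 1):(p[2] + 1)]
    w <- pmax(w, 0)
    if (sum(w) == 0) return(as.numeric(p))
    c(p[1] + sum((-1:1) * rowSums(w)) / sum(w),
      p[2] + sum((-1:1) * colSums(w)) / sum(w))
  }))
  data.frame(x_px = sub[, 1], y_px = sub[, 2],
             x_um = (sub[, 1] - 0.5) * mpp, y_um = (sub[, 2] - 0.5) * mpp,
             response = dog[is_max])
}

#' Percent of tissue area stained within an ROI
#'
#' The headline FISH readout: `100 * |stain & tissue & roi| /
#' |tissue & roi|`. Because it is ambiguous whether such figures are
#' normalized to the ROI or to tissue within the ROI, both are reported
#' (`percent_area` uses the tissue denominator; `percent_area_roi` uses the
#' full ROI denominator).
#'
#' @param stain_mask logical matrix of stained pixels.
#' @param tissue_mask logical matrix of tissue pixels.
#' @param roi a [roi_region()], or `NULL` for the whole image.
#' @return one-row data frame: `roi`, `percent_area`, `percent_area_roi`,
#'   `stained_px`, `tissue_px`.
#' @export
percent_area_stained <- function(stain_mask, tissue_mask, roi = NULL) {
  if (!identical(dim(stain_mask), dim(tissue_mask)))
    bad_arg("stain_mask", "shape differs from tissue mask")
  roi_mask <- if (is.null(roi)) {
    matrix(TRUE, nrow(stain_mask), ncol(stain_mask))
  } else {
    stopifnot(inherits(roi, "roi_region"))
    if (!identical(dim(roi$mask), dim(stain_mask)))
      bad_arg("roi", "shape differs from masks")
    roi$mask
  }
  tis <- tissue_mask & roi_mask
  n_tis <- sum(tis)
  if (n_tis == 0)
    stop("tissue-within-ROI is empty: percent area is undefined",
         call. = FALSE)
  n_roi <- sum(roi_mask)
  stained <- sum(stain_mask & tis)
  data.frame(roi = if (is.null(roi)) "image" else roi$name,
             percent_area = 100 * stained / n_tis,
             percent_area_roi = 100 * stained / n_roi,
             stained_px = stained, tissue_px = n_tis)
}
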