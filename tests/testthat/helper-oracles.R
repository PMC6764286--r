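# Shared fixtures and independent oracles used across test files.

# Small, fast stack spec for unit tests (full-size specs are exercised in
# the acceptance tests).
small_stack_spec <- function(n_cells = 5, ...) {
  stack_spec(shape_xyz = c(96L, 96L, 20L), n_cells = n_cells,
             min_separation = 18, ...)
}

# Nearest-neighbour distances from each truth centroid to the detections.
nn_dist <- function(truth_xyz, det_xyz) {
  vapply(seq_len(nrow(truth_xyz)), function(i) {
    min(sqrt(colSums((t(det_xyz) - as.numeric(truth_xyz[i, ]))^2)))
  }, numeric(1))
}

# Exhaustive bin-scan oracle for the two-sample KS statistic on binned
# counts: walks every bin boundary and tracks the largest CDF gap.
ks_oracle_D <- function(counts_a, counts_b) {
  na <- sum(counts_a); nb <- sum(counts_b)
  best <- 0
  ca <- 0; cb <- 0
  for (j in seq_along(counts_a)) {
    ca <- ca + counts_a[j]
    cb <- cb + counts_b[j]
    gap <- abs(ca / na - cb / nb)
    if (gap > best) best <- gap
  }
  best
}

# Build an intensity_histogram object directly from bin counts.
hist_from_counts <- function(counts) {
  stopifnot(length(counts) == 51)
  structure(list(bin_edges = seq(0, 255, by = 5), counts = counts),
            class = "intensity_histogram")
}

# Render an extra isolated stained cell straight into an existing synthetic
# slide image, far from all current cells; returns the modified slide.
add_isolated_cell <- function(slide, spec, cx, cy, r_um) {
  r_px <- r_um / slide$mpp
  d <- dim(slide$image)[1:2]
  ix <- max(1L, floor(cx - r_px)):min(d[1], ceiling(cx + r_px))
  iy <- max(1L, floor(cy - r_px)):min(d[2], ceiling(cy + r_px))
  w <- pmax(0, 1 - outer((ix - cx)^2, (iy - cy)^2, `+`) / r_px^2)
  for (ch in 1:3) {
    sub <- slide$image[ix, iy, ch]
    slide$image[ix, iy, ch] <- sub * (1 - w) + spec$stain_color[ch] * w
  }
  slide
}
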