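test_that("puncta detection: blank, exact recovery, shift equivariance", {
  expect_identical(nrow(detect_puncta(matrix(0, 64, 64), mpp = 0.46)), 0L)

  sp <- fish_spec(shape_xy = c(512L, 512L),
                  target_percent_area = 100 * 200 * 15 / (0.85 * 512^2))
  fs <- generate_fish_slide(sp, seed = 1)
  n_true <- nrow(fs$centers)
  p <- detect_puncta(fs$signal, mpp = fs$mpp)
  expect_lte(abs(nrow(p) - n_true), 2)

  # integer translation moves every detection by the same amount
  sh <- 5L
  img2 <- matrix(0, nrow(fs$signal), ncol(fs$signal))
  img2[(sh + 1):nrow(img2), (sh + 1):ncol(img2)] <-
    fs$signal[1:(nrow(img2) - sh), 1:(ncol(img2) - sh)]
  p2 <- detect_puncta(img2, mpp = fs$mpp)
  # match on the common region away from borders
  keep <- p$x_px < nrow(img2) - 2 * sh & p$y_px < ncol(img2) - 2 * sh
  a <- p[keep, c("x_px", "y_px")]
  b <- p2[, c("x_px", "y_px")]; b$x_px <- b$x_px - sh; b$y_px <- b$y_px - sh
  nn <- nn_dist(a, as.matrix(b))
  expect_lt(max(nn), 0.5)
})

test_that("percent area stained: trivial cases and exact arithmetic", {
  tissue <- matrix(TRUE, 32, 32)
  expect_equal(percent_area_stained(tissue, tissue)$percent_area, 100)
  expect_equal(percent_area_stained(matrix(FALSE, 32, 32),
                                    tissue)$percent_area, 0)
  expect_error(percent_area_stained(tissue, matrix(FALSE, 32, 32)),
               "undefined")
  # both denominators reported
  roi <- roi_region("r", matrix(TRUE, 32, 32), 1)
  half_tissue <- rbind(matrix(TRUE, 16, 32), matrix(FALSE, 16, 32))
  stain <- matrix(FALSE, 32, 32); stain[1:8, ] <- TRUE
  res <- percent_area_stained(stain, half_tissue, roi)
  expect_equal(res$percent_area, 50)
  expect_equal(res$percent_area_roi, 25)
})

test_that("percent area is invariant under joint translation", {
  fs <- generate_fish_slide(fish_spec(shape_xy = c(256L, 256L),
                                      target_percent_area = 3), seed = 2)
  base <- percent_area_stained(fs$signal_mask, fs$tissue_mask)
  sh <- 7L
  move <- function(m) {
    out <- matrix(FALSE, nrow(m) + sh, ncol(m) + sh)
    out[(sh + 1):(nrow(m) + sh), (sh + 1):(ncol(m) + sh)] <- m
    out
  }
  shifted <- percent_area_stained(move(fs$signal_mask), move(fs$tissue_mask))
  expect_equal(shifted$percent_area, base$percent_area, tolerance = 1e-12)
})

test_that("stained pixels are additive over disjoint ROIs", {
  fs <- generate_fish_slide(fish_spec(shape_xy = c(256L, 256L),
                                      target_percent_area = 4), seed = 3)
  left <- matrix(FALSE, 256, 256); left[1:128, ] <- TRUE
  right <- !left
  a <- percent_area_stained(fs$signal_mask, fs$tissue_mask,
                            roi_region("L", left, fs$mpp))
  b <- percent_area_stained(fs$signal_mask, fs$tissue_mask,
                            roi_region("R", right, fs$mpp))
  whole <- percent_area_stained(fs$signal_mask, fs$tissue_mask)
  expect_identical(a$stained_px + b$stained_px, whole$stained_px)
})

test_that("raising the stain threshold never increases percent area", {
  fs <- generate_fish_slide(fish_spec(shape_xy = c(256L, 256L),
                                      target_percent_area = 3), seed = 4)
  pct <- vapply(seq(0.2, 0.9, by = 0.1), function(th) {
    percent_area_stained(fs$signal > th, fs$tissue_mask)$percent_area
  }, numeric(1))
  expect_true(all(diff(pct) <= 0))
})
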