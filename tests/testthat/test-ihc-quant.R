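test_that("tissue segmentation: white slide empty, coverage recovered", {
  white <- list(image = array(1, c(64, 64, 3)), mpp = 0.46)
  expect_identical(sum(segment_tissue(white)$mask), 0L)

  sp <- slide_spec(shape_xy = c(512L, 512L), tissue_fraction = 0.5,
                   n_positive_cells = 0)
  sl <- generate_ihc_slide(sp, seed = 5)
  tis <- segment_tissue(sl)
  expect_lt(abs(sum(tis$mask) - sum(sl$tissue_mask)) / sum(sl$tissue_mask),
            0.05)
})

test_that("morphological filtering removes isolated salt noise", {
  sp <- slide_spec(shape_xy = c(256L, 256L), n_positive_cells = 0)
  sl <- generate_ihc_slide(sp, seed = 6)
  clean <- segment_tissue(sl)
  noisy <- sl
  set.seed(1)
  bg <- which(!sl$tissue_mask)
  pick <- sample(bg, 10)
  for (p in pick) {
    xy <- arrayInd(p, dim(sl$tissue_mask))
    noisy$image[xy[1], xy[2], ] <- c(0.3, 0.3, 0.3)  # dark speck on white
  }
  expect_identical(segment_tissue(noisy)$mask, clean$mask)
})

test_that("stain segmentation recovers rendered DAB pixels", {
  sp <- slide_spec(shape_xy = c(768L, 768L), n_positive_cells = 60)
  sl <- generate_ihc_slide(sp, seed = 7)
  stain <- segment_stain(sl)
  expect_identical(sum(segment_stain(list(image = array(1, c(32, 32, 3)),
                                          mpp = 1))), 0L)
  expect_lt(abs(sum(stain) - sum(sl$stain_mask)) / sum(sl$stain_mask), 0.10)
})

test_that("stained area is invariant to uniform brightness scaling", {
  sp <- slide_spec(shape_xy = c(512L, 512L), n_positive_cells = 30)
  sl <- generate_ihc_slide(sp, seed = 8)
  base <- segment_stain(sl)
  for (f in c(0.9, 1.1)) {
    scaled <- sl
    scaled$image <- sl$image * f
    scaled$image[scaled$image > 1] <- 1
    expect_identical(segment_stain(scaled), base)
  }
})

test_that("watershed counting: isolated exact, pairs split, bounds hold", {
  sp <- slide_spec(n_positive_cells = 100, touching_pair_fraction = 0)
  sl <- generate_ihc_slide(sp, seed = 9)
  tis <- segment_tissue(sl)
  stain <- segment_stain(sl)
  lum <- rgb_luminance(sl$image)
  cnt <- count_positive_cells(stain, lum, tis)
  expect_identical(cnt$n_positive, 100L)

  sp2 <- slide_spec(n_positive_cells = 100, touching_pair_fraction = 0.2)
  sl2 <- generate_ihc_slide(sp2, seed = 10)
  tis2 <- segment_tissue(sl2)
  stain2 <- segment_stain(sl2)
  lum2 <- rgb_luminance(sl2$image)
  ws <- count_positive_cells(stain2, lum2, tis2)
  cc <- count_positive_cells(stain2, lum2, tis2, split_touching = FALSE)
  expect_identical(cc$n_positive, 90L)       # 10 merged pairs
  expect_gte(ws$n_positive, cc$n_positive)   # watershed lower bound
  expect_lte(abs(ws$n_positive - 100L), 3L)

  # empty stain mask
  none <- count_positive_cells(matrix(FALSE, 1024, 1024), lum2, tis2)
  expect_identical(none$n_positive, 0L)
  expect_error(count_positive_cells(stain2, lum2,
                                    roi_region("x", matrix(FALSE, 1024, 1024),
                                               0.46)),
               "empty")
})

test_that("adding an isolated cell inside the ROI never lowers the count", {
  sp <- slide_spec(shape_xy = c(512L, 512L), n_positive_cells = 20,
                   touching_pair_fraction = 0)
  sl <- generate_ihc_slide(sp, seed = 11)
  tis <- segment_tissue(sl)
  base <- count_positive_cells(segment_stain(sl), rgb_luminance(sl$image), tis)
  # a free tissue spot far from every rendered cell and the image border
  inner <- sl$tissue_mask
  inner[c(1:16, 497:512), ] <- FALSE
  inner[, c(1:16, 497:512)] <- FALSE
  cand <- which(inner, arr.ind = TRUE)
  dd <- vapply(seq_len(nrow(cand)), function(i) {
    min(sqrt((sl$truth$x_px - cand[i, 1])^2 + (sl$truth$y_px - cand[i, 2])^2))
  }, numeric(1))
  spot <- cand[which.max(dd), ]
  sl2 <- add_isolated_cell(sl, sp, spot[1], spot[2], r_um = 5)
  more <- count_positive_cells(segment_stain(sl2), rgb_luminance(sl2$image),
                               tis)
  expect_gte(more$n_positive, base$n_positive)
  expect_identical(more$n_positive, base$n_positive + 1L)
})

test_that("density normalization is exact in the ROI area", {
  lab_img <- matrix(FALSE, 200, 200)
  lab_img[50:60, 50:60] <- TRUE      # one square "cell"
  inten <- matrix(0.5, 200, 200)
  half <- roi_region("half", cbind(matrix(TRUE, 200, 100),
                                   matrix(FALSE, 200, 100)), mpp = 1)
  full <- roi_region("full", matrix(TRUE, 200, 200), mpp = 1)
  c1 <- count_positive_cells(lab_img, inten, half, min_area = 10,
                             split_touching = FALSE)
  c2 <- count_positive_cells(lab_img, inten, full, min_area = 10,
                             split_touching = FALSE)
  expect_identical(c1$n_positive, c2$n_positive)
  expect_equal(c2$density_per_mm2, c1$density_per_mm2 / 2, tolerance = 1e-12)
})

test_that("intensity histogram bins 5-wide, conserves cells, handles 255", {
  labs <- matrix(0L, 40, 40)
  labs[2:5, 2:5] <- 1L; labs[20:23, 20:23] <- 2L; labs[30:33, 30:33] <- 3L
  inten <- matrix(0, 40, 40)
  inten[labs == 1L] <- 100 / 255   # mean 100 -> bin [100,105)
  inten[labs == 2L] <- 1           # 255 -> terminal bin
  inten[labs == 3L] <- 1
  h <- intensity_histogram(labs, inten)
  expect_identical(sum(h$counts), 3L)
  expect_identical(h$counts[100 / 5 + 1], 1L)
  expect_identical(h$counts[51], 2L)
  expect_identical(h$bin_edges, seq(0, 255, by = 5))
})
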