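test_that("preprocessing identity and constant-image cases", {
  st <- image_stack(array(runif(16 * 16 * 4), c(16, 16, 4)), 0.5, 1)
  out <- preprocess_stack(st, smoothing_sigma = 0, background_radius = 0)
  expect_identical(out$data, st$data)

  const <- image_stack(array(7, c(32, 32, 4)), 0.5, 1)
  bg <- preprocess_stack(const, smoothing_sigma = 0, background_radius = 5)
  expect_true(all(abs(bg$data) < 1e-10))

  st$data[1] <- NA
  expect_error(preprocess_stack(st), "finite")
})

test_that("preprocessing never degrades foreground/background separability", {
  seps <- vapply(1:10, function(s) {
    g <- generate_stack(small_stack_spec(), seed = s)
    pre <- preprocess_stack(g$stack)
    c(gliaquant:::otsu_separation(g$stack$data),
      gliaquant:::otsu_separation(pre$data))
  }, numeric(2))
  expect_true(all(seps[2, ] >= seps[1, ]))
})

test_that("detection recovers well-separated cells with matched centroids", {
  g <- generate_stack(small_stack_spec(n_cells = 5), seed = 11)
  det <- detect_cells_3d(preprocess_stack(g$stack))
  expect_identical(nrow(det$cells), 5L)
  nn <- nn_dist(g$truth[, c("x_um", "y_um", "z_um")],
                det$cells[, c("x_um", "y_um", "z_um")])
  expect_true(all(nn <= g$truth$soma_radius_um))
})

test_that("all-background and constant stacks yield zero cells", {
  g <- generate_stack(small_stack_spec(n_cells = 0), seed = 2)
  det <- detect_cells_3d(preprocess_stack(g$stack))
  expect_identical(nrow(det$cells), 0L)
  const <- image_stack(array(3, c(24, 24, 6)), 0.5, 1)
  expect_identical(nrow(detect_cells_3d(const)$cells), 0L)
})

test_that("two merged somata split with watershed on, stay merged off", {
  # two gaussian blobs whose thresholded masks form one component with two
  # intensity maxima
  d <- c(48L, 24L, 16L)
  a <- array(0, d)
  c1 <- c(18, 12, 8); c2 <- c(30, 12, 8)
  for (x in 1:48) for (y in 1:24) for (z in 1:16) {
    a[x, y, z] <- 100 * exp(-sum((c(x, y, z) - c1)^2) / 30) +
                  100 * exp(-sum((c(x, y, z) - c2)^2) / 30)
  }
  st <- image_stack(a + 1, voxel_xy = 1, voxel_z = 1)
  merged <- detect_cells_3d(st, threshold_method = "fixed", threshold = 20,
                            min_volume = 20, split_touching = FALSE)
  expect_identical(nrow(merged$cells), 1L)
  split <- detect_cells_3d(st, threshold_method = "fixed", threshold = 20,
                           min_volume = 20, split_touching = TRUE)
  expect_identical(nrow(split$cells), 2L)
  # the two pieces sit on opposite sides, near the true centers
  xs <- sort(split$cells$x_um)
  expect_lt(abs(xs[1] - 17.5), 3)
  expect_lt(abs(xs[2] - 29.5), 3)
})

test_that("labels are disjoint and sizes bounded by thresholded foreground", {
  g <- generate_stack(small_stack_spec(n_cells = 6), seed = 13)
  pre <- preprocess_stack(g$stack)
  det <- detect_cells_3d(pre)
  # every labelled voxel belongs to exactly one cell by construction of the
  # label array; check the bookkeeping agrees with it
  expect_identical(sum(det$cells$n_voxels), sum(det$labels > 0))
  thr <- gliaquant:::otsu_threshold(pre$data)
  expect_lte(sum(det$cells$n_voxels), sum(pre$data > thr))
})

test_that("volumetric density follows the count-over-volume definition", {
  st <- image_stack(array(0, c(1024, 1024, 100)), 0.592, 1.5)
  vol_mm3 <- (1024 * 0.592)^2 * (100 * 1.5) / 1e9
  rec <- compute_density(100, st, animal_id = "m1", region = "cortex")
  expect_equal(rec$volume_mm3, vol_mm3, tolerance = 1e-12)
  expect_equal(rec$density_per_mm3, 100 / vol_mm3, tolerance = 1e-12)
  expect_equal(compute_density(0, st)$density_per_mm3, 0)
  # linearity in count
  expect_equal(compute_density(200, st)$density_per_mm3,
               2 * rec$density_per_mm3, tolerance = 1e-12)
})

test_that("areal density matches the 2D definition and scales with mpp", {
  rec <- compute_density_2d(200, c(1024, 1024), 2.3649)
  area <- (1024 * 2.3649)^2 / 1e6
  expect_equal(rec$area_mm2, area, tolerance = 1e-12)
  expect_equal(rec$density_per_mm2, 200 / area, tolerance = 1e-12)
  expect_equal(compute_density_2d(0, c(64, 64), 1)$density_per_mm2, 0)
  half <- compute_density_2d(200, c(1024, 1024), 2.3649 / 2)
  expect_equal(half$density_per_mm2, 4 * rec$density_per_mm2,
               tolerance = 1e-12)
})

test_that("cell size is voxel count times voxel volume, additive, convergent", {
  expect_equal(measure_cell_size(1L, 0.592, 1.5), 0.592^2 * 1.5,
               tolerance = 1e-12)
  m1 <- rasterize_ball(4, 0.5); m2 <- rasterize_ball(3, 0.5)
  expect_equal(measure_cell_size(m1, 0.5, 0.5) +
                 measure_cell_size(m2, 0.5, 0.5),
               (sum(m1) + sum(m2)) * 0.125, tolerance = 1e-12)
  expect_error(measure_cell_size(0L, 0.5, 0.5), "non-empty")
  # resolution convergence toward the analytic sphere volume
  truth <- 4 / 3 * pi * 10^3
  errs <- vapply(c(2, 1, 0.5), function(p) {
    abs(measure_cell_size(rasterize_ball(10, p), p, p) - truth) / truth
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.05)
})
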