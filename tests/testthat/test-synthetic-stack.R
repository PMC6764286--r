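test_that("stack generation is a pure function of spec and seed", {
  sp <- small_stack_spec()
  g1 <- generate_stack(sp, seed = 7)
  g2 <- generate_stack(sp, seed = 7)
  g3 <- generate_stack(sp, seed = 8)
  expect_identical(g1$stack$data, g2$stack$data)
  expect_identical(g1$truth, g2$truth)
  expect_false(identical(g1$truth$x_um, g3$truth$x_um))
  # caller RNG stream untouched
  set.seed(123); before <- rnorm(3)
  set.seed(123); invisible(generate_stack(sp, seed = 1)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("zero cells yields pure background plus noise and empty truth", {
  sp <- small_stack_spec(n_cells = 0)
  g <- generate_stack(sp, seed = 1)
  expect_identical(nrow(g$truth), 0L)
  expect_lt(max(g$stack$data),
            sp$background_level + 6 * sp$noise_sd)
})

test_that("placed centroids respect the minimum separation", {
  sp <- stack_spec(shape_xyz = c(256L, 256L, 48L), n_cells = 20,
                   min_separation = 25)
  g <- generate_stack(sp, seed = 3)
  expect_identical(nrow(g$truth), 20L)
  dmat <- as.matrix(dist(g$truth[, c("x_um", "y_um", "z_um")]))
  expect_gte(min(dmat[upper.tri(dmat)]), 25)
  # centroids inside the physical bounds
  ext <- sp$shape_xyz * c(sp$voxel_xy, sp$voxel_xy, sp$voxel_z)
  expect_true(all(g$truth$x_um > 0 & g$truth$x_um < ext[1]))
  expect_true(all(g$truth$z_um > 0 & g$truth$z_um < ext[3]))
  expect_true(all(g$truth$true_volume_um3 > 0))
})

test_that("an overcrowded spec fails with an infeasibility error", {
  sp <- stack_spec(shape_xyz = c(96L, 96L, 20L), n_cells = 200,
                   min_separation = 20)
  expect_error(generate_stack(sp, seed = 1), "infeasible")
})

test_that("spec invariants are enforced at construction", {
  expect_error(stack_spec(n_cells = -1), "n_cells")
  expect_error(stack_spec(n_cells = 5, min_separation = 8,
                          soma_radius_range = c(4, 5)), "min_separation")
  expect_error(stack_spec(voxel_xy = 0), "voxel")
  expect_error(stack_spec(soma_radius_range = c(5, 4)), "soma_radius_range")
})

test_that("truth centroids round-trip um -> voxel -> um within one pitch", {
  sp <- small_stack_spec()
  g <- generate_stack(sp, seed = 5)
  for (col in c("x_um", "y_um", "z_um")) {
    pitch <- if (col == "z_um") sp$voxel_z else sp$voxel_xy
    v <- gliaquant:::um_to_voxel(g$truth[[col]], pitch)
    back <- gliaquant:::voxel_to_um(v, pitch)
    expect_true(all(abs(back - g$truth[[col]]) <= pitch))
  }
})

test_that("every generator conserves ground truth over random specs", {
  set.seed(42)
  for (i in 1:8) {
    n <- sample(0:6, 1)
    sp <- stack_spec(shape_xyz = c(72L, 72L, 16L), n_cells = n,
                     min_separation = 16,
                     soma_radius_range = sort(runif(2, 3, 5)))
    g <- generate_stack(sp, seed = i)
    expect_identical(nrow(g$truth), as.integer(n))
  }
  for (i in 1:8) {
    n <- sample(0:30, 1)
    sp <- slide_spec(shape_xy = c(512L, 512L), n_positive_cells = n,
                     touching_pair_fraction = runif(1, 0, 0.4))
    sl <- generate_ihc_slide(sp, seed = i)
    expect_identical(nrow(sl$truth), as.integer(n))
  }
  for (i in 1:8) {
    pct <- runif(1, 0.5, 6)
    fs <- generate_fish_slide(fish_spec(shape_xy = c(256L, 256L),
                                        target_percent_area = pct), seed = i)
    expect_lt(abs(fs$true_percent_area - pct), 0.5)
    expect_identical(sum(fs$signal_mask & !fs$tissue_mask), 0L)
  }
})
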