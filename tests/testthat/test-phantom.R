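test_that("rasterized cylinder matches the analytic volume", {
  # r = 4.7 um, L = 470 um at 0.94 um voxels: V = pi r^2 L ~ 32,630 um^3
  voxel <- 0.94
  shape <- c(504, 16, 16)
  tb <- tube_spec(rbind(c(0, 7 * voxel, 7 * voxel),
                        c(470, 7 * voxel, 7 * voxel)), 4.7)
  ph <- generate_phantom(phantom_spec(shape, voxel, list(tb),
                                      tissue_noise_sd = 0))
  expect_equal(ph$truth$vessel_volume_um3, pi * 4.7^2 * 470,
               tolerance = 0.05)
  # truth mask count and volume come from the same rasterization
  expect_identical(ph$truth$vessel_volume_um3,
                   sum(ph$truth$vessel_mask$data) * voxel^3)
  expect_equal(ph$truth$total_length_um, 470)
})

test_that("lumen polarity fractions control the rendered intensities", {
  mk <- function(bf) tube_phantom(c(32, 24, 24), bright_fraction = bf,
                                  noise_sd = 0)
  dark <- mk(0)
  lum <- dark$truth$vessel_mask$data
  expect_true(all(dark$volume$data[lum] == 40))     # dark_level
  bright <- mk(1)
  expect_true(all(bright$volume$data[lum] == 200))  # bright_level
  mixed <- mk(0.5)
  vals <- mixed$volume$data[lum]
  expect_setequal(unique(vals), c(40, 200))
  # contiguous arclength block: bright half at low z, dark half at high z
  co <- arrayInd(which(lum), dim(lum))
  zb <- co[mixed$volume$data[lum] == 200, 1]
  zd <- co[mixed$volume$data[lum] == 40, 1]
  expect_lt(max(zb), min(zd) + 2)
})

test_that("phantom generation is deterministic and geometry is independent
           of the noise seed", {
  sp <- function(seed) {
    tb <- tube_spec(rbind(c(5, 10, 10), c(25, 10, 10)), 3)
    phantom_spec(c(32, 24, 24), 1, list(tb), rng_seed = seed)
  }
  a <- generate_phantom(sp(5))
  b <- generate_phantom(sp(5))
  expect_identical(a$volume$data, b$volume$data)
  c3 <- generate_phantom(sp(99))
  expect_identical(a$truth$vessel_mask$data, c3$truth$vessel_mask$data)
  expect_false(identical(a$volume$data, c3$volume$data))
})

test_that("clipped tubes are flagged, and only those", {
  inside <- tube_spec(rbind(c(5, 10, 10), c(25, 10, 10)), 2)
  exits <- tube_spec(rbind(c(5, 10, 10), c(60, 10, 10)), 2)  # z > extent
  ph <- generate_phantom(phantom_spec(c(32, 24, 24), 1, list(inside, exits),
                                      tissue_noise_sd = 0))
  expect_identical(ph$truth$clipped, c(FALSE, TRUE))
})

test_that("phantom spec validation catches bad intensity models and
           sub-resolution tubes", {
  tb <- tube_spec(rbind(c(5, 10, 10), c(25, 10, 10)), 2)
  expect_error(phantom_spec(c(32, 24, 24), 1, list(tb),
                            dark_level = 150, tissue_mean = 120),
               "ordering")
  tiny <- tube_spec(rbind(c(5, 10, 10), c(25, 10, 10)), 0.4)
  expect_warning(generate_phantom(phantom_spec(c(32, 24, 24), 1, list(tiny))),
                 "sub-resolution")
  expect_error(tube_spec(rbind(c(0, 0, 0), c(1, 1, 1)), -1), "positive")
  expect_error(tube_spec(matrix(0, 1, 3), 1), "n >= 2")
})

test_that("branching_tree_spec degenerates to a single tube and passes
           diameters through", {
  sp1 <- branching_tree_spec(1, c(9.4), rng_seed = 3,
                             shape = c(96, 96, 96), voxel_size_um = 0.94)
  expect_length(sp1$tubes, 1L)
  expect_equal(sp1$tubes[[1]]$radius_um, 4.7)
  sp <- branching_tree_spec(5, c(9.4), rng_seed = 3,
                            shape = c(128, 128, 128), voxel_size_um = 0.94)
  expect_true(all(vapply(sp$tubes, function(t) t$radius_um, 1) == 4.7))
  # the tree is connected: its rasterization is one 26-connected component
  ph <- generate_phantom(sp)
  one <- geodesic_select(ph$truth$vessel_mask,
                         binary_mask(ball_mask(dim(ph$truth$vessel_mask),
                                               sp$tubes[[1]]$centerline[1, ] /
                                                 0.94 + 1, 3), 0.94))
  expect_identical(one$data, ph$truth$vessel_mask$data)
})

test_that("a constructed bifurcating tree yields one skeleton branch per
           tube after junction decomposition", {
  tube <- function(a, b, r = 4.7) tube_spec(rbind(a, b), r)
  tubes <- list(
    tube(c(10, 90, 90), c(70, 90, 90)),
    tube(c(70, 90, 90), c(110, 130, 90)),
    tube(c(70, 90, 90), c(110, 50, 90)),
    tube(c(110, 130, 90), c(150, 130, 130)),
    tube(c(110, 130, 90), c(150, 130, 50)),
    tube(c(110, 50, 90), c(150, 50, 130)),
    tube(c(110, 50, 90), c(150, 50, 50)))
  ph <- generate_phantom(phantom_spec(c(192, 192, 192), 0.94, tubes,
                                      tissue_noise_sd = 0))
  sk <- prune_branches(skeletonize_3d(ph$truth$vessel_mask), 25)
  expect_identical(nrow(sk$branches), 7L)
  expect_equal(total_skeleton_length_um(sk), ph$truth$total_length_um,
               tolerance = 0.05)
})

test_that("increasing tissue noise does not improve segmentation", {
  dice_at <- function(sd, seed) {
    ph <- tube_phantom(c(48, 40, 40), noise_sd = sd, seed = seed)
    mask_dice(segment_fine(ph$volume, edge_params(median_kernels = c(5, 9), min_object_um3 = 500)),
              ph$truth$vessel_mask)
  }
  lo <- mean(sapply(1:4, function(s) dice_at(8, s)))
  hi <- mean(sapply(1:4, function(s) dice_at(64, s)))
  expect_gte(lo, hi)
})
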