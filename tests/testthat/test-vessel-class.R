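test_that("geodesic selection keeps exactly the components the seed touches", {
  d <- c(40, 20, 20)
  two <- ball_mask(d, c(10, 10, 10), 5) | ball_mask(d, c(30, 10, 10), 5)
  dim(two) <- d
  mask <- binary_mask(two, 1)
  seed <- binary_mask(ball_mask(d, c(10, 10, 10), 2), 1)
  sel <- geodesic_select(mask, seed_region(seed, "left"))
  expect_identical(sel$data, array(ball_mask(d, c(10, 10, 10), 5), d))
  # seed disjoint from the mask: empty selection
  far <- binary_mask(ball_mask(d, c(20, 4, 4), 2), 1)
  expect_identical(sum(geodesic_select(mask, far)$data), 0L)
  # idempotence on a full seed
  expect_identical(geodesic_select(mask, mask)$data, mask$data)
  expect_error(geodesic_select(mask, binary_mask(array(FALSE, d), 1)),
               "empty")
})

test_that("geodesic selection equals a BFS flood fill from the seed", {
  for (seed in 1:10) {
    set.seed(seed)
    d <- c(sample(16:24, 1), sample(16:24, 1), sample(16:24, 1))
    m <- array(runif(prod(d)) < 0.35, d)
    sd_idx <- sample(prod(d), 30)
    seeds <- array(FALSE, d); seeds[sd_idx] <- TRUE
    if (!any(seeds & m)) next
    got <- geodesic_select(binary_mask(m, 1), binary_mask(seeds, 1))
    oracle <- bfs_flood(m, which(seeds))
    expect_identical(got$data, oracle)
  }
})

test_that("central/peripheral split follows seed reachability with central
           precedence", {
  d <- c(60, 40, 40)
  central_tree <- cylinder_mask(d, 4, c(12, 20))
  peripheral_tree <- cylinder_mask(d, 4, c(30, 20))
  m <- central_tree | peripheral_tree
  dim(m) <- d
  mask <- binary_mask(m, 1)
  sulcus <- binary_mask(array(ball_mask(d, c(2, 12, 20), 3), d), 1)
  surface <- binary_mask(array(ball_mask(d, c(2, 30, 20), 3), d), 1)
  res <- split_central_peripheral(mask, sulcus, surface)
  expect_identical(res$central$data, array(central_tree, d))
  expect_identical(res$peripheral$data, array(peripheral_tree, d))
  expect_false(any(res$components$ambiguous))
  expect_setequal(res$components$class, c("central", "peripheral"))
  # one component touching both seeds: central wins, flagged ambiguous
  both <- split_central_peripheral(binary_mask(array(central_tree, d), 1),
                                   sulcus, sulcus)
  expect_identical(both$components$class, "central")
  expect_true(all(both$components$ambiguous))
})

test_that("short/long classification keys on reach of the far face", {
  d <- c(40, 30, 30)
  long_c <- cylinder_mask(d, 3, c(8, 8))         # spans all of z
  short_c <- array(FALSE, d)
  short_c[5:20, 15:25, 15:25] <- ball_mask(c(16, 11, 11), c(8, 6, 6), 5)
  m <- long_c | short_c
  dim(m) <- d
  res <- classify_short_long(binary_mask(m, 1), "z+", tolerance_vox = 2)
  expect_identical(sort(unique(res$components$length_class)),
                   c("long", "short"))
  expect_identical(res$long$data, array(long_c, d))
  expect_identical(res$short$data, array(short_c & !long_c, d))
  # invariant to voxel-size rescaling of the same geometry
  res2 <- classify_short_long(binary_mask(m, 4.94), "z+", tolerance_vox = 2)
  expect_identical(res2$components$length_class,
                   res$components$length_class)
  expect_error(classify_short_long(binary_mask(m, 1), "w+"), "face")
})

test_that("maximum inscribed diameters match closed forms and the brute
           oracle", {
  d <- c(24, 24, 24)
  ball <- binary_mask(ball_mask(d, c(12, 12, 12), 8), 1)
  expect_equal(max_inscribed_diameter(ball), 16, tolerance = 1 / 16)
  # tapering tube, radius 3 -> 7 voxels: the largest sphere sits at the
  # wide end
  dt <- c(60, 30, 30)
  taper <- generate_phantom(phantom_spec(dt, 1, list(
    tube_spec(rbind(c(5, 15, 15), c(55, 15, 15)), c(3, 7))),
    tissue_noise_sd = 0))$truth$vessel_mask
  expect_equal(max_inscribed_diameter(taper), 14, tolerance = 1 / 14)
  # brute-force oracle on a random blob
  m <- random_blob(c(18, 18, 18), n_balls = 2, seed = 3)
  dim(m) <- c(18, 18, 18)
  oracle <- 2 * sqrt(max(brute_edt_sq(m)))
  expect_equal(max_inscribed_diameter(binary_mask(m, 1)), oracle,
               tolerance = 1e-12)
  expect_error(max_inscribed_diameter(binary_mask(array(FALSE, d), 1)),
               "empty")
})

test_that("component_max_diameters reports one row per component", {
  d <- c(40, 20, 20)
  m <- ball_mask(d, c(10, 10, 10), 6) | ball_mask(d, c(30, 10, 10), 3)
  dim(m) <- d
  res <- component_max_diameters(binary_mask(m, 2))
  expect_identical(nrow(res), 2L)
  expect_equal(sort(res$max_diameter_um), c(2 * 3 * 2, 2 * 6 * 2),
               tolerance = 0.07)
})

test_that("the pooled t-test matches the textbook computation and handles
           degenerate input", {
  r <- two_sample_ttest(c(10, 12, 14), c(20, 22, 24))
  expect_equal(r$statistic, -6.123724, tolerance = 1e-6)
  expect_equal(r$p_value, 2 * pt(-10 / sqrt(4 * (1 / 3 + 1 / 3)), 4),
               tolerance = 1e-12)
  expect_identical(r$df, 4)
  # identical groups: t = 0, p = 1
  same <- two_sample_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_identical(same$statistic, 0)
  expect_identical(same$p_value, 1)
  # p decreases monotonically as the separation grows
  ps <- sapply(c(1, 5, 20), function(delta)
    two_sample_ttest(c(1, 2, 3), c(1, 2, 3) + delta)$p_value)
  expect_true(all(diff(ps) < 0))
  # degenerate: zero pooled variance
  expect_identical(two_sample_ttest(c(2, 2, 2), c(2, 2))$p_value, 1)
  expect_error(two_sample_ttest(c(2, 2, 2), c(3, 3)), "zero pooled")
  expect_error(two_sample_ttest(1, c(1, 2)), "at least 2")
})

test_that("QC voxel sampling is deterministic, in-mask and clamped", {
  d <- c(30, 30, 30)
  m <- binary_mask(array(cylinder_mask(d, 6), d), 1)
  qc1 <- sample_qc_voxels(m, n = 100, rng_seed = 7)
  qc2 <- sample_qc_voxels(m, n = 100, rng_seed = 7)
  expect_identical(qc1$coordinates, qc2$coordinates)
  expect_identical(nrow(qc1$coordinates), 100L)
  expect_identical(nrow(unique(qc1$coordinates)), 100L)
  idx <- with(qc1$coordinates, z + d[1] * (y - 1) + d[1] * d[2] * (x - 1))
  expect_true(all(m$data[idx]))
  qc3 <- sample_qc_voxels(m, n = 100, rng_seed = 8)
  expect_false(identical(qc1$coordinates, qc3$coordinates))
  # requesting more voxels than the mask has returns them all, with warning
  small <- binary_mask(array(ball_mask(d, c(15, 15, 15), 2), d), 1)
  expect_warning(qcs <- sample_qc_voxels(small, n = sum(small$data) + 5,
                                         rng_seed = 1), "returning all")
  expect_identical(nrow(qcs$coordinates), sum(small$data))
  # orthogonal patches come back when a volume is supplied
  vol <- voxel_volume(array(rnorm(prod(d)), d), 1)
  qcp <- sample_qc_voxels(m, n = 5, rng_seed = 2, vol = vol,
                          half_width_vox = 4)
  expect_length(qcp$patches, 5L)
  expect_named(qcp$patches[[1]], c("xy", "xz", "yz"))
})
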