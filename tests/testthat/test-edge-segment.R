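test_that("3D median filter equals the exhaustive neighbourhood median", {
  set.seed(11)
  d <- c(16, 16, 16)
  # integer-valued volume exercises the running-histogram path
  ai <- array(sample(0:255, prod(d), TRUE), d)
  expect_identical(median_filter_3d(voxel_volume(ai, 1), 3)$data,
                   brute_median3d(ai, 3))
  expect_identical(median_filter_3d(voxel_volume(ai, 1), 5)$data,
                   brute_median3d(ai, 5))
  # non-integer volume exercises the sorting path
  af <- ai + runif(prod(d), 0, 0.5)
  dim(af) <- d
  expect_equal(median_filter_3d(voxel_volume(af, 1), 3)$data,
               brute_median3d(af, 3))
})

test_that("median filter preserves constants, rejects impulses, validates k", {
  cv <- voxel_volume(array(42, c(12, 12, 12)), 1)
  expect_identical(median_filter_3d(cv, 7)$data, cv$data)
  imp <- array(0, c(15, 15, 15)); imp[8, 8, 8] <- 100
  out <- median_filter_3d(voxel_volume(imp, 1), 7)
  expect_true(all(out$data == 0))
  expect_error(median_filter_3d(cv, 4), "odd")
  expect_error(median_filter_3d(cv, -3), "odd")
})

test_that("recursive Deriche gradient matches FIR convolution with the
           analytic kernel", {
  set.seed(12)
  d <- c(32, 32, 32)
  a <- array(rnorm(prod(d)), d)
  g <- deriche_gradient(voxel_volume(a, 1), alpha = 0.8)
  for (axis in 1:3) {
    ref <- fir_deriche_component(a, 0.8, axis)
    got <- list(g$gz, g$gy, g$gx)[[axis]]
    rel_rms <- sqrt(mean((got - ref)^2)) / sqrt(mean(ref^2))
    expect_lt(rel_rms, 1e-3)
  }
})

test_that("Deriche gradient vanishes on constants and localizes a step", {
  g <- deriche_gradient(voxel_volume(array(7, c(20, 20, 20)), 1), 0.5)
  expect_lt(max(g$magnitude), 1e-10)
  st <- array(0, c(16, 16, 32)); st[, , 17:32] <- 100
  gs <- deriche_gradient(voxel_volume(st, 1), 0.7)
  peak <- which(gs$magnitude == max(gs$magnitude), arr.ind = TRUE)
  expect_true(all(peak[, 3] %in% c(16, 17)))  # the step plane
  expect_lt(max(abs(gs$gy)), 1e-10)
  expect_lt(max(abs(gs$gz)), 1e-10)
  expect_error(deriche_gradient(voxel_volume(st, 1), 0), "alpha")
})

test_that("Canny edges hug the boundary of a bright cylinder", {
  d <- c(32, 48, 48)
  a <- array(80, d)
  a[cylinder_mask(d, 10, c(24.5, 24.5))] <- 200
  dim(a) <- d
  e <- canny_edges_3d(voxel_volume(a, 1))
  expect_gt(sum(e$data), 0)
  ec <- arrayInd(which(e$data), d)
  rho <- sqrt((ec[, 2] - 24.5)^2 + (ec[, 3] - 24.5)^2)
  expect_gte(mean(abs(rho - 10) <= 1), 0.95)
})

test_that("Canny degenerates safely: constants and unreachable thresholds", {
  cv <- voxel_volume(array(5, c(16, 16, 16)), 1)
  expect_identical(sum(canny_edges_3d(cv)$data), 0L)
  st <- array(0, c(16, 16, 32)); st[, , 17:32] <- 100
  v <- voxel_volume(st, 1)
  high <- edge_params(t_low = 1e6, t_high = 1e7)
  expect_identical(sum(canny_edges_3d(v, high)$data), 0L)
  expect_error(edge_params(t_low = 3, t_high = 1), "t_low")
})

test_that("combine_scales is an OR with geometry checks", {
  d <- c(8, 8, 8)
  a <- array(FALSE, d); a[2, 2, 2] <- TRUE
  b <- array(FALSE, d); b[5, 5, 5] <- TRUE
  ma <- binary_mask(a, 1); mb <- binary_mask(b, 1)
  expect_identical(combine_scales(ma, binary_mask(array(FALSE, d), 1))$data,
                   ma$data)
  expect_identical(combine_scales(ma, mb)$data, combine_scales(mb, ma)$data)
  expect_identical(sum(combine_scales(ma, mb)$data), 2L)
  expect_error(combine_scales(ma, binary_mask(array(FALSE, c(4, 8, 8)), 1)),
               "shape")
})

test_that("island removal applies the physical volume threshold strictly", {
  # at 0.94 um voxels: 2,000 voxels = 1,661 um^3 (removed),
  # 4,000 voxels = 3,322 um^3 (kept) under the 2.5e3 um^3 threshold
  d <- c(40, 40, 60)
  m <- array(FALSE, d)
  m[1:10, 1:10, 1:20] <- TRUE    # 2000 voxels
  m[20:29, 20:39, 31:50] <- TRUE # 4000 voxels
  out <- remove_small_objects(binary_mask(m, 0.94), 2.5e3)
  expect_identical(sum(out$data), 4000L)
  expect_true(all(which(out$data) %in% which(m)))
  # component exactly at the threshold volume is kept (strict "smaller than")
  d2 <- c(10, 10, 10)
  cube <- array(FALSE, d2); cube[4:6, 4:6, 4:6] <- TRUE  # 27 voxels
  at <- remove_small_objects(binary_mask(cube, 1), 27)
  expect_identical(sum(at$data), 27L)
  below <- remove_small_objects(binary_mask(cube, 1), 27 + 1e-9)
  expect_identical(sum(below$data), 0L)
  empty <- remove_small_objects(binary_mask(array(FALSE, d2), 1), 100)
  expect_identical(sum(empty$data), 0L)
})

test_that("closing bridges small gaps and is idempotent", {
  d <- c(40, 16, 16)
  m <- cylinder_mask(d, 3)
  m[20, , ] <- FALSE  # one-voxel gap
  dim(m) <- d
  closed <- close_3d(binary_mask(m, 1), 1)
  lab <- vesselmorph:::cpp_label26(closed$data)
  expect_identical(attr(lab, "n_components"), 1L)
  expect_identical(close_3d(closed, 1)$data, closed$data)
  expect_identical(sum(close_3d(binary_mask(array(FALSE, c(8, 8, 8)), 1),
                                1)$data), 0L)
  expect_error(close_3d(closed, 0), "radius")
})

test_that("fill_holes fills enclosed cavities and open tube lumens but
           never removes voxels", {
  d <- c(20, 20, 20)
  co <- arrayInd(seq_len(prod(d)), d)
  r2 <- rowSums(sweep(co, 2, c(10.5, 10.5, 10.5))^2)
  shell <- array(r2 <= 64 & r2 >= 36, d)
  filled <- fill_holes(binary_mask(shell, 1))
  expect_identical(filled$data, array(r2 <= 64, d))
  # open-ended cylindrical shell spanning z: lumen acquired via the
  # per-slice fill; interior count ~ pi r^2 L
  d2 <- c(30, 24, 24)
  rr <- cylinder_mask(d2, 10) & !cylinder_mask(d2, 8)
  dim(rr) <- d2
  fc <- fill_holes(binary_mask(rr, 1))
  expect_equal(sum(fc$data), 30 * pi * 100, tolerance = 0.05)
  # solid masks are unchanged; filling is monotone
  ball <- ball_mask(d, c(10.5, 10.5, 10.5), 8)
  expect_identical(fill_holes(binary_mask(ball, 1))$data, ball)
  expect_true(all(fc$data[rr]))
})

test_that("region growing equals flood fill within the intensity window", {
  # two intensity plateaus: tissue 100, paraffin 20
  d <- c(24, 24, 24)
  a <- array(20, d); a[, , 9:24] <- 100; dim(a) <- d
  grown <- region_grow_tissue(voxel_volume(a, 1), c(12, 12, 20), 80, 120)
  expect_identical(grown$data, array(a == 100, d))
  expect_error(region_grow_tissue(voxel_volume(a, 1), c(12, 12, 20), 150, 10),
               "lo")
  expect_error(region_grow_tissue(voxel_volume(a, 1), c(1, 1, 1), 80, 120),
               "seed")
  # random-threshold volumes: BFS oracle (plus the documented hole fill)
  for (seed in 1:5) {
    set.seed(seed)
    v <- array(sample(1:4, 20^3, TRUE), c(20, 20, 20))
    seedv <- c(10, 10, 10)
    v[10, 10, 10] <- 2
    ok <- v >= 2 & v <= 3
    dim(ok) <- dim(v)
    oracle <- bfs_flood(ok, 10 + 20 * 9 + 400 * 9)
    got <- region_grow_tissue(voxel_volume(v, 1), seedv, 2, 3)
    expect_identical(got$data, fill_holes(binary_mask(oracle, 1))$data)
  }
})

test_that("fine segmentation recovers a noise-free tube and returns empty
           for constant volumes", {
  ph <- tube_phantom(c(48, 40, 40), noise_sd = 0)
  seg <- segment_fine(ph$volume, edge_params(median_kernels = c(5, 9), min_object_um3 = 500))
  expect_gte(mask_dice(seg, ph$truth$vessel_mask), 0.95)
  cv <- voxel_volume(array(120, c(32, 32, 32)), 0.94)
  expect_identical(sum(segment_fine(cv)$data), 0L)
})

test_that("segmentation is invariant to an additive intensity offset", {
  ph <- tube_phantom(c(40, 36, 36), bright_fraction = 0.5, noise_sd = 10)
  p <- edge_params(median_kernels = c(5, 9), min_object_um3 = 500)
  seg1 <- segment_fine(ph$volume, p)
  shifted <- voxel_volume(ph$volume$data + 30, ph$volume$voxel_size_um)
  seg2 <- segment_fine(shifted, p)
  expect_identical(seg1$data, seg2$data)
})

test_that("post-processing stages are monotone in the documented sense", {
  for (seed in 1:3) {
    m <- random_blob(c(24, 24, 24), seed = seed)
    m[sample(length(m), 200)] <- TRUE   # add speckle
    dim(m) <- c(24, 24, 24)
    bm <- binary_mask(m, 1)
    expect_true(all(which(remove_small_objects(bm, 30)$data) %in% which(m)))
    expect_true(all(m[close_3d(bm, 1)$data == FALSE] == FALSE))
    expect_true(all(which(m) %in% which(close_3d(bm, 1)$data)))
    expect_true(all(which(m) %in% which(fill_holes(bm)$data)))
  }
})

test_that("coarse segmentation confines vessels to the tissue mask", {
  # tissue slab in paraffin, one tube inside it and one crossing out
  voxel <- 1
  d <- c(48, 48, 48)
  tissue <- array(FALSE, d); tissue[, , 13:48] <- TRUE
  a <- array(30, d); a[tissue] <- 120
  dim(a) <- d
  inside <- cylinder_mask(d, 4, c(24, 32))
  crossing <- array(FALSE, d)
  co <- arrayInd(seq_len(prod(d)), d)
  crossing[(co[, 2] - 24)^2 + (co[, 1] - 24)^2 <= 16] <- TRUE  # along x
  dim(crossing) <- d
  a[inside] <- 210; a[crossing] <- 210
  dim(a) <- d
  vol <- voxel_volume(a, voxel)
  tis <- binary_mask(tissue, voxel)
  p <- edge_params(min_object_um3 = 200)
  seg <- segment_coarse(vol, tis, p)
  expect_identical(sum(seg$data & !tissue), 0L)
  # the crossing tube is segmented only where it lies inside the tissue
  expect_gt(sum(seg$data & crossing & tissue), 0)
  expect_identical(sum(seg$data & crossing & !tissue), 0L)
  # an all-true tissue mask changes nothing relative to unmasked processing
  allt <- binary_mask(array(TRUE, d), voxel)
  seg_all <- segment_coarse(vol, allt, p)
  unmasked <- vesselmorph:::postprocess_edges(canny_edges_3d(vol, p), p)
  expect_identical(seg_all$data, unmasked$data)
})

test_that("the global-threshold baseline misses one lumen polarity", {
  ph <- tube_phantom(c(48, 40, 40), bright_fraction = 0.5, noise_sd = 8)
  truth <- ph$truth$vessel_mask
  base <- segment_global_threshold(ph$volume, "bright")
  # bright-side threshold finds at most (about) half the mixed lumen
  expect_lt(mask_dice(base, truth), 0.7)
})
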