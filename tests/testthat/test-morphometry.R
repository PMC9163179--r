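test_that("thinning reduces canonical shapes to their medial axes", {
  # straight solid tube spanning z: one branch along the axis
  d <- c(200, 24, 24)
  sk <- skeletonize_3d(binary_mask(cylinder_mask(d, 5), 1))
  expect_identical(nrow(sk$branches), 1L)
  expect_equal(sk$branches$length_um, 200, tolerance = 0.05)
  # solid torus: a single closed loop, no endpoints
  dt <- c(40, 40, 16)
  co <- arrayInd(seq_len(prod(dt)), dt)
  rho <- sqrt((co[, 1] - 20.5)^2 + (co[, 2] - 20.5)^2)
  torus <- array((rho - 12)^2 + (co[, 3] - 8.5)^2 <= 16, dt)
  skt <- skeletonize_3d(binary_mask(torus, 1))
  expect_identical(nrow(skt$branches), 1L)
  expect_true(skt$branches$is_loop)
  expect_identical(nrow(skt$nodes), 0L)
  # solid ball: collapses to at most 3 voxels
  db <- c(20, 20, 20)
  skb <- skeletonize_3d(binary_mask(ball_mask(db, c(10.5, 10.5, 10.5), 7), 1))
  expect_lte(nrow(skb$voxels), 3L)
  # empty mask: empty skeleton, not an error
  ske <- skeletonize_3d(binary_mask(array(FALSE, c(8, 8, 8)), 1))
  expect_identical(nrow(ske$voxels), 0L)
  expect_identical(nrow(ske$branches), 0L)
})

test_that("skeletonization preserves connectivity and loop structure", {
  n_comp <- function(m) attr(vesselmorph:::cpp_label26(m), "n_components")
  shapes <- list(
    two_balls = ball_mask(c(40, 20, 20), c(10, 10, 10), 6) |
      ball_mask(c(40, 20, 20), c(30, 10, 10), 6),
    blob = random_blob(c(28, 28, 28), seed = 4),
    tube = cylinder_mask(c(60, 20, 20), 4))
  for (nm in names(shapes)) {
    m <- shapes[[nm]]
    dim(m) <- dim(shapes[[nm]])
    sk <- skeletonize_3d(binary_mask(m, 1))
    skm <- skeleton_mask(sk)
    expect_identical(n_comp(skm$data), n_comp(m))
  }
})

test_that("pruning removes short free tips only, in a single pass", {
  # Y: two long arms and a 10 um terminal spur at the junction
  t1 <- tube_spec(rbind(c(10, 50, 50), c(110, 50, 50)), 4)
  t2 <- tube_spec(rbind(c(110, 50, 50), c(190, 90, 50)), 4)
  spur <- tube_spec(rbind(c(110, 50, 50), c(113, 40, 50)), 3)
  ph <- generate_phantom(phantom_spec(c(200, 100, 100), 1,
                                      list(t1, t2, spur),
                                      tissue_noise_sd = 0))
  sk <- skeletonize_3d(ph$truth$vessel_mask)
  pk <- prune_branches(sk, 25)
  # the spur is gone; the two arms remain (merged through the now-degree-2
  # junction) with essentially their full length
  expect_lt(total_skeleton_length_um(sk) - total_skeleton_length_um(pk), 25)
  expect_gt(total_skeleton_length_um(pk), 180)
  expect_true(all(pk$branches$length_um > 25))
  # no-op when everything is long enough; degrees recomputed
  expect_identical(nrow(prune_branches(pk, 25)$branches),
                   nrow(pk$branches))
  # a closed loop shorter than the cutoff is never pruned
  dt <- c(30, 30, 12)
  co <- arrayInd(seq_len(prod(dt)), dt)
  rho <- sqrt((co[, 1] - 15.5)^2 + (co[, 2] - 15.5)^2)
  torus <- array((rho - 8)^2 + (co[, 3] - 6.5)^2 <= 6, dt)
  skt <- skeletonize_3d(binary_mask(torus, 0.4))  # loop ~ 20 um
  expect_lt(total_skeleton_length_um(skt), 25)
  expect_identical(nrow(prune_branches(skt, 25)$branches), 1L)
})

test_that("vessel volume fraction follows the printed formula", {
  d <- c(100, 100, 100)
  roi <- binary_mask(array(TRUE, d), 1)
  cyl <- binary_mask(cylinder_mask(d, 10), 1)
  expect_identical(vessel_volume_fraction(roi, roi), 100)
  expect_identical(vessel_volume_fraction(binary_mask(array(FALSE, d), 1),
                                          roi), 0)
  expect_equal(vessel_volume_fraction(cyl, roi),
               100 * pi * 10^2 * 100 / 100^3, tolerance = 0.05)
  expect_error(vessel_volume_fraction(cyl, binary_mask(array(FALSE, d), 1)),
               "ROI")
})

test_that("length density applies the squared shrinkage correction exactly", {
  # build a skeleton whose total length is exactly 1 mm
  d <- c(1002, 5, 5)
  line <- array(FALSE, d); line[1:1001, 3, 3] <- TRUE
  sk <- skeletonize_3d(binary_mask(line, 1))  # 1000 steps of 1 um
  expect_equal(total_skeleton_length_um(sk), 1000)
  expect_equal(vessel_length_density(sk, 1e9, 1), 1)           # 1 mm / mm^3
  expect_equal(vessel_length_density(sk, 1e9, 0.8), 1.5625, tolerance = 1e-12)
  expect_error(vessel_length_density(sk, -1, 1), "roi_volume")
  expect_error(vessel_length_density(sk, 1e9, 0), "shrinkage")
})

test_that("shrinkage factor is the cube root of the volume ratio", {
  expect_identical(estimate_shrinkage(5, 5), 1)
  expect_equal(estimate_shrinkage(1, 0.512), 0.8)
  expect_error(estimate_shrinkage(0, 1), "> 0")
  expect_error(estimate_shrinkage(1, -2), "> 0")
})

test_that("local thickness matches closed forms for slabs and cylinders", {
  # slab of width 9: centre-to-centre radii read the width one voxel high
  # (the documented convention of the local-thickness plugin family), so
  # the interior value is (9 + 1) * voxel size exactly
  d <- c(20, 20, 20)
  slab <- array(FALSE, d); slab[, 6:14, ] <- TRUE
  th <- local_thickness(binary_mask(slab, 2))
  expect_equal(th$data[10, 10, 10], 10 * 2, tolerance = 1e-12)
  expect_true(all(th$data[!slab] == 0))
  # cylinder radius 5: on-axis thickness 10 voxels +- 1
  dc <- c(40, 24, 24)
  cyl <- cylinder_mask(dc, 5, c(12, 12))
  thc <- local_thickness(binary_mask(cyl, 0.94))
  axis_vals <- thc$data[, 12, 12] / 0.94
  expect_true(all(abs(axis_vals - 10) <= 1))
})

test_that("local thickness equals the exhaustive inscribed-sphere oracle", {
  m <- random_blob(c(14, 14, 14), n_balls = 2, seed = 9)
  dim(m) <- c(14, 14, 14)
  th <- local_thickness(binary_mask(m, 1))
  edt <- brute_edt_sq(m)
  co <- arrayInd(seq_len(prod(dim(m))), dim(m))
  fg <- which(m)
  fgco <- co[fg, , drop = FALSE]
  r2 <- edt[fg]   # squared radius of each inscribed sphere
  for (i in seq_along(fg)) {
    d2 <- rowSums(sweep(fgco, 2, fgco[i, ])^2)
    covering <- d2 <= r2 | seq_along(fg) == i
    oracle <- 2 * sqrt(max(r2[covering]))
    expect_equal(th$data[fg[i]], oracle, tolerance = 1e-12)
  }
})

test_that("local thickness is monotone under dilation", {
  m <- random_blob(c(20, 20, 20), seed = 2)
  dim(m) <- c(20, 20, 20)
  th1 <- local_thickness(binary_mask(m, 1))
  dil <- vesselmorph:::cpp_dilate(m, vesselmorph:::ball_offsets(1))
  th2 <- local_thickness(binary_mask(array(dil, dim(m)), 1))
  expect_true(all(th2$data[m] >= th1$data[m]))
})

test_that("diameter histograms are anchored at zero and find the mode", {
  dc <- c(60, 24, 24)
  cyl <- binary_mask(cylinder_mask(dc, 5, c(12, 12)), 0.94)
  sk <- skeletonize_3d(cyl)
  th <- local_thickness(cyl)
  dd <- diameter_distribution(sk, th, bin_width_um = 1.6)
  # d = 9.4 um truth: the mode bin must cover it
  expect_lte(dd$mode_bin_um[1], 9.4)
  expect_gt(dd$mode_bin_um[2], 9.4 - 1.6)
  expect_identical(sum(dd$histogram$count), nrow(sk$voxels))
  expect_equal(dd$histogram$bin_lo_um,
               seq(0, by = 1.6, length.out = nrow(dd$histogram)))
  # empty skeleton: empty histogram
  ske <- skeletonize_3d(binary_mask(array(FALSE, c(8, 8, 8)), 1))
  the <- local_thickness(binary_mask(array(FALSE, c(8, 8, 8)), 1))
  dde <- diameter_distribution(ske, the)
  expect_identical(nrow(dde$histogram), 0L)
  expect_null(dde$mode_bin_um)
})
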