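# Shared fixture builders: all fixtures are generated in code.

# reflect 1-based indices into [1, n] (symmetric / half-sample)
reflect_idx <- function(i, n) {
  while (any(i < 1 | i > n)) {
    i[i < 1] <- 1 - i[i < 1]
    i[i > n] <- 2 * n + 1 - i[i > n]
  }
  i
}

# solid cylinder along z spanning the volume; centre in-plane, radius in vox
cylinder_mask <- function(dim, radius_vox, center = (dim[2:3] + 1) / 2) {
  co <- arrayInd(seq_len(prod(dim)), dim)
  m <- (co[, 2] - center[1])^2 + (co[, 3] - center[2])^2 <= radius_vox^2
  array(m, dim)
}

ball_mask <- function(dim, center, radius_vox) {
  co <- arrayInd(seq_len(prod(dim)), dim)
  m <- rowSums(sweep(co, 2, center)^2) <= radius_vox^2
  array(m, dim)
}

# random interior blob: union of a few random balls, away from the border
random_blob <- function(dim, n_balls = 3, seed = 1) {
  set.seed(seed)
  m <- array(FALSE, dim)
  for (i in seq_len(n_balls)) {
    ctr <- sapply(dim, function(n) runif(1, n * 0.3, n * 0.7))
    m <- m | ball_mask(dim, ctr, runif(1, min(dim) * 0.12, min(dim) * 0.22))
  }
  m
}

# exhaustive per-voxel neighbourhood median with reflected borders
brute_median3d <- function(a, k) {
  d <- dim(a)
  p <- k %/% 2
  out <- array(0, d)
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    nb <- a[reflect_idx((z - p):(z + p), d[1]),
            reflect_idx((y - p):(y + p), d[2]),
            reflect_idx((x - p):(x + p), d[3])]
    out[z, y, x] <- median(nb)
  }
  out
}

# FIR convolution oracle for the Deriche gradient along one axis
# (analytic kernels truncated at `taps`, symmetric reflection)
fir_deriche_component <- function(a, alpha, axis, taps = 40) {
  e <- exp(-alpha)
  s <- -taps:taps
  kk <- (1 - e)^2 / (1 + 2 * alpha * e - e^2)
  smooth_k <- kk * (alpha * abs(s) + 1) * exp(-alpha * abs(s))
  cc <- (1 - e)^3 / (2 * e * (1 + e))
  deriv_k <- rev(-cc * s * exp(-alpha * abs(s)))
  conv_axis <- function(arr, ker, ax) {
    out <- array(0, dim(arr))
    nn <- dim(arr)[ax]
    for (i in seq_along(s)) {
      idx <- reflect_idx(seq_len(nn) + s[i], nn)
      sl <- switch(ax, arr[idx, , , drop = FALSE], arr[, idx, , drop = FALSE],
                   arr[, , idx, drop = FALSE])
      out <- out + ker[i] * sl
    }
    out
  }
  res <- conv_axis(a, deriv_k, axis)
  for (other in setdiff(1:3, axis)) res <- conv_axis(res, smooth_k, other)
  res
}

# breadth-first flood fill over a boolean array from seed voxels,
# 26-connectivity, frontier-vectorized (independent of the package's
# labelling kernel)
bfs_flood <- function(ok, seeds_idx) {
  d <- dim(ok)
  visited <- array(FALSE, d)
  frontier <- unique(seeds_idx[ok[seeds_idx]])
  visited[frontier] <- TRUE
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  while (length(frontier)) {
    co <- arrayInd(frontier, d)
    nxt <- integer(0)
    for (r in seq_len(nrow(offs))) {
      p <- sweep(co, 2, -offs[r, ])
      keep <- p[, 1] >= 1 & p[, 1] <= d[1] & p[, 2] >= 1 & p[, 2] <= d[2] &
        p[, 3] >= 1 & p[, 3] <= d[3]
      if (!any(keep)) next
      i <- p[keep, 1] + d[1] * (p[keep, 2] - 1) + d[1] * d[2] * (p[keep, 3] - 1)
      i <- i[ok[i] & !visited[i]]
      visited[i] <- TRUE
      nxt <- c(nxt, i)
    }
    frontier <- unique(nxt)
  }
  visited
}

# brute-force squared EDT (distance to nearest background voxel centre)
brute_edt_sq <- function(m) {
  d <- dim(m)
  co <- arrayInd(seq_len(prod(d)), d)
  bg <- co[!m, , drop = FALSE]
  out <- array(0, d)
  for (i in which(m)) {
    out[i] <- min(rowSums(sweep(bg, 2, co[i, ])^2))
  }
  out
}
# a small noisy tube phantom used by several segmentation tests
tube_phantom <- function(shape = c(64, 64, 64), radius_um = 5.6,
                         bright_fraction = 1, noise_sd = 16, seed = 1,
                         voxel = 0.94) {
  ext <- (shape - 1) * voxel
  tb <- tube_spec(rbind(c(0, ext[2] / 2, ext[3] / 2),
                        c(ext[1], ext[2] / 2, ext[3] / 2)),
                  radius_um, bright_fraction)
  generate_phantom(phantom_spec(shape, voxel, list(tb),
                                tissue_noise_sd = noise_sd, rng_seed = seed))
}
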