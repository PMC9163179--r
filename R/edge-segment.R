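#' Edge-detection and post-processing parameters
#'
#' Parameters of the edge-based segmentation pipeline.  The hysteresis
#' thresholds may be given as absolute gradient magnitudes (`t_low`,
#' `t_high`) or derived automatically, per volume, from the distribution
#' of the non-zero suppressed gradient magnitude — which makes the
#' defaults intensity-scale-free:
#' * `"noise_adaptive"` (default): `t_high` is the larger of two
#'   scale-free estimates on the log suppressed magnitudes — Otsu's
#'   threshold (which separates modes when edges carry appreciable mass
#'   but can sink into a broad noise mode when vessels are rare) and the
#'   decay point of the dominant noise mode (the first histogram bin
#'   right of the global mode below 1 percent of the mode height with
#'   mass remaining beyond it; absent in near-noise-free volumes).
#'   Taking the maximum keeps the threshold above the noise floor in
#'   both regimes.  `t_low = low_high_ratio * t_high`.
#' * `"otsu_log"`: always use Otsu's threshold on the log magnitudes.
#'   Works when edges carry an appreciable share of the survivors, but
#'   the split can fall inside a broad noise mode when vessels are rare.
#' * `"quantile"`: thresholds at `threshold_quantiles` of the non-zero
#'   suppressed magnitude.  Rank-based, so only appropriate when the
#'   foreground fraction is known and stable.
#'
#' @param alpha Deriche smoothing parameter (> 0; smaller = smoother).
#' @param t_low,t_high absolute hysteresis thresholds on gradient
#'   magnitude; `NULL` (default) derives them via `threshold_method`.
#' @param threshold_method `"noise_adaptive"`, `"otsu_log"` or
#'   `"quantile"` (see above).
#' @param low_high_ratio `t_low / t_high` for the automatic methods
#'   (classic Canny 1:2 ratio by default).
#' @param threshold_quantiles length-2 vector of quantiles of the non-zero
#'   suppressed gradient magnitude for `threshold_method = "quantile"`.
#' @param median_kernels odd kernel sizes of the dual-scale median
#'   pre-filter (the fine workflow uses 7 and 19; the coarse workflow uses
#'   none).
#' @param min_object_um3 island-removal threshold: connected components
#'   with physical volume strictly smaller than this are removed.
#' @param closing_radius_vox radius (voxels) of the ball used by the
#'   morphological closing.  The default of 2 matters for downstream
#'   skeletonization: a radius-1 ball is just the 6-neighbourhood and
#'   cannot seal the corner-touch micro-handles and wall pores of a noisy
#'   edge shell, which otherwise survive as thousands of spurious
#'   topological loops in the (topology-preserving) skeleton.
#' @return An object of class `edge_params`.
#' @export
edge_params <- function(alpha = 0.5, t_low = NULL, t_high = NULL,
                        threshold_method = c("noise_adaptive", "otsu_log",
                                             "quantile"),
                        low_high_ratio = 0.5,
                        threshold_quantiles = c(0.70, 0.90),
                        median_kernels = c(7L, 19L),
                        min_object_um3 = 2.5e3, closing_radius_vox = 2L) {
  threshold_method <- match.arg(threshold_method)
  if (alpha <= 0) stop("`alpha` must be > 0", call. = FALSE)
  if (!is.null(t_low) && !is.null(t_high)) {
    if (t_low <= 0 || t_low > t_high)
      stop("thresholds must satisfy 0 < t_low <= t_high", call. = FALSE)
  } else if (xor(is.null(t_low), is.null(t_high))) {
    stop("give both `t_low` and `t_high`, or neither", call. = FALSE)
  } else {
    if (low_high_ratio <= 0 || low_high_ratio > 1)
      stop("`low_high_ratio` must be in (0, 1]", call. = FALSE)
    if (length(threshold_quantiles) != 2L ||
        any(threshold_quantiles <= 0) || any(threshold_quantiles >= 1) ||
        threshold_quantiles[1] > threshold_quantiles[2])
      stop("`threshold_quantiles` must be increasing and inside (0, 1)",
           call. = FALSE)
  }
  median_kernels <- as.integer(median_kernels)
  if (length(median_kernels) &&
      (any(median_kernels < 3L) || any(median_kernels %% 2L == 0L)))
    stop("median kernels must be odd and >= 3", call. = FALSE)
  if (min_object_um3 < 0) stop("`min_object_um3` must be >= 0", call. = FALSE)
  if (closing_radius_vox < 1L)
    stop("`closing_radius_vox` must be >= 1", call. = FALSE)
  structure(list(alpha = alpha, t_low = t_low, t_high = t_high,
                 threshold_method = threshold_method,
                 low_high_ratio = low_high_ratio,
                 threshold_quantiles = threshold_quantiles,
                 median_kernels = median_kernels,
                 min_object_um3 = min_object_um3,
                 closing_radius_vox = as.integer(closing_radius_vox)),
            class = "edge_params")
}

#' 3D median filter
#'
#' Each output voxel is the exact median of its k^3 neighbourhood, with
#' symmetric reflection at the borders.  Integer-valued volumes use an
#' exact running-histogram implementation; other volumes fall back to an
#' exhaustive per-voxel median.
#'
#' @param vol a [voxel_volume()].
#' @param k odd kernel size, >= 3.
#' @return A [voxel_volume()] of the same geometry.
#' @export
median_filter_3d <- function(vol, k) {
  stopifnot(inherits(vol, "voxel_volume"))
  k <- as.integer(k)
  if (length(k) != 1L || k < 3L || k %% 2L == 0L)
    stop("`k` must be a single odd integer >= 3", call. = FALSE)
  a <- vol$data
  lo <- min(a)
  # the histogram path needs an integer lattice; volumes straight from a
  # scanner are integers, downscaled ones live on a 1/8 grid
  mult <- NA
  if (all(is.finite(a))) {
    for (m in c(1, 2, 4, 8)) {
      if ((max(a) - lo) * m < 65536 && all(a * m == round(a * m))) {
        mult <- m
        break
      }
    }
  }
  out <- if (!is.na(mult)) {
    shifted <- (a - lo) * mult
    res <- cpp_median3d_int(shifted, k, as.integer(max(shifted)) + 1L)
    res / mult + lo
  } else {
    cpp_median3d_brute(a, k)
  }
  dim(out) <- dim(a)
  voxel_volume(out, vol$voxel_size_um)
}

#' Deriche recursive gradient
#'
#' Separable recursive (IIR) Deriche filtering: the derivative operator
#' along one axis combined with Deriche smoothing along the other two,
#' for each of the three axes; the magnitude is the Euclidean norm of the
#' three components.  Borders are handled by symmetric reflection.
#'
#' @param vol a [voxel_volume()].
#' @param alpha smoothing parameter (> 0; smaller = smoother).
#' @return A list with numeric arrays `gz`, `gy`, `gx` and `magnitude`.
#' @export
deriche_gradient <- function(vol, alpha = 0.5) {
  stopifnot(inherits(vol, "voxel_volume"))
  if (alpha <= 0) stop("`alpha` must be > 0", call. = FALSE)
  a <- vol$data
  grad1 <- function(axis) {
    g <- cpp_deriche_axis(a, alpha, axis, 1L)
    for (other in setdiff(0:2, axis)) g <- cpp_deriche_axis(g, alpha, other, 0L)
    g
  }
  gz <- grad1(0L); gy <- grad1(1L); gx <- grad1(2L)
  mag <- sqrt(gz^2 + gy^2 + gx^2)
  dim(mag) <- dim(a)
  list(gz = gz, gy = gy, gx = gx, magnitude = mag)
}

#' 3D Canny edge detection
#'
#' Deriche gradient, non-maximum suppression along the 26-quantized
#' gradient direction, then hysteresis: weak edges (>= `t_low`) are kept
#' only when 26-connected to a strong edge (>= `t_high`).  The output is a
#' thin boundary-shell mask.
#'
#' @param vol a [voxel_volume()].
#' @param params an [edge_params()].
#' @return A [binary_mask()] of edge voxels.
#' @export
canny_edges_3d <- function(vol, params = edge_params()) {
  stopifnot(inherits(vol, "voxel_volume"), inherits(params, "edge_params"))
  g <- deriche_gradient(vol, params$alpha)
  nms <- cpp_nms26(g$gz, g$gy, g$gx)
  # numerical floor: gradients below 1e-9 of the intensity range are
  # round-off, not structure (a constant volume must give no edges)
  floor_mag <- max(1e-9 * diff(range(vol$data)),
                   1e-12 * (max(abs(vol$data)) + 1))
  nms[nms <= floor_mag] <- 0
  if (is.null(params$t_low)) {
    nz <- nms[nms > 0]
    if (length(nz) == 0L)
      return(binary_mask(array(FALSE, dim(vol$data)), vol$voxel_size_um))
    if (params$threshold_method %in% c("noise_adaptive", "otsu_log")) {
      t_high <- if (params$threshold_method == "noise_adaptive")
        noise_mode_cut(nz) else 10^otsu_threshold(log10(nz))
      t_low <- params$low_high_ratio * t_high
    } else {
      th <- stats::quantile(nz, params$threshold_quantiles, names = FALSE)
      t_low <- th[1]; t_high <- th[2]
    }
  } else {
    t_low <- params$t_low; t_high <- params$t_high
  }
  edges <- cpp_hysteresis(nms, t_low, t_high)
  binary_mask(edges, vol$voxel_size_um)
}

#' Combine edge maps from two filter scales
#'
#' Voxelwise logical OR of the fine- and coarse-scale edge maps.
#'
#' @param edge_fine,edge_coarse [binary_mask()] objects with identical
#'   geometry.
#' @return A [binary_mask()].
#' @export
combine_scales <- function(edge_fine, edge_coarse) {
  check_same_geometry(edge_fine, edge_coarse, "edge maps")
  binary_mask(edge_fine$data | edge_coarse$data, edge_fine$voxel_size_um)
}

#' Remove small connected components ("islands")
#'
#' Deletes 26-connected components whose physical volume is strictly
#' smaller than `min_object_um3`; components exactly at the threshold are
#' kept.
#'
#' @param mask a [binary_mask()].
#' @param min_object_um3 volume threshold in cubic micrometres.
#' @return A [binary_mask()].
#' @export
remove_small_objects <- function(mask, min_object_um3 = 2.5e3) {
  stopifnot(inherits(mask, "binary_mask"))
  lab <- cpp_label26(mask$data)
  n <- attr(lab, "n_components")
  if (n == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  keep <- sizes * voxel_volume_um3(mask) >= min_object_um3
  out <- array(lab > 0L & keep[pmax(lab, 1L)], dim = dim(mask$data))
  binary_mask(out, mask$voxel_size_um)
}

#' Morphological closing with a ball structuring element
#'
#' Dilation followed by erosion with the discrete Euclidean ball of the
#' given radius; bridges small gaps in the vessel structure.
#'
#' @param mask a [binary_mask()].
#' @param radius_vox ball radius in voxels (>= 1).
#' @return A [binary_mask()].
#' @export
close_3d <- function(mask, radius_vox = 1L) {
  stopifnot(inherits(mask, "binary_mask"))
  if (radius_vox < 1) stop("`radius_vox` must be >= 1", call. = FALSE)
  off <- ball_offsets(radius_vox)
  out <- cpp_erode(cpp_dilate(mask$data, off), off)
  binary_mask(out, mask$voxel_size_um)
}

#' Fill cavities inside the vascular space
#'
#' Two complementary fills, unioned:
#' * fully enclosed 3D cavities (6-connected background components not
#'   reaching the volume border);
#' * tri-axial 2D per-slice hole filling along z, y and x, so open-ended
#'   tubular edge shells — whose lumens are 3D-connected to the exterior
#'   through the tube mouths but form closed rings in cross-section —
#'   acquire solid lumens at any tube orientation.
#'
#' @param mask a [binary_mask()].
#' @return A [binary_mask()]; never removes voxels.
#' @export
fill_holes <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  out <- cpp_fill_holes_3d(mask$data)
  for (axis in 0:2)
    out <- out | cpp_fill_holes_slices(mask$data, axis)
  out <- array(out, dim = dim(mask$data))
  binary_mask(out, mask$voxel_size_um)
}

#' Region-growing tissue segmentation
#'
#' The 26-connected component of voxels with intensity inside `[lo, hi]`
#' that contains the seed, followed by [fill_holes()] so interior vascular
#' spaces belong to the tissue mask.
#'
#' @param vol a [voxel_volume()].
#' @param seed_vox integer triple `(z, y, x)`, 1-based voxel index of the
#'   seed; its intensity must lie inside `[lo, hi]`.
#' @param lo,hi inclusive intensity window.
#' @return A [binary_mask()] of the grown tissue region.
#' @export
region_grow_tissue <- function(vol, seed_vox, lo, hi) {
  stopifnot(inherits(vol, "voxel_volume"))
  if (lo > hi) stop("`lo` must be <= `hi`", call. = FALSE)
  seed_vox <- as.integer(seed_vox)
  if (length(seed_vox) != 3L || any(seed_vox < 1L) ||
      any(seed_vox > dim(vol$data)))
    stop("`seed_vox` must be a (z, y, x) index inside the volume",
         call. = FALSE)
  sv <- vol$data[seed_vox[1], seed_vox[2], seed_vox[3]]
  if (sv < lo || sv > hi)
    stop("seed intensity is outside [lo, hi]", call. = FALSE)
  inwin <- vol$data >= lo & vol$data <= hi
  dim(inwin) <- dim(vol$data)
  lab <- cpp_label26(inwin)
  seed_lab <- lab[seed_vox[1], seed_vox[2], seed_vox[3]]
  grown <- array(lab == seed_lab & seed_lab > 0L, dim = dim(vol$data))
  fill_holes(binary_mask(grown, vol$voxel_size_um))
}

#' Fine-resolution vessel segmentation
#'
#' The high-resolution workflow: for each median kernel size, median
#' filtering followed by Deriche-Canny edge detection; the edge maps of
#' the two scales are combined by logical OR (the small kernel preserves
#' capillaries, the large kernel preserves larger vessels with weaker edge
#' contrast); then island removal, closing and hole filling, in that
#' order.
#'
#' @param vol a [voxel_volume()].
#' @param params an [edge_params()]; `median_kernels` defaults to 7 and 19.
#' @return A [binary_mask()] of the vascular space.
#' @export
segment_fine <- function(vol, params = edge_params()) {
  stopifnot(inherits(vol, "voxel_volume"), inherits(params, "edge_params"))
  kernels <- params$median_kernels
  if (length(kernels) == 0L)
    stop("fine segmentation needs at least one median kernel", call. = FALSE)
  edges <- NULL
  for (k in kernels) {
    ek <- canny_edges_3d(median_filter_3d(vol, k), params)
    edges <- if (is.null(edges)) ek else combine_scales(edges, ek)
  }
  postprocess_edges(edges, params)
}

#' Coarse-resolution vessel segmentation
#'
#' The low-resolution workflow: the Deriche-Canny edge filter is applied
#' directly (no median pre-filtering); edges outside the tissue — notably
#' the tissue-paraffin boundary shell — are masked out using the tissue
#' mask eroded by one voxel; then the shared post-processing.
#'
#' @param vol a [voxel_volume()].
#' @param tissue a [binary_mask()] of the tissue, aligned with `vol`
#'   (e.g. from [region_grow_tissue()]).
#' @param params an [edge_params()].
#' @return A [binary_mask()].
#' @export
segment_coarse <- function(vol, tissue, params = edge_params()) {
  stopifnot(inherits(vol, "voxel_volume"), inherits(tissue, "binary_mask"))
  check_same_geometry(vol, tissue, "volume and tissue mask")
  edges <- canny_edges_3d(vol, params)
  interior <- cpp_erode(tissue$data, ball_offsets(1L))
  masked <- binary_mask(array(edges$data & interior, dim = dim(edges$data)),
                        edges$voxel_size_um)
  postprocess_edges(masked, params)
}

# island removal -> closing -> hole filling (shared post-processing order)
postprocess_edges <- function(edges, params) {
  out <- remove_small_objects(edges, params$min_object_um3)
  out <- close_3d(out, params$closing_radius_vox)
  fill_holes(out)
}

#' Global-threshold baseline segmentation
#'
#' Single global intensity threshold (Otsu) keeping one polarity only —
#' the standard approach that the edge-based pipeline is designed to
#' outperform when the lumen contrast is mixed, since a one-sided
#' threshold necessarily misses the other lumen polarity.
#'
#' @param vol a [voxel_volume()].
#' @param polarity `"bright"` keeps voxels above the threshold, `"dark"`
#'   below.
#' @return A [binary_mask()].
#' @export
segment_global_threshold <- function(vol, polarity = c("bright", "dark")) {
  stopifnot(inherits(vol, "voxel_volume"))
  polarity <- match.arg(polarity)
  thr <- otsu_threshold(vol$data)
  keep <- if (polarity == "bright") vol$data > thr else vol$data < thr
  binary_mask(array(keep, dim = dim(vol$data)), vol$voxel_size_um)
}

# Strong-edge threshold from the log-magnitude histogram: the larger of
# Otsu's split and the decay point of the dominant (noise) mode — the
# first bin right of the global mode below 1% of its height with mass
# remaining beyond it.
noise_mode_cut <- function(nz) {
  lg <- log10(nz)
  t_otsu <- otsu_threshold(lg)
  h <- graphics::hist(lg, breaks = 64, plot = FALSE)
  counts <- as.numeric(stats::filter(h$counts, rep(1 / 5, 5), sides = 2))
  counts[is.na(counts)] <- h$counts[is.na(counts)]  # unsmoothed ends
  gm <- which.max(counts)
  nb <- length(counts)
  t_decay <- -Inf
  total <- sum(h$counts)
  # the decay cut is only a correction for the case where Otsu's split has
  # sunk into (or left of) a dominant noise mode; when Otsu already sits
  # right of the global mode, or the mode does not carry the majority of
  # the survivors (then it is just the strongest *edge* family), trust Otsu
  if (t_otsu <= h$mids[gm] && gm < nb - 1L) {
    for (i in seq(gm + 1L, nb - 1L)) {
      if (counts[i] <= 0.01 * counts[gm] &&
          sum(h$counts[seq_len(i)]) >= 0.5 * total &&
          sum(h$counts[seq(i + 1L, nb)]) > 0) {
        t_decay <- h$mids[i]
        break
      }
    }
  }
  10^max(t_otsu, t_decay)
}

# Otsu's threshold on a 256-bin histogram
otsu_threshold <- function(x) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = 257L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = 256L)
  p <- h / sum(h)
  mids <- (br[-1] + br[-257]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[256]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}
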