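#' Seed region
#'
#' A labelled seed mask used for geodesic vessel selection (e.g. the
#' intercollicular sulcus for central collicular vessels, or the
#' collicular surface for peripheral ones).
#'
#' @param mask a non-empty [binary_mask()].
#' @param label free-text anatomical label.
#' @return An object of class `seed_region`.
#' @export
seed_region <- function(mask, label = "seed") {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$data)) stop("seed region is empty", call. = FALSE)
  structure(list(mask = mask, label = label), class = "seed_region")
}

#' Geodesic selection of vessel components from a seed region
#'
#' Morphological reconstruction by dilation of `seed & mask` under `mask`:
#' the union of 26-connected components of the vessel mask that intersect
#' the seed.
#'
#' @param mask vessel [binary_mask()].
#' @param seed a [seed_region()] (or a [binary_mask()]) aligned with
#'   `mask`.
#' @return A [binary_mask()] of the reached components.
#' @export
geodesic_select <- function(mask, seed) {
  stopifnot(inherits(mask, "binary_mask"))
  seed_mask <- if (inherits(seed, "seed_region")) seed$mask else seed
  stopifnot(inherits(seed_mask, "binary_mask"))
  if (!any(seed_mask$data)) stop("seed region is empty", call. = FALSE)
  check_same_geometry(mask, seed_mask, "mask and seed")
  lab <- cpp_label26(mask$data)
  hit <- unique(lab[seed_mask$data & lab > 0L])
  out <- array(lab %in% hit & lab > 0L, dim = dim(mask$data))
  binary_mask(out, mask$voxel_size_um)
}

#' Split vessels into central and peripheral classes by seed reachability
#'
#' Components reached from the sulcus seed are labelled `central`;
#' components reached from the surface seed `peripheral`; components
#' reached from both are labelled `central` (precedence rule) and flagged
#' ambiguous; the rest are `unassigned`.
#'
#' @param mask vessel [binary_mask()].
#' @param sulcus_seed seed for central vessels ([seed_region()]).
#' @param surface_seed seed for peripheral vessels ([seed_region()]).
#' @return A list with `components` (data frame: `component_id`, `class`,
#'   `ambiguous`, `voxel_count`), `labels` (integer array of component
#'   ids), `central` and `peripheral` ([binary_mask()]s).
#' @export
split_central_peripheral <- function(mask, sulcus_seed, surface_seed) {
  stopifnot(inherits(mask, "binary_mask"))
  s1 <- if (inherits(sulcus_seed, "seed_region")) sulcus_seed$mask else sulcus_seed
  s2 <- if (inherits(surface_seed, "seed_region")) surface_seed$mask else surface_seed
  if (!any(s1$data) || !any(s2$data))
    stop("seed region is empty", call. = FALSE)
  check_same_geometry(mask, s1, "mask and sulcus seed")
  check_same_geometry(mask, s2, "mask and surface seed")
  lab <- cpp_label26(mask$data)
  ncomp <- attr(lab, "n_components")
  from_sulcus <- unique(lab[s1$data & lab > 0L])
  from_surface <- unique(lab[s2$data & lab > 0L])
  cls <- rep("unassigned", ncomp)
  cls[from_surface] <- "peripheral"
  cls[from_sulcus] <- "central"      # precedence: central wins
  amb <- seq_len(ncomp) %in% intersect(from_sulcus, from_surface)
  counts <- tabulate(lab[lab > 0L], nbins = ncomp)
  comp <- data.frame(component_id = seq_len(ncomp), class = cls,
                     ambiguous = amb, voxel_count = counts)
  dimlab <- array(lab, dim = dim(mask$data))
  mk <- function(classes) {
    binary_mask(array(dimlab > 0L & cls[pmax(dimlab, 1L)] %in% classes,
                      dim = dim(mask$data)), mask$voxel_size_um)
  }
  list(components = comp, labels = dimlab,
       central = mk("central"), peripheral = mk("peripheral"))
}

# parse a face spec like "y+" into list(axis = 2, side = +1)
parse_face <- function(face) {
  if (!is.character(face) || length(face) != 1L ||
      !grepl("^[zyx][+-]$", face))
    stop('`fov_far_face` must be one of "z-","z+","y-","y+","x-","x+"',
         call. = FALSE)
  axis <- match(substr(face, 1, 1), c("z", "y", "x"))
  side <- if (substr(face, 2, 2) == "+") 1L else -1L
  list(axis = axis, side = side)
}

#' Classify vessel components as short or long by field-of-view reach
#'
#' A component is `long` iff it contains a voxel within `tolerance_vox` of
#' the specified far face of the field of view (it "reaches the end of the
#' field of view"); otherwise it is `short` (it ends within the field of
#' view).
#'
#' @param mask vessel [binary_mask()].
#' @param fov_far_face face specification: `"z-"`, `"z+"`, `"y-"`, `"y+"`,
#'   `"x-"` or `"x+"` (axis and side).
#' @param tolerance_vox how close to the face (in voxels) counts as
#'   reaching it; default 2, robust to border erosion of the
#'   reconstruction.
#' @return A list with `components` (data frame: `component_id`,
#'   `length_class`, `voxel_count`), `labels`, `short` and `long`
#'   ([binary_mask()]s).
#' @export
classify_short_long <- function(mask, fov_far_face, tolerance_vox = 2L) {
  stopifnot(inherits(mask, "binary_mask"))
  f <- parse_face(fov_far_face)
  d <- dim(mask$data)
  lab <- cpp_label26(mask$data)
  ncomp <- attr(lab, "n_components")
  dimlab <- array(lab, dim = d)
  # slab of voxels within tolerance of the far face
  n_ax <- d[f$axis]
  sel <- if (f$side > 0) seq(max(1L, n_ax - tolerance_vox), n_ax)
         else seq(1L, min(n_ax, 1L + tolerance_vox))
  slab <- switch(f$axis,
                 dimlab[sel, , , drop = FALSE],
                 dimlab[, sel, , drop = FALSE],
                 dimlab[, , sel, drop = FALSE])
  long_ids <- unique(slab[slab > 0L])
  lclass <- ifelse(seq_len(ncomp) %in% long_ids, "long", "short")
  counts <- tabulate(lab[lab > 0L], nbins = ncomp)
  comp <- data.frame(component_id = seq_len(ncomp), length_class = lclass,
                     voxel_count = counts)
  mk <- function(cl) {
    binary_mask(array(dimlab > 0L & lclass[pmax(dimlab, 1L)] == cl, dim = d),
                mask$voxel_size_um)
  }
  list(components = comp, labels = dimlab, short = mk("short"),
       long = mk("long"))
}

#' Maximum inscribed-sphere diameter of a vessel component
#'
#' Twice the maximum Euclidean distance from a component voxel to the
#' nearest background voxel, in micrometres — the diameter of the largest
#' inscribed sphere under the same centre-to-centre distance convention as
#' [local_thickness()].
#'
#' @param component a non-empty [binary_mask()] containing the component
#'   (any other structures should be absent from the mask).
#' @return Diameter in micrometres.
#' @export
max_inscribed_diameter <- function(component) {
  stopifnot(inherits(component, "binary_mask"))
  if (!any(component$data)) stop("empty component", call. = FALSE)
  edt2 <- cpp_edt_sq(component$data)
  2 * sqrt(max(edt2)) * component$voxel_size_um
}

#' Per-component maximum inscribed diameters
#'
#' Labels the mask (26-connectivity) and computes
#' [max_inscribed_diameter()] for each component on its own cropped
#' bounding box.
#'
#' @param mask vessel [binary_mask()].
#' @return Data frame with `component_id`, `voxel_count`,
#'   `max_diameter_um`.
#' @export
component_max_diameters <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  lab <- cpp_label26(mask$data)
  ncomp <- attr(lab, "n_components")
  dimlab <- array(lab, dim = dim(mask$data))
  counts <- tabulate(lab[lab > 0L], nbins = ncomp)
  dia <- vapply(seq_len(ncomp), function(k) {
    w <- which(dimlab == k, arr.ind = TRUE)
    rng <- apply(w, 2, range)
    sub <- dimlab[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2],
                  rng[1, 3]:rng[2, 3], drop = FALSE] == k
    sub <- array(sub, dim = c(rng[2, 1] - rng[1, 1] + 1L,
                              rng[2, 2] - rng[1, 2] + 1L,
                              rng[2, 3] - rng[1, 3] + 1L))
    max_inscribed_diameter(binary_mask(sub, mask$voxel_size_um))
  }, numeric(1))
  data.frame(component_id = seq_len(ncomp), voxel_count = counts,
             max_diameter_um = dia)
}

#' Two-sample Student t-test (pooled variance)
#'
#' Classical two-sample t-test with pooled variance and
#' `df = n_a + n_b - 2`, two-sided.  Degenerate input (zero pooled
#' variance with equal means) yields `t = 0`, `p = 1`; zero pooled
#' variance with different means is an error.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return A list with `statistic`, `p_value`, `df`, `mean_a`, `mean_b`.
#' @export
two_sample_ttest <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 observations", call. = FALSE)
  pooled_var <- (sum((group_a - mean(group_a))^2) +
                 sum((group_b - mean(group_b))^2)) /
    (length(group_a) + length(group_b) - 2L)
  if (pooled_var == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(list(statistic = 0, p_value = 1,
                  df = length(group_a) + length(group_b) - 2L,
                  mean_a = mean(group_a), mean_b = mean(group_b)))
    }
    stop("zero pooled variance with unequal means", call. = FALSE)
  }
  tt <- stats::t.test(group_a, group_b, var.equal = TRUE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_a = mean(group_a),
       mean_b = mean(group_b))
}

#' Random quality-control voxel sample from a vascular map
#'
#' Uniform sample without replacement of `n` foreground voxels,
#' deterministic under the seed; used to export locations (and optional
#' orthogonal image patches) for manual false-positive review.
#'
#' @param mask vessel [binary_mask()], non-empty.
#' @param n number of voxels to sample (default 100); clamped to the mask
#'   size with a warning when larger.
#' @param rng_seed integer seed.
#' @param vol optional [voxel_volume()] aligned with the mask; when given,
#'   three orthogonal patches around each sampled voxel are extracted.
#' @param half_width_vox half-width of the square patches in voxels.
#' @return A list with `coordinates` (data frame `z`, `y`, `x`, 1-based)
#'   and `patches` (per-voxel list of `xy`, `xz`, `yz` matrices, or
#'   `NULL` when `vol` is missing).
#' @export
sample_qc_voxels <- function(mask, n = 100L, rng_seed = 1L, vol = NULL,
                             half_width_vox = 10L) {
  stopifnot(inherits(mask, "binary_mask"))
  fg <- which(mask$data)
  if (length(fg) == 0L) stop("mask is empty", call. = FALSE)
  if (n > length(fg)) {
    warning(sprintf("requested %d voxels but mask has only %d; returning all",
                    n, length(fg)))
    n <- length(fg)
  }
  sel <- with_seed(rng_seed, sample(fg, n))
  coords <- arrayInd(sel, dim(mask$data))
  colnames(coords) <- c("z", "y", "x")
  coords <- as.data.frame(coords)
  patches <- NULL
  if (!is.null(vol)) {
    stopifnot(inherits(vol, "voxel_volume"))
    check_same_geometry(mask, vol, "mask and volume")
    d <- dim(vol$data)
    w <- as.integer(half_width_vox)
    clamp <- function(i, lo, hi) seq(max(lo, i - w), min(hi, i + w))
    patches <- lapply(seq_len(n), function(i) {
      z <- coords$z[i]; y <- coords$y[i]; x <- coords$x[i]
      list(xy = vol$data[z, clamp(y, 1L, d[2]), clamp(x, 1L, d[3])],
           xz = vol$data[clamp(z, 1L, d[1]), y, clamp(x, 1L, d[3])],
           yz = vol$data[clamp(z, 1L, d[1]), clamp(y, 1L, d[2]), x])
    })
  }
  list(coordinates = coords, patches = patches)
}

#' Write QC voxel samples to disk
#'
#' Writes the sampled coordinates as CSV and, when patches are present and
#' the `png` package is installed, each patch set as a grayscale PNG.
#'
#' @param qc result of [sample_qc_voxels()].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_qc_samples <- function(qc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(qc$coordinates, file.path(dir, "qc_voxels.csv"),
                   row.names = FALSE)
  if (!is.null(qc$patches) && requireNamespace("png", quietly = TRUE)) {
    for (i in seq_along(qc$patches)) {
      p <- qc$patches[[i]]
      for (view in names(p)) {
        img <- as.matrix(p[[view]])
        rng <- range(img)
        img <- if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1])
               else img * 0
        png::writePNG(img, file.path(dir, sprintf("qc_%03d_%s.png", i, view)))
      }
    }
  }
  invisible(dir)
}
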