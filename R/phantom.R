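#' Tube specification for the vessel phantom
#'
#' One tubular vascular space: a centerline polyline (micrometres), a
#' radius that may vary linearly along the tube, and the fraction of the
#' lumen rendered hyper-intense.  PC-uCT of unstained tissue shows the
#' vascular space as partly bright (collapsed vessel walls, blood remains)
#' and partly dark (voids); `lumen_bright_fraction` controls that mix as a
#' single contiguous arclength block from the tube start — mirroring real
#' vessels where one stretch contains remains and the adjacent stretch is
#' void.
#'
#' @param centerline numeric matrix with columns `(z_um, y_um, x_um)` and
#'   at least 2 rows.
#' @param radius_um positive scalar, or length-2 vector for a radius that
#'   varies linearly from the first to the last centerline point.
#' @param lumen_bright_fraction scalar in `[0, 1]`: the leading fraction of
#'   the tube arclength rendered at `bright_level`; the remainder is
#'   rendered at `dark_level`.
#' @return An object of class `tube_spec`.
#' @export
tube_spec <- function(centerline, radius_um, lumen_bright_fraction = 1) {
  centerline <- as.matrix(centerline)
  if (ncol(centerline) != 3L || nrow(centerline) < 2L)
    stop("`centerline` must be an n x 3 matrix (z, y, x in um) with n >= 2",
         call. = FALSE)
  if (!all(radius_um > 0) || !length(radius_um) %in% c(1L, 2L))
    stop("`radius_um` must be a positive scalar or length-2 vector",
         call. = FALSE)
  if (lumen_bright_fraction < 0 || lumen_bright_fraction > 1)
    stop("`lumen_bright_fraction` must be in [0, 1]", call. = FALSE)
  structure(list(centerline = centerline,
                 radius_um = as.numeric(radius_um),
                 lumen_bright_fraction = lumen_bright_fraction),
            class = "tube_spec")
}

#' Phantom specification
#'
#' Defines a synthetic PC-uCT-like volume: tubes embedded in noisy mid-gray
#' tissue, with lumens split into hyper- and hypo-intense arclength blocks,
#' optional point-spread blur and an optional phase-contrast-like edge
#' fringe.  Intensities use an 8-bit-like scale; the rendered volume is
#' rounded and clamped to `[0, 255]`, as scanner reconstructions are
#' exported as integer stacks.
#'
#' Default intensity model: tissue 120, bright lumen 200, dark lumen 40
#' (symmetric +/- 80 contrast about tissue, so neither lumen polarity is
#' favoured) and noise SD 16, i.e. a contrast-to-noise ratio of 5.
#'
#' @param shape integer triple `(nz, ny, nx)`.
#' @param voxel_size_um voxel edge in micrometres.
#' @param tubes list of [tube_spec()] objects.
#' @param tissue_mean,tissue_noise_sd tissue intensity model.
#' @param bright_level,dark_level lumen intensities; must satisfy
#'   `dark_level < tissue_mean < bright_level`.
#' @param blur_sigma_um Gaussian point-spread blur applied after intensity
#'   assignment (0 = none).
#' @param edge_fringe_amplitude optional bright/dark fringe amplitude at
#'   the tissue-lumen boundary (phase-contrast edge enhancement); 0 = off.
#' @param fringe_width_vox width of each fringe ring in voxels.
#' @param rng_seed integer seed; all phantom randomness flows through it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape, voxel_size_um, tubes,
                         tissue_mean = 120, tissue_noise_sd = 16,
                         bright_level = 200, dark_level = 40,
                         blur_sigma_um = 0, edge_fringe_amplitude = 0,
                         fringe_width_vox = 1L, rng_seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("`shape` must be a positive integer triple", call. = FALSE)
  check_voxel_size(voxel_size_um)
  if (!is.list(tubes) || !all(vapply(tubes, inherits, logical(1), "tube_spec")))
    stop("`tubes` must be a list of tube_spec objects", call. = FALSE)
  if (!(dark_level < tissue_mean && tissue_mean < bright_level))
    stop("intensity ordering must satisfy dark < tissue < bright",
         call. = FALSE)
  if (tissue_noise_sd < 0 || blur_sigma_um < 0)
    stop("noise SD and blur sigma must be >= 0", call. = FALSE)
  structure(list(shape = shape, voxel_size_um = voxel_size_um, tubes = tubes,
                 tissue_mean = tissue_mean, tissue_noise_sd = tissue_noise_sd,
                 bright_level = bright_level, dark_level = dark_level,
                 blur_sigma_um = blur_sigma_um,
                 edge_fringe_amplitude = edge_fringe_amplitude,
                 fringe_width_vox = as.integer(fringe_width_vox),
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

# flatten tube polylines into the segment table consumed by the rasterizer
tube_segments <- function(spec) {
  segs <- list()
  lens <- numeric(length(spec$tubes))
  for (t in seq_along(spec$tubes)) {
    tb <- spec$tubes[[t]]
    p <- tb$centerline
    steps <- sqrt(rowSums((p[-1, , drop = FALSE] -
                           p[-nrow(p), , drop = FALSE])^2))
    total <- sum(steps)
    lens[t] <- total
    cum <- c(0, cumsum(steps))
    r <- tb$radius_um
    rad_at <- function(s) {
      if (length(r) == 1L) rep(r, length(s))
      else r[1] + (r[2] - r[1]) * (if (total > 0) s / total else 0)
    }
    for (i in seq_len(nrow(p) - 1L)) {
      segs[[length(segs) + 1L]] <- c(p[i, ], p[i + 1L, ],
                                     rad_at(cum[i]), rad_at(cum[i + 1L]),
                                     cum[i], t)
    }
  }
  list(segs = do.call(rbind, segs), tube_lengths_um = lens)
}

#' Generate a synthetic vessel phantom with ground truth
#'
#' Rasterizes the tubes of a [phantom_spec()] (a voxel is vessel iff its
#' centre lies within the local radius of a centerline), renders the
#' intensity model (contiguous bright/dark lumen blocks by arclength,
#' noisy tissue, optional fringe and blur) and returns both the volume and
#' the exact pre-blur geometry as ground truth.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `volume` (a [voxel_volume()], integer-valued in
#'   `[0, 255]`) and `truth` (class `phantom_truth`): `vessel_mask`,
#'   `centerlines_um`, `radii_um`, `tube_lengths_um`, `total_length_um`,
#'   `vessel_volume_um3`, `clipped` (per-tube flag: centerline exits the
#'   domain) and `rng_seed`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$voxel_size_um
  st <- tube_segments(spec)
  if (any(vapply(spec$tubes, function(t) min(t$radius_um), numeric(1)) < h))
    warning("tube radius below one voxel: sub-resolution tube(s)")
  ras <- cpp_rasterize_tubes(spec$shape, h, st$segs)
  mask <- ras$mask
  # truth bookkeeping (pre-blur geometry)
  extent <- (spec$shape - 1L) * h
  clipped <- vapply(spec$tubes, function(t) {
    any(t$centerline < 0) ||
      any(sweep(t$centerline, 2, extent) > 0)
  }, logical(1))
  truth <- structure(list(
    vessel_mask = binary_mask(mask, h),
    centerlines_um = lapply(spec$tubes, `[[`, "centerline"),
    radii_um = lapply(spec$tubes, `[[`, "radius_um"),
    tube_lengths_um = st$tube_lengths_um,
    total_length_um = sum(st$tube_lengths_um),
    vessel_volume_um3 = sum(mask) * h^3,
    clipped = clipped,
    rng_seed = spec$rng_seed), class = "phantom_truth")
  # intensity rendering
  vol <- array(spec$tissue_mean, dim = spec$shape)
  bf <- vapply(spec$tubes, `[[`, numeric(1), "lumen_bright_fraction")
  fg <- which(mask)
  if (length(fg)) {
    tid <- ras$tube[fg]
    frac <- ras$arc_um[fg] / pmax(st$tube_lengths_um[tid], 1e-12)
    vol[fg] <- ifelse(frac <= bf[tid] & bf[tid] > 0,
                      spec$bright_level, spec$dark_level)
  }
  if (spec$edge_fringe_amplitude > 0) {
    off <- ball_offsets(spec$fringe_width_vox)
    outer_ring <- cpp_dilate(mask, off) & !mask
    inner_ring <- mask & !cpp_erode(mask, off)
    vol[outer_ring] <- vol[outer_ring] + spec$edge_fringe_amplitude
    vol[inner_ring] <- vol[inner_ring] - spec$edge_fringe_amplitude
  }
  if (spec$tissue_noise_sd > 0) {
    vol <- vol + with_seed(spec$rng_seed,
                           array(rnorm(length(vol), 0, spec$tissue_noise_sd),
                                 dim = spec$shape))
  }
  if (spec$blur_sigma_um > 0)
    vol <- cpp_gauss_blur(vol, spec$blur_sigma_um / h)
  vol <- round(pmin(pmax(vol, 0), 255))
  dim(vol) <- spec$shape
  list(volume = voxel_volume(vol, h), truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %d tube(s), total length %.4g um, vessel volume %.4g um^3\n",
              length(x$centerlines_um), x$total_length_um,
              x$vessel_volume_um3))
  if (any(x$clipped))
    cat("  clipped tubes:", paste(which(x$clipped), collapse = ", "), "\n")
  invisible(x)
}

#' Random bifurcating vessel tree specification
#'
#' Builds a [phantom_spec()] containing a connected tree of straight
#' branches: a root entering from a face and children attached to existing
#' branch endpoints at moderate bifurcation angles.  Branch diameters are
#' drawn from `diameter_set_um`, emulating distinct vessel populations
#' (e.g. capillary-scale ~9 um next to large ~46 um vessels).
#'
#' @param n_branches number of branches (>= 1).
#' @param diameter_set_um vector of branch diameters to draw from
#'   (micrometres); each must be at least one voxel.
#' @param rng_seed integer seed for tree geometry (also becomes the
#'   phantom's noise seed).
#' @param shape,voxel_size_um domain geometry.
#' @param branch_length_um range of branch lengths to draw from; default
#'   scales with the domain.
#' @param lumen_bright_fraction passed to every [tube_spec()].
#' @param ... further arguments passed to [phantom_spec()] (intensity
#'   model, blur, ...).
#' @param max_tries retries for placing each branch inside the domain
#'   before giving up with an error.
#' @return A [phantom_spec()] whose `tubes` form the tree; the attribute
#'   `branch_parent` records each branch's parent index (0 for the root).
#' @export
branching_tree_spec <- function(n_branches, diameter_set_um, rng_seed = 1L,
                                shape = c(128L, 128L, 128L),
                                voxel_size_um = 0.94,
                                branch_length_um = NULL,
                                lumen_bright_fraction = 1, ...,
                                max_tries = 200L) {
  if (n_branches < 1L) stop("`n_branches` must be >= 1", call. = FALSE)
  if (any(diameter_set_um < voxel_size_um))
    stop("all diameters must be at least one voxel", call. = FALSE)
  shape <- as.integer(shape)
  extent <- (shape - 1L) * voxel_size_um
  if (is.null(branch_length_um))
    branch_length_um <- c(0.2, 0.35) * min(extent)
  rmax <- max(diameter_set_um) / 2
  margin <- rmax + 2 * voxel_size_um
  with_seed(rng_seed, {
    rand_dir <- function() {
      v <- rnorm(3)
      v / sqrt(sum(v^2))
    }
    # direction within `ang` of `d0`
    cone_dir <- function(d0, ang_lo = 30, ang_hi = 60) {
      for (i in 1:50) {
        v <- rand_dir()
        cosang <- sum(v * d0)
        a <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
        if (a >= ang_lo && a <= ang_hi) return(v)
      }
      d0
    }
    inside <- function(p) all(p >= margin) && all(p <= extent - margin)
    starts <- list(); ends <- list(); dirs <- list(); parent <- integer(0)
    diam <- numeric(0); n_children <- integer(0)
    min_sep_deg <- 35
    angle_deg <- function(u, v)
      acos(pmin(pmax(sum(u * v), -1), 1)) * 180 / pi
    tries <- 0L
    while (length(starts) < n_branches) {
      tries <- tries + 1L
      if (tries > max_tries * n_branches)
        stop("could not place the tree inside the domain", call. = FALSE)
      if (length(starts) == 0L) {
        # root: start near the centre of the z- face, pointing inward
        p0 <- c(margin,
                extent[2] * runif(1, 0.35, 0.65),
                extent[3] * runif(1, 0.35, 0.65))
        d0 <- c(1, rnorm(2, 0, 0.2))
        d0 <- d0 / sqrt(sum(d0^2))
        pa <- 0L
        len <- runif(1, branch_length_um[1], branch_length_um[2])
        p1 <- p0 + len * d0
        if (!inside(p1) || !inside(p0)) next
      } else {
        # bifurcation: <= 2 children per endpoint, and half-filled endpoints
        # are completed first so attachments form proper Y-junctions
        half <- which(n_children == 1L)
        open <- if (length(half)) half else which(n_children == 0L)
        pa <- open[sample.int(length(open), 1L)]
        p0 <- ends[[pa]]
        sibs <- which(parent == pa)
        placed <- FALSE
        for (attempt in seq_len(30L)) {
          d0 <- cone_dir(dirs[[pa]])
          # keep siblings well separated so junctions stay clean
          if (length(sibs) &&
              any(vapply(sibs, function(s) angle_deg(d0, dirs[[s]]),
                         numeric(1)) < min_sep_deg)) next
          # progressively shorter draws near the domain wall
          len <- runif(1, branch_length_um[1], branch_length_um[2]) *
            0.9^(attempt - 1L)
          if (len < 3 * rmax) break
          p1 <- p0 + len * d0
          if (inside(p1)) { placed <- TRUE; break }
        }
        if (!placed) next
      }
      k <- length(starts) + 1L
      starts[[k]] <- p0; ends[[k]] <- p1; dirs[[k]] <- d0
      parent[k] <- pa
      if (pa > 0L) n_children[pa] <- n_children[pa] + 1L
      n_children[k] <- 0L
      diam[k] <- sample(rep(diameter_set_um, 2), 1L)
    }
    tubes <- lapply(seq_along(starts), function(k) {
      tube_spec(rbind(starts[[k]], ends[[k]]), diam[k] / 2,
                lumen_bright_fraction)
    })
    sp <- phantom_spec(shape, voxel_size_um, tubes, rng_seed = rng_seed, ...)
    attr(sp, "branch_parent") <- parent
    sp
  })
}
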