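#' Pipeline configuration
#'
#' Bundles everything one published workflow variant needs:
#' * `fine` — high-resolution volumes: dual-kernel median + edge
#'   segmentation, then skeleton morphometry;
#' * `coarse` — low-resolution volumes: direct edge segmentation inside a
#'   region-grown tissue mask, then geodesic central/peripheral
#'   classification;
#' * `downsampled` — 0.5 trilinear downscale, single 7^3 median + edge
#'   segmentation under a circular FOV mask, phase-correlation stitching
#'   of tiles, peripheral selection, short/long split and maximum
#'   inscribed diameters with a t-test.
#'
#' @param mode `"fine"`, `"coarse"` or `"downsampled"`.
#' @param voxel_size_um voxel size of the *input* volumes.
#' @param input a [voxel_volume()] or TIFF path (fine/coarse modes).
#' @param tiles list of [voxel_volume()]s or TIFF paths (downsampled
#'   mode).
#' @param approx_offsets list of integer triples: prior tile offsets
#'   (one per tile after the first).
#' @param out_dir output directory; created if needed.
#' @param params an [edge_params()].
#' @param roi optional ROI [binary_mask()] or TIFF path (fine mode;
#'   defaults to the whole volume).
#' @param tissue_seed coarse mode: a [binary_mask()]/path used directly as
#'   tissue mask seed via [geodesic_select()], or a list
#'   `list(seed_vox =, lo =, hi =)` for [region_grow_tissue()].
#' @param sulcus_seed,surface_seed seed masks/paths for classification.
#' @param shrinkage_factor linear shrinkage factor for length density.
#' @param prune_um terminal-branch pruning threshold (micrometres).
#' @param bin_width_um diameter histogram bin width.
#' @param fov_margin_vox circular FOV mask margin (downsampled mode).
#' @param fov_far_face far-face spec for the short/long split.
#' @param tolerance_vox face tolerance for the short/long split.
#' @param rng_seed seed recorded in the provenance log and used by any
#'   stochastic step (QC sampling).
#' @param qc_n number of QC voxels to sample from the final mask (0 = no
#'   QC sampling).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("fine", "coarse", "downsampled"),
                            voxel_size_um, input = NULL, tiles = NULL,
                            approx_offsets = NULL, out_dir = tempfile("run"),
                            params = edge_params(), roi = NULL,
                            tissue_seed = NULL, sulcus_seed = NULL,
                            surface_seed = NULL, shrinkage_factor = 1,
                            prune_um = 25, bin_width_um = 1.6,
                            fov_margin_vox = 0L, fov_far_face = "z+",
                            tolerance_vox = 2L, rng_seed = 1L, qc_n = 0L) {
  mode <- match.arg(mode)
  check_voxel_size(voxel_size_um)
  stopifnot(inherits(params, "edge_params"))
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (cfg$mode %in% c("fine", "coarse") && is.null(cfg$input))
    stop(sprintf("%s mode requires `input`", cfg$mode), call. = FALSE)
  if (cfg$mode == "coarse" && is.null(cfg$tissue_seed))
    stop("coarse mode requires `tissue_seed`", call. = FALSE)
  if (cfg$mode == "downsampled") {
    if (is.null(cfg$tiles) || length(cfg$tiles) < 1L)
      stop("downsampled mode requires `tiles`", call. = FALSE)
    if (is.null(cfg$fov_margin_vox))
      stop("downsampled mode requires `fov_margin_vox`", call. = FALSE)
    if (length(cfg$tiles) > 1L &&
        (is.null(cfg$approx_offsets) ||
         length(cfg$approx_offsets) != length(cfg$tiles) - 1L))
      stop("downsampled mode needs one `approx_offsets` entry per tile after the first",
           call. = FALSE)
  }
  invisible(cfg)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Scalar fields map directly to [pipeline_config()] arguments; the
#' `params` block maps to [edge_params()].  Volume/mask fields hold file
#' paths.
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else stop("config must be YAML or JSON", call. = FALSE)
  ep <- do.call(edge_params, as.list(raw$params %||% list()))
  raw$params <- NULL
  do.call(pipeline_config, c(raw, list(params = ep)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_volume_input <- function(x, voxel_size_um) {
  if (inherits(x, "voxel_volume")) x
  else if (is.character(x)) read_volume(x, voxel_size_um)
  else stop("expected a voxel_volume or a TIFF path", call. = FALSE)
}

load_mask_input <- function(x, voxel_size_um) {
  if (inherits(x, "binary_mask")) x
  else if (is.character(x)) read_mask(x, voxel_size_um)
  else stop("expected a binary_mask or a TIFF path", call. = FALSE)
}

#' Run a configured workflow end to end
#'
#' Executes the stage sequence of the configured mode, writing all
#' intermediate masks, a metrics CSV and a provenance log (JSON + text;
#' every parameter and per-stage foreground voxel counts) into
#' `out_dir`.  Outputs are reproducible from config + inputs + seed.
#'
#' @param config a [pipeline_config()] (or a YAML/JSON path).
#' @return A list of results (invisible elements depend on the mode):
#'   always `mask` (final [binary_mask()]), `log`, `out_dir`; fine mode
#'   adds `skeleton`, `metrics`, `diameters`; coarse mode adds
#'   `classification`; downsampled mode adds `length_classes`,
#'   `diameters_by_class`, `ttest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  validate_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(mode = config$mode, rng_seed = config$rng_seed,
              voxel_size_um = config$voxel_size_um,
              params = unclass(config$params),
              prune_um = config$prune_um,
              shrinkage_factor = config$shrinkage_factor,
              bin_width_um = config$bin_width_um,
              fov_margin_vox = config$fov_margin_vox,
              fov_far_face = config$fov_far_face,
              tolerance_vox = config$tolerance_vox,
              stages = list())
  stage <- function(name, mask) {
    log$stages[[length(log$stages) + 1L]] <<-
      list(stage = name, foreground_voxels = sum(mask$data))
    mask
  }
  res <- switch(config$mode,
                fine = run_fine(config, stage),
                coarse = run_coarse(config, stage),
                downsampled = run_downsampled(config, stage))
  write_mask(res$mask, file.path(config$out_dir, "vessel_mask.tif"))
  if (config$qc_n > 0L && any(res$mask$data)) {
    qc <- sample_qc_voxels(res$mask, config$qc_n, config$rng_seed,
                           vol = res$volume)
    write_qc_samples(qc, file.path(config$out_dir, "qc"))
    res$qc <- qc
  }
  res$log <- log
  jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(c(sprintf("vesselmorph %s run", config$mode),
               utils::capture.output(utils::str(log))),
             file.path(config$out_dir, "run_log.txt"))
  res$out_dir <- config$out_dir
  invisible(res)
}

run_fine <- function(config, stage) {
  vol <- load_volume_input(config$input, config$voxel_size_um)
  mask <- stage("segment_fine", segment_fine(vol, config$params))
  roi <- if (is.null(config$roi)) {
    binary_mask(array(TRUE, dim(vol$data)), vol$voxel_size_um)
  } else load_mask_input(config$roi, config$voxel_size_um)
  skel <- prune_branches(skeletonize_3d(mask), config$prune_um)
  thick <- local_thickness(mask)
  dd <- diameter_distribution(skel, thick, config$bin_width_um)
  roi_vol_um3 <- sum(roi$data) * voxel_volume_um3(roi)
  metrics <- data.frame(
    volume_fraction_pct = vessel_volume_fraction(mask, roi),
    length_density_mm_per_mm3 =
      vessel_length_density(skel, roi_vol_um3, config$shrinkage_factor),
    shrinkage_factor = config$shrinkage_factor,
    total_length_um = total_skeleton_length_um(skel),
    vessel_volume_um3 = sum(mask$data) * voxel_volume_um3(mask),
    roi_volume_um3 = roi_vol_um3,
    n_branches = nrow(skel$branches))
  utils::write.csv(metrics, file.path(config$out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(dd$histogram,
                   file.path(config$out_dir, "diameter_histogram.csv"),
                   row.names = FALSE)
  utils::write.csv(dd$branch_table,
                   file.path(config$out_dir, "branches.csv"),
                   row.names = FALSE)
  write_volume(thick, file.path(config$out_dir, "local_thickness.tif"))
  list(mask = mask, volume = vol, skeleton = skel, metrics = metrics,
       diameters = dd)
}

run_coarse <- function(config, stage) {
  vol <- load_volume_input(config$input, config$voxel_size_um)
  tissue <- if (is.list(config$tissue_seed) &&
                !inherits(config$tissue_seed, "binary_mask")) {
    region_grow_tissue(vol, config$tissue_seed$seed_vox,
                       config$tissue_seed$lo, config$tissue_seed$hi)
  } else {
    load_mask_input(config$tissue_seed, config$voxel_size_um)
  }
  stage("tissue_mask", tissue)
  mask <- stage("segment_coarse", segment_coarse(vol, tissue, config$params))
  res <- list(mask = mask, volume = vol, tissue = tissue)
  if (!is.null(config$sulcus_seed) && !is.null(config$surface_seed)) {
    cls <- split_central_peripheral(
      mask,
      load_mask_input(config$sulcus_seed, config$voxel_size_um),
      load_mask_input(config$surface_seed, config$voxel_size_um))
    utils::write.csv(cls$components,
                     file.path(config$out_dir, "components.csv"),
                     row.names = FALSE)
    res$classification <- cls
  }
  res
}

run_downsampled <- function(config, stage) {
  seg_tile <- function(x) {
    vol <- downscale_half(load_volume_input(x, config$voxel_size_um))
    med <- median_filter_3d(vol, 7L)
    edges <- canny_edges_3d(med, config$params)
    fov <- circular_fov_mask(dim(vol$data), config$fov_margin_vox,
                             vol$voxel_size_um)
    edges <- binary_mask(array(edges$data & fov$data, dim(edges$data)),
                         edges$voxel_size_um)
    postprocess_edges(edges, config$params)
  }
  masks <- lapply(config$tiles, seg_tile)
  fused <- masks[[1L]]
  if (length(masks) > 1L) {
    for (i in seq_along(masks)[-1L]) {
      st <- stitch_translation(fused, masks[[i]],
                               approx_offset = config$approx_offsets[[i - 1L]])
      fused <- st$fused
    }
  }
  mask <- stage("stitched_mask", fused)
  res <- list(mask = mask, volume = NULL, tile_masks = masks)
  if (!is.null(config$surface_seed)) {
    periph <- geodesic_select(mask, load_mask_input(config$surface_seed,
                                                    mask$voxel_size_um))
    mask <- stage("peripheral", periph)
    res$mask <- mask
  }
  sl <- classify_short_long(mask, config$fov_far_face, config$tolerance_vox)
  dia <- component_max_diameters(mask)
  dia$length_class <- sl$components$length_class[
    match(dia$component_id, sl$components$component_id)]
  utils::write.csv(dia, file.path(config$out_dir, "component_diameters.csv"),
                   row.names = FALSE)
  res$length_classes <- sl
  res$diameters_by_class <- dia
  a <- dia$max_diameter_um[dia$length_class == "short"]
  b <- dia$max_diameter_um[dia$length_class == "long"]
  if (length(a) >= 2L && length(b) >= 2L)
    res$ttest <- two_sample_ttest(a, b)
  res
}
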