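#' Read a 3D volume from a multipage TIFF stack
#'
#' Each TIFF page becomes one z-slice; page rows map to y, page columns to
#' x.  Integer TIFFs (uint8/uint16) are read bit-exact.  Float volumes
#' written by [write_volume()] are stored as 32-bit samples rescaled to
#' `[0, 1]` with the original range recorded in a JSON sidecar, and are
#' restored on read (exact to 32-bit quantization).
#'
#' @param path path to a multipage TIFF stack.
#' @param voxel_size_um voxel edge length in micrometres.  If `NULL`, taken
#'   from the JSON sidecar written by [write_volume()].
#' @return A [voxel_volume()].
#' @export
read_volume <- function(path, voxel_size_um = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  meta <- read_sidecar(path)
  if (is.null(voxel_size_um)) {
    voxel_size_um <- meta$voxel_size_um
    if (is.null(voxel_size_um))
      stop("`voxel_size_um` not given and no JSON sidecar found", call. = FALSE)
  }
  check_voxel_size(voxel_size_um)
  scaled <- identical(meta$sample_type, "float32_scaled")
  pages <- tryCatch(
    if (scaled) tiff::readTIFF(path, all = TRUE)
    else tiff::readTIFF(path, all = TRUE, as.is = TRUE),
    error = function(e) tiff::readTIFF(path, all = TRUE))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L)
    stop("not a 3D stack: TIFF has fewer than 2 pages", call. = FALSE)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
    stop("unsupported TIFF: pages must be single-channel 2D images",
         call. = FALSE)
  nz <- length(pages)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  arr <- array(0, dim = c(nz, ny, nx))
  for (z in seq_len(nz)) arr[z, , ] <- pages[[z]]
  if (scaled) {
    rmin <- meta$data_min; rmax <- meta$data_max
    arr <- arr * (rmax - rmin) + rmin
  }
  voxel_volume(arr, voxel_size_um)
}

#' Write a 3D volume as a multipage TIFF stack
#'
#' Integer-valued volumes in `[0, 255]` are written as uint8 and in
#' `[0, 65535]` as uint16, bit-exact.  Other volumes are rescaled to
#' `[0, 1]` and written with 32-bit samples; the original range goes into
#' the JSON sidecar so [read_volume()] can restore the values.
#'
#' @param vol a [voxel_volume()].
#' @param path output TIFF path.  A sidecar `<path>.json` with voxel size
#'   and sample-type provenance is written alongside.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "voxel_volume"))
  a <- vol$data
  meta <- list(voxel_size_um = vol$voxel_size_um,
               shape_zyx = dim(a),
               written_by = "vesselmorph")
  is_int <- all(is.finite(a)) && all(a == round(a)) && min(a) >= 0
  if (is_int && max(a) <= 255) {
    pages <- split_pages(a / 255)
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
    meta$sample_type <- "uint8"
  } else if (is_int && max(a) <= 65535) {
    pages <- split_pages(a / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    meta$sample_type <- "uint16"
  } else {
    rmin <- min(a); rmax <- max(a)
    scl <- if (rmax > rmin) (a - rmin) / (rmax - rmin) else a * 0
    tiff::writeTIFF(split_pages(scl), path, bits.per.sample = 32L)
    meta$sample_type <- "float32_scaled"
    meta$data_min <- rmin
    meta$data_max <- rmax
  }
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a binary mask from a TIFF stack
#'
#' Any strictly positive sample is foreground.
#'
#' @inheritParams read_volume
#' @return A [binary_mask()].
#' @export
read_mask <- function(path, voxel_size_um = NULL) {
  v <- read_volume(path, voxel_size_um)
  binary_mask(v$data > 0, v$voxel_size_um)
}

#' Write a binary mask as a uint8 \{0, 255\} TIFF stack
#'
#' @param mask a [binary_mask()].
#' @param path output TIFF path.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  a <- array(as.numeric(mask$data) * 255, dim = dim(mask$data))
  write_volume(voxel_volume(a, mask$voxel_size_um), path)
}

sidecar_path <- function(path) paste0(path, ".json")

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (file.exists(sp)) jsonlite::read_json(sp, simplifyVector = TRUE)
  else list()
}

split_pages <- function(a) {
  lapply(seq_len(dim(a)[1]), function(z) a[z, , ])
}

#' Downscale a volume by a factor 0.5 with trilinear interpolation
#'
#' Output sample `k` (0-based) is the trilinear interpolant at input
#' coordinate `2k + 0.5`, i.e. the mean of each 2x2x2 input cell
#' (cell-centred alignment).  The voxel size doubles; each output dimension
#' is `floor(input / 2)`.
#'
#' @param vol a [voxel_volume()]; every dimension must be at least 2.
#' @return A [voxel_volume()] with halved dimensions and doubled
#'   `voxel_size_um`.
#' @export
downscale_half <- function(vol) {
  stopifnot(inherits(vol, "voxel_volume"))
  d <- dim(vol)
  if (any(d < 2L))
    stop("every dimension must be >= 2 to downscale", call. = FALSE)
  d2 <- d %/% 2L
  a <- vol$data[seq_len(2L * d2[1]), seq_len(2L * d2[2]), seq_len(2L * d2[3]),
                drop = FALSE]
  odd <- function(n) seq(1L, 2L * n, by = 2L)
  evn <- function(n) seq(2L, 2L * n, by = 2L)
  a <- (a[odd(d2[1]), , , drop = FALSE] + a[evn(d2[1]), , , drop = FALSE]) / 2
  a <- (a[, odd(d2[2]), , drop = FALSE] + a[, evn(d2[2]), , drop = FALSE]) / 2
  a <- (a[, , odd(d2[3]), drop = FALSE] + a[, , evn(d2[3]), drop = FALSE]) / 2
  voxel_volume(array(a, dim = d2), 2 * vol$voxel_size_um)
}

#' Circular field-of-view mask
#'
#' Tomographic reconstructions have a circular in-plane field of view;
#' voxels near its rim carry edge artefacts.  This builds a per-slice disk
#' of radius `min(ny, nx) / 2 - margin_vox` centred on the slice centre,
#' identical across z.
#'
#' @param shape integer triple `(nz, ny, nx)`.
#' @param margin_vox non-negative integer margin subtracted from the disk
#'   radius.
#' @param voxel_size_um voxel size carried by the returned mask.
#' @return A [binary_mask()].
#' @export
circular_fov_mask <- function(shape, margin_vox = 0L, voxel_size_um = 1) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("`shape` must be a positive integer triple (nz, ny, nx)",
         call. = FALSE)
  if (any(shape[2:3] < 2L))
    stop("in-plane dimensions must be >= 2", call. = FALSE)
  if (margin_vox < 0) stop("`margin_vox` must be >= 0", call. = FALSE)
  r <- min(shape[2], shape[3]) / 2 - margin_vox
  if (r <= 0)
    stop("margin leaves a non-positive field-of-view radius", call. = FALSE)
  cy <- (shape[2] + 1) / 2
  cx <- (shape[3] + 1) / 2
  dy2 <- (seq_len(shape[2]) - cy)^2
  dx2 <- (seq_len(shape[3]) - cx)^2
  disk <- outer(dy2, dx2, `+`) <= r^2
  data <- array(rep(disk, each = shape[1]), dim = shape)
  binary_mask(data, voxel_size_um)
}

#' Translation-only stitching of two tiles by phase correlation
#'
#' Finds the integer-voxel translation of `tile_b` relative to `tile_a`
#' that maximises the normalised phase correlation within a search window
#' around `approx_offset`, then fuses the tiles on a common canvas.  The
#' recovered `offset` is defined by `tile_b[v] == tile_a[v + offset]` in
#' the overlap, i.e. the position of tile_b's origin in tile_a's index
#' frame (order `(z, y, x)`, 0-based).
#'
#' Overlapping grayscale voxels are fused by their mean; masks by logical
#' OR (masks are the stitched product of the downsampled workflow).
#'
#' @param tile_a,tile_b two [voxel_volume()] or two [binary_mask()] objects
#'   with identical shape and voxel size.
#' @param approx_offset integer triple, prior guess of the offset.
#' @param search_radius Chebyshev radius (voxels) of the candidate window
#'   around `approx_offset`.
#' @param min_correlation phase-correlation peak below which the result is
#'   flagged low-confidence.
#' @return A list with `offset` (integer triple), `fused` (same class as
#'   the inputs), `correlation` (peak value) and `low_confidence` (flag).
#' @export
stitch_translation <- function(tile_a, tile_b, approx_offset = c(0L, 0L, 0L),
                               search_radius = 16L, min_correlation = 0.1) {
  is_mask <- inherits(tile_a, "binary_mask")
  if (is_mask != inherits(tile_b, "binary_mask"))
    stop("tiles must both be volumes or both be masks", call. = FALSE)
  check_same_geometry(tile_a, tile_b, "tiles")
  d <- dim(tile_a)
  approx_offset <- as.integer(round(approx_offset))
  if (length(approx_offset) != 3L)
    stop("`approx_offset` must be an integer triple", call. = FALSE)
  if (any(abs(approx_offset) >= d))
    stop("no expected overlap under `approx_offset`", call. = FALSE)
  a <- tile_a$data * 1.0
  b <- tile_b$data * 1.0
  a <- a - mean(a); b <- b - mean(b)
  fa <- stats::fft(a)
  fb <- stats::fft(b)
  cross <- fa * Conj(fb)
  pc <- Re(stats::fft(cross / pmax(Mod(cross), 1e-12), inverse = TRUE)) /
    length(a)
  # candidate shifts within the window (offsets wrap modulo the tile shape)
  rng <- function(c0, n) {
    lo <- c0 - search_radius
    hi <- c0 + search_radius
    pmin(pmax(seq(lo, hi), -(n - 1L)), n - 1L)
  }
  cand <- expand.grid(dz = unique(rng(approx_offset[1], d[1])),
                      dy = unique(rng(approx_offset[2], d[2])),
                      dx = unique(rng(approx_offset[3], d[3])))
  ov <- pmax(d[1] - abs(cand$dz), 0) * pmax(d[2] - abs(cand$dy), 0) *
    pmax(d[3] - abs(cand$dx), 0)
  cand <- cand[ov > 0, , drop = FALSE]
  if (nrow(cand) == 0L)
    stop("empty overlap under all candidate offsets", call. = FALSE)
  idx <- cbind((cand$dz %% d[1]) + 1L,
               (cand$dy %% d[2]) + 1L,
               (cand$dx %% d[3]) + 1L)
  vals <- pc[idx]
  best <- which.max(vals)
  offset <- c(cand$dz[best], cand$dy[best], cand$dx[best])
  corr <- vals[best]
  fused <- fuse_tiles(tile_a, tile_b, offset, is_mask)
  list(offset = offset, fused = fused, correlation = corr,
       low_confidence = corr < min_correlation)
}

# place tile_b at `offset` in tile_a's frame on a union canvas
fuse_tiles <- function(tile_a, tile_b, offset, is_mask) {
  d <- dim(tile_a)
  lo <- pmin(c(0L, 0L, 0L), offset)          # canvas origin in a-frame
  hi <- pmax(d, offset + d)
  cd <- hi - lo
  if (is_mask) {
    canvas <- array(FALSE, dim = cd)
    ai <- lapply(1:3, function(k) seq_len(d[k]) - lo[k])
    bi <- lapply(1:3, function(k) seq_len(d[k]) + offset[k] - lo[k])
    canvas[ai[[1]], ai[[2]], ai[[3]]] <- tile_a$data
    canvas[bi[[1]], bi[[2]], bi[[3]]] <-
      canvas[bi[[1]], bi[[2]], bi[[3]]] | tile_b$data
    binary_mask(canvas, tile_a$voxel_size_um)
  } else {
    acc <- array(0, dim = cd)
    cnt <- array(0, dim = cd)
    ai <- lapply(1:3, function(k) seq_len(d[k]) - lo[k])
    bi <- lapply(1:3, function(k) seq_len(d[k]) + offset[k] - lo[k])
    acc[ai[[1]], ai[[2]], ai[[3]]] <- acc[ai[[1]], ai[[2]], ai[[3]]] +
      tile_a$data
    cnt[ai[[1]], ai[[2]], ai[[3]]] <- cnt[ai[[1]], ai[[2]], ai[[3]]] + 1
    acc[bi[[1]], bi[[2]], bi[[3]]] <- acc[bi[[1]], bi[[2]], bi[[3]]] +
      tile_b$data
    cnt[bi[[1]], bi[[2]], bi[[3]]] <- cnt[bi[[1]], bi[[2]], bi[[3]]] + 1
    voxel_volume(acc / pmax(cnt, 1), tile_a$voxel_size_um)
  }
}
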