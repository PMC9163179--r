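#' Voxel volume
#'
#' A 3D scalar intensity grid with isotropic voxel size.  Axis order is
#' `(z, y, x)` with `z` the slice index.
#'
#' @param data 3D numeric array, dim `(nz, ny, nx)`.
#' @param voxel_size_um positive scalar, micrometres per voxel edge
#'   (isotropic).
#' @return An object of class `voxel_volume`: a list with elements `data`
#'   and `voxel_size_um`.
#' @examples
#' v <- voxel_volume(array(rnorm(8 * 8 * 8), dim = c(8, 8, 8)), 0.94)
#' dim(v)
#' @export
voxel_volume <- function(data, voxel_size_um) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (!is.numeric(data))
    stop("`data` must be numeric", call. = FALSE)
  check_voxel_size(voxel_size_um)
  structure(list(data = data, voxel_size_um = as.numeric(voxel_size_um)),
            class = "voxel_volume")
}

#' Binary mask
#'
#' A 3D boolean grid geometrically aligned to a [voxel_volume()]:
#' segmentations, seed regions, ROIs.  Foreground connectivity is
#' 26-neighbour, background connectivity 6-neighbour throughout the
#' package.
#'
#' @param data 3D logical array (numeric input is coerced with `!= 0`).
#' @param voxel_size_um positive scalar, micrometres per voxel edge.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, voxel_size_um) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (!is.logical(data)) {
    dm <- dim(data)
    data <- data != 0
    dim(data) <- dm
  }
  check_voxel_size(voxel_size_um)
  structure(list(data = data, voxel_size_um = as.numeric(voxel_size_um)),
            class = "binary_mask")
}

check_voxel_size <- function(voxel_size_um) {
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0)
    stop("`voxel_size_um` must be a single positive number", call. = FALSE)
  invisible(voxel_size_um)
}

#' @export
dim.voxel_volume <- function(x) dim(x$data)

#' @export
dim.binary_mask <- function(x) dim(x$data)

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<voxel_volume> %d x %d x %d (z, y, x), voxel %.4g um\n",
              d[1], d[2], d[3], x$voxel_size_um))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x)
  n <- sum(x$data)
  cat(sprintf("<binary_mask> %d x %d x %d (z, y, x), voxel %.4g um\n",
              d[1], d[2], d[3], x$voxel_size_um))
  cat(sprintf("  %d foreground voxels (%.3g%% of volume, %.4g um^3)\n",
              n, 100 * n / prod(d), n * x$voxel_size_um^3))
  invisible(x)
}

# geometry identity between two containers (shape and voxel size)
check_same_geometry <- function(a, b, what = "inputs") {
  if (!identical(dim(a$data), dim(b$data)))
    stop(sprintf("%s have mismatching shapes", what), call. = FALSE)
  if (abs(a$voxel_size_um - b$voxel_size_um) >
      1e-9 * max(a$voxel_size_um, b$voxel_size_um))
    stop(sprintf("%s have mismatching voxel sizes", what), call. = FALSE)
  invisible(TRUE)
}

as_mask_data <- function(x) {
  if (inherits(x, "binary_mask")) x$data
  else if (is.array(x) && is.logical(x)) x
  else stop("expected a `binary_mask`", call. = FALSE)
}

#' Physical voxel volume
#'
#' @param x a `voxel_volume` or `binary_mask`.
#' @return Voxel volume in cubic micrometres (`voxel_size_um^3`).
#' @export
voxel_volume_um3 <- function(x) x$voxel_size_um^3

#' Dice overlap coefficient between two masks
#'
#' `2 |A & B| / (|A| + |B|)`; 1 for identical non-empty masks, defined as 1
#' when both masks are empty.
#'
#' @param a,b `binary_mask` objects with identical geometry.
#' @return Scalar in `[0, 1]`.
#' @export
mask_dice <- function(a, b) {
  check_same_geometry(a, b, "masks")
  na <- sum(a$data); nb <- sum(b$data)
  if (na + nb == 0L) return(1)
  2 * sum(a$data & b$data) / (na + nb)
}

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# ball structuring element offsets (Euclidean radius r), rows (dz, dy, dx)
ball_offsets <- function(radius_vox) {
  r <- as.integer(radius_vox)
  g <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)
  g <- g[g$dz^2 + g$dy^2 + g$dx^2 <= radius_vox^2, , drop = FALSE]
  as.matrix(g)
}
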