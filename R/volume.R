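#' 3D image volume
#'
#' A `volume3d` is the package's container for scalar 3D images (PET activity,
#' MR intensity, or label maps): a numeric array on a regular grid together
#' with the voxel spacing in mm and a 4x4 grid-to-world affine. Voxel indices
#' are 0-based throughout the package.
#'
#' @param data 3D numeric array; all dimensions must be at least 8 and all
#'   values finite.
#' @param spacing numeric length-3, mm per voxel along each axis (all > 0).
#' @param affine 4x4 grid-to-world matrix; defaults to a diagonal scaling by
#'   `spacing`.
#' @return An object of class `volume3d` with fields `data`, `spacing`,
#'   `affine`.
#' @examples
#' v <- volume3d(array(1, c(8, 8, 8)))
#' dim(v$data)
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(dim(data) < 8L))
    stop("all volume dimensions must be >= 8")
  if (!all(is.finite(data)))
    stop("volume data must be finite everywhere")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers")
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix")
  structure(list(data = data, spacing = spacing, affine = affine),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d, spacing %s mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 3), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

.as_vol_array <- function(x) {
  if (inherits(x, "volume3d")) x$data else x
}

#' Read a NIfTI volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [volume3d].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- arr[, , , 1, drop = TRUE]
  arr <- array(as.numeric(arr), dim(arr))   # drop NIfTI attributes
  spacing <- RNifti::pixdim(img)[1:3]
  volume3d(arr, spacing = spacing, affine = unclass(RNifti::xform(img)))
}

#' Write a NIfTI volume
#'
#' @param volume a [volume3d].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$data, reference = NULL)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::qform(img) <- structure(volume$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# 0-based voxel coordinates of every grid point, column-major (x fastest),
# as three vectors of length prod(shape).
.grid_coords <- function(shape) {
  d1 <- shape[1]; d2 <- shape[2]; d3 <- shape[3]
  list(x = rep.int(as.double(0:(d1 - 1)), d2 * d3),
       y = rep.int(rep(as.double(0:(d2 - 1)), each = d1), d3),
       z = rep(as.double(0:(d3 - 1)), each = d1 * d2))
}

# Zero-pad a volume with a 1-voxel border; out-of-range coordinates are
# clamped into the border so every corner gather is a plain index lookup.
.pad_zero <- function(vol) {
  d <- dim(vol)
  p <- array(0, d + 2L)
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- vol
  p
}

# Trilinear sampling of `vol` (3D array) at 0-based positions (px,py,pz),
# via the compiled kernel. pad = "zero": out-of-bounds corners contribute 0
# (used for images); pad = "clamp": coordinates are clamped to the grid
# (used for displacement fields). With grad = TRUE also returns the spatial
# gradient of the interpolant at each sample position.
.sample_trilinear <- function(vol, px, py, pz, grad = FALSE, pad = "zero",
                              padded = NULL) {
  if (!is.double(vol)) storage.mode(vol) <- "double"
  cpp_sample_trilinear(vol, dim(vol), px, py, pz,
                       grad, if (pad == "clamp") 1L else 0L)
}

.sample_nearest <- function(vol, px, py, pz) {
  d <- dim(vol)
  ix <- round(px); iy <- round(py); iz <- round(pz)
  ok <- ix >= 0 & ix < d[1] & iy >= 0 & iy < d[2] & iz >= 0 & iz < d[3]
  out <- numeric(length(ix))
  out[ok] <- vol[ix[ok] + d[1] * (iy[ok] + d[2] * iz[ok]) + 1]
  out
}

# Separable Gaussian smoothing of a 3D array (kernel truncated at 3 sigma,
# renormalized at the edges so constants are preserved).
.gauss_kernel_matrix <- function(n, sigma) {
  idx <- outer(seq_len(n), seq_len(n), "-")
  K <- exp(-idx^2 / (2 * sigma^2))
  K[abs(idx) > ceiling(3 * sigma)] <- 0
  K / rowSums(K)
}

gauss_smooth3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  for (ax in 1:3) {
    d <- dim(arr)
    K <- .gauss_kernel_matrix(d[1], sigma)
    arr <- array(K %*% matrix(arr, d[1], d[2] * d[3]), d)
    arr <- aperm(arr, c(2, 3, 1))
  }
  arr
}
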