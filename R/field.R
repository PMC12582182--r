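#' Dense deformation field
#'
#' Per-voxel 3-vector displacements, in voxel units, defined on the template
#' grid. The package uses pull semantics everywhere: a field maps each
#' template-grid voxel `v` to the source-space position `v + disp[v]`, so a
#' field paired with a native-space image resamples that image onto the
#' template grid (template -> native). Push-semantics fields are not accepted.
#'
#' @param disp 4D numeric array `c(nx, ny, nz, 3)` of displacements (voxels),
#'   finite everywhere.
#' @return An object of class `deformation_field`.
#' @export
deformation_field <- function(disp) {
  if (!is.array(disp) || length(dim(disp)) != 4L || dim(disp)[4] != 3L)
    stop("`disp` must be a 4D array with last dimension 3")
  if (!all(is.finite(disp)))
    stop("displacements must be finite")
  structure(list(disp = disp), class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  d <- dim(x$disp)
  m <- field_magnitude(x)
  cat(sprintf("<deformation_field> %d x %d x %d, |disp| mean %.3f max %.3f voxels\n",
              d[1], d[2], d[3], mean(m), max(m)))
  invisible(x)
}

.zero_field <- function(shape) deformation_field(array(0, c(shape, 3L)))

.field_shape <- function(field) dim(field$disp)[1:3]

#' Per-voxel displacement magnitude
#'
#' @param field a [deformation_field].
#' @return 3D array of Euclidean displacement norms (voxels).
#' @export
field_magnitude <- function(field) {
  d <- field$disp
  sqrt(d[, , , 1]^2 + d[, , , 2]^2 + d[, , , 3]^2)
}

#' Jacobian determinant of a deformation
#'
#' Determinant of the Jacobian of the mapping `v -> v + disp[v]`, estimated by
#' central finite differences. Values are returned for interior voxels only
#' (the outermost voxel layer is dropped). Positive values everywhere mean the
#' mapping is locally invertible and orientation preserving.
#'
#' @param field a [deformation_field].
#' @return 3D array of size `dim - 2` with the determinant at each interior
#'   voxel.
#' @export
jacobian_det <- function(field) {
  u <- field$disp
  d <- dim(u)[1:3]
  i <- 2:(d[1] - 1); j <- 2:(d[2] - 1); k <- 2:(d[3] - 1)
  # central difference of component c along axis a, at interior voxels
  g <- function(cc, ax) {
    uc <- u[, , , cc]
    switch(ax,
           (uc[i + 1, j, k] - uc[i - 1, j, k]) / 2,
           (uc[i, j + 1, k] - uc[i, j - 1, k]) / 2,
           (uc[i, j, k + 1] - uc[i, j, k - 1]) / 2)
  }
  a11 <- 1 + g(1, 1); a12 <- g(1, 2); a13 <- g(1, 3)
  a21 <- g(2, 1); a22 <- 1 + g(2, 2); a23 <- g(2, 3)
  a31 <- g(3, 1); a32 <- g(3, 2); a33 <- 1 + g(3, 3)
  a11 * (a22 * a33 - a23 * a32) -
    a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
}

# Sample a field's displacement vectors at arbitrary 0-based positions
# (clamped trilinear, since displacements are defined over the whole grid).
.sample_field <- function(field, px, py, pz) {
  u <- field$disp
  cbind(.sample_trilinear(u[, , , 1], px, py, pz, pad = "clamp")$v,
        .sample_trilinear(u[, , , 2], px, py, pz, pad = "clamp")$v,
        .sample_trilinear(u[, , , 3], px, py, pz, pad = "clamp")$v)
}

#' Numerically invert a deformation field
#'
#' Fixed-point inversion of `v -> v + disp[v]`: finds `inv` such that
#' composing the two mappings is close to the identity. Converges for the
#' smooth, Jacobian-positive fields produced by [sample_deformation()].
#'
#' @param field a [deformation_field].
#' @param iterations fixed-point iterations.
#' @return The inverse [deformation_field] on the same grid.
#' @export
invert_field <- function(field, iterations = 30L) {
  shape <- .field_shape(field)
  g <- .grid_coords(shape)
  phi <- matrix(0, length(g$x), 3)
  for (it in seq_len(iterations)) {
    phi <- -.sample_field(field, g$x + phi[, 1], g$y + phi[, 2], g$z + phi[, 3])
  }
  deformation_field(array(phi, c(shape, 3L)))
}

#' Mean endpoint error between two deformation fields
#'
#' Mean Euclidean distance (voxels) between the displacement vectors of two
#' fields on the same grid, optionally restricted to a logical mask.
#'
#' @param field_a,field_b [deformation_field]s on congruent grids.
#' @param mask optional 3D logical array selecting the voxels to average over.
#' @return Scalar mean endpoint error in voxels.
#' @export
endpoint_error <- function(field_a, field_b, mask = NULL) {
  if (!all(.field_shape(field_a) == .field_shape(field_b)))
    stop("fields must be on congruent grids")
  d <- field_a$disp - field_b$disp
  e <- sqrt(d[, , , 1]^2 + d[, , , 2]^2 + d[, , , 3]^2)
  if (!is.null(mask)) e <- e[mask]
  mean(e)
}

# --- sparse grid operators -------------------------------------------------

# Block-average pooling operator: (nvox/f^3) x nvox sparse matrix.
.pool_matrix <- function(shape, factor) {
  if (any(shape %% factor != 0))
    stop("grid dimensions must be divisible by the pooling factor")
  g <- .grid_coords(shape)
  nb <- shape %/% factor
  bi <- g$x %/% factor; bj <- g$y %/% factor; bk <- g$z %/% factor
  row <- bi + nb[1] * (bj + nb[2] * bk) + 1
  Matrix::sparseMatrix(i = row, j = seq_along(row), x = 1 / factor^3,
                       dims = c(prod(nb), prod(shape)))
}

# Trilinear upsampling operator from a control grid with spacing `stride`
# (control point c sits at voxel coordinate c*stride; edges replicate):
# nvox x nctrl sparse matrix applied per displacement component.
.upsample_matrix <- function(shape, stride) {
  nc <- pmax((shape - 1L) %/% stride + 1L, 2L)
  g <- .grid_coords(shape)
  px <- pmin(g$x / stride, nc[1] - 1)
  py <- pmin(g$y / stride, nc[2] - 1)
  pz <- pmin(g$z / stride, nc[3] - 1)
  x0 <- pmin(floor(px), nc[1] - 2); fx <- px - x0
  y0 <- pmin(floor(py), nc[2] - 2); fy <- py - y0
  z0 <- pmin(floor(pz), nc[3] - 2); fz <- pz - z0
  n <- length(px)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
         (if (dz) fz else 1 - fz)
    keep <- w > 0
    rows <- c(rows, which(keep))
    cols <- c(cols, ((x0 + dx) + nc[1] * ((y0 + dy) + nc[2] * (z0 + dz)) + 1)[keep])
    vals <- c(vals, w[keep])
  }
  list(M = Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                                dims = c(n, prod(nc))),
       ctrl_dim = nc)
}
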