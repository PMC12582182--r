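#' Resample a volume through a deformation field
#'
#' Pull-semantics warp: `output[v] = input(v + disp[v])`, with trilinear or
#' nearest-neighbour interpolation and zero outside the input grid. The field
#' lives on the output (template) grid; the input volume must be on a grid of
#' the same dimensions.
#'
#' @param volume a [volume3d] (use `interpolation = "nearest"` for label
#'   maps).
#' @param field a [deformation_field] on the output grid.
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @return The warped [volume3d] on the field's grid.
#' @export
warp <- function(volume, field, interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  arr <- .as_vol_array(volume)
  shape <- .field_shape(field)
  if (!all(dim(arr) == shape))
    stop("volume and field grids are not congruent")
  g <- .grid_coords(shape)
  px <- g$x + as.vector(field$disp[, , , 1])
  py <- g$y + as.vector(field$disp[, , , 2])
  pz <- g$z + as.vector(field$disp[, , , 3])
  vals <- if (interpolation == "trilinear") {
    .sample_trilinear(arr, px, py, pz)$v
  } else {
    .sample_nearest(arr, px, py, pz)
  }
  out <- array(vals, shape)
  if (inherits(volume, "volume3d")) {
    volume3d(out, spacing = volume$spacing, affine = volume$affine)
  } else {
    out
  }
}

#' Image similarity loss
#'
#' Dissimilarity between a warped volume and the template; lower is better.
#' `"mse"` is the mean squared intensity difference. `"ncc"` is one minus the
#' global normalized cross-correlation, which is invariant to affine intensity
#' rescaling of either image and therefore robust to the PET/template
#' intensity-scale mismatch; if either image has zero variance the loss is
#' defined as 1.
#'
#' @param warped,template [volume3d]s (or arrays) on congruent grids.
#' @param kind `"ncc"` (default) or `"mse"`.
#' @return Scalar loss.
#' @export
similarity_loss <- function(warped, template, kind = c("ncc", "mse")) {
  kind <- match.arg(kind)
  .sim_loss_grad(.as_vol_array(warped), .as_vol_array(template), kind,
                 grad = FALSE)$loss
}

# Loss and (optionally) gradient with respect to the warped intensities.
.sim_loss_grad <- function(w, t, kind, grad = TRUE) {
  if (!all(dim(w) == dim(t)))
    stop("warped and template grids are not congruent")
  n <- length(w)
  if (kind == "mse") {
    d <- w - t
    out <- list(loss = mean(d^2))
    if (grad) out$grad <- 2 * d / n
    return(out)
  }
  a <- w - mean(w)
  b <- t - mean(t)
  na2 <- sum(a^2); nb2 <- sum(b^2)
  if (na2 <= 0 || nb2 <= 0) {
    return(list(loss = 1, grad = if (grad) array(0, dim(w))))
  }
  denom <- sqrt(na2 * nb2)
  ncc <- sum(a * b) / denom
  out <- list(loss = 1 - ncc)
  if (grad) {
    g <- b / denom - ncc * a / na2
    out$grad <- -(g - mean(g))   # centering projection, d(1-ncc)/dw
  }
  out
}

#' Diffusion regularizer of a deformation field
#'
#' Smoothness penalty: for each displacement component, the mean squared
#' forward finite difference is taken along each grid axis; the three per-axis
#' means are summed and the result averaged over the three components. Zero
#' for any constant field (translations are free).
#'
#' @param field a [deformation_field].
#' @return Scalar penalty (voxels squared per voxel).
#' @export
regularizer <- function(field) {
  .reg_grad(field$disp, grad = FALSE)$value
}

.reg_grad <- function(u, grad = TRUE) {
  if (!is.double(u)) storage.mode(u) <- "double"
  out <- cpp_reg_grad(u, dim(u)[1:3], grad)
  if (grad) out$grad <- array(out$grad, dim(u))
  out
}

# Rigid pull map: output[v] = vol(R (v - c) + c + t), angles in degrees,
# translations in voxels, rotation about the grid center.
.rigid_coords <- function(shape, angles, trans) {
  g <- .grid_coords(shape)
  ctr <- (shape - 1) / 2
  R <- .rot3(angles)
  P <- cbind(g$x - ctr[1], g$y - ctr[2], g$z - ctr[3]) %*% t(R)
  list(x = P[, 1] + ctr[1] + trans[1],
       y = P[, 2] + ctr[2] + trans[2],
       z = P[, 3] + ctr[3] + trans[3])
}

.rot3 <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Random rigid-plus-noise augmentation
#'
#' Training-time data augmentation: a random rigid transform (uniform
#' translation within `translation` voxels and rotation within `rotation`
#' degrees per axis, resampled trilinearly about the grid center) followed by
#' additive Gaussian intensity noise. With all ranges zero the input is
#' returned unchanged.
#'
#' @param volume a [volume3d].
#' @param ranges list with elements `noise_sd` (intensity units),
#'   `translation` (voxels) and `rotation` (degrees); missing elements
#'   default to 0.
#' @param seed integer seed; the same seed reproduces the same augmentation.
#' @return The augmented [volume3d].
#' @export
augment <- function(volume, ranges = list(), seed = 1L) {
  r <- utils::modifyList(list(noise_sd = 0, translation = 0, rotation = 0),
                         ranges)
  if (r$noise_sd == 0 && r$translation == 0 && r$rotation == 0)
    return(volume)
  arr <- .as_vol_array(volume)
  shape <- dim(arr)
  out <- withr::with_seed(seed, {
    trans <- stats::runif(3, -r$translation, r$translation)
    angles <- stats::runif(3, -r$rotation, r$rotation)
    a <- if (any(trans != 0) || any(angles != 0)) {
      p <- .rigid_coords(shape, angles, trans)
      array(.sample_trilinear(arr, p$x, p$y, p$z)$v, shape)
    } else arr
    if (r$noise_sd > 0)
      a <- a + array(stats::rnorm(length(a), 0, r$noise_sd), shape)
    a
  })
  if (inherits(volume, "volume3d")) {
    volume3d(out, spacing = volume$spacing, affine = volume$affine)
  } else {
    out
  }
}
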