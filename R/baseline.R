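#' Rigid transform
#'
#' Six-parameter rigid body transform: rotation angles (degrees, about the
#' grid center) and translations (voxels). Applied with pull semantics:
#' `output[v] = input(R (v - c) + c + t)`. This is a functional stand-in for
#' an SPM-style coregistration step, not a reimplementation of any external
#' tool.
#'
#' @param angles numeric length-3, degrees.
#' @param translation numeric length-3, voxels.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(angles = c(0, 0, 0), translation = c(0, 0, 0)) {
  structure(list(angles = as.numeric(angles),
                 translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> angles (%s) deg, translation (%s) vox\n",
              paste(signif(x$angles, 3), collapse = ", "),
              paste(signif(x$translation, 3), collapse = ", ")))
  invisible(x)
}

#' Apply a rigid transform to a volume
#'
#' @param volume a [volume3d].
#' @param transform a [rigid_transform()].
#' @return The resampled [volume3d] (trilinear, zero outside).
#' @export
apply_rigid <- function(volume, transform) {
  arr <- .as_vol_array(volume)
  p <- .rigid_coords(dim(arr), transform$angles, transform$translation)
  out <- array(.sample_trilinear(arr, p$x, p$y, p$z)$v, dim(arr))
  if (inherits(volume, "volume3d")) {
    volume3d(out, spacing = volume$spacing, affine = volume$affine)
  } else out
}

.rigid_ncc <- function(par, marr, farr, shape) {
  p <- .rigid_coords(shape, par[1:3], par[4:6])
  w <- .sample_trilinear(marr, p$x, p$y, p$z)$v
  .sim_loss_grad(array(w, shape), farr, "ncc", grad = FALSE)$loss
}

#' Rigid PET-to-MR coregistration
#'
#' Estimates the six rigid parameters maximizing global normalized
#' cross-correlation between the transformed moving volume and the fixed
#' volume. A deterministic coarse translation search is followed by
#' Nelder-Mead refinement from multiple starts (identity plus seeded
#' jitters); the best is returned.
#'
#' @param moving,fixed [volume3d]s on congruent grids (e.g. PET and MR).
#' @param config list: `n_starts` extra random starts, `search` half-width
#'   of the coarse translation grid (voxels), `seed`.
#' @return A [rigid_transform()] such that `apply_rigid(moving, .)` aligns
#'   `moving` to `fixed`.
#' @export
rigid_coregister <- function(moving, fixed,
                             config = list(n_starts = 3L, search = 6,
                                           seed = 1L)) {
  config <- utils::modifyList(list(n_starts = 3L, search = 6, seed = 1L),
                              config)
  marr <- .as_vol_array(moving)
  farr <- .as_vol_array(fixed)
  if (!all(dim(marr) == dim(farr)))
    stop("moving and fixed grids are not congruent")
  shape <- dim(marr)

  # coarse translation grid (step 2 voxels)
  steps <- seq(-config$search, config$search, by = 2)
  best_t <- c(0, 0, 0)
  best_l <- .rigid_ncc(c(0, 0, 0, best_t), marr, farr, shape)
  for (tx in steps) for (ty in steps) for (tz in steps) {
    l <- .rigid_ncc(c(0, 0, 0, tx, ty, tz), marr, farr, shape)
    if (l < best_l) { best_l <- l; best_t <- c(tx, ty, tz) }
  }

  starts <- withr::with_seed(as.integer(config$seed), {
    s <- list(c(0, 0, 0, best_t))
    for (i in seq_len(config$n_starts)) {
      s[[i + 1L]] <- c(stats::runif(3, -3, 3),
                       best_t + stats::runif(3, -1.5, 1.5))
    }
    s
  })
  best <- NULL
  for (p0 in starts) {
    fit <- stats::optim(p0, .rigid_ncc, marr = marr, farr = farr,
                        shape = shape, method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-8))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  rigid_transform(angles = best$par[1:3], translation = best$par[4:6])
}

#' Iterative MR-to-template nonlinear normalization
#'
#' Classic-pipeline counterpart of the learned model: multi-resolution
#' demons-style optimization of the same NCC + diffusion objective by direct
#' gradient descent on the displacement field, with Gaussian field smoothing
#' after every update. Deterministic (no randomness).
#'
#' @param mr moving [volume3d] (native-space MR).
#' @param template fixed [volume3d] on a congruent grid.
#' @param levels number of resolution levels (coarsest is
#'   `2^(levels-1)`-fold pooled); grid dimensions must be divisible by the
#'   coarsest pooling factor.
#' @param iterations per-level iteration counts (recycled to `levels`).
#' @param step maximum displacement update per iteration (voxels).
#' @param field_sigma Gaussian smoothing sd applied to the field each
#'   iteration (voxels).
#' @return The template-to-native [deformation_field].
#' @export
iterative_normalize <- function(mr, template, levels = 2L,
                                iterations = c(80L, 40L), step = 0.4,
                                field_sigma = 1.2) {
  marr <- .as_vol_array(mr)
  tarr <- .as_vol_array(template)
  if (!all(dim(marr) == dim(tarr)))
    stop("MR and template grids are not congruent")
  iterations <- rep_len(iterations, levels)
  shape <- dim(marr)
  u <- NULL
  for (lev in seq(levels, 1)) {
    f <- 2^(lev - 1)
    if (any(shape %% f != 0))
      stop("grid dimensions must be divisible by ", f)
    sh <- shape %/% f
    P <- if (f > 1) .pool_matrix(shape, f)
    ml <- if (f > 1) array(as.numeric(P %*% as.vector(marr)), sh) else marr
    tl <- if (f > 1) array(as.numeric(P %*% as.vector(tarr)), sh) else tarr
    g <- .grid_coords(sh)
    if (is.null(u)) {
      u <- matrix(0, prod(sh), 3)
    } else {
      # upsample previous level's field (displacements scale with resolution)
      prev_sh <- shape %/% (2 * f)
      up <- .upsample_from(sh, prev_sh)
      u <- 2 * as.matrix(up %*% u)
    }
    for (it in seq_len(iterations[lev])) {
      smp <- .sample_trilinear(ml, g$x + u[, 1], g$y + u[, 2], g$z + u[, 3],
                               grad = TRUE)
      sl <- .sim_loss_grad(array(smp$v, sh), tl, "ncc")
      gsim <- as.vector(sl$grad)
      G <- cbind(gsim * smp$gx, gsim * smp$gy, gsim * smp$gz)
      gmax <- max(abs(G))
      if (gmax <= 0) break
      u <- u - (step / gmax) * G
      for (cc in 1:3) {
        u[, cc] <- as.vector(gauss_smooth3d(array(u[, cc], sh), field_sigma))
      }
    }
  }
  deformation_field(array(u, c(shape, 3L)))
}

# trilinear upsampling operator between two arbitrary congruent grids
.upsample_from <- function(shape_to, shape_from) {
  g <- .grid_coords(shape_to)
  sc <- (shape_from - 1) / pmax(shape_to - 1, 1)
  n <- length(g$x)
  px <- g$x * sc[1]; py <- g$y * sc[2]; pz <- g$z * sc[3]
  x0 <- pmin(floor(px), shape_from[1] - 2); fx <- px - x0
  y0 <- pmin(floor(py), shape_from[2] - 2); fy <- py - y0
  z0 <- pmin(floor(pz), shape_from[3] - 2); fz <- pz - z0
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
         (if (dz) fz else 1 - fz)
    keep <- w > 0
    rows <- c(rows, which(keep))
    cols <- c(cols, ((x0 + dx) + shape_from[1] *
                       ((y0 + dy) + shape_from[2] * (z0 + dz)) + 1)[keep])
    vals <- c(vals, w[keep])
  }
  Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                       dims = c(n, prod(shape_from)))
}

#' Classic MR-based pipeline
#'
#' The comparison path: rigidly coregister the PET to its MR, nonlinearly
#' normalize the MR to the template, then apply the composed transform to the
#' PET in a single resampling (world-space concatenation, one interpolation —
#' never two successive resamplings).
#'
#' @param pet,mr native-space [volume3d]s on the template grid dimensions;
#'   `mr = NULL` raises an error pointing to the MR-free path.
#' @param template template [volume3d].
#' @param config list passed to [rigid_coregister()] plus optional
#'   `levels`/`iterations` for [iterative_normalize()].
#' @return list with `warped_pet` (template-space [volume3d]), `rigid` (the
#'   PET-to-MR [rigid_transform()]) and `field` (the MR-to-template
#'   [deformation_field]).
#' @export
run_classic <- function(pet, mr, template, config = list()) {
  if (is.null(mr))
    stop("classic pipeline requires a structural MR image; ",
         "use the MR-free path (normalize()) when no MR is available")
  config <- utils::modifyList(list(n_starts = 3L, search = 6, seed = 1L,
                                   levels = 2L, iterations = c(80L, 40L)),
                              config)
  parr <- .as_vol_array(pet)
  shape <- dim(parr)
  rigid <- rigid_coregister(pet, mr, config = config[c("n_starts", "search",
                                                       "seed")])
  field <- iterative_normalize(mr, template, levels = config$levels,
                               iterations = config$iterations)
  # compose: template voxel v -> MR position v + u(v) -> PET position via the
  # rigid map; one trilinear resampling of the PET
  g <- .grid_coords(shape)
  px <- g$x + as.vector(field$disp[, , , 1])
  py <- g$y + as.vector(field$disp[, , , 2])
  pz <- g$z + as.vector(field$disp[, , , 3])
  ctr <- (shape - 1) / 2
  R <- .rot3(rigid$angles)
  P <- cbind(px - ctr[1], py - ctr[2], pz - ctr[3]) %*% t(R)
  w <- .sample_trilinear(parr, P[, 1] + ctr[1] + rigid$translation[1],
                         P[, 2] + ctr[2] + rigid$translation[2],
                         P[, 3] + ctr[3] + rigid$translation[3])$v
  spacing <- if (inherits(pet, "volume3d")) pet$spacing else c(1, 1, 1)
  list(warped_pet = volume3d(array(w, shape), spacing = spacing),
       rigid = rigid, field = field)
}
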