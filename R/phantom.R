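#' @title ROI atlas on the template grid
#'
#' @description An integer label map congruent with the template plus a table
#' mapping each label to one or more ROI roles. One label per voxel; composite
#' ROIs (the Braak-stage and metatemporal sets) are unions of labels, so a
#' single label may carry several roles (e.g. the entorhinal blob belongs to
#' `ec`, `braak12` and `metatemporal`).
#'
#' @param labels 3D integer array (0 = background).
#' @param roles data.frame with columns `label` (integer) and `role`
#'   (character), one row per (label, role) membership.
#' @return An object of class `roi_atlas`.
#' @export
roi_atlas <- function(labels, roles) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array")
  storage.mode(labels) <- "integer"
  roles <- as.data.frame(roles)
  if (!all(c("label", "role") %in% names(roles)))
    stop("`roles` needs columns `label` and `role`")
  bad <- setdiff(roles$role, .atlas_roles)
  if (length(bad))
    stop("unknown ROI role(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(roles[c("label", "role")]))
    stop("duplicate (label, role) rows in the role table")
  present <- setdiff(sort(unique(as.vector(labels))), 0L)
  uncovered <- setdiff(present, roles$label)
  if (length(uncovered))
    stop("label(s) without any role: ", paste(uncovered, collapse = ", "))
  atlas <- structure(list(labels = labels, roles = roles), class = "roi_atlas")
  if (length(.role_voxels(atlas, "cerebellar_gray")) == 0L)
    stop("cerebellar_gray must be nonempty")
  atlas
}

.atlas_roles <- c("braak12", "braak34", "braak56", "metatemporal",
                  "ec", "itg", "cerebellar_gray", "background")

# flat voxel indices belonging to a role (union over its labels)
.role_voxels <- function(atlas, role) {
  labs <- atlas$roles$label[atlas$roles$role == role]
  which(atlas$labels %in% labs)
}

#' @export
print.roi_atlas <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<roi_atlas> %d x %d x %d, %d labels, roles: %s\n",
              d[1], d[2], d[3], length(setdiff(unique(as.vector(x$labels)), 0L)),
              paste(sort(unique(x$roles$role)), collapse = ", ")))
  invisible(x)
}

# One-voxel 6-neighbour erosion of a logical mask.
.erode <- function(mask, shape) {
  m <- array(mask, shape)
  out <- m
  d <- shape
  sh <- function(a, ax, by) {
    r <- array(FALSE, d)
    if (ax == 1) { if (by > 0) r[2:d[1], , ] <- a[1:(d[1] - 1), , ]
                   else r[1:(d[1] - 1), , ] <- a[2:d[1], , ] }
    if (ax == 2) { if (by > 0) r[, 2:d[2], ] <- a[, 1:(d[2] - 1), ]
                   else r[, 1:(d[2] - 1), ] <- a[, 2:d[2], ] }
    if (ax == 3) { if (by > 0) r[, , 2:d[3]] <- a[, , 1:(d[3] - 1)]
                   else r[, , 1:(d[3] - 1)] <- a[, , 2:d[3]] }
    r
  }
  for (ax in 1:3) for (by in c(1, -1)) out <- out & sh(m, ax, by)
  out
}

# Ellipsoid membership in normalized [-1,1]^3 coordinates.
.ellipsoid <- function(xi, center, radii) {
  ((xi$x - center[1]) / radii[1])^2 +
    ((xi$y - center[2]) / radii[2])^2 +
    ((xi$z - center[3]) / radii[3])^2 <= 1
}

#' Synthetic head template and ROI atlas
#'
#' Builds a fully synthetic, smooth "head": nested ellipsoidal tissue classes
#' (background, cortical gray, central white, cerebellum) with MR-like
#' contrast, plus seven deterministic ROI blobs standing in for the
#' Braak-stage composites, the metatemporal composite and the entorhinal /
#' inferior-temporal subregions. Blob centers are jittered slightly by `seed`
#' so different seeds give different (but fixed) anatomies. The atlas is
#' congruent with the template grid; the role taxonomy, not real anatomy, is
#' what is reproduced.
#'
#' @param shape grid dimensions, each at least 24.
#' @param seed integer seed.
#' @param spacing voxel size in mm.
#' @return list with elements `template` ([volume3d], MR-like intensities)
#'   and `atlas` ([roi_atlas]).
#' @examples
#' tp <- make_template(c(32, 32, 32), seed = 7)
#' table(tp$atlas$labels[tp$atlas$labels > 0])
#' @export
make_template <- function(shape = c(32L, 32L, 32L), seed = 1L,
                          spacing = c(2, 2, 2)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 24L))
    stop("each template dimension must be >= 24")
  g <- .grid_coords(shape)
  ctr <- (shape - 1) / 2
  xi <- list(x = (g$x - ctr[1]) / ctr[1],
             y = (g$y - ctr[2]) / ctr[2],
             z = (g$z - ctr[3]) / ctr[3])

  brain <- .ellipsoid(xi, c(0, 0.08, 0.12), c(0.74, 0.78, 0.62))
  white <- .ellipsoid(xi, c(0, 0.08, 0.20), c(0.46, 0.50, 0.34))
  cereb <- .ellipsoid(xi, c(0, -0.52, -0.46), c(0.36, 0.28, 0.24)) & !brain
  vent <- (.ellipsoid(xi, c(-0.14, 0.12, 0.18), c(0.10, 0.20, 0.13)) |
           .ellipsoid(xi, c(0.14, 0.12, 0.18), c(0.10, 0.20, 0.13))) & brain
  # scalp/skull shell with off-target uptake, so brain edges do not border
  # zero-activity background directly
  scalp <- .ellipsoid(xi, c(0, -0.04, -0.04), c(0.92, 0.96, 0.86)) &
    !brain & !cereb

  blobs <- withr::with_seed(as.integer(seed), {
    base <- list(
      braak12_l = list(c(-0.33, 0.10, -0.24), c(0.33, 0.28, 0.26)),
      ec_r      = list(c(0.33, 0.10, -0.26), c(0.27, 0.24, 0.23)),
      braak34_l = list(c(-0.34, -0.20, 0.12), c(0.34, 0.29, 0.27)),
      itg_r     = list(c(0.36, -0.18, 0.00), c(0.29, 0.26, 0.25)),
      braak56_f = list(c(0, 0.50, 0.30), c(0.42, 0.36, 0.33)),
      braak56_p = list(c(0, -0.34, 0.48), c(0.40, 0.34, 0.30)),
      meta_mtg  = list(c(-0.38, 0.40, 0.08), c(0.27, 0.24, 0.24)))
    list(blobs = lapply(base, function(b) {
      list(center = b[[1]] + stats::runif(3, -0.03, 0.03), radii = b[[2]])
    }),
    # low-frequency intensity texture standing in for gyral/sulcal detail
    texture = {
      tex <- gauss_smooth3d(array(stats::rnorm(prod(shape)), shape), 1.5)
      0.14 * tex / stats::sd(tex)
    })
  })
  texture <- blobs$texture
  blobs <- blobs$blobs

  labels <- array(0L, shape)
  labels[.erode(cereb, shape)] <- 1L        # eroded cerebellar-gray reference
  for (i in seq_along(blobs)) {
    inside <- .ellipsoid(xi, blobs[[i]]$center, blobs[[i]]$radii) &
      brain & !vent & labels == 0L
    labels[inside] <- i + 1L
  }

  roles <- data.frame(
    label = c(1L, 2L, 3L, 3L, 3L, 4L, 5L, 5L, 5L, 6L, 7L, 8L),
    role = c("cerebellar_gray",
             "braak12",
             "braak12", "ec", "metatemporal",
             "braak34",
             "braak34", "itg", "metatemporal",
             "braak56", "braak56",
             "metatemporal"),
    stringsAsFactors = FALSE)

  intensity <- array(0, shape)
  intensity[brain] <- 0.7
  intensity[white] <- 1.0
  intensity[cereb] <- 0.75
  intensity[scalp] <- 0.33
  intensity[vent] <- 0.12
  intensity[brain | cereb] <- intensity[brain | cereb] +
    texture[brain | cereb]
  intensity <- gauss_smooth3d(intensity, 0.7)

  list(template = volume3d(intensity, spacing = spacing),
       atlas = roi_atlas(labels, roles))
}

#' Sample a smooth invertible random deformation
#'
#' Gaussian-smoothed white-noise displacement plus a small random affine
#' (rotation + translation) component, rescaled so the peak displacement
#' magnitude equals `amplitude` voxels. The field is rejected and rescaled
#' (factor 0.8, at most 10 retries) until the minimum finite-difference
#' Jacobian determinant over interior voxels exceeds 0.1, guaranteeing an
#' invertible ground truth. `amplitude = 0` returns the zero field exactly.
#'
#' @param shape grid dimensions.
#' @param amplitude peak displacement magnitude in voxels (>= 0).
#' @param smoothness Gaussian smoothing sd in voxels (> 0).
#' @param seed integer seed.
#' @return A [deformation_field] on `shape`.
#' @export
sample_deformation <- function(shape, amplitude = 2, smoothness = 4,
                               seed = 1L) {
  shape <- as.integer(shape)
  if (amplitude < 0) stop("`amplitude` must be >= 0")
  if (smoothness <= 0) stop("`smoothness` must be > 0")
  if (amplitude == 0) return(.zero_field(shape))
  u <- withr::with_seed(as.integer(seed), {
    raw <- array(stats::rnorm(prod(shape) * 3), c(shape, 3L))
    for (cc in 1:3) raw[, , , cc] <- gauss_smooth3d(raw[, , , cc], smoothness)
    mag <- sqrt(raw[, , , 1]^2 + raw[, , , 2]^2 + raw[, , , 3]^2)
    raw <- raw * (0.7 * amplitude / max(mag))
    # small affine component: rotation/translation displacement capped at
    # 30% of the amplitude
    angles <- stats::runif(3, -1, 1)
    trans <- stats::runif(3, -1, 1)
    p <- .rigid_coords(shape, angles, trans)
    g <- .grid_coords(shape)
    aff <- cbind(p$x - g$x, p$y - g$y, p$z - g$z)
    amax <- max(sqrt(rowSums(aff^2)))
    if (amax > 0) aff <- aff * (0.3 * amplitude / amax)
    tot <- raw + array(aff, c(shape, 3L))
    mag <- sqrt(tot[, , , 1]^2 + tot[, , , 2]^2 + tot[, , , 3]^2)
    tot * (amplitude / max(mag))
  })
  for (try in 0:10) {
    f <- deformation_field(u)
    if (min(jacobian_det(f)) > 0.1) return(f)
    u <- u * 0.8
  }
  stop("could not generate a deformation with Jacobian determinant > 0.1")
}

# --- uptake painting -------------------------------------------------------

#' Stage-dependent tau uptake profiles
#'
#' Default relative uptake levels (SUVR-like, cerebellar gray = 1) per ROI
#' role for the three clinical stages: cognitively normal subjects sit near
#' 1.0-1.2, mild cognitive impairment elevates the early Braak regions, and
#' AD elevates all stages. An `amyloid` profile (diffuse cortical uptake with
#' little staging gradient) is provided as a second tracer for transfer
#' learning experiments.
#'
#' @param stage one of `"CN"`, `"MCI"`, `"AD"`, `"amyloid"`.
#' @return named numeric vector of role -> uptake level.
#' @export
stage_profile <- function(stage = c("CN", "MCI", "AD", "amyloid")) {
  stage <- match.arg(stage)
  switch(stage,
    CN = c(braak12 = 1.10, ec = 1.15, braak34 = 1.05, itg = 1.05,
           braak56 = 1.00, metatemporal = 1.08, cerebellar_gray = 1),
    MCI = c(braak12 = 1.45, ec = 1.55, braak34 = 1.30, itg = 1.35,
            braak56 = 1.15, metatemporal = 1.35, cerebellar_gray = 1),
    AD = c(braak12 = 1.80, ec = 1.90, braak34 = 1.70, itg = 1.75,
           braak56 = 1.55, metatemporal = 1.75, cerebellar_gray = 1),
    amyloid = c(braak12 = 1.35, ec = 1.35, braak34 = 1.40, itg = 1.40,
                braak56 = 1.45, metatemporal = 1.40, cerebellar_gray = 1))
}

# Uptake level painted for each label = max over the label's roles of the
# profile level (the most specific role dominates); cerebellar gray is pinned
# to 1 so it is a clean reference.
.label_levels <- function(atlas, profile) {
  labs <- sort(setdiff(unique(atlas$roles$label), 0L))
  sapply(labs, function(l) {
    rr <- atlas$roles$role[atlas$roles$label == l]
    if ("cerebellar_gray" %in% rr) return(1)
    max(profile[rr], na.rm = TRUE)
  }) |> stats::setNames(labs)
}

# Per-subject label uptake levels: stage profile times a lognormal ROI-level
# jitter (reference label 1 is never jittered). Shared by the full volume
# synthesis and the score-only cohort fast path so both see identical truth.
.subject_levels <- function(atlas, profile, seed, suvr_jitter) {
  levels <- .label_levels(atlas, profile)
  if (suvr_jitter > 0) {
    jit <- withr::with_seed(as.integer(seed),
                            exp(stats::rnorm(length(levels), 0, suvr_jitter)))
    jit[names(levels) == "1"] <- 1
    levels <- levels * jit
  }
  levels
}

.head_mask <- function(template, atlas) {
  .as_vol_array(template) > 0.05 | atlas$labels > 0L
}

# Tissue-dependent base PET activity derived from the MR-like template
# intensity by a piecewise-linear lookup (CSF low, gray high, white
# intermediate -- the gray/white/CSF contrast real tau PET shows); labeled
# ROI voxels are pinned to gray activity 1 so painted uptake levels are
# relative to gray matter.
.pet_base <- function(template, atlas) {
  arr <- .as_vol_array(template)
  act <- array(stats::approx(x = c(-10, 0.03, 0.15, 0.36, 0.52, 0.70, 1.10, 10),
                             y = c(0, 0, 0.28, 0.35, 0.95, 1.05, 0.55, 0.50),
                             xout = as.vector(arr), rule = 2)$y, dim(arr))
  act[atlas$labels > 0L] <- 1
  act
}

# Paint a template-space PET: base activity 1 inside the head, label levels
# on the ROI blobs, then mild smoothing (shared by subjects and the PET-like
# registration template so ROI means stay consistent).
.paint_pet <- function(template, atlas, levels, smooth_sigma = 0.6) {
  pet <- .pet_base(template, atlas)
  for (l in names(levels)) {
    pet[atlas$labels == as.integer(l)] <- levels[[l]]
  }
  gauss_smooth3d(pet, smooth_sigma)
}

# Painting followed by ROI averaging is linear in the label levels, so the
# true SUVR of any subject can be computed from a cached role x label matrix
# without materializing the volume. Exact (not approximate) by linearity of
# the Gaussian smoothing.
.suvr_linear_map <- function(template, atlas, smooth_sigma = 0.6) {
  roles <- setdiff(unique(atlas$roles$role), "background")
  labs <- sort(setdiff(unique(atlas$roles$label), 0L))
  vox <- lapply(roles, function(r) .role_voxels(atlas, r))
  names(vox) <- roles
  S0 <- gauss_smooth3d(.pet_base(template, atlas), smooth_sigma)
  b <- vapply(vox, function(v) mean(S0[v]), numeric(1))
  M <- matrix(0, length(roles), length(labs),
              dimnames = list(roles, as.character(labs)))
  for (l in labs) {
    Sl <- gauss_smooth3d(array(as.numeric(atlas$labels == l),
                               dim(atlas$labels)), smooth_sigma)
    M[, as.character(l)] <- vapply(vox, function(v) mean(Sl[v]), numeric(1))
  }
  list(roles = roles, base = b, M = M)
}

.suvr_from_levels <- function(map, levels) {
  num <- map$base + as.vector(map$M[, names(levels), drop = FALSE] %*%
                                (levels - 1))
  names(num) <- map$roles
  num / num[["cerebellar_gray"]]
}

# True SUVR per role from a painted template-space PET (before warping,
# scaling and noise): role mean over the reference mean.
.painted_suvr <- function(pet, atlas, roles) {
  ref <- mean(pet[.role_voxels(atlas, "cerebellar_gray")])
  sapply(roles, function(r) mean(pet[.role_voxels(atlas, r)]) / ref)
}

#' Synthesize a native-space phantom subject
#'
#' Paints stage-dependent tracer uptake onto the template-space atlas,
#' records the ground-truth SUVR per ROI role (painted ROI mean divided by
#' painted cerebellar-gray mean, before any warping or noise), then maps the
#' painted PET and the MR-like template into "native" space with the supplied
#' ground-truth deformation and adds Gaussian noise. `field` follows the
#' package's pull convention (template -> native): it is the field a perfect
#' normalization model would predict, and native volumes are created by
#' resampling through its numerical inverse.
#'
#' @param template,atlas output of [make_template()].
#' @param stage `"CN"`, `"MCI"`, `"AD"` or `"amyloid"` (see
#'   [stage_profile()]), ignored when `profile` is given.
#' @param field ground-truth [deformation_field] on the template grid.
#' @param noise_sd Gaussian noise sd as a fraction of the mean brain
#'   activity.
#' @param seed integer seed (per-subject ROI-level uptake jitter and noise).
#' @param profile optional named role -> uptake level vector overriding the
#'   stage profile.
#' @param suvr_jitter sd of the per-label lognormal uptake jitter.
#' @param activity_scale global PET activity scale (arbitrary units).
#' @param smooth_sigma Gaussian sd (voxels) of the mild post-painting
#'   smoothing (a point-spread stand-in); 0 paints sharp uptake, in which
#'   case a uniform profile yields true SUVR exactly 1 in every ROI.
#' @return An object of class `phantom_subject` with fields `pet_native`,
#'   `mr_native`, `true_field`, `true_suvr`, `stage`.
#' @export
synthesize_subject <- function(template, atlas, stage = "CN", field = NULL,
                               noise_sd = 0.05, seed = 1L, profile = NULL,
                               suvr_jitter = 0.08, activity_scale = 1000,
                               smooth_sigma = 0.6) {
  arr <- .as_vol_array(template)
  shape <- dim(arr)
  if (is.null(field)) field <- .zero_field(shape)
  if (!all(.field_shape(field) == shape))
    stop("field is not on the template grid")
  if (is.null(profile)) profile <- stage_profile(stage)

  levels <- .subject_levels(atlas, profile, seed, suvr_jitter)
  out <- withr::with_seed(as.integer(seed) + 1L, {
    pet_t <- .paint_pet(template, atlas, levels, smooth_sigma)
    roles <- setdiff(unique(atlas$roles$role), "background")
    true_suvr <- .painted_suvr(pet_t, atlas, roles)

    zero <- all(field$disp == 0)
    inv <- if (zero) field else invert_field(field)
    pet_n <- .as_vol_array(warp(pet_t, inv))
    mr_n <- .as_vol_array(warp(arr, inv))
    if (noise_sd > 0) {
      sd_abs <- noise_sd * mean(pet_n[pet_n > 0])
      pet_n <- pet_n + array(stats::rnorm(length(pet_n), 0, sd_abs), shape)
      mr_n <- mr_n + array(stats::rnorm(length(mr_n), 0, noise_sd * mean(mr_n[mr_n > 0])), shape)
    }
    list(pet = pet_n * activity_scale, mr = mr_n, suvr = true_suvr)
  })

  structure(list(
    pet_native = volume3d(out$pet, spacing = template$spacing,
                          affine = template$affine),
    mr_native = volume3d(out$mr, spacing = template$spacing,
                         affine = template$affine),
    true_field = field,
    true_suvr = out$suvr,
    stage = stage), class = "phantom_subject")
}

#' @export
print.phantom_subject <- function(x, ...) {
  cat(sprintf("<phantom_subject> stage %s, true SUVR: %s\n", x$stage,
              paste(sprintf("%s=%.3f", names(x$true_suvr), x$true_suvr),
                    collapse = ", ")))
  invisible(x)
}

#' Write a phantom subject to disk
#'
#' Writes `pet.nii.gz`, `mr.nii.gz` and `field.nii.gz` (displacements stacked
#' along a 4th dimension are not portable in this simple writer, so each
#' component goes to `field_<c>.nii.gz`) plus a JSON sidecar with the true
#' SUVR and stage.
#'
#' @param subject a `phantom_subject`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(subject, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(subject$pet_native, file.path(dir, "pet.nii.gz"))
  write_volume(subject$mr_native, file.path(dir, "mr.nii.gz"))
  for (cc in 1:3) {
    comp <- volume3d(subject$true_field$disp[, , , cc],
                     spacing = subject$pet_native$spacing)
    write_volume(comp, file.path(dir, sprintf("field_%d.nii.gz", cc)))
  }
  jsonlite::write_json(
    list(stage = subject$stage, true_suvr = as.list(subject$true_suvr)),
    file.path(dir, "subject.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
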