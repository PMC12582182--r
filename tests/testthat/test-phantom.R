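test_that("template generation is deterministic and well-formed", {
  a <- make_template(c(32, 32, 32), seed = 7)
  b <- make_template(c(32, 32, 32), seed = 7)
  expect_identical(a$template$data, b$template$data)
  expect_identical(a$atlas$labels, b$atlas$labels)

  expect_gt(length(petnorm:::.role_voxels(a$atlas, "cerebellar_gray")), 0)
  for (r in c("braak12", "braak34", "braak56", "metatemporal", "ec", "itg"))
    expect_gt(length(petnorm:::.role_voxels(a$atlas, r)), 0)

  # EC within Braak I-II union III-IV, ITG within III-IV (atlas invariant)
  ec <- petnorm:::.role_voxels(a$atlas, "ec")
  b12 <- petnorm:::.role_voxels(a$atlas, "braak12")
  b34 <- petnorm:::.role_voxels(a$atlas, "braak34")
  itg <- petnorm:::.role_voxels(a$atlas, "itg")
  expect_true(all(ec %in% union(b12, b34)))
  expect_true(all(itg %in% b34))

  expect_error(make_template(c(16, 32, 32)), "24")
})

test_that("non-background voxel fraction matches a brute-force count", {
  tp <- make_template(c(32, 32, 32), seed = 7)
  labs <- tp$atlas$labels
  count <- 0L
  for (k in seq_len(dim(labs)[3]))           # deliberate slow loop oracle
    for (j in seq_len(dim(labs)[2]))
      count <- count + sum(labs[, j, k] > 0L)
  expect_identical(sum(labs > 0L), count)
  frac <- count / length(labs)
  expect_gt(frac, 0.005)
  expect_lt(frac, 0.2)
})

test_that("sampled deformations are smooth, bounded and invertible", {
  shape <- c(32L, 32L, 32L)
  f1 <- sample_deformation(shape, amplitude = 2, smoothness = 4, seed = 3)
  f2 <- sample_deformation(shape, amplitude = 2, smoothness = 4, seed = 3)
  expect_identical(f1$disp, f2$disp)
  expect_equal(max(field_magnitude(f1)), 2, tolerance = 1e-12)

  zero <- sample_deformation(shape, amplitude = 0, smoothness = 4, seed = 3)
  expect_true(all(zero$disp == 0))

  # brute-force central-difference Jacobian determinant at every interior
  # voxel of a smaller field (independent of jacobian_det's vectorized path)
  fs <- sample_deformation(c(16L, 16L, 16L), amplitude = 2, smoothness = 3,
                           seed = 5)
  u <- fs$disp
  mins <- Inf
  for (i in 2:15) for (j in 2:15) for (k in 2:15) {
    J <- diag(3)
    for (cc in 1:3) {
      J[cc, 1] <- J[cc, 1] + (u[i + 1, j, k, cc] - u[i - 1, j, k, cc]) / 2
      J[cc, 2] <- J[cc, 2] + (u[i, j + 1, k, cc] - u[i, j - 1, k, cc]) / 2
      J[cc, 3] <- J[cc, 3] + (u[i, j, k + 1, cc] - u[i, j, k - 1, cc]) / 2
    }
    mins <- min(mins, det(J))
  }
  expect_gt(mins, 0.1)
  expect_equal(min(jacobian_det(fs)), mins, tolerance = 1e-12)
  expect_gt(min(jacobian_det(f1)), 0.1)
})

test_that("field inversion composes to the identity", {
  shape <- c(24L, 24L, 24L)
  f <- sample_deformation(shape, amplitude = 2, smoothness = 4, seed = 11)
  inv <- invert_field(f)
  g <- petnorm:::.grid_coords(shape)
  phi <- matrix(f$disp, ncol = 3)
  back <- petnorm:::.sample_field(inv, g$x + phi[, 1], g$y + phi[, 2],
                                  g$z + phi[, 3])
  resid <- sqrt(rowSums((phi + back)^2))
  expect_lt(mean(resid), 0.05)
})

test_that("synthesized subjects carry exact ground-truth SUVR", {
  tp <- phantom_fixture(c(32, 32, 32), seed = 2)

  # uniform uptake, no jitter, zero field, no noise, sharp painting ->
  # SUVR identically 1 (ratio of equal means)
  uni <- stage_profile("CN"); uni[] <- 1
  s0 <- synthesize_subject(tp$template, tp$atlas, field = NULL, noise_sd = 0,
                           seed = 4, profile = uni, suvr_jitter = 0,
                           smooth_sigma = 0)
  expect_equal(unname(s0$true_suvr), rep(1, length(s0$true_suvr)),
               tolerance = 1e-12)

  # AD paints more early-Braak uptake than CN under the identical seed
  ad <- synthesize_subject(tp$template, tp$atlas, "AD", NULL, 0, seed = 4)
  cn <- synthesize_subject(tp$template, tp$atlas, "CN", NULL, 0, seed = 4)
  expect_gt(ad$true_suvr[["braak12"]], cn$true_suvr[["braak12"]])

  # end-to-end identity: noise-free zero-field native PET quantifies to the
  # recorded truth (activity scaling must cancel in the ratio)
  est <- compute_suvr(cn$pet_native, tp$atlas,
                      roi_roles = names(cn$true_suvr))
  expect_equal(est$suvr, unname(cn$true_suvr[est$roi_role]),
               tolerance = 1e-9)

  # determinism
  cn2 <- synthesize_subject(tp$template, tp$atlas, "CN", NULL, 0, seed = 4)
  expect_identical(cn$pet_native$data, cn2$pet_native$data)
})

test_that("phantom volumes and sidecar round-trip through disk", {
  tp <- phantom_fixture(c(24, 24, 24), seed = 1)
  f <- sample_deformation(c(24, 24, 24), 1.5, 4, seed = 2)
  sub <- synthesize_subject(tp$template, tp$atlas, "MCI", f, 0.05, seed = 3)
  dir <- withr::local_tempdir()
  write_phantom(sub, dir)
  expect_true(all(file.exists(file.path(dir, c("pet.nii.gz", "mr.nii.gz",
                                               "subject.json")))))
  pet <- read_volume(file.path(dir, "pet.nii.gz"))
  expect_equal(pet$data, sub$pet_native$data, tolerance = 1e-6,
               ignore_attr = TRUE)
  side <- jsonlite::read_json(file.path(dir, "subject.json"))
  expect_identical(side$stage, "MCI")
  expect_equal(side$true_suvr$braak12, sub$true_suvr[["braak12"]],
               tolerance = 1e-9)
})
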