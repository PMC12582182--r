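test_that("uniform activity gives SUVR 1 in every ROI", {
  tp <- phantom_fixture(c(24, 24, 24))
  pet <- array(3.7, c(24, 24, 24))
  tab <- compute_suvr(pet, tp$atlas)
  expect_equal(tab$suvr, rep(1, nrow(tab)), tolerance = 1e-12)
})

test_that("SUVR is the voxel-pooled ROI mean over the reference mean", {
  # toy atlas: ROI voxels {2,2,4,4}, reference voxels {2,2} -> 1.5
  labs <- array(0L, c(8, 8, 8))
  labs[1:4, 1, 1] <- 2L
  labs[1:2, 2, 1] <- 1L
  atlas <- roi_atlas(labs, data.frame(label = c(1L, 2L),
                                      role = c("cerebellar_gray", "braak12")))
  pet <- array(1, c(8, 8, 8))
  pet[1:4, 1, 1] <- c(2, 2, 4, 4)
  pet[1:2, 2, 1] <- c(2, 2)
  expect_equal(compute_suvr(pet, atlas, roi_roles = "braak12")$suvr, 1.5)

  # composite pooling is voxel-weighted, not a mean of sub-ROI means
  labs2 <- labs
  labs2[5:6, 3, 1] <- 3L                  # second braak12 label, 2 voxels
  atlas2 <- roi_atlas(labs2, data.frame(
    label = c(1L, 2L, 3L), role = c("cerebellar_gray", "braak12", "braak12")))
  pet[5:6, 3, 1] <- c(8, 8)
  pooled <- mean(c(2, 2, 4, 4, 8, 8)) / 2
  expect_equal(compute_suvr(pet, atlas2, roi_roles = "braak12")$suvr, pooled)
})

test_that("SUVR matches a brute-force voxel accumulation oracle", {
  tp <- make_template(c(24, 24, 24), seed = 13)
  set.seed(14)
  pet <- array(abs(rnorm(24^3, mean = 2)), c(24, 24, 24))
  tab <- compute_suvr(pet, tp$atlas)
  labs <- tp$atlas$labels
  roles <- tp$atlas$roles
  for (r in tab$roi_role) {
    num <- den <- cnt <- rcnt <- 0
    member <- roles$label[roles$role == r]
    refs <- roles$label[roles$role == "cerebellar_gray"]
    for (i in seq_along(labs)) {          # independent slow accumulation
      if (labs[i] %in% member) { num <- num + pet[i]; cnt <- cnt + 1 }
      if (labs[i] %in% refs) { den <- den + pet[i]; rcnt <- rcnt + 1 }
    }
    expect_equal(tab$suvr[tab$roi_role == r], (num / cnt) / (den / rcnt),
                 tolerance = 1e-9)
  }
})

test_that("SUVR is scale invariant and ROI-monotone", {
  tp <- phantom_fixture(c(24, 24, 24))
  set.seed(15)
  pet <- array(abs(rnorm(24^3, mean = 2)), c(24, 24, 24))
  base <- compute_suvr(pet, tp$atlas)
  for (c in c(0.25, 7, 1234)) {
    expect_equal(compute_suvr(c * pet, tp$atlas)$suvr, base$suvr,
                 tolerance = 1e-12)
  }
  # raising activity only inside braak56 raises only ROIs overlapping it
  vox <- petnorm:::.role_voxels(tp$atlas, "braak56")
  pet2 <- pet; pet2[vox] <- pet2[vox] + 1
  up <- compute_suvr(pet2, tp$atlas)
  expect_gt(up$suvr[up$roi_role == "braak56"],
            base$suvr[base$roi_role == "braak56"])
  for (r in c("braak12", "braak34", "metatemporal", "ec", "itg")) {
    expect_equal(up$suvr[up$roi_role == r], base$suvr[base$roi_role == r],
                 tolerance = 1e-12)
  }
})

test_that("quantification errors are explicit", {
  tp <- phantom_fixture(c(24, 24, 24))
  pet <- array(1, c(24, 24, 24))
  expect_warning(tab <- compute_suvr(pet, tp$atlas,
                                     roi_roles = c("braak12", "background")),
                 "no voxels")
  expect_true(is.na(tab$suvr[tab$roi_role == "background"]))
  expect_error(compute_suvr(array(0, c(24, 24, 24)), tp$atlas),
               "reference")
  expect_error(compute_suvr(array(1, c(16, 16, 16)), tp$atlas),
               "congruent")
})

test_that("atlases round-trip through NIfTI + CSV and are validated", {
  tp <- phantom_fixture(c(24, 24, 24))
  dir <- withr::local_tempdir()
  lp <- file.path(dir, "atlas.nii.gz"); rp <- file.path(dir, "roles.csv")
  write_atlas(tp$atlas, lp, rp)
  back <- load_atlas(lp, rp)
  expect_identical(back$labels, tp$atlas$labels)
  expect_identical(back$roles$role, tp$atlas$roles$role)

  bad <- tp$atlas$roles
  bad$role[1] <- "hippocampus"
  utils::write.csv(bad, rp, row.names = FALSE)
  expect_error(load_atlas(lp, rp), "unknown ROI role")

  dup <- rbind(tp$atlas$roles, tp$atlas$roles[1, ])
  utils::write.csv(dup, rp, row.names = FALSE)
  expect_error(load_atlas(lp, rp), "duplicate")
})

test_that("SUVR tables round-trip through CSV", {
  tp <- phantom_fixture(c(24, 24, 24))
  tab <- compute_suvr(array(2, c(24, 24, 24)), tp$atlas,
                      subject_id = "P001", scan_id = "P001_v1",
                      pipeline = "mrfree")
  path <- withr::local_tempfile(fileext = ".csv")
  write_suvr(tab, path)
  back <- read_suvr(path)
  expect_equal(back$suvr, tab$suvr, tolerance = 1e-12)
  expect_identical(back$pipeline, tab$pipeline)
})
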