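test_that("warping with the zero field is the identity", {
  tp <- phantom_fixture(c(24, 24, 24))
  zero <- petnorm:::.zero_field(c(24, 24, 24))
  out <- warp(tp$template, zero)
  expect_identical(out$data, tp$template$data)
})

test_that("constant integer displacement produces an exact shifted copy", {
  set.seed(21)
  arr <- array(rnorm(12^3), c(12, 12, 12))
  disp <- array(0, c(12, 12, 12, 3))
  disp[, , , 3] <- 2                      # sample from z + 2
  out <- warp(arr, deformation_field(disp))
  expect_equal(out[, , 1:10], arr[, , 3:12], tolerance = 1e-12)
  expect_true(all(out[, , 11:12] == 0))   # beyond the input grid
})

test_that("warp matches the per-voxel interpolation oracle", {
  set.seed(31)
  for (rep in 1:3) {
    arr <- array(rnorm(8^3), c(8, 8, 8))
    disp <- array(rnorm(8^3 * 3, sd = 1.5), c(8, 8, 8, 3))
    out <- warp(arr, deformation_field(disp))
    g <- petnorm:::.grid_coords(c(8, 8, 8))
    expected <- oracle_trilinear(arr,
                                 g$x + as.vector(disp[, , , 1]),
                                 g$y + as.vector(disp[, , , 2]),
                                 g$z + as.vector(disp[, , , 3]))
    expect_equal(as.vector(out), expected, tolerance = 1e-6)
  }
})

test_that("nearest-neighbour warp preserves label values", {
  tp <- phantom_fixture(c(24, 24, 24))
  f <- sample_deformation(c(24, 24, 24), 1.5, 4, seed = 8)
  labs <- array(as.numeric(tp$atlas$labels), dim(tp$atlas$labels))
  out <- warp(labs, f, interpolation = "nearest")
  expect_true(all(out %in% unique(as.vector(labs))))
})

test_that("similarity losses match direct arithmetic", {
  set.seed(5)
  a <- array(rnorm(27), c(3, 3, 3))
  b <- array(rnorm(27), c(3, 3, 3))
  expect_equal(similarity_loss(a, a, "mse"), 0)
  expect_equal(similarity_loss(a, a, "ncc"), 0, tolerance = 1e-12)

  expect_equal(similarity_loss(a, b, "mse"), mean((a - b)^2),
               tolerance = 1e-12)
  expect_equal(similarity_loss(a, b, "ncc"),
               1 - stats::cor(as.vector(a), as.vector(b)),
               tolerance = 1e-12)

  # affine intensity rescaling: ncc invariant, mse is not
  w <- 2.5 * b + 0.3
  expect_equal(similarity_loss(w, b, "ncc"), 0, tolerance = 1e-12)
  expect_equal(similarity_loss(w, b, "mse"), mean((1.5 * b + 0.3)^2),
               tolerance = 1e-12)

  # zero-variance guard
  expect_equal(similarity_loss(array(1, c(3, 3, 3)), b, "ncc"), 1)
})

test_that("ncc gradient agrees with finite differences", {
  set.seed(6)
  w <- array(rnorm(4^3), c(4, 4, 4))
  t <- array(rnorm(4^3), c(4, 4, 4))
  for (kind in c("ncc", "mse")) {
    sl <- petnorm:::.sim_loss_grad(w, t, kind)
    eps <- 1e-6
    for (idx in c(1L, 17L, 64L)) {
      wp <- w; wp[idx] <- wp[idx] + eps
      num <- (petnorm:::.sim_loss_grad(wp, t, kind, grad = FALSE)$loss -
                sl$loss) / eps
      expect_equal(sl$grad[idx], num, tolerance = 1e-4)
    }
  }
})

test_that("diffusion regularizer matches a finite-difference oracle", {
  shape <- c(8L, 8L, 8L)
  expect_equal(regularizer(petnorm:::.zero_field(shape)), 0)

  const <- array(1.7, c(shape, 3))        # translations are free
  expect_equal(regularizer(deformation_field(const)), 0)

  # independent oracle: accumulate squared forward differences by loops
  oracle_reg <- function(u) {
    d <- dim(u)[1:3]
    tot <- 0
    for (cc in 1:3) {
      s1 <- s2 <- s3 <- 0
      for (i in 1:(d[1] - 1)) s1 <- s1 + sum((u[i + 1, , , cc] - u[i, , , cc])^2)
      for (j in 1:(d[2] - 1)) s2 <- s2 + sum((u[, j + 1, , cc] - u[, j, , cc])^2)
      for (k in 1:(d[3] - 1)) s3 <- s3 + sum((u[, , k + 1, cc] - u[, , k, cc])^2)
      tot <- tot + s1 / ((d[1] - 1) * d[2] * d[3]) +
        s2 / (d[1] * (d[2] - 1) * d[3]) + s3 / (d[1] * d[2] * (d[3] - 1))
    }
    tot / 3
  }

  ramp <- array(0, c(shape, 3))
  ramp[, , , 1] <- array(petnorm:::.grid_coords(shape)$x, shape)
  expect_equal(oracle_reg(ramp), 1 / 3, tolerance = 1e-12)
  expect_equal(regularizer(deformation_field(ramp)), 1 / 3,
               tolerance = 1e-12)

  set.seed(41)
  u <- array(rnorm(prod(shape) * 3), c(shape, 3))
  expect_equal(regularizer(deformation_field(u)), oracle_reg(u),
               tolerance = 1e-12)
})

test_that("augmentation is seeded, optional and rigidly invertible", {
  tp <- phantom_fixture(c(24, 24, 24))
  v <- tp$template

  expect_identical(augment(v, list(), seed = 1)$data, v$data)

  r <- list(noise_sd = 0.05, translation = 2, rotation = 5)
  a1 <- augment(v, r, seed = 9)
  a2 <- augment(v, r, seed = 9)
  expect_identical(a1$data, a2$data)
  expect_false(identical(a1$data, augment(v, r, seed = 10)$data))

  # integer translation round trip through the same resampling machinery:
  # shift by (0,0,3), undo with a constant pull field of -3
  shifted <- apply_rigid(v, rigid_transform(translation = c(0, 0, 3)))
  disp <- array(0, c(24, 24, 24, 3)); disp[, , , 3] <- -3
  back <- warp(shifted, deformation_field(disp))
  interior <- back$data[, , 4:21]
  expect_equal(interior, v$data[, , 4:21], tolerance = 1e-5)
})
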