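test_that("warp with a zero field is the identity, exactly", {
  set.seed(1)
  v <- voxel_volume(matrix(rnorm(30 * 30), 30, 30), 2)
  z <- displacement_field(array(0, c(30, 30, 2)), 2)
  expect_identical(warp(v, z)$values, v$values)
  # constant-shift invariance away from edges
  vc <- voxel_volume(v$values + 7, 2)
  d <- array(0, c(30, 30, 2)); d[, , 1] <- 1.3; d[, , 2] <- -0.7
  f <- displacement_field(d, 2)
  w1 <- warp(v, f)$values; w2 <- warp(vc, f)$values
  expect_equal(w2[3:28, 3:28], w1[3:28, 3:28] + 7, tolerance = 1e-12)
})

test_that("integer-voxel translations move a delta by exactly that offset", {
  for (shift in list(c(2L, 0L), c(0L, 3L), c(-1L, 2L))) {
    img <- matrix(0, 25, 25); img[13, 13] <- 5
    v <- voxel_volume(img, 4)
    d <- array(0, c(25, 25, 2))
    d[, , 1] <- shift[1] * 4; d[, , 2] <- shift[2] * 4
    w <- warp(v, displacement_field(d, 4))$values
    # pull-back: the delta appears shifted by -shift
    expect_equal(w[13 - shift[1], 13 - shift[2]], 5)
    expect_equal(sum(w), 5)
  }
})

test_that("warp_matrix reproduces warp and has the right adjoint", {
  set.seed(2)
  v <- voxel_volume(matrix(runif(20 * 20), 20, 20), 3)
  d <- array(rnorm(20 * 20 * 2, 0, 2), c(20, 20, 2))
  f <- displacement_field(d, 3)
  W <- warp_matrix(f)
  expect_equal(as.numeric(W %*% as.vector(v$values)),
               as.vector(warp(v, f)$values), tolerance = 1e-12)
  # adjoint identity <Wx, y> == <x, W'y>
  x <- rnorm(400); y <- rnorm(400)
  expect_equal(sum(as.numeric(W %*% x) * y),
               sum(x * as.numeric(Matrix::crossprod(W, y))),
               tolerance = 1e-10)
})

test_that("smooth small deformations approximately preserve total activity", {
  ph <- fix$phantom
  fld <- motion_at(fix$truth, 0.15)   # ~3 mm peak, smooth
  w <- warp(ph$activity, fld)
  expect_lt(abs(sum(w$values) - sum(ph$activity$values)) /
              sum(ph$activity$values), 0.01)
})

test_that("field inversion composes to the identity for smooth fields", {
  fld <- motion_at(full_fix$truth, 0.8)
  inv <- invert_field(fld)
  # compose: x + d(x) + e(x + d(x)) should return to x (interior voxels)
  v <- voxel_volume(full_fix$phantom$activity$values, 3)
  back <- warp(warp(v, inv), fld)
  inner <- 10:86
  err <- abs(back$values[inner, inner] - v$values[inner, inner])
  expect_lt(mean(err), 0.02 * max(v$values))
})

test_that("gaussian postfilter preserves totals for interior objects", {
  img <- matrix(0, 40, 40); img[15:25, 15:25] <- 3
  v <- voxel_volume(img, 3)
  f <- gaussian_postfilter(v, 4)
  expect_lt(abs(sum(f$values) - sum(img)) / sum(img), 0.005)
  expect_error(gaussian_postfilter(v, -1), "FWHM")
})

test_that("geometry errors are caught", {
  v <- voxel_volume(matrix(0, 10, 10), 3)
  f <- displacement_field(array(0, c(12, 12, 2)), 3)
  expect_error(warp(v, f), "grid")
  expect_error(voxel_volume(matrix(0, 4, 4), -1), "spacing")
  expect_error(displacement_field(array(Inf, c(4, 4, 2)), 1), "finite")
})
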