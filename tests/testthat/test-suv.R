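test_that("SUV scaling follows the standard formula", {
  v <- voxel_volume(matrix(10, 8, 8), 3)
  s <- suv_scale(v, weight_kg = 70, dose_MBq = 350)
  expect_equal(unique(as.vector(s$values)), 2.0)
  expect_equal(s$semantics, "suv")
  # zero image and dose scaling
  expect_true(all(suv_scale(voxel_volume(matrix(0, 4, 4), 3), 70, 350)$values == 0))
  s2 <- suv_scale(v, 70, 700)
  expect_equal(s2$values, s$values / 2)
  expect_error(suv_scale(v, 0, 350), "weight")
})

test_that("uniform images give SUV_peak and SUV_max equal to the value", {
  v <- voxel_volume(matrix(1.7, 20, 20), 3)
  roi <- matrix(FALSE, 20, 20); roi[8:12, 8:12] <- TRUE
  expect_equal(suv_peak(v, roi), 1.7)
  expect_equal(suv_max(v, roi), 1.7)
})

test_that("SUV metrics match exhaustive brute-force sweeps exactly", {
  set.seed(77)
  for (rep in 1:6) {
    dims <- sample(18:40, 2)
    v <- voxel_volume(matrix(runif(prod(dims), 0, 10), dims[1], dims[2]),
                      sample(2:4, 1))
    roi <- matrix(FALSE, dims[1], dims[2])
    roi[sample(prod(dims), 40)] <- TRUE
    expect_identical(suv_peak(v, roi), brute_suv_peak(v, roi))
    expect_identical(suv_max(v, roi), brute_suv_max(v, roi))
  }
  # and on a 3D volume
  v3 <- voxel_volume(array(runif(20^3), c(20, 20, 20)), 3)
  roi3 <- array(FALSE, c(20, 20, 20)); roi3[8:12, 8:12, 8:12] <- TRUE
  expect_identical(suv_peak(v3, roi3), brute_suv_peak(v3, roi3))
})

test_that("a small hot lesion has SUV_peak strictly below SUV_max", {
  img <- matrix(0.2, 30, 30)
  img[14:15, 14:15] <- 8    # 6-mm lesion at 3-mm spacing
  v <- voxel_volume(img, 3)
  roi <- matrix(FALSE, 30, 30); roi[10:20, 10:20] <- TRUE
  expect_lt(suv_peak(v, roi), suv_max(v, roi))
})

test_that("suv_peak <= suv_max when the peak sphere covers its center", {
  set.seed(5)
  for (rep in 1:5) {
    v <- voxel_volume(matrix(rexp(900), 30, 30), 3)
    roi <- matrix(FALSE, 30, 30); roi[5:26, 5:26] <- TRUE
    expect_lte(suv_peak(v, roi), suv_max(v, roi))
  }
})

test_that("ROI errors are caught", {
  v <- voxel_volume(matrix(1, 10, 10), 3)
  expect_error(suv_peak(v, matrix(FALSE, 10, 10)), "empty")
  expect_error(suv_peak(voxel_volume(matrix(1, 3, 3), 3),
                        matrix(TRUE, 3, 3)), "larger than the grid")
  expect_error(suv_max(v, matrix(TRUE, 4, 4)), "differ")
})

test_that("percent SUV changes and the considerable rule follow the definition", {
  u <- data.frame(lesion = c("a", "b", "c", "d"),
                  suv_peak = c(10, 5, 5, 0),
                  suv_max = c(12, 6, 6, 0))
  mc <- data.frame(lesion = c("a", "b", "c", "d"),
                   suv_peak = c(11.24, 5, 5.3, 1),
                   suv_max = c(13.5, 6, 6.24, 1))
  d <- delta_suv(u, mc)
  expect_equal(d$dsuv_peak_pct[d$lesion == "a"], 12.4, tolerance = 1e-9)
  expect_true(d$considerable[d$lesion == "a"])  # both metrics above 5%
  expect_equal(d$dsuv_peak_pct[d$lesion == "b"], 0)
  expect_false(d$considerable[d$lesion == "b"])
  # +6% peak but +4% max: not considerable (both metrics must exceed 5%)
  expect_equal(d$dsuv_peak_pct[d$lesion == "c"], 6, tolerance = 1e-9)
  expect_equal(d$dsuv_max_pct[d$lesion == "c"], 4, tolerance = 1e-9)
  expect_false(d$considerable[d$lesion == "c"])
  expect_true(d$undefined[d$lesion == "d"])
  expect_true(is.na(d$dsuv_peak_pct[d$lesion == "d"]))
})
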