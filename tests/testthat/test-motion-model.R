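test_that("noise-free linear displacements are recovered to 1e-6 mm", {
  sr <- synthetic_regset(n_images = 60, noise_sd = 0)
  m <- fit_model(sr$reg)
  expect_lt(max(abs(m$c0[, , 2] - sr$c0)), 1e-6)
  expect_lt(max(abs(m$c1[, , 2] - sr$c1 * sr$p1)), 1e-6)
  expect_lt(max(abs(m$c2[, , 2] - sr$c2 * sr$p2)), 1e-6)
})

test_that("zero displacements yield the exactly null model", {
  sr <- synthetic_regset(n_images = 30, c0 = 0, c1 = 0, c2 = 0)
  m <- fit_model(sr$reg)
  expect_true(all(m$c0 == 0) && all(m$c1 == 0) && all(m$c2 == 0))
  z <- predict_field(m, 0.7, 0.2)
  expect_true(all(z$d == 0))
})

test_that("noisy slope recovery is within 5% where the slope is material", {
  # RMS over voxels: the per-voxel sampling error at the 2-mm slope floor is
  # ~5% (sigma = 0.5 mm over 200 images), so the voxelwise maximum is not a
  # meaningful bound, the aggregate is
  sr <- synthetic_regset(n_images = 200, noise_sd = 0.5, seed = 21)
  m <- fit_model(sr$reg)
  truth <- sr$c1 * sr$p1
  sel <- abs(truth) >= 2
  rel <- (m$c1[, , 2][sel] - truth[sel]) / truth[sel]
  expect_lt(sqrt(mean(rel^2)), 0.05)
  expect_lt(sqrt(mean((m$c0[, , 2] - sr$c0)^2)), 0.1)
})

test_that("Huber weighting contains gross outlier damage; OLS does not", {
  base <- synthetic_regset(n_images = 200, noise_sd = 0.5, seed = 31)
  dirty <- synthetic_regset(n_images = 200, noise_sd = 0.5,
                            outlier_frac = 0.10, outlier_mm = 20, seed = 31)
  truth <- base$c1 * base$p1
  sel <- abs(truth) >= 2
  err <- function(m) mean(abs(m$c1[, , 2][sel] - truth[sel]))
  e_clean <- err(fit_model(base$reg))
  e_huber <- err(fit_model(dirty$reg, robust = "huber"))
  e_ols <- err(fit_model(dirty$reg, robust = "ols"))
  expect_lt(e_huber, 2 * e_clean)
  expect_gt(e_ols, e_huber)        # plain least squares degrades more
})

test_that("prediction is exactly linear and flags extrapolation", {
  sr <- synthetic_regset(n_images = 40, noise_sd = 0.2, seed = 5)
  m <- fit_model(sr$reg)
  fa <- predict_field(m, 0.2, 0.1)$d
  fb <- predict_field(m, 0.5, -0.3)$d
  fab <- predict_field(m, 0.7, -0.2)$d
  f0 <- predict_field(m, 0, 0)$d
  expect_lt(max(abs(fa + fb - f0 - fab)), 1e-10 * max(1, max(abs(fab))))
  # midpoint property at sdot = 0
  mid <- predict_field(m, 0.5)$d
  ends <- (predict_field(m, 0)$d + predict_field(m, 1)$d) / 2
  expect_equal(mid, ends, tolerance = 1e-12)
  expect_false(attr(predict_field(m, 0.5), "extrapolated"))
  expect_true(attr(predict_field(m, 1.3), "extrapolated"))
  expect_error(predict_field(m, Inf), "finite")
})

test_that("prediction at the fit-reference state is near zero", {
  # s_power = 2 gives a long end-exhale dwell, so the modal state is
  # unambiguously near s = 0 where the displacements vanish
  sr <- synthetic_regset(n_images = 100, c0 = 0, noise_sd = 0.3, seed = 6,
                         s_power = 2)
  m <- fit_model(sr$reg)
  f <- predict_field(m, m$ref_state[["s"]], m$ref_state[["s_dot"]])
  # reference is the modal (end-exhale) state where displacements vanish
  expect_lt(max(abs(f$d)), 0.5)
})

test_that("degenerate designs are rejected with informative errors", {
  sr <- synthetic_regset(n_images = 30)
  reg <- sr$reg
  reg$s <- rep(0.5, 30)
  expect_error(fit_model(reg), "degenerate surrogate: s is")
  reg2 <- sr$reg
  reg2$s_dot <- 2 * reg2$s
  expect_error(fit_model(reg2), "collinear")
  expect_silent(fit_model(reg2, surrogates = "s"))
  reg3 <- sr$reg
  reg3$outlier <- c(rep(FALSE, 4), rep(TRUE, 26))
  expect_error(fit_model(reg3), "at least 6")
})

test_that("the fit is stable under removal of any single image", {
  sr <- synthetic_regset(n_images = 80, noise_sd = 0.3, seed = 41)
  m_full <- fit_model(sr$reg)
  truth <- sr$c1 * sr$p1
  sel <- abs(truth) >= 2
  for (drop in c(3L, 40L, 77L)) {
    reg <- sr$reg
    reg$outlier[drop] <- TRUE
    m_d <- fit_model(reg)
    rel <- abs(m_d$c1[, , 2][sel] - m_full$c1[, , 2][sel]) /
      abs(m_full$c1[, , 2][sel])
    expect_lt(max(rel), 0.05)
  }
})

test_that("the gradient term improves fits when the truth has hysteresis", {
  # truth d = c1 p1 s + c2 p2 sdot with distinct spatial patterns
  sr <- synthetic_regset(n_images = 150, c2 = 3, noise_sd = 0.3, seed = 51)
  m2 <- fit_model(sr$reg)
  m1 <- fit_model(sr$reg, surrogates = "s")
  states <- data.frame(s = sr$s[seq(1, 150, 10)],
                       s_dot = sr$s_dot[seq(1, 150, 10)])
  err <- function(m) mean(vapply(seq_len(nrow(states)), function(i) {
    pred <- predict_field(m, states$s[i], states$s_dot[i])$d[, , 2]
    tru <- sr$c0 + sr$c1 * sr$p1 * states$s[i] +
      sr$c2 * sr$p2 * states$s_dot[i]
    mean(abs(pred - tru))
  }, numeric(1)))
  expect_lt(err(m2), err(m1))
})
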