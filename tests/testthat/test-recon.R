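small_settings <- recon_settings(subsets = 21, iters = 3, fwhm_mm = 4)

test_that("all-zero data reconstructs to the zero image", {
  proj <- fix$proj
  y <- rep(0, proj$n_bins * proj$n_angles)
  r <- osem(y, proj, NULL, recon_settings(7, 1, 0))
  expect_true(all(r$volume$values == 0))
})

test_that("1-subset OSEM equals an independently coded MLEM", {
  proj <- fix$proj
  ph <- fix$phantom
  fr <- acquire_pet(ph, proj, NULL, NULL, duration = 60, noise = TRUE,
                    seed = 13)
  y <- rowSums(fr$counts)
  sc <- fr$calib * 60; bgv <- fr$bg_rate * 60
  r1 <- osem(y, proj, ph$mu, recon_settings(1, 12, 0), scale = sc, bg = bgv)
  # test-local MLEM
  att <- exp(-as.numeric(proj$A %*% as.vector(ph$mu$values)) / 10)
  x <- rep(1, prod(proj$dims))
  sens <- sc * as.numeric(Matrix::crossprod(proj$A, att))
  for (i in 1:12) {
    yh <- sc * att * as.numeric(proj$A %*% x) + bgv
    ratio <- ifelse(yh > 0, y / yh, 0)
    x <- x / sens * sc * as.numeric(Matrix::crossprod(proj$A, att * ratio))
  }
  expect_lt(max(abs(x - as.vector(r1$volume$values))) / max(x), 1e-8)
})

test_that("OSEM forward-projects back to noiseless data within 5%, monotonically", {
  proj <- fix$proj
  ph <- fix$phantom
  fr <- acquire_pet(ph, proj, NULL, NULL, duration = 120, noise = FALSE)
  y <- rowSums(fr$counts)
  r <- osem(y, proj, ph$mu, recon_settings(21, 3, 0),
            scale = fr$calib * 120, bg = fr$bg_rate * 120, track_fit = TRUE)
  expect_length(r$fit_track, 63L)
  expect_lt(tail(r$fit_track, 1), 0.05)
  expect_true(all(diff(r$fit_track) <= 1e-10))
  expect_true(all(r$volume$values >= 0))
})

test_that("pooled uncorrected recon equals plain OSEM when nothing moves", {
  proj <- fix$proj
  fr <- acquire_pet(fix$phantom, proj, NULL, NULL, duration = 30,
                    noise = TRUE, seed = 3)
  mum <- acquire_mumap(fix$phantom, NULL)
  ru <- recon_uncorrected(fr, mum, proj, small_settings)
  ro <- osem(rowSums(fr$counts), proj, mum$mu, small_settings,
             scale = fr$calib * 30, bg = fr$bg_rate * 30)
  expect_identical(ru$volume$values, ro$volume$values)
})

test_that("a zero-motion model makes MC equal the uncorrected recon", {
  proj <- fix$proj
  wf <- make_waveform(60, seed = 2)
  fr <- acquire_pet(fix$phantom, proj, fix$truth, wf, duration = 60,
                    noise = TRUE, seed = 4)
  mum <- acquire_mumap(fix$phantom, NULL)
  null_model <- truth_motion_model(make_motion_truth(fix$phantom, 0, 0))
  g <- make_gates(fr$hidden, n = 4, frame_counts = colSums(fr$counts))
  ru <- recon_uncorrected(fr, mum, proj, small_settings)
  rmc <- recon_motion_corrected(fr, mum, null_model, g, proj, small_settings)
  rel <- sqrt(sum((rmc$volume$values - ru$volume$values)^2)) /
    sqrt(sum(ru$volume$values^2))
  expect_lt(rel, 1e-6)
  # event accounting: MC consumed every acquired count
  expect_equal(rmc$provenance$counts_used, sum(fr$counts))
})

test_that("motion blurs the lesion; MC restores it (small-scale check)", {
  proj <- fix$proj
  ph <- fix$phantom; tr <- fix$truth
  wf <- make_waveform(120, seed = 6)
  fr_mov <- acquire_pet(ph, proj, tr, wf, duration = 120, noise = FALSE)
  fr_sta <- acquire_pet(ph, proj, NULL, NULL, duration = 120, noise = FALSE)
  mum <- acquire_mumap(ph, NULL)
  ru <- recon_uncorrected(fr_mov, mum, proj, small_settings)
  rs <- recon_uncorrected(fr_sta, mum, proj, small_settings)
  prof_width <- function(r) {
    ij <- round(c(181, 144) / 6) + 1
    prof <- r$volume$values[ij[1], ]
    sum(prof > max(prof) / 2) # apparent FWHM in voxels along SI
  }
  expect_gt(prof_width(ru), prof_width(rs))
  g <- make_gates(fr_mov$hidden, n = 4)
  rmc <- recon_motion_corrected(fr_mov, mum, truth_motion_model(tr), g,
                                proj, small_settings)
  expect_lte(prof_width(rmc), prof_width(ru))
  expect_true(all(rmc$volume$values >= 0))
})

test_that("reconstruct-transform-average agrees broadly with MCIR", {
  proj <- fix$proj
  wf <- make_waveform(60, seed = 7)
  fr <- acquire_pet(fix$phantom, proj, fix$truth, wf, duration = 60,
                    noise = TRUE, seed = 8)
  mum <- acquire_mumap(fix$phantom, NULL)
  g <- make_gates(fr$hidden, n = 4, frame_counts = colSums(fr$counts))
  m <- truth_motion_model(fix$truth)
  rmcir <- recon_motion_corrected(fr, mum, m, g, proj, small_settings)
  rrta <- recon_motion_corrected(fr, mum, m, g, proj, small_settings,
                                 mode = "rta")
  expect_gt(cor(as.vector(rmcir$volume$values),
                as.vector(rrta$volume$values)), 0.98)
})

test_that("invalid reconstruction settings are rejected", {
  expect_error(recon_settings(0, 3, 4), "subsets")
  expect_error(recon_settings(21, 0, 4), "iterations")
  expect_error(recon_settings(21, 3, -1), "FWHM")
})
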