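test_that("motionless noiseless acquisition gives a flagged zero surrogate", {
  fr <- acquire_pet(fix$phantom, fix$proj, NULL, NULL, duration = 10,
                    noise = FALSE)
  s <- extract_surrogate(fr)
  expect_true(attr(s, "degenerate"))
  expect_true(all(s$s == 0))
})

test_that("noise-free sinusoidal motion is recovered with |r| > 0.99", {
  # hysteresis off: with a lag term the anatomy's motion is not a pure
  # sinusoid of one phase and the surrogate rightly picks up the admixture
  tr <- make_motion_truth(full_fix$phantom, hysteresis_mm = 0)
  wf <- make_waveform(60, period_cv = 0, amp_cv = 0, k = 1, seed = 1)
  fr <- acquire_pet(full_fix$phantom, full_fix$proj, tr, wf,
                    duration = 60, noise = FALSE)
  s <- extract_surrogate(fr)          # default: PCA on frame sinograms
  expect_gt(abs(cor(s$s, fr$hidden$s)), 0.99)
  expect_gt(cor(s$s, fr$hidden$s), 0)  # sign convention
  sc <- extract_surrogate(fr, method = "com")
  expect_gt(cor(sc$s, fr$hidden$s), 0.97)
})

test_that("surrogate is invariant to global count scaling", {
  wf <- make_waveform(30, seed = 2)
  fr <- acquire_pet(fix$phantom, fix$proj, fix$truth, wf, duration = 30,
                    noise = FALSE)
  s1 <- extract_surrogate(fr)
  fr2 <- fr; fr2$counts <- fr$counts * 5
  s2 <- extract_surrogate(fr2)
  expect_equal(s1$s, s2$s, tolerance = 1e-9)
  # and deterministic across repeated runs
  s3 <- extract_surrogate(fr)
  expect_identical(s1$s, s3$s)
})

test_that("gradient of a pure sinusoid has the right amplitude ratio", {
  # frames whose score is an exact raised cosine of period 4 s; 0.2-s
  # sampling keeps the central-difference amplitude bias below 2%
  n_f <- 300; dt <- 0.2
  t <- (seq_len(n_f) - 1) * dt
  omega <- 2 * pi / 4
  sig <- (1 - cos(omega * t)) / 2
  pattern <- c(outer(exp(-((1:30) - 15)^2 / 20), rep(1, 10)))
  counts <- round(1000 + 2000 * outer(pattern, sig))
  fr <- structure(list(counts = counts, t_start = t, frame_dur = dt,
                       n_bins = 30L, n_angles = 10L),
                  class = "frame_series")
  s <- extract_surrogate(fr)
  # s normalized to [0,1]; derivative peak should be omega/2 within 5%
  expect_equal(max(abs(s$s_dot)) / max(abs(s$s)), omega / 2,
               tolerance = 0.05)
})

test_that("all-zero frames raise a degenerate-signal error", {
  fr <- structure(list(counts = matrix(0, 10, 5), t_start = 0:4,
                       frame_dur = 1, n_bins = 5L, n_angles = 2L),
                  class = "frame_series")
  expect_error(extract_surrogate(fr), "zero")
})

test_that("injected clock shifts are recovered within a quarter second", {
  wf <- make_waveform(240, seed = 5)
  fr <- acquire_pet(full_fix$phantom, full_fix$proj, full_fix$truth, wf,
                    seed = 6)
  surr <- extract_surrogate(fr)
  for (tau in c(-2, 0, 3.5)) {
    mr <- acquire_dynamic_mr(full_fix$phantom, full_fix$truth, wf,
                             clock_rate = 1, clock_offset = tau, seed = 8)
    al <- align_clocks(surr, mr)
    expect_lt(abs(al$tau - tau), 0.25)
    # argmax property: returned objective >= all grid objectives
    expect_gte(al$objective + 1e-9, max(al$grid$objective, na.rm = TRUE))
  }
})

test_that("clock-rate co-estimation limits end-of-series timing error", {
  wf <- make_waveform(240, seed = 5)
  fr <- acquire_pet(full_fix$phantom, full_fix$proj, full_fix$truth, wf,
                    seed = 6)
  surr <- extract_surrogate(fr)
  rate <- 1 + 1e-4
  mr <- acquire_dynamic_mr(full_fix$phantom, full_fix$truth, wf,
                           clock_rate = rate, clock_offset = 1, seed = 8)
  al <- align_clocks(surr, mr, estimate_rate = TRUE)
  t_true <- mr$hidden$t_pet
  t_est <- mr_to_pet_time(al, mr$t_mr)
  expect_lt(abs(t_est[length(t_est)] - t_true[length(t_true)]), 0.25)
})

test_that("degenerate alignment inputs raise errors", {
  wf <- make_waveform(60, seed = 1)
  fr <- acquire_pet(fix$phantom, fix$proj, fix$truth, wf, duration = 60,
                    seed = 2)
  surr <- extract_surrogate(fr)
  mr_flat <- acquire_dynamic_mr(fix$phantom, NULL, NULL, duration = 9,
                                noise_sd = 0)
  expect_error(align_clocks(surr, mr_flat), "flat")
  # non-overlapping windows
  mr_far <- acquire_dynamic_mr(fix$phantom, fix$truth, wf, duration = 9,
                               start_time = 5000, seed = 3)
  expect_error(align_clocks(surr, mr_far), "overlap")
})
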