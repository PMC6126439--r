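test_that("motionless noiseless frames are identical and timing is exact", {
  fr <- acquire_pet(fix$phantom, fix$proj, NULL, NULL, duration = 10,
                    frame_dur = 0.5, noise = FALSE)
  expect_equal(ncol(fr$counts), 20)
  expect_true(all(fr$counts == fr$counts[, 1]))
  expect_equal(fr$t_start, seq(0, 9.5, by = 0.5))
  expect_error(acquire_pet(fix$phantom, fix$proj, duration = 10,
                           frame_dur = 0.7), "divide")
  expect_error(acquire_pet(fix$phantom, fix$proj, frame_dur = -1), "> 0")
})

test_that("a 240-s window at 0.5-s frames yields 480 frames", {
  wf <- make_waveform(240, seed = 1)
  fr <- acquire_pet(fix$phantom, fix$proj, fix$truth, wf, duration = 240,
                    noise = FALSE)
  expect_equal(ncol(fr$counts), 480L)
})

test_that("Poisson sampling conserves total counts within 3 sigma", {
  wf <- make_waveform(30, seed = 2)
  fr0 <- acquire_pet(fix$phantom, fix$proj, fix$truth, wf, duration = 30,
                     noise = FALSE)
  frn <- acquire_pet(fix$phantom, fix$proj, fix$truth, wf, duration = 30,
                     noise = TRUE, seed = 7)
  lambda <- sum(fr0$counts)
  expect_lt(abs(sum(frn$counts) - lambda), 3 * sqrt(lambda))
  expect_true(all(frn$counts == round(frn$counts)))
})

test_that("dynamic MR cycles 9 positions at 0.3 s per image", {
  wf <- make_waveform(240, seed = 1)
  mr <- acquire_dynamic_mr(fix$phantom, fix$truth, wf, seed = 3)
  expect_equal(dim(mr$images)[3], 200L)
  tab <- table(mr$position)
  expect_length(tab, 9L)
  expect_true(all(tab >= 22 - 1 & tab <= 22 + 1))
  expect_true(all(diff(mr$t_mr) > 0))
  expect_error(acquire_dynamic_mr(fix$phantom, clock_rate = 0), "rate")
})

test_that("motionless noiseless MR images are identical per position", {
  mr <- acquire_dynamic_mr(fix$phantom, NULL, NULL, duration = 9,
                           noise_sd = 0)
  for (p in unique(mr$position)) {
    idx <- which(mr$position == p)
    expect_true(all(mr$images[, , idx] == c(mr$images[, , idx[1]])))
  }
})

test_that("the diaphragm edge in noiseless MR oscillates with the waveform", {
  wf <- make_waveform(60, period_cv = 0, amp_cv = 0, seed = 1)
  mr <- acquire_dynamic_mr(full_fix$phantom, full_fix$truth, wf,
                           duration = 60, start_time = 0, noise_sd = 0)
  trace <- respimoco:::mr_diaphragm_trace(mr)
  expect_gt(abs(cor(trace, mr$hidden$s)), 0.95)
})

test_that("mu-map acquisition records its state; reference state is exact", {
  m0 <- acquire_mumap(fix$phantom, fix$truth, s = 0, s_dot = 0)
  expect_identical(m0$mu$values, fix$phantom$mu$values)
  expect_equal(unname(m0$state), c(0, 0))
  # diaphragm boundary shifts by about the configured excursion at s = 1
  m1 <- acquire_mumap(full_fix$phantom, full_fix$truth, s = 1)
  edge_row <- function(mu) {
    prof <- colMeans(mu$values)
    g <- abs(diff(prof))
    j <- 20 + which.max(g[21:70])
    j
  }
  shift_mm <- (edge_row(m1$mu) - edge_row(full_fix$phantom$mu)) * 3
  expect_gt(shift_mm, 12)   # peak 20 mm tapers off-axis; band average less
  expect_lt(shift_mm, 28)
  # states beyond the breathing range are allowed (deep inhale breath-hold)
  m13 <- acquire_mumap(full_fix$phantom, full_fix$truth, s = 1.3)
  expect_equal(unname(m13$state[1]), 1.3)
})
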