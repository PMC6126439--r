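#' Simulate a time-binned PET acquisition of the moving phantom
#'
#' Stand-in for list-mode data: the scan window is cut into short frames
#' (default 0.5 s, resolving 4-s breathing cycles); for each frame the
#' activity and mu maps are warped to the frame-midpoint respiratory state,
#' forward projected with attenuation, scaled by frame duration and the
#' calibration factor, a known uniform additive background (simulated randoms
#' plus scatter) is added, and Poisson noise is sampled if requested. The true
#' (s, s_dot) per frame is recorded as hidden truth for validation only.
#'
#' @param phantom a [build_phantom()] result.
#' @param proj a [make_projector()] on the phantom grid.
#' @param truth a [make_motion_truth()] generator, or `NULL` for a motionless
#'   acquisition.
#' @param waveform a [make_waveform()] result, or `NULL` for no breathing.
#' @param duration scan window, s (default 240 s: four consecutive minutes).
#' @param frame_dur frame duration, s; must divide the window.
#' @param noise Poisson-sample the frames?
#' @param background_frac expected background counts as a fraction of the
#'   reference-state true counts (default 0.10); the background is a known
#'   uniform sinogram passed to reconstruction as the additive term.
#' @param calib calibration factor, counts per (kBq/mL * mm) per second
#'   (default 0.3, giving roughly 2e7 counts over the 4-min window -- a
#'   desk-scale stand-in for clinical list-mode count levels).
#' @param seed RNG seed.
#' @return an object of class `frame_series`: counts matrix (LORs x frames),
#'   frame timing, calibration, background rate and hidden truth states.
#' @export
acquire_pet <- function(phantom, proj, truth = NULL, waveform = NULL,
                        duration = 240, frame_dur = 0.5, noise = TRUE,
                        background_frac = 0.10, calib = 0.3, seed = 1L) {
  if (frame_dur <= 0) stop("frame duration must be > 0")
  n_frames <- round(duration / frame_dur)
  if (abs(n_frames * frame_dur - duration) > 1e-9) {
    stop("frame duration must divide the scan window")
  }
  t_start <- (seq_len(n_frames) - 1) * frame_dur
  t_mid <- t_start + frame_dur / 2
  if (is.null(waveform) || is.null(truth)) {
    s <- rep(0, n_frames); s_dot <- rep(0, n_frames)
  } else {
    st <- waveform_state(waveform, t_mid)
    s <- st$s; s_dot <- st$s_dot
  }
  n_lor <- proj$n_bins * proj$n_angles
  moving <- !is.null(truth) && !(all(s == 0) && all(s_dot == 0))

  ref_sino <- as.numeric(project(phantom$activity, phantom$mu, proj))
  bg_rate <- background_frac * sum(ref_sino) * calib / n_lor  # counts/s/LOR

  expected <- matrix(0, n_lor, n_frames)
  if (!moving) {
    e1 <- calib * frame_dur * ref_sino + bg_rate * frame_dur
    expected[] <- e1
  } else {
    for (f in seq_len(n_frames)) {
      fld <- motion_at(truth, s[f], s_dot[f])
      act_f <- warp(phantom$activity, fld)
      mu_f <- warp(phantom$mu, fld)
      expected[, f] <- calib * frame_dur *
        as.numeric(project(act_f, mu_f, proj)) + bg_rate * frame_dur
    }
  }
  counts <- expected
  if (noise) {
    set.seed(as.integer(seed))
    counts <- matrix(stats::rpois(length(expected), expected),
                     n_lor, n_frames)
  }
  structure(list(counts = counts, t_start = t_start, frame_dur = frame_dur,
                 duration = duration, calib = calib, bg_rate = bg_rate,
                 noise = noise,
                 n_bins = proj$n_bins, n_angles = proj$n_angles,
                 hidden = data.frame(t_mid = t_mid, s = s, s_dot = s_dot)),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat("<frame_series> ", ncol(x$counts), " frames x ", x$frame_dur,
      " s, total counts ", format(sum(x$counts), big.mark = ","),
      if (x$noise) " (Poisson)" else " (noiseless)", "\n", sep = "")
  invisible(x)
}

#' Simulate the 1-min free-breathing dynamic MR acquisition
#'
#' 2D snapshots of the organ contrast map warped to the instantaneous
#' respiratory state, one image per 0.3 s, cycling 9 nominal sagittal slice
#' positions. In the 2D slab geometry every position views the same coronal
#' plane; the position index drives timing, grouping and per-position
#' reference selection exactly as a multi-slice acquisition would.
#' Timestamps are on the MR hardware clock: `t_mr = t_pet * clock_rate +
#' clock_offset`.
#'
#' @param phantom a [build_phantom()] result (its `mr` contrast map is
#'   imaged).
#' @param truth,waveform motion generator and breathing waveform (`NULL`
#'   disables motion).
#' @param duration MR acquisition length, s (default 60).
#' @param img_dur acquisition time per image, s (default 0.3).
#' @param n_positions number of cycled slice positions (default 9).
#' @param start_time PET-clock start of the MR window, s (default 180: the
#'   last minute of a 4-min PET window).
#' @param clock_rate MR clock rate relative to the PET clock.
#' @param clock_offset MR clock offset, s (the time shift the alignment step
#'   must recover).
#' @param noise_sd gaussian image noise, a.u.
#' @param seed RNG seed.
#' @return an object of class `dynamic_mr_series`.
#' @export
acquire_dynamic_mr <- function(phantom, truth = NULL, waveform = NULL,
                               duration = 60, img_dur = 0.3,
                               n_positions = 9L, start_time = 180,
                               clock_rate = 1 + 1e-5, clock_offset = 0,
                               noise_sd = 0.02, seed = 1L) {
  if (duration <= 0) stop("duration must be > 0")
  if (clock_rate <= 0) stop("clock rate factor must be > 0")
  n_img <- floor(duration / img_dur + 1e-9)
  position <- ((seq_len(n_img) - 1L) %% n_positions) + 1L
  t_pet <- start_time + (seq_len(n_img) - 1) * img_dur + img_dur / 2
  t_mr <- t_pet * clock_rate + clock_offset
  if (is.null(waveform) || is.null(truth)) {
    s <- rep(0, n_img); s_dot <- rep(0, n_img)
  } else {
    st <- waveform_state(waveform, t_pet)
    s <- st$s; s_dot <- st$s_dot
  }
  dims <- dim(phantom$mr$values)
  images <- array(0, c(dims, n_img))
  moving <- !is.null(truth) && !(all(s == 0) && all(s_dot == 0))
  base <- phantom$mr$values
  set.seed(as.integer(seed))
  for (i in seq_len(n_img)) {
    img <- if (moving) {
      warp(phantom$mr, motion_at(truth, s[i], s_dot[i]))$values
    } else base
    if (noise_sd > 0) img <- img + matrix(stats::rnorm(prod(dims), 0, noise_sd),
                                          dims[1], dims[2])
    images[, , i] <- img
  }
  structure(list(images = images, position = position, t_mr = t_mr,
                 img_dur = img_dur, n_positions = as.integer(n_positions),
                 spacing = phantom$mr$spacing,
                 hidden = data.frame(t_pet = t_pet, s = s, s_dot = s_dot,
                                     clock_rate = clock_rate,
                                     clock_offset = clock_offset)),
            class = "dynamic_mr_series")
}

#' Simulate the breath-hold mu-map acquisition
#'
#' The attenuation map is warped to the requested respiratory state and the
#' state is recorded with it, emulating a breath-hold Dixon acquisition that
#' may happen at any -- possibly extreme -- respiratory position (e.g. a deep
#' inhale or exhale well outside the free-breathing range).
#'
#' @param phantom a [build_phantom()] result.
#' @param truth a [make_motion_truth()] generator (`NULL` = no motion).
#' @param s,s_dot respiratory state of the acquisition (true surrogate
#'   units).
#' @return an object of class `mumap_acquisition`: the warped mu
#'   [voxel_volume()] plus the recorded state.
#' @export
acquire_mumap <- function(phantom, truth = NULL, s = 0, s_dot = 0) {
  if (!is.finite(s) || !is.finite(s_dot)) stop("state must be finite")
  mu <- if (is.null(truth) || (s == 0 && s_dot == 0)) phantom$mu
        else warp(phantom$mu, motion_at(truth, s, s_dot))
  structure(list(mu = mu, state = c(s = s, s_dot = s_dot)),
            class = "mumap_acquisition")
}
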