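#' Simulate a breathing surrogate waveform
#'
#' Cycle template is a raised-cosine power, s(t) = A_c sin^(2k)(pi t/T_c)
#' (for k = 1 this is the pure raised cosine (1 - cos(2 pi t/T))/2), which
#' gives the long end-exhale dwell typical of free breathing; s = 0 is the
#' reference end-exhale state and s = 1 the nominal end-inhale. Each cycle
#' draws its own amplitude and period (intercycle variability); an optional
#' linear baseline drift can be added.
#'
#' @param duration total simulated time, s.
#' @param period_mean mean breathing period, s (default 4 s).
#' @param period_cv coefficient of variation of the per-cycle period.
#' @param amp_mean mean per-cycle amplitude (surrogate units).
#' @param amp_cv coefficient of variation of the per-cycle amplitude
#'   (default 0.15).
#' @param k half the cosine power; larger k lengthens the end-exhale dwell.
#' @param drift baseline drift in surrogate units per minute (0 = off).
#' @param dt sampling interval of the stored waveform, s.
#' @param seed RNG seed.
#' @return an object of class `breathing_waveform`: a data.frame with columns
#'   `time`, `s`, `s_dot`, plus cycle draws in attributes.
#' @export
make_waveform <- function(duration = 240, period_mean = 4, period_cv = 0.10,
                          amp_mean = 1, amp_cv = 0.15, k = 2L,
                          drift = 0, dt = 0.05, seed = 1L) {
  if (!is.finite(duration) || duration <= 0) stop("duration must be > 0")
  if (!is.finite(period_mean) || period_mean <= 0) stop("period must be > 0")
  set.seed(as.integer(seed))
  # draw cycles until the window is covered
  t0 <- c(); periods <- c(); amps <- c()
  t <- 0
  while (t < duration) {
    Tc <- max(period_mean * 0.3, stats::rnorm(1, period_mean, period_cv * period_mean))
    Ac <- max(0, stats::rnorm(1, amp_mean, amp_cv * amp_mean))
    t0 <- c(t0, t); periods <- c(periods, Tc); amps <- c(amps, Ac)
    t <- t + Tc
  }
  times <- seq(0, duration, by = dt)
  cyc <- findInterval(times, t0)
  tau <- (times - t0[cyc]) / periods[cyc]            # cycle phase in [0,1)
  sn <- sin(pi * tau)
  s <- amps[cyc] * sn^(2L * k)
  s_dot <- amps[cyc] * 2L * k * sn^(2L * k - 1L) * cos(pi * tau) * pi / periods[cyc]
  if (drift != 0) {
    s <- s + drift * times / 60
    s_dot <- s_dot + drift / 60
  }
  wf <- data.frame(time = times, s = s, s_dot = s_dot)
  structure(wf, class = c("breathing_waveform", "data.frame"),
            period_mean = period_mean, k = k,
            cycles = data.frame(start = t0, period = periods, amplitude = amps),
            seed = as.integer(seed))
}

#' Evaluate a waveform at arbitrary times
#'
#' Linear interpolation of the stored samples; times outside the window clamp
#' to the ends.
#'
#' @param wf a [make_waveform()] result.
#' @param t times (s).
#' @return list with numeric vectors `s` and `s_dot`.
#' @export
waveform_state <- function(wf, t) {
  list(s = stats::approx(wf$time, wf$s, t, rule = 2)$y,
       s_dot = stats::approx(wf$time, wf$s_dot, t, rule = 2)$y)
}

# closed-form mean of the unit cycle template sin^(2k), by Wallis' formula
waveform_template_mean <- function(k) choose(2L * k, k) / 4^k
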