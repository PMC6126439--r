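#' Extract the PET-derived respiratory surrogate
#'
#' Per-frame scalar respiratory signal derived from the frame sinograms
#' alone, with no external hardware. Default method: score of the first
#' principal component of the mean-centered frame sinograms; alternative:
#' superior-inferior center of mass of counts. The sign is fixed so that the
#' surrogate correlates positively with the center-of-mass proxy, making the
#' convention deterministic across runs. The smoothed signal is min-max
#' normalized to [0, 1] over the series (per-window, not per-cycle) and the
#' gradient is taken by central differences of the normalized, smoothed
#' signal.
#'
#' @param frames a [acquire_pet()] frame series.
#' @param method "pca" (default) or "com".
#' @param smooth_window_s local-polynomial (Savitzky-Golay) smoothing window
#'   before differentiation, s.
#' @return an object of class `surrogate_series`: data.frame with `time`,
#'   `s`, `s_dot`; attribute `degenerate` flags a motionless series (then
#'   s is identically 0).
#' @export
extract_surrogate <- function(frames, method = c("pca", "com"),
                              smooth_window_s = 1.5) {
  method <- match.arg(method)
  X <- frames$counts
  n_f <- ncol(X)
  if (n_f < 2L) stop("need at least 2 frames")
  if (all(X == 0)) stop("all frames are zero: degenerate signal")
  t_mid <- frames$t_start + frames$frame_dur / 2
  # SI center-of-mass proxy: radial coordinate at the angle closest to 90
  # degrees projects onto the superior-inferior axis
  n_bins <- frames$n_bins; n_angles <- frames$n_angles
  angles <- (seq_len(n_angles) - 1) * pi / n_angles
  k90 <- which.min(abs(angles - pi / 2))
  rows90 <- (k90 - 1L) * n_bins + seq_len(n_bins)
  rcoord <- seq_len(n_bins) - (n_bins + 1) / 2
  sub <- X[rows90, , drop = FALSE]
  tot <- colSums(sub)
  com <- ifelse(tot > 0, colSums(sub * rcoord) / pmax(tot, 1e-12), 0)

  if (method == "pca") {
    keep <- rowMeans(X) > 0
    Xc <- X[keep, , drop = FALSE]
    Xc <- Xc - rowMeans(Xc)
    if (max(abs(Xc)) < 1e-12) {
      score <- rep(0, n_f)
    } else {
      G <- crossprod(Xc)
      ev <- eigen(G, symmetric = TRUE)
      score <- ev$vectors[, 1] * sqrt(max(ev$values[1], 0))
    }
  } else {
    score <- com
  }

  degenerate <- diff(range(score)) < 1e-9 * (max(abs(score)) + 1)
  if (degenerate) {
    s <- rep(0, n_f); s_dot <- rep(0, n_f)
  } else {
    if (stats::sd(com) > 0 && stats::cor(score, com) < 0) score <- -score
    dt <- frames$frame_dur
    win <- max(5L, round(smooth_window_s / dt))
    if (win %% 2L == 0L) win <- win + 1L
    win <- min(win, if (n_f %% 2L == 1L) n_f else n_f - 1L)
    sm <- if (win >= 5L) signal::sgolayfilt(score, p = 3, n = win) else score
    rng <- range(sm)
    if (diff(rng) < 1e-12) {
      s <- rep(0, n_f); s_dot <- rep(0, n_f); degenerate <- TRUE
    } else {
      s <- (sm - rng[1]) / diff(rng)
      s_dot <- central_diff(s, dt)
    }
  }
  out <- data.frame(time = t_mid, s = s, s_dot = s_dot)
  structure(out, class = c("surrogate_series", "data.frame"),
            method = method, degenerate = degenerate,
            smooth_window_s = smooth_window_s)
}

central_diff <- function(y, dt) {
  n <- length(y)
  d <- numeric(n)
  if (n >= 3L) d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (2 * dt)
  d[1] <- (y[2] - y[1]) / dt
  d[n] <- (y[n] - y[n - 1]) / dt
  d
}

# Diaphragm-edge trace: per image, subvoxel location of the strongest
# superior-inferior intensity edge of the lateral-mean profile.
mr_diaphragm_trace <- function(mr) {
  n <- dim(mr$images)[3]
  vapply(seq_len(n), function(i) {
    prof <- colMeans(mr$images[, , i])      # mean over lateral -> SI profile
    g <- abs(diff(prof))
    j <- which.max(g)
    lo <- max(1L, j - 2L); hi <- min(length(g), j + 2L)
    w <- g[lo:hi]
    sum((lo:hi) * w) / sum(w)               # gradient-centroid, subvoxel
  }, numeric(1))
}

#' Align the MR and PET clocks
#'
#' Estimates the time shift (and optionally the relative clock rate) mapping
#' MR timestamps to the PET clock, by maximizing the correlation between the
#' PET-derived surrogate (interpolated) and a 1D MR motion trace -- the
#' diaphragm edge position per image, standardized per slice position and
#' concatenated. Grid search with parabolic refinement.
#'
#' @param surrogate a [extract_surrogate()] series (PET clock).
#' @param mr a [acquire_dynamic_mr()] series.
#' @param tau_bound search bound for the shift, s (default +-10).
#' @param tau_step grid step, s (default 0.1).
#' @param estimate_rate co-estimate the clock-rate factor on a 2D grid?
#' @param rate_span half-width of the rate grid around 1 (default 2e-4).
#' @param trace_fun optional custom MR trace extractor, `function(mr)` ->
#'   numeric per image.
#' @return an object of class `clock_alignment` with elements `tau`, `rate`,
#'   `objective`.
#' @export
align_clocks <- function(surrogate, mr, tau_bound = 10, tau_step = 0.1,
                         estimate_rate = FALSE, rate_span = 2e-4,
                         trace_fun = NULL) {
  if (isTRUE(attr(surrogate, "degenerate"))) {
    stop("degenerate (flat) PET surrogate: cannot align clocks")
  }
  trace <- if (is.null(trace_fun)) mr_diaphragm_trace(mr) else trace_fun(mr)
  # standardize per slice position
  for (p in unique(mr$position)) {
    idx <- mr$position == p
    v <- trace[idx]
    if (stats::sd(v) < 1e-9) stop("flat MR motion trace: degenerate alignment")
    trace[idx] <- (v - mean(v)) / stats::sd(v)
  }
  taus <- seq(-tau_bound, tau_bound, by = tau_step)
  rates <- if (estimate_rate) 1 + seq(-rate_span, rate_span, by = rate_span / 10)
           else 1
  obj_at <- function(tau, rate) {
    t_pet <- (mr$t_mr - tau) / rate
    inside <- t_pet >= min(surrogate$time) & t_pet <= max(surrogate$time)
    if (mean(inside) < 0.5) return(NA_real_)
    sv <- stats::approx(surrogate$time, surrogate$s, t_pet, rule = 2)$y
    if (stats::sd(sv) < 1e-9) return(NA_real_)
    abs(stats::cor(sv, trace))
  }
  best <- c(tau = NA, rate = 1, obj = -Inf)
  objs_best <- NULL
  for (r in rates) {
    objs <- vapply(taus, obj_at, numeric(1), rate = r)
    if (all(is.na(objs))) next
    j <- which.max(objs)
    if (objs[j] > best["obj"]) {
      best <- c(tau = taus[j], rate = r, obj = objs[j])
      objs_best <- objs
    }
  }
  if (!is.finite(best["obj"])) {
    stop("MR and PET acquisition windows do not overlap")
  }
  # parabolic refinement of tau around the grid optimum
  j <- which(taus == best["tau"])
  tau_hat <- best[["tau"]]
  if (j > 1 && j < length(taus) &&
      !any(is.na(objs_best[(j - 1):(j + 1)]))) {
    y1 <- objs_best[j - 1]; y2 <- objs_best[j]; y3 <- objs_best[j + 1]
    denom <- y1 - 2 * y2 + y3
    if (abs(denom) > 1e-12) {
      delta <- 0.5 * (y1 - y3) / denom
      if (abs(delta) <= 1) tau_hat <- taus[j] + delta * tau_step
    }
  }
  structure(list(tau = tau_hat, rate = best[["rate"]],
                 objective = best[["obj"]],
                 grid = data.frame(tau = taus, objective = objs_best)),
            class = "clock_alignment")
}

#' Map MR timestamps onto the PET clock
#'
#' @param alignment a [align_clocks()] result.
#' @param t_mr MR-clock timestamps, s.
#' @return PET-clock times, s.
#' @export
mr_to_pet_time <- function(alignment, t_mr) {
  (t_mr - alignment$tau) / alignment$rate
}
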