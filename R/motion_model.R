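new_motion_model <- function(c0, c1, c2, spacing, ref_state, s_range,
                             diagnostics = list()) {
  structure(list(c0 = c0, c1 = c1, c2 = c2,
                 spacing = rep_len(as.numeric(spacing), 2L),
                 ref_state = ref_state, s_range = s_range,
                 diagnostics = diagnostics),
            class = "motion_model")
}

#' Fit the per-voxel two-surrogate linear motion model
#'
#' For every voxel and displacement component, regresses the registration
#' displacement on `(1, s, s_dot)`: `d = c0 + c1 s + c2 s_dot`. The fit is
#' robust to per-slice registration errors via iteratively reweighted least
#' squares with Huber weights (tuning constant 1.345 sigma, sigma from the
#' per-voxel MAD of residuals); images flagged as registration outliers are
#' excluded up front. A 1-surrogate variant (`surrogates = "s"`) drops the
#' gradient term for comparison.
#'
#' When `surrogate` and `alignment` are supplied (and the registration set
#' carries MR timestamps), the residual clock shift is co-optimized with the
#' model: a small grid of extra shifts around the alignment's tau is scanned
#' and the one minimizing the fit residual (on the highest-motion voxels) is
#' kept. A phase error between surrogate and anatomy masquerades as a
#' gradient term, so this joint refinement is what makes the hysteresis
#' coefficients identifiable.
#'
#' @param reg a [registration_set()].
#' @param robust "huber" (default) or "ols".
#' @param surrogates "s+sdot" (default, the 2-surrogate model) or "s".
#' @param huber_k Huber tuning constant in units of sigma.
#' @param max_iter maximum IRLS iterations.
#' @param surrogate,alignment optional [extract_surrogate()] series and
#'   [align_clocks()] result enabling time-shift refinement.
#' @param tau_refine_window,tau_refine_step grid half-width and step (s) for
#'   the refinement.
#' @return an object of class `motion_model` with per-voxel coefficient
#'   arrays `c0`, `c1`, `c2` (mm; `c2` is zero for the 1-surrogate model),
#'   an `r2` diagnostic array, the fit-reference state (modal end-exhale
#'   s, s_dot = 0) and the fitted surrogate range.
#' @export
fit_model <- function(reg, robust = c("huber", "ols"),
                      surrogates = c("s+sdot", "s"),
                      huber_k = 1.345, max_iter = 8L,
                      surrogate = NULL, alignment = NULL,
                      tau_refine_window = 0.4, tau_refine_step = 0.05) {
  robust <- match.arg(robust)
  surrogates <- match.arg(surrogates)
  use <- !reg$outlier & is.finite(reg$s) & is.finite(reg$s_dot)
  n <- sum(use)
  if (n < 6L) stop("need at least 6 usable images to fit the motion model")
  tau_extra <- 0
  if (!is.null(surrogate) && !is.null(alignment) && !is.null(reg$t_mr)) {
    # the scan uses the amplitude-only design: its residual has a single
    # sharp minimum at the true shift, whereas scanning with the gradient
    # term present lets the shift and the gradient coefficient trade off
    tau_extra <- refine_tau(reg, surrogate, alignment, use,
                            two = FALSE,
                            window = tau_refine_window,
                            step = tau_refine_step)
    t_pet <- (reg$t_mr - (alignment$tau + tau_extra)) / alignment$rate
    reg$s <- stats::approx(surrogate$time, surrogate$s, t_pet, rule = 2)$y
    reg$s_dot <- stats::approx(surrogate$time, surrogate$s_dot, t_pet,
                               rule = 2)$y
  }
  s <- reg$s[use]; s_dot <- reg$s_dot[use]
  if (stats::sd(s) < 1e-9) {
    stop("degenerate surrogate: s is (near-)constant over the images")
  }
  two <- surrogates == "s+sdot"
  if (two) {
    if (stats::sd(s_dot) < 1e-12 ||
        abs(stats::cor(s, s_dot)) > 0.9999) {
      stop("degenerate surrogate: s_dot is collinear with s; fit the ",
           "1-surrogate model instead")
    }
    X <- cbind(1, s, s_dot)
  } else {
    X <- cbind(1, s)
  }
  p <- ncol(X)
  dims <- dim(reg$fields)[1:2]
  nvox <- prod(dims)
  m <- nvox * 2L
  Y <- t(matrix(reg$fields[, , , use, drop = FALSE], nrow = m))  # n x m

  B <- solve(crossprod(X), crossprod(X, Y))                      # p x m, OLS
  W <- matrix(1, n, m)
  if (robust == "huber") {
    for (it in seq_len(max_iter)) {
      R <- Y - X %*% B
      sigma <- 1.4826 * col_medians(abs(R))
      live <- sigma > 1e-9
      if (!any(live)) break
      W[] <- 1
      aR <- abs(R[, live, drop = FALSE])
      W[, live] <- pmin(1, huber_k * rep(sigma[live], each = n) /
                             pmax(aR, 1e-12))
      Bnew <- weighted_lsfit(X, Y, W, B)
      if (max(abs(Bnew - B)) < 1e-10) { B <- Bnew; break }
      B <- Bnew
    }
  }
  R <- Y - X %*% B
  sst <- colSums(sweep(Y, 2, colMeans(Y))^2)
  r2 <- ifelse(sst > 1e-12, 1 - colSums(R^2) / sst, 1)

  # fit-reference state: modal end-exhale value of s, s_dot = 0
  dens <- stats::density(s, n = 128)
  s_ref <- dens$x[which.max(dens$y)]

  shape <- c(dims, 2L)
  c0 <- array(B[1, ], shape)
  c1 <- array(B[2, ], shape)
  c2 <- if (two) array(B[3, ], shape) else array(0, shape)
  new_motion_model(
    c0 = c0, c1 = c1, c2 = c2, spacing = reg$spacing,
    ref_state = c(s = s_ref, s_dot = 0), s_range = range(s),
    diagnostics = list(r2 = array(r2, shape), n_used = n, robust = robust,
                       surrogates = surrogates, tau_extra = tau_extra,
                       weight_sum = array(colSums(W), shape)))
}

# Column medians of a matrix via one global radix order (much faster than
# apply(M, 2, median) for wide matrices).
col_medians <- function(M) {
  n <- nrow(M); m <- ncol(M)
  S <- matrix(M[order(col(M), M)], n, m)
  if (n %% 2L == 1L) S[(n + 1L) %/% 2L, ]
  else (S[n %/% 2L, ] + S[n %/% 2L + 1L, ]) / 2
}

col_vars <- function(M) {
  n <- nrow(M)
  (colSums(M^2) - colSums(M)^2 / n) / (n - 1)
}

# Joint time-shift refinement: scan extra shifts around the alignment tau,
# fitting the linear model by OLS on the highest-motion voxels, and return
# the shift minimizing the total squared residual (parabolic-refined).
refine_tau <- function(reg, surrogate, alignment, use, two, window, step) {
  dims <- dim(reg$fields)[1:2]
  nvox <- prod(dims) * 2L
  Yall <- t(matrix(reg$fields[, , , use, drop = FALSE], nrow = nvox))
  v <- col_vars(Yall)
  top <- order(v, decreasing = TRUE)[seq_len(min(300L, nvox))]
  Y <- Yall[, top, drop = FALSE]
  t_mr <- reg$t_mr[use]
  deltas <- seq(-window, window, by = step)
  sse <- vapply(deltas, function(d) {
    t_pet <- (t_mr - (alignment$tau + d)) / alignment$rate
    s <- stats::approx(surrogate$time, surrogate$s, t_pet, rule = 2)$y
    sd <- stats::approx(surrogate$time, surrogate$s_dot, t_pet, rule = 2)$y
    X <- if (two) cbind(1, s, sd) else cbind(1, s)
    if (qr(X)$rank < ncol(X)) return(Inf)
    B <- solve(crossprod(X), crossprod(X, Y))
    sum((Y - X %*% B)^2)
  }, numeric(1))
  j <- which.min(sse)
  d <- deltas[j]
  if (j > 1 && j < length(deltas) && all(is.finite(sse[(j - 1):(j + 1)]))) {
    den <- sse[j - 1] - 2 * sse[j] + sse[j + 1]
    if (den > 1e-12) {
      off <- 0.5 * (sse[j - 1] - sse[j + 1]) / den
      if (abs(off) <= 1) d <- d + off * step
    }
  }
  d
}

# Per-column weighted least squares sharing one design matrix: solves the
# p x p normal equations voxelwise with explicit cofactor formulas.
weighted_lsfit <- function(X, Y, W, fallback) {
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  S <- vector("list", p * p)
  for (i in seq_len(p)) for (j in i:p) {
    S[[(i - 1) * p + j]] <- as.vector(crossprod(W, X[, i] * X[, j]))
  }
  V <- matrix(0, p, m)
  WY <- W * Y
  for (i in seq_len(p)) V[i, ] <- as.vector(crossprod(WY, X[, i]))
  B <- matrix(0, p, m)
  if (p == 2L) {
    a <- S[[1]]; b <- S[[2]]; d <- S[[4]]
    det <- a * d - b * b
    bad <- abs(det) < 1e-12
    det[bad] <- 1
    B[1, ] <- (d * V[1, ] - b * V[2, ]) / det
    B[2, ] <- (-b * V[1, ] + a * V[2, ]) / det
  } else {
    a <- S[[1]]; b <- S[[2]]; c <- S[[3]]
    d <- S[[5]]; e <- S[[6]]; f <- S[[9]]
    det <- a * (d * f - e * e) - b * (b * f - c * e) + c * (b * e - c * d)
    bad <- abs(det) < 1e-12
    det[bad] <- 1
    i11 <- d * f - e * e; i12 <- c * e - b * f; i13 <- b * e - c * d
    i22 <- a * f - c * c; i23 <- b * c - a * e
    i33 <- a * d - b * b
    B[1, ] <- (i11 * V[1, ] + i12 * V[2, ] + i13 * V[3, ]) / det
    B[2, ] <- (i12 * V[1, ] + i22 * V[2, ] + i23 * V[3, ]) / det
    B[3, ] <- (i13 * V[1, ] + i23 * V[2, ] + i33 * V[3, ]) / det
  }
  if (any(bad)) B[, bad] <- fallback[, bad]
  B
}

#' Predict a deformation field from the motion model
#'
#' `d = c0 + c1 s + c2 s_dot` per voxel; exactly linear in both surrogates.
#' Values outside the fitted surrogate range are permitted (the model
#' extrapolates, e.g. to a deep-inhale breath-hold) and flagged in the
#' result's `extrapolated` attribute.
#'
#' @param model a [fit_model()] or [truth_motion_model()] result.
#' @param s surrogate value.
#' @param s_dot surrogate gradient.
#' @return a [displacement_field()] (mm, pull-back convention).
#' @export
predict_field <- function(model, s, s_dot = 0) {
  if (!is.finite(s) || !is.finite(s_dot)) stop("s and s_dot must be finite")
  d <- model$c0 + model$c1 * s + model$c2 * s_dot
  fld <- displacement_field(d, model$spacing)
  attr(fld, "extrapolated") <-
    s < model$s_range[1] || s > model$s_range[2]
  fld
}

#' Mean prediction error of a motion model against ground truth
#'
#' RMS over voxels (within an optional mask) and states of the difference
#' between predicted and ground-truth displacement fields; used to compare
#' the 2-surrogate and 1-surrogate models under hysteresis.
#'
#' @param model a motion model.
#' @param truth a [make_motion_truth()] generator.
#' @param states data.frame with columns `s`, `s_dot` at which to evaluate.
#' @param mask optional logical matrix restricting the voxel set.
#' @return mean RMS prediction error, mm.
#' @export
model_prediction_error <- function(model, truth, states, mask = NULL) {
  errs <- vapply(seq_len(nrow(states)), function(i) {
    pred <- predict_field(model, states$s[i], states$s_dot[i])$d
    tru <- motion_at(truth, states$s[i], states$s_dot[i])$d
    e2 <- (pred - tru)^2
    e <- sqrt(e2[, , 1] + e2[, , 2])
    if (!is.null(mask)) mean(e[mask]) else mean(e)
  }, numeric(1))
  mean(errs)
}
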