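#' Pairwise deformable 2D registration (demons-style)
#'
#' Multi-resolution intensity-driven registration estimating the pull-back
#' field `d` such that `moving(x + d(x))` matches `fixed(x)`. Classic
#' additive demons forces with gaussian field regularization; no sliding
#' interface model. Identical images return an exactly zero field.
#'
#' @param fixed,moving 2D matrices (same size) or [voxel_volume()]s.
#' @param spacing voxel spacing, mm (taken from the volumes if given).
#' @param levels number of multi-resolution levels.
#' @param iters iterations per level, coarsest first.
#' @param field_sigma gaussian regularization of the field, voxels.
#' @return list with `field` (a [displacement_field()], mm) and `residual`
#'   (RMS intensity mismatch after warping, normalized by the fixed image
#'   spread).
#' @export
register_pair <- function(fixed, moving, spacing = c(1, 1), levels = 3L,
                          iters = c(60L, 40L, 20L), field_sigma = 1.5) {
  if (inherits(fixed, "voxel_volume")) { spacing <- fixed$spacing; fixed <- fixed$values }
  if (inherits(moving, "voxel_volume")) moving <- moving$values
  if (!identical(dim(fixed), dim(moving))) stop("image sizes differ")
  spacing <- rep_len(as.numeric(spacing), 2L)
  iters <- rep_len(as.integer(iters), levels)

  pyr_f <- list(fixed); pyr_m <- list(moving); pyr_sp <- list(spacing)
  for (l in seq_len(levels - 1L)) {
    pyr_f[[l + 1L]] <- downsample2(pyr_f[[l]])
    pyr_m[[l + 1L]] <- downsample2(pyr_m[[l]])
    pyr_sp[[l + 1L]] <- pyr_sp[[l]] * 2
  }
  d <- NULL  # field in mm
  for (l in rev(seq_len(levels))) {
    F <- pyr_f[[l]]; M <- pyr_m[[l]]; sp <- pyr_sp[[l]]
    dims <- dim(F)
    if (is.null(d)) {
      d <- array(0, c(dims, 2L))
    } else {
      d <- upsample_field(d, dims)
    }
    ms <- mean(sp)
    for (it in seq_len(iters[l])) {
      fld <- displacement_field(d, sp)
      Mw <- if (all(d == 0)) M else {
        warp(voxel_volume(M, sp, semantics = "mr"), fld)$values
      }
      diffI <- F - Mw
      if (max(abs(diffI)) == 0) break
      gx <- grad_central(Mw, 1L) / sp[1]
      gy <- grad_central(Mw, 2L) / sp[2]
      den <- gx^2 + gy^2 + (diffI / ms)^2
      den[den < 1e-12] <- Inf
      ux <- diffI * gx / den
      uy <- diffI * gy / den
      d[, , 1] <- gaussian_smooth(d[, , 1] + ux, field_sigma)
      d[, , 2] <- gaussian_smooth(d[, , 2] + uy, field_sigma)
    }
  }
  fld <- displacement_field(d, spacing)
  Mw <- warp(voxel_volume(moving, spacing, semantics = "mr"), fld)$values
  res <- sqrt(mean((fixed - Mw)^2)) / max(stats::sd(fixed), 1e-12)
  list(field = fld, residual = res)
}

grad_central <- function(x, k) {
  dims <- dim(x)
  g <- array(0, dims)
  if (k == 1L) {
    n <- dims[1]
    g[2:(n - 1), ] <- (x[3:n, ] - x[1:(n - 2), ]) / 2
    g[1, ] <- x[2, ] - x[1, ]; g[n, ] <- x[n, ] - x[n - 1, ]
  } else {
    n <- dims[2]
    g[, 2:(n - 1)] <- (x[, 3:n] - x[, 1:(n - 2)]) / 2
    g[, 1] <- x[, 2] - x[, 1]; g[, n] <- x[, n] - x[, n - 1]
  }
  g
}

downsample2 <- function(x) {
  dims <- dim(x)
  nx <- dims[1] %/% 2L; ny <- dims[2] %/% 2L
  x <- x[seq_len(2L * nx), seq_len(2L * ny)]
  0.25 * (x[seq(1, 2 * nx, 2), seq(1, 2 * ny, 2)] +
          x[seq(2, 2 * nx, 2), seq(1, 2 * ny, 2)] +
          x[seq(1, 2 * nx, 2), seq(2, 2 * ny, 2)] +
          x[seq(2, 2 * nx, 2), seq(2, 2 * ny, 2)])
}

upsample_field <- function(d, dims) {
  src <- dim(d)[1:2]
  out <- array(0, c(dims, 2L))
  coords <- grid_index_coords(dims)
  scale <- (src - 1) / pmax(dims - 1, 1)
  cc <- sweep(coords, 2, scale, `*`)
  for (k in 1:2) {
    out[, , k] <- array(interp_linear(d[, , k], cc, fill = 0), dims)
  }
  out
}

#' Register all dynamic MR images to per-position references
#'
#' For each slice position the reference image is the one whose aligned
#' surrogate value is closest to the end-exhale mode (the mode of the
#' surrogate histogram, preferring small |s_dot|); every image of that
#' position is then deformably registered to it. Images whose registration
#' residual is far above the per-position typical value are flagged as
#' outliers (they stay in the set but are excluded from the model fit).
#'
#' @param mr a [acquire_dynamic_mr()] series.
#' @param surrogate optional [extract_surrogate()] series used for reference
#'   selection and for attaching (s, s_dot) to each image.
#' @param alignment optional [align_clocks()] result mapping MR timestamps to
#'   the PET clock (required if `surrogate` is given).
#' @param reference "end-exhale" (default, needs surrogate) or "first".
#' @param outlier_k outlier threshold in robust standard deviations of the
#'   per-position residuals.
#' @param ... passed to [register_pair()].
#' @return an object of class `registration_set`.
#' @export
register_slices <- function(mr, surrogate = NULL, alignment = NULL,
                            reference = c("end-exhale", "first"),
                            outlier_k = 5, ...) {
  reference <- match.arg(reference)
  n <- dim(mr$images)[3]
  dims <- dim(mr$images)[1:2]
  s <- rep(NA_real_, n); s_dot <- rep(NA_real_, n)
  if (!is.null(surrogate)) {
    if (is.null(alignment)) stop("alignment required when surrogate is given")
    t_pet <- mr_to_pet_time(alignment, mr$t_mr)
    s <- stats::approx(surrogate$time, surrogate$s, t_pet, rule = 2)$y
    s_dot <- stats::approx(surrogate$time, surrogate$s_dot, t_pet, rule = 2)$y
  } else if (reference == "end-exhale") {
    reference <- "first"
  }
  ref_idx <- integer(0)
  fields <- array(0, c(dims, 2L, n))
  residual <- numeric(n)
  if (reference == "end-exhale") {
    h <- stats::density(s, n = 128)
    s_mode <- h$x[which.max(h$y)]
  }
  for (p in unique(mr$position)) {
    idx <- which(mr$position == p)
    if (length(idx) < 2L) stop("need >= 2 images per slice position")
    r <- if (reference == "end-exhale") {
      cost <- abs(s[idx] - s_mode) + 0.1 * abs(s_dot[idx])
      idx[which.min(cost)]
    } else idx[1]
    ref_idx <- c(ref_idx, r)
    refimg <- mr$images[, , r]
    for (i in idx) {
      if (i == r) { residual[i] <- 0; next }  # reference maps to itself
      rr <- register_pair(mr$images[, , i], refimg, spacing = mr$spacing, ...)
      fields[, , , i] <- rr$field$d
      residual[i] <- rr$residual
    }
  }
  outlier <- rep(FALSE, n)
  for (p in unique(mr$position)) {
    idx <- which(mr$position == p)
    res_p <- residual[idx]
    nonref <- res_p[res_p > 0]
    if (length(nonref) >= 3L) {
      thr <- stats::median(nonref) + outlier_k * stats::mad(nonref) + 1e-9
      outlier[idx] <- res_p > max(thr, 1e-9)
    }
  }
  registration_set(fields, s, s_dot, spacing = mr$spacing,
                   residual = residual, outlier = outlier,
                   position = mr$position, ref_idx = ref_idx,
                   t_mr = mr$t_mr)
}

#' Construct a registration set
#'
#' Container for per-image displacement fields with their surrogate states;
#' produced by [register_slices()] and constructible directly for synthetic
#' fitting experiments.
#'
#' @param fields array `[nx, ny, 2, n_images]` of pull-back displacements, mm.
#' @param s,s_dot surrogate state per image.
#' @param spacing voxel spacing, mm.
#' @param residual,outlier,position,ref_idx,t_mr optional per-image metadata
#'   (`t_mr` enables time-shift refinement in [fit_model()]).
#' @return an object of class `registration_set`.
#' @export
registration_set <- function(fields, s, s_dot, spacing,
                             residual = NULL, outlier = NULL,
                             position = NULL, ref_idx = NULL, t_mr = NULL) {
  n <- dim(fields)[4]
  stopifnot(length(s) == n, length(s_dot) == n)
  if (is.null(residual)) residual <- rep(0, n)
  if (is.null(outlier)) outlier <- rep(FALSE, n)
  if (is.null(position)) position <- rep(1L, n)
  structure(list(fields = fields, s = s, s_dot = s_dot,
                 spacing = rep_len(as.numeric(spacing), 2L),
                 residual = residual, outlier = outlier,
                 position = position, ref_idx = ref_idx, t_mr = t_mr),
            class = "registration_set")
}
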