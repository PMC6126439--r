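#' Phantom specification
#'
#' Parametric 2D coronal thorax slab: body outline, two lungs, liver, plus a
#' configurable list of spherical lesions. Organ activities are FDG-like
#' concentrations (kBq/mL) and attenuation coefficients are 511-keV values
#' (1/cm). Geometry is index-based: world = origin + 0-based index * spacing.
#'
#' @param dim grid size in voxels (2 values).
#' @param spacing voxel spacing, mm.
#' @param activities named activity concentrations (kBq/mL) for
#'   `soft`, `lung`, `liver`.
#' @param mu named linear attenuation coefficients (1/cm) for the same organs.
#' @param mr_intensity named MR contrast values (a.u.) per organ, used by the
#'   dynamic-MR simulator.
#' @param lesions list of lesions, each `list(center = c(x, y) mm,
#'   diameter = mm, activity = kBq/mL)`.
#' @param weight_kg,dose_MBq patient weight and injected dose for SUV
#'   calibration.
#' @param seed RNG seed associated with the phantom.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(96L, 96L), spacing = 3,
                         activities = c(soft = 1.0, lung = 0.3, liver = 2.0),
                         mu = c(soft = 0.096, lung = 0.03, liver = 0.096),
                         mr_intensity = c(soft = 0.55, lung = 0.15,
                                          liver = 0.85, lesion = 1.0),
                         lesions = list(list(center = c(181, 144),
                                             diameter = 10, activity = 8.0)),
                         weight_kg = 70, dose_MBq = 350, seed = 1L) {
  dim <- as.integer(rep_len(dim, 2L))
  spacing <- rep_len(as.numeric(spacing), 2L)
  if (any(spacing <= 0)) stop("voxel spacing must be > 0")
  for (les in lesions) {
    if (les$diameter <= 0) stop("lesion diameter must be > 0")
    if (les$activity < 0) stop("activities must be >= 0")
  }
  if (any(activities < 0) || any(mu < 0)) stop("activities and mu must be >= 0")
  structure(list(dim = dim, spacing = spacing, activities = activities,
                 mu = mu, mr_intensity = mr_intensity, lesions = lesions,
                 weight_kg = weight_kg, dose_MBq = dose_MBq,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# organ label codes
PH_AIR <- 0L; PH_SOFT <- 1L; PH_LUNG <- 2L; PH_LIVER <- 3L; PH_LESION_BASE <- 10L

# ellipse mask helper; center/semi in mm (world), grid given by dims/spacing
ellipse_mask <- function(dims, spacing, center, semi) {
  x <- (seq_len(dims[1]) - 1) * spacing[1]
  y <- (seq_len(dims[2]) - 1) * spacing[2]
  xg <- matrix(x, dims[1], dims[2])
  yg <- matrix(y, dims[1], dims[2], byrow = TRUE)
  ((xg - center[1]) / semi[1])^2 + ((yg - center[2]) / semi[2])^2 <= 1
}

# canonical organ layout, in fractions of the field of view
phantom_layout <- function(spec) {
  fov <- spec$dim * spec$spacing
  list(
    body    = list(center = c(0.50, 0.52) * fov, semi = c(0.40, 0.44) * fov),
    lung_l  = list(center = c(0.35, 0.30) * fov, semi = c(0.115, 0.160) * fov),
    lung_r  = list(center = c(0.65, 0.29) * fov, semi = c(0.125, 0.175) * fov),
    liver   = list(center = c(0.63, 0.56) * fov, semi = c(0.170, 0.115) * fov),
    diaphragm_y = 0.465 * fov[2],
    apex_y      = 0.115 * fov[2],
    body_bottom_y = (0.52 + 0.44) * fov[2],
    body_x      = c(0.10, 0.90) * fov[1]
  )
}

#' Build the digital thorax phantom
#'
#' @param spec a [phantom_spec()].
#' @return a list of class `phantom` with elements `activity` and `mu`
#'   ([voxel_volume()]s on the same grid), `labels` (integer organ map:
#'   0 air, 1 soft tissue, 2 lung, 3 liver, 10+i lesion i), `lesion_masks`
#'   (list of logical matrices), `mr` (MR contrast map) and `spec`.
#' @export
build_phantom <- function(spec) {
  dims <- spec$dim; sp <- spec$spacing
  lay <- phantom_layout(spec)
  labels <- matrix(PH_AIR, dims[1], dims[2])
  body <- ellipse_mask(dims, sp, lay$body$center, lay$body$semi)
  labels[body] <- PH_SOFT
  labels[ellipse_mask(dims, sp, lay$lung_l$center, lay$lung_l$semi) & body] <- PH_LUNG
  labels[ellipse_mask(dims, sp, lay$lung_r$center, lay$lung_r$semi) & body] <- PH_LUNG
  labels[ellipse_mask(dims, sp, lay$liver$center, lay$liver$semi) & body] <- PH_LIVER

  act <- c(0, spec$activities[c("soft", "lung", "liver")])[labels + 1L]
  muv <- c(0, spec$mu[c("soft", "lung", "liver")])[labels + 1L]
  mrv <- c(0, spec$mr_intensity[c("soft", "lung", "liver")])[labels + 1L]
  act <- matrix(act, dims[1], dims[2])
  muv <- matrix(muv, dims[1], dims[2])
  mrv <- matrix(mrv, dims[1], dims[2])

  lesion_masks <- list()
  for (i in seq_along(spec$lesions)) {
    les <- spec$lesions[[i]]
    m <- ellipse_mask(dims, sp, les$center, rep(les$diameter / 2, 2))
    if (!all(body[m])) {
      stop(sprintf("lesion %d extends outside the body", i))
    }
    labels[m] <- PH_LESION_BASE + i
    act[m] <- les$activity
    muv[m] <- spec$mu["soft"]  # lesions attenuate like soft tissue
    mrv[m] <- spec$mr_intensity["lesion"]
    lesion_masks[[i]] <- m
  }

  structure(list(
    activity = voxel_volume(act, sp, semantics = "activity"),
    mu = voxel_volume(muv, sp, semantics = "mu"),
    mr = voxel_volume(mrv, sp, semantics = "mr"),
    labels = labels, lesion_masks = lesion_masks, spec = spec
  ), class = "phantom")
}

#' Ground-truth respiratory deformation generator
#'
#' Per-voxel linear generator `d(x; s, s_dot) = g1(x) s + g2(x) s_dot`
#' (+ optional quadratic-in-s mismatch term), zero at the reference state.
#' Displacement is superior-inferior, scaled by a smooth spatial envelope that
#' peaks (value 1) at the diaphragm on the body midline, falls to zero at the
#' lung apices and the inferior body edge, and tapers laterally to zero at the
#' body outline. The `hysteresis_mm` term (g2, driven by the surrogate
#' gradient) makes inhalation and exhalation follow different paths at equal
#' amplitude; it carries its own, more localized envelope (a 25-mm gaussian
#' band around the diaphragm), since a hysteresis pattern exactly
#' proportional to the amplitude pattern would be indistinguishable from a
#' global time shift of the surrogate.
#'
#' @param phantom a [build_phantom()] result.
#' @param excursion_mm peak superior-inferior displacement at the diaphragm
#'   for s = 1 (default 20 mm, the average diaphragm excursion).
#' @param hysteresis_mm peak displacement per unit surrogate gradient (mm.s).
#' @param mismatch if `TRUE`, add a quadratic-in-s term (peak
#'   `mismatch_mm`) so the generator is no longer of the model's linear form.
#' @param mismatch_mm amplitude of the quadratic mismatch term.
#' @return an object of class `motion_truth`.
#' @export
make_motion_truth <- function(phantom, excursion_mm = 20, hysteresis_mm = 3,
                              mismatch = FALSE, mismatch_mm = 3) {
  spec <- phantom$spec
  dims <- spec$dim; sp <- spec$spacing
  lay <- phantom_layout(spec)
  y <- (seq_len(dims[2]) - 1) * sp[2]
  x <- (seq_len(dims[1]) - 1) * sp[1]
  ya <- lay$apex_y; yd <- lay$diaphragm_y; yb <- lay$body_bottom_y
  fy <- numeric(dims[2])
  up <- y >= ya & y <= yd
  fy[up] <- 0.5 - 0.5 * cos(pi * (y[up] - ya) / (yd - ya))
  dn <- y > yd & y <= yb
  fy[dn] <- 0.5 + 0.5 * cos(pi * (y[dn] - yd) / (yb - yd))
  gx <- numeric(dims[1])
  inx <- x >= lay$body_x[1] & x <= lay$body_x[2]
  gx[inx] <- sin(pi * (x[inx] - lay$body_x[1]) / diff(lay$body_x))
  env <- outer(gx, fy)
  env <- env / max(env)
  # hysteresis has its own, more localized spatial pattern (a band around
  # the diaphragm): tissues do not lag uniformly, so the gradient term is
  # not a rescaled copy of the amplitude term (which would make it
  # indistinguishable from a clock shift)
  fy2 <- exp(-0.5 * ((y - yd) / 25)^2)
  env_h <- outer(gx, fy2)
  env_h <- env_h / max(env_h)
  structure(list(envelope = env, envelope_h = env_h,
                 excursion_mm = excursion_mm,
                 hysteresis_mm = hysteresis_mm,
                 mismatch = isTRUE(mismatch), mismatch_mm = mismatch_mm,
                 spacing = sp, dim = dims),
            class = "motion_truth")
}

#' Evaluate the ground-truth deformation at a respiratory state
#'
#' @param truth a [make_motion_truth()] generator.
#' @param s surrogate amplitude (0 = reference end-exhale).
#' @param s_dot surrogate gradient (1/s).
#' @return a [displacement_field()] in mm (pull-back convention).
#' @export
motion_at <- function(truth, s, s_dot = 0) {
  if (!is.finite(s) || !is.finite(s_dot)) stop("s and s_dot must be finite")
  dy <- -truth$excursion_mm * s * truth$envelope -
    truth$hysteresis_mm * s_dot * truth$envelope_h
  if (truth$mismatch) dy <- dy - truth$mismatch_mm * s^2 * truth$envelope
  d <- array(0, c(truth$dim, 2L))
  d[, , 2] <- dy
  displacement_field(d, truth$spacing)
}

#' Ground-truth motion factor at a world position
#'
#' The spatial envelope of the generator, interpolated at a position (mm).
#' A lesion's true displacement amplitude is `excursion_mm * motion_factor`.
#'
#' @param truth a [make_motion_truth()] generator.
#' @param center_mm world position, mm.
#' @return scalar in `[0, 1]`.
#' @export
motion_factor <- function(truth, center_mm) {
  coords <- matrix(center_mm / truth$spacing, nrow = 1)
  interp_linear(truth$envelope, coords, fill = 0)
}

#' Diaphragm band region of interest
#'
#' A band across the diaphragm (default +-12 mm around the lung/liver
#' boundary, laterally restricted to the right-lung/liver sector), inside
#' the body. This is where emission/attenuation mismatch from a misaligned
#' breath-hold mu-map produces the curved intensity ("banana") artifact, and
#' it is the region over which artifact bias is quantified.
#'
#' @param phantom a [build_phantom()] result.
#' @param half_width_mm half-width of the band, mm.
#' @return logical mask on the phantom grid.
#' @export
diaphragm_band_roi <- function(phantom, half_width_mm = 12) {
  spec <- phantom$spec
  lay <- phantom_layout(spec)
  dims <- spec$dim; sp <- spec$spacing
  y <- (seq_len(dims[2]) - 1) * sp[2]
  x <- (seq_len(dims[1]) - 1) * sp[1]
  fov <- dims * sp
  band_y <- abs(y - lay$diaphragm_y) <= half_width_mm
  band_x <- x >= 0.47 * fov[1] & x <= 0.80 * fov[1]
  outer(band_x, band_y) & phantom$labels > 0
}

#' Wrap the ground-truth generator as a fitted-form motion model
#'
#' Returns the generator's own linear coefficients in the container used by
#' [predict_field()], for experiments that bypass model fitting (the mismatch
#' term, if enabled, is not representable and is dropped with a warning).
#'
#' @param truth a [make_motion_truth()] generator.
#' @return a `motion_model` object with c0 = 0, c1, c2 from the generator.
#' @export
truth_motion_model <- function(truth) {
  if (truth$mismatch) {
    warning("mismatch term is not representable by the linear model; dropped")
  }
  dims <- truth$dim
  zero <- array(0, c(dims, 2L))
  c1 <- array(0, c(dims, 2L)); c2 <- array(0, c(dims, 2L))
  c1[, , 2] <- -truth$excursion_mm * truth$envelope
  c2[, , 2] <- -truth$hysteresis_mm * truth$envelope_h
  new_motion_model(c0 = zero, c1 = c1, c2 = c2, spacing = truth$spacing,
                   ref_state = c(s = 0, s_dot = 0), s_range = c(0, 1),
                   diagnostics = list(source = "ground-truth generator"))
}
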