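#' Convert an activity image to standardized uptake values
#'
#' SUV = concentration (kBq/mL) * weight (kg) / dose (MBq); dimensionless
#' under the 1 g/mL tissue-density convention (the kBq->MBq and kg->g factors
#' cancel).
#'
#' @param x a `recon_image` or activity [voxel_volume()].
#' @param weight_kg patient weight, kg.
#' @param dose_MBq injected dose, MBq.
#' @return an SUV [voxel_volume()].
#' @export
suv_scale <- function(x, weight_kg, dose_MBq) {
  if (inherits(x, "recon_image")) x <- x$volume
  if (!inherits(x, "voxel_volume")) stop("x must be a recon_image or voxel_volume")
  if (is.null(weight_kg) || is.null(dose_MBq) ||
      !is.finite(weight_kg) || !is.finite(dose_MBq) ||
      weight_kg <= 0 || dose_MBq <= 0) {
    stop("SUV calibration requires weight > 0 kg and dose > 0 MBq")
  }
  vv_like(x, x$values * weight_kg / dose_MBq, semantics = "suv")
}

# Voxel offsets (index units) whose centers lie within radius_mm of a sphere
# center, for a 2D (disk) or 3D grid.
sphere_offsets <- function(radius_mm, spacing) {
  nd <- length(spacing)
  rng <- lapply(seq_len(nd), function(k) {
    r <- floor(radius_mm / spacing[k])
    (-r):r
  })
  g <- as.matrix(do.call(expand.grid, rng))
  d2 <- rowSums(sweep(g, 2, spacing, `*`)^2)
  g[d2 <= radius_mm^2 + 1e-9, , drop = FALSE]
}

#' SUV peak within a lesion ROI
#'
#' Maximum, over sphere centers inside the ROI, of the mean SUV within a
#' 12-mm-diameter sphere centered there. The sphere may extend outside the
#' ROI; its voxel set is discretized by voxel-center inclusion (centers
#' within 6 mm), and clipped to the grid at the edges. In 2D the "sphere" is
#' the corresponding disk.
#'
#' @param suv an SUV (or activity) [voxel_volume()].
#' @param roi logical mask of the same dimension (the candidate centers).
#' @param sphere_diameter_mm averaging sphere diameter, mm (default 12).
#' @return maximum sphere-mean SUV (scalar).
#' @export
suv_peak <- function(suv, roi, sphere_diameter_mm = 12) {
  dims <- dim(suv$values)
  if (!identical(dim(roi), dims)) stop("ROI and volume grids differ")
  if (!any(roi)) stop("ROI is empty")
  offs <- sphere_offsets(sphere_diameter_mm / 2, suv$spacing)
  if (any(2 * floor(sphere_diameter_mm / 2 / suv$spacing) + 1 > dims)) {
    stop("averaging sphere is larger than the grid")
  }
  nd <- length(dims)
  sum_img <- array(0, dims)
  cnt_img <- array(0, dims)
  idx_all <- grid_index_coords(dims)  # 0-based
  for (oi in seq_len(nrow(offs))) {
    src <- sweep(idx_all, 2, offs[oi, ], `+`)
    inside <- rep(TRUE, nrow(src))
    for (k in seq_len(nd)) inside <- inside & src[, k] >= 0 & src[, k] <= dims[k] - 1
    lin <- rep(1, nrow(src)); mult <- 1
    for (k in seq_len(nd)) { lin <- lin + src[, k] * mult; mult <- mult * dims[k] }
    v <- numeric(nrow(src))
    v[inside] <- suv$values[lin[inside]]
    sum_img <- sum_img + array(v, dims)
    cnt_img <- cnt_img + array(as.numeric(inside), dims)
  }
  mean_img <- sum_img / cnt_img
  max(mean_img[roi])
}

#' SUV max within a lesion ROI
#'
#' @param suv an SUV (or activity) [voxel_volume()].
#' @param roi logical mask.
#' @return maximum voxel value inside the ROI.
#' @export
suv_max <- function(suv, roi) {
  if (!identical(dim(roi), dim(suv$values))) stop("ROI and volume grids differ")
  if (!any(roi)) stop("ROI is empty")
  max(suv$values[roi])
}

#' Per-lesion SUV report
#'
#' @param suv an SUV [voxel_volume()].
#' @param rois named list of logical lesion masks.
#' @param sphere_diameter_mm see [suv_peak()].
#' @return data.frame with columns `lesion`, `suv_peak`, `suv_max`.
#' @export
suv_report <- function(suv, rois, sphere_diameter_mm = 12) {
  if (is.null(names(rois))) names(rois) <- paste0("lesion", seq_along(rois))
  do.call(rbind, lapply(names(rois), function(nm) {
    data.frame(lesion = nm,
               suv_peak = suv_peak(suv, rois[[nm]], sphere_diameter_mm),
               suv_max = suv_max(suv, rois[[nm]]))
  }))
}

#' Percent SUV change between uncorrected and motion-corrected images
#'
#' Delta% = (MC - U) / U * 100 per metric, with the uncorrected value as
#' denominator. A change is "considerable" when it exceeds 5% in magnitude
#' for *both* SUV_peak and SUV_max. Undefined (NA, flagged) when the
#' uncorrected value is 0.
#'
#' @param u,mc [suv_report()] data.frames for the uncorrected and
#'   motion-corrected images.
#' @param considerable_pct threshold for a considerable change (default 5).
#' @return merged data.frame with `dsuv_peak_pct`, `dsuv_max_pct`,
#'   `considerable` and `undefined` columns.
#' @export
delta_suv <- function(u, mc, considerable_pct = 5) {
  d <- merge(u, mc, by = "lesion", suffixes = c("_u", "_mc"))
  und <- d$suv_peak_u <= 0 | d$suv_max_u <= 0
  d$dsuv_peak_pct <- ifelse(und, NA_real_,
                            (d$suv_peak_mc - d$suv_peak_u) / d$suv_peak_u * 100)
  d$dsuv_max_pct <- ifelse(und, NA_real_,
                           (d$suv_max_mc - d$suv_max_u) / d$suv_max_u * 100)
  inc <- !und & d$dsuv_peak_pct > considerable_pct &
    d$dsuv_max_pct > considerable_pct
  dec <- !und & d$dsuv_peak_pct < -considerable_pct &
    d$dsuv_max_pct < -considerable_pct
  d$considerable <- inc | dec
  d$direction <- ifelse(inc, "increase", ifelse(dec, "decrease", "none"))
  d$undefined <- und
  d
}
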