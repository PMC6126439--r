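#' Parallel-beam PET projector
#'
#' Builds the sparse system matrix of an ideal 2D parallel-beam tomograph:
#' pixel-driven line integrals with linear interpolation between radial bins,
#' in mm units (a uniform object of value a and chord length L projects to
#' a*L). The matrix transpose is the exact adjoint (backprojector), which is
#' what the EM updates require.
#'
#' @param dims image grid size (2 values).
#' @param spacing voxel spacing, mm.
#' @param n_angles number of projection angles over 180 degrees (default 84,
#'   divisible by 21 subsets).
#' @param n_bins number of radial bins; defaults to cover the full grid
#'   diagonal so no counts are lost.
#' @param bin_width radial bin width, mm (defaults to the voxel spacing).
#' @param psf_fwhm_mm optional in-plane detector resolution model: a gaussian
#'   of this FWHM applied along the radial direction of each projection
#'   (0 = ideal detector).
#' @return an object of class `pet_projector`.
#' @export
make_projector <- function(dims, spacing, n_angles = 84L, n_bins = NULL,
                           bin_width = NULL, psf_fwhm_mm = 0) {
  dims <- as.integer(rep_len(dims, 2L))
  spacing <- rep_len(as.numeric(spacing), 2L)
  if (is.null(bin_width)) bin_width <- min(spacing)
  if (is.null(n_bins)) {
    fov_diag <- sqrt(sum((dims * spacing)^2))
    n_bins <- as.integer(ceiling(fov_diag / bin_width)) + 3L
  }
  angles <- (seq_len(n_angles) - 1) * pi / n_angles
  cx <- (dims[1] - 1) / 2 * spacing[1]
  cy <- (dims[2] - 1) / 2 * spacing[2]
  xs <- (seq_len(dims[1]) - 1) * spacing[1] - cx
  ys <- (seq_len(dims[2]) - 1) * spacing[2] - cy
  xg <- as.vector(matrix(xs, dims[1], dims[2]))
  yg <- as.vector(matrix(ys, dims[1], dims[2], byrow = TRUE))
  nvox <- prod(dims)
  area_w <- prod(spacing) / bin_width
  rows <- vector("list", n_angles); cols <- vector("list", n_angles)
  vals <- vector("list", n_angles)
  ctr <- (n_bins + 1) / 2
  for (k in seq_len(n_angles)) {
    r <- xg * cos(angles[k]) + yg * sin(angles[k])
    b <- r / bin_width + ctr           # continuous 1-based bin coordinate
    b0 <- floor(b)
    fb <- b - b0
    base <- (k - 1L) * n_bins
    ok0 <- b0 >= 1 & b0 <= n_bins
    ok1 <- (b0 + 1) >= 1 & (b0 + 1) <= n_bins
    rows[[k]] <- c(base + b0[ok0], base + b0[ok1] + 1L)
    cols[[k]] <- c(which(ok0), which(ok1))
    vals[[k]] <- c((1 - fb[ok0]) * area_w, fb[ok1] * area_w)
  }
  A <- Matrix::sparseMatrix(i = unlist(rows), j = unlist(cols),
                            x = unlist(vals),
                            dims = c(n_angles * n_bins, nvox))
  psf <- NULL
  if (psf_fwhm_mm > 0) {
    sig <- psf_fwhm_mm / (2 * sqrt(2 * log(2))) / bin_width
    r <- max(1L, ceiling(3 * sig))
    ker <- exp(-0.5 * ((-r):r / sig)^2); ker <- ker / sum(ker)
    psf <- ker
  }
  structure(list(A = A, dims = dims, spacing = spacing, angles = angles,
                 n_angles = as.integer(n_angles), n_bins = as.integer(n_bins),
                 bin_width = bin_width, psf = psf),
            class = "pet_projector")
}

# radial PSF convolution applied per angle on a stacked sinogram vector
apply_psf <- function(proj, p) {
  if (is.null(proj$psf)) return(p)
  m <- matrix(p, proj$n_bins, proj$n_angles)
  as.vector(conv_along(m, proj$psf, 1L))
}

proj_forward <- function(proj, img_vec) {
  apply_psf(proj, as.numeric(proj$A %*% img_vec))
}

proj_back <- function(proj, sino_vec) {
  as.numeric(Matrix::crossprod(proj$A, apply_psf(proj, sino_vec)))
}

# attenuation factors per line of response from a mu image (1/cm); path
# lengths from the projector are mm, hence the /10.
attenuation_factors <- function(proj, mu_vec) {
  exp(-as.numeric(proj$A %*% mu_vec) / 10)
}

#' Attenuated forward projection
#'
#' Line integrals of activity, each multiplied by the survival probability
#' `exp(-integral of mu)` along the same line (PET attenuation acts on the
#' whole line of response, independent of emission position).
#'
#' @param activity,mu [voxel_volume()]s on the projector grid (mu may be
#'   `NULL` for an unattenuated projection).
#' @param proj a [make_projector()].
#' @return a `sinogram`: numeric matrix n_bins x n_angles with geometry
#'   attributes.
#' @export
project <- function(activity, mu = NULL, proj) {
  if (!identical(as.integer(dim(activity$values)), proj$dims)) {
    stop("activity grid does not match projector")
  }
  if (any(activity$values < 0)) stop("activity must be >= 0")
  p <- proj_forward(proj, as.vector(activity$values))
  if (!is.null(mu)) {
    if (any(mu$values < 0)) stop("mu must be >= 0")
    p <- p * attenuation_factors(proj, as.vector(mu$values))
  }
  sino <- matrix(p, proj$n_bins, proj$n_angles)
  structure(sino, class = c("sinogram", "matrix"),
            bin_width = proj$bin_width, angles = proj$angles)
}

# Angle-interleaved subset allocation with a bit-reversal processing order,
# so successive subsets are maximally separated in angle.
subset_indices <- function(proj, n_subsets) {
  n_angles <- proj$n_angles
  if (n_subsets < 1L) stop("subsets must be >= 1")
  if (n_angles %% n_subsets != 0) {
    warning(sprintf("%d angles split into %d near-equal subsets", n_angles,
                    n_subsets))
  }
  groups <- split(seq_len(n_angles), (seq_len(n_angles) - 1L) %% n_subsets)
  nb <- proj$n_bins
  rows <- lapply(groups, function(gk) {
    as.vector(outer(seq_len(nb), (gk - 1L) * nb, `+`))
  })
  # bit-reversed order of subset processing
  nbits <- ceiling(log2(max(n_subsets, 2)))
  rev_bits <- function(i) {
    b <- as.integer(intToBits(i))[seq_len(nbits)]
    sum(b * 2^((nbits - 1):0))
  }
  ord <- order(vapply(seq_len(n_subsets) - 1L, rev_bits, numeric(1)))
  rows[ord]
}
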