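#' Voxel volume
#'
#' A scalar field on a regular grid. Values are stored as a 2D or 3D array;
#' `spacing` gives the physical size of a voxel in mm along each dimension,
#' `origin` the world coordinate (mm) of voxel index 0 (indices are 0-based:
#' world = origin + index * spacing). The `semantics` tag records what the
#' intensities mean and travels with the object through the pipeline.
#'
#' @param values numeric 2D or 3D array (or matrix).
#' @param spacing voxel spacing in mm, one value per dimension (recycled if
#'   scalar).
#' @param origin world coordinate of voxel (0,0[,0]) in mm.
#' @param semantics one of "activity" (kBq/mL), "mu" (1/cm at 511 keV),
#'   "mr" (a.u.), "suv" (dimensionless), "label".
#' @return an object of class `voxel_volume`.
#' @export
voxel_volume <- function(values, spacing, origin = NULL,
                         semantics = c("activity", "mu", "mr", "suv", "label")) {
  semantics <- match.arg(semantics)
  if (is.null(dim(values))) stop("values must be a matrix or array")
  nd <- length(dim(values))
  if (!nd %in% c(2L, 3L)) stop("only 2D and 3D volumes are supported")
  spacing <- rep_len(as.numeric(spacing), nd)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("voxel spacing must be finite and > 0")
  }
  if (is.null(origin)) origin <- rep(0, nd)
  origin <- rep_len(as.numeric(origin), nd)
  if (any(!is.finite(values))) stop("volume values must be finite")
  structure(list(values = values, spacing = spacing, origin = origin,
                 semantics = semantics),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat("<voxel_volume> ", paste(dim(x$values), collapse = " x "),
      " @ ", paste(signif(x$spacing, 4), collapse = " x "), " mm [",
      x$semantics, "]\n", sep = "")
  cat("  range: ", paste(signif(range(x$values), 5), collapse = " .. "), "\n",
      sep = "")
  invisible(x)
}

vv_like <- function(template, values, semantics = template$semantics) {
  voxel_volume(values, template$spacing, template$origin, semantics)
}

#' Displacement field
#'
#' Per-voxel displacement vectors in mm on the same grid as the volumes they
#' deform. The convention is pull-back: for each output (reference) voxel the
#' field stores where, in the input image, to sample -- `out(x) = in(x + d(x))`.
#' A zero field is the identity.
#'
#' @param d numeric array of dimension `c(grid dim, ndim)` holding the mm
#'   displacement per voxel and axis.
#' @param spacing,origin grid geometry as in [voxel_volume()].
#' @return an object of class `displacement_field`.
#' @export
displacement_field <- function(d, spacing, origin = NULL) {
  dims <- dim(d)
  nd <- length(dims) - 1L
  if (!nd %in% c(2L, 3L) || dims[length(dims)] != nd) {
    stop("d must have dimension c(grid, ndim) with matching trailing axis")
  }
  if (any(!is.finite(d))) stop("displacement field must be finite")
  spacing <- rep_len(as.numeric(spacing), nd)
  if (is.null(origin)) origin <- rep(0, nd)
  structure(list(d = d, spacing = spacing, origin = rep_len(origin, nd)),
            class = "displacement_field")
}

zero_field <- function(vol) {
  nd <- length(dim(vol$values))
  displacement_field(array(0, c(dim(vol$values), nd)), vol$spacing, vol$origin)
}

field_magnitude <- function(field) {
  nd <- length(dim(field$d)) - 1L
  m <- 0
  for (k in seq_len(nd)) m <- m + slice_component(field$d, k)^2
  sqrt(m)
}

slice_component <- function(d, k) {
  dims <- dim(d)
  nd <- length(dims) - 1L
  if (nd == 2L) array(d[, , k], dims[1:2]) else array(d[, , , k], dims[1:3])
}

# 0-based voxel-index coordinates of every voxel, as an nvox x nd matrix
# (column-major voxel order, matching as.vector()). Cached per grid size;
# callers may modify the returned matrix (copy-on-write protects the cache).
.grid_coord_cache <- new.env(parent = emptyenv())
grid_index_coords <- function(dims) {
  key <- paste(dims, collapse = "x")
  hit <- .grid_coord_cache[[key]]
  if (!is.null(hit)) return(hit)
  nd <- length(dims)
  g <- lapply(dims, function(n) seq_len(n) - 1)
  out <- as.matrix(do.call(expand.grid, g))[, seq_len(nd), drop = FALSE]
  dimnames(out) <- NULL
  .grid_coord_cache[[key]] <- out
  out
}

# Multilinear interpolation of `values` at 0-based continuous index
# coordinates `coords` (nvox x nd). Out-of-grid samples take `fill`.
interp_linear <- function(values, coords, fill = 0) {
  dims <- dim(values)
  nd <- length(dims)
  n <- nrow(coords)
  out <- numeric(n)
  i0 <- floor(coords)
  fr <- coords - i0
  acc <- numeric(n)
  corners <- as.matrix(do.call(expand.grid, rep(list(0:1), nd)))
  for (ci in seq_len(nrow(corners))) {
    off <- corners[ci, ]
    idx <- sweep(i0, 2, off, `+`)
    w <- rep(1, n)
    for (k in seq_len(nd)) {
      w <- w * (if (off[k] == 1) fr[, k] else 1 - fr[, k])
    }
    inside <- rep(TRUE, n)
    for (k in seq_len(nd)) {
      inside <- inside & idx[, k] >= 0 & idx[, k] <= dims[k] - 1
    }
    lin <- rep(1, n)
    mult <- 1
    for (k in seq_len(nd)) {
      lin <- lin + idx[, k] * mult
      mult <- mult * dims[k]
    }
    v <- numeric(n)
    v[inside] <- values[lin[inside]]
    v[!inside] <- fill
    acc <- acc + w * v
  }
  acc
}

interp_nearest <- function(values, coords, fill = 0) {
  dims <- dim(values)
  nd <- length(dims)
  idx <- round(coords)
  n <- nrow(coords)
  inside <- rep(TRUE, n)
  for (k in seq_len(nd)) {
    inside <- inside & idx[, k] >= 0 & idx[, k] <= dims[k] - 1
  }
  lin <- rep(1, n)
  mult <- 1
  for (k in seq_len(nd)) {
    lin <- lin + idx[, k] * mult
    mult <- mult * dims[k]
  }
  out <- rep(fill, n)
  out[inside] <- values[lin[inside]]
  out
}

#' Warp a volume with a displacement field
#'
#' Pull-back resampling: `out(x) = volume(x + d(x))`, with linear
#' interpolation by default. Samples falling outside the grid take `fill`
#' (0 for both activity and attenuation by convention).
#'
#' @param vol a [voxel_volume()].
#' @param field a [displacement_field()] on the same grid.
#' @param order interpolation order: 1 (multilinear, default) or 0 (nearest).
#' @param fill value for out-of-grid samples.
#' @return a warped [voxel_volume()].
#' @export
warp <- function(vol, field, order = 1L, fill = 0) {
  dims <- dim(vol$values)
  fdims <- dim(field$d)
  if (!identical(as.integer(dims), as.integer(fdims[-length(fdims)]))) {
    stop("volume and displacement field grids do not match")
  }
  if (all(field$d == 0)) return(vol)  # exact identity
  nd <- length(dims)
  coords <- grid_index_coords(dims)
  for (k in seq_len(nd)) {
    coords[, k] <- coords[, k] + as.vector(slice_component(field$d, k)) / vol$spacing[k]
  }
  v <- if (order == 0L) interp_nearest(vol$values, coords, fill)
       else interp_linear(vol$values, coords, fill)
  vv_like(vol, array(v, dims))
}

#' Warp operator as a sparse matrix
#'
#' Returns the sparse matrix `W` such that `W %*% as.vector(v)` equals
#' `as.vector(warp(v, field))` with linear interpolation. Its transpose is the
#' exact adjoint used in motion-compensated backprojection.
#'
#' @param field a [displacement_field()].
#' @param dims grid dimension (defaults to the field's grid).
#' @return a `dgCMatrix` of size nvox x nvox.
#' @export
warp_matrix <- function(field, dims = NULL) {
  fdims <- dim(field$d)
  nd <- length(fdims) - 1L
  if (is.null(dims)) dims <- fdims[seq_len(nd)]
  nvox <- prod(dims)
  if (all(field$d == 0)) {
    return(Matrix::Diagonal(nvox))
  }
  coords <- grid_index_coords(dims)
  for (k in seq_len(nd)) {
    coords[, k] <- coords[, k] + as.vector(slice_component(field$d, k)) / field$spacing[k]
  }
  i0 <- floor(coords)
  fr <- coords - i0
  corners <- as.matrix(do.call(expand.grid, rep(list(0:1), nd)))
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  rowid <- seq_len(nvox)
  for (ci in seq_len(nrow(corners))) {
    off <- corners[ci, ]
    idx <- sweep(i0, 2, off, `+`)
    w <- rep(1, nvox)
    for (k in seq_len(nd)) {
      w <- w * (if (off[k] == 1) fr[, k] else 1 - fr[, k])
    }
    inside <- rep(TRUE, nvox)
    for (k in seq_len(nd)) {
      inside <- inside & idx[, k] >= 0 & idx[, k] <= dims[k] - 1
    }
    keep <- inside & w > 0
    if (!any(keep)) next
    lin <- rep(1, nvox)
    mult <- 1
    for (k in seq_len(nd)) {
      lin <- lin + idx[, k] * mult
      mult <- mult * dims[k]
    }
    rows <- c(rows, rowid[keep])
    cols <- c(cols, lin[keep])
    vals <- c(vals, w[keep])
  }
  Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(nvox, nvox))
}

#' Invert a displacement field
#'
#' Fixed-point iteration for the inverse of a pull-back field:
#' `e(x) = -d(x + e(x))`. Converges for the smooth, moderate-amplitude
#' respiratory fields used here.
#'
#' @param field a [displacement_field()].
#' @param iters number of fixed-point iterations.
#' @return the approximate inverse [displacement_field()].
#' @export
invert_field <- function(field, iters = 25L) {
  if (all(field$d == 0)) return(field)
  dims <- dim(field$d)
  nd <- length(dims) - 1L
  gdims <- dims[seq_len(nd)]
  base <- grid_index_coords(gdims)
  e <- array(0, dims)
  for (it in seq_len(iters)) {
    coords <- base
    for (k in seq_len(nd)) {
      coords[, k] <- coords[, k] + as.vector(slice_component(e, k)) / field$spacing[k]
    }
    enew <- array(0, dims)
    for (k in seq_len(nd)) {
      dk <- slice_component(field$d, k)
      val <- -interp_linear(dk, coords, fill = 0)
      if (nd == 2L) enew[, , k] <- val else enew[, , , k] <- val
    }
    e <- enew
  }
  displacement_field(e, field$spacing, field$origin)
}

# Separable gaussian smoothing of a 2D/3D array; sigma in voxels per dim.
# Kernel normalized to sum 1, zero-padded edges.
gaussian_smooth <- function(x, sigma) {
  dims <- dim(x)
  nd <- length(dims)
  sigma <- rep_len(sigma, nd)
  for (k in seq_len(nd)) {
    if (sigma[k] <= 0) next
    r <- max(1L, ceiling(3 * sigma[k]))
    ker <- exp(-0.5 * ((-r):r / sigma[k])^2)
    ker <- ker / sum(ker)
    x <- conv_along(x, ker, k)
  }
  x
}

# 1D convolution (zero padded) along dimension k of an array.
conv_along <- function(x, ker, k) {
  dims <- dim(x)
  nd <- length(dims)
  perm <- c(k, setdiff(seq_len(nd), k))
  xp <- aperm(x, perm)
  m <- dim(xp)[1]
  xm <- matrix(xp, nrow = m)
  r <- (length(ker) - 1L) / 2L
  pad <- matrix(0, nrow = r, ncol = ncol(xm))
  xpad <- rbind(pad, xm, pad)
  out <- matrix(0, nrow = m, ncol = ncol(xm))
  for (j in seq_along(ker)) {
    out <- out + ker[j] * xpad[j:(j + m - 1L), , drop = FALSE]
  }
  res <- array(out, dim(xp))
  aperm(res, order(perm))
}

#' Smooth a volume with a gaussian of given FWHM
#'
#' @param vol a [voxel_volume()].
#' @param fwhm_mm full width at half maximum of the gaussian kernel, mm.
#' @return the filtered [voxel_volume()].
#' @export
gaussian_postfilter <- function(vol, fwhm_mm) {
  if (fwhm_mm < 0) stop("FWHM must be >= 0")
  if (fwhm_mm == 0) return(vol)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / vol$spacing
  vv_like(vol, gaussian_smooth(vol$values, sigma_vox))
}
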