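# Shared fixtures, built once per test run. The small geometry keeps unit
# tests fast; acceptance tests build the full-size study geometry themselves.

small_spec <- function(...) {
  phantom_spec(dim = c(48L, 48L), spacing = 6,
               lesions = list(list(center = c(181, 144), diameter = 18,
                                   activity = 8.0)), ...)
}

fix <- local({
  spec <- small_spec()
  ph <- build_phantom(spec)
  list(
    spec = spec,
    phantom = ph,
    truth = make_motion_truth(ph),
    proj = make_projector(spec$dim, spec$spacing, n_angles = 42L)
  )
})

full_fix <- local({
  spec <- phantom_spec()
  ph <- build_phantom(spec)
  list(
    spec = spec,
    phantom = ph,
    truth = make_motion_truth(ph),
    proj = make_projector(spec$dim, spec$spacing)
  )
})

# synthetic registration set with displacements following a known linear
# generator plus optional noise/outliers
synthetic_regset <- function(n_images = 200, dims = c(24L, 24L), spacing = 3,
                             c0 = 2, c1 = 5, c2 = 1, noise_sd = 0,
                             outlier_frac = 0, outlier_mm = 20, seed = 1,
                             s_power = 1) {
  set.seed(seed)
  t <- seq(0, by = 0.3, length.out = n_images)
  base <- (1 - cos(2 * pi * t / 4)) / 2
  s <- base^s_power
  s_dot <- s_power * base^(s_power - 1) * pi / 4 * sin(2 * pi * t / 4)
  # spatial patterns: c1 scaled by a smooth bump, c2 by a different one
  xg <- outer(seq_len(dims[1]), rep(1, dims[2]))
  yg <- outer(rep(1, dims[1]), seq_len(dims[2]))
  p1 <- exp(-((xg - dims[1] / 2)^2 + (yg - dims[2] / 2)^2) / (dims[1]))
  p1 <- p1 / max(p1)
  p2 <- exp(-((xg - dims[1] / 3)^2 + (yg - 2 * dims[2] / 3)^2) / (dims[1]))
  p2 <- p2 / max(p2)
  fields <- array(0, c(dims, 2L, n_images))
  for (i in seq_len(n_images)) {
    d <- c0 + c1 * p1 * s[i] + c2 * p2 * s_dot[i]
    if (noise_sd > 0) d <- d + matrix(rnorm(prod(dims), 0, noise_sd),
                                      dims[1], dims[2])
    fields[, , 2, i] <- d
  }
  if (outlier_frac > 0) {
    bad <- sample(n_images, round(outlier_frac * n_images))
    for (i in bad) {
      fields[, , 2, i] <- fields[, , 2, i] +
        sample(c(-1, 1), 1) * outlier_mm
    }
  }
  list(reg = registration_set(fields, s, s_dot, spacing),
       s = s, s_dot = s_dot, p1 = p1, p2 = p2,
       c0 = c0, c1 = c1, c2 = c2)
}

# independent brute-force SUV oracles (deliberately simple loops)
brute_suv_peak <- function(suv, roi, diameter_mm = 12) {
  dims <- dim(suv$values)
  sp <- suv$spacing
  nd <- length(dims)
  centers <- which(roi, arr.ind = TRUE)
  offs <- respimoco:::sphere_offsets(diameter_mm / 2, sp)
  best <- -Inf
  for (ci in seq_len(nrow(centers))) {
    vals <- c()
    for (oi in seq_len(nrow(offs))) {
      idx <- centers[ci, ] + offs[oi, ]
      if (all(idx >= 1) && all(idx <= dims)) {
        vals <- c(vals, suv$values[matrix(idx, 1)])
      }
    }
    best <- max(best, mean(vals))
  }
  best
}

brute_suv_max <- function(suv, roi) max(suv$values[which(roi)])

# independent exact Wilcoxon enumeration (kept separate from the package's)
enum_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  m <- length(d)
  total <- 0; ge <- 0; le <- 0
  for (mask in 0:(2^m - 1)) {
    w <- sum(r[bitwAnd(bitwShiftR(mask, seq_len(m) - 1L), 1L) == 1L])
    total <- total + 1
    if (w >= W) ge <- ge + 1
    if (w <= W) le <- le + 1
  }
  min(1, 2 * min(ge / total, le / total))
}
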