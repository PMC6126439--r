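#' Wilcoxon signed-rank test with exact enumeration
#'
#' Paired test on `before`/`after` (or a vector of differences). Zero
#' differences are dropped (classic Wilcoxon zero handling; `zero_method =
#' "pratt"` keeps them in the ranking and then drops their contribution);
#' tied absolute differences get average ranks. For m <= `exact_max` non-zero
#' pairs the two-sided p-value is computed by full enumeration of the 2^m
#' sign assignments (which handles ties exactly); otherwise a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param before,after paired numeric vectors; if `after` is `NULL`, `before`
#'   is taken to be the differences.
#' @param mode "auto" (exact when m <= `exact_max`), "exact" or "approx".
#' @param exact_max largest m for which enumeration is used in auto mode.
#' @param zero_method "wilcox" (drop zeros, default) or "pratt".
#' @return list with `statistic` (W+, the positive-rank sum), `p.value`,
#'   `n_nonzero`, `method`.
#' @export
wilcoxon_signed_rank <- function(before, after = NULL,
                                 mode = c("auto", "exact", "approx"),
                                 exact_max = 12L,
                                 zero_method = c("wilcox", "pratt")) {
  mode <- match.arg(mode)
  zero_method <- match.arg(zero_method)
  d <- if (is.null(after)) as.numeric(before) else as.numeric(before) - as.numeric(after)
  if (zero_method == "wilcox") {
    d <- d[d != 0]
    if (length(d) == 0L) {
      warning("all differences are zero; p = 1")
      return(list(statistic = 0, p.value = 1, n_nonzero = 0L,
                  method = "degenerate"))
    }
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    ranks <- r
  } else {
    if (all(d == 0)) {
      warning("all differences are zero; p = 1")
      return(list(statistic = 0, p.value = 1, n_nonzero = 0L,
                  method = "degenerate"))
    }
    r <- rank(abs(d))
    keep <- d != 0
    W <- sum(r[d > 0])
    ranks <- r[keep]
    d <- d[keep]
  }
  m <- length(d)
  use_exact <- switch(mode, exact = TRUE, approx = FALSE,
                      auto = m <= exact_max)
  if (use_exact) {
    if (m > 20L) stop("exact enumeration limited to 20 non-zero pairs")
    # all 2^m sign assignments of the realized ranks
    signs <- as.matrix(do.call(expand.grid, rep(list(c(0, 1)), m)))
    Wdist <- as.numeric(signs %*% ranks)
    p <- min(1, 2 * min(mean(Wdist <= W), mean(Wdist >= W)))
    method <- "exact enumeration"
  } else {
    # sign-flip moments conditional on the realized (tie-averaged) ranks
    mu <- sum(ranks) / 2
    sig2 <- sum(ranks^2) / 4
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    if (W == mu) z <- 0
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = W, p.value = p, n_nonzero = m, method = method)
}

#' Paired-sample t test
#'
#' Classical paired t on the differences, two-sided p from the t distribution
#' with n - 1 degrees of freedom.
#'
#' @param u,mc paired numeric vectors (e.g. SUV metrics on uncorrected and
#'   motion-corrected images).
#' @return list with `statistic`, `p.value`, `df`, `mean_diff`.
#' @export
paired_t <- function(u, mc) {
  d <- as.numeric(mc) - as.numeric(u)
  n <- length(d)
  if (n < 2L) stop("need at least 2 pairs")
  s <- stats::sd(d)
  if (s == 0) stop("zero variance of differences: t statistic undefined")
  tstat <- mean(d) / (s / sqrt(n))
  list(statistic = tstat, p.value = 2 * stats::pt(-abs(tstat), n - 1),
       df = n - 1L, mean_diff = mean(d))
}
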