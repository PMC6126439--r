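#' Build a respiratory gating scheme
#'
#' Partitions frames into gates in surrogate space. Default scheme
#' (`"amp_dir"`): frames are first split by the sign of the surrogate
#' gradient (inhalation vs exhalation) and then into equal-count amplitude
#' bins of s within each direction, which preserves hysteresis information in
#' the per-gate representative states. `"amplitude"` uses pure equal-count
#' amplitude bins. Every frame is assigned to exactly one gate, so the union
#' of the gates is 100% of the acquired data; the representative state of a
#' gate is the count-weighted mean (s, s_dot) of its frames.
#'
#' @param surrogate a [extract_surrogate()] series (one row per frame), or
#'   any data.frame with `s` and `s_dot` columns of frame length.
#' @param n number of gates.
#' @param scheme "amp_dir" (default) or "amplitude". With `n = 1` or odd `n`,
#'   amplitude binning is used.
#' @param frame_counts optional per-frame total counts used to weight the
#'   representative states (defaults to equal weights).
#' @return an object of class `gating_scheme`: per-frame `assignment`,
#'   `n_gates`, and a `rep` data.frame (s, s_dot, n_frames, counts per gate).
#' @export
make_gates <- function(surrogate, n = 8L, scheme = c("amp_dir", "amplitude"),
                       frame_counts = NULL) {
  scheme <- match.arg(scheme)
  n <- as.integer(n)
  if (n < 1L) stop("number of gates must be >= 1")
  s <- surrogate$s; s_dot <- surrogate$s_dot
  nf <- length(s)
  if (n > nf) stop("more gates than frames")
  if (is.null(frame_counts)) frame_counts <- rep(1, nf)
  equal_bins <- function(v, k) {
    if (k == 1L) return(rep(1L, length(v)))
    r <- rank(v, ties.method = "first")
    as.integer(ceiling(r / length(v) * k))
  }
  if (scheme == "amp_dir" && n > 1L && n %% 2L == 0L &&
      any(s_dot >= 0) && any(s_dot < 0)) {
    assignment <- integer(nf)
    up <- s_dot >= 0
    assignment[up] <- equal_bins(s[up], n %/% 2L)
    assignment[!up] <- n %/% 2L + equal_bins(s[!up], n %/% 2L)
  } else {
    scheme <- "amplitude"
    assignment <- equal_bins(s, n)
  }
  rep_df <- do.call(rbind, lapply(seq_len(n), function(g) {
    idx <- assignment == g
    w <- frame_counts[idx]
    if (!any(idx) || sum(w) <= 0) w <- rep(1, sum(idx))
    data.frame(gate = g,
               s = stats::weighted.mean(s[idx], w),
               s_dot = stats::weighted.mean(s_dot[idx], w),
               n_frames = sum(idx), counts = sum(frame_counts[idx]))
  }))
  if (any(rep_df$n_frames == 0L)) stop("empty gate produced; reduce n")
  structure(list(assignment = assignment, n_gates = n, rep = rep_df,
                 scheme = scheme),
            class = "gating_scheme")
}
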