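#' Match reader marks against the reference lesion set
#'
#' Implements the reference-reading rules: a mark matching a reference lesion
#' (within the distance tolerance, greedy nearest-first, one-to-one) is a
#' true positive (TP); a mark matching nothing is a false positive (FP); a
#' reference lesion left unmarked by a reader in an image mode is a
#' false-negative and imputed with a confidence score of 0.
#'
#' @param marks data.frame of raw reader marks with columns `reader`, `mode`
#'   ("U" or "MC"), `x_mm`, `y_mm`, `chi` (confidence 1..4).
#' @param reference data.frame of reference lesions with columns `lesion`,
#'   `x_mm`, `y_mm`.
#' @param tolerance_mm maximum mark-to-lesion distance for a match
#'   (default 15).
#' @return a `score_table` data.frame: one row per mark or imputed
#'   false-negative, with `lesion` (matched id or NA), `label`
#'   ("TP"/"FP"/"FN") and `chi` (0 for FN).
#' @export
match_marks <- function(marks, reference, tolerance_mm = 15) {
  req <- c("reader", "mode", "x_mm", "y_mm", "chi")
  if (!all(req %in% names(marks))) {
    stop("marks must have columns: ", paste(req, collapse = ", "))
  }
  if (!all(marks$chi %in% 1:4)) stop("chi scores must be in 1..4")
  out <- list()
  for (rd in unique(marks$reader)) for (md in unique(marks$mode)) {
    mk <- marks[marks$reader == rd & marks$mode == md, , drop = FALSE]
    matched_lesion <- rep(NA_character_, nrow(mk))
    if (nrow(mk) > 0 && nrow(reference) > 0) {
      dmat <- outer(seq_len(nrow(mk)), seq_len(nrow(reference)),
                    Vectorize(function(i, j) {
                      sqrt((mk$x_mm[i] - reference$x_mm[j])^2 +
                           (mk$y_mm[i] - reference$y_mm[j])^2)
                    }))
      dmat[dmat > tolerance_mm] <- NA
      # greedy by distance, one-to-one
      while (any(is.finite(dmat))) {
        best <- which(dmat == min(dmat, na.rm = TRUE), arr.ind = TRUE)[1, ]
        matched_lesion[best[1]] <- reference$lesion[best[2]]
        dmat[best[1], ] <- NA
        dmat[, best[2]] <- NA
      }
    }
    mk$lesion <- matched_lesion
    mk$label <- ifelse(is.na(matched_lesion), "FP", "TP")
    if (any(duplicated(stats::na.omit(matched_lesion)))) {
      stop("duplicate lesion match for one reader/mode")
    }
    missed <- setdiff(reference$lesion, matched_lesion)
    if (length(missed) > 0) {
      fn <- data.frame(reader = rd, mode = md, x_mm = NA_real_,
                       y_mm = NA_real_, chi = 0, lesion = missed,
                       label = "FN")
      mk <- rbind(mk[, names(fn)], fn)
    }
    out[[length(out) + 1L]] <- mk
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("score_table", "data.frame")
  res
}

#' Detection and score-change summary
#'
#' Per-reader and pooled TP rates, FP counts per image mode, per-lesion score
#' changes Delta-chi = chi(MC) - chi(U) per reader and summed over readers
#' (Delta-chi_1+2), the both-readers-agree subset, and a Wilcoxon signed-rank
#' test on the paired chi scores.
#'
#' @param scores a [match_marks()] `score_table` containing both "U" and
#'   "MC" modes.
#' @return a list of class `detection_stats`.
#' @export
detection_summary <- function(scores) {
  readers <- sort(unique(scores$reader))
  modes <- c("U", "MC")
  ref_lesions <- sort(unique(scores$lesion[scores$label != "FP"]))
  n_ref <- length(ref_lesions)

  tp_rate <- expand.grid(reader = readers, mode = modes,
                         stringsAsFactors = FALSE)
  tp_rate$rate <- mapply(function(rd, md) {
    sum(scores$reader == rd & scores$mode == md & scores$label == "TP") /
      max(n_ref, 1L)
  }, tp_rate$reader, tp_rate$mode)
  pooled_tp <- vapply(modes, function(md) {
    mean(tp_rate$rate[tp_rate$mode == md])
  }, numeric(1))
  fp_counts <- vapply(modes, function(md) {
    sum(scores$mode == md & scores$label == "FP")
  }, numeric(1))

  # per-lesion chi by reader and mode (FN already imputed as 0)
  chi_of <- function(rd, md) {
    vapply(ref_lesions, function(l) {
      v <- scores$chi[scores$reader == rd & scores$mode == md &
                        !is.na(scores$lesion) & scores$lesion == l]
      if (length(v) == 0) 0 else v[1]
    }, numeric(1))
  }
  dchi <- lapply(readers, function(rd) chi_of(rd, "MC") - chi_of(rd, "U"))
  names(dchi) <- paste0("reader_", readers)
  dchi_sum <- Reduce(`+`, dchi)

  agree_pos <- agree_neg <- character(0)
  if (length(readers) >= 2) {
    pos <- Reduce(`&`, lapply(dchi, function(d) d > 0))
    neg <- Reduce(`&`, lapply(dchi, function(d) d < 0))
    agree_pos <- ref_lesions[pos]
    agree_neg <- ref_lesions[neg]
  }

  chi_u <- unlist(lapply(readers, function(rd) chi_of(rd, "U")))
  chi_mc <- unlist(lapply(readers, function(rd) chi_of(rd, "MC")))
  wil <- if (n_ref > 0) {
    suppressWarnings(wilcoxon_signed_rank(chi_mc, chi_u))
  } else NULL

  structure(list(
    tp_rate = tp_rate, tp_rate_pooled = pooled_tp, fp_counts = fp_counts,
    dchi = dchi, dchi_sum = dchi_sum,
    dchi_hist = lapply(dchi, table), dchi_sum_hist = table(dchi_sum),
    mean_chi = c(U = mean(chi_u), MC = mean(chi_mc)),
    agree_positive = agree_pos, agree_negative = agree_neg,
    wilcoxon = wil, n_reference = n_ref
  ), class = "detection_stats")
}
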