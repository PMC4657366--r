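#' Vessel-overlap precision and recall
#'
#' The registration quality metric: within the overlapped scanning region,
#' true positives are vessel pixels present in both reference and target,
#' false positives are target-only vessel pixels, false negatives are
#' reference-only vessel pixels; `precision = TP / (TP + FP)`,
#' `recall = TP / (TP + FN)`. A zero denominator (no vessels in one mask)
#' yields a flagged `NA`, not 0 — undefined values propagate as missing
#' data into the comparison models.
#'
#' @param ref,tgt `vessel_mask` objects in a common frame (the target
#'   already transformed, nearest-neighbour, when evaluating
#'   post-registration).
#' @param overlap optional `overlap_mask`; default the overlap of the two
#'   masks' valid regions.
#' @return an object of class `precision_recall` with counts, fractions and
#'   the overlap mask used.
#' @export
precision_recall <- function(ref, tgt, overlap = NULL) {
  if (!all(dim(ref$mask) == dim(tgt$mask))) {
    stop("masks must share one frame", call. = FALSE)
  }
  if (is.null(overlap)) {
    overlap <- suppressWarnings(overlap_region(ref, tgt))
  }
  m <- overlap$mask
  r <- ref$mask == 1 & m
  t_ <- tgt$mask == 1 & m
  n_tp <- sum(r & t_)
  n_fp <- sum(t_ & !r)
  n_fn <- sum(r & !t_)
  precision <- if (n_tp + n_fp > 0) n_tp / (n_tp + n_fp) else NA_real_
  recall <- if (n_tp + n_fn > 0) n_tp / (n_tp + n_fn) else NA_real_
  structure(list(n_tp = n_tp, n_fp = n_fp, n_fn = n_fn,
                 precision = precision, recall = recall, overlap = overlap,
                 undefined_precision = is.na(precision),
                 undefined_recall = is.na(recall)),
            class = "precision_recall")
}

#' @export
print.precision_recall <- function(x, ...) {
  cat(sprintf("<precision_recall P=%.4f R=%.4f (TP=%d FP=%d FN=%d)>\n",
              x$precision, x$recall, x$n_tp, x$n_fp, x$n_fn))
  invisible(x)
}

#' Evaluate vessel overlap across a longitudinal series
#'
#' For every non-reference session, computes precision/recall of its vessel
#' mask against the subject's reference mask before registration
#' (`condition = "none"`) and after applying each algorithm's estimated
#' correction. Corrections are applied to the vessel masks with
#' nearest-neighbour resampling.
#'
#' @param records a `session_series` (or list of session records).
#' @param results named list of per-algorithm result lists (e.g.
#'   `list(MI = ..., LPCC = ...)`), each parallel to `records` with a
#'   `registration_result` (or `NULL`) per record; `NULL`/missing entries
#'   yield rows with `NA` metrics and are counted in the `n_missing`
#'   attribute.
#' @return a long-format data frame with columns `subject`, `day`,
#'   `condition`, `precision`, `recall`, `n_tp`, `n_fp`, `n_fn`, ordered by
#'   subject, day, condition.
#' @export
evaluate_series <- function(records, results = list()) {
  subj <- vapply(records, `[[`, "", "subject_id")
  refs <- which(vapply(records, `[[`, TRUE, "reference"))
  names(refs) <- subj[refs]
  conditions <- c("none", names(results))
  rows <- list()
  n_missing <- 0L
  for (i in seq_along(records)) {
    rec <- records[[i]]
    if (rec$reference) next
    ref_rec <- records[[refs[[rec$subject_id]]]]
    for (cond in conditions) {
      if (cond == "none") {
        tgt <- rec$vessels
      } else {
        res <- results[[cond]][[i]]
        if (is.null(res)) {
          n_missing <- n_missing + 1L
          rows[[length(rows) + 1L]] <- data.frame(
            subject = rec$subject_id, day = rec$day, condition = cond,
            precision = NA_real_, recall = NA_real_,
            n_tp = NA_integer_, n_fp = NA_integer_, n_fn = NA_integer_)
          next
        }
        tgt <- apply_transform(rec$vessels, res$transform)
      }
      pr <- precision_recall(ref_rec$vessels, tgt)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = rec$subject_id, day = rec$day, condition = cond,
        precision = pr$precision, recall = pr$recall,
        n_tp = pr$n_tp, n_fp = pr$n_fp, n_fn = pr$n_fn)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$subject, out$day, out$condition), ]
  rownames(out) <- NULL
  attr(out, "n_missing") <- n_missing
  out
}
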