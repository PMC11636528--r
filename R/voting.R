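#' Ensemble hard voting over cross-validation runs
#'
#' Assigns each subject the class it was more often predicted as across
#' all runs in which it appeared in the test pair. Ties go to the positive
#' class: the costlier miss is an undetected treatment-resistant patient,
#' so ambiguity resolves toward flagging. Subjects never drawn into a test
#' pair (possible at very small run counts) get no voted label; they are
#' reported and excluded from the confusion counts with a warning.
#'
#' @param runs a `run_set` from [run_pairwise_cv()].
#' @param truth binary outcome vector for the cohort.
#' @return a `voted_result`: list with `voted` (per-subject class, `NA` if
#'   never tested), `votes_pos`, `votes_neg`, `appearances`, `confusion`
#'   (named vector TP/FN/TN/FP), `never_tested` (indices).
#' @export
vote_labels <- function(runs, truth) {
  stopifnot(inherits(runs, "run_set"))
  n <- length(truth)
  votes_pos <- votes_neg <- integer(n)
  df <- runs$runs
  for (r in seq_len(nrow(df))) {
    for (side in c("pos", "neg")) {
      s <- df[[paste0("test_", side)]][r]
      p <- df[[paste0("pred_", side)]][r]
      if (p == 1) votes_pos[s] <- votes_pos[s] + 1L
      else votes_neg[s] <- votes_neg[s] + 1L
    }
  }
  appearances <- votes_pos + votes_neg
  voted <- ifelse(appearances == 0, NA_integer_,
                  as.integer(votes_pos >= votes_neg))  # ties -> positive
  never <- which(appearances == 0)
  if (length(never) > 0)
    warning(sprintf("%d subject(s) never appeared in a test pair; excluded from confusion counts",
                    length(never)))
  ok <- !is.na(voted)
  confusion <- c(TP = sum(ok & voted == 1 & truth == 1),
                 FN = sum(ok & voted == 0 & truth == 1),
                 TN = sum(ok & voted == 0 & truth == 0),
                 FP = sum(ok & voted == 1 & truth == 0))
  structure(list(voted = voted, votes_pos = votes_pos,
                 votes_neg = votes_neg, appearances = appearances,
                 confusion = confusion, never_tested = never),
            class = "voted_result")
}

#' Classification metrics from voted confusion counts
#'
#' Standard accuracy, sensitivity, specificity and precision in percent,
#' reported to two decimals. Ratios with a zero denominator are returned
#' as `NA` (not available), never as 0.
#'
#' @param v a `voted_result`, or a named vector/list with `TP`, `FN`,
#'   `TN`, `FP`.
#' @return named numeric vector `accuracy`, `sensitivity`, `specificity`,
#'   `precision` (percent).
#' @export
confusion_metrics <- function(v) {
  cc <- if (inherits(v, "voted_result")) v$confusion else unlist(v)
  tp <- cc[["TP"]]; fn <- cc[["FN"]]; tn <- cc[["TN"]]; fp <- cc[["FP"]]
  if (any(c(tp, fn, tn, fp) < 0)) stop("negative confusion counts")
  total <- tp + fn + tn + fp
  if (total == 0) stop("all confusion counts are zero")
  pct <- function(num, den) if (den > 0) round(100 * num / den, 2) else NA_real_
  c(accuracy = pct(tp + tn, total),
    sensitivity = pct(tp, tp + fn),
    specificity = pct(tn, tn + fp),
    precision = pct(tp, tp + fp))
}
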