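#' Binarize wake probabilities
#'
#' An epoch is called wake iff its probability is greater than or equal
#' to the threshold (boundary goes to wake).
#'
#' @param probs Numeric vector of wake probabilities in \[0, 1\].
#' @param threshold Threshold in (0, 1).
#' @return Integer vector, 1 = wake, 0 = sleep.
#' @export
binarize <- function(probs, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1) {
    abort_actisleep("threshold must lie strictly inside (0, 1)",
                    "actisleep_invalid_argument")
  }
  if (any(probs < 0 | probs > 1)) {
    abort_actisleep("probabilities must lie in [0, 1]",
                    "actisleep_invalid_argument")
  }
  as.integer(probs >= threshold)
}

# The canonical threshold grid: 0.05 to 0.95 in steps of 0.01 (91 values).
threshold_grid <- function() {
  0.05 + (0:90) * 0.01
}

#' Sweep the binarization threshold
#'
#' Evaluates kappa, concordance (raw agreement), specificity
#' (wake-detection rate) and sensitivity (sleep-detection rate) at each
#' of the 91 grid thresholds between 0.05 and 0.95 (step 0.01).
#'
#' @param probs Wake probabilities.
#' @param truth Reference wake indicators (1 = wake), same length.
#' @return A tibble of class `threshold_curve` with columns
#'   `threshold`, `kappa`, `concordance`, `specificity`, `sensitivity`.
#' @export
threshold_sweep <- function(probs, truth) {
  if (length(probs) != length(truth)) {
    abort_actisleep("probs and truth must have equal length",
                    "actisleep_invalid_argument")
  }
  if (length(unique(truth)) < 2) {
    abort_actisleep("reference contains a single class",
                    "actisleep_single_class")
  }
  grid <- threshold_grid()
  rows <- lapply(grid, function(thr) {
    m <- epoch_metrics(confusion_counts(binarize(probs, thr), truth))
    tibble(threshold = thr, kappa = m$kappa, concordance = m$accuracy,
           specificity = m$specificity, sensitivity = m$sensitivity)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("threshold_curve", class(out))
  out
}

#' Balance-point threshold of a sweep curve
#'
#' The threshold minimizing the absolute difference between specificity
#' and sensitivity; ties resolve to the lowest threshold. An
#' alternative criterion maximizing concordance is available.
#'
#' @param curve A [threshold_sweep()] curve.
#' @param criterion `"balance"` (default) or `"concordance"`.
#' @return A single threshold value.
#' @export
balanced_threshold <- function(curve, criterion = c("balance", "concordance")) {
  criterion <- match.arg(criterion)
  score <- switch(criterion,
    balance = -abs(curve$specificity - curve$sensitivity),
    concordance = curve$concordance
  )
  curve$threshold[which.max(score)]
}

#' Per-subject balance thresholds from LOSO outputs
#'
#' For each subject, the balance-point threshold is computed on that
#' subject's own leave-one-subject-out fold probabilities; the
#' arithmetic mean across subjects is reported alongside. Subjects
#' whose reference contains a single class are excluded with a warning.
#'
#' @param loso_probs Tibble with columns `subject_id`, `prob`, `truth`
#'   (1 = wake), as produced by [loso_evaluate()].
#' @param criterion Passed to [balanced_threshold()].
#' @return List with `thresholds` (tibble: subject_id, threshold) and
#'   `mean_threshold`.
#' @export
per_subject_thresholds <- function(loso_probs,
                                   criterion = c("balance", "concordance")) {
  criterion <- match.arg(criterion)
  split_probs <- split(loso_probs, loso_probs$subject_id)
  rows <- list()
  for (sid in names(split_probs)) {
    d <- split_probs[[sid]]
    if (length(unique(d$truth)) < 2) {
      warn(sprintf("subject %s has a single reference class; excluded", sid))
      next
    }
    thr <- balanced_threshold(threshold_sweep(d$prob, d$truth), criterion)
    rows[[sid]] <- tibble(subject_id = sid, threshold = thr)
  }
  if (length(rows) == 0) {
    abort_actisleep("no subject with both classes", "actisleep_single_class")
  }
  thresholds <- dplyr::bind_rows(rows)
  list(thresholds = thresholds,
       mean_threshold = mean(thresholds$threshold))
}

#' Averaged-curve threshold from LOSO outputs
#'
#' Each subject's full sweep curve is computed, the four metrics are
#' averaged across subjects at every grid threshold, and the balance
#' criterion is applied to the averaged curve.
#'
#' @inheritParams per_subject_thresholds
#' @return A single threshold value.
#' @export
averaged_curve_threshold <- function(loso_probs,
                                     criterion = c("balance", "concordance")) {
  criterion <- match.arg(criterion)
  split_probs <- split(loso_probs, loso_probs$subject_id)
  curves <- list()
  for (sid in names(split_probs)) {
    d <- split_probs[[sid]]
    if (length(unique(d$truth)) < 2) {
      warn(sprintf("subject %s has a single reference class; excluded", sid))
      next
    }
    curves[[sid]] <- threshold_sweep(d$prob, d$truth)
  }
  if (length(curves) == 0) {
    abort_actisleep("no subject with both classes", "actisleep_single_class")
  }
  avg <- dplyr::bind_rows(curves) |>
    dplyr::group_by(.data$threshold) |>
    dplyr::summarise(dplyr::across(c("kappa", "concordance", "specificity",
                                     "sensitivity"), mean),
                     .groups = "drop")
  class(avg) <- c("threshold_curve", class(avg))
  balanced_threshold(avg, criterion)
}
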