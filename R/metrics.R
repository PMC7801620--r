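# Epoch-by-epoch and night-level agreement metrics. The orientation
# convention is centralized here: the model outputs wake probabilities,
# but the confusion table treats SLEEP as the positive class, so that
# sensitivity reads "ability to detect sleep" and specificity "ability
# to detect wake", as is conventional in actigraphy validation.

#' Confusion counts with sleep as the positive class
#'
#' @param pred Predicted wake indicators (1 = wake, 0 = sleep).
#' @param truth Reference wake indicators, same length.
#' @return A one-row tibble of class `confusion_counts` with columns
#'   `tp`, `tn`, `fp`, `fn`, where TP counts epochs scored sleep by
#'   both, TN epochs scored wake by both.
#' @export
confusion_counts <- function(pred, truth) {
  if (length(pred) != length(truth) || length(pred) == 0) {
    abort_actisleep("pred and truth must be non-empty and of equal length",
                    "actisleep_invalid_argument")
  }
  ps <- pred == 0   # predicted sleep
  ts <- truth == 0  # reference sleep
  out <- tibble(
    tp = sum(ps & ts),
    tn = sum(!ps & !ts),
    fp = sum(ps & !ts),
    fn = sum(!ps & ts)
  )
  class(out) <- c("confusion_counts", class(out))
  out
}

metric_or_na <- function(num, den) {
  if (den == 0) NA_real_ else num / den
}

#' Epoch-by-epoch agreement metrics from a confusion table
#'
#' Standard forms are primary: accuracy (concordance) `(TP+TN)/n`,
#' sensitivity `TP/(TP+FN)` (sleep detection), specificity
#' `TN/(TN+FP)` (wake detection), precision `TP/(TP+FP)`, recall
#' (= sensitivity), F1 as the harmonic mean of precision and recall,
#' and Cohen's kappa `(p_o - p_e)/(1 - p_e)` with the chance agreement
#' `p_e` built from the marginals. Printed-variant columns
#' (`accuracy_printed` with TP-only numerator, `f1_printed` as the
#' harmonic mean of sensitivity and specificity, `kappa_printed` with
#' a leading `1 -`) are retained for audit against the literature's
#' typeset formulas. Metrics with a zero denominator are returned as
#' `NA` rather than propagating NaN.
#'
#' @param counts A [confusion_counts()] row.
#' @return A one-row tibble of metrics (plus `p_e` and `n`).
#' @export
epoch_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  n <- tp + tn + fp + fn
  if (n == 0) {
    abort_actisleep("empty confusion table", "actisleep_invalid_argument")
  }
  sens <- metric_or_na(tp, tp + fn)
  spec <- metric_or_na(tn, tn + fp)
  prec <- metric_or_na(tp, tp + fp)
  acc <- (tp + tn) / n
  p_e <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / n^2
  kappa <- if (p_e == 1) NA_real_ else (acc - p_e) / (1 - p_e)
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_ else
    2 * prec * sens / (prec + sens)
  f1p <- if (is.na(sens) || is.na(spec) || sens + spec == 0) NA_real_ else
    2 * sens * spec / (sens + spec)
  tibble(
    accuracy = acc,
    sensitivity = sens,
    specificity = spec,
    precision = prec,
    recall = sens,
    f1 = f1,
    kappa = kappa,
    accuracy_printed = tp / n,
    f1_printed = f1p,
    kappa_printed = if (is.na(kappa)) NA_real_ else 1 - kappa,
    p_e = p_e,
    n = n
  )
}

#' Locate the reference night
#'
#' The analyzed night runs from the first to the last epoch scored
#' sleep in the reference; both scorers' sleep metrics are computed
#' over this same interval.
#'
#' @param truth Reference wake indicators (1 = wake).
#' @return List with `onset` and `offset` (1-based epoch indices).
#' @export
detect_night <- function(truth) {
  sleep_idx <- which(truth == 0)
  if (length(sleep_idx) == 0) {
    abort_actisleep("reference contains no sleep epochs",
                    "actisleep_invalid_argument")
  }
  list(onset = min(sleep_idx), offset = max(sleep_idx))
}

#' Night-level sleep metrics over an interval
#'
#' Over epochs `[onset, offset]` (30-s epochs): total sleep time
#' TST = 0.5 min per sleep epoch, wake after sleep onset WASO = 0.5 min
#' per wake epoch, and sleep efficiency SE = 100 * TST / (TST + WASO).
#' By construction TST + WASO equals the night span in minutes.
#'
#' @param binary Wake indicators (1 = wake) of the scoring to measure.
#' @param onset,offset Night interval (1-based epoch indices),
#'   typically from [detect_night()] on the reference scoring.
#' @param epoch_len_s Epoch length in seconds.
#' @return One-row tibble: `onset_epoch`, `offset_epoch`, `tst_min`,
#'   `waso_min`, `se_pct`.
#' @export
sleep_metrics <- function(binary, onset, offset, epoch_len_s = 30) {
  n <- length(binary)
  if (onset < 1 || offset > n || onset > offset) {
    abort_actisleep("invalid night interval", "actisleep_invalid_argument")
  }
  night <- binary[onset:offset]
  min_per_epoch <- epoch_len_s / 60
  tst <- sum(night == 0) * min_per_epoch
  waso <- sum(night == 1) * min_per_epoch
  tibble(
    onset_epoch = onset,
    offset_epoch = offset,
    tst_min = tst,
    waso_min = waso,
    se_pct = 100 * tst / (tst + waso)
  )
}

#' Bland-Altman agreement between reference and estimate
#'
#' Differences are reference minus estimate; the bias is their mean and
#' the limits of agreement are bias +/- 1.96 sample SD. The fraction of
#' subjects within the a-priori clinically satisfactory band (30 min
#' for TST/WASO) is reported.
#'
#' @param ref Reference values (one per subject).
#' @param est Estimated values, paired with `ref`.
#' @param limit Clinical agreement band half-width (same units as the
#'   values; default 30).
#' @return A one-row tibble of class `bland_altman` with `bias`,
#'   `loa_low`, `loa_high`, `sd_diff`, `frac_within_limit`, `n`; the
#'   paired values are attached for plotting.
#' @export
bland_altman <- function(ref, est, limit = 30) {
  if (length(ref) != length(est) || length(ref) < 2) {
    abort_actisleep("need >= 2 paired values", "actisleep_invalid_argument")
  }
  d <- ref - est
  bias <- mean(d)
  s <- sd(d)
  out <- tibble(
    bias = bias,
    loa_low = bias - 1.96 * s,
    loa_high = bias + 1.96 * s,
    sd_diff = s,
    frac_within_limit = mean(abs(d) <= limit),
    n = length(d)
  )
  attr(out, "pairs") <- tibble(ref = ref, est = est,
                               mean = (ref + est) / 2, diff = d)
  attr(out, "limit") <- limit
  class(out) <- c("bland_altman", class(out))
  out
}

#' ROC and precision-recall curves on wake probability
#'
#' Wake is the positive class of these threshold-free curves (the raw
#' model output is a wake probability). The ROC curve and its
#' trapezoidal AUC are computed with \pkg{pROC}; the precision-recall
#' curve is evaluated at every distinct score cut.
#'
#' @param probs Wake probabilities.
#' @param truth Reference wake indicators (1 = wake).
#' @return A list of class `roc_pr`: `roc` (tibble fpr/tpr/threshold),
#'   `pr` (tibble recall/precision/threshold), `auc`.
#' @export
roc_pr <- function(probs, truth) {
  if (length(unique(truth)) < 2) {
    abort_actisleep("reference contains a single class",
                    "actisleep_single_class")
  }
  r <- pROC::roc(response = truth, predictor = probs,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  roc_tbl <- tibble(
    threshold = rev(r$thresholds),
    fpr = rev(1 - r$specificities),
    tpr = rev(r$sensitivities)
  )
  cuts <- sort(unique(probs))
  pr_rows <- lapply(cuts, function(ct) {
    pred_wake <- probs >= ct
    tp <- sum(pred_wake & truth == 1)
    fp <- sum(pred_wake & truth == 0)
    fn <- sum(!pred_wake & truth == 1)
    tibble(threshold = ct,
           recall = metric_or_na(tp, tp + fn),
           precision = metric_or_na(tp, tp + fp))
  })
  structure(list(
    roc = roc_tbl,
    pr = dplyr::bind_rows(pr_rows),
    auc = as.numeric(pROC::auc(r))
  ), class = "roc_pr")
}
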