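# ggplot2 autoplot() methods for the package's result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   geom_vline geom_step labs theme_minimal facet_wrap geom_boxplot
#'   geom_jitter geom_abline
NULL

#' Plot a threshold sweep curve
#'
#' Kappa, concordance, specificity and sensitivity against the
#' binarization threshold, with the balance-point threshold marked.
#'
#' @param object A [threshold_sweep()] curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot threshold_curve
#' @export
autoplot.threshold_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"threshold",
                              names_to = "metric", values_to = "value")
  thr <- balanced_threshold(object)
  ggplot(long, aes(x = .data$threshold, y = .data$value,
                   colour = .data$metric)) +
    geom_line() +
    geom_vline(xintercept = thr, linetype = "dashed") +
    labs(x = "binarization threshold", y = NULL,
         title = sprintf("Threshold sweep (balance point %.2f)", thr)) +
    theme_minimal()
}

#' Bland-Altman plot
#'
#' Paired differences (reference minus estimate) against pair means,
#' with bias, 1.96 SD limits of agreement and the a-priori clinical
#' band.
#'
#' @param object A [bland_altman()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  pairs <- attr(object, "pairs")
  limit <- attr(object, "limit")
  ggplot(pairs, aes(x = .data$mean, y = .data$diff)) +
    geom_point() +
    geom_hline(yintercept = 0, linetype = "dashed") +
    geom_hline(yintercept = object$bias, colour = "blue") +
    geom_hline(yintercept = c(object$loa_low, object$loa_high),
               colour = "blue", linetype = "dotted") +
    geom_hline(yintercept = c(-limit, limit), colour = "red") +
    labs(x = "pair mean", y = "reference - estimate",
         title = sprintf("Bland-Altman: bias %.2f, LoA [%.2f, %.2f]",
                         object$bias, object$loa_low, object$loa_high)) +
    theme_minimal()
}

#' ROC and precision-recall plot
#'
#' @param object A [roc_pr()] result.
#' @param ... Unused.
#' @return A ggplot object with ROC and PR panels.
#' @method autoplot roc_pr
#' @export
autoplot.roc_pr <- function(object, ...) {
  roc_df <- dplyr::mutate(object$roc, panel = "ROC",
                          x = .data$fpr, y = .data$tpr)
  pr_df <- dplyr::mutate(object$pr, panel = "Precision-Recall",
                         x = .data$recall, y = .data$precision)
  both <- dplyr::bind_rows(roc_df[, c("panel", "x", "y")],
                           pr_df[, c("panel", "x", "y")])
  ggplot(both, aes(x = .data$x, y = .data$y)) +
    geom_line() +
    facet_wrap(~panel, scales = "free") +
    labs(x = NULL, y = NULL,
         title = sprintf("Wake-probability curves (AUC %.3f)", object$auc)) +
    theme_minimal()
}

#' Per-subject LOSO metric distributions
#'
#' @param object A [loso_evaluate()] result.
#' @param metrics Metric columns to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot loso_result
#' @export
autoplot.loso_result <- function(object,
                                 metrics = c("kappa", "f1", "accuracy",
                                             "specificity", "sensitivity"),
                                 ...) {
  long <- tidyr::pivot_longer(object$folds[, c("subject_id", metrics)],
                              -"subject_id", names_to = "metric",
                              values_to = "value")
  ggplot(long, aes(x = .data$metric, y = .data$value)) +
    geom_boxplot(outlier.shape = NA) +
    geom_jitter(width = 0.15, alpha = 0.6) +
    labs(x = NULL, y = NULL,
         title = sprintf("LOSO per-subject metrics (%s)", object$model)) +
    theme_minimal()
}

#' Plot a hypnogram
#'
#' @param object A [hypnogram()].
#' @param ... Unused.
#' @return A ggplot step plot of stage against time.
#' @method autoplot hypnogram
#' @export
autoplot.hypnogram <- function(object, ...) {
  epoch_len <- hypnogram_epoch_len(object)
  df <- tibble(
    hour = (object$epoch_index - 1) * epoch_len / 3600,
    level = as.integer(factor(object$stage,
                              levels = c("N3", "N2", "N1", "REM", "W")))
  )
  ggplot(df, aes(x = .data$hour, y = .data$level)) +
    geom_step() +
    ggplot2::scale_y_continuous(breaks = 1:5,
                                labels = c("N3", "N2", "N1", "REM", "W")) +
    labs(x = "time (h)", y = NULL, title = "Hypnogram") +
    theme_minimal()
}
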