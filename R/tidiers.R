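# broom-style tidy()/glance() methods.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the training history of a fitted lightCNNA
#'
#' @param x A `lightcnna_fit`.
#' @param ... Unused.
#' @return Tibble with one row per training epoch: `epoch`, `loss`,
#'   `val_kappa`.
#' @method tidy lightcnna_fit
#' @export
tidy.lightcnna_fit <- function(x, ...) {
  x$history
}

#' One-row summary of a fitted lightCNNA
#'
#' @param x A `lightcnna_fit`.
#' @param ... Unused.
#' @return Tibble with parameter count, FLOPs (profiler-equivalent
#'   convention), receptive field, epochs trained, final loss and
#'   final validation kappa.
#' @method glance lightcnna_fit
#' @export
glance.lightcnna_fit <- function(x, ...) {
  tibble(
    n_params = count_params(x$spec),
    flops = count_flops(x$spec, "profiler_equivalent"),
    receptive_field = receptive_field(x$spec),
    input_len = x$spec$input_len,
    epochs_trained = nrow(x$history),
    final_loss = tail(x$history$loss, 1),
    val_kappa = tail(x$history$val_kappa, 1),
    threshold = x$threshold
  )
}

#' Per-subject fold metrics of a LOSO run
#'
#' @param x A `loso_result`.
#' @param ... Unused.
#' @return The per-fold metric tibble (one row per held-out subject).
#' @method tidy loso_result
#' @export
tidy.loso_result <- function(x, ...) {
  x$folds
}

#' Across-subject summary of a LOSO run
#'
#' @param x A `loso_result`.
#' @param ... Unused.
#' @return One-row tibble with the model name, fold count and
#'   median/MAD of the headline epoch metrics.
#' @method glance loso_result
#' @export
glance.loso_result <- function(x, ...) {
  s <- x$summary
  out <- tibble(model = x$model, n_folds = nrow(x$folds))
  for (i in seq_len(nrow(s))) {
    out[[paste0(s$metric[i], "_median")]] <- s$median[i]
    out[[paste0(s$metric[i], "_mad")]] <- s$mad[i]
  }
  out
}

#' Tidy a group comparison
#'
#' @param x A [group_compare()] result.
#' @param ... Unused.
#' @return The pairwise comparison tibble.
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) {
  x$pairwise
}

#' Omnibus summary of a group comparison
#'
#' @param x A [group_compare()] result.
#' @param ... Unused.
#' @return One-row tibble with the omnibus method, statistic and p.
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  x$omnibus
}
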