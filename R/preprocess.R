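#' Decimate a recording without filtering
#'
#' Keeps every `factor`-th sample starting at the first, with no
#' anti-alias filtering or interpolation -- the point is to emulate a
#' genuinely slower accelerometer, not to resample cleanly. The nominal
#' rate is divided by `factor`; output length is `ceiling(n / factor)`.
#'
#' A factor of 12 from a ~99.7 Hz device yields the 8.3 Hz operating
#' point at which the classifier performs best.
#'
#' @param recording An [accel_recording()].
#' @param factor Positive integer decimation factor.
#' @return A decimated [accel_recording()].
#' @export
decimate_recording <- function(recording, factor) {
  if (!is_count(factor)) {
    abort_actisleep("decimation factor must be a positive integer",
                    "actisleep_invalid_argument")
  }
  if (factor == 1) return(recording)
  keep <- seq(1, nrow(recording), by = factor)
  out <- recording[keep, ]
  attr(out, "nominal_rate_hz") <- accel_rate(recording) / factor
  attr(out, "resolution_bits") <- attr(recording, "resolution_bits")
  attr(out, "start_time") <- attr(recording, "start_time")
  attr(out, "dynamic_range_g") <- attr(recording, "dynamic_range_g")
  class(out) <- unique(c("accel_recording", class(out)))
  out
}

#' Fit a per-channel min-max scaler
#'
#' Maps each channel's observed minimum to -1 and maximum to +1 (the
#' same affine map as the usual machine-learning min-max scaler, with
#' feature range \[-1, 1\]). Fitting is per recording, so per-device
#' offsets drop out and the transform is implementable on-device.
#'
#' @param recording An [accel_recording()] (or any data frame with the
#'   `x_g`, `y_g`, `z_g` columns).
#' @return A tibble with columns `channel`, `min`, `max` of class
#'   `minmax_scaler`.
#' @export
fit_minmax <- function(recording) {
  if (nrow(recording) == 0) {
    abort_actisleep("cannot fit a scaler on an empty recording",
                    "actisleep_invalid_argument")
  }
  chans <- c("x_g", "y_g", "z_g")
  out <- tibble(
    channel = chans,
    min = vapply(chans, function(ch) min(recording[[ch]]), numeric(1)),
    max = vapply(chans, function(ch) max(recording[[ch]]), numeric(1))
  )
  class(out) <- c("minmax_scaler", class(out))
  out
}

#' Apply a fitted min-max scaler
#'
#' A constant channel (max == min) is mapped to all zeros, the midpoint
#' of the target range.
#'
#' @param recording An [accel_recording()].
#' @param scaler A scaler from [fit_minmax()].
#' @return The recording with channels affinely mapped into \[-1, 1\].
#' @export
apply_minmax <- function(recording, scaler) {
  out <- recording
  for (i in seq_len(nrow(scaler))) {
    ch <- scaler$channel[i]
    lo <- scaler$min[i]
    hi <- scaler$max[i]
    if (hi > lo) {
      out[[ch]] <- 2 * (recording[[ch]] - lo) / (hi - lo) - 1
    } else {
      out[[ch]] <- rep(0, nrow(recording))
    }
  }
  out
}

#' Cut a recording into per-epoch context windows
#'
#' For each scored epoch `k` the window holds the samples of epochs
#' `k-1, k, k+1` -- a 90-s context block of fixed length `L = 3 *
#' round(epoch_len_s * rate)` samples. The first and last epochs lack a
#' neighbour; their missing 30-s block is filled by replicating the edge
#' epoch, and such windows are flagged `edge` so training can drop them
#' while inference still yields one prediction per scored epoch.
#'
#' @param recording An [accel_recording()] covering the hypnogram span
#'   (up to one epoch of slack at the end is tolerated and padded).
#' @param hypnogram A [hypnogram()].
#' @param subject_id Optional subject identifier carried into the
#'   window metadata.
#' @return An object of class `windowed_epochs`: list with `windows`
#'   (array `[n_epochs, L, 3]`), `meta` (tibble with `subject_id`,
#'   `epoch_index`, `label` (1 = wake), `edge`), `window_len` and
#'   `rate_hz`.
#' @export
window_epochs <- function(recording, hypnogram, subject_id = NA_character_) {
  rate <- accel_rate(recording)
  epoch_len <- hypnogram_epoch_len(hypnogram)
  n_ep <- nrow(hypnogram)
  spe <- round(epoch_len * rate) # samples per epoch (frozen integer)
  L <- 3L * spe
  n <- nrow(recording)
  expected <- round(n_ep * epoch_len * rate)
  if (n < expected - spe || n > expected + spe) {
    abort_actisleep(
      sprintf(paste0("recording length (%d samples) does not match the ",
                     "hypnogram span (expected ~%d) within one epoch"),
              n, expected),
      "actisleep_invalid_argument")
  }
  sig <- accel_matrix(recording)
  labels <- stage_to_wake(hypnogram)
  windows <- array(0, dim = c(n_ep, L, 3))
  for (k in seq_len(n_ep)) {
    # True clock boundary of epoch k-1 (0-based sample index), so that
    # fractional samples-per-epoch do not accumulate drift over the night.
    b_prev <- round((k - 2) * epoch_len * rate)
    idx <- b_prev + seq_len(L)
    # Edge replication: indices before the first sample re-use the first
    # epoch's block; indices beyond the end re-use the last epoch's block.
    idx[idx < 1] <- idx[idx < 1] + spe
    idx[idx > n] <- idx[idx > n] - spe
    idx <- pmax(1L, pmin(n, idx))
    windows[k, , ] <- sig[idx, ]
  }
  structure(list(
    windows = windows,
    meta = tibble(
      subject_id = subject_id,
      epoch_index = seq_len(n_ep),
      label = labels,
      edge = seq_len(n_ep) %in% c(1L, n_ep)
    ),
    window_len = L,
    rate_hz = rate
  ), class = "windowed_epochs")
}

#' @export
print.windowed_epochs <- function(x, ...) {
  cat(sprintf(
    "<windowed_epochs> %d windows of %d samples x 3 channels @ %.3f Hz (%d wake)\n",
    nrow(x$meta), x$window_len, x$rate_hz, sum(x$meta$label)))
  invisible(x)
}

#' Combine windowed datasets from several subjects
#'
#' @param datasets List of `windowed_epochs` objects with identical
#'   window length.
#' @param drop_edges Drop edge-replicated windows (recommended for
#'   training sets)?
#' @return A single `windowed_epochs` object.
#' @export
bind_windows <- function(datasets, drop_edges = FALSE) {
  if (length(datasets) == 0) {
    abort_actisleep("need at least one dataset", "actisleep_invalid_argument")
  }
  Ls <- vapply(datasets, function(d) d$window_len, numeric(1))
  if (length(unique(Ls)) != 1) {
    abort_actisleep("window lengths differ across datasets",
                    "actisleep_invalid_argument")
  }
  keep <- lapply(datasets, function(d) {
    if (drop_edges) which(!d$meta$edge) else seq_len(nrow(d$meta))
  })
  windows <- do.call(abind1, Map(function(d, k) {
    d$windows[k, , , drop = FALSE]
  }, datasets, keep))
  meta <- dplyr::bind_rows(Map(function(d, k) d$meta[k, ], datasets, keep))
  structure(list(
    windows = windows,
    meta = meta,
    window_len = datasets[[1]]$window_len,
    rate_hz = datasets[[1]]$rate_hz
  ), class = "windowed_epochs")
}

# rbind for 3-D arrays along the first dimension.
abind1 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  n <- sum(vapply(parts, function(p) dim(p)[1], numeric(1)))
  out <- array(0, dim = c(n, d[2], d[3]))
  at <- 0
  for (p in parts) {
    np <- dim(p)[1]
    if (np > 0) out[at + seq_len(np), , ] <- p
    at <- at + np
  }
  out
}

subset_windows <- function(ds, idx) {
  structure(list(
    windows = ds$windows[idx, , , drop = FALSE],
    meta = ds$meta[idx, ],
    window_len = ds$window_len,
    rate_hz = ds$rate_hz
  ), class = "windowed_epochs")
}

#' Chunk-and-shuffle a training stream
#'
#' Partitions the window sequence into fixed-length chunks and shuffles
#' the chunks (a bias-reduction step applied before every training
#' epoch). Every window is preserved exactly once; the permutation is a
#' deterministic function of `(seed, training_epoch)`.
#'
#' @param dataset A `windowed_epochs` object (or list of them, combined
#'   with edge windows dropped).
#' @param seed Base seed of the training run.
#' @param training_epoch 1-based index of the training epoch, folded
#'   into the stream seed so successive epochs see different orders.
#' @param chunk_len Number of consecutive windows per chunk.
#' @return The dataset with windows permuted.
#' @export
chunk_and_shuffle <- function(dataset, seed = 1L, training_epoch = 1L,
                              chunk_len = 64L) {
  if (is.list(dataset) && !inherits(dataset, "windowed_epochs")) {
    dataset <- bind_windows(dataset, drop_edges = TRUE)
  }
  n <- nrow(dataset$meta)
  chunk_id <- ceiling(seq_len(n) / chunk_len)
  ord <- with_seed(derive_seed(seed, training_epoch), {
    perm <- sample(unique(chunk_id))
    unlist(lapply(perm, function(cid) which(chunk_id == cid)), use.names = FALSE)
  })
  subset_windows(dataset, ord)
}
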