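# Shared fixtures: everything is generated in code at test time.

# A small, fast synthetic configuration: short recordings at a reduced
# native rate (25 Hz, decimated by 3 to ~8.3 Hz) so windows keep the
# canonical 750-sample length while cohorts stay light.
tiny_synth_config <- function(n_subjects = 2, seed = 7, ...) {
  synth_config(n_subjects = n_subjects,
               duration_h_mean = 1, duration_h_sd = 0.01,
               sample_rate_hz = 25, seed = seed, ...)
}

tiny_cohort <- local({
  cache <- new.env(parent = emptyenv())
  function(n_subjects = 2, seed = 7) {
    key <- paste(n_subjects, seed, sep = "_")
    if (is.null(cache[[key]])) {
      cache[[key]] <- generate_cohort(tiny_synth_config(n_subjects, seed))
    }
    cache[[key]]
  }
})

# Windowed toy problem with a clean variance signature: sleep windows
# are low-amplitude noise, wake windows high-amplitude. Window length 80
# (just above the canonical 71-sample receptive field) keeps the CNN fast.
toy_windowed <- function(n = 60, L = 80, seed = 1, wake_sd = 0.5,
                         sleep_sd = 0.05, subject_id = "T01") {
  set.seed(seed)
  labels <- rep(c(0L, 1L), length.out = n)
  windows <- array(0, dim = c(n, L, 3))
  for (i in seq_len(n)) {
    s <- if (labels[i] == 1) wake_sd else sleep_sd
    windows[i, , ] <- matrix(rnorm(L * 3, sd = s), L, 3)
  }
  structure(list(
    windows = windows,
    meta = tibble::tibble(subject_id = subject_id, epoch_index = seq_len(n),
                          label = labels,
                          edge = seq_len(n) %in% c(1L, n)),
    window_len = L,
    rate_hz = 8.3
  ), class = "windowed_epochs")
}

# Straight-loop (no vectorization) reference forward pass: the oracle
# against which the batched implementation is gated. Written directly
# from the architecture definition with scalar loops only.
oracle_forward <- function(weights, window) {
  spec <- attr(weights, "spec")
  H <- window # [L, C]
  for (l in seq_len(spec$n_conv_layers)) {
    W <- weights[[paste0("conv", l, "_kernel")]]
    k <- dim(W)[1]; Cin <- dim(W)[2]; Fo <- dim(W)[3]
    d <- spec$dilation_rates[l]
    Tout <- nrow(H) - (k - 1) * d
    Z <- matrix(0, Tout, Fo)
    for (t in seq_len(Tout)) {
      for (f in seq_len(Fo)) {
        acc <- 0
        for (j in seq_len(k)) {
          for (c in seq_len(Cin)) {
            acc <- acc + H[t + (j - 1) * d, c] * W[j, c, f]
          }
        }
        if (spec$conv_bias) {
          acc <- acc + weights[[paste0("conv", l, "_bias")]][f]
        }
        Z[t, f] <- max(acc, 0)
      }
    }
    H <- Z
  }
  pooled <- numeric(ncol(H))
  for (f in seq_len(ncol(H))) pooled[f] <- mean(H[, f])
  dense <- numeric(spec$dense_units)
  for (u in seq_len(spec$dense_units)) {
    acc <- 0
    for (f in seq_along(pooled)) {
      acc <- acc + pooled[f] * weights$dense_kernel[f, u]
    }
    if (spec$dense_bias) acc <- acc + weights$dense_bias[u]
    dense[u] <- max(acc, 0)
  }
  z <- 0
  for (u in seq_len(spec$dense_units)) {
    z <- z + dense[u] * weights$output_kernel[u, 1]
  }
  if (spec$output_bias) z <- z + as.numeric(weights$output_bias)
  1 / (1 + exp(-z))
}
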