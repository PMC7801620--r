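#' Five-state hypnogram stage alphabet
#'
#' AASM scoring assigns each non-overlapping 30-s epoch one of five
#' behavioral states: waking plus the N1/N2/N3 NREM stages and REM sleep.
#'
#' @export
STAGE_LEVELS <- c("W", "N1", "N2", "N3", "REM")

#' Construct a triaxial acceleration recording
#'
#' A recording is a tibble with columns `time_s` (seconds from recording
#' start, strictly increasing), `x_g`, `y_g`, `z_g` (acceleration in g),
#' carrying the nominal sampling rate, ADC resolution and an ISO-8601
#' start-time anchor as attributes.
#'
#' @param data Data frame with columns `time_s`, `x_g`, `y_g`, `z_g`.
#' @param nominal_rate_hz Nominal sampling rate in Hz.
#' @param resolution_bits ADC resolution in bits (the signal lives on a
#'   signed grid of `2^resolution_bits` levels over the dynamic range).
#' @param start_time ISO-8601 timestamp of the first sample.
#' @param dynamic_range_g Half-width of the accelerometer's dynamic range
#'   in g (quantizer grid spans `[-dynamic_range_g, +dynamic_range_g)`).
#' @return A tibble of class `accel_recording`.
#' @export
accel_recording <- function(data, nominal_rate_hz, resolution_bits = 10,
                            start_time = "1970-01-01T00:00:00Z",
                            dynamic_range_g = 4) {
  need <- c("time_s", "x_g", "y_g", "z_g")
  if (!all(need %in% names(data))) {
    abort_actisleep(
      paste0("recording must have columns ", paste(need, collapse = ", ")),
      "actisleep_format_error")
  }
  if (nrow(data) == 0) {
    abort_actisleep("recording has no samples", "actisleep_format_error")
  }
  if (any(diff(data$time_s) <= 0)) {
    bad <- which(diff(data$time_s) <= 0)[1] + 1
    abort_actisleep(
      sprintf("timestamps are not strictly increasing at row %d", bad),
      "actisleep_format_error")
  }
  out <- as_tibble(data[need])
  attr(out, "nominal_rate_hz") <- nominal_rate_hz
  attr(out, "resolution_bits") <- resolution_bits
  attr(out, "start_time") <- start_time
  attr(out, "dynamic_range_g") <- dynamic_range_g
  class(out) <- c("accel_recording", class(out))
  out
}

#' Sampling rate of a recording
#'
#' Returns the stored nominal rate, or (if the attribute has been stripped
#' by data-frame manipulation) the median reciprocal inter-sample interval.
#'
#' @param recording An [accel_recording()].
#' @return Rate in Hz.
#' @export
accel_rate <- function(recording) {
  r <- attr(recording, "nominal_rate_hz")
  if (!is.null(r)) return(r)
  median(1 / diff(recording$time_s))
}

accel_matrix <- function(recording) {
  as.matrix(recording[, c("x_g", "y_g", "z_g")])
}

#' Construct a hypnogram
#'
#' A hypnogram is a tibble with one row per scored 30-s epoch: columns
#' `epoch_index` (1-based) and `stage` (factor over
#' `W, N1, N2, N3, REM`).
#'
#' @param stages Character or factor vector of stage labels.
#' @param epoch_len_s Epoch length in seconds (30 under AASM scoring).
#' @param start_time ISO-8601 timestamp of the first epoch's start.
#' @return A tibble of class `hypnogram`.
#' @export
hypnogram <- function(stages, epoch_len_s = 30,
                      start_time = "1970-01-01T00:00:00Z") {
  stages <- toupper(as.character(stages))
  if (length(stages) == 0) {
    abort_actisleep("hypnogram must contain at least one epoch",
                    "actisleep_format_error")
  }
  bad <- setdiff(unique(stages), STAGE_LEVELS)
  if (length(bad) > 0) {
    abort_actisleep(
      sprintf("unknown stage label(s): %s", paste(bad, collapse = ", ")),
      "actisleep_format_error")
  }
  out <- tibble(
    epoch_index = seq_along(stages),
    stage = factor(stages, levels = STAGE_LEVELS)
  )
  attr(out, "epoch_len_s") <- epoch_len_s
  attr(out, "start_time") <- start_time
  class(out) <- c("hypnogram", class(out))
  out
}

#' Collapse hypnogram stages to binary wake indicators
#'
#' @param stages A hypnogram tibble or a vector of stage labels.
#' @return Integer vector, 1 = wake, 0 = sleep (any of N1/N2/N3/REM).
#' @export
stage_to_wake <- function(stages) {
  if (is.data.frame(stages)) stages <- stages$stage
  as.integer(toupper(as.character(stages)) == "W")
}

hypnogram_epoch_len <- function(hyp) {
  len <- attr(hyp, "epoch_len_s")
  if (is.null(len)) 30 else len
}
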