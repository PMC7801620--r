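# CSV readers/writers for recordings and hypnograms, nearest-sample
# clock alignment, and the weight container + flat text export for
# OS-less deployment targets. Readers reject malformed input rather
# than silently repairing it.

#' Write a recording to CSV
#'
#' Columns `time_s, x_g, y_g, z_g`; metadata (ISO-8601 start anchor,
#' nominal rate, resolution, dynamic range) goes into `#`-prefixed
#' header comments.
#'
#' @param recording An [accel_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_accel_csv <- function(recording, path) {
  hdr <- c(
    sprintf("# start_time: %s", attr(recording, "start_time") %||% ""),
    sprintf("# nominal_rate_hz: %.10g", accel_rate(recording)),
    sprintf("# resolution_bits: %d",
            as.integer(attr(recording, "resolution_bits") %||% 10)),
    sprintf("# dynamic_range_g: %.10g",
            attr(recording, "dynamic_range_g") %||% 4)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("time_s,x_g,y_g,z_g", con)
  writeLines(sprintf("%.17g,%.17g,%.17g,%.17g", recording$time_s,
                     recording$x_g, recording$y_g, recording$z_g), con)
  invisible(path)
}

read_header_comments <- function(path) {
  lines <- character(0)
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    l <- readLines(con, n = 1)
    if (length(l) == 0 || !startsWith(l, "#")) break
    lines <- c(lines, l)
  }
  out <- list()
  for (l in lines) {
    m <- regmatches(l, regexec("^#\\s*([a-z_]+):\\s*(.*)$", l))[[1]]
    if (length(m) == 3) out[[m[2]]] <- m[3]
  }
  out
}

#' Read a recording from CSV
#'
#' Enforces the four documented columns and strictly monotone
#' timestamps (a duplicated timestamp is a format error naming the
#' row). The nominal rate is taken from the header comment when
#' present, otherwise estimated as the median reciprocal inter-sample
#' interval.
#'
#' @param path CSV file written by [write_accel_csv()] (or compatible).
#' @return An [accel_recording()].
#' @export
read_accel_csv <- function(path) {
  if (!file.exists(path)) {
    abort_actisleep(sprintf("file not found: %s", path),
                    "actisleep_format_error")
  }
  hdr <- read_header_comments(path)
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  need <- c("time_s", "x_g", "y_g", "z_g")
  if (!all(need %in% names(df))) {
    abort_actisleep(
      sprintf("missing column(s): %s",
              paste(setdiff(need, names(df)), collapse = ", ")),
      "actisleep_format_error")
  }
  for (col in need) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad) > 0) {
      abort_actisleep(
        sprintf("unparseable value in column %s at data row %d", col, bad[1]),
        "actisleep_format_error")
    }
  }
  rate <- if (!is.null(hdr$nominal_rate_hz)) as.numeric(hdr$nominal_rate_hz)
          else median(1 / diff(df$time_s))
  accel_recording(
    df,
    nominal_rate_hz = rate,
    resolution_bits = as.integer(hdr$resolution_bits %||% 10),
    start_time = hdr$start_time %||% "1970-01-01T00:00:00Z",
    dynamic_range_g = as.numeric(hdr$dynamic_range_g %||% 4)
  )
}

#' Write a hypnogram to CSV
#'
#' Columns `epoch_index, stage`; epoch length and start anchor in
#' header comments.
#'
#' @param hypnogram A [hypnogram()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hypnogram_csv <- function(hypnogram, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# start_time: %s", attr(hypnogram, "start_time") %||% ""),
    sprintf("# epoch_len_s: %d", as.integer(hypnogram_epoch_len(hypnogram))),
    "epoch_index,stage"
  ), con)
  writeLines(sprintf("%d,%s", hypnogram$epoch_index,
                     as.character(hypnogram$stage)), con)
  invisible(path)
}

BINARY_SLEEP_LABELS <- c("S", "SLEEP", "1")
BINARY_WAKE_LABELS <- c("WAKE", "0")

#' Read a hypnogram from CSV
#'
#' Accepts five-state (`W/N1/N2/N3/REM`, any case) or binary
#' (`sleep/wake`, `S/W`, `1/0`) label files. Binary files are promoted
#' to five-state form with sleep mapped to the `N2` placeholder and the
#' result flagged with attribute `promoted_from_binary`. Unknown labels
#' and empty files are format errors.
#'
#' @param path CSV with columns `epoch_index, stage` (header comments
#'   allowed).
#' @return A [hypnogram()].
#' @export
read_hypnogram_csv <- function(path) {
  if (!file.exists(path)) {
    abort_actisleep(sprintf("file not found: %s", path),
                    "actisleep_format_error")
  }
  hdr <- read_header_comments(path)
  df <- tryCatch(
    readr::read_csv(path, comment = "#", show_col_types = FALSE,
                    progress = FALSE,
                    col_types = readr::cols(.default = readr::col_character())),
    error = function(e) NULL)
  if (is.null(df) || nrow(df) == 0 || !all(c("epoch_index", "stage") %in% names(df))) {
    abort_actisleep("empty or malformed hypnogram file",
                    "actisleep_format_error")
  }
  labels <- toupper(trimws(df$stage))
  promoted <- FALSE
  if (any(labels %in% c(BINARY_SLEEP_LABELS, BINARY_WAKE_LABELS))) {
    unknown <- setdiff(unique(labels),
                       c(BINARY_SLEEP_LABELS, BINARY_WAKE_LABELS, "W"))
    if (length(unknown) > 0) {
      abort_actisleep(
        sprintf("unknown label(s): %s", paste(unknown, collapse = ", ")),
        "actisleep_format_error")
    }
    labels <- ifelse(labels %in% BINARY_SLEEP_LABELS, "N2", "W")
    promoted <- TRUE
  }
  out <- hypnogram(labels,
                   epoch_len_s = as.integer(hdr$epoch_len_s %||% 30),
                   start_time = hdr$start_time %||% "1970-01-01T00:00:00Z")
  attr(out, "promoted_from_binary") <- promoted
  out
}

#' Align a recording to a reference scoring clock
#'
#' Finds the recording samples nearest the reference start and stop
#' timestamps (no interpolation; an equidistant tie resolves to the
#' earlier sample). Because the reference clock has one-second
#' resolution, the reported maximum synchronization error is 2 s.
#'
#' @param recording An [accel_recording()].
#' @param ref_start,ref_stop Reference interval bounds, in the same
#'   seconds-from-start scale as `recording$time_s`.
#' @return List of class `alignment_result`: `start_index`,
#'   `stop_index` (1-based sample indices), `max_error_s = 2`.
#' @export
align_to_reference <- function(recording, ref_start, ref_stop) {
  t <- recording$time_s
  if (ref_stop < t[1] || ref_start > t[length(t)]) {
    abort_actisleep("reference interval does not overlap the recording",
                    "actisleep_alignment_error")
  }
  if (ref_start >= ref_stop) {
    abort_actisleep("ref_start must precede ref_stop",
                    "actisleep_alignment_error")
  }
  nearest <- function(x) {
    i <- findInterval(x, t, all.inside = TRUE)
    # candidates i and i+1; tie -> earlier sample
    if (i < length(t) && abs(t[i + 1] - x) < abs(t[i] - x)) i + 1L else i
  }
  start_index <- nearest(ref_start)
  stop_index <- nearest(ref_stop)
  if (start_index >= stop_index) {
    abort_actisleep("aligned interval is empty", "actisleep_alignment_error")
  }
  structure(list(start_index = start_index, stop_index = stop_index,
                 max_error_s = 2), class = "alignment_result")
}

spec_fingerprint <- function(spec) {
  fields <- spec[c("input_len", "n_conv_layers", "filters", "kernel_size",
                   "dilation_rates", "conv_bias", "dense_bias", "output_bias",
                   "dense_units", "input_channels")]
  fnv1a32(paste(vapply(fields, function(f) paste(f, collapse = ","),
                       character(1)), collapse = ";"))
}

WEIGHT_FORMAT_VERSION <- 1L

#' Write a weight set to a text container
#'
#' A JSON file holding the format version, the architecture fingerprint
#' and spec, and every tensor (in serialization order) with its shape
#' and values serialized as `%.17g` strings, so the round trip is
#' bit-exact.
#'
#' @param weights A `lightcnna_weights` set.
#' @param path Output file path.
#' @param spec The matching [lightcnna_spec()] (defaults to the one
#'   attached to the weights).
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path, spec = attr(weights, "spec")) {
  payload <- list(
    format_version = WEIGHT_FORMAT_VERSION,
    fingerprint = spec_fingerprint(spec),
    spec = unclass(spec),
    tensors = lapply(names(weights), function(nm) {
      list(name = nm, shape = dim(weights[[nm]]),
           values = sprintf("%.17g", as.numeric(weights[[nm]])))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a weight set from a text container
#'
#' @param path File written by [write_weights()].
#' @param spec Optional [lightcnna_spec()] to check the stored
#'   fingerprint against; a mismatch is an incompatibility error.
#' @return A `lightcnna_weights` set.
#' @export
read_weights <- function(path, spec = NULL) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  stored_spec <- payload$spec
  stored_spec$dilation_rates <- as.integer(stored_spec$dilation_rates)
  class(stored_spec) <- "lightcnna_spec"
  if (!is.null(spec) && spec_fingerprint(spec) != payload$fingerprint) {
    abort_actisleep(
      "stored weights were trained for a different architecture (fingerprint mismatch)",
      "actisleep_incompatibility_error")
  }
  weights <- lapply(payload$tensors, function(tn) {
    array(as.numeric(tn$values), dim = as.integer(tn$shape))
  })
  names(weights) <- vapply(payload$tensors, function(tn) tn$name, character(1))
  attr(weights, "spec") <- if (is.null(spec)) stored_spec else spec
  class(weights) <- "lightcnna_weights"
  weights
}

#' Export weights as a flat decimal text array
#'
#' The deployment format for targets without an operating system: one
#' `%.17g` value per line in the documented concatenation order
#' (layer-major, then filter-major, then channel-major within each
#' kernel tap), preceded by `#` shape-header lines. The number of data
#' lines equals the trainable-parameter count (1361 for the canonical
#' architecture).
#'
#' @param weights A `lightcnna_weights` set.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_flat_array <- function(weights, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(weights)) {
    writeLines(sprintf("# %s shape: %s", nm,
                       paste(dim(weights[[nm]]), collapse = "x")), con)
  }
  for (nm in names(weights)) {
    w <- weights[[nm]]
    if (length(dim(w)) == 3) {
      # filter-major, channel-major, tap last: v[f, c, j] stream
      vals <- as.numeric(aperm(w, c(3, 2, 1)))
    } else {
      vals <- as.numeric(w)
    }
    writeLines(sprintf("%.17g", vals), con)
  }
  invisible(path)
}
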