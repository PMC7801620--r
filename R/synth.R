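#' Synthetic actigraphy cohort configuration
#'
#' Parameters of the generative model used to emulate overnight wrist
#' actigraphy with concurrent reference scoring. Defaults reproduce the
#' acquisition conditions of ambulatory studies with open-source
#' actigraphs: ~14.3 h recordings sampled near 99.7 Hz at 10-bit
#' resolution, sleep/wake bouts on a 30-s epoch grid with brief
#' awakenings, and wake movement bursts confined to the 0.6-8 Hz band of
#' voluntary human movement.
#'
#' @param n_subjects Number of subjects in the cohort.
#' @param duration_h_mean,duration_h_sd Mean and SD of per-subject
#'   recording duration in hours (cohort durations are normal, truncated
#'   below at 1 h).
#' @param sample_rate_hz Accelerometer sampling rate in Hz.
#' @param resolution_bits ADC resolution; samples are quantized to a
#'   signed grid of `2^resolution_bits` levels over
#'   `[-dynamic_range_g, +dynamic_range_g)`.
#' @param epoch_len_s Scoring epoch length in seconds (fixed at 30).
#' @param mean_sleep_bout_epochs,mean_wake_bout_epochs Mean lengths (in
#'   epochs) of the geometric sleep and wake bouts of the alternating
#'   two-super-state process.
#' @param brief_awakening_rate Poisson rate (per hour of sleep) of brief
#'   1-3 epoch wake insertions inside sleep.
#' @param burst_rate_per_wake_epoch Poisson mean number of movement
#'   bursts per wake epoch.
#' @param burst_band_hz Length-2 numeric, the passband (Hz) of movement
#'   bursts; must sit below the Nyquist frequency.
#' @param burst_amp_g Typical burst amplitude in g.
#' @param tremor_amp_g Amplitude (g) of the continuous low-level
#'   band-limited motion present throughout wake epochs.
#' @param noise_amp_g Sensor white-noise SD in g.
#' @param posture_shift_rate Poisson rate (per hour) of full gravity-vector
#'   re-orientations (posture shifts during sleep and wake).
#' @param orientation_wander Scale of the persistent wrist re-orientation
#'   left behind by each wake movement burst (perturbation SD of the unit
#'   gravity vector; ~0.2 corresponds to a typical ~10 degree change).
#'   Wake therefore carries many small orientation steps while sleep
#'   posture stays stable between shifts, as on a real wrist.
#' @param dynamic_range_g Quantizer half-range in g.
#' @param seed Master seed; per-subject seeds are derived via
#'   [derive_seed()].
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 8,
                         duration_h_mean = 14.3,
                         duration_h_sd = 2.2,
                         sample_rate_hz = 99.7,
                         resolution_bits = 10,
                         epoch_len_s = 30,
                         mean_sleep_bout_epochs = 90,
                         mean_wake_bout_epochs = 40,
                         brief_awakening_rate = 2,
                         burst_rate_per_wake_epoch = 1.5,
                         burst_band_hz = c(0.6, 8),
                         burst_amp_g = 0.3,
                         tremor_amp_g = 0.02,
                         noise_amp_g = 0.01,
                         posture_shift_rate = 2,
                         orientation_wander = 0.2,
                         dynamic_range_g = 4,
                         seed = 1L) {
  cfg <- list(
    n_subjects = n_subjects,
    duration_h_mean = duration_h_mean,
    duration_h_sd = duration_h_sd,
    sample_rate_hz = sample_rate_hz,
    resolution_bits = resolution_bits,
    epoch_len_s = epoch_len_s,
    mean_sleep_bout_epochs = mean_sleep_bout_epochs,
    mean_wake_bout_epochs = mean_wake_bout_epochs,
    brief_awakening_rate = brief_awakening_rate,
    burst_rate_per_wake_epoch = burst_rate_per_wake_epoch,
    burst_band_hz = burst_band_hz,
    burst_amp_g = burst_amp_g,
    tremor_amp_g = tremor_amp_g,
    noise_amp_g = noise_amp_g,
    posture_shift_rate = posture_shift_rate,
    orientation_wander = orientation_wander,
    dynamic_range_g = dynamic_range_g,
    seed = seed
  )
  validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

validate_synth_config <- function(cfg) {
  if (!is_count(cfg$n_subjects)) {
    abort_actisleep("n_subjects must be a positive integer",
                    "actisleep_invalid_argument")
  }
  if (cfg$duration_h_mean <= 0) {
    abort_actisleep("duration must be positive", "actisleep_invalid_argument")
  }
  if (cfg$sample_rate_hz <= 0) {
    abort_actisleep("sample_rate_hz must be positive",
                    "actisleep_invalid_argument")
  }
  if (!is_count(cfg$resolution_bits)) {
    abort_actisleep("resolution_bits must be >= 1",
                    "actisleep_invalid_argument")
  }
  b <- cfg$burst_band_hz
  if (length(b) != 2 || b[1] <= 0 || b[1] >= b[2] ||
      b[2] > cfg$sample_rate_hz / 2) {
    abort_actisleep(
      "burst_band_hz must satisfy 0 < low < high <= sample_rate/2",
      "actisleep_invalid_argument")
  }
  rates <- c(cfg$brief_awakening_rate, cfg$burst_rate_per_wake_epoch,
             cfg$posture_shift_rate)
  if (any(rates < 0)) {
    abort_actisleep("rates must be >= 0", "actisleep_invalid_argument")
  }
  if (cfg$mean_sleep_bout_epochs < 1 || cfg$mean_wake_bout_epochs < 1) {
    abort_actisleep("mean bout lengths must be >= 1 epoch",
                    "actisleep_invalid_argument")
  }
  invisible(cfg)
}

# Geometric bout length on {1, 2, ...} with the given mean; an infinite
# mean never leaves the current state.
rbout <- function(mean_epochs) {
  if (!is.finite(mean_epochs)) return(Inf)
  rgeom(1, prob = 1 / mean_epochs) + 1
}

# Cyclic NREM/REM filling pattern for sleep bouts: descent through N1-N3,
# lightening, then REM -- a minimal caricature of the ultradian cycle.
SLEEP_CYCLE <- c("N1", "N2", "N2", "N3", "N3", "N3", "N2", "N2", "REM", "REM")

#' Simulate a reference hypnogram
#'
#' Draws a two-super-state (sleep block vs wake block) semi-Markov
#' sequence with geometric bout lengths, starting in wake (pre-onset) and
#' ending with wake (post-offset). Sleep blocks are filled with
#' N1/N2/N3/REM substates by a fixed cyclic scheme, and brief 1-3 epoch
#' awakenings are inserted into sleep at a Poisson rate.
#'
#' @param config A [synth_config()].
#' @param duration_epochs Number of 30-s epochs to simulate.
#' @param seed Optional seed overriding `config$seed`.
#' @return A [hypnogram()] tibble.
#' @export
simulate_hypnogram <- function(config, duration_epochs, seed = NULL) {
  validate_synth_config(config)
  if (!is_count(duration_epochs)) {
    abort_actisleep("duration_epochs must be a positive integer",
                    "actisleep_invalid_argument")
  }
  seed <- if (is.null(seed)) config$seed else seed
  with_seed(seed, {
    n <- as.integer(duration_epochs)
    stages <- character(n)
    pos <- 1L
    state <- "W" # recordings begin with pre-onset wake
    while (pos <= n) {
      len <- rbout(if (state == "W") config$mean_wake_bout_epochs
                   else config$mean_sleep_bout_epochs)
      len <- min(len, n - pos + 1)
      idx <- pos:(pos + len - 1)
      if (state == "W") {
        stages[idx] <- "W"
      } else {
        stages[idx] <- rep_len(SLEEP_CYCLE, len)
      }
      pos <- pos + len
      state <- if (state == "W") "SLEEP" else "W"
    }
    # Brief awakenings: Poisson count over total sleep time, 1-3 epochs each.
    sleep_idx <- which(stages != "W")
    if (length(sleep_idx) > 0 && config$brief_awakening_rate > 0) {
      sleep_hours <- length(sleep_idx) * config$epoch_len_s / 3600
      n_bw <- rpois(1, config$brief_awakening_rate * sleep_hours)
      if (n_bw > 0) {
        starts <- sample(sleep_idx, min(n_bw, length(sleep_idx)))
        for (s in starts) {
          len <- sample(1:3, 1)
          stages[s:min(n, s + len - 1)] <- "W"
        }
      }
    }
    # Post-offset wake: the recording always ends out of bed.
    stages[n] <- "W"
    hypnogram(stages, epoch_len_s = config$epoch_len_s)
  })
}

# White noise band-passed to `band` Hz with a 4th-order Butterworth,
# rescaled to unit SD. Consumes the current RNG stream.
bandlimited_noise <- function(n, rate_hz, band) {
  w <- rnorm(n)
  ny <- rate_hz / 2
  bf <- signal::butter(4, pmin(band / ny, 0.999), type = "pass")
  y <- as.numeric(signal::filter(bf, w))
  s <- sd(y)
  if (s > 0) y / s else y
}

#' Simulate raw triaxial accelerometry for a hypnogram
#'
#' The signal is a slowly re-oriented gravity unit vector plus white
#' sensor noise, plus -- during wake epochs only -- continuous low-level
#' band-limited motion and randomly placed higher-amplitude movement
#' bursts in the 0.6-8 Hz voluntary-movement band. The result is
#' quantized to the configured ADC grid.
#'
#' @param hypnogram A [hypnogram()].
#' @param config A [synth_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return An [accel_recording()].
#' @export
simulate_accelerometry <- function(hypnogram, config, seed = NULL) {
  validate_synth_config(config)
  if (nrow(hypnogram) == 0) {
    abort_actisleep("hypnogram must be non-empty", "actisleep_invalid_argument")
  }
  seed <- if (is.null(seed)) config$seed else seed
  with_seed(seed, {
    rate <- config$sample_rate_hz
    n_ep <- nrow(hypnogram)
    dur_s <- n_ep * config$epoch_len_s
    n <- round(dur_s * rate)
    t <- (seq_len(n) - 1) / rate
    xyz <- matrix(0, n, 3)

    # Episodic movement bursts within wake epochs: drawn first because
    # each burst leaves the wrist resting in a slightly different
    # orientation, so burst ends are orientation events.
    wake_eps <- which(stage_to_wake(hypnogram) == 1)
    bursts <- list()
    if (length(wake_eps) > 0 && config$burst_rate_per_wake_epoch > 0 &&
        config$burst_amp_g > 0) {
      for (ep in wake_eps) {
        nb <- rpois(1, config$burst_rate_per_wake_epoch)
        if (nb == 0) next
        ep_start <- (ep - 1) * config$epoch_len_s
        for (b in seq_len(nb)) {
          dur_b <- runif(1, 0.5, 3)
          t0 <- ep_start + runif(1, 0, max(config$epoch_len_s - dur_b, 0))
          bursts[[length(bursts) + 1]] <-
            list(t0 = t0, dur = dur_b,
                 amp = config$burst_amp_g * runif(1, 0.5, 1.5),
                 wgt = runif(3, 0.3, 1))
        }
      }
    }

    # Gravity: piecewise-constant unit vector. Full re-draws at Poisson
    # posture-shift times; a small persistent perturbation at the end of
    # every movement burst (wake re-positions the wrist continually,
    # sleep posture is stable between shifts).
    n_shift <- rpois(1, config$posture_shift_rate * dur_s / 3600)
    shift_t <- sort(runif(n_shift, 0, dur_s))
    events <- rbind(
      if (n_shift > 0) data.frame(time = shift_t, type = "redraw"),
      if (length(bursts) > 0) {
        data.frame(time = vapply(bursts, function(b) b$t0 + b$dur, numeric(1)),
                   type = "wander")
      }
    )
    events <- if (is.null(events)) {
      data.frame(time = numeric(0), type = character(0))
    } else {
      events[order(events$time), , drop = FALSE]
    }
    g <- rnorm(3)
    g <- g / sqrt(sum(g^2))
    bounds <- c(0, events$time, dur_s)
    for (i in seq_len(length(bounds) - 1)) {
      # samples with bounds[i] <= t < bounds[i+1]
      i0 <- ceiling(bounds[i] * rate - 1e-9) + 1
      i1 <- min(n, ceiling(bounds[i + 1] * rate - 1e-9))
      if (i1 >= i0) {
        xyz[i0:i1, ] <- matrix(g, i1 - i0 + 1, 3, byrow = TRUE)
      }
      if (i <= nrow(events)) {
        if (events$type[i] == "redraw") {
          g <- rnorm(3)
        } else {
          g <- g + rnorm(3, sd = config$orientation_wander)
        }
        g <- g / sqrt(sum(g^2))
      }
    }

    # Sensor noise on all three axes.
    if (config$noise_amp_g > 0) {
      xyz <- xyz + matrix(rnorm(3 * n, sd = config$noise_amp_g), n, 3)
    }

    # Wake-epoch sample mask (epoch k covers [ (k-1)*30, k*30 ) seconds).
    ep_of_sample <- pmin(n_ep, floor(t / config$epoch_len_s) + 1)
    wake_sample <- stage_to_wake(hypnogram)[ep_of_sample] == 1

    # Continuous wakeful motion: low-amplitude band-limited noise.
    if (any(wake_sample) && config$tremor_amp_g > 0) {
      for (ax in 1:3) {
        tr <- bandlimited_noise(n, rate, config$burst_band_hz)
        xyz[wake_sample, ax] <- xyz[wake_sample, ax] +
          config$tremor_amp_g * tr[wake_sample]
      }
    }

    # Burst waveforms: band-limited carriers under a raised-cosine
    # envelope with per-axis weights.
    for (bu in bursts) {
      i0 <- max(1, round(bu$t0 * rate) + 1)
      len_b <- max(8, round(bu$dur * rate))
      i1 <- min(n, i0 + len_b - 1)
      len_b <- i1 - i0 + 1
      if (len_b < 8) next
      env <- 0.5 * (1 - cos(2 * pi * (seq_len(len_b) - 1) / (len_b - 1)))
      for (ax in 1:3) {
        carrier <- bandlimited_noise(len_b, rate, config$burst_band_hz)
        xyz[i0:i1, ax] <- xyz[i0:i1, ax] + bu$amp * bu$wgt[ax] * env * carrier
      }
    }

    xyz <- quantize_signal(xyz, config$resolution_bits, config$dynamic_range_g)
    accel_recording(
      tibble(time_s = t, x_g = xyz[, 1], y_g = xyz[, 2], z_g = xyz[, 3]),
      nominal_rate_hz = rate,
      resolution_bits = config$resolution_bits,
      dynamic_range_g = config$dynamic_range_g
    )
  })
}

#' Quantize a signal to a signed ADC grid
#'
#' @param x Numeric vector or matrix in g.
#' @param bits Resolution in bits.
#' @param range_g Half-range of the quantizer in g.
#' @return `x` rounded to the `2^bits`-level grid over
#'   `[-range_g, range_g)` and clipped at the rails.
#' @export
quantize_signal <- function(x, bits, range_g = 4) {
  step <- 2 * range_g / 2^bits
  q <- round(x / step)
  q <- pmax(pmin(q, 2^(bits - 1) - 1), -2^(bits - 1))
  q * step
}

#' Generate a synthetic actigraphy cohort
#'
#' Per-subject recording durations are drawn from the configured normal
#' distribution (truncated below at 1 h); each subject's generator seed
#' is derived deterministically from the master seed, so cohorts are
#' bit-identical across calls with the same configuration.
#'
#' @param config A [synth_config()].
#' @return A nested tibble of class `acti_cohort` with columns
#'   `subject_id`, `recording` (list of [accel_recording()]) and
#'   `hypnogram` (list of [hypnogram()]).
#' @export
generate_cohort <- function(config) {
  validate_synth_config(config)
  if (config$n_subjects < 1) {
    abort_actisleep("n_subjects must be >= 1", "actisleep_invalid_argument")
  }
  subjects <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    seed_s <- derive_seed(config$seed, s)
    dur_h <- with_seed(seed_s, {
      d <- rnorm(1, config$duration_h_mean, config$duration_h_sd)
      tries <- 0
      while (d < 1 && tries < 1000) {
        d <- rnorm(1, config$duration_h_mean, config$duration_h_sd)
        tries <- tries + 1
      }
      max(d, 1) # durations are truncated below at 1 h
    })
    n_epochs <- max(1, round(dur_h * 3600 / config$epoch_len_s))
    hyp <- simulate_hypnogram(config, n_epochs, seed = derive_seed(seed_s, 1))
    rec <- simulate_accelerometry(hyp, config, seed = derive_seed(seed_s, 2))
    subjects[[s]] <- tibble(
      subject_id = sprintf("S%02d", s),
      recording = list(rec),
      hypnogram = list(hyp)
    )
  }
  out <- dplyr::bind_rows(subjects)
  class(out) <- c("acti_cohort", class(out))
  out
}
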