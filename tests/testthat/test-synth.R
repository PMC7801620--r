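# Synthetic actigraphy generator.

test_that("hypnogram simulation handles degenerate configurations", {
  cfg <- tiny_synth_config()
  # never leaving wake
  cfg_w <- synth_config(n_subjects = 1, sample_rate_hz = 25,
                        mean_wake_bout_epochs = Inf, seed = 1)
  hyp <- simulate_hypnogram(cfg_w, 50)
  expect_true(all(hyp$stage == "W"))
  # a single epoch works
  h1 <- simulate_hypnogram(cfg, 1)
  expect_equal(nrow(h1), 1)
  expect_error(simulate_hypnogram(cfg, 0), class = "actisleep_invalid_argument")
  # starts and ends awake (pre-onset and post-offset wake)
  h <- simulate_hypnogram(cfg, 200, seed = 5)
  expect_equal(as.character(h$stage[1]), "W")
  expect_equal(as.character(h$stage[200]), "W")
})

test_that("long-run wake fraction matches alternating-renewal theory", {
  # mean sleep bout 20, mean wake bout 5 -> stationary wake fraction
  # 5 / 25 = 0.2; check the replicate mean within 3 standard errors
  cfg <- synth_config(n_subjects = 1, sample_rate_hz = 25,
                      mean_sleep_bout_epochs = 20, mean_wake_bout_epochs = 5,
                      brief_awakening_rate = 0, seed = 1)
  fracs <- vapply(1:20, function(s) {
    mean(stage_to_wake(simulate_hypnogram(cfg, 10000, seed = s)))
  }, numeric(1))
  se <- sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - 0.2), 3 * se + 1e-6)
})

test_that("accelerometry sample count and quantization grid", {
  cfg <- synth_config(n_subjects = 1, seed = 2) # 99.7 Hz
  hyp <- simulate_hypnogram(cfg, 2, seed = 2)   # 60 s
  rec <- simulate_accelerometry(hyp, cfg, seed = 2)
  expect_equal(nrow(rec), round(60 * 99.7)) # 5982
  expect_equal(nrow(rec), 5982)
  # every value sits on the 2^10-level grid over +/- 4 g
  step <- 8 / 2^10
  vals <- c(rec$x_g, rec$y_g, rec$z_g)
  expect_true(all(abs(vals / step - round(vals / step)) < 1e-9))
  expect_true(all(vals >= -4 & vals < 4))
})

test_that("quiet sleep reduces to gravity within one quantization step", {
  cfg <- synth_config(n_subjects = 1, sample_rate_hz = 25,
                      burst_rate_per_wake_epoch = 0, noise_amp_g = 0,
                      tremor_amp_g = 0, posture_shift_rate = 0, seed = 3)
  hyp <- hypnogram(rep("N2", 4))
  rec <- simulate_accelerometry(hyp, cfg, seed = 3)
  step <- 8 / 2^10
  for (ch in c("x_g", "y_g", "z_g")) {
    expect_lt(diff(range(rec[[ch]])), step + 1e-12)
  }
  # magnitude is 1 g up to quantization error
  mag <- sqrt(rec$x_g^2 + rec$y_g^2 + rec$z_g^2)
  expect_lt(max(abs(mag - 1)), 2 * step)
})

test_that("wake epochs carry more magnitude variance than quiet sleep", {
  cfg <- tiny_synth_config()
  wins <- 0
  for (s in 1:100) {
    hyp <- hypnogram(c("N2", "W"))
    rec <- simulate_accelerometry(hyp, cfg, seed = 1000 + s)
    spe <- round(30 * accel_rate(rec))
    mag <- sqrt(rec$x_g^2 + rec$y_g^2 + rec$z_g^2)
    v_sleep <- var(mag[seq_len(spe)])
    v_wake <- var(mag[spe + seq_len(spe)])
    wins <- wins + (v_wake > v_sleep)
  }
  expect_equal(wins, 100)
})

test_that("cohorts are reproducible, seed-sensitive, with sane durations", {
  c1 <- generate_cohort(tiny_synth_config(n_subjects = 1, seed = 5))
  c2 <- generate_cohort(tiny_synth_config(n_subjects = 1, seed = 5))
  expect_identical(c1$recording[[1]]$x_g, c2$recording[[1]]$x_g)
  expect_identical(as.character(c1$hypnogram[[1]]$stage),
                   as.character(c2$hypnogram[[1]]$stage))
  c3 <- generate_cohort(tiny_synth_config(n_subjects = 1, seed = 6))
  expect_false(identical(c1$recording[[1]]$x_g, c3$recording[[1]]$x_g))
  expect_error(generate_cohort(synth_config(n_subjects = 0)),
               class = "actisleep_invalid_argument")
})

test_that("cohort durations follow the configured normal distribution", {
  cfg <- synth_config(n_subjects = 30, duration_h_mean = 14.3,
                      duration_h_sd = 2.2, seed = 8)
  durs <- vapply(seq_len(cfg$n_subjects), function(s) {
    seed_s <- derive_seed(cfg$seed, s)
    with_seed <- actisleep:::with_seed
    with_seed(seed_s, {
      d <- rnorm(1, cfg$duration_h_mean, cfg$duration_h_sd)
      tries <- 0
      while (d < 1 && tries < 1000) {
        d <- rnorm(1, cfg$duration_h_mean, cfg$duration_h_sd)
        tries <- tries + 1
      }
      max(d, 1)
    })
  }, numeric(1))
  se <- 2.2 / sqrt(30)
  expect_lt(abs(mean(durs) - 14.3), 3 * se)
})

test_that("hypnogram/signal epoch alignment holds on the sample grid", {
  cfg <- tiny_synth_config()
  hyp <- simulate_hypnogram(cfg, 20, seed = 4)
  rec <- simulate_accelerometry(hyp, cfg, seed = 4)
  rate <- accel_rate(rec)
  expect_equal(nrow(rec), round(20 * 30 * rate))
  # epoch k covers samples (k-1)*30*rate .. k*30*rate (0-based)
  expect_equal(rec$time_s[round(5 * 30 * rate) + 1], 5 * 30, tolerance = 1 / rate)
})

test_that("variance-threshold oracle is learnable on default-style cohorts", {
  # guarantees downstream training checks are meaningful: a plain
  # per-epoch variance threshold must already score kappa > 0.5
  coh <- tiny_cohort(n_subjects = 2, seed = 7)
  v <- c(); lab <- c()
  for (i in 1:2) {
    rec <- decimate_recording(coh$recording[[i]], 3)
    hyp <- coh$hypnogram[[i]]
    rate <- accel_rate(rec)
    spe <- round(30 * rate)
    mag <- sqrt(rec$x_g^2 + rec$y_g^2 + rec$z_g^2)
    for (k in seq_len(nrow(hyp))) {
      i0 <- round((k - 1) * 30 * rate) + 1
      i1 <- min(length(mag), round(k * 30 * rate))
      v <- c(v, var(mag[i0:i1]))
      lab <- c(lab, stage_to_wake(hyp)[k])
    }
  }
  pred <- as.integer(v >= median(v))
  kappa <- epoch_metrics(confusion_counts(pred, lab))$kappa
  expect_gt(kappa, 0.5)
})
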