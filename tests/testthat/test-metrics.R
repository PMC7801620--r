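# Epoch-level and night-level agreement metrics.

test_that("confusion counts use sleep as the positive class", {
  # pred == truth, mixed classes -> no off-diagonal mass
  cc <- confusion_counts(c(0, 1, 0, 1), c(0, 1, 0, 1))
  expect_equal(cc$fp + cc$fn, 0)
  expect_equal(cc$tp, 2) # two sleep epochs agreed
  # all-sleep truth, all-wake predictions: everything is a missed sleep
  cc2 <- confusion_counts(rep(1, 5), rep(0, 5))
  expect_equal(cc2$tp, 0)
  expect_equal(cc2$fn, 5)
  expect_error(confusion_counts(1, c(1, 0)),
               class = "actisleep_invalid_argument")
})

test_that("confusion counts match a straight-loop tally on random pairs", {
  set.seed(42)
  pred <- sample(0:1, 100, replace = TRUE)
  truth <- sample(0:1, 100, replace = TRUE)
  tally <- c(tp = 0, tn = 0, fp = 0, fn = 0)
  for (i in 1:100) {
    if (pred[i] == 0 && truth[i] == 0) tally["tp"] <- tally["tp"] + 1
    if (pred[i] == 1 && truth[i] == 1) tally["tn"] <- tally["tn"] + 1
    if (pred[i] == 0 && truth[i] == 1) tally["fp"] <- tally["fp"] + 1
    if (pred[i] == 1 && truth[i] == 0) tally["fn"] <- tally["fn"] + 1
  }
  cc <- confusion_counts(pred, truth)
  expect_equal(c(cc$tp, cc$tn, cc$fp, cc$fn), unname(tally))
})

test_that("epoch metrics reproduce hand-computed tables", {
  m <- epoch_metrics(tibble::tibble(tp = 40, tn = 40, fp = 10, fn = 10))
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$p_e, 0.5)
  expect_equal(m$kappa, 0.6) # (0.8 - 0.5) / (1 - 0.5)

  m2 <- epoch_metrics(tibble::tibble(tp = 45, tn = 90, fp = 10, fn = 5))
  expect_equal(m2$sensitivity, 0.9)
  expect_equal(m2$specificity, 0.9)
  expect_equal(m2$precision, 45 / 55)
  expect_equal(m2$recall, m2$sensitivity)

  perfect <- epoch_metrics(tibble::tibble(tp = 30, tn = 20, fp = 0, fn = 0))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$kappa, 1)
  expect_equal(perfect$f1, 1)

  # printed-variant audit columns
  expect_equal(m$accuracy_printed, 40 / 100)
  expect_equal(m$kappa_printed, 1 - m$kappa)
  expect_equal(m2$f1_printed, 2 * 0.9 * 0.9 / (0.9 + 0.9))
})

test_that("degenerate denominators yield NA, never NaN", {
  m <- epoch_metrics(tibble::tibble(tp = 0, tn = 10, fp = 0, fn = 0))
  expect_true(is.na(m$sensitivity))
  expect_true(is.na(m$precision))
  expect_false(any(is.nan(unlist(m))))
})

test_that("kappa never exceeds accuracy (fuzzed confusion tables)", {
  set.seed(7)
  for (i in 1:200) {
    cc <- tibble::tibble(tp = rpois(1, 30), tn = rpois(1, 30),
                         fp = rpois(1, 10), fn = rpois(1, 10))
    if (sum(unlist(cc)) == 0) next
    m <- epoch_metrics(cc)
    if (!is.na(m$kappa) && m$p_e >= 0 && m$p_e < 1) {
      expect_lte(m$kappa, m$accuracy + 1e-12)
    }
  }
})

test_that("night detection finds first and last reference sleep epoch", {
  # W W S S W S S S W (1-based: onset 3, offset 8)
  truth <- c(1, 1, 0, 0, 1, 0, 0, 0, 1)
  night <- detect_night(truth)
  expect_equal(night$onset, 3)
  expect_equal(night$offset, 8)
  expect_equal(detect_night(rep(0, 5)), list(onset = 1, offset = 5))
  expect_equal(detect_night(c(1, 1, 0, 1)), list(onset = 3, offset = 3))
  expect_error(detect_night(rep(1, 4)), class = "actisleep_invalid_argument")
})

test_that("sleep metrics: hand counts and the TST/WASO/SE identities", {
  truth <- c(1, 1, 0, 0, 1, 0, 0, 0, 1)
  sm <- sleep_metrics(truth, 3, 8)
  expect_equal(sm$tst_min, 2.5)
  expect_equal(sm$waso_min, 0.5)
  expect_equal(sm$se_pct, 100 * 2.5 / 3, tolerance = 1e-10)
  # identity: TST + WASO spans the night
  expect_equal(sm$tst_min + sm$waso_min, (8 - 3 + 1) * 0.5)
  # all-sleep interval
  sm2 <- sleep_metrics(rep(0, 10), 1, 10)
  expect_equal(sm2$waso_min, 0)
  expect_equal(sm2$se_pct, 100)
  # consistency with typical clinical magnitudes: a night of 736 sleep
  # and 142 wake epochs gives TST 368 min, WASO 71 min, SE 83.8%
  night <- c(rep(0, 736), rep(1, 142))
  sm3 <- sleep_metrics(night, 1, length(night))
  expect_equal(sm3$tst_min, 368)
  expect_equal(sm3$waso_min, 71)
  expect_equal(round(sm3$se_pct, 1), 83.8)
  expect_equal(sm3$se_pct, 100 * sm3$tst_min / (sm3$tst_min + sm3$waso_min))
  expect_error(sleep_metrics(truth, 5, 3), class = "actisleep_invalid_argument")
})

test_that("Bland-Altman agreement: hand-computed cases", {
  ba0 <- bland_altman(c(300, 350, 400), c(300, 350, 400))
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_low, 0)
  expect_equal(ba0$loa_high, 0)
  expect_equal(ba0$frac_within_limit, 1)

  ba <- bland_altman(c(10, 0), c(0, 10))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, sqrt(200), tolerance = 1e-6) # sd of (+10, -10)
  expect_equal(ba$loa_high, 1.96 * 14.142136, tolerance = 1e-4)

  ba2 <- bland_altman(c(35, 5, -40), c(0, 0, 0))
  expect_equal(ba2$frac_within_limit, 1 / 3)
  expect_error(bland_altman(1, numeric(0)),
               class = "actisleep_invalid_argument")
})

test_that("ROC AUC equals the O(n^2) pairwise concordance oracle", {
  concordance_auc <- function(probs, truth) {
    pos <- probs[truth == 1]
    neg <- probs[truth == 0]
    tot <- 0
    for (p in pos) for (q in neg) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
    tot / (length(pos) * length(neg))
  }
  # perfectly separated
  probs <- c(rep(0.1, 10), rep(0.9, 10))
  truth <- c(rep(0, 10), rep(1, 10))
  expect_equal(roc_pr(probs, truth)$auc, 1)
  # random scores agree with the quadratic oracle
  for (seed in 1:5) {
    set.seed(seed)
    n <- 150
    probs <- runif(n)
    truth <- sample(0:1, n, replace = TRUE)
    expect_equal(roc_pr(probs, truth)$auc, concordance_auc(probs, truth),
                 tolerance = 1e-10)
  }
  # labels independent of scores -> AUC near 1/2
  set.seed(99)
  probs <- runif(4000)
  truth <- sample(0:1, 4000, replace = TRUE)
  expect_lt(abs(roc_pr(probs, truth)$auc - 0.5), 0.03)
  expect_error(roc_pr(runif(5), rep(1, 5)), class = "actisleep_single_class")
})
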