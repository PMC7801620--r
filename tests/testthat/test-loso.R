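# Hold-out splitting, LOSO folds, and the group statistics.

test_that("hold-out split is an exact, stratified, seeded partition", {
  meta <- tibble::tibble(subject_id = rep("A", 1000))
  sp <- holdout_split(meta, fraction = 0.2, seed = 3)
  expect_length(sp$validation, 200)
  expect_setequal(c(sp$train, sp$validation), seq_len(1000))
  expect_length(intersect(sp$train, sp$validation), 0)
  # reproducible
  sp2 <- holdout_split(meta, fraction = 0.2, seed = 3)
  expect_identical(sp, sp2)
  # stratification: each subject contributes its share
  meta2 <- tibble::tibble(subject_id = rep(c("A", "B"), c(100, 300)))
  sp3 <- holdout_split(meta2, fraction = 0.25, seed = 1)
  expect_length(intersect(sp3$validation, 1:100), 25)
  expect_length(intersect(sp3$validation, 101:400), 75)
  # subject-level variant holds out whole subjects
  sp4 <- holdout_split(meta2, fraction = 0.5, seed = 2, by_subject = TRUE)
  held <- unique(meta2$subject_id[sp4$validation])
  expect_length(held, 1)
  expect_error(holdout_split(meta, fraction = 1),
               class = "actisleep_invalid_argument")
})

test_that("LOSO folds are leak-free, complete and deterministic", {
  coh <- tiny_cohort(n_subjects = 3, seed = 21)
  cfg <- pipeline_config(decimation_factor = 3,
                         threshold_mode = "fixed", fixed_threshold = 0.5,
                         train = train_config(max_epochs = 2, batch_size = 32,
                                              chunk_len = 8),
                         seed = 9)
  res <- loso_evaluate(coh, model = "nb", config = cfg)
  # fold count == subject count, every subject held out exactly once
  expect_equal(nrow(res$folds), 3)
  expect_setequal(res$folds$subject_id, coh$subject_id)
  # fingerprint audit: each fold's training set excludes its subject
  for (i in seq_len(3)) {
    expected <- actisleep:::fnv1a32(
      paste(sort(setdiff(coh$subject_id, coh$subject_id[i])), collapse = "|"))
    expect_equal(
      res$fingerprints$fold_fingerprint[res$fingerprints$held_out ==
                                          coh$subject_id[i]],
      expected)
  }
  # identical folds for a second model on the same cohort/config
  res2 <- loso_evaluate(coh, model = "rf", config = cfg)
  expect_identical(res$fingerprints, res2$fingerprints)
  # determinism of the full result
  res3 <- loso_evaluate(coh, model = "nb", config = cfg)
  expect_identical(res$folds, res3$folds)
  expect_error(loso_evaluate(coh[1, ], model = "nb", config = cfg),
               class = "actisleep_invalid_argument")
})

test_that("LOSO emits night-level metrics satisfying the identities", {
  coh <- tiny_cohort(n_subjects = 2, seed = 22)
  cfg <- pipeline_config(decimation_factor = 3,
                         threshold_mode = "fixed",
                         train = train_config(max_epochs = 1, batch_size = 32),
                         seed = 4)
  res <- loso_evaluate(coh, model = "nb", config = cfg)
  # TST + WASO equals the night span for both scorers on every fold
  for (i in seq_len(nrow(res$folds))) {
    row <- res$folds[i, ]
    span_min <- (row$tst_ref + row$waso_ref)
    expect_equal(row$tst_est + row$waso_est, span_min)
    expect_equal(row$se_ref, 100 * row$tst_ref / span_min)
  }
  # probabilities cover every scored epoch of every subject
  counts <- table(res$probs$subject_id)
  expect_equal(unname(as.integer(counts)),
               vapply(coh$hypnogram, nrow, integer(1)))
  # summary is median +- MAD over folds
  k <- res$summary[res$summary$metric == "kappa", ]
  expect_equal(k$median, median(res$folds$kappa))
  expect_equal(k$mad, mad(res$folds$kappa))
})

test_that("group comparison gates on normality and runs Dunn post hocs", {
  set.seed(31)
  # identical groups: omnibus must not reject
  g <- rnorm(12)
  m_same <- cbind(a = g, b = g + rnorm(12, sd = 1e-3),
                  c = g + rnorm(12, sd = 1e-3))
  res_same <- group_compare(m_same)
  expect_gt(res_same$omnibus$p_value, 0.05)
  # well-separated groups: strong rejection
  m_sep <- cbind(a = rnorm(30), b = rnorm(30, mean = 5), c = rnorm(30))
  res_sep <- group_compare(m_sep)
  expect_lt(res_sep$omnibus$p_value, 0.001)
  # Dunn pairwise count = k (k - 1) / 2
  expect_equal(nrow(res_sep$pairwise), 3 * 2 / 2)
  m4 <- cbind(m_sep, d = rnorm(30))
  expect_equal(nrow(group_compare(m4)$pairwise), 4 * 3 / 2)
  # paired variant uses the Friedman omnibus
  res_f <- group_compare(m_sep, paired = TRUE)
  expect_match(res_f$omnibus$method, "Friedman")
  expect_lt(res_f$omnibus$p_value, 0.001)
  expect_error(group_compare(m_sep[1:2, ]),
               class = "actisleep_invalid_argument")
})

test_that("Dunn z statistics agree with a direct computation", {
  set.seed(32)
  vals <- c(rnorm(10), rnorm(10, 2))
  grp <- factor(rep(c("a", "b"), each = 10))
  dn <- actisleep:::dunn_test(vals, grp)
  r <- rank(vals)
  rb <- tapply(r, grp, mean)
  N <- 20
  se <- sqrt((N * (N + 1) / 12) * (1 / 10 + 1 / 10)) # no ties here
  expect_equal(dn$statistic, unname((rb[["a"]] - rb[["b"]]) / se))
})

test_that("tidiers expose fold metrics and summaries", {
  coh <- tiny_cohort(n_subjects = 2, seed = 22)
  cfg <- pipeline_config(decimation_factor = 3, threshold_mode = "fixed",
                         train = train_config(max_epochs = 1, batch_size = 32),
                         seed = 4)
  res <- loso_evaluate(coh, model = "nb", config = cfg)
  td <- generics::tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2)
  gl <- generics::glance(res)
  expect_equal(gl$n_folds, 2)
  expect_true("kappa_median" %in% names(gl))
})
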