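# Leave-one-subject-out and hold-out validation drivers, plus the
# nonparametric group comparison used to contrast classifiers.

#' Pipeline configuration for validation runs
#'
#' @param decimation_factor Integer decimation factor applied to every
#'   recording before feature/window extraction (12 reproduces the
#'   8.3 Hz operating point from a ~99.7 Hz device).
#' @param threshold_mode How CNN wake probabilities are binarized per
#'   subject: `"per_subject"` (balance point on the subject's own fold
#'   probabilities), `"averaged"` (balance point of the cross-subject
#'   averaged sweep curve), or `"fixed"`.
#' @param fixed_threshold Threshold used when `threshold_mode="fixed"`.
#' @param train A [train_config()].
#' @param seed Master seed; folds, inits and shuffles derive from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(decimation_factor = 12L,
                            threshold_mode = c("per_subject", "averaged",
                                               "fixed"),
                            fixed_threshold = 0.5,
                            train = train_config(),
                            seed = 1L) {
  threshold_mode <- match.arg(threshold_mode)
  if (!is_count(decimation_factor)) {
    abort_actisleep("decimation_factor must be a positive integer",
                    "actisleep_invalid_argument")
  }
  structure(list(decimation_factor = as.integer(decimation_factor),
                 threshold_mode = threshold_mode,
                 fixed_threshold = fixed_threshold,
                 train = train, seed = as.integer(seed)),
            class = "pipeline_config")
}

# Per-subject preprocessed views of a cohort: decimated recording,
# min-max normalized windows for the CNN, raw-feature table for the
# baselines.
prepare_subjects <- function(cohort, config) {
  lapply(seq_len(nrow(cohort)), function(i) {
    rec <- decimate_recording(cohort$recording[[i]], config$decimation_factor)
    hyp <- cohort$hypnogram[[i]]
    scaler <- fit_minmax(rec)
    ds <- window_epochs(apply_minmax(rec, scaler), hyp,
                        subject_id = cohort$subject_id[i])
    feats <- epoch_features(rec, hyp, subject_id = cohort$subject_id[i])
    list(subject_id = cohort$subject_id[i], windows = ds, features = feats,
         truth = stage_to_wake(hyp))
  })
}

#' Leave-one-subject-out evaluation of a classifier
#'
#' For each held-out subject the model is trained from a fresh
#' seed-derived initialization on all remaining subjects, wake
#' probabilities (CNN) or calls (baselines) are produced for the
#' held-out night, the configured threshold mode is applied, and
#' epoch-level plus night-level metrics are computed over the reference
#' night. The summary reports the across-subject median and median
#' absolute deviation of each metric. Fold assignments are
#' fingerprinted so that different models can be audited to have used
#' identical leak-free folds.
#'
#' @param cohort An `acti_cohort` nested tibble (see
#'   [generate_cohort()]), or a list of prepared subjects.
#' @param model `"lightcnna"` or one of [baseline_registry()].
#' @param config A [pipeline_config()].
#' @return An object of class `loso_result`: list with `folds`
#'   (per-subject metric tibble), `probs` (per-epoch probabilities and
#'   truth; CNN only), `summary`, `model`, `thresholds`,
#'   `fingerprints`.
#' @export
loso_evaluate <- function(cohort, model = "lightcnna",
                          config = pipeline_config()) {
  subjects <- if (is.data.frame(cohort)) prepare_subjects(cohort, config)
              else cohort
  n_sub <- length(subjects)
  if (n_sub < 2) {
    abort_actisleep("LOSO needs at least 2 subjects",
                    "actisleep_invalid_argument")
  }
  ids <- vapply(subjects, function(s) s$subject_id, character(1))
  is_cnn <- model == "lightcnna"
  if (!is_cnn && !model %in% baseline_registry()) {
    abort_actisleep(sprintf("unknown model '%s'", model),
                    "actisleep_invalid_argument")
  }

  fingerprints <- tibble(
    held_out = ids,
    fold_fingerprint = vapply(seq_len(n_sub), function(i) {
      fnv1a32(paste(sort(ids[-i]), collapse = "|"))
    }, character(1))
  )

  prob_rows <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    fold_seed <- derive_seed(config$seed, i)
    test <- subjects[[i]]
    train_set <- subjects[-i]
    if (is_cnn) {
      tc <- config$train
      tc$seed <- fold_seed
      fit <- lightcnna_train(lapply(train_set, function(s) s$windows),
                             config = tc)
      prob <- predict(fit, test$windows, type = "prob")
    } else {
      feats <- dplyr::bind_rows(lapply(train_set, function(s) s$features))
      bfit <- fit_baseline(model, feats, feats$label, seed = fold_seed)
      prob <- as.numeric(predict_baseline(bfit, test$features))
    }
    prob_rows[[i]] <- tibble(
      subject_id = test$subject_id,
      epoch_index = seq_along(test$truth),
      prob = prob,
      truth = test$truth
    )
  }
  probs <- dplyr::bind_rows(prob_rows)

  # Threshold assignment. Baseline predictions are already binary; a
  # fixed 0.5 cut leaves them untouched.
  thr_tbl <- if (is_cnn && config$threshold_mode == "per_subject") {
    per_subject_thresholds(probs)$thresholds
  } else if (is_cnn && config$threshold_mode == "averaged") {
    tibble(subject_id = ids,
           threshold = averaged_curve_threshold(probs))
  } else {
    tibble(subject_id = ids,
           threshold = if (is_cnn) config$fixed_threshold else 0.5)
  }

  fold_rows <- lapply(seq_len(n_sub), function(i) {
    d <- probs[probs$subject_id == ids[i], ]
    thr <- thr_tbl$threshold[match(ids[i], thr_tbl$subject_id)]
    if (is.na(thr)) thr <- 0.5 # subject excluded from calibration
    pred <- binarize(d$prob, thr)
    em <- epoch_metrics(confusion_counts(pred, d$truth))
    night <- detect_night(d$truth)
    sm_ref <- sleep_metrics(d$truth, night$onset, night$offset)
    sm_est <- sleep_metrics(pred, night$onset, night$offset)
    dplyr::bind_cols(
      tibble(subject_id = ids[i], threshold = thr),
      em,
      tibble(tst_ref = sm_ref$tst_min, tst_est = sm_est$tst_min,
             waso_ref = sm_ref$waso_min, waso_est = sm_est$waso_min,
             se_ref = sm_ref$se_pct, se_est = sm_est$se_pct)
    )
  })
  folds <- dplyr::bind_rows(fold_rows)

  metric_cols <- c("accuracy", "sensitivity", "specificity", "f1", "kappa")
  summary <- dplyr::bind_rows(lapply(metric_cols, function(mc) {
    v <- folds[[mc]]
    tibble(metric = mc, median = median(v, na.rm = TRUE),
           mad = mad(v, na.rm = TRUE))
  }))

  structure(list(
    model = model,
    folds = folds,
    probs = probs,
    thresholds = thr_tbl,
    summary = summary,
    fingerprints = fingerprints,
    config = config
  ), class = "loso_result")
}

#' @export
print.loso_result <- function(x, ...) {
  k <- x$summary[x$summary$metric == "kappa", ]
  cat(sprintf("<loso_result> model %s, %d folds; median kappa %.3f (MAD %.3f)\n",
              x$model, nrow(x$folds), k$median, k$mad))
  invisible(x)
}

#' Epoch-level hold-out split
#'
#' Randomly assigns a fraction of windows to a validation set,
#' stratified by subject (each subject contributes
#' `round(fraction * n_subject)` validation epochs), so the split is
#' disjoint, exhaustive and reproducible.
#'
#' @param meta Data frame with a `subject_id` column, one row per
#'   window/epoch. Set `by_subject = TRUE` to hold out whole subjects
#'   instead of epochs.
#' @param fraction Validation fraction in (0, 1); default 0.20.
#' @param seed Seed for the draw.
#' @param by_subject Hold out entire subjects rather than epochs.
#' @return List with integer row indices `train` and `validation`.
#' @export
holdout_split <- function(meta, fraction = 0.20, seed = 1L,
                          by_subject = FALSE) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    abort_actisleep("fraction must lie strictly inside (0, 1)",
                    "actisleep_invalid_argument")
  }
  n <- nrow(meta)
  val <- with_seed(seed, {
    if (by_subject) {
      subs <- unique(meta$subject_id)
      n_val <- max(1, round(fraction * length(subs)))
      hold <- sample(subs, n_val)
      which(meta$subject_id %in% hold)
    } else {
      unlist(lapply(split(seq_len(n), meta$subject_id), function(idx) {
        k <- round(fraction * length(idx))
        if (k == 0) integer(0) else sample(idx, k)
      }), use.names = FALSE)
    }
  })
  list(train = setdiff(seq_len(n), val), validation = sort(val))
}

#' Nonparametric comparison of per-subject metrics across models
#'
#' Normality of each group is probed with the Shapiro-Wilk test. For
#' independent groups the omnibus is the Kruskal-Wallis rank test when
#' any group departs from normality (p < 0.05), one-way ANOVA with
#' pairwise t tests (Holm) otherwise. With `paired = TRUE` (repeated
#' measures over the same subjects, e.g. per-subject sleep metrics from
#' several scorers) the Friedman rank ANOVA is used. Rank omnibus tests
#' are followed by Dunn's multiple-comparison z tests with Bonferroni
#' adjustment. Pure reporting: no downstream decision depends on it.
#'
#' @param metric_matrix Numeric matrix or data frame, one column per
#'   model/group, one row per subject.
#' @param paired Treat rows as repeated measures (Friedman)?
#' @return A list of class `group_comparison`: `normality`, `omnibus`,
#'   `pairwise` tibbles.
#' @export
group_compare <- function(metric_matrix, paired = FALSE) {
  m <- as.matrix(metric_matrix)
  k <- ncol(m)
  if (k < 2 || nrow(m) < 3) {
    abort_actisleep("need >= 2 groups with >= 3 observations each",
                    "actisleep_invalid_argument")
  }
  if (is.null(colnames(m))) colnames(m) <- paste0("g", seq_len(k))
  normality <- dplyr::bind_rows(lapply(colnames(m), function(g) {
    v <- m[, g]
    p <- if (length(unique(v)) == 1) 0 else stats::shapiro.test(v)$p.value
    tibble(group = g, shapiro_w_p = p)
  }))
  nonnormal <- any(normality$shapiro_w_p < 0.05)
  long <- tibble(
    value = as.vector(m),
    group = factor(rep(colnames(m), each = nrow(m)), levels = colnames(m)),
    block = factor(rep(seq_len(nrow(m)), times = k))
  )
  if (paired) {
    # repeated measures over the same subjects: rank ANOVA regardless of
    # normality (valid either way, and the usual choice for sleep metrics)
    om <- stats::friedman.test(m)
    omnibus <- tibble(method = "Friedman rank ANOVA",
                      statistic = unname(om$statistic),
                      p_value = om$p.value)
    pairwise <- dunn_friedman(m)
  } else if (nonnormal) {
    om <- stats::kruskal.test(value ~ group, data = long)
    omnibus <- tibble(method = "Kruskal-Wallis",
                      statistic = unname(om$statistic),
                      p_value = om$p.value)
    pairwise <- dunn_test(long$value, long$group)
  } else {
    om <- stats::oneway.test(value ~ group, data = long, var.equal = TRUE)
    omnibus <- tibble(method = "one-way ANOVA",
                      statistic = unname(om$statistic),
                      p_value = om$p.value)
    pw <- stats::pairwise.t.test(long$value, long$group, p.adjust.method = "holm")
    idx <- which(!is.na(pw$p.value), arr.ind = TRUE)
    pairwise <- tibble(
      group1 = rownames(pw$p.value)[idx[, 1]],
      group2 = colnames(pw$p.value)[idx[, 2]],
      statistic = NA_real_,
      p_value = pw$p.value[idx],
      p_adjusted = pw$p.value[idx]
    )
  }
  structure(list(normality = normality, omnibus = omnibus,
                 pairwise = pairwise), class = "group_comparison")
}

# Dunn's post-hoc z tests on pooled ranks with tie correction,
# Bonferroni-adjusted (the classic Dunn 1964 procedure).
dunn_test <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  tie_tab <- table(values)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  groups <- factor(groups)
  gl <- levels(groups)
  rbar <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  combs <- utils::combn(gl, 2)
  rows <- lapply(seq_len(ncol(combs)), function(j) {
    g1 <- combs[1, j]; g2 <- combs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ns[[g1]] + 1 / ns[[g2]]))
    z <- (rbar[[g1]] - rbar[[g2]]) / se
    tibble(group1 = g1, group2 = g2, statistic = z,
           p_value = 2 * stats::pnorm(-abs(z)))
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- pmin(1, out$p_value * nrow(out))
  out
}

# Dunn's method for Friedman designs: z on within-block rank sums.
dunn_friedman <- function(m) {
  k <- ncol(m)
  n <- nrow(m)
  ranks <- t(apply(m, 1, rank))
  rsum <- colSums(ranks)
  se <- sqrt(n * k * (k + 1) / 6)
  combs <- utils::combn(colnames(m), 2)
  rows <- lapply(seq_len(ncol(combs)), function(j) {
    g1 <- combs[1, j]; g2 <- combs[2, j]
    z <- (rsum[[g1]] - rsum[[g2]]) / se
    tibble(group1 = g1, group2 = g2, statistic = z,
           p_value = 2 * stats::pnorm(-abs(z)))
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- pmin(1, out$p_value * nrow(out))
  out
}
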