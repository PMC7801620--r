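# Feature-based reference classifiers: a 12-value per-epoch summary of
# the raw decimated signal, fed to six standard algorithms evaluated
# under the identical LOSO folds as the CNN.

#' Names of the twelve per-epoch features, in fixed order
#'
#' Per axis (x, y, z): median, standard deviation, minimum, maximum of
#' the raw epoch samples.
#'
#' @return Character vector of length 12.
#' @export
feature_names <- function() {
  as.vector(t(outer(c("x", "y", "z"), c("median", "sd", "min", "max"),
                    paste, sep = "_")))
}

#' Extract the 12-feature vector of one epoch
#'
#' @param epoch_samples Numeric matrix (samples x 3 axes) of one 30-s
#'   epoch of raw acceleration.
#' @return A named numeric vector of length 12, ordered
#'   x/y/z by median, sd, min, max.
#' @export
extract_features <- function(epoch_samples) {
  if (is.null(dim(epoch_samples)) || nrow(epoch_samples) == 0 ||
      ncol(epoch_samples) != 3) {
    abort_actisleep("epoch block must be a non-empty samples x 3 matrix",
                    "actisleep_invalid_argument")
  }
  out <- numeric(0)
  for (ax in 1:3) {
    v <- epoch_samples[, ax]
    out <- c(out, median(v), if (length(v) > 1) sd(v) else 0, min(v), max(v))
  }
  names(out) <- feature_names()
  out
}

#' Per-epoch feature table for a recording/hypnogram pair
#'
#' Epoch boundaries follow the same true-clock grid as
#' [window_epochs()], so the CNN and the feature classifiers score the
#' same epochs. Features are computed on the raw (pre-normalization)
#' decimated samples.
#'
#' @param recording An [accel_recording()] (typically decimated).
#' @param hypnogram A [hypnogram()].
#' @param subject_id Optional identifier column.
#' @return Tibble with `subject_id`, `epoch_index`, `label` (1 = wake)
#'   and the 12 feature columns.
#' @export
epoch_features <- function(recording, hypnogram, subject_id = NA_character_) {
  rate <- accel_rate(recording)
  epoch_len <- hypnogram_epoch_len(hypnogram)
  n_ep <- nrow(hypnogram)
  sig <- accel_matrix(recording)
  n <- nrow(sig)
  labels <- stage_to_wake(hypnogram)
  rows <- matrix(NA_real_, n_ep, 12)
  for (k in seq_len(n_ep)) {
    i0 <- round((k - 1) * epoch_len * rate) + 1
    i1 <- min(n, round(k * epoch_len * rate))
    if (i1 < i0) i1 <- i0 <- min(i0, n)
    rows[k, ] <- extract_features(sig[i0:i1, , drop = FALSE])
  }
  colnames(rows) <- feature_names()
  dplyr::bind_cols(
    tibble(subject_id = subject_id, epoch_index = seq_len(n_ep),
           label = labels),
    as_tibble(rows)
  )
}

#' The six-classifier baseline registry
#'
#' @return Character vector of registered model names: linear SVM,
#'   random forest, naive Bayes, AdaBoost, gradient boosting and a
#'   single-hidden-layer perceptron.
#' @export
baseline_registry <- function() {
  c("svm", "rf", "nb", "ada", "gb", "perceptron")
}

#' Fit a baseline classifier on epoch features
#'
#' Library defaults with threaded seeds; the fitted object predicts
#' binary wake calls through [predict_baseline()].
#'
#' @param name One of [baseline_registry()].
#' @param features Data frame of the 12 feature columns (extra columns
#'   `subject_id`, `epoch_index`, `label` are ignored as predictors).
#' @param labels Integer wake indicators (1 = wake).
#' @param seed Seed for the stochastic learners.
#' @return A classifier object of class `baseline_fit`.
#' @export
fit_baseline <- function(name, features, labels, seed = 1L) {
  if (!name %in% baseline_registry()) {
    abort_actisleep(sprintf("unknown baseline '%s'", name),
                    "actisleep_invalid_argument")
  }
  if (length(unique(labels)) < 2) {
    abort_actisleep("training labels contain a single class",
                    "actisleep_single_class")
  }
  X <- as.data.frame(features[, feature_names()])
  y <- factor(ifelse(labels == 1, "wake", "sleep"),
              levels = c("sleep", "wake"))
  fit <- with_seed(seed, switch(
    name,
    svm = e1071::svm(X, y, kernel = "linear"),
    rf = randomForest::randomForest(X, y),
    nb = e1071::naiveBayes(X, y),
    ada = adaboost_stumps(X, y),
    gb = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 3,
                    eta = 0.3, nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(as.matrix(X),
                                  label = as.integer(y == "wake")),
      nrounds = 50, verbose = 0
    ),
    perceptron = nnet::nnet(X, nnet::class.ind(y), size = 16, decay = 1e-4,
                            maxit = 200, trace = FALSE, softmax = TRUE)
  ))
  structure(list(name = name, fit = fit), class = "baseline_fit")
}

#' Predict binary wake calls from a fitted baseline
#'
#' @param object A [fit_baseline()] result.
#' @param features Data frame containing the 12 feature columns.
#' @return Integer vector, 1 = wake.
#' @export
predict_baseline <- function(object, features) {
  X <- as.data.frame(features[, feature_names()])
  pred <- switch(
    object$name,
    svm = as.character(predict(object$fit, X)),
    rf = as.character(predict(object$fit, X)),
    nb = as.character(predict(object$fit, X)),
    ada = predict_adaboost(object$fit, X),
    gb = ifelse(predict(object$fit, as.matrix(X)) >= 0.5, "wake", "sleep"),
    perceptron = ifelse(predict(object$fit, X)[, "wake"] >= 0.5,
                        "wake", "sleep")
  )
  as.integer(pred == "wake")
}

# AdaBoost (SAMME / discrete AdaBoost.M1) over depth-1 rpart stumps.
# No installed package provides it, and it is a small standard algorithm.
adaboost_stumps <- function(X, y, n_rounds = 50) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  yy <- ifelse(y == "wake", 1, -1)
  stumps <- list()
  alphas <- numeric(0)
  df <- cbind(X, .y = y)
  for (m in seq_len(n_rounds)) {
    stump <- rpart::rpart(
      .y ~ ., data = df, weights = w, method = "class",
      control = rpart::rpart.control(maxdepth = 1, cp = -1,
                                     minsplit = 2, xval = 0))
    pred <- ifelse(predict(stump, X, type = "class") == "wake", 1, -1)
    err <- sum(w * (pred != yy))
    err <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    if (err >= 0.5) break
    w <- w * exp(-alpha * yy * pred)
    w <- w / sum(w)
    stumps[[length(stumps) + 1]] <- stump
    alphas <- c(alphas, alpha)
  }
  if (length(stumps) == 0) {
    # degenerate: fall back to the majority class
    maj <- names(which.max(table(y)))
    return(list(stumps = list(), alphas = numeric(0), majority = maj))
  }
  list(stumps = stumps, alphas = alphas, majority = NULL)
}

predict_adaboost <- function(model, X) {
  if (length(model$stumps) == 0) {
    return(rep(model$majority, nrow(X)))
  }
  score <- rep(0, nrow(X))
  for (m in seq_along(model$stumps)) {
    pred <- ifelse(predict(model$stumps[[m]], X, type = "class") == "wake",
                   1, -1)
    score <- score + model$alphas[m] * pred
  }
  ifelse(score >= 0, "wake", "sleep")
}
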