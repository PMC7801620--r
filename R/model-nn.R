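# Dilated 1-D convolution network internals. Activations are batched
# 3-D arrays [batch, time, channel]; the conv forward/backward pair is
# compiled (src/conv.cpp), the pooled dense head stays in R. The
# straight-loop reference in the test suite is the correctness oracle
# for this path.

#' Initialize a weight set for a spec
#'
#' Glorot-uniform initialization per tensor; biases start at zero. The
#' first convolutional layer's kernels are centred to zero mean per
#' channel and filter (DC-blocking initialization): a zero-mean kernel
#' gives no response to the constant gravity component of a resting
#' wrist, so at the start of training the network sees movement, not
#' orientation. Training is free to reintroduce mean components. See
#' the methods vignette for why this matters on small cohorts.
#'
#' @param spec A [lightcnna_spec()].
#' @param seed Seed for the initialization draw.
#' @param dc_block Centre first-layer kernels to zero mean (default
#'   `TRUE`).
#' @return A named list of arrays of class `lightcnna_weights`, in
#'   serialization order, with the spec attached as an attribute.
#' @export
init_weights <- function(spec, seed = 1L, dc_block = TRUE) {
  shapes <- weight_shapes(spec)
  weights <- with_seed(seed, {
    lapply(names(shapes), function(nm) {
      shp <- shapes[[nm]]
      n <- prod(shp)
      if (grepl("bias", nm)) {
        array(0, dim = if (length(shp) > 1) shp else c(shp, 1))
      } else {
        if (length(shp) == 3) {
          fan_in <- shp[1] * shp[2]
          fan_out <- shp[1] * shp[3]
        } else {
          fan_in <- shp[1]
          fan_out <- shp[2]
        }
        lim <- sqrt(6 / (fan_in + fan_out))
        array(runif(n, -lim, lim), dim = if (length(shp) > 1) shp else c(shp, 1))
      }
    })
  })
  names(weights) <- names(shapes)
  if (dc_block && spec$n_conv_layers > 0) {
    W1 <- weights$conv1_kernel
    for (c in seq_len(dim(W1)[2])) {
      for (f in seq_len(dim(W1)[3])) {
        W1[, c, f] <- W1[, c, f] - mean(W1[, c, f])
      }
    }
    weights$conv1_kernel <- W1
  }
  attr(weights, "spec") <- spec
  class(weights) <- "lightcnna_weights"
  weights
}

#' Total scalar count of a weight set
#' @param weights A `lightcnna_weights` list.
#' @return Number of trainable scalars.
#' @export
n_weight_scalars <- function(weights) {
  sum(vapply(weights, length, numeric(1)))
}

# Dilated valid convolution of X [N, L, Cin] with W [k, Cin, F];
# delegates to the compiled per-tap subview kernel.
conv1d_dilated <- function(X, W, dilation) {
  .conv_forward(X, W, as.integer(dilation))
}

# Mean over the time dimension of H [N, T, F] -> [N, F].
pool_time <- function(H) {
  d <- dim(H)
  M <- matrix(H, d[1], d[2] * d[3])
  out <- matrix(0, d[1], d[3])
  for (f in seq_len(d[3])) {
    out[, f] <- rowMeans(M[, (f - 1) * d[2] + seq_len(d[2]), drop = FALSE])
  }
  out
}

# Forward pass with caches for backprop. `keep_inputs` retains each
# conv layer's input for the backward pass.
lightcnna_forward_full <- function(weights, X, keep_inputs = FALSE) {
  spec <- attr(weights, "spec")
  cache <- list(inputs = list(), pre = list())
  H <- X
  for (l in seq_len(spec$n_conv_layers)) {
    if (keep_inputs) cache$inputs[[l]] <- H
    Z <- conv1d_dilated(H, weights[[paste0("conv", l, "_kernel")]],
                        spec$dilation_rates[l])
    if (spec$conv_bias) {
      b <- as.numeric(weights[[paste0("conv", l, "_bias")]])
      Z <- Z + array(rep(b, each = dim(Z)[1] * dim(Z)[2]), dim = dim(Z))
    }
    cache$pre[[l]] <- Z
    H <- .relu_fwd(Z)
  }
  # Temporal global average pooling -> [N, F]
  pooled <- if (spec$n_conv_layers > 0) pool_time(H) else pool_time(X)
  cache$H_last_dim <- dim(H)
  cache$pooled <- pooled
  Zd <- pooled %*% matrix(weights$dense_kernel, dim(weights$dense_kernel)[1])
  if (spec$dense_bias) {
    Zd <- sweep(Zd, 2, as.numeric(weights$dense_bias), "+")
  }
  cache$dense_pre <- Zd
  A <- relu(Zd)
  cache$dense_act <- A
  z <- A %*% matrix(weights$output_kernel, ncol = 1)
  if (spec$output_bias) z <- z + as.numeric(weights$output_bias)
  cache$logit <- as.numeric(z)
  list(prob = sigmoid(cache$logit), cache = cache)
}

#' Forward pass: wake probability of each window
#'
#' @param weights A `lightcnna_weights` set.
#' @param X A single window (`L x 3` matrix) or a batch
#'   (`N x L x 3` array) of normalized acceleration.
#' @return Numeric vector of wake probabilities in (0, 1).
#' @export
lightcnna_forward <- function(weights, X) {
  spec <- attr(weights, "spec")
  if (is.matrix(X)) X <- array(X, dim = c(1, dim(X)))
  if (length(dim(X)) != 3 || dim(X)[2] != spec$input_len ||
      dim(X)[3] != spec$input_channels) {
    abort_actisleep(
      sprintf("window shape (%s) does not match spec input %d x %d",
              paste(dim(X), collapse = " x "),
              spec$input_len, spec$input_channels),
      "actisleep_invalid_argument")
  }
  lightcnna_forward_full(weights, X)$prob
}

# Backward pass: gradients of mean binary cross-entropy w.r.t. every
# tensor. `y` in {0,1} (1 = wake).
lightcnna_backward <- function(weights, X, y, fwd) {
  spec <- attr(weights, "spec")
  cache <- fwd$cache
  N <- dim(X)[1]
  grads <- list()
  dz <- matrix((fwd$prob - y) / N, ncol = 1) # d(BCE)/d(logit)

  A <- cache$dense_act
  grads$output_kernel <- array(t(A) %*% dz,
                               dim = dim(weights$output_kernel))
  if (spec$output_bias) {
    grads$output_bias <- array(sum(dz), dim = dim(weights$output_bias))
  }
  dA <- dz %*% t(matrix(weights$output_kernel, ncol = 1))
  dZd <- dA * (cache$dense_pre > 0)
  grads$dense_kernel <- array(crossprod(cache$pooled, dZd),
                              dim = dim(weights$dense_kernel))
  if (spec$dense_bias) {
    grads$dense_bias <- array(colSums(dZd), dim = dim(weights$dense_bias))
  }
  dpooled <- tcrossprod(dZd, matrix(weights$dense_kernel,
                                    dim(weights$dense_kernel)[1]))

  if (spec$n_conv_layers > 0) {
    hd <- cache$H_last_dim # c(N, Tlast, F)
    # d pooled / d H = 1 / Tlast at every time position
    dH <- .gap_bwd(dpooled, hd[2])
    for (l in rev(seq_len(spec$n_conv_layers))) {
      dZ <- .relu_bwd(dH, cache$pre[[l]])
      W <- weights[[paste0("conv", l, "_kernel")]]
      bw <- .conv_backward(cache$inputs[[l]], W, dZ,
                           as.integer(spec$dilation_rates[l]),
                           need_dx = l > 1)
      grads[[paste0("conv", l, "_kernel")]] <- bw$gW
      if (spec$conv_bias) {
        grads[[paste0("conv", l, "_bias")]] <-
          array(apply(dZ, 3, sum), dim = dim(weights[[paste0("conv", l, "_bias")]]))
      }
      dH <- if (l > 1) bw$dX else NULL
    }
  }
  grads
}

#' Training configuration
#'
#' Adam with the canonical rates (initial learning rate 0.001, beta1
#' 0.9, beta2 0.999), L2 weight regularization and binary cross-entropy
#' on the wake probability.
#'
#' @param learning_rate,beta1,beta2 Adam parameters.
#' @param l2_lambda L2 penalty strength applied to all weight tensors
#'   (not to the output bias).
#' @param batch_size Minibatch size.
#' @param max_epochs Number of passes over the training stream.
#' @param chunk_len Chunk length for the pre-epoch chunk shuffle.
#' @param dc_constrain Keep the first conv layer's kernels at zero mean
#'   throughout training (projection after every update), so the front
#'   end stays blind to the constant gravity component and must encode
#'   movement. A zero-mean kernel is an ordinary kernel: inference
#'   semantics and the parameter count are unchanged. See the methods
#'   vignette for the rationale and evidence.
#' @param seed Seed for initialization and shuffling.
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, beta1 = 0.9, beta2 = 0.999,
                         l2_lambda = 1e-4, batch_size = 64L,
                         max_epochs = 20L, chunk_len = 8L,
                         dc_constrain = TRUE, seed = 1L) {
  if (beta1 <= 0 || beta1 >= 1 || beta2 <= 0 || beta2 >= 1) {
    abort_actisleep("beta1/beta2 must lie in (0, 1)",
                    "actisleep_invalid_argument")
  }
  if (l2_lambda < 0) {
    abort_actisleep("l2_lambda must be >= 0", "actisleep_invalid_argument")
  }
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 l2_lambda = l2_lambda, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 chunk_len = as.integer(chunk_len),
                 dc_constrain = isTRUE(dc_constrain),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Train lightCNNA on a windowed stream
#'
#' Minimizes mean binary cross-entropy plus an L2 penalty with Adam.
#' Before every training epoch the stream is re-partitioned into chunks
#' and chunk-shuffled. Training is deterministic for a fixed seed.
#'
#' @param train_ds A `windowed_epochs` object (or list of them; edge
#'   windows are dropped from training).
#' @param spec A [lightcnna_spec()]; defaults to the canonical
#'   architecture at the stream's window length.
#' @param config A [train_config()].
#' @param val_ds Optional `windowed_epochs` validation set; per-epoch
#'   validation kappa (at threshold 0.5) is recorded in the history.
#' @return An object of class `lightcnna_fit`: list with `weights`,
#'   `spec`, `config`, `history` (tibble: epoch, loss, val_kappa) and
#'   `threshold` (NA until calibrated).
#' @export
lightcnna_train <- function(train_ds, spec = NULL, config = train_config(),
                            val_ds = NULL) {
  if (is.list(train_ds) && !inherits(train_ds, "windowed_epochs")) {
    train_ds <- bind_windows(train_ds, drop_edges = TRUE)
  }
  n <- nrow(train_ds$meta)
  if (n == 0) {
    abort_actisleep("empty training stream", "actisleep_invalid_argument")
  }
  if (length(unique(train_ds$meta$label)) < 2) {
    abort_actisleep(
      "training labels contain a single class; both sleep and wake epochs are required",
      "actisleep_single_class")
  }
  if (is.null(spec)) spec <- lightcnna_spec(input_len = train_ds$window_len)
  if (spec$input_len != train_ds$window_len) {
    abort_actisleep("spec input_len does not match the window length",
                    "actisleep_invalid_argument")
  }

  weights <- init_weights(spec, seed = derive_seed(config$seed, 0))
  m <- lapply(weights, function(w) array(0, dim = dim(w)))
  v <- lapply(weights, function(w) array(0, dim = dim(w)))
  step <- 0
  history <- vector("list", config$max_epochs)

  for (ep in seq_len(config$max_epochs)) {
    stream <- chunk_and_shuffle(train_ds, seed = config$seed,
                                training_epoch = ep,
                                chunk_len = config$chunk_len)
    losses <- c()
    starts <- seq(1, n, by = config$batch_size)
    for (s in starts) {
      idx <- s:min(n, s + config$batch_size - 1)
      X <- stream$windows[idx, , , drop = FALSE]
      y <- stream$meta$label[idx]
      fwd <- lightcnna_forward_full(weights, X, keep_inputs = TRUE)
      p <- pmin(pmax(fwd$prob, 1e-12), 1 - 1e-12)
      bce <- -mean(y * log(p) + (1 - y) * log(1 - p))
      grads <- lightcnna_backward(weights, X, y, fwd)
      step <- step + 1
      l2 <- 0
      for (nm in names(weights)) {
        g <- grads[[nm]]
        if (config$l2_lambda > 0 && !grepl("output_bias", nm)) {
          g <- g + config$l2_lambda * weights[[nm]]
          l2 <- l2 + 0.5 * config$l2_lambda * sum(weights[[nm]]^2)
        }
        m[[nm]] <- config$beta1 * m[[nm]] + (1 - config$beta1) * g
        v[[nm]] <- config$beta2 * v[[nm]] + (1 - config$beta2) * g^2
        mhat <- m[[nm]] / (1 - config$beta1^step)
        vhat <- v[[nm]] / (1 - config$beta2^step)
        weights[[nm]] <- weights[[nm]] -
          config$learning_rate * mhat / (sqrt(vhat) + 1e-8)
      }
      if (isTRUE(config$dc_constrain) && spec$n_conv_layers > 0 &&
          config$learning_rate > 0) {
        W1 <- weights$conv1_kernel
        for (ci in seq_len(dim(W1)[2])) {
          for (fi in seq_len(dim(W1)[3])) {
            W1[, ci, fi] <- W1[, ci, fi] - mean(W1[, ci, fi])
          }
        }
        weights$conv1_kernel <- W1
      }
      losses <- c(losses, bce + l2)
    }
    val_kappa <- NA_real_
    if (!is.null(val_ds)) {
      vp <- lightcnna_forward(weights, val_ds$windows)
      pred <- binarize(vp, 0.5)
      if (length(unique(val_ds$meta$label)) > 1) {
        val_kappa <- epoch_metrics(
          confusion_counts(pred, val_ds$meta$label))$kappa
      }
    }
    history[[ep]] <- tibble(epoch = ep, loss = mean(losses),
                            val_kappa = val_kappa)
  }

  structure(list(
    weights = weights,
    spec = spec,
    config = config,
    history = dplyr::bind_rows(history),
    threshold = NA_real_
  ), class = "lightcnna_fit")
}

#' @export
print.lightcnna_fit <- function(x, ...) {
  cat(sprintf(
    "<lightcnna_fit> %d parameters, trained %d epoch(s), final loss %.4f\n",
    count_params(x$spec), nrow(x$history), tail(x$history$loss, 1)))
  if (!is.na(x$threshold)) {
    cat(sprintf("  binarization threshold: %.3f\n", x$threshold))
  }
  invisible(x)
}

#' Predict wake probabilities or classes from a fitted model
#'
#' @param object A `lightcnna_fit`.
#' @param newdata A `windowed_epochs` object or `[N, L, 3]` array.
#' @param type `"prob"` for wake probabilities, `"class"` for binary
#'   wake calls.
#' @param threshold Binarization threshold for `type = "class"`;
#'   defaults to the fit's calibrated threshold, else 0.5.
#' @param ... Unused.
#' @return Numeric vector of probabilities or integer wake indicators.
#' @export
predict.lightcnna_fit <- function(object, newdata, type = c("prob", "class"),
                                  threshold = NULL, ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "windowed_epochs")) newdata$windows else newdata
  p <- lightcnna_forward(object$weights, X)
  if (type == "prob") return(p)
  thr <- threshold %||% (if (!is.na(object$threshold)) object$threshold else 0.5)
  binarize(p, thr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
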