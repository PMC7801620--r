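# Architecture accounting and the forward/backward engine.

test_that("canonical spec carries the published hyperparameters", {
  spec <- lightcnna_spec()
  expect_equal(spec$n_conv_layers, 3L)
  expect_equal(spec$filters, 8L)
  expect_equal(spec$kernel_size, 8L)
  expect_equal(spec$dilation_rates, c(6L, 3L, 1L))
  expect_false(spec$conv_bias)
  expect_false(spec$dense_bias)
  expect_true(spec$output_bias)
  expect_equal(spec$dense_units, 16L)
})

test_that("receptive field matches the closed form and an impulse probe", {
  spec <- lightcnna_spec()
  expect_equal(receptive_field(spec), 71L)
  # tiny cases
  expect_equal(receptive_field(lightcnna_spec(input_len = 10, n_conv_layers = 1,
                                              kernel_size = 2,
                                              dilation_rates = 1L)), 2L)
  # monotone in dilation
  expect_gt(receptive_field(lightcnna_spec(dilation_rates = c(12L, 6L, 2L))),
            receptive_field(spec))

  # Impulse probe: with all-ones kernels and a unit impulse, the last
  # conv layer's final output position responds iff the impulse lies
  # within the receptive field ending at the input's last sample.
  w <- init_weights(spec, seed = 1)
  for (nm in names(w)) w[[nm]][] <- 1
  L <- spec$input_len
  probe <- function(pos) {
    x <- matrix(0, L, 3)
    x[pos, ] <- 1
    f <- actisleep:::lightcnna_forward_full(w, array(x, dim = c(1, L, 3)))
    # pooled conv activation is nonzero iff some output position sees pos
    any(f$cache$pre[[3]] > 0)
  }
  expect_true(probe(L))                 # inside every window tail
  expect_true(probe(L - 70))            # first sample of the last RF
  expect_true(probe(1))                 # seen by the first output position
  # an isolated last-position check: input of length exactly RF has one
  # conv output position, which sees all 71 samples
  spec71 <- lightcnna_spec(input_len = 71)
  w71 <- init_weights(spec71, seed = 1)
  for (nm in names(w71)) w71[[nm]][] <- 1
  for (pos in c(1, 36, 71)) {
    x <- matrix(0, 71, 3)
    x[pos, ] <- 1
    f <- actisleep:::lightcnna_forward_full(w71, array(x, dim = c(1, 71, 3)))
    dims <- dim(f$cache$pre[[3]])
    expect_equal(dims[2], 1L)
    # taps of the stacked dilated kernels only touch a subset of the 71
    # samples; the closed-form RF is the span, so the edge positions
    # (which are true taps) must always respond
    if (pos %in% c(1, 71)) expect_true(any(f$cache$pre[[3]] > 0))
  }
  expect_error(lightcnna_spec(input_len = 10), class = "actisleep_error")
})

test_that("parameter count is exact for canonical and modified specs", {
  expect_equal(count_params(lightcnna_spec()), 1361)
  # no conv layers, dense straight on the 3 pooled channels
  expect_equal(count_params(lightcnna_spec(input_len = 10, n_conv_layers = 0,
                                           dilation_rates = integer(0))),
               3 * 16 + 16 + 1)
  # conv biases add 8 per layer
  expect_equal(count_params(lightcnna_spec(conv_bias = TRUE)), 1361 + 24)
  # serialized weight sets agree with the count, fuzzed over specs
  for (seed in 1:5) {
    set.seed(seed)
    spec <- lightcnna_spec(
      input_len = 400,
      n_conv_layers = 2,
      filters = sample(2:12, 1),
      kernel_size = sample(2:6, 1),
      dilation_rates = sample(1:4, 2, replace = TRUE),
      conv_bias = sample(c(TRUE, FALSE), 1),
      dense_bias = sample(c(TRUE, FALSE), 1),
      dense_units = sample(4:20, 1)
    )
    expect_equal(n_weight_scalars(init_weights(spec, seed)),
                 count_params(spec))
  }
})

test_that("FLOP accounting: profiler-equivalent vs dense-unrolled", {
  spec <- lightcnna_spec()
  expect_equal(count_flops(spec, "profiler_equivalent"), 2727)
  # identity behind the convention
  expect_equal(count_flops(spec, "profiler_equivalent"),
               2 * count_params(spec) + 5)
  # an empty network costs nothing
  empty <- lightcnna_spec(input_len = 10, n_conv_layers = 0,
                          dilation_rates = integer(0), dense_units = 0,
                          output_bias = FALSE)
  expect_equal(count_params(empty), 0)
  expect_equal(count_flops(empty, "profiler_equivalent"), 0)
  # unrolled cost dominates whenever conv output length exceeds one
  for (L in c(100, 300, 750)) {
    s <- lightcnna_spec(input_len = L)
    expect_gte(count_flops(s, "dense_unrolled"),
               count_flops(s, "profiler_equivalent"))
  }
  expect_error(count_flops(spec, "made_up"))
})

test_that("forward pass matches the straight-loop oracle", {
  # small spec for speed of the scalar-loop oracle
  spec <- lightcnna_spec(input_len = 90, kernel_size = 4,
                         dilation_rates = c(3L, 2L, 1L), filters = 5,
                         dense_units = 7)
  for (draw in 1:100) {
    w <- init_weights(spec, seed = draw)
    set.seed(1000 + draw)
    x <- matrix(rnorm(90 * 3), 90, 3)
    expect_equal(lightcnna_forward(w, x), oracle_forward(w, x),
                 tolerance = 1e-5)
  }
  # and for the canonical architecture on a few draws
  spec_c <- lightcnna_spec(input_len = 120)
  for (draw in 1:3) {
    w <- init_weights(spec_c, seed = draw)
    set.seed(2000 + draw)
    x <- matrix(rnorm(120 * 3), 120, 3)
    expect_equal(lightcnna_forward(w, x), oracle_forward(w, x),
                 tolerance = 1e-5)
  }
})

test_that("forward output is a probability; zero weights give exactly 0.5", {
  spec <- lightcnna_spec(input_len = 80)
  w <- init_weights(spec, seed = 1)
  for (nm in names(w)) w[[nm]][] <- 0
  x <- matrix(rnorm(80 * 3), 80, 3)
  expect_identical(lightcnna_forward(w, x), 0.5)
  # strict interior for arbitrary finite inputs
  w2 <- init_weights(spec, seed = 2)
  for (i in 1:20) {
    set.seed(i)
    p <- lightcnna_forward(w2, matrix(rnorm(80 * 3, sd = 10^runif(1, -2, 2)),
                                      80, 3))
    expect_true(p > 0 && p < 1)
  }
  expect_error(lightcnna_forward(w2, matrix(0, 10, 3)),
               class = "actisleep_invalid_argument")
})

test_that("gradients match finite differences on a tiny spec", {
  spec <- lightcnna_spec(input_len = 30, kernel_size = 3,
                         dilation_rates = c(2L, 1L), n_conv_layers = 2,
                         filters = 3, dense_units = 4)
  w <- init_weights(spec, seed = 5)
  set.seed(9)
  X <- array(rnorm(4 * 30 * 3), dim = c(4, 30, 3))
  y <- c(0, 1, 1, 0)
  loss_at <- function(weights) {
    p <- pmin(pmax(lightcnna_forward(weights, X), 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  fwd <- actisleep:::lightcnna_forward_full(w, X, keep_inputs = TRUE)
  grads <- actisleep:::lightcnna_backward(w, X, y, fwd)
  eps <- 1e-6
  for (nm in c("conv1_kernel", "conv2_kernel", "dense_kernel",
               "output_kernel", "output_bias")) {
    idx <- sample(length(w[[nm]]), min(4, length(w[[nm]])))
    for (i in idx) {
      wp <- w; wp[[nm]][i] <- wp[[nm]][i] + eps
      wm <- w; wm[[nm]][i] <- wm[[nm]][i] - eps
      num <- (loss_at(wp) - loss_at(wm)) / (2 * eps)
      expect_equal(grads[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("training reduces loss on a separable toy and is deterministic", {
  ds <- toy_windowed(n = 60, L = 80, seed = 3)
  cfg <- train_config(max_epochs = 5, batch_size = 16, chunk_len = 4,
                      seed = 11)
  fit <- lightcnna_train(ds, spec = lightcnna_spec(input_len = 80),
                         config = cfg)
  expect_true(all(diff(fit$history$loss) < 0))
  fit2 <- lightcnna_train(ds, spec = lightcnna_spec(input_len = 80),
                          config = cfg)
  expect_identical(fit$weights, fit2$weights)
})

test_that("zero learning rate leaves the initialization untouched", {
  ds <- toy_windowed(n = 20, L = 80, seed = 4)
  cfg <- train_config(learning_rate = 0, l2_lambda = 0, max_epochs = 2,
                      batch_size = 8, seed = 11)
  fit <- lightcnna_train(ds, spec = lightcnna_spec(input_len = 80),
                         config = cfg)
  w0 <- init_weights(lightcnna_spec(input_len = 80),
                     seed = derive_seed(11, 0))
  expect_equal(unclass(fit$weights)[names(w0)],
               unclass(w0)[names(w0)],
               ignore_attr = TRUE)
})

test_that("single-class training labels are refused with a diagnostic", {
  ds <- toy_windowed(n = 20, L = 80, seed = 5)
  ds$meta$label <- rep(1L, 20)
  expect_error(lightcnna_train(ds, spec = lightcnna_spec(input_len = 80)),
               class = "actisleep_single_class")
})

test_that("pooled logit responds boundedly to small burst shifts", {
  # translation-response smoke property of the pooled head: moving a
  # burst by less than half the receptive field changes the logit less
  # than removing it entirely
  spec <- lightcnna_spec(input_len = 300)
  w <- init_weights(spec, seed = 8)
  base <- matrix(0, 300, 3)
  with_burst <- function(at) {
    x <- base
    x[at:(at + 20), ] <- 1
    log(lightcnna_forward(w, x) / (1 - lightcnna_forward(w, x)))
  }
  l0 <- with_burst(100)
  l_shift <- with_burst(130) # shifted by 30 < RF/2 positions of input
  l_none <- log(lightcnna_forward(w, base) / (1 - lightcnna_forward(w, base)))
  expect_lt(abs(l_shift - l0), abs(l_none - l0) + 1e-8)
})
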