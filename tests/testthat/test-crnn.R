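test_that("output length follows the sliding-window formula", {
  expect_identical(output_length(128, 0, 8, 1), 121L)
  expect_identical(output_length(128, 7, 8, 1), 128L)
  expect_identical(output_length(128, 0, 2, 1), 127L)
  expect_identical(output_length(10, 0, 3, 2), 4L)
  expect_error(output_length(4, 0, 8, 1), "v \\+ p")
})

test_that("parameter accounting matches the architecture", {
  pc <- count_parameters(crnn_config())
  expect_identical(pc$conv, 144)
  expect_equal(pc$bn, 32)
  expect_identical(pc$flatten, 28672)
  expect_identical(pc$lstm, 3674240)
  expect_identical(pc$head, 4 * 33)
  # toy: one unit, one input -> 4 * 1 * (1 + 1 + 1) = 12
  toy <- crnn_config(n_filters = 1, kernel_size = 1, lstm_units = 1,
                     n_channels = 1, input_length = 1)
  expect_identical(count_parameters(toy)$lstm, 12)
})

test_that("channel-shared convolution matches the brute-force oracle", {
  W <- matrix(0, 16, 8); b <- numeric(16)
  zeroseg <- matrix(0, 14, 128)
  b[1] <- 0.5
  out <- conv1d_same(zeroseg, W, b)
  expect_true(all(out[, , 1] == 0.5))
  expect_true(all(out[, , 2] == 0))
  # delta kernel copies the input (first tap convention)
  W1 <- matrix(0, 1, 8); W1[1, 1] <- 1
  set.seed(5)
  seg <- matrix(rnorm(14 * 128), 14)
  expect_equal(conv1d_same(seg, W1, 0)[, , 1], seg, tolerance = 1e-12)
  # random instance vs triple loop
  set.seed(6)
  W <- matrix(rnorm(16 * 8), 16); b <- rnorm(16)
  out <- conv1d_same(seg, W, b)
  segp <- cbind(seg, matrix(0, 14, 7))
  oracle <- array(0, c(14, 128, 16))
  for (q in 1:16) for (ch in 1:14) for (v in 1:128) {
    oracle[ch, v, q] <- b[q] + sum(W[q, ] * segp[ch, v:(v + 7)])
  }
  expect_lt(max(abs(out - oracle)), 1e-10)
})

test_that("batch normalisation standardises and rescales per kernel", {
  set.seed(8)
  x <- matrix(rnorm(500 * 3, mean = 2, sd = 4), 500, 3)
  y <- batchnorm_forward(x, gamma = rep(1, 3), beta = rep(0, 3), "train")
  expect_lt(max(abs(colMeans(y))), 1e-7)
  expect_lt(max(abs(apply(y, 2, function(c) mean((c - mean(c))^2)) - 1)),
            1e-4)
  y2 <- batchnorm_forward(x, gamma = rep(2, 3), beta = rep(3, 3), "train")
  expect_lt(max(abs(colMeans(y2) - 3)), 1e-7)
  # two-pass oracle with the epsilon in place
  mu <- colMeans(x)
  v <- apply(x, 2, function(c) mean((c - mean(c))^2))
  oracle <- sweep(sweep(x, 2, mu), 2, sqrt(v + 1e-5), "/")
  expect_equal(y, oracle, tolerance = 1e-10)
  # eval mode uses the provided running statistics
  ye <- batchnorm_forward(x, rep(1, 3), rep(0, 3), "eval",
                          running_mean = mu, running_var = v)
  expect_equal(ye, oracle, tolerance = 1e-10)
  expect_error(batchnorm_forward(x[1, , drop = FALSE], 1, 0, "train"),
               "batch size")
})

test_that("activations implement their element-wise formulas", {
  expect_identical(activation(-1.5, "relu"), 0)
  expect_identical(activation(2, "relu"), 2)
  expect_identical(activation(0, "sigmoid"), 0.5)
  x <- seq(-3, 3, length.out = 101)
  expect_lt(max(abs(activation(x, "tanh") -
                      (2 * activation(2 * x, "sigmoid") - 1))), 1e-12)
  expect_error(activation(1, "softplus"))
})

test_that("stride-1 max pooling keeps length via the trailing zero pad", {
  expect_equal(maxpool_same(c(1, 3, 2)), c(3, 3, 2))
  mono <- c(5, 4, 3, 2, 1)
  expect_equal(maxpool_same(mono), mono)
  set.seed(12)
  x <- abs(rnorm(100))
  expect_true(all(maxpool_same(x) >= x))
  # matrix form pools along rows, column-wise
  m <- cbind(c(1, 3, 2), c(0, 1, 0))
  expect_equal(maxpool_same(m), cbind(c(3, 3, 2), c(1, 1, 0)))
  # constant non-negative input is a fixed point
  expect_equal(maxpool_same(rep(2, 7)), rep(2, 7))
})

test_that("dropout masks in training and passes through in eval", {
  set.seed(13)
  x <- rnorm(1e5)
  expect_identical(dropout(x, 0.5, "eval"), x)
  expect_identical(dropout(x, 0, "train"), x)
  y <- dropout(x, 0.5, "train")
  frac <- mean(y == 0)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 1e5))
  # survivors are rescaled by 1/(1-p)
  nz <- y != 0
  expect_equal(y[nz], x[nz] * 2, tolerance = 1e-12)
})

test_that("the LSTM step matches the gate equations", {
  # all-zero input and weights with unit forget bias -> zero state
  u <- 2; d <- 4
  p0 <- list(lstm_wx = matrix(0, 4 * u, d), lstm_wh = matrix(0, 4 * u, u),
             lstm_b = c(0, 0, 1, 1, 0, 0, 0, 0))
  expect_equal(lstm_features(rep(0, d), p0), rep(0, u),
               ignore_attr = TRUE)
  # tanh-bounded output
  set.seed(14)
  p1 <- list(lstm_wx = matrix(rnorm(4 * u * d, sd = 2), 4 * u, d),
             lstm_wh = matrix(rnorm(4 * u * u), 4 * u, u),
             lstm_b = rnorm(4 * u))
  h <- lstm_features(rnorm(d) * 5, p1)
  expect_true(all(abs(h) < 1))
  # hand-rolled gate-equation oracle
  x <- rnorm(d)
  z <- p1$lstm_wx %*% x + p1$lstm_b
  sig <- function(v) 1 / (1 + exp(-v))
  i <- sig(z[1:u]); g <- tanh(z[(2 * u + 1):(3 * u)])
  o <- sig(z[(3 * u + 1):(4 * u)])
  expect_lt(max(abs(lstm_features(x, p1) - o * tanh(i * g))), 1e-10)
  expect_error(lstm_features(rnorm(3), p1), "does not match")
})

test_that("compiled batch forward agrees with the public-op composition", {
  cfg <- crnn_config(dropout_p = 0)
  prm <- random_params(cfg)
  set.seed(20)
  X <- array(rnorm(14 * 128 * 3), c(14, 128, 3))
  S <- memoraffect:::stack_batch(X)
  got <- memoraffect:::.cpp_crnn_eval(
    S, prm$conv_w, prm$conv_b, prm$bn_gamma, prm$bn_beta, prm$bn_mean,
    prm$bn_var, prm$lstm_wx, prm$lstm_b, prm$head_w, prm$head_b,
    cfg$n_channels, cfg$bn_eps, cfg$literal_eq6)
  ref <- memoraffect:::crnn_forward_ref(S, prm, cfg)
  expect_lt(max(abs(got$h - ref$h)), 1e-10)
  expect_lt(max(abs(got$logits - ref$logits)), 1e-10)
})

test_that("compiled gradients match finite differences", {
  cfg <- tiny_config()
  prm <- random_params(cfg, seed = 3)
  set.seed(21)
  B <- 6
  X <- array(rnorm(cfg$n_channels * cfg$input_length * B),
             c(cfg$n_channels, cfg$input_length, B))
  S <- memoraffect:::stack_batch(X)
  y <- rep(1:4, length.out = B)
  Y <- matrix(0, 4, B); Y[cbind(y, 1:B)] <- 1
  step <- function(p) {
    memoraffect:::.cpp_crnn_train_step(
      S, Y, p$conv_w, p$conv_b, p$bn_gamma, p$bn_beta, p$lstm_wx,
      p$lstm_b, p$head_w, p$head_b, cfg$n_channels, cfg$bn_eps,
      FALSE, 0)
  }
  base <- step(prm)
  grads <- list(conv_w = base$g_conv_w, conv_b = base$g_conv_b,
                bn_gamma = base$g_bn_gamma, bn_beta = base$g_bn_beta,
                lstm_wx = base$g_lstm_wx, lstm_b = base$g_lstm_b,
                head_w = base$g_head_w, head_b = base$g_head_b)
  eps <- 1e-6
  for (nm in names(grads)) {
    idx <- seq_len(min(4, length(prm[[nm]])))
    for (j in idx) {
      pp <- prm; pp[[nm]][j] <- pp[[nm]][j] + eps
      pm <- prm; pm[[nm]][j] <- pm[[nm]][j] - eps
      fd <- (step(pp)$loss - step(pm)$loss) / (2 * eps)
      expect_lt(abs(fd - grads[[nm]][j]),
                1e-5 * max(1, abs(fd)))
    }
  }
})

test_that("training is deterministic and learns separable segments", {
  # four classes with distinct constant-frequency content
  set.seed(30)
  n <- 96
  t <- (1:128) / 128
  freqs <- c(HVHA = 5, HVLA = 12, LVHA = 20, LVLA = 35)
  data <- array(0, c(14, 128, n))
  labels <- rep(names(freqs), each = n / 4)
  for (i in seq_len(n)) {
    ph <- runif(14, 0, 2 * pi)
    base <- t(sapply(ph, function(p) sin(2 * pi * freqs[labels[i]] * t + p)))
    data[, , i] <- zscore_segment(base + matrix(rnorm(14 * 128, sd = 0.2),
                                                14))
  }
  ds <- segment_dataset(data, tibble::tibble(
    subject_id = 1L, trial_id = seq_len(n), segment_index = 0L,
    label = labels))
  cfg <- crnn_config(epochs = 8, batch_size = 48, seed = 42)
  f1 <- train_crnn(ds, cfg)
  f2 <- train_crnn(ds, cfg)
  expect_identical(f1$history$loss[1], f2$history$loss[1])
  expect_identical(f1$params$lstm_wx[1:5], f2$params$lstm_wx[1:5])
  # loss decreases in trend
  expect_lt(tail(f1$history$loss, 1), f1$history$loss[1])
  # eval-mode features are reproducible and finite
  ft1 <- extract_features(ds, f1)
  ft2 <- extract_features(ds, f1)
  expect_identical(ft1, ft2)
  expect_true(all(is.finite(feature_matrix(ft1))))
  expect_equal(ncol(feature_matrix(ft1)), 32)
  # features separate the two extreme classes after training
  fm <- feature_matrix(ft1)
  a <- fm[labels == "HVHA", ]; b <- fm[labels == "LVLA", ]
  between <- sqrt(sum((colMeans(a) - colMeans(b))^2))
  within <- mean(c(apply(a, 2, sd), apply(b, 2, sd)))
  expect_gt(between, within)
})
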