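#' CRNN architecture configuration
#'
#' Hyperparameters of the convolutional-recurrent feature extractor:
#' a single channel-shared 1D convolution block (16 kernels of length
#' 8, stride 1, trailing zero-padding of 7 so the output length stays
#' 128), batch normalisation, ReLU, size-2 stride-1 max pooling with a
#' trailing zero pad, dropout, a 32-unit LSTM applied to the flattened
#' 14 x 128 x 16 activation tensor as one time step, and a 4-class
#' softmax head used during end-to-end training.
#'
#' @param n_filters Number of convolution kernels (16).
#' @param kernel_size Kernel length `k` (8).
#' @param stride Convolution stride (1).
#' @param pool_size Max-pool window (2).
#' @param pool_stride Max-pool stride (1).
#' @param dropout_p Dropout probability (0.5).
#' @param lstm_units LSTM hidden units (32).
#' @param n_classes Output classes (4).
#' @param epochs Training epochs (90).
#' @param batch_size Mini-batch size (240).
#' @param learning_rate Initial Adam learning rate (1e-3).
#' @param grad_decay Adam squared-gradient moving-average decay (0.99).
#' @param bn_eps Batch-norm variance epsilon (1e-5).
#' @param literal_eq6 If `TRUE`, batch-norm divides by the variance
#'   itself rather than its square root (fidelity switch; see the
#'   methods vignette).
#' @param n_channels Input channels (14).
#' @param input_length Samples per segment (128).
#' @param seed Integer seed controlling initialisation, shuffling and
#'   dropout.
#'
#' @return An object of class `crnn_config`.
#' @export
crnn_config <- function(n_filters = 16, kernel_size = 8, stride = 1,
                        pool_size = 2, pool_stride = 1, dropout_p = 0.5,
                        lstm_units = 32, n_classes = 4, epochs = 90,
                        batch_size = 240, learning_rate = 1e-3,
                        grad_decay = 0.99, bn_eps = 1e-5,
                        literal_eq6 = FALSE, n_channels = 14,
                        input_length = 128, seed = 1) {
  stopifnot(kernel_size <= input_length, dropout_p >= 0, dropout_p < 1,
            stride == 1, pool_size == 2, pool_stride == 1)
  structure(list(
    n_filters = n_filters, kernel_size = kernel_size, stride = stride,
    pool_size = pool_size, pool_stride = pool_stride,
    dropout_p = dropout_p, lstm_units = lstm_units,
    n_classes = n_classes, epochs = epochs, batch_size = batch_size,
    learning_rate = learning_rate, grad_decay = grad_decay,
    bn_eps = bn_eps, literal_eq6 = literal_eq6,
    n_channels = n_channels, input_length = input_length, seed = seed
  ), class = "crnn_config")
}

#' Convolution/pooling output length
#'
#' Length of a strided sliding-window operation over a sequence:
#' `floor((v + p - k) / sl) + 1` for input length `v`, padding `p`,
#' window `k` and stride `sl`.
#'
#' @param v Input length.
#' @param p Total padding.
#' @param k Window length.
#' @param sl Stride.
#' @return Integer output length.
#' @export
#' @examples
#' output_length(128, 0, 8, 1) # 121
#' output_length(128, 7, 8, 1) # 128
#' output_length(128, 0, 2, 1) # 127
output_length <- function(v, p, k, sl) {
  if (v + p < k || sl < 1) stop("require v + p >= k and sl >= 1")
  as.integer(floor((v + p - k) / sl) + 1)
}

#' Per-layer learnable parameter counts
#'
#' Parameter accounting for the architecture: convolution
#' `n_filters * (k + 1)`, batch norm `2 * n_filters`, LSTM
#' `4 * u * (d + u + 1)` with `d` the flattened activation length,
#' and the softmax head `n_classes * (u + 1)`.
#'
#' @param config A [crnn_config()].
#' @return Named list with `conv`, `bn`, `flatten` (activation count,
#'   not learnable), `lstm`, `head`, `total`.
#' @export
#' @examples
#' count_parameters(crnn_config())$conv # 144
#' count_parameters(crnn_config())$lstm # 3674240
count_parameters <- function(config) {
  d <- config$n_channels * config$input_length * config$n_filters
  u <- config$lstm_units
  conv <- config$n_filters * (config$kernel_size + 1)
  bn <- 2L * config$n_filters
  lstm <- 4 * u * (d + u + 1)
  head <- config$n_classes * (u + 1)
  list(conv = conv, bn = bn, flatten = d, lstm = lstm, head = head,
       total = conv + bn + lstm + head)
}

#' Initialise CRNN parameters
#'
#' Glorot-uniform convolution and head weights with zero biases,
#' Glorot-Gaussian LSTM input weights, orthogonal recurrent weights,
#' and a unit forget-gate bias. Gates are stacked in i, f, g, o order.
#'
#' @param config A [crnn_config()].
#' @return A list of parameter matrices (class `crnn_params`).
#' @export
crnn_init <- function(config) {
  set.seed(config$seed)
  nf <- config$n_filters; k <- config$kernel_size
  u <- config$lstm_units
  d <- config$n_channels * config$input_length * nf
  lim_c <- sqrt(6 / (k + 1))
  conv_w <- matrix(runif(nf * k, -lim_c, lim_c), nf, k)
  conv_b <- numeric(nf)
  bn_gamma <- rep(1, nf); bn_beta <- numeric(nf)
  bn_mean <- numeric(nf); bn_var <- rep(1, nf)
  lstm_wx <- matrix(rnorm(4 * u * d, sd = sqrt(2 / (d + u))), 4 * u, d)
  lstm_wh <- do.call(rbind, lapply(1:4, function(i) {
    qr.Q(qr(matrix(rnorm(u * u), u, u)))
  }))
  lstm_b <- numeric(4 * u)
  lstm_b[(u + 1):(2 * u)] <- 1 # unit forget-gate bias
  lim_h <- sqrt(6 / (u + config$n_classes))
  head_w <- matrix(runif(config$n_classes * u, -lim_h, lim_h),
                   config$n_classes, u)
  head_b <- numeric(config$n_classes)
  structure(list(conv_w = conv_w, conv_b = conv_b,
                 bn_gamma = bn_gamma, bn_beta = bn_beta,
                 bn_mean = bn_mean, bn_var = bn_var,
                 lstm_wx = lstm_wx, lstm_wh = lstm_wh, lstm_b = lstm_b,
                 head_w = head_w, head_b = head_b),
            class = "crnn_params")
}

#' Channel-shared 1D convolution, same-length output
#'
#' Slides each kernel over each channel independently (weights shared
#' across channels); the input is right-padded with `k - 1` zeros so
#' the output length equals the input length.
#'
#' @param segment Channels x samples matrix.
#' @param weights `n_filters x k` kernel matrix.
#' @param biases Length-`n_filters` bias vector.
#' @return Channels x samples x n_filters array of pre-activations.
#' @export
conv1d_same <- function(segment, weights, biases) {
  n_ch <- nrow(segment); len <- ncol(segment)
  k <- ncol(weights); nf <- nrow(weights)
  S <- rbind(t(segment), matrix(0, k - 1, n_ch)) # time x channels, padded
  out <- array(0, dim = c(n_ch, len, nf))
  for (q in seq_len(nf)) {
    acc <- matrix(biases[q], len, n_ch)
    for (i in seq_len(k)) {
      acc <- acc + weights[q, i] * S[i:(i + len - 1), , drop = FALSE]
    }
    out[, , q] <- t(acc)
  }
  out
}

#' Batch normalisation forward pass
#'
#' Standardises each kernel's pre-activations by batch statistics
#' (training) or running statistics (evaluation), then applies the
#' learned per-kernel scale and shift.
#'
#' @param x Observations x kernels matrix.
#' @param gamma,beta Per-kernel scale and shift.
#' @param mode `"train"` (batch statistics) or `"eval"` (running).
#' @param running_mean,running_var Running statistics used in eval
#'   mode.
#' @param eps Variance epsilon.
#' @param literal_eq6 Divide by the variance itself instead of its
#'   square root.
#' @return Matrix of the same shape as `x`.
#' @export
batchnorm_forward <- function(x, gamma, beta, mode = c("train", "eval"),
                              running_mean = NULL, running_var = NULL,
                              eps = 1e-5, literal_eq6 = FALSE) {
  mode <- match.arg(mode)
  if (mode == "train" && nrow(x) < 2) stop("train mode needs batch size >= 2")
  out <- x
  for (q in seq_len(ncol(x))) {
    if (mode == "train") {
      mu <- mean(x[, q]); v <- mean((x[, q] - mu)^2)
    } else {
      mu <- running_mean[q]; v <- running_var[q]
    }
    denom <- if (literal_eq6) (v + eps) else sqrt(v + eps)
    out[, q] <- gamma[q] * (x[, q] - mu) / denom + beta[q]
  }
  out
}

#' Element-wise activation
#'
#' @param x Numeric vector, matrix or array.
#' @param kind `"sigmoid"`, `"tanh"` or `"relu"`.
#' @return Same shape as `x`.
#' @export
activation <- function(x, kind = c("relu", "sigmoid", "tanh")) {
  kind <- match.arg(kind)
  switch(kind,
         sigmoid = 1 / (1 + exp(-x)),
         tanh = tanh(x),
         relu = pmax(x, 0))
}

#' Size-2, stride-1 max pooling with trailing zero pad
#'
#' `mp[v] = max(x[v], x[v + 1])` along the time axis; the final
#' position is compared against a zero pad, so the output length
#' equals the input length.
#'
#' @param x Numeric vector, or a time x signals matrix pooled along
#'   rows.
#' @return Same shape as `x`.
#' @export
#' @examples
#' maxpool_same(c(1, 3, 2)) # 3 3 2
maxpool_same <- function(x) {
  if (is.matrix(x)) {
    n <- nrow(x)
    out <- x
    if (n > 1) out[1:(n - 1), ] <- pmax(x[1:(n - 1), , drop = FALSE],
                                        x[2:n, , drop = FALSE])
    out[n, ] <- pmax(x[n, ], 0)
    out
  } else {
    n <- length(x)
    out <- pmax(x, c(x[-1], 0))
    out
  }
}

#' Dropout
#'
#' In training mode each unit is zeroed independently with probability
#' `p` and survivors are scaled by `1 / (1 - p)`; in evaluation mode
#' the input passes through unchanged.
#'
#' @param x Numeric vector, matrix or array.
#' @param p Dropout probability.
#' @param mode `"train"` or `"eval"`.
#' @return Same shape as `x`.
#' @export
dropout <- function(x, p = 0.5, mode = c("train", "eval")) {
  mode <- match.arg(mode)
  if (mode == "eval" || p == 0) return(x)
  mask <- runif(length(x)) >= p
  x * mask / (1 - p)
}

#' LSTM feature map (single time step)
#'
#' Applies one LSTM step to an input vector treated as a single time
#' step from zero initial hidden and cell state. With sigmoid gate
#' activations and tanh state activations, the returned feature vector
#' is the hidden state `h = o * tanh(i * g)`.
#'
#' @param x Input vector of length `d`, or `d x B` matrix for a batch.
#' @param params List with `lstm_wx` (`4u x d`), `lstm_wh` (`4u x u`),
#'   `lstm_b` (`4u`); gates stacked in i, f, g, o order.
#' @return Length-`u` feature vector (or `u x B` matrix).
#' @export
lstm_features <- function(x, params) {
  d <- ncol(params$lstm_wx)
  if (is.matrix(x)) stopifnot(nrow(x) == d) else {
    if (length(x) != d) stop("input length ", length(x),
                             " does not match LSTM input dim ", d)
    x <- matrix(x, ncol = 1)
  }
  u <- nrow(params$lstm_wx) / 4
  Z <- params$lstm_wx %*% x + params$lstm_b # h0 = 0: Wh contributes nothing
  i <- 1 / (1 + exp(-Z[1:u, , drop = FALSE]))
  g <- tanh(Z[(2 * u + 1):(3 * u), , drop = FALSE])
  o <- 1 / (1 + exp(-Z[(3 * u + 1):(4 * u), , drop = FALSE]))
  h <- o * tanh(i * g)
  if (ncol(h) == 1) drop(h) else h
}

# ---- internal batched forward/backward ------------------------------
# the fused batch step (conv -> BN -> ReLU -> pool -> dropout -> LSTM ->
# head, with gradients) is compiled; see src/crnn_step.cpp

# X: n_channels x len x B array -> S: len x (n_channels * B) matrix
stack_batch <- function(X) {
  d <- dim(X)
  matrix(aperm(X, c(2, 1, 3)), nrow = d[2])
}

# reference R forward pass over a stacked batch (the compiled step is
# the production path; this composition of the public ops backs the
# cross-implementation consistency tests)
crnn_forward_ref <- function(S, params, config, mode = "eval") {
  nf <- config$n_filters; len <- config$input_length
  m <- ncol(S); B <- m / config$n_channels
  rows_per_q <- len * config$n_channels
  Fmat <- matrix(0, rows_per_q * nf, B)
  # rebuild the per-segment array and run the public single-segment ops
  X <- aperm(array(S, dim = c(len, config$n_channels, B)), c(2, 1, 3))
  for (b in seq_len(B)) {
    A <- conv1d_same(X[, , b], params$conv_w, params$conv_b)
    for (q in seq_len(nf)) {
      pre <- matrix(aperm(A[, , q, drop = FALSE], c(2, 1, 3)), ncol = 1)
      bn <- batchnorm_forward(pre, params$bn_gamma[q], params$bn_beta[q],
                              mode = "eval",
                              running_mean = params$bn_mean[q],
                              running_var = params$bn_var[q],
                              eps = config$bn_eps,
                              literal_eq6 = config$literal_eq6)
      r <- activation(matrix(bn, len, config$n_channels), "relu")
      p <- maxpool_same(r)
      Fmat[((q - 1) * rows_per_q + 1):(q * rows_per_q), b] <- as.vector(p)
    }
  }
  h <- lstm_features(Fmat, params)
  if (!is.matrix(h)) h <- matrix(h, ncol = 1)
  logits <- params$head_w %*% h + params$head_b
  list(h = h, logits = logits)
}

#' Train the convolutional-recurrent feature extractor
#'
#' End-to-end training of conv -> batch norm -> ReLU -> max pool ->
#' dropout -> LSTM -> softmax head by backpropagation with the Adam
#' optimiser (first-moment decay 0.9, second-moment decay
#' `grad_decay`). Deterministic for a fixed `config$seed`.
#'
#' @param dataset A `segment_dataset` with all four quadrant labels.
#' @param config A [crnn_config()].
#' @return An object of class `crnn_fit`: trained parameters (with
#'   batch-norm running statistics), the config, and a per-epoch
#'   `history` tibble (`epoch`, `loss`, `accuracy`).
#' @export
train_crnn <- function(dataset, config = crnn_config()) {
  X <- dataset$data
  labels <- factor(dataset$manifest$label, levels = QUADRANTS)
  stopifnot(!anyNA(labels))
  n <- dim(X)[3]
  y <- as.integer(labels)
  Yfull <- matrix(0, config$n_classes, n)
  Yfull[cbind(y, seq_len(n))] <- 1
  params <- crnn_init(config) # seeds the RNG for the whole run
  opt_state <- list(m = lapply(params, function(p) p * 0),
                    v = lapply(params, function(p) p * 0), t = 0)
  # note: the recurrent weights receive no gradient (zero initial
  # state, single step) and keep their orthogonal initialisation
  bsz <- min(config$batch_size, n)
  history <- vector("list", config$epochs)
  bn_momentum <- 0.1
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(n)
    n_batch <- ceiling(n / bsz)
    ep_loss <- 0; ep_correct <- 0
    for (bi in seq_len(n_batch)) {
      idx <- ord[((bi - 1) * bsz + 1):min(bi * bsz, n)]
      if (length(idx) < 2) next # BN needs a real batch
      S <- stack_batch(X[, , idx, drop = FALSE])
      Y <- Yfull[, idx, drop = FALSE]
      step <- .cpp_crnn_train_step(
        S, Y, params$conv_w, params$conv_b, params$bn_gamma,
        params$bn_beta, params$lstm_wx, params$lstm_b, params$head_w,
        params$head_b, config$n_channels, config$bn_eps,
        config$literal_eq6, config$dropout_p)
      if (!is.finite(step$loss)) {
        stop("non-finite training loss at epoch ", epoch, ", batch ", bi)
      }
      ep_loss <- ep_loss + step$loss * length(idx)
      ep_correct <- ep_correct + step$n_correct
      # update batch-norm running statistics
      params$bn_mean <- (1 - bn_momentum) * params$bn_mean +
        bn_momentum * drop(step$bn_mean_batch)
      params$bn_var <- (1 - bn_momentum) * params$bn_var +
        bn_momentum * drop(step$bn_var_batch)
      grads <- list(conv_w = step$g_conv_w, conv_b = drop(step$g_conv_b),
                    bn_gamma = drop(step$g_bn_gamma),
                    bn_beta = drop(step$g_bn_beta),
                    lstm_wx = step$g_lstm_wx,
                    lstm_b = drop(step$g_lstm_b),
                    head_w = step$g_head_w,
                    head_b = drop(step$g_head_b))
      opt_state$t <- opt_state$t + 1
      b1 <- 0.9; b2 <- config$grad_decay; adam_eps <- 1e-8
      # bias correction folded into the step size (standard fused form)
      lr_t <- config$learning_rate *
        sqrt(1 - b2^opt_state$t) / (1 - b1^opt_state$t)
      for (nm in names(grads)) {
        .cpp_adam_update(params[[nm]], opt_state$m[[nm]],
                         opt_state$v[[nm]], grads[[nm]], lr_t, b1, b2,
                         adam_eps)
      }
    }
    history[[epoch]] <- tibble::tibble(epoch = epoch,
                                       loss = ep_loss / n,
                                       accuracy = ep_correct / n)
  }
  structure(list(params = params, config = config,
                 history = dplyr::bind_rows(history),
                 classes = QUADRANTS),
            class = "crnn_fit")
}

#' @export
print.crnn_fit <- function(x, ...) {
  pc <- count_parameters(x$config)
  cat("<crnn_fit>", pc$total, "parameters,",
      nrow(x$history), "epochs trained\n")
  if (nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat("  final loss", signif(last$loss, 4),
        " train accuracy", signif(last$accuracy, 4), "\n")
  }
  invisible(x)
}

# eval-mode forward in bounded-memory chunks; returns list(H, logits)
crnn_infer <- function(dataset, fit, chunk = 512L) {
  X <- dataset$data
  n <- dim(X)[3]
  u <- fit$config$lstm_units
  H <- matrix(0, u, n)
  L <- matrix(0, fit$config$n_classes, n)
  p <- fit$params; cfg <- fit$config
  at <- 1L
  while (at <= n) {
    idx <- at:min(at + chunk - 1L, n)
    S <- stack_batch(X[, , idx, drop = FALSE])
    fw <- .cpp_crnn_eval(S, p$conv_w, p$conv_b, p$bn_gamma, p$bn_beta,
                         p$bn_mean, p$bn_var, p$lstm_wx, p$lstm_b,
                         p$head_w, p$head_b, cfg$n_channels, cfg$bn_eps,
                         cfg$literal_eq6)
    H[, idx] <- fw$h
    L[, idx] <- fw$logits
    at <- at + chunk
  }
  list(H = H, logits = L)
}

#' Extract 32-dimensional features from a trained CRNN
#'
#' Evaluation-mode forward pass (no dropout, running batch-norm
#' statistics) up to the LSTM hidden state, the last named
#' representation before the softmax head.
#'
#' @param dataset A `segment_dataset`.
#' @param fit A `crnn_fit`.
#' @return A tibble: the dataset manifest followed by feature columns
#'   `f01` ... `f32`.
#' @export
extract_features <- function(dataset, fit) {
  H <- crnn_infer(dataset, fit)$H
  feat <- t(H)
  colnames(feat) <- sprintf("f%02d", seq_len(ncol(feat)))
  dplyr::bind_cols(dataset$manifest, tibble::as_tibble(feat))
}

#' Predict quadrants with the CRNN's own softmax head
#'
#' @param fit A `crnn_fit`.
#' @param dataset A `segment_dataset`.
#' @return Character vector of predicted quadrant labels.
#' @export
predict_crnn <- function(fit, dataset) {
  L <- crnn_infer(dataset, fit)$logits
  fit$classes[max.col(t(L), ties.method = "first")]
}

#' Extract the numeric feature matrix from a feature tibble
#'
#' @param features Tibble from [extract_features()], or a numeric
#'   matrix (returned as is).
#' @return Numeric matrix, observations x features.
#' @export
feature_matrix <- function(features) {
  if (is.matrix(features)) return(features)
  as.matrix(dplyr::select(features, dplyr::matches("^f[0-9]+$")))
}
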