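# shared fixtures built in code

# small labeled segment dataset with random content (no signal
# structure): n segments of 14 x 128, balanced over the four quadrants
random_dataset <- function(n = 48, seed = 1, n_subjects = 2) {
  set.seed(seed)
  stopifnot(n %% 4 == 0)
  data <- array(rnorm(14 * 128 * n), c(14, 128, n))
  manifest <- tibble::tibble(
    subject_id = rep_len(seq_len(n_subjects), n),
    trial_id = rep(seq_len(n %/% 4), each = 4)[seq_len(n)],
    segment_index = rep_len(0:9, n),
    label = rep(quadrant_levels(), each = n %/% 4)
  )
  segment_dataset(data, manifest)
}

# tiny CRNN configuration used by gradient and consistency checks
tiny_config <- function(...) {
  crnn_config(n_filters = 2, kernel_size = 3, lstm_units = 3,
              n_channels = 2, input_length = 8, dropout_p = 0,
              batch_size = 6, epochs = 1, ...)
}

# random parameter set drawn independently of crnn_init's seeding
random_params <- function(config, seed = 42) {
  set.seed(seed)
  nf <- config$n_filters; k <- config$kernel_size
  u <- config$lstm_units
  d <- config$n_channels * config$input_length * nf
  list(conv_w = matrix(rnorm(nf * k, sd = 0.5), nf, k),
       conv_b = rnorm(nf, sd = 0.1),
       bn_gamma = runif(nf, 0.5, 1.5), bn_beta = rnorm(nf, sd = 0.2),
       bn_mean = rnorm(nf, sd = 0.1), bn_var = runif(nf, 0.5, 2),
       lstm_wx = matrix(rnorm(4 * u * d, sd = 0.1), 4 * u, d),
       lstm_wh = matrix(rnorm(4 * u * u, sd = 0.1), 4 * u, u),
       lstm_b = rnorm(4 * u, sd = 0.1),
       head_w = matrix(rnorm(config$n_classes * u, sd = 0.5),
                       config$n_classes, u),
       head_b = rnorm(config$n_classes, sd = 0.1))
}

# Table of printed confusion-matrix counts used by the metric
# arithmetic tests (rows = predicted HVHA/HVLA/LVHA/LVLA)
reference_cm_counts <- function() {
  m <- rbind(c(202, 23, 82, 104),
             c(12, 270, 15, 9),
             c(13, 24, 202, 31),
             c(99, 9, 27, 182))
  dimnames(m) <- list(predicted = quadrant_levels(),
                      true = quadrant_levels())
  m
}

# expectation of the round-then-clip integer rating under a normal
# annotation distribution (numeric oracle for the sampler tests)
expected_clipped_mean <- function(mean, sd) {
  ks <- -4:4
  probs <- vapply(ks, function(k) {
    lo <- if (k == -4) -Inf else k - 0.5
    hi <- if (k == 4) Inf else k + 0.5
    stats::pnorm(hi, mean, sd) - stats::pnorm(lo, mean, sd)
  }, numeric(1))
  sum(ks * probs)
}
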