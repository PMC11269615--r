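test_that("downsampling preserves length arithmetic and tone content", {
  x <- matrix(sin(2 * pi * 10 * (1:5632) / 512), 1)
  y <- downsample(x, 512, 128)
  expect_equal(ncol(y), 1408)
  sp <- stats::spec.pgram(stats::ts(y[1, ], frequency = 128),
                          plot = FALSE)
  expect_lt(abs(sp$freq[which.max(sp$spec)] - 10), 0.5)
  # amplitude essentially preserved away from the edges
  expect_lt(abs(sd(y[1, 100:1300]) / sd(x[1, 400:5200]) - 1), 0.05)
  # equal rates pass through unchanged
  expect_identical(downsample(x, 128, 128), x)
  expect_error(downsample(x, 128, 256), "must not exceed")
})

test_that("common average reference removes the instantaneous mean", {
  set.seed(4)
  x <- matrix(rnorm(14 * 128), 14)
  y <- common_average_reference(x)
  expect_lt(max(abs(colMeans(y))), 1e-10)
  # identical channels cancel exactly
  same <- matrix(rep(rnorm(64), each = 5), 5, byrow = FALSE)
  expect_lt(max(abs(common_average_reference(same))), 1e-12)
  # brute-force loop oracle
  oracle <- x
  for (j in seq_len(ncol(x))) oracle[, j] <- x[, j] - mean(x[, j])
  expect_equal(y, oracle, tolerance = 1e-12)
})

test_that("broadband filter rejects drift and DC but keeps 10 Hz", {
  n <- 1280
  t <- (1:n) / 128
  dc <- matrix(5, 2, n)
  expect_lt(max(abs(rowMeans(bandpass_1_50(dc)))), 5e-3 * 5)
  tone <- sin(2 * pi * 10 * t)
  drift <- sin(2 * pi * 0.2 * t)
  y_tone <- bandpass_1_50(rbind(tone, tone))[1, ]
  expect_lt(abs(sd(y_tone[100:1180]) / sd(tone[100:1180]) - 1), 0.05)
  y_mix <- bandpass_1_50(rbind(tone + drift, tone))[1, ]
  # drift residual at least 20 dB below the tone
  resid <- y_mix - y_tone
  expect_lt(sd(resid[100:1180]), 0.1 * sd(tone))
})

test_that("epoching extracts labeled trials and drops zero-axis ones", {
  p <- protocol_config(n_subjects = 1)
  sig <- signature_preset("strong")
  s <- generate_session(1, p, sig, word_affect_stats(), seed = 21)
  s128 <- downsample_session(s, 128)
  trials <- epoch_trials(s128)
  labs <- quadrant_of(s$annotations$valence, s$annotations$arousal)
  expect_equal(length(trials), sum(!is.na(labs)))
  expect_true(all(vapply(trials, function(t) ncol(t$baseline), 0L) == 128))
  expect_true(all(vapply(trials, function(t) ncol(t$recall), 0L) == 1280))
  expect_true(all(vapply(trials, `[[`, "", "label") %in% quadrant_levels()))
  # a marker too close to the start is skipped with a warning
  s2 <- s128
  s2$markers$sample[1] <- 50L
  expect_warning(t2 <- epoch_trials(s2), "skipped")
  expect_lt(length(t2), length(trials))
})

test_that("annotation-table labeled fraction matches printed totals", {
  stats <- word_affect_stats()
  n_lab <- sum(stats$n_hvha + stats$n_hvla + stats$n_lvha + stats$n_lvla)
  n_tot <- n_lab + sum(stats$n_none)
  expect_lt(abs(n_lab / n_tot - (3312 - 200) / 3312), 0.01)
})

test_that("baseline correction subtracts the pre-onset second", {
  set.seed(9)
  trial <- structure(list(
    subject_id = 1L, trial_id = 1L, word = "Calm", label = "HVHA",
    baseline = matrix(rnorm(14 * 128), 14),
    recall = matrix(rnorm(14 * 1280), 14)
  ), class = "trial")
  segs <- baseline_correct_segments(trial)
  expect_length(segs, 10)
  # loop oracle on a random segment
  i <- 4
  oracle <- trial$recall[, (i * 128 + 1):((i + 1) * 128)] - trial$baseline
  expect_equal(segs[[i + 1]]$data, oracle, tolerance = 1e-12)
  expect_identical(segs[[i + 1]]$segment_index, 4L)
  expect_identical(segs[[i + 1]]$label, "HVHA")
  # recall identical to baseline cancels exactly
  trial$recall <- do.call(cbind, rep(list(trial$baseline), 10))
  expect_true(all(vapply(baseline_correct_segments(trial),
                         function(s) max(abs(s$data)), 0) == 0))
  # zero baseline leaves the raw slices
  trial$baseline <- trial$baseline * 0
  expect_equal(baseline_correct_segments(trial)[[1]]$data,
               trial$recall[, 1:128])
})

test_that("z-scoring standardises channels and is affine invariant", {
  set.seed(10)
  x <- matrix(rnorm(14 * 128, sd = 3, mean = 2), 14)
  z <- zscore_segment(x)
  expect_lt(max(abs(rowMeans(z))), 1e-10)
  expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-10)
  expect_equal(zscore_segment(2.5 * x + 7), z, tolerance = 1e-10)
  # two-pass oracle
  oracle <- t(apply(x, 1, function(r) (r - mean(r)) / sd(r)))
  expect_equal(z, oracle, tolerance = 1e-12)
  bad <- x
  rownames(bad) <- eeg_channels()
  bad["T7", ] <- 1
  expect_error(zscore_segment(bad), "T7")
})

test_that("rhythm decomposition is band selective and linear", {
  t <- (1:128) / 128
  tone10 <- matrix(sin(2 * pi * 10 * t), 14, 128, byrow = TRUE)
  bank <- extract_rhythms(tone10)
  expect_named(bank, c("delta", "theta", "alpha", "beta", "gamma"))
  expect_true(all(vapply(bank, function(b) all(dim(b) == c(14, 128)),
                         TRUE)))
  # steady-state selectivity, measured away from zero-phase edge
  # transients
  mid <- 33:96
  expect_gt(sd(bank$alpha[1, mid]) / sd(bank$delta[1, mid]), 5)
  # 2 Hz tone: delta dominates gamma by at least the 10 dB design
  tone2 <- matrix(sin(2 * pi * 2 * t), 14, 128, byrow = TRUE)
  bank2 <- extract_rhythms(tone2)
  expect_gt(20 * log10(sd(bank2$delta[1, ]) / sd(bank2$gamma[1, ])), 10)
  # all-zero in, all-zero out; scaling commutes (LTI)
  expect_true(all(vapply(extract_rhythms(tone10 * 0),
                         function(b) all(b == 0), TRUE)))
  set.seed(2)
  x <- matrix(rnorm(14 * 128), 14)
  b1 <- extract_rhythms(x)
  b3 <- extract_rhythms(3 * x)
  for (nm in names(b1)) {
    expect_lt(max(abs(b3[[nm]] - 3 * b1[[nm]])) / max(abs(b1[[nm]])),
              1e-8)
  }
})

test_that("class balancing downsamples every class to the minimum", {
  ds <- random_dataset(48)
  # unbalance: drop most LVLA segments -> counts {12, 12, 12, 3}
  keep <- c(which(ds$manifest$label != "LVLA"),
            which(ds$manifest$label == "LVLA")[1:3])
  unb <- subset_dataset(ds, sort(keep))
  bal <- balance_classes(unb, seed = 1)
  expect_equal(unname(class_counts(bal)), rep(3L, 4))
  expect_equal(dim(bal$data)[3], 12)
  # already balanced input is returned as the same multiset
  bal2 <- balance_classes(ds, seed = 1)
  expect_equal(class_counts(bal2), class_counts(ds))
  expect_equal(dim(bal2$data), dim(ds$data))
  # empty class errors
  none <- subset_dataset(ds, which(ds$manifest$label != "LVLA"))
  expect_error(balance_classes(none), "LVLA")
  # deterministic under seed
  b1 <- balance_classes(unb, seed = 9)
  b2 <- balance_classes(unb, seed = 9)
  expect_identical(b1$manifest, b2$manifest)
})

test_that("the session pipeline emits 14 x 128 segments, ten per trial", {
  p <- protocol_config(n_subjects = 1, n_sessions = 1)
  sig <- signature_preset("strong")
  s <- generate_session(1, p, sig, word_affect_stats(), seed = 31)
  ds <- preprocess_session(s)
  labs <- quadrant_of(s$annotations$valence, s$annotations$arousal)
  expect_equal(dim(ds$data)[1:2], c(14, 128))
  expect_equal(dim(ds$data)[3], 10 * sum(!is.na(labs)))
  expect_true(all(is.finite(ds$data)))
  # per-channel standardisation within every emitted segment
  m1 <- apply(ds$data, 3, function(seg) max(abs(rowMeans(seg))))
  expect_lt(max(m1), 1e-6)
  sds <- apply(ds$data, 3, function(seg) max(abs(apply(seg, 1, sd) - 1)))
  expect_lt(max(sds), 1e-6)
})
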