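#' Downsample a multichannel signal
#'
#' Anti-alias filtered resampling to the working rate (128 Hz by
#' default). Integer decimation factors use an IIR anti-alias filter;
#' rational ratios go through polyphase resampling.
#'
#' @param signal Channels x samples numeric matrix.
#' @param from_rate Input sampling rate in Hz.
#' @param to_rate Output sampling rate in Hz (default 128).
#'
#' @return Channels x `round(samples * to_rate / from_rate)` matrix.
#' @export
downsample <- function(signal, from_rate, to_rate = 128) {
  if (to_rate > from_rate) stop("to_rate must not exceed from_rate")
  if (from_rate == to_rate) return(signal)
  n_out <- round(ncol(signal) * to_rate / from_rate)
  fac <- from_rate / to_rate
  out <- matrix(0, nrow = nrow(signal), ncol = n_out)
  if (fac == round(fac)) {
    # zero-phase Chebyshev-I anti-alias low-pass, then keep every
    # fac-th sample (the standard IIR decimator design)
    aa <- signal::cheby1(8, 0.05, 0.8 / fac)
    y <- filtfilt_mat(aa$b, aa$a, t(signal))
    keep <- seq(1L, by = round(fac), length.out = n_out)
    out[, ] <- t(y[keep, , drop = FALSE])
  } else {
    r <- to_rate / from_rate
    # reduce to integers p/q
    den <- 1
    while (abs(r * den - round(r * den)) > 1e-9) den <- den + 1
    p <- round(r * den); q <- den
    for (ch in seq_len(nrow(signal))) {
      y <- signal::resample(signal[ch, ], p, q)
      out[ch, ] <- y[seq_len(n_out)]
    }
  }
  rownames(out) <- rownames(signal)
  out
}

#' Downsample a recording session
#'
#' Applies [downsample()] to the continuous signal and remaps marker
#' sample indices to the new rate.
#'
#' @param session A `recording_session`.
#' @param to_rate Target rate in Hz.
#' @return The session at `to_rate`.
#' @export
downsample_session <- function(session, to_rate = 128) {
  if (session$rate == to_rate) return(session)
  r <- to_rate / session$rate
  session$signal <- downsample(session$signal, session$rate, to_rate)
  session$markers$sample <- as.integer(round((session$markers$sample - 1L) * r) + 1L)
  session$rate <- to_rate
  session
}

#' Common average reference
#'
#' Subtracts the instantaneous mean over channels from every channel.
#'
#' @param signal Channels x samples matrix with at least 2 channels.
#' @return Re-referenced matrix of the same shape.
#' @export
common_average_reference <- function(signal) {
  stopifnot(nrow(signal) >= 2)
  sweep(signal, 2, colMeans(signal))
}

#' Broadband 1-50 Hz band-pass
#'
#' Zero-phase (forward-backward) 4th-order Butterworth band-pass that
#' removes slow drifts and powerline-range interference while leaving
#' the 1-50 Hz EEG band intact.
#'
#' @param signal Channels x samples matrix.
#' @param rate Sampling rate in Hz (must exceed 100).
#' @return Filtered matrix, same shape.
#' @export
bandpass_1_50 <- function(signal, rate = 128) {
  stopifnot(rate > 100)
  ny <- rate / 2
  filt <- signal::butter(4, c(1, 50) / ny, type = "pass")
  t(filtfilt_mat(filt$b, filt$a, t(signal)))
}

#' Optional ocular-artifact hook
#'
#' Placeholder stage in the preprocessing chain where ocular-artifact
#' removal would sit when processing real recordings. The default (and
#' only built-in) method is the identity: the synthetic generator
#' produces no ocular artifacts.
#'
#' @param signal Channels x samples matrix.
#' @param method `"none"`.
#' @return The signal unchanged.
#' @export
remove_ocular_artifacts <- function(signal, method = c("none")) {
  method <- match.arg(method)
  signal
}

#' Cut a session into labeled trials
#'
#' For each recall-onset marker, extracts the 1-s pre-onset baseline
#' and the 10-s recall period, labels the trial with the quadrant of
#' its self-annotation, and drops trials whose annotation falls on a
#' zero axis (no quadrant). Markers too close to a recording edge are
#' skipped with a warning.
#'
#' @param session A `recording_session` at 128 Hz.
#' @return List of `trial` objects: `subject_id`, `trial_id`, `word`,
#'   `label`, `baseline` (14 x 128), `recall` (14 x 1280).
#' @export
epoch_trials <- function(session) {
  rate <- session$rate
  nb <- rate
  nr <- 10L * rate
  total <- ncol(session$signal)
  trials <- list()
  labels <- quadrant_of(session$annotations$valence,
                        session$annotations$arousal)
  n_skipped <- 0L
  for (j in seq_len(nrow(session$markers))) {
    m <- session$markers$sample[j]
    if (m - nb < 1L || m + nr - 1L > total) {
      n_skipped <- n_skipped + 1L
      next
    }
    if (is.na(labels[j])) next
    trials[[length(trials) + 1L]] <- structure(list(
      subject_id = session$subject_id,
      trial_id = j,
      word = session$markers$word[j],
      label = labels[j],
      baseline = session$signal[, (m - nb):(m - 1L), drop = FALSE],
      recall = session$signal[, m:(m + nr - 1L), drop = FALSE]
    ), class = "trial")
  }
  if (n_skipped > 0L) {
    warning(n_skipped, " marker(s) too close to the recording edge; ",
            "trial(s) skipped")
  }
  trials
}

#' Baseline-corrected 1-s segments of a trial
#'
#' Splits the 10-s recall into ten 1-s segments and subtracts the 1-s
#' pre-onset baseline from each, isolating recall-related activity.
#'
#' @param trial A `trial` from [epoch_trials()].
#' @return List of 10 labeled segments, each a list with `data`
#'   (14 x 128 matrix), `label`, `subject_id`, `trial_id`,
#'   `segment_index` (0-9).
#' @export
baseline_correct_segments <- function(trial) {
  n <- ncol(trial$baseline)
  lapply(0:9, function(i) {
    seg <- trial$recall[, (i * n + 1L):((i + 1L) * n), drop = FALSE] -
      trial$baseline
    list(data = seg, label = trial$label, subject_id = trial$subject_id,
         trial_id = trial$trial_id, segment_index = i)
  })
}

#' Per-channel z-score normalisation
#'
#' Standardises each channel of a segment to zero mean and unit
#' standard deviation over its 128 samples.
#'
#' @param segment Channels x samples matrix.
#' @return Standardised matrix of the same shape.
#' @export
zscore_segment <- function(segment) {
  m <- rowMeans(segment)
  s <- apply(segment, 1, sd)
  if (any(s == 0)) {
    bad <- rownames(segment)[s == 0]
    if (is.null(bad)) bad <- which(s == 0)
    stop("zero-variance channel(s): ", paste(bad, collapse = ", "),
         " (constant synthetic channel indicates a configuration bug)")
  }
  (segment - m) / s
}

# vectorised zero-phase IIR filtering of many signals at once: X is
# time x signals; odd-reflection padding as in standard filtfilt,
# forward and backward passes in direct form II transposed (compiled).
filtfilt_mat <- function(b, a, X) {
  nf <- max(length(a), length(b))
  npad <- 3L * (nf - 1L)
  n <- nrow(X)
  stopifnot(n > npad)
  pre <- 2 * X[rep(1L, npad), , drop = FALSE] - X[(npad + 1L):2L, , drop = FALSE]
  post <- 2 * X[rep(n, npad), , drop = FALSE] -
    X[(n - 1L):(n - npad), , drop = FALSE]
  Y <- rbind(pre, X, post)
  Y <- .cpp_iir_df2t(b, a, Y)
  Y <- .cpp_iir_df2t(b, a, Y[nrow(Y):1L, , drop = FALSE])
  Y <- Y[nrow(Y):1L, , drop = FALSE]
  Y[(npad + 1L):(npad + n), , drop = FALSE]
}

# Chebyshev type-II band-pass designs for the five rhythms at 128 Hz:
# order 6, 10 dB stopband attenuation, stopband edges 1 Hz outside the
# passband (0.5 Hz below delta's lower edge). Each band is realised as
# a cascade of an order-6 high-pass and an order-6 low-pass section: a
# single order-12 band-pass polynomial is numerically unstable for the
# narrow low-frequency delta band (poles drift outside the unit
# circle), while the cascade keeps every section stable.
rhythm_filters <- function(rate = 128) {
  ny <- rate / 2
  edges <- list(delta = c(0.5, 5), theta = c(3, 9), alpha = c(7, 14),
                beta = c(12, 31), gamma = c(29, 50))
  lapply(edges, function(e) {
    c(design_sos(signal::cheby2(6, 10, e[1] / ny, type = "high")),
      design_sos(signal::cheby2(6, 10, e[2] / ny, type = "low")))
  })
}

# factor a designed filter into second-order sections (biquads); the
# direct polynomial form is ill-conditioned for near-DC edges
design_sos <- function(filt) {
  zpg <- signal::as.Zpg(filt)
  quads <- function(roots) {
    tol <- 1e-10
    cplx <- roots[Im(roots) > tol] # one representative per pair
    reals <- Re(roots[abs(Im(roots)) <= tol])
    secs <- lapply(cplx, function(p) c(1, -2 * Re(p), Mod(p)^2))
    while (length(reals) >= 2) {
      secs[[length(secs) + 1]] <- c(1, -(reals[1] + reals[2]),
                                    reals[1] * reals[2])
      reals <- reals[-(1:2)]
    }
    if (length(reals) == 1) {
      secs[[length(secs) + 1]] <- c(1, -reals[1], 0)
    }
    secs
  }
  bz <- quads(zpg$zero)
  az <- quads(zpg$pole)
  stopifnot(length(bz) == length(az))
  sos <- lapply(seq_along(az), function(i) list(b = bz[[i]], a = az[[i]]))
  sos[[1]]$b <- sos[[1]]$b * Re(zpg$gain)
  sos
}

# zero-phase cascade over the biquad sections: odd-reflection padding
# sized for the whole cascade, one forward and one backward sweep
# through every section
apply_rhythm_filter <- function(sos, X) {
  total_order <- sum(vapply(sos, function(s) length(s$a) - 1L, 1L))
  npad <- min(3L * total_order, nrow(X) - 1L)
  n <- nrow(X)
  pre <- 2 * X[rep(1L, npad), , drop = FALSE] -
    X[(npad + 1L):2L, , drop = FALSE]
  post <- 2 * X[rep(n, npad), , drop = FALSE] -
    X[(n - 1L):(n - npad), , drop = FALSE]
  Y <- rbind(pre, X, post)
  for (s in sos) Y <- .cpp_iir_df2t(s$b, s$a, Y)
  Y <- Y[nrow(Y):1L, , drop = FALSE]
  for (s in sos) Y <- .cpp_iir_df2t(s$b, s$a, Y)
  Y <- Y[nrow(Y):1L, , drop = FALSE]
  Y[(npad + 1L):(npad + n), , drop = FALSE]
}

#' Rhythm-band decomposition of a segment
#'
#' Splits a 1-s segment into the five canonical EEG rhythms -- delta
#' (1-4 Hz), theta (4-8 Hz), alpha (8-13 Hz), beta (13-30 Hz), gamma
#' (30-49 Hz) -- with zero-phase Chebyshev type-II band-pass filters
#' (order 6, 10 dB stopband attenuation).
#'
#' @param segment Channels x 128 matrix at 128 Hz.
#' @param rate Sampling rate; must be 128.
#' @param filters Optional precomputed [rhythm_filters()].
#' @return Named list (`delta`, `theta`, `alpha`, `beta`, `gamma`) of
#'   matrices, each the same shape as `segment`.
#' @export
extract_rhythms <- function(segment, rate = 128, filters = NULL) {
  stopifnot(rate == 128)
  if (is.null(filters)) filters <- rhythm_filters(rate)
  lapply(filters, function(f) {
    t(apply_rhythm_filter(f, t(segment)))
  })
}

#' Segment dataset container
#'
#' Bundles preprocessed 1-s segments (a 14 x 128 x n array) with their
#' provenance manifest.
#'
#' @param data 14 x 128 x n numeric array.
#' @param manifest Tibble with columns `subject_id`, `trial_id`,
#'   `segment_index`, `label` (one row per segment).
#' @return An object of class `segment_dataset`.
#' @export
segment_dataset <- function(data, manifest) {
  stopifnot(dim(data)[3] == nrow(manifest))
  structure(list(data = data, manifest = tibble::as_tibble(manifest)),
            class = "segment_dataset")
}

#' @export
print.segment_dataset <- function(x, ...) {
  cat("<segment_dataset>", dim(x$data)[3], "segments (",
      paste(dim(x$data)[1:2], collapse = " x "), ")\n")
  print(class_counts(x))
  invisible(x)
}

#' Class counts of a segment dataset
#'
#' @param dataset A `segment_dataset`.
#' @return Named integer vector of segment counts per quadrant.
#' @export
class_counts <- function(dataset) {
  tab <- table(factor(dataset$manifest$label, levels = QUADRANTS))
  stats::setNames(as.integer(tab), QUADRANTS)
}

#' Subset a segment dataset by index
#'
#' @param dataset A `segment_dataset`.
#' @param idx Integer indices of segments to keep.
#' @return A `segment_dataset` with the selected segments.
#' @export
subset_dataset <- function(dataset, idx) {
  segment_dataset(dataset$data[, , idx, drop = FALSE],
                  dataset$manifest[idx, ])
}

#' Preprocess one session into labeled segments
#'
#' Runs the full per-session chain: downsample to 128 Hz, common
#' average reference, 1-50 Hz band-pass, (identity) ocular hook,
#' epoch into trials, baseline-correct the ten 1-s recall segments,
#' and z-score each segment per channel.
#'
#' @param session A `recording_session`.
#' @return A `segment_dataset` (possibly with zero segments).
#' @export
preprocess_session <- function(session) {
  s <- downsample_session(session, 128)
  s$signal <- common_average_reference(s$signal)
  s$signal <- bandpass_1_50(s$signal, s$rate)
  s$signal <- remove_ocular_artifacts(s$signal)
  trials <- epoch_trials(s)
  segs <- unlist(lapply(trials, baseline_correct_segments),
                 recursive = FALSE)
  n <- length(segs)
  if (n == 0L) {
    return(segment_dataset(array(0, dim = c(14, 128, 0)),
                           tibble::tibble(subject_id = integer(),
                                          trial_id = integer(),
                                          segment_index = integer(),
                                          label = character())))
  }
  data <- array(0, dim = c(nrow(segs[[1]]$data), ncol(segs[[1]]$data), n))
  for (i in seq_len(n)) data[, , i] <- zscore_segment(segs[[i]]$data)
  manifest <- tibble::tibble(
    subject_id = vapply(segs, function(s) as.integer(s$subject_id),
                        integer(1)),
    trial_id = vapply(segs, function(s) as.integer(s$trial_id), integer(1)),
    segment_index = vapply(segs, function(s) as.integer(s$segment_index),
                           integer(1)),
    label = vapply(segs, function(s) s$label, character(1))
  )
  segment_dataset(data, manifest)
}

#' Preprocess a cohort of sessions
#'
#' Applies [preprocess_session()] to every session and concatenates
#' the resulting segments into one dataset.
#'
#' @param sessions List of `recording_session` objects.
#' @return A `segment_dataset` over the whole cohort.
#' @export
preprocess_cohort <- function(sessions) {
  parts <- lapply(sessions, preprocess_session)
  datas <- lapply(parts, `[[`, "data")
  n <- sum(vapply(datas, function(d) dim(d)[3], integer(1)))
  data <- array(0, dim = c(14, 128, n))
  at <- 0L
  for (d in datas) {
    k <- dim(d)[3]
    if (k > 0) data[, , (at + 1L):(at + k)] <- d
    at <- at + k
  }
  manifest <- dplyr::bind_rows(lapply(parts, `[[`, "manifest"))
  segment_dataset(data, manifest)
}

#' Balance classes by random down-sampling
#'
#' Randomly discards segments so that every quadrant retains exactly
#' the minimum per-class count; the result has `4 x min_count`
#' segments.
#'
#' @param dataset A `segment_dataset` containing all four classes.
#' @param seed Integer seed for the random discard.
#' @return A balanced `segment_dataset`.
#' @export
balance_classes <- function(dataset, seed = 1) {
  counts <- class_counts(dataset)
  if (any(counts == 0)) {
    stop("class(es) with zero segments: ",
         paste(names(counts)[counts == 0], collapse = ", "))
  }
  set.seed(seed)
  m <- min(counts)
  keep <- unlist(lapply(QUADRANTS, function(q) {
    idx <- which(dataset$manifest$label == q)
    if (length(idx) > m) sort(sample(idx, m)) else idx
  }))
  subset_dataset(dataset, sort(keep))
}

#' Per-band versions of a segment dataset
#'
#' Applies the rhythm decomposition to every segment and returns one
#' dataset per band (sharing the manifest of the input).
#'
#' @param dataset A `segment_dataset` of broadband segments.
#' @param bands Character vector of bands to compute (default all
#'   five).
#' @return Named list of `segment_dataset` objects.
#' @export
rhythm_datasets <- function(dataset,
                            bands = names(RHYTHM_BANDS)) {
  stopifnot(all(bands %in% names(RHYTHM_BANDS)))
  filters <- rhythm_filters(128)[bands]
  n <- dim(dataset$data)[3]
  n_ch <- dim(dataset$data)[1]
  len <- dim(dataset$data)[2]
  # stack all segments side by side (time x channel-instances) so each
  # band needs a single vectorised filtfilt pass
  X <- matrix(aperm(dataset$data, c(2, 1, 3)), nrow = len)
  out <- lapply(filters, function(f) {
    Y <- apply_rhythm_filter(f, X)
    arr <- aperm(array(Y, dim = c(len, n_ch, n)), c(2, 1, 3))
    segment_dataset(arr, dataset$manifest)
  })
  names(out) <- bands
  out
}
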