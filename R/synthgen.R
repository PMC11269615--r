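#' Acquisition protocol configuration
#'
#' Describes the word-cued recall protocol: each subject sees each of 16
#' affect-denoting words once per session, over `n_sessions` sessions
#' (48 trials per subject at the defaults). Every trial is a 1-s neutral
#' pre-cue baseline, a 10-s recall period, and a 10-s self-annotation
#' gap before the next cue. Signals are synthesised at `native_rate`
#' and later downsampled to 128 Hz by the preprocessing stage.
#'
#' @param n_subjects Number of subjects in the cohort (default 69).
#' @param words Character vector of the 16 cue words.
#' @param n_sessions Sessions per subject (default 3).
#' @param baseline_duration Pre-cue baseline length in seconds.
#' @param recall_duration Recall period length in seconds.
#' @param annotation_duration Inter-trial annotation gap in seconds.
#' @param native_rate Acquisition sampling rate in Hz (default 512).
#' @param channel_names Channel labels; must have length 14.
#'
#' @return An object of class `protocol_config`.
#' @export
#' @examples
#' p <- protocol_config(n_subjects = 2)
#' p$n_trials # 48
protocol_config <- function(n_subjects = 69,
                            words = word_affect_stats()$word,
                            n_sessions = 3,
                            baseline_duration = 1,
                            recall_duration = 10,
                            annotation_duration = 10,
                            native_rate = 512,
                            channel_names = eeg_channels()) {
  stopifnot(n_subjects >= 1, n_sessions >= 1, length(channel_names) == 14L)
  if (baseline_duration * native_rate %% 1 != 0 ||
      recall_duration * native_rate %% 1 != 0) {
    stop("baseline and recall durations must be integer numbers of samples")
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    words = words,
    n_sessions = as.integer(n_sessions),
    baseline_duration = baseline_duration,
    recall_duration = recall_duration,
    annotation_duration = annotation_duration,
    native_rate = native_rate,
    channel_names = channel_names,
    n_trials = length(words) * as.integer(n_sessions)
  ), class = "protocol_config")
}

#' Per-word self-annotation statistics
#'
#' The word-level valence/arousal annotation statistics the generator
#' samples from: per-word mean and standard deviation of the integer
#' -4..4 self-ratings, and the observed per-word quadrant counts
#' (HVHA, HVLA, LVHA, LVLA plus unclassifiable "None" trials in which
#' one of the two ratings was zero).
#'
#' @return A tibble with one row per cue word: `word`, `valence_mean`,
#'   `valence_sd`, `arousal_mean`, `arousal_sd`, `n_hvha`, `n_hvla`,
#'   `n_lvha`, `n_lvla`, `n_none`.
#' @export
#' @examples
#' word_affect_stats()
word_affect_stats <- function() {
  tibble::tribble(
    ~word, ~valence_mean, ~valence_sd, ~arousal_mean, ~arousal_sd,
    ~n_hvha, ~n_hvla, ~n_lvha, ~n_lvla, ~n_none,
    "Excited",         2.8213, 1.3409,  2.9420, 1.3426, 191,  1,  1,   4, 10,
    "Cheerful",        2.8357, 1.4588,  2.8454, 1.3054, 190,  0,  1,   4, 12,
    "Bored",          -1.6763, 1.7644, -0.8019, 2.1912,   2, 14, 50, 109, 12,
    "Unhappy",        -2.3961, 1.7003, -0.9420, 2.4329,   9,  8, 52, 126, 12,
    "Disappointment", -2.3382, 1.8829, -0.9130, 2.4834,  10,  8, 59, 118, 12,
    "Fearful",        -2.3623, 1.6777, -2.0628, 2.6349,  14,  4, 86,  92, 11,
    "Alert",          -0.3671, 2.3853,  2.3092, 1.6073,  85,  3, 98,  10, 11,
    "Aroused",         1.7778, 2.2008,  2.0676, 1.8787, 147,  9, 24,  13, 14,
    "Idle",           -1.0773, 1.8018, -0.4251, 1.9738,  50, 12, 39,  85, 21,
    "Lively",          2.5942, 1.6219,  2.8406, 1.2766, 183,  0,  7,   3, 14,
    "Calm",            2.3671, 1.5361,  1.1304, 2.2027, 150, 37,  5,   4, 11,
    "Relaxed",         2.6667, 1.5201,  1.5894, 2.2856, 161, 30,  5,   4,  7,
    "Pleased",         2.8841, 1.5092,  2.8019, 1.4294, 186,  3,  4,   3, 11,
    "Still",          -1.2174, 1.8424, -0.7343, 1.8518,  36, 20, 36,  98, 17,
    "Dulled",         -1.7536, 1.6641, -0.9034, 1.9411,   8,  8, 41, 125, 15,
    "Nervous",        -2.0676, 1.7081,  0.1787, 2.6110,  19,  6, 91,  81, 10
  )
}

#' Spectral class signature for one quadrant
#'
#' The synthetic stand-in for class-discriminative EEG content: during
#' recall, a quadrant's trials carry band-limited oscillations whose
#' per-band RMS amplitudes are given by `band_gains`, superimposed on
#' 1/f background noise of scale `noise_scale`. `subject_gain_spread`
#' is the log-normal sdlog of per-subject, per-band multiplicative
#' gains, creating the inter-subject variability that makes
#' leave-one-subject-out validation harder than random splits.
#'
#' @param quadrant One of `"HVHA"`, `"HVLA"`, `"LVHA"`, `"LVLA"`.
#' @param band_gains Named numeric vector over
#'   `c("delta","theta","alpha","beta","gamma")`; non-negative RMS
#'   amplitudes (arbitrary units, same scale as `noise_scale`).
#' @param noise_scale Non-negative RMS of the 1/f background.
#' @param subject_gain_spread Non-negative sdlog of the per-subject
#'   log-normal band gain multipliers.
#' @param freq_ranges Optional named list mapping a band to a
#'   `c(lo, hi)` Hz range inside that band; the quadrant's
#'   oscillations for that band are drawn from this sub-range instead
#'   of the full band. Lets classes be coded by frequency at equal
#'   power.
#'
#' @return An object of class `class_signature`.
#' @export
class_signature <- function(quadrant,
                            band_gains = c(delta = 0, theta = 0, alpha = 0,
                                           beta = 0, gamma = 0),
                            noise_scale = 1,
                            subject_gain_spread = 0.25,
                            freq_ranges = list()) {
  stopifnot(quadrant %in% QUADRANTS, noise_scale >= 0,
            subject_gain_spread >= 0, all(band_gains >= 0))
  gains <- c(delta = 0, theta = 0, alpha = 0, beta = 0, gamma = 0)
  gains[names(band_gains)] <- band_gains
  for (nm in names(freq_ranges)) {
    stopifnot(nm %in% names(RHYTHM_BANDS),
              freq_ranges[[nm]][1] >= RHYTHM_BANDS[[nm]][1],
              freq_ranges[[nm]][2] <= RHYTHM_BANDS[[nm]][2])
  }
  structure(list(quadrant = quadrant, band_gains = gains,
                 noise_scale = noise_scale,
                 subject_gain_spread = subject_gain_spread,
                 freq_ranges = freq_ranges),
            class = "class_signature")
}

#' Ready-made signature sets
#'
#' Named presets covering the study conditions the package's own
#' experiments use: `"strong"` gives each quadrant a large oscillation
#' in a distinct rhythm band (alpha/beta/theta/gamma for
#' HVHA/HVLA/LVHA/LVLA, RMS 4x the noise floor), `"null"` sets every
#' band gain to zero (labels carry no signal; classification must fall
#' to chance), and `"alpha"` codes the quadrants by alpha-band
#' frequency at equal power (four sub-ranges of 8-13 Hz) so that the
#' alpha band, and only the alpha band, is class-informative -- an
#' equal-power coding is required because per-segment z-scoring would
#' otherwise couple amplitude differences into every band's relative
#' noise floor.
#'
#' @param preset One of `"strong"`, `"null"`, `"alpha"`.
#' @param noise_scale Background 1/f RMS passed to every signature.
#' @param subject_gain_spread Per-subject gain sdlog passed to every
#'   signature.
#'
#' @return Named list of four `class_signature` objects.
#' @export
#' @examples
#' sig <- signature_preset("strong")
#' sig$HVHA$band_gains
signature_preset <- function(preset = c("strong", "null", "alpha"),
                             noise_scale = 1,
                             subject_gain_spread = 0.25) {
  preset <- match.arg(preset)
  gains <- switch(preset,
    strong = list(HVHA = c(alpha = 4), HVLA = c(beta = 4),
                  LVHA = c(theta = 4), LVLA = c(gamma = 4)),
    null = list(HVHA = c(alpha = 0), HVLA = c(alpha = 0),
                LVHA = c(alpha = 0), LVLA = c(alpha = 0)),
    alpha = list(HVHA = c(alpha = 4), HVLA = c(alpha = 4),
                 LVHA = c(alpha = 4), LVLA = c(alpha = 4))
  )
  freqs <- if (preset == "alpha") {
    list(HVHA = list(alpha = c(8, 9.25)),
         HVLA = list(alpha = c(9.25, 10.5)),
         LVHA = list(alpha = c(10.5, 11.75)),
         LVLA = list(alpha = c(11.75, 13)))
  } else {
    list(HVHA = list(), HVLA = list(), LVHA = list(), LVLA = list())
  }
  out <- lapply(QUADRANTS, function(q) {
    class_signature(q, gains[[q]], noise_scale = noise_scale,
                    subject_gain_spread = subject_gain_spread,
                    freq_ranges = freqs[[q]])
  })
  names(out) <- QUADRANTS
  out
}

#' Sample a self-annotation for one word
#'
#' Draws valence and arousal independently from the word's normal
#' annotation distribution, rounds to the nearest integer and clips to
#' the -4..4 rating grid.
#'
#' @param stats One row of [word_affect_stats()] (data frame or list).
#'
#' @return A list with integer `valence`, `arousal`, and `word`.
#' @export
#' @examples
#' set.seed(1)
#' s <- word_affect_stats()[1, ]
#' sample_annotation(s)
sample_annotation <- function(stats) {
  v <- rnorm(1, stats$valence_mean, stats$valence_sd)
  a <- rnorm(1, stats$arousal_mean, stats$arousal_sd)
  clip <- function(x) as.integer(pmin(4, pmax(-4, round(x))))
  list(valence = clip(v), arousal = clip(a), word = stats$word)
}

#' Sample a self-annotation from the word's observed quadrant counts
#'
#' Alternative categorical sampler giving exact marginal control: the
#' quadrant (or "None") is drawn with probability proportional to the
#' word's observed counts, then an integer rating pair consistent with
#' that quadrant is drawn from the word's truncated, rounded normal
#' distribution ("None" yields a zero on one axis).
#'
#' @inheritParams sample_annotation
#' @return A list with integer `valence`, `arousal`, and `word`.
#' @export
sample_annotation_categorical <- function(stats) {
  counts <- c(HVHA = stats$n_hvha, HVLA = stats$n_hvla,
              LVHA = stats$n_lvha, LVLA = stats$n_lvla,
              None = stats$n_none)
  q <- sample(names(counts), 1, prob = counts)
  draw_signed <- function(mean, sd, sign) {
    # rejection-sample an integer rating with the required sign
    for (i in 1:200) {
      x <- as.integer(pmin(4, pmax(-4, round(rnorm(1, mean, sd)))))
      if (sign > 0 && x > 0) return(x)
      if (sign < 0 && x < 0) return(x)
    }
    as.integer(sign) # fallback: the nearest in-quadrant rating
  }
  if (q == "None") {
    if (runif(1) < 0.5) {
      v <- 0L
      a <- as.integer(pmin(4, pmax(-4, round(rnorm(1, stats$arousal_mean,
                                                   stats$arousal_sd)))))
    } else {
      a <- 0L
      v <- as.integer(pmin(4, pmax(-4, round(rnorm(1, stats$valence_mean,
                                                   stats$valence_sd)))))
    }
  } else {
    sv <- if (q %in% c("HVHA", "HVLA")) 1 else -1
    sa <- if (q %in% c("HVHA", "LVHA")) 1 else -1
    v <- draw_signed(stats$valence_mean, stats$valence_sd, sv)
    a <- draw_signed(stats$arousal_mean, stats$arousal_sd, sa)
  }
  list(valence = v, arousal = a, word = stats$word)
}

#' Map a rating pair to its valence-arousal quadrant
#'
#' Positive/negative valence and arousal define the four quadrants; a
#' zero on either axis is unclassifiable and returns `NA` (such trials
#' are excluded from the four-class dataset).
#'
#' @param valence Integer vector of valence ratings in -4..4.
#' @param arousal Integer vector of arousal ratings in -4..4.
#'
#' @return Character vector of quadrant labels (`"HVHA"`, `"HVLA"`,
#'   `"LVHA"`, `"LVLA"`) or `NA` for zero-axis ratings.
#' @export
#' @examples
#' quadrant_of(c(3, 0, -1), c(3, 4, 2)) # "HVHA" NA "LVHA"
quadrant_of <- function(valence, arousal) {
  out <- rep(NA_character_, length(valence))
  out[valence > 0 & arousal > 0] <- "HVHA"
  out[valence > 0 & arousal < 0] <- "HVLA"
  out[valence < 0 & arousal > 0] <- "LVHA"
  out[valence < 0 & arousal < 0] <- "LVLA"
  out
}

# 1/f ("pink") noise via spectral shaping: white Gaussian spectrum
# scaled by f^(-1/2), inverse transformed, normalised to unit RMS.
pink_noise <- function(n) {
  if (n < 4) return(rnorm(n))
  # pad to a 2-3-5-smooth length so the FFT stays fast, then truncate
  n_fft <- stats::nextn(n, c(2, 3, 5))
  if (n_fft > n) {
    x <- pink_noise_exact(n_fft)[seq_len(n)]
    return(x / sd(x))
  }
  pink_noise_exact(n)
}

pink_noise_exact <- function(n) {
  m <- n %/% 2
  f <- seq_len(m)
  amp <- f^(-0.5)
  phase <- runif(m, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- complex(real = numeric(n))
  full[2:(m + 1)] <- spec
  if (n %% 2 == 0) {
    full[m + 1] <- complex(real = Re(spec[m]))
    if (m > 1) full[(m + 2):n] <- Conj(spec[(m - 1):1])
  } else {
    full[(m + 2):n] <- Conj(spec[m:1])
  }
  x <- Re(fft(full, inverse = TRUE)) / n
  x / sd(x)
}

RHYTHM_BANDS <- list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
                     beta = c(13, 30), gamma = c(30, 49))

# band-limited oscillation: sum of sinusoids at random in-band
# frequencies and phases, scaled to the requested RMS
band_oscillation <- function(n, rate, band, rms, n_sin = 3) {
  freqs <- runif(n_sin, band[1], band[2])
  phases <- runif(n_sin, 0, 2 * pi)
  t <- seq_len(n) / rate
  x <- rowSums(vapply(seq_len(n_sin),
                      function(i) sin(2 * pi * freqs[i] * t + phases[i]),
                      numeric(n)))
  x * rms / sd(x)
}

#' Synthesise one subject's recording session
#'
#' Builds a continuous 14-channel recording following the acquisition
#' protocol: for each of the subject's trials a cue word is shown
#' (each word once per session, in per-session shuffled order), a
#' self-annotation is sampled from the word's statistics, and the
#' signal carries a 1-s neutral 1/f-noise baseline followed by a 10-s
#' recall period in which the annotation's quadrant adds its spectral
#' signature (band-limited oscillations scaled by the subject's
#' log-normal band gains) to the noise floor. Trials annotated on a
#' zero axis ("None") contribute noise only.
#'
#' @param subject_id Subject identifier (integer or string).
#' @param protocol A [protocol_config()].
#' @param signatures Named list of [class_signature()] covering all
#'   four quadrants.
#' @param stats Word statistics table, as [word_affect_stats()].
#' @param seed Integer seed; the session is a deterministic function
#'   of it.
#' @param sampler `"gaussian"` ([sample_annotation()]) or
#'   `"categorical"` ([sample_annotation_categorical()]).
#'
#' @return An object of class `recording_session`: list with
#'   `subject_id`, `rate`, `signal` (14 x samples matrix), `markers`
#'   (tibble of recall-onset sample indices and words), and
#'   `annotations` (tibble of word, valence, arousal per trial).
#' @export
#' @examples
#' p <- protocol_config(n_subjects = 1, n_sessions = 1)
#' s <- generate_session(1, p, signature_preset("strong"),
#'                       word_affect_stats(), seed = 7)
#' nrow(s$markers) # 16
generate_session <- function(subject_id, protocol, signatures, stats,
                             seed = 1,
                             sampler = c("gaussian", "categorical")) {
  sampler <- match.arg(sampler)
  missing_q <- setdiff(QUADRANTS, names(signatures))
  if (length(missing_q) > 0) {
    stop("missing class signature for quadrant(s): ",
         paste(missing_q, collapse = ", "))
  }
  set.seed(seed)
  rate <- protocol$native_rate
  n_ch <- length(protocol$channel_names)
  nb <- as.integer(protocol$baseline_duration * rate)
  nr <- as.integer(protocol$recall_duration * rate)
  na <- as.integer(protocol$annotation_duration * rate)
  trial_len <- nb + nr + na
  lead_in <- rate # 1 s of extra context before the first trial
  n_trials <- protocol$n_trials
  total <- lead_in + n_trials * trial_len

  # per-subject log-normal band gain multipliers (inter-subject spread
  # taken from the first signature; the spread is a cohort property)
  spread <- signatures[[1]]$subject_gain_spread
  subj_gain <- stats::rlnorm(5, meanlog = 0, sdlog = spread)
  names(subj_gain) <- names(RHYTHM_BANDS)

  # word order: each session is an independent shuffle of the 16 words
  word_seq <- unlist(lapply(seq_len(protocol$n_sessions),
                            function(s) sample(protocol$words)))

  sample_fun <- if (sampler == "gaussian") sample_annotation else
    sample_annotation_categorical
  stats_by_word <- split(stats, stats$word)

  noise_scale <- signatures[[1]]$noise_scale
  signal <- matrix(0, nrow = n_ch, ncol = total)
  if (noise_scale > 0) {
    for (ch in seq_len(n_ch)) {
      signal[ch, ] <- noise_scale * pink_noise(total)
    }
  }

  markers <- integer(n_trials)
  ann <- vector("list", n_trials)
  for (j in seq_len(n_trials)) {
    w <- word_seq[j]
    a <- sample_fun(stats_by_word[[w]][1, ])
    ann[[j]] <- a
    onset <- lead_in + (j - 1L) * trial_len + nb + 1L
    markers[j] <- onset
    q <- quadrant_of(a$valence, a$arousal)
    if (!is.na(q)) {
      sig <- signatures[[q]]
      # per-channel weighting keeps channels correlated but not equal
      ch_w <- runif(n_ch, 0.5, 1)
      for (band in names(RHYTHM_BANDS)) {
        g <- sig$band_gains[[band]] * subj_gain[[band]]
        if (g > 0) {
          rng <- sig$freq_ranges[[band]]
          if (is.null(rng)) rng <- RHYTHM_BANDS[[band]]
          osc <- band_oscillation(nr, rate, rng, g)
          idx <- onset:(onset + nr - 1L)
          signal[, idx] <- signal[, idx] + outer(ch_w, osc)
        }
      }
    }
  }
  rownames(signal) <- protocol$channel_names
  structure(list(
    subject_id = subject_id,
    rate = rate,
    signal = signal,
    markers = tibble::tibble(sample = markers, word = word_seq),
    annotations = tibble::tibble(
      word = word_seq,
      valence = vapply(ann, `[[`, integer(1), "valence"),
      arousal = vapply(ann, `[[`, integer(1), "arousal")
    )
  ), class = "recording_session")
}

#' @export
print.recording_session <- function(x, ...) {
  cat("<recording_session> subject", x$subject_id, "-",
      nrow(x$signal), "channels x", ncol(x$signal), "samples @",
      x$rate, "Hz,", nrow(x$markers), "trials\n")
  invisible(x)
}

#' Synthesise a cohort of recording sessions
#'
#' One session per subject, each generated from a seed derived
#' deterministically from `master_seed`, so the whole cohort is
#' reproducible end-to-end.
#'
#' @inheritParams generate_session
#' @param master_seed Integer seed for the cohort.
#'
#' @return List of `recording_session` objects, length
#'   `protocol$n_subjects`.
#' @export
generate_cohort <- function(protocol, signatures,
                            stats = word_affect_stats(),
                            master_seed = 1,
                            sampler = c("gaussian", "categorical")) {
  sampler <- match.arg(sampler)
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, protocol$n_subjects)
  lapply(seq_len(protocol$n_subjects), function(i) {
    generate_session(i, protocol, signatures, stats,
                     seed = seeds[i], sampler = sampler)
  })
}
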