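#' Confusion matrix (rows predicted, columns true)
#'
#' Counts of (predicted, true) label pairs over the four quadrants in
#' canonical order.
#'
#' @param true_labels Character/factor vector of true quadrants.
#' @param predicted_labels Same length, predicted quadrants.
#' @return A 4 x 4 integer matrix of class `confusion_matrix`; rows
#'   are the predicted (output) class, columns the true (target)
#'   class.
#' @export
confusion_matrix <- function(true_labels, predicted_labels) {
  stopifnot(length(true_labels) == length(predicted_labels))
  if (!all(c(true_labels, predicted_labels) %in% QUADRANTS)) {
    stop("labels outside the four-quadrant set")
  }
  tr <- factor(true_labels, levels = QUADRANTS)
  pr <- factor(predicted_labels, levels = QUADRANTS)
  cm <- table(predicted = pr, true = tr)
  out <- matrix(as.integer(cm), 4, 4,
                dimnames = list(predicted = QUADRANTS, true = QUADRANTS))
  structure(out, class = c("confusion_matrix", "matrix"))
}

#' Classification metrics from a confusion matrix
#'
#' One-vs-rest TP/FP/TN/FN per class, yielding precision
#' `TP / (TP + FP)`, sensitivity `TP / (TP + FN)`, specificity
#' `TN / (TN + FP)` and F-measure (harmonic mean of precision and
#' sensitivity); overall accuracy is the trace over the total count.
#' A zero denominator yields `NA` (flagged, not an error).
#'
#' @param cm A `confusion_matrix` (or 4 x 4 count matrix, rows
#'   predicted).
#' @return An object of class `metrics_report`: list with `per_class`
#'   (tibble: class, tp, fp, fn, tn, precision, sensitivity,
#'   specificity, f_measure) and `accuracy`.
#' @export
metrics_from_cm <- function(cm) {
  cm <- unclass(cm)
  total <- sum(cm)
  stopifnot(total > 0)
  safe_div <- function(num, den) ifelse(den == 0, NA_real_, num / den)
  rows <- lapply(seq_len(nrow(cm)), function(i) {
    tp <- cm[i, i]
    fp <- sum(cm[i, ]) - tp # predicted i, true other
    fn <- sum(cm[, i]) - tp # true i, predicted other
    tn <- total - tp - fp - fn
    precision <- safe_div(tp, tp + fp)
    sensitivity <- safe_div(tp, tp + fn)
    specificity <- safe_div(tn, tn + fp)
    f <- safe_div(2 * precision * sensitivity, precision + sensitivity)
    tibble::tibble(class = QUADRANTS[i], tp = tp, fp = fp, fn = fn,
                   tn = tn, precision = precision,
                   sensitivity = sensitivity, specificity = specificity,
                   f_measure = f)
  })
  structure(list(per_class = dplyr::bind_rows(rows),
                 accuracy = sum(diag(cm)) / total,
                 total = total),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> accuracy", signif(x$accuracy, 4), "on",
      x$total, "samples\n")
  print(x$per_class)
  invisible(x)
}

# mean and population (divide-by-N) standard deviation
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

protocol_result <- function(runs, cms, protocol) {
  structure(list(runs = runs, cms = cms, protocol = protocol,
                 mean_accuracy = mean(runs$accuracy),
                 sd_accuracy = pop_sd(runs$accuracy)),
            class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat("<protocol_result>", x$protocol, "-", nrow(x$runs), "run(s)\n")
  cat("  mean accuracy", signif(x$mean_accuracy, 4),
      " population sd", signif(x$sd_accuracy, 4), "\n")
  invisible(x)
}

# train CRNN on the train split, extract features, fit ELM on an
# internal 80:20 split of the train features, evaluate on test
fit_and_score <- function(dataset, train_idx, test_idx, crnn_cfg,
                          elm_hidden, seed) {
  train_ds <- subset_dataset(dataset, train_idx)
  test_ds <- subset_dataset(dataset, test_idx)
  fit <- train_crnn(train_ds, crnn_cfg)
  tr_feat <- extract_features(train_ds, fit)
  te_feat <- extract_features(test_ds, fit)
  tr_lab <- train_ds$manifest$label
  sp <- internal_split(tr_lab, 0.8, seed = seed)
  model <- elm_fit(tr_feat[sp$train, ], tr_lab[sp$train],
                   n_hidden = elm_hidden, seed = seed)
  val_acc <- mean(elm_predict(model, tr_feat[sp$validation, ])$labels ==
                    tr_lab[sp$validation])
  pred <- elm_predict(model, te_feat)$labels
  truth <- test_ds$manifest$label
  list(accuracy = mean(pred == truth),
       val_accuracy = val_acc,
       cm = confusion_matrix(truth, pred),
       crnn_fit = fit)
}

#' Repeated random-split evaluation protocol
#'
#' Repeats an 80:20 random split of the (balanced) segment dataset:
#' per repeat the CRNN is trained on the train side, ELM features are
#' extracted, the ELM is fitted on an internal 80:20 split of the
#' train features, and accuracy is measured on the held-out test
#' segments. Splits are at segment level by default (sibling segments
#' of one trial may straddle the split); `group_by` offers
#' leakage-safe alternatives.
#'
#' @param dataset A balanced `segment_dataset`.
#' @param crnn_cfg A [crnn_config()].
#' @param elm_hidden ELM hidden-layer size.
#' @param n_repeats Number of random splits (default 3).
#' @param train_frac Training fraction (default 0.8).
#' @param group_by `"segment"`, `"trial"` or `"subject"` split
#'   granularity.
#' @param seed Master seed; per-repeat seeds are derived from it.
#' @return A `protocol_result` with one row per repeat, mean accuracy
#'   and population standard deviation.
#' @export
random_split_protocol <- function(dataset, crnn_cfg = crnn_config(),
                                  elm_hidden = 9000, n_repeats = 3,
                                  train_frac = 0.8,
                                  group_by = c("segment", "trial",
                                               "subject"),
                                  seed = 1) {
  group_by <- match.arg(group_by)
  n <- dim(dataset$data)[3]
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_repeats)
  runs <- vector("list", n_repeats)
  cms <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    set.seed(rep_seeds[r])
    if (group_by == "segment") {
      train_idx <- sort(sample(n, round(train_frac * n)))
    } else {
      key <- if (group_by == "trial") {
        paste(dataset$manifest$subject_id, dataset$manifest$trial_id)
      } else {
        as.character(dataset$manifest$subject_id)
      }
      groups <- unique(key)
      tr_groups <- sample(groups, round(train_frac * length(groups)))
      train_idx <- which(key %in% tr_groups)
    }
    test_idx <- setdiff(seq_len(n), train_idx)
    cfg <- crnn_cfg
    cfg$seed <- rep_seeds[r] %% 100000L
    res <- fit_and_score(dataset, train_idx, test_idx, cfg, elm_hidden,
                         seed = cfg$seed + 1L)
    runs[[r]] <- tibble::tibble(run = r, accuracy = res$accuracy,
                                val_accuracy = res$val_accuracy,
                                n_train = length(train_idx),
                                n_test = length(test_idx))
    cms[[r]] <- res$cm
  }
  protocol_result(dplyr::bind_rows(runs), cms, "random_split")
}

#' Leave-one-subject-out evaluation protocol
#'
#' Per held-out subject, the full pipeline (CRNN training, feature
#' extraction, ELM) is re-fitted on all other subjects' segments and
#' evaluated on the held-out subject's segments, measuring
#' subject-independent generalisation.
#'
#' @inheritParams random_split_protocol
#' @return A `protocol_result` with one run per subject (subjects
#'   without labeled segments are skipped with a warning).
#' @export
loso_protocol <- function(dataset, crnn_cfg = crnn_config(),
                          elm_hidden = 9000, seed = 1) {
  subjects <- unique(dataset$manifest$subject_id)
  stopifnot(length(subjects) >= 2)
  runs <- list()
  cms <- list()
  for (si in seq_along(subjects)) {
    s <- subjects[si]
    test_idx <- which(dataset$manifest$subject_id == s)
    if (length(test_idx) == 0) {
      warning("subject ", s, " has no labeled segments; skipped")
      next
    }
    train_idx <- setdiff(seq_len(dim(dataset$data)[3]), test_idx)
    cfg <- crnn_cfg
    cfg$seed <- (seed * 1000L + si) %% .Machine$integer.max
    res <- fit_and_score(dataset, train_idx, test_idx, cfg, elm_hidden,
                         seed = cfg$seed + 1L)
    runs[[length(runs) + 1L]] <-
      tibble::tibble(run = length(runs) + 1L, subject_id = s,
                     accuracy = res$accuracy,
                     val_accuracy = res$val_accuracy,
                     n_train = length(train_idx),
                     n_test = length(test_idx))
    cms[[length(cms) + 1L]] <- res$cm
  }
  protocol_result(dplyr::bind_rows(runs), cms, "loso")
}

#' Per-rhythm evaluation
#'
#' Runs the random-split protocol independently on each requested
#' rhythm band and, optionally, on the all-band combination in which
#' the five per-band 32-dimensional CRNN feature vectors are
#' concatenated (160 features) before the ELM.
#'
#' @param dataset A balanced broadband `segment_dataset`.
#' @param bands Bands to evaluate (subset of delta..gamma).
#' @param include_combined Also evaluate the concatenated all-band
#'   features (requires all five bands).
#' @inheritParams random_split_protocol
#' @param group_by Split granularity passed to the per-band protocols.
#' @return Named list of `protocol_result`, one per band (plus
#'   `"all"` when combined).
#' @export
per_rhythm_evaluation <- function(dataset, crnn_cfg = crnn_config(),
                                  elm_hidden = 9000,
                                  bands = c("delta", "theta", "alpha",
                                            "beta", "gamma"),
                                  include_combined = FALSE,
                                  n_repeats = 1,
                                  group_by = c("segment", "trial",
                                               "subject"),
                                  seed = 1) {
  group_by <- match.arg(group_by)
  band_ds <- rhythm_datasets(dataset, bands)
  out <- lapply(bands, function(b) {
    random_split_protocol(band_ds[[b]], crnn_cfg, elm_hidden,
                          n_repeats = n_repeats, group_by = group_by,
                          seed = seed)
  })
  names(out) <- bands
  if (include_combined) {
    stopifnot(setequal(bands, c("delta", "theta", "alpha", "beta",
                                "gamma")))
    out$all <- combined_band_protocol(band_ds, crnn_cfg, elm_hidden,
                                      n_repeats = n_repeats, seed = seed)
  }
  out
}

# all-band combination: per band, train a CRNN on the train split of
# that band's segments and extract 32 features; concatenate across
# bands (160 features) into the ELM
combined_band_protocol <- function(band_ds, crnn_cfg, elm_hidden,
                                   n_repeats = 1, seed = 1) {
  first <- band_ds[[1]]
  n <- dim(first$data)[3]
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_repeats)
  runs <- vector("list", n_repeats)
  cms <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    set.seed(rep_seeds[r])
    train_idx <- sort(sample(n, round(0.8 * n)))
    test_idx <- setdiff(seq_len(n), train_idx)
    tr_parts <- list(); te_parts <- list()
    for (b in names(band_ds)) {
      cfg <- crnn_cfg
      cfg$seed <- (rep_seeds[r] + match(b, names(band_ds))) %% 100000L
      tr_ds <- subset_dataset(band_ds[[b]], train_idx)
      te_ds <- subset_dataset(band_ds[[b]], test_idx)
      fit <- train_crnn(tr_ds, cfg)
      tr_parts[[b]] <- feature_matrix(extract_features(tr_ds, fit))
      te_parts[[b]] <- feature_matrix(extract_features(te_ds, fit))
    }
    Xtr <- do.call(cbind, tr_parts)
    Xte <- do.call(cbind, te_parts)
    tr_lab <- first$manifest$label[train_idx]
    truth <- first$manifest$label[test_idx]
    sp <- internal_split(tr_lab, 0.8, seed = rep_seeds[r] %% 100000L)
    model <- elm_fit(Xtr[sp$train, , drop = FALSE], tr_lab[sp$train],
                     n_hidden = elm_hidden, seed = rep_seeds[r] %% 100000L)
    pred <- elm_predict(model, Xte)$labels
    runs[[r]] <- tibble::tibble(run = r, accuracy = mean(pred == truth),
                                val_accuracy = NA_real_,
                                n_train = length(train_idx),
                                n_test = length(test_idx))
    cms[[r]] <- confusion_matrix(truth, pred)
  }
  protocol_result(dplyr::bind_rows(runs), cms, "random_split_combined")
}

#' Compare classifiers on a fixed feature fold
#'
#' Trains several classifiers on identical train/test folds of the
#' extracted features and tabulates their test accuracies: the ELM,
#' a softmax (multinomial logistic) layer, a support vector machine,
#' k-nearest neighbours and a random forest, each at its library
#' defaults.
#'
#' @param features Feature tibble or matrix.
#' @param labels Quadrant labels, length `nrow(features)`.
#' @param classifiers Subset of
#'   `c("elm", "softmax", "svm", "knn", "rf")`.
#' @param elm_hidden ELM hidden-layer size.
#' @param train_frac Training fraction of the shared fold.
#' @param seed Integer seed fixing the fold and every stochastic
#'   classifier.
#' @return A tibble with columns `classifier` and `accuracy`.
#' @export
classifier_comparison <- function(features, labels,
                                  classifiers = c("elm", "softmax",
                                                  "svm", "knn", "rf"),
                                  elm_hidden = 9000, train_frac = 0.8,
                                  seed = 1) {
  X <- feature_matrix(features)
  labels <- as.character(labels)
  set.seed(seed)
  n <- nrow(X)
  train <- sort(sample(n, round(train_frac * n)))
  test <- setdiff(seq_len(n), train)
  ytr <- factor(labels[train], levels = QUADRANTS)
  yte <- labels[test]
  acc <- vapply(classifiers, function(cl) {
    set.seed(seed)
    pred <- switch(cl,
      elm = {
        m <- elm_fit(X[train, , drop = FALSE], labels[train],
                     n_hidden = elm_hidden, seed = seed)
        elm_predict(m, X[test, , drop = FALSE])$labels
      },
      softmax = {
        df <- data.frame(y = ytr, X[train, , drop = FALSE])
        m <- nnet::multinom(y ~ ., data = df, trace = FALSE,
                            MaxNWts = 10000)
        as.character(predict(m, data.frame(X[test, , drop = FALSE])))
      },
      svm = {
        m <- e1071::svm(X[train, , drop = FALSE], ytr)
        as.character(predict(m, X[test, , drop = FALSE]))
      },
      knn = {
        as.character(class::knn(X[train, , drop = FALSE],
                                X[test, , drop = FALSE], ytr))
      },
      rf = {
        m <- randomForest::randomForest(X[train, , drop = FALSE], ytr)
        as.character(predict(m, X[test, , drop = FALSE]))
      },
      stop("unknown classifier: ", cl)
    )
    mean(pred == yte)
  }, numeric(1))
  tibble::tibble(classifier = classifiers, accuracy = unname(acc))
}
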