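test_that("confusion matrix counts predicted-by-true pairs", {
  truth <- rep(quadrant_levels(), each = 2)
  cm <- confusion_matrix(truth, truth)
  expect_equal(unname(diag(unclass(cm))), rep(2L, 4))
  expect_equal(sum(cm), 8)
  # degenerate predictor puts everything in the first row
  cm2 <- confusion_matrix(truth, rep("HVHA", 8))
  expect_equal(unname(unclass(cm2)[1, ]), rep(2L, 4))
  expect_equal(sum(unclass(cm2)[-1, ]), 0)
  # dictionary-counting oracle on random labels
  set.seed(2)
  tr <- sample(quadrant_levels(), 200, replace = TRUE)
  pr <- sample(quadrant_levels(), 200, replace = TRUE)
  cm3 <- unclass(confusion_matrix(tr, pr))
  for (i in 1:4) for (j in 1:4) {
    expect_identical(cm3[i, j],
                     sum(pr == quadrant_levels()[i] &
                           tr == quadrant_levels()[j]))
  }
  expect_error(confusion_matrix(c("HVHA", "X"), c("HVHA", "HVHA")),
               "outside")
})

test_that("metric arithmetic reproduces the reference confusion matrix", {
  cm <- reference_cm_counts()
  rep_ <- metrics_from_cm(cm)
  pc <- rep_$per_class
  expect_equal(pc$precision[pc$class == "HVLA"], 270 / 306,
               tolerance = 1e-12)
  expect_equal(round(100 * pc$precision[pc$class == "HVLA"], 1), 88.2)
  expect_equal(round(100 * pc$precision[pc$class == "HVHA"], 1), 49.1)
  expect_equal(round(100 * rep_$accuracy, 1), 65.6)
  # per-class one-vs-rest counts always partition the total
  expect_true(all(pc$tp + pc$fp + pc$fn + pc$tn == sum(cm)))
  # perfect classifier: all metrics one
  perf <- metrics_from_cm(diag(c(5, 7, 9, 11)))
  expect_true(all(perf$per_class$precision == 1))
  expect_true(all(perf$per_class$specificity == 1))
  expect_identical(perf$accuracy, 1)
})

test_that("metrics are equivariant under class permutation", {
  cm <- reference_cm_counts()
  perm <- c(3, 1, 4, 2)
  cmp <- cm[perm, perm]
  a <- metrics_from_cm(cm)$per_class
  b <- metrics_from_cm(cmp)$per_class
  expect_equal(b$precision, a$precision[perm])
  expect_equal(b$sensitivity, a$sensitivity[perm])
  expect_equal(b$f_measure, a$f_measure[perm])
})

test_that("accuracy from the matrix equals direct label agreement", {
  set.seed(3)
  tr <- sample(quadrant_levels(), 500, replace = TRUE)
  pr <- sample(quadrant_levels(), 500, replace = TRUE)
  expect_equal(metrics_from_cm(confusion_matrix(tr, pr))$accuracy,
               mean(tr == pr))
})

test_that("zero denominators yield flagged NA, not errors", {
  cm <- matrix(0L, 4, 4)
  cm[2, ] <- c(5L, 6L, 7L, 8L) # everything predicted HVLA
  rep_ <- metrics_from_cm(cm)
  expect_true(is.na(rep_$per_class$precision[1])) # no HVHA predictions
  expect_false(is.na(rep_$per_class$precision[2]))
})

test_that("split aggregation uses mean and population deviation", {
  runs <- c(65.64, 66.03, 65.26)
  expect_equal(round(mean(runs), 2), 65.64)
  psd <- memoraffect:::pop_sd(runs)
  expect_equal(round(psd, 2), 0.31)
  # constant accuracies aggregate to zero deviation
  expect_identical(memoraffect:::pop_sd(c(0.5, 0.5, 0.5)), 0)
  # oracle on random lists
  set.seed(4)
  x <- runif(7)
  expect_equal(memoraffect:::pop_sd(x),
               sqrt(sum((x - mean(x))^2) / length(x)), tolerance = 1e-12)
})

test_that("leave-one-subject-out yields one fold per subject", {
  ds <- random_dataset(n = 48, n_subjects = 3)
  cfg <- crnn_config(epochs = 1, batch_size = 16, seed = 1)
  res <- loso_protocol(ds, cfg, elm_hidden = 40, seed = 2)
  expect_s3_class(res, "protocol_result")
  expect_equal(nrow(res$runs), 3)
  expect_setequal(res$runs$subject_id, 1:3)
  g <- glance(res)
  expect_equal(g$mean_accuracy, mean(res$runs$accuracy))
  expect_equal(g$sd_accuracy, memoraffect:::pop_sd(res$runs$accuracy))
})

test_that("random-split protocol is seeded and reports every repeat", {
  ds <- random_dataset(n = 48, n_subjects = 2)
  cfg <- crnn_config(epochs = 1, batch_size = 16, seed = 1)
  r1 <- random_split_protocol(ds, cfg, elm_hidden = 40, n_repeats = 2,
                              seed = 5)
  r2 <- random_split_protocol(ds, cfg, elm_hidden = 40, n_repeats = 2,
                              seed = 5)
  expect_equal(nrow(r1$runs), 2)
  expect_identical(r1$runs$accuracy, r2$runs$accuracy)
  expect_length(r1$cms, 2)
  expect_true(all(vapply(r1$cms, sum, 0) == r1$runs$n_test))
  # trial-grouped splits never straddle a trial
  r3 <- random_split_protocol(ds, cfg, elm_hidden = 40, n_repeats = 1,
                              group_by = "trial", seed = 5)
  expect_s3_class(r3, "protocol_result")
})

test_that("classifier comparison scores all models on one fixed fold", {
  set.seed(9)
  n <- 200
  labs <- rep(quadrant_levels(), each = n / 4)
  centers <- matrix(c(3, 0, 0, 0, 0, 3, 0, 0,
                      0, 0, 3, 0, 0, 0, 0, 3), 4, 4, byrow = TRUE)
  X <- centers[match(labs, quadrant_levels()), ] +
    matrix(rnorm(n * 4, sd = 0.2), n, 4)
  tab <- classifier_comparison(X, labs, elm_hidden = 200, seed = 3)
  expect_equal(nrow(tab), 5)
  expect_setequal(tab$classifier, c("elm", "softmax", "svm", "knn", "rf"))
  # linearly separable toy: every classifier near ceiling
  expect_true(all(tab$accuracy >= 0.95))
  tab2 <- classifier_comparison(X, labs, elm_hidden = 200, seed = 3)
  expect_identical(tab, tab2)
})
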