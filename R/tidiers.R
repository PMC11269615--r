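#' Tidy a confusion matrix into long form
#'
#' @param x A `confusion_matrix`.
#' @param ... Unused.
#' @return Tibble with `predicted`, `true`, `n`, and `prop` (of the
#'   grand total).
#' @export
tidy.confusion_matrix <- function(x, ...) {
  m <- unclass(x)
  out <- tidyr::expand_grid(predicted = rownames(m), true = colnames(m))
  out$n <- as.integer(m[cbind(out$predicted, out$true)])
  out$prop <- out$n / sum(m)
  out
}

#' Per-class metrics of a metrics report
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return Tibble of per-class counts and metrics.
#' @export
tidy.metrics_report <- function(x, ...) x$per_class

#' One-row summary of a metrics report
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return Tibble with `accuracy`, `n`, and macro-averaged metrics.
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy, n = x$total,
    macro_precision = mean(x$per_class$precision, na.rm = TRUE),
    macro_sensitivity = mean(x$per_class$sensitivity, na.rm = TRUE),
    macro_f = mean(x$per_class$f_measure, na.rm = TRUE)
  )
}

#' Per-run results of an evaluation protocol
#'
#' @param x A `protocol_result`.
#' @param ... Unused.
#' @return Tibble with one row per run.
#' @export
tidy.protocol_result <- function(x, ...) x$runs

#' One-row summary of an evaluation protocol
#'
#' @param x A `protocol_result`.
#' @param ... Unused.
#' @return Tibble with `protocol`, `n_runs`, `mean_accuracy`,
#'   `sd_accuracy` (population).
#' @export
glance.protocol_result <- function(x, ...) {
  tibble::tibble(protocol = x$protocol, n_runs = nrow(x$runs),
                 mean_accuracy = x$mean_accuracy,
                 sd_accuracy = x$sd_accuracy)
}

#' Training history of a CRNN fit
#'
#' @param x A `crnn_fit`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `loss`, `accuracy`.
#' @export
tidy.crnn_fit <- function(x, ...) x$history

#' One-row summary of a CRNN fit
#'
#' @param x A `crnn_fit`.
#' @param ... Unused.
#' @return Tibble with parameter count and final training loss and
#'   accuracy.
#' @export
glance.crnn_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(n_parameters = count_parameters(x$config)$total,
                 epochs = nrow(x$history),
                 final_loss = last$loss,
                 final_accuracy = last$accuracy)
}

#' Plot a CRNN training history
#'
#' Loss and training accuracy per epoch.
#'
#' @param object A `crnn_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crnn_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, c("loss", "accuracy"),
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch,
                                     y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "CRNN training history")
}

#' Plot a confusion matrix as a tile heatmap
#'
#' @param object A `confusion_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  d <- tidy.confusion_matrix(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$true, y = .data$predicted,
                                  fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "true class", y = "predicted class",
                  title = "Confusion matrix")
}

#' Plot per-run accuracies of an evaluation protocol
#'
#' @param object A `protocol_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.protocol_result <- function(object, ...) {
  ggplot2::ggplot(object$runs, ggplot2::aes(x = .data$run,
                                            y = .data$accuracy)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$mean_accuracy,
                        linetype = "dashed") +
    ggplot2::labs(x = "run", y = "accuracy",
                  title = paste("Protocol:", object$protocol),
                  subtitle = sprintf("mean %.3f, population sd %.3f",
                                     object$mean_accuracy,
                                     object$sd_accuracy))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
generics::tidy

#' @export
generics::glance
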