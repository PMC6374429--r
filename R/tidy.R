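#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-fold metric records of an evaluation
#'
#' @param x An `mmgru_eval`.
#' @param ... Unused.
#' @return Tibble with one row per repeat x fold: `dt`, `scheme`,
#'   `repeat_`, `fold`, `n_test`, `prevalence`, `accuracy`, `sensitivity`,
#'   `specificity`, `auc`.
#' @export
tidy.mmgru_eval <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(dt = x$dt, scheme = x$scheme), x$records)
}

#' One-row summary of an evaluation
#'
#' @param x An `mmgru_eval`.
#' @param ... Unused.
#' @return Tibble with the mean and sd of each metric over fold records.
#' @export
glance.mmgru_eval <- function(x, ...) {
  r <- x$records
  tibble::tibble(
    dt = x$dt, scheme = x$scheme, n_records = nrow(r),
    accuracy = mean(r$accuracy), accuracy_sd = stats::sd(r$accuracy),
    sensitivity = mean(r$sensitivity),
    sensitivity_sd = stats::sd(r$sensitivity),
    specificity = mean(r$specificity),
    specificity_sd = stats::sd(r$specificity),
    auc = mean(r$auc), auc_sd = stats::sd(r$auc)
  )
}

#' Fusion-model coefficients
#'
#' @param x An `mmgru_fusion`.
#' @param ... Unused.
#' @return Tibble with `term` (intercept then features) and `estimate`.
#' @export
tidy.mmgru_fusion <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", paste0("h", seq_along(x$weights))),
    estimate = c(x$intercept, x$weights)
  )
}

#' One-row summary of a fusion model
#' @param x An `mmgru_fusion`.
#' @param ... Unused.
#' @return Tibble with `lambda`, `n_nonzero`, `n_features`.
#' @export
glance.mmgru_fusion <- function(x, ...) {
  tibble::tibble(lambda = x$lambda,
                 n_nonzero = sum(x$weights != 0),
                 n_features = length(x$weights))
}

#' Metric distributions across schemes and horizons
#'
#' Boxplots of the per-fold metric records, faceted by metric, one panel
#' column per horizon.
#'
#' @param object An `mmgru_eval` or a list of them.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mmgru_eval <- function(object, ...) {
  plot_eval(list(object))
}

#' @rdname autoplot.mmgru_eval
#' @param results List of `mmgru_eval` objects.
#' @export
plot_eval <- function(results, ...) {
  df <- purrr::map_dfr(results, tidy) |>
    tidyr::pivot_longer(c("accuracy", "sensitivity", "specificity", "auc"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scheme, y = .data$value,
                                   fill = .data$scheme)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_grid(metric ~ dt, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1),
                   legend.position = "none")
}

#' ROC points from labels and probabilities
#'
#' Sorted (1 - specificity, sensitivity) pairs over all thresholds, for
#' export or plotting.
#'
#' @param labels Binary labels (1 = converter).
#' @param probabilities Predicted probabilities.
#' @return Tibble with `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(labels, probabilities) {
  thr <- c(Inf, sort(unique(probabilities), decreasing = TRUE))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  purrr::map_dfr(thr, function(t) {
    pred <- probabilities >= t
    tibble::tibble(threshold = t,
                   fpr = sum(pred & labels == 0) / n_neg,
                   tpr = sum(pred & labels == 1) / n_pos)
  })
}
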