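#' Plot a cross-validation report
#'
#' One panel per metric, showing the per-(run, fold) distribution as
#' boxplots with the individual scores overlaid.
#'
#' @param object a `cv_report` from [inverted_kfold()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot cv_report
#' @export
autoplot.cv_report <- function(object, ...) {
  metrics <- intersect(c("accuracy", "f1_max", "resnik"), names(object))
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = "score",
                  title = sprintf("Inverted %d-fold CV (%d runs)",
                                  attr(object, "k"), attr(object, "n_runs"))) +
    ggplot2::theme_minimal()
}

#' Compare methods across cross-validation reports
#'
#' @param reports named list of `cv_report`s (names are method labels).
#' @param metric which metric column to compare.
#' @return a ggplot object: mean with one-standard-deviation error bars
#'   per method.
#' @export
plot_method_comparison <- function(reports, metric = "accuracy") {
  df <- purrr::imap(reports, function(r, nm) {
    tibble::tibble(method = nm, value = r[[metric]])
  }) |>
    dplyr::bind_rows() |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}

#' Heatmap of a DSD matrix
#'
#' @param object a `dsd_matrix`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot dsd_matrix
#' @export
autoplot.dsd_matrix <- function(object, ...) {
  df <- tibble::as_tibble(as.data.frame(as.table(unclass(object))))
  names(df) <- c("from", "to", "dsd")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$from, y = .data$to,
                                   fill = .data$dsd)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "DSD") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Precision-recall trace of the F1-max computation
#'
#' @param f1 the list returned by [f1_max()].
#' @return a ggplot object of precision, recall and F1 against the
#'   confidence threshold.
#' @export
plot_f1_curve <- function(f1) {
  long <- tidyr::pivot_longer(f1$curve,
                              c("precision", "recall", "f1"),
                              names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$tau, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = f1$tau, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = expression(tau), y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
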