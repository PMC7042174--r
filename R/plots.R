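# ggplot2 visualisations for screening results

#' ROC curve of a scored screen
#'
#' @param scored Tibble with `score` and `label` columns.
#' @return A ggplot object.
#' @export
plot_roc <- function(scored) {
  if (!all(c("score", "label") %in% names(scored))) {
    abort("`scored` needs `score` and `label` columns.")
  }
  df <- scored |>
    dplyr::arrange(dplyr::desc(.data$score)) |>
    dplyr::mutate(tpr = cumsum(.data$label == "active") / sum(.data$label == "active"),
                  fpr = cumsum(.data$label == "decoy") / sum(.data$label == "decoy"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUC = %.3f)", roc_auc(scored))) +
    ggplot2::theme_minimal()
}

#' Cumulative-enrichment curve of a ranked screen
#'
#' Fraction of all actives recovered as a function of the fraction of the
#' ranked library inspected; the diagonal is the random-screening
#' expectation.
#'
#' @param ranked Ranked tibble with `score` and `label`, non-increasing
#'   in score.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(ranked) {
  check_ranked(ranked)
  df <- tibble::tibble(
    screened = seq_len(nrow(ranked)) / nrow(ranked),
    recovered = cumsum(ranked$label == "active") / sum(ranked$label == "active")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$screened, y = .data$recovered)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "Fraction of library screened", y = "Fraction of actives found") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.usrml_sweep <- function(object, metric = c("ef1", "auc"), ...) {
  metric <- match.arg(metric)
  df <- dplyr::filter(object, !is.na(.data[[metric]]))
  df$fraction_label <- factor(df$fraction_label, levels = unique(object$fraction_label))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction_label, y = .data[[metric]],
                                   colour = .data$mode, group = .data$mode)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Training actives retained",
                  y = if (metric == "ef1") "Enrichment factor at 1%" else "ROC AUC",
                  colour = "Conformer mode",
                  title = sprintf("Training-set size sweep (%s)",
                                  attr(object, "family") %||% "model")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.usrml_report <- function(object, ...) {
  df <- object$ef
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$x_percent), y = .data$ef)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Top percentage of ranked library", y = "Enrichment factor",
                  title = sprintf("ROC AUC = %.3f", object$roc_auc)) +
    ggplot2::theme_minimal()
}
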