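# ggplot2 figures for index series and skill summaries.

#' Plot observed and forecast index time series
#'
#' Observed values in black, forecast ensemble means coloured by lead,
#' in the style of retrospective-forecast index figures.
#'
#' @param forecast Index tibble with `target`, `lead` and a value column.
#' @param observed Optional observed index tibble with `date` and the same
#'   value column.
#' @param value Name of the value column (`"hci"` or `"total"`).
#' @param leads Optional subset of leads to show.
#' @return A ggplot object.
#' @export
plot_index_series <- function(forecast, observed = NULL, value = "hci",
                              leads = NULL) {
  if (!is.null(leads)) forecast <- dplyr::filter(forecast, lead %in% leads)
  p <- ggplot2::ggplot(forecast,
                       ggplot2::aes(x = target, y = .data[[value]],
                                    colour = factor(lead))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = NULL, y = value, colour = "lead (months)") +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_line(
      data = observed,
      ggplot2::aes(x = date, y = .data[[value]]),
      colour = "black", inherit.aes = FALSE
    )
  }
  p
}

#' Heat map of a skill metric by target month and lead
#'
#' One tile per (target month, lead); significant cells are dotted.
#' Undefined values (e.g. SEDI with no false positives) stay grey.
#'
#' @param report A [skill_report()] tibble with `lead` and a month column.
#' @param metric Column to fill by (`"r"`, `"accuracy"`, `"sedi"`).
#' @param month_col Name of the month column.
#' @return A ggplot object.
#' @export
plot_skill_heatmap <- function(report, metric = "r", month_col = "month") {
  sig_col <- switch(metric, r = "sig_corr", accuracy = "sig_accuracy",
                    sedi = "sig_sedi", NULL)
  p <- ggplot2::ggplot(report,
                       ggplot2::aes(x = factor(.data[[month_col]]),
                                    y = factor(lead),
                                    fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey70") +
    ggplot2::labs(x = "target month", y = "lead (months)", fill = metric) +
    ggplot2::theme_minimal()
  if (!is.null(sig_col) && sig_col %in% names(report)) {
    p <- p + ggplot2::geom_point(
      data = dplyr::filter(report, .data[[sig_col]] %in% TRUE),
      shape = 16, size = 1, colour = "black"
    )
  }
  p
}

#' Box plots of skill by forecast configuration
#'
#' Compares correlation, accuracy and SEDI across configurations, each
#' (month, lead) cell contributing one value, in the style of
#' ensemble-size comparison figures.
#'
#' @param report A [configuration_skill()] tibble (must have a `config`
#'   column).
#' @param metrics Metric columns to include.
#' @return A ggplot object.
#' @export
plot_skill_boxplot <- function(report,
                               metrics = c("r", "accuracy", "sedi")) {
  long <- report |>
    dplyr::select(config, dplyr::all_of(metrics)) |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric",
                        values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = config, y = value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
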