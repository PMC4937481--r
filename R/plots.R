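# ggplot2 figures for the main result types.

#' Plot the ortholog-count histogram
#'
#' @param histogram tibble from [count_orthologs()].
#' @return A ggplot.
#' @export
plot_ortholog_histogram <- function(histogram) {
  ggplot2::ggplot(histogram, ggplot2::aes(x = .data$k, y = .data$n_introns)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "orthologous introns found",
                  y = "number of focal introns") +
    ggplot2::theme_minimal()
}

#' Box plot of intron expression by prediction group
#'
#' Ribosomal-protein introns, raw and host-normalised, split by
#' presence of a predicted structure.
#'
#' @param expr expression table from [expression_table()].
#' @return A ggplot.
#' @export
plot_group_expression <- function(expr) {
  d <- expr |>
    filter(.data$class == "intron", .data$is_rp) |>
    tidyr::pivot_longer(c("rpkm", "normalized"), names_to = "measure",
                        values_to = "value") |>
    filter(!is.na(.data$value)) |>
    mutate(group = ifelse(.data$has_prediction, "with prediction",
                          "no prediction"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::scale_y_continuous(trans = "log1p") +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "intron expression") +
    ggplot2::theme_minimal()
}

#' Autoplot a fitted growth curve
#'
#' @param object a `growth_fit`.
#' @param ... unused.
#' @return A ggplot of the normalised data with the fitted curve.
#' @export
autoplot.growth_fit <- function(object, ...) {
  d <- tibble(t = object$time_min / 60, od = object$od_norm)
  grid <- tibble(t = seq(min(d$t), max(d$t), length.out = 200))
  grid$od <- object$fitted(grid$t)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$od)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(x = "time (h)", y = "normalised OD",
                  subtitle = sprintf("%s fit: A=%.2f, mu=%.2f/h, lambda=%.1f h",
                                     object$model, object$a_max, object$mu,
                                     object$lambda)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot exosome-association percentiles by group
#'
#' @param exo tibble from [average_and_flag()].
#' @param structured character vector of structured-intron gene ids.
#' @return A ggplot.
#' @export
plot_exosome_scores <- function(exo, structured) {
  d <- exo |> mutate(group = ifelse(.data$gene_id %in% structured,
                                    "predicted structure", "other"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group,
                                  y = .data$average_percentile)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "average exosome CRAC percentile") +
    ggplot2::theme_minimal()
}
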