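# ggplot2 helpers for the main result types.

#' Plot per-sample geoaccumulation indices by zone
#'
#' Boxplots of Igeo per metal, faceted nothing, coloured by zone, with the
#' class boundaries as reference lines.
#'
#' @param indices Output of [assess_contamination()].
#' @return A ggplot object.
#' @export
plot_igeo <- function(indices) {
  long <- indices |>
    tidyr::pivot_longer(dplyr::starts_with("igeo_"), names_to = "metal",
                        values_to = "igeo", names_prefix = "igeo_") |>
    dplyr::mutate(metal = factor(.data$metal, levels = dust_metals))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metal, y = .data$igeo,
                                     fill = .data$zone)) +
    ggplot2::geom_hline(yintercept = 0:5, linetype = "dotted",
                        colour = "grey70") +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::labs(x = NULL, y = expression(I[geo]), fill = "Zone") +
    ggplot2::theme_minimal()
}

#' Plot mean speciation profiles as stacked shares
#'
#' @param records Completed speciation records (from [speciate()]).
#' @return A ggplot object.
#' @export
plot_speciation <- function(records) {
  prof <- mobility_summary(records) |>
    tidyr::pivot_longer(dplyr::starts_with("pct_f"), names_to = "pool",
                        values_to = "pct") |>
    dplyr::mutate(
      pool = factor(.data$pool, levels = paste0("pct_f", 1:5),
                    labels = c("exchangeable", "carbonate-bound",
                               "Fe/Mn oxide", "organic/sulfide", "residual")),
      metal = factor(.data$metal, levels = dust_metals)
    )
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$metal, y = .data$pct,
                                     fill = .data$pool)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "Mean share (%)", fill = "Pool") +
    ggplot2::theme_minimal()
}

#' Cumulative probability curves for a Monte Carlo simulation
#'
#' Empirical CDF of the hazard index or total cancer risk per population,
#' with the advisory threshold drawn as a vertical line.
#'
#' @param object A `dust_mc` object.
#' @param output `"hi"` or `"tcr"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot dust_mc
autoplot.dust_mc <- function(object, output = c("hi", "tcr"), ...) {
  output <- match.arg(output)
  threshold <- if (output == "hi") 1 else 1e-6
  ggplot2::ggplot(object$draws,
                  ggplot2::aes(x = .data[[output]],
                               colour = .data$population)) +
    ggplot2::stat_ecdf() +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = toupper(output), y = "Cumulative probability",
                  colour = "Population") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
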