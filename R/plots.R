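#' Plot a Lee-Carter fit
#'
#' Three panels: the age pattern a_x, the age loadings b_x and the period
#' index k_t with its drift line.
#'
#' @param object An `lc_fit`.
#' @param ... Unused.
#' @return A ggplot object (faceted by term).
#' @method autoplot lc_fit
#' @export
autoplot.lc_fit <- function(object, ...) {
  td <- tidy(object) |>
    dplyr::group_by(.data$term) |>
    dplyr::mutate(pos = dplyr::row_number()) |>
    dplyr::ungroup()
  ggplot2::ggplot(td, ggplot2::aes(x = .data$pos, y = .data$estimate)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = "age group / year index", y = "estimate",
                  title = "Lee-Carter parameters") +
    ggplot2::theme_minimal()
}

#' Heatmap of weekly death rates by year
#'
#' Quick diagnostic view of a weekly rate series (seasonality shows as
#' vertical banding, shocks as hot cells).
#'
#' @param history Tibble with `year`, `week`, `rate`.
#' @return A ggplot object.
#' @export
plot_weekly_rates <- function(history) {
  ggplot2::ggplot(history, ggplot2::aes(x = .data$week, y = factor(.data$year),
                                        fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "week", y = "year", fill = "rate",
                  title = "Weekly death rates") +
    ggplot2::theme_minimal()
}

#' Bar chart of a validation report
#'
#' @param report Tibble from [check_internal()] / [check_external()].
#' @return A ggplot object.
#' @export
plot_validation <- function(report) {
  ggplot2::ggplot(report, ggplot2::aes(x = .data$check, fill = .data$status)) +
    ggplot2::geom_bar() +
    ggplot2::scale_fill_manual(values = c(pass = "seagreen", warn = "orange",
                                          fail = "firebrick", skipped = "grey70")) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "checks", title = "Consistency checks") +
    ggplot2::theme_minimal()
}
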