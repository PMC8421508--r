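#' Weekly person-week death rate
#'
#' Divides a weekly death count by one week of the annual exposure:
#' m = D / (E / 52). Expressed this way a weekly rate is numerically
#' comparable with an annual death rate — under deaths spread uniformly over
#' 52 weeks, the mean weekly rate equals the annual rate.
#'
#' @param deaths Weekly death count(s), nonnegative.
#' @param exposure Annual person-years exposure(s), strictly positive.
#' @return Numeric vector of per person-week rates.
#' @export
#' @examples
#' weekly_rate(70, 3640) # == 1
weekly_rate <- function(deaths, exposure) {
  if (any(exposure <= 0)) rlang::abort("annual exposure must be positive")
  deaths / (exposure / 52)
}

#' Available baseline (reference-level) methods
#'
#' Expected weekly mortality can be defined in several ways; this registry
#' lists the implemented options. `week_mean` — week-specific mean over the
#' reference years (the conventional five-year average); `week_median` —
#' week-specific median; `week_mean_trend` — per-week ordinary least squares
#' of rate on year, evaluated at the target year (needs >= 3 reference
#' years); `annual_min_year` — the single reference year with the lowest
#' mean weekly rate; `specific_year` — a user-chosen reference year verbatim;
#' `week_mean_excluding_shocks` — week-specific trimmed mean that discards
#' the most extreme reference values.
#'
#' @return Character vector of method identifiers.
#' @export
baseline_methods <- function() {
  c("week_mean", "week_median", "week_mean_trend", "annual_min_year",
    "specific_year", "week_mean_excluding_shocks")
}

#' Expected weekly rates from reference years
#'
#' Computes one expected rate per week of a target year from the week-indexed
#' history of reference years, using one of [baseline_methods()].
#'
#' @param history Tibble with columns `year`, `week`, `rate` covering the
#'   reference years.
#' @param method One of [baseline_methods()]; default `"week_mean"`.
#' @param reference_years Years of `history` to use (default: all).
#' @param target_year Year the baseline is for (required by
#'   `week_mean_trend`; recorded in the result otherwise).
#' @param specific_year The year used by method `"specific_year"`.
#' @param trim Trim fraction per tail for `"week_mean_excluding_shocks"`
#'   (default 0.2).
#' @return Tibble with `week` and `expected`; attributes `method` and
#'   `reference_years`.
#' @export
baseline <- function(history, method = "week_mean", reference_years = NULL,
                     target_year = NULL, specific_year = NULL, trim = 0.2) {
  method <- match.arg(method, baseline_methods())
  if (is.null(reference_years)) reference_years <- sort(unique(history$year))
  h <- dplyr::filter(history, .data$year %in% reference_years)
  if (nrow(h) == 0) rlang::abort("empty reference window")
  exp_tab <- switch(
    method,
    week_mean = h |>
      dplyr::group_by(.data$week) |>
      dplyr::summarise(expected = mean(.data$rate), .groups = "drop"),
    week_median = h |>
      dplyr::group_by(.data$week) |>
      dplyr::summarise(expected = stats::median(.data$rate), .groups = "drop"),
    week_mean_trend = {
      if (length(unique(h$year)) < 3) {
        rlang::abort("week_mean_trend requires at least 3 reference years")
      }
      if (is.null(target_year)) rlang::abort("week_mean_trend requires target_year")
      h |>
        dplyr::group_by(.data$week) |>
        dplyr::summarise(expected = {
          fit <- stats::lm(rate ~ year, data = dplyr::pick("rate", "year"))
          unname(stats::predict(fit, newdata = data.frame(year = target_year)))
        }, .groups = "drop")
    },
    annual_min_year = {
      ymin <- h |>
        dplyr::group_by(.data$year) |>
        dplyr::summarise(mr = mean(.data$rate), .groups = "drop")
      best <- ymin$year[which.min(ymin$mr)]
      h |>
        dplyr::filter(.data$year == best) |>
        dplyr::select("week", expected = "rate")
    },
    specific_year = {
      if (is.null(specific_year)) rlang::abort("specific_year method requires specific_year")
      if (!specific_year %in% h$year) {
        rlang::abort(sprintf("year %d not in the reference window", specific_year))
      }
      h |>
        dplyr::filter(.data$year == specific_year) |>
        dplyr::select("week", expected = "rate")
    },
    week_mean_excluding_shocks = h |>
      dplyr::group_by(.data$week) |>
      dplyr::summarise(expected = mean(.data$rate, trim = trim), .groups = "drop")
  )
  exp_tab <- dplyr::arrange(exp_tab, .data$week)
  attr(exp_tab, "method") <- method
  attr(exp_tab, "reference_years") <- reference_years
  attr(exp_tab, "target_year") <- target_year
  exp_tab
}

#' Weekly excess mortality
#'
#' Excess is the plain difference between observed and expected weekly death
#' rates (positive = excess, negative = deficit); with an exposure it is also
#' expressed as excess death counts (rate excess times exposure / 52).
#' Cumulative excess over a window is the sum of the weekly values.
#'
#' @param observed Tibble with `week` and `rate` (optionally `deaths`) for
#'   the target year.
#' @param expected Tibble with `week` and `expected`, e.g. from
#'   [baseline()].
#' @param exposure Annual person-years exposure for the count conversion
#'   (optional).
#' @param completeness_cutoff Last week considered complete; later weeks
#'   (registration lag) are dropped from the result. Default: no cutoff.
#' @return A tibble of class `excess_result`: `week`, `observed`, `expected`,
#'   `excess_rate` and, when `exposure` is given, `observed_deaths`,
#'   `expected_deaths`, `excess_deaths`. Attributes `method`,
#'   `reference_years`, `exposure`.
#' @export
excess <- function(observed, expected, exposure = NULL,
                   completeness_cutoff = NULL) {
  if (!is.null(completeness_cutoff)) {
    observed <- dplyr::filter(observed, .data$week <= completeness_cutoff)
    expected <- dplyr::filter(expected, .data$week <= completeness_cutoff)
  }
  missing_w <- setdiff(observed$week, expected$week)
  extra_w <- setdiff(expected$week, observed$week)
  if (length(missing_w) > 0 || length(extra_w) > 0) {
    rlang::abort(sprintf(
      "misaligned weeks: expected series lacks [%s]; observed series lacks [%s]",
      paste(missing_w, collapse = ", "), paste(extra_w, collapse = ", ")))
  }
  out <- dplyr::inner_join(dplyr::select(observed, "week", observed = "rate"),
                           expected, by = "week") |>
    dplyr::arrange(.data$week) |>
    dplyr::mutate(excess_rate = .data$observed - .data$expected)
  if (!is.null(exposure)) {
    out <- dplyr::mutate(out,
                         observed_deaths = .data$observed * exposure / 52,
                         expected_deaths = .data$expected * exposure / 52,
                         excess_deaths = .data$excess_rate * exposure / 52)
  }
  structure(out, class = c("excess_result", class(out)),
            method = attr(expected, "method"),
            reference_years = attr(expected, "reference_years"),
            exposure = exposure)
}

#' Cumulative excess over a window of weeks
#'
#' @param x An `excess_result`.
#' @param weeks Weeks to sum over (default all).
#' @param measure `"deaths"` (if available) or `"rate"`.
#' @return A single number.
#' @export
cumulative_excess <- function(x, weeks = NULL, measure = c("deaths", "rate")) {
  measure <- match.arg(measure)
  if (measure == "deaths" && !"excess_deaths" %in% names(x)) measure <- "rate"
  if (!is.null(weeks)) x <- dplyr::filter(x, .data$week %in% weeks)
  if (measure == "deaths") sum(x$excess_deaths) else sum(x$excess_rate)
}

#' @export
print.excess_result <- function(x, ...) {
  ref <- attr(x, "reference_years")
  cat(sprintf("Weekly excess mortality (%d weeks, baseline %s, reference %s)\n",
              nrow(x), attr(x, "method") %||% "?",
              if (is.null(ref)) "?" else paste(range(ref), collapse = "-")))
  cat(sprintf("  cumulative excess: %.2f %s\n",
              cumulative_excess(x),
              if ("excess_deaths" %in% names(x)) "deaths" else "(rate units)"))
  NextMethod()
}

#' Plot a weekly excess-mortality series
#'
#' Observed and expected weekly rates as lines, with the excess/deficit area
#' shaded (excess above the baseline, deficit below).
#'
#' @param object An `excess_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot excess_result
#' @export
autoplot.excess_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$week)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmin(.data$observed, .data$expected),
                                      ymax = .data$observed,
                                      fill = .data$excess_rate > 0),
                         alpha = 0.4, show.legend = FALSE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$expected), linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed)) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "orange", `FALSE` = "steelblue")) +
    ggplot2::labs(x = "week", y = "death rate (per person-week)",
                  title = "Observed vs expected weekly death rates") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang %||% .data
NULL
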