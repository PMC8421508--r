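#' Internal consistency checks on a harmonized table
#'
#' Runs the within-dataset consistency checks: (i) age-group death counts sum
#' to the all-ages total in every row; (ii) male + female counts reproduce
#' the both-sex counts per (year, week, age group); (iii) processed weekly
#' totals match the raw weekly totals when the raw records are supplied
#' (harmonization redistributes but never creates or destroys deaths);
#' (iv) the male/female ratio of death rates stays inside a plausibility
#' band per age group. Failures and warnings are report rows, never
#' exceptions, and the input is never modified.
#'
#' @param stmf Wide harmonized table from [build_stmf()].
#' @param raw Optional raw weekly tibble the table was built from.
#' @param tol Relative tolerance for the sum checks (default 1e-9... on the
#'   count scale, `tol * max(total, 1)`).
#' @param sex_ratio_band Two-element numeric band for the m/f rate ratio
#'   (default `c(0.2, 5)`); outside it the check status is `"warn"`.
#' @return A validation-report tibble: `check`, `scope`, `status`
#'   (`pass`/`warn`/`fail`/`skipped`), `metric`, `threshold`.
#' @export
check_internal <- function(stmf, raw = NULL, tol = 1e-9,
                           sex_ratio_band = c(0.2, 5)) {
  cols <- stmf_out_cols()
  gcols <- cols$deaths[-length(cols$deaths)]
  tcol <- cols$deaths[length(cols$deaths)]

  # (i) age sums vs total
  r1 <- stmf |>
    dplyr::mutate(metric = abs(rowSums(dplyr::pick(dplyr::all_of(gcols))) -
                                 .data[[tcol]]) / pmax(.data[[tcol]], 1)) |>
    dplyr::transmute(check = "age_sum_vs_total",
                     scope = sprintf("%s/%d/w%02d/%s", .data$CountryCode,
                                     .data$Year, .data$Week, .data$Sex),
                     status = ifelse(.data$metric <= tol, "pass", "fail"),
                     metric = .data$metric, threshold = tol)

  # (ii) m + f vs b per week and age group
  long <- stmf |>
    tidyr::pivot_longer(dplyr::all_of(c(gcols, tcol)),
                        names_to = "group", values_to = "deaths")
  mf <- long |>
    tidyr::pivot_wider(id_cols = c("CountryCode", "Year", "Week", "group"),
                       names_from = "Sex", values_from = "deaths")
  r2 <- if (all(c("m", "f", "b") %in% names(mf))) {
    mf |>
      dplyr::mutate(metric = abs(.data$m + .data$f - .data$b) / pmax(.data$b, 1)) |>
      dplyr::transmute(check = "sex_sum_vs_both",
                       scope = sprintf("%s/%d/w%02d/%s", .data$CountryCode,
                                       .data$Year, .data$Week, .data$group),
                       status = ifelse(.data$metric <= tol, "pass", "fail"),
                       metric = .data$metric, threshold = tol)
  } else tibble::tibble()

  # (iii) processed vs raw weekly totals
  r3 <- if (!is.null(raw)) {
    raw_tot <- raw |>
      dplyr::group_by(.data$year, .data$week) |>
      dplyr::summarise(raw_deaths = sum(.data$deaths), .groups = "drop")
    proc_tot <- stmf |>
      dplyr::filter(.data$Sex %in% c("m", "f")) |>
      dplyr::group_by(.data$Year, .data$Week) |>
      dplyr::summarise(proc_deaths = sum(.data[[tcol]]), .groups = "drop")
    raw_sexes <- unique(raw$sex)
    if (identical(sort(raw_sexes), "b") || !any(c("m", "f") %in% raw_sexes)) {
      # raw published both sexes combined only
      proc_tot <- proc_tot
    }
    dplyr::inner_join(raw_tot, proc_tot, by = c(year = "Year", week = "Week")) |>
      dplyr::mutate(metric = abs(.data$proc_deaths - .data$raw_deaths) /
                      pmax(.data$raw_deaths, 1)) |>
      dplyr::transmute(check = "processed_vs_raw",
                       scope = sprintf("%d/w%02d", .data$year, .data$week),
                       status = ifelse(.data$metric <= tol, "pass", "fail"),
                       metric = .data$metric, threshold = tol)
  } else tibble::tibble()

  # (iv) sex ratio of rates per age group (annualized over the data)
  rcols <- cols$rates[-length(cols$rates)]
  rl <- stmf |>
    tidyr::pivot_longer(dplyr::all_of(rcols), names_to = "group",
                        values_to = "rate") |>
    dplyr::filter(.data$Sex %in% c("m", "f")) |>
    dplyr::group_by(.data$CountryCode, .data$Year, .data$group, .data$Sex) |>
    dplyr::summarise(rate = mean(.data$rate), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "Sex", values_from = "rate")
  r4 <- if (all(c("m", "f") %in% names(rl))) {
    rl |>
      dplyr::mutate(metric = ifelse(.data$f > 0, .data$m / .data$f, NA_real_)) |>
      dplyr::transmute(check = "sex_rate_ratio",
                       scope = sprintf("%s/%d/%s", .data$CountryCode, .data$Year,
                                       .data$group),
                       status = dplyr::case_when(
                         is.na(.data$metric) ~ "skipped",
                         .data$metric >= sex_ratio_band[1] &
                           .data$metric <= sex_ratio_band[2] ~ "pass",
                         TRUE ~ "warn"),
                       metric = .data$metric, threshold = sex_ratio_band[2])
  } else tibble::tibble()

  dplyr::bind_rows(r1, r2, r3, r4)
}

#' External consistency check against official annual totals
#'
#' The sum of the weekly death counts over a statistical year should be close
#' to the official yearly figure. Reports the relative difference per (year,
#' sex); pass when it does not exceed `tol` (default 1%). Years without an
#' official figure are reported as `skipped`.
#'
#' @param stmf Wide harmonized table from [build_stmf()].
#' @param official Tibble with `year`, `sex`, `deaths` (official totals).
#' @param tol Relative tolerance, default 0.01.
#' @return Validation-report tibble (same shape as [check_internal()]).
#' @export
check_external <- function(stmf, official, tol = 0.01) {
  tcol <- stmf_out_cols()$deaths |> utils::tail(1)
  weekly <- stmf |>
    dplyr::group_by(.data$CountryCode, .data$Year, .data$Sex) |>
    dplyr::summarise(weekly_sum = sum(.data[[tcol]]), .groups = "drop")
  dplyr::left_join(weekly,
                   dplyr::select(official, Year = "year", Sex = "sex",
                                 official = "deaths"),
                   by = c("Year", "Sex")) |>
    dplyr::mutate(
      metric = dplyr::case_when(
        is.na(.data$official) ~ NA_real_,
        .data$official == 0 & .data$weekly_sum > 0 ~ Inf,
        .data$official == 0 ~ 0,
        TRUE ~ abs(.data$weekly_sum - .data$official) / .data$official)) |>
    dplyr::transmute(check = "weekly_vs_official_annual",
                     scope = sprintf("%s/%d/%s", .data$CountryCode, .data$Year,
                                     .data$Sex),
                     status = dplyr::case_when(
                       is.na(.data$metric) ~ "skipped",
                       .data$metric <= tol ~ "pass",
                       TRUE ~ "fail"),
                     metric = .data$metric, threshold = tol)
}

#' Flag outlying weeks in a weekly rate series
#'
#' Each week's rate is centered on the same-week median across the other
#' years of the series (leave-one-out, so a value never shrinks its own
#' residual), and the resulting residuals are scored with a robust z-score;
#' weeks with |z| above the threshold are flagged. The scale is the MAD of
#' the residuals pooled over all weeks: with the handful of reference years
#' typical of weekly mortality series, a per-week MAD from 5 values is far
#' too noisy to support a 4-sigma rule, while the pooled estimate has
#' hundreds of degrees of freedom and keeps the advertised false-flag rate.
#' When the pooled MAD is zero the mean absolute deviation is used; when
#' that is also zero nothing can be scored and nothing is flagged. Flags are
#' advisory diagnostics — the data are never altered. Robust statistics are
#' used precisely because shock weeks are the signal of interest and must
#' not inflate the scale estimate.
#'
#' @param history Tibble with `year`, `week`, `rate` over >= 2 years.
#' @param threshold |z| above which a week is flagged, default 4.
#' @return Tibble of flagged weeks: `year`, `week`, `rate`, `z`.
#' @export
detect_outliers <- function(history, threshold = 4) {
  if (length(unique(history$year)) < 2) {
    rlang::abort("outlier detection requires at least 2 years")
  }
  loo_median <- function(x) {
    vapply(seq_along(x), function(i) stats::median(x[-i]), numeric(1))
  }
  h <- history |>
    dplyr::group_by(.data$week) |>
    dplyr::mutate(center = loo_median(.data$rate)) |>
    dplyr::ungroup() |>
    dplyr::mutate(resid = .data$rate - .data$center)
  scale <- stats::mad(h$resid, center = 0)
  if (scale == 0) scale <- mean(abs(h$resid))
  if (scale == 0) return(tibble::tibble(year = integer(), week = integer(),
                                        rate = double(), z = double()))
  h |>
    dplyr::filter(abs(.data$resid) / scale > threshold) |>
    dplyr::transmute(.data$year, .data$week, .data$rate,
                     z = .data$resid / scale)
}

#' Summarize a validation report
#'
#' @param report Tibble from [check_internal()] / [check_external()].
#' @return A tibble of counts per check and status.
#' @export
summarize_report <- function(report) {
  report |>
    dplyr::count(.data$check, .data$status) |>
    tidyr::pivot_wider(names_from = "status", values_from = "n", values_fill = 0L)
}

#' Write a validation report as JSON lines
#'
#' @param report Validation-report tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(report))) {
    writeLines(jsonlite::toJSON(as.list(report[i, ]), auto_unbox = TRUE,
                                digits = NA, na = "null"), con)
  }
  invisible(path)
}
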