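#' Configuration for the synthetic weekly-mortality generator
#'
#' Describes a synthetic population with known ground truth: baseline annual
#' death rates and exposures per age group and sex, a sinusoidal seasonal
#' factor peaking in early January (week 2), a secular log-linear trend, an
#' optional mortality shock (additive deaths or a rate multiplier over a
#' window of weeks, concentrated at old ages by default), optional Poisson
#' noise on the weekly counts, and a coarsening step applied separately by
#' [coarsen()]. The defaults emulate a mid-size high-income country of about
#' ten million people with modern mortality levels.
#'
#' @param years Calendar years to simulate (each 52 weeks).
#' @param age_groups Age-group table, default [stmf_age_groups()].
#' @param rates_m,rates_f Baseline annual death rates per age group in the
#'   first simulated year, males and females.
#' @param exposure_m,exposure_f Annual person-years per age group (constant
#'   over the simulated span).
#' @param seasonal_amplitude Relative winter peak of the weekly sinusoid
#'   (0 = none). The factor averages exactly 1 over a 52-week year.
#' @param trend Annual drift of the log rates (e.g. -0.01 for a 1% yearly
#'   mortality decline).
#' @param shock `NULL`, or a list with `year`, `weeks`, `mode`
#'   (`"add"`: `total` extra expected deaths spread evenly over the weeks;
#'   `"mult"`: `factor` multiplying the expected counts), and optionally
#'   `age_weights` (default concentrated at old ages).
#' @param noise If `TRUE`, weekly counts are Poisson draws around their
#'   expectations; if `FALSE`, the expectations themselves.
#' @param pop_name Population code written into the raw records.
#' @param seed RNG seed; a fixed seed makes the output bit-reproducible.
#' @return A `sim_config` list.
#' @export
sim_config <- function(years = 2015:2020,
                       age_groups = stmf_age_groups(),
                       rates_m = c(0.00025, 0.0030, 0.0200, 0.0500, 0.1500),
                       rates_f = c(0.00020, 0.0015, 0.0110, 0.0330, 0.1200),
                       exposure_m = c(7.5e5, 3.30e6, 5.5e5, 3.5e5, 1.2e5),
                       exposure_f = c(7.1e5, 3.25e6, 6.2e5, 4.6e5, 2.4e5),
                       seasonal_amplitude = 0.15,
                       trend = -0.01,
                       shock = NULL,
                       noise = TRUE,
                       pop_name = "SYN",
                       seed = 1L) {
  ng <- nrow(age_groups)
  stopifnot(length(rates_m) == ng, length(rates_f) == ng,
            length(exposure_m) == ng, length(exposure_f) == ng,
            all(rates_m > 0), all(rates_f > 0),
            all(exposure_m > 0), all(exposure_f > 0),
            seasonal_amplitude >= 0, seasonal_amplitude < 1)
  if (!is.null(shock)) {
    shock$mode <- match.arg(shock$mode %||% "add", c("add", "mult"))
    if (is.null(shock$age_weights)) {
      shock$age_weights <- rep(0, ng)
      old <- age_groups$age_start >= 65
      shock$age_weights[old] <- c(0.25, 0.3, 0.45)[seq_len(sum(old))]
      shock$age_weights <- shock$age_weights / sum(shock$age_weights)
    }
    stopifnot(length(shock$age_weights) == ng,
              shock$year %in% years, all(shock$weeks %in% 1:52))
  }
  structure(list(years = years, age_groups = age_groups,
                 rates = list(m = rates_m, f = rates_f),
                 exposure = list(m = exposure_m, f = exposure_f),
                 seasonal_amplitude = seasonal_amplitude, trend = trend,
                 shock = shock, noise = noise, pop_name = pop_name,
                 seed = as.integer(seed)),
            class = "sim_config")
}

seasonal_factor <- function(week, amplitude) {
  1 + amplitude * cos(2 * pi * (week - 2) / 52)
}

#' Generate a synthetic weekly mortality dataset
#'
#' Produces an internally consistent triple of (raw weekly death records,
#' annual deaths/exposures table, official annual totals) plus a `truth`
#' record. Expected weekly counts are annual rate x exposure / 52 x seasonal
#' factor, plus the shock contribution; realized counts are Poisson draws
#' when noise is on. The annual death counts are defined as the sums of the
#' realized fine-grained weekly counts, so every generated dataset is
#' internally consistent by construction and proportional splitting can
#' recover the fine table exactly in the noise-free, week-stationary case.
#'
#' @param config A [sim_config()].
#' @return List with elements `raw` (long weekly tibble in the layout of
#'   [read_raw_deaths()]), `annual`, `official`, `truth` (fine weekly tibble
#'   with expected and realized counts plus `shock_total`), `config`.
#' @export
simulate_mortality <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  g <- config$age_groups
  grid <- tidyr::expand_grid(year = config$years, week = 1:52,
                             sex = c("m", "f"), gi = seq_len(nrow(g)))
  grid <- grid |>
    dplyr::mutate(
      age_start = g$age_start[.data$gi],
      age_interval = g$age_interval[.data$gi],
      exposure = purrr::map2_dbl(.data$sex, .data$gi,
                                 ~ config$exposure[[.x]][.y]),
      rate = purrr::map2_dbl(.data$sex, .data$gi, ~ config$rates[[.x]][.y]) *
        exp(config$trend * (.data$year - config$years[1])),
      lambda_base = .data$rate * .data$exposure / 52 *
        seasonal_factor(.data$week, config$seasonal_amplitude),
      lambda = .data$lambda_base)
  if (!is.null(config$shock)) {
    s <- config$shock
    in_shock <- grid$year == s$year & grid$week %in% s$weeks
    if (s$mode == "add") {
      # sex share within each age group proportional to baseline expectation
      sex_tot <- grid |>
        dplyr::filter(in_shock) |>
        dplyr::group_by(.data$week, .data$gi) |>
        dplyr::mutate(cell_share = .data$lambda_base / sum(.data$lambda_base)) |>
        dplyr::ungroup()
      add <- s$total / length(s$weeks) * s$age_weights[sex_tot$gi] * sex_tot$cell_share
      grid$lambda[in_shock] <- grid$lambda_base[in_shock] + add
    } else {
      bump <- 1 + (s$factor - 1) * (s$age_weights[grid$gi] / max(s$age_weights))
      grid$lambda[in_shock] <- grid$lambda_base[in_shock] * bump[in_shock]
    }
  }
  grid$deaths <- if (config$noise) stats::rpois(nrow(grid), grid$lambda) else grid$lambda

  truth <- dplyr::select(grid, "year", "week", "sex", "age_start",
                         "age_interval", "exposure", "rate",
                         "lambda_base", "lambda", "deaths")
  attr(truth, "shock_total") <- sum(grid$lambda - grid$lambda_base)

  raw <- tibble::tibble(
    pop_name = config$pop_name, area = "", year = as.integer(truth$year),
    week = as.integer(truth$week), sex = truth$sex,
    age_start = truth$age_start, age_interval = truth$age_interval,
    deaths = truth$deaths, data_type = "O", access = "1")

  annual <- truth |>
    dplyr::group_by(.data$year, .data$sex, .data$age_start, .data$age_interval) |>
    dplyr::summarise(deaths = sum(.data$deaths), exposure = .data$exposure[1],
                     .groups = "drop") |>
    dplyr::mutate(source = "observed")

  official <- annual |>
    dplyr::group_by(.data$year, .data$sex) |>
    dplyr::summarise(deaths = sum(.data$deaths), .groups = "drop")
  official_b <- official |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(deaths = sum(.data$deaths), .groups = "drop") |>
    dplyr::mutate(sex = "b")
  official <- dplyr::bind_rows(official, official_b[, names(official)])

  list(raw = raw, annual = annual, official = official, truth = truth,
       config = config)
}

#' Coarsen a fine-grained weekly table as a source country would publish it
#'
#' Aggregates the fine weekly records into broad age groups (which must be
#' tiled exactly by the fine groups), optionally merges the sexes into
#' both-sex records, and optionally moves a fixed fraction of every
#' stratum's deaths into an unknown-age row. The unknown-age extraction is
#' deterministic and proportional across ages so that the stratum total and
#' the age distribution of the remainder are preserved exactly.
#'
#' @param raw Long weekly tibble (layout of [read_raw_deaths()]).
#' @param groups Broad age-group table, or `NULL` to keep the age grouping.
#' @param combine_sex Merge male and female records into `"b"` records.
#' @param unknown_fraction Fraction of each stratum's deaths moved to an
#'   unknown-age row, in `[0, 1)`.
#' @return Long weekly tibble in the same layout.
#' @export
coarsen <- function(raw, groups = NULL, combine_sex = FALSE,
                    unknown_fraction = 0) {
  stopifnot(unknown_fraction >= 0, unknown_fraction < 1)
  x <- raw
  if (!is.null(groups)) {
    idx <- purrr::map_int(seq_len(nrow(x)), function(i) {
      hit <- which(nests_in(x$age_start[i], x$age_interval[i],
                            groups$age_start, groups$age_interval))
      if (length(hit) != 1L) {
        rlang::abort(sprintf("fine group %s does not nest in the broad grouping",
                             age_label(x$age_start[i], x$age_interval[i])))
      }
      hit
    })
    x$age_start <- groups$age_start[idx]
    x$age_interval <- groups$age_interval[idx]
  }
  if (combine_sex) x$sex <- "b"
  x <- x |>
    dplyr::group_by(.data$pop_name, .data$area, .data$year, .data$week,
                    .data$sex, .data$age_start, .data$age_interval,
                    .data$data_type, .data$access) |>
    dplyr::summarise(deaths = sum(.data$deaths), .groups = "drop")
  if (unknown_fraction > 0) {
    unk <- x |>
      dplyr::group_by(.data$pop_name, .data$area, .data$year, .data$week,
                      .data$sex, .data$data_type, .data$access) |>
      dplyr::summarise(deaths = unknown_fraction * sum(.data$deaths),
                       .groups = "drop") |>
      dplyr::mutate(age_start = NA_real_, age_interval = NA_real_)
    x$deaths <- x$deaths * (1 - unknown_fraction)
    x <- dplyr::bind_rows(x, unk[, names(x)])
  }
  dplyr::arrange(x[, names(raw)], .data$year, .data$week, .data$sex,
                 .data$age_start)
}
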