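#' Build a pipeline configuration
#'
#' Collects everything the end-to-end run needs: input paths (or in-memory
#' tibbles), the country code and its week-numbering scheme, the target age
#' grouping, the Lee-Carter fitting window, the excess-mortality baseline,
#' validation thresholds and output paths. A configuration can equally be
#' read from a YAML file with [read_pipeline_config()].
#'
#' @param raw Raw weekly input: a file path or a tibble.
#' @param annual Annual deaths/exposures: a file path or a tibble.
#' @param official Optional official annual totals: path or tibble with
#'   `year`, `sex`, `deaths`.
#' @param country Country/population code (used for the week scheme lookup
#'   and the output `CountryCode`). Default: taken from the raw records.
#' @param week_scheme Week-numbering scheme id, or `NULL` to look the
#'   country up in [default_week_scheme_map()].
#' @param targets Target age grouping.
#' @param lc_start_year Lee-Carter fitting-window start.
#' @param lc_horizon Forecast horizon, or `NULL` to forecast exactly the
#'   weekly years missing from the annual table.
#' @param baseline_method,reference_years,target_year Excess baseline
#'   settings; `target_year = NULL` skips the excess stage.
#' @param external_tol,outlier_threshold Validation thresholds.
#' @param week53 `"merge"` or `"drop"` (see [clamp_to_52()]).
#' @param out_dir Directory for output files, or `NULL` to return tibbles
#'   only.
#' @param seed Seed applied before any stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(raw, annual, official = NULL, country = NULL,
                            week_scheme = NULL, targets = stmf_age_groups(),
                            lc_start_year = 2005, lc_horizon = NULL,
                            baseline_method = "week_mean",
                            reference_years = NULL, target_year = NULL,
                            external_tol = 0.01, outlier_threshold = 4,
                            week53 = "merge", out_dir = NULL, seed = 1L) {
  structure(list(raw = raw, annual = annual, official = official,
                 country = country, week_scheme = week_scheme,
                 targets = targets, lc_start_year = lc_start_year,
                 lc_horizon = lc_horizon, baseline_method = baseline_method,
                 reference_years = reference_years, target_year = target_year,
                 external_tol = external_tol,
                 outlier_threshold = outlier_threshold, week53 = week53,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are the arguments of
#'   [pipeline_config()]; `targets` may be given as lists of `starts` and
#'   `intervals` (use `".inf"`/`"+"` for the open group).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$targets)) {
    iv <- vapply(y$targets$intervals,
                 function(v) if (v %in% c("+", "Inf", ".inf")) Inf else as.numeric(v),
                 numeric(1))
    y$targets <- age_group_table(as.numeric(y$targets$starts), iv)
  }
  do.call(pipeline_config, y)
}

#' Run the full weekly-mortality pipeline
#'
#' Executes the stages end to end: read raw weekly counts, enforce the
#' 52-week year, extend the annual table by Lee-Carter forecasting for the
#' weekly years it does not cover, harmonize (unknown-age redistribution,
#' age split, sex split), compute weekly person-week rates and assemble the
#' wide output with Split/SplitSex/Forecast flags, run the consistency
#' checks, and — when a target year is configured — estimate weekly excess
#' mortality. Validation failures never abort the run; they are reported.
#' Every merge, fallback and flooring event is appended to the run log.
#' Identical configuration, inputs and seed give identical outputs.
#'
#' @param config A [pipeline_config()] or path to its YAML file.
#' @return List with `stmf` (wide harmonized table), `validation` (report
#'   tibble), `excess` (an `excess_result` or `NULL`), `outliers`, `annual`
#'   (the possibly forecast-extended annual table) and `log` (character
#'   vector of events). Files are also written when `out_dir` is set.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  log <- character()
  say <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))

  raw <- if (is.character(config$raw)) read_raw_deaths(config$raw) else config$raw
  annual <- if (is.character(config$annual)) read_annual(config$annual) else config$annual
  official <- if (is.character(config$official)) {
    o <- readr::read_csv(config$official, col_types = readr::cols(), progress = FALSE)
    names(o) <- tolower(names(o))
    o$sex <- normalize_sex(o$sex)
    o
  } else config$official
  country <- config$country %||% raw$pop_name[1]
  say("read %d raw records for %s (week scheme: %s)", nrow(raw), country,
      config$week_scheme %||% country_week_scheme(country))

  raw <- clamp_to_52(raw, mode = config$week53)
  cl <- attr(raw, "clamp_log")
  if (!is.null(cl) && nrow(cl) > 0) {
    for (i in seq_len(nrow(cl))) {
      say("week 53 of %d: %s %.2f deaths", cl$year[i],
          if (cl$action[i] == "merge") "merged into week 52," else "dropped,",
          cl$deaths_moved[i])
    }
  }

  if (!"source" %in% names(annual)) annual$source <- "observed"
  missing_years <- setdiff(unique(raw$year), unique(annual$year))
  horizon <- config$lc_horizon %||%
    (if (length(missing_years) > 0) max(missing_years) - max(annual$year) else 0)
  if (horizon > 0) {
    annual <- forecast_annual(annual, horizon, start_year = config$lc_start_year)
    say("annual table extended by Lee-Carter forecast: horizon %d (years %s)",
        horizon, paste(setdiff(unique(annual$year[annual$source == "forecast"]),
                               NULL), collapse = ", "))
  }

  harm <- harmonize(raw, annual, config$targets)
  rl <- attr(harm, "redistribute_log")
  if (!is.null(rl) && nrow(rl) > 0) {
    say("unknown-age fallback to annual distribution in %d stratum(s)", nrow(rl))
  }
  stmf <- build_stmf(harm, annual, config$targets)
  stmf$CountryCode <- country

  validation <- check_internal(stmf, raw = raw)
  if (!is.null(official)) {
    validation <- dplyr::bind_rows(validation,
                                   check_external(stmf, official,
                                                  tol = config$external_tol))
  }
  n_fail <- sum(validation$status == "fail")
  say("validation: %d checks, %d fail, %d warn", nrow(validation), n_fail,
      sum(validation$status == "warn"))

  tcol <- utils::tail(stmf_out_cols(config$targets)$rates, 1)
  hist_rates <- stmf |>
    dplyr::filter(.data$Sex == "b") |>
    dplyr::select(year = "Year", week = "Week", rate = dplyr::all_of(tcol))
  outliers <- if (length(unique(hist_rates$year)) >= 2) {
    detect_outliers(hist_rates, threshold = config$outlier_threshold)
  } else tibble::tibble()

  exc <- NULL
  if (!is.null(config$target_year)) {
    ref_years <- config$reference_years %||%
      setdiff(sort(unique(hist_rates$year)), config$target_year)
    bl <- baseline(dplyr::filter(hist_rates, .data$year != config$target_year),
                   method = config$baseline_method,
                   reference_years = ref_years,
                   target_year = config$target_year)
    obs <- dplyr::filter(hist_rates, .data$year == config$target_year)
    e_tot <- sum(aggregate_annual(annual, config$targets) |>
                   dplyr::filter(.data$sex == "b",
                                 .data$year == config$target_year) |>
                   dplyr::pull("exposure"))
    exc <- excess(obs, bl, exposure = e_tot)
    say("excess vs %s baseline over %s: cumulative %.1f deaths",
        config$baseline_method, paste(range(ref_years), collapse = "-"),
        cumulative_excess(exc))
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_stmf(stmf, file.path(config$out_dir, "stmf_output.csv"))
    write_report(validation, file.path(config$out_dir, "validation.jsonl"))
    if (!is.null(exc)) {
      readr::write_csv(tibble::as_tibble(exc),
                       file.path(config$out_dir, "excess.csv"), progress = FALSE)
    }
    writeLines(log, file.path(config$out_dir, "run.log"))
  }

  list(stmf = stmf, validation = validation, excess = exc,
       outliers = outliers, annual = annual, log = log)
}
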