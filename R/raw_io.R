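#' Field names of the raw weekly death-count CSV
#'
#' The raw input dialect is a comma-separated file with one record per weekly
#' death count, carrying the population code, sub-area, year, week, sex, age
#' interval, data type (occurrence vs registration) and access level. The
#' exact header spelling is configurable; these are the defaults.
#'
#' @return Named character vector mapping internal column names to file
#'   header names.
#' @export
stmf_raw_cols <- function() {
  c(pop_name = "PopName", area = "Area", year = "Year", week = "Week",
    sex = "Sex", age = "Age", age_interval = "AgeInterval",
    type = "Type", access = "Access", deaths = "Deaths")
}

# sentinel tokens in the Age / AgeInterval columns
UNK_AGE <- "UNK"
OPEN_INTERVAL <- "+"

#' Read a raw weekly death-count file
#'
#' Parses the raw CSV dialect into a long tibble of weekly death records.
#' Unknown-age rows (Age = `"UNK"`) are preserved with `age_start = NA`;
#' the open-ended terminal interval (AgeInterval = `"+"`) becomes
#' `age_interval = Inf`. Death counts may be fractional (upstream splitting
#' produces non-integers); no rounding is applied.
#'
#' @param path Path to a CSV file with the header of [stmf_raw_cols()].
#' @param col_names Named character vector overriding the expected header
#'   spelling, in the shape of [stmf_raw_cols()].
#' @return A tibble with columns `pop_name`, `area`, `year`, `week`, `sex`
#'   (`"m"`, `"f"` or `"b"`), `age_start` (`NA` for unknown age),
#'   `age_interval` (`Inf` for the open group, `NA` for unknown age),
#'   `deaths`, `data_type` (`"O"` occurrence / `"R"` registration), `access`.
#' @export
read_raw_deaths <- function(path, col_names = stmf_raw_cols()) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(unname(col_names), names(raw))
  if (length(missing) > 0) {
    rlang::abort(sprintf("missing required column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  x <- tibble::tibble(
    pop_name = raw[[col_names[["pop_name"]]]],
    area = dplyr::coalesce(raw[[col_names[["area"]]]], ""),
    year = as.integer(raw[[col_names[["year"]]]]),
    week = as.integer(raw[[col_names[["week"]]]]),
    sex = normalize_sex(raw[[col_names[["sex"]]]]),
    age_start = suppressWarnings(as.numeric(ifelse(
      toupper(raw[[col_names[["age"]]]]) == UNK_AGE, NA, raw[[col_names[["age"]]]]))),
    age_interval = parse_age_interval(raw[[col_names[["age_interval"]]]],
                                      toupper(raw[[col_names[["age"]]]]) == UNK_AGE),
    deaths = as.numeric(raw[[col_names[["deaths"]]]]),
    data_type = toupper(raw[[col_names[["type"]]]]),
    access = raw[[col_names[["access"]]]]
  )
  validate_raw_deaths(x)
  x
}

parse_age_interval <- function(v, unknown) {
  out <- suppressWarnings(as.numeric(ifelse(v == OPEN_INTERVAL, Inf, v)))
  out[unknown] <- NA_real_
  out
}

normalize_sex <- function(v) {
  s <- tolower(substr(trimws(v), 1, 1))
  if (!all(s %in% c("m", "f", "b"))) {
    bad <- which(!s %in% c("m", "f", "b"))
    rlang::abort(sprintf("unrecognized sex code in row(s) %s",
                         paste(utils::head(bad, 5), collapse = ", ")))
  }
  s
}

validate_raw_deaths <- function(x) {
  if (anyNA(x$deaths)) {
    rlang::abort(sprintf("non-numeric death count in row(s) %s",
                         paste(utils::head(which(is.na(x$deaths)), 5), collapse = ", ")))
  }
  if (any(x$deaths < 0)) {
    rlang::abort(sprintf("negative death count in row(s) %s",
                         paste(utils::head(which(x$deaths < 0), 5), collapse = ", ")))
  }
  if (any(is.na(x$week) | x$week < 1)) {
    bad <- which(is.na(x$week) | x$week < 1)
    rlang::abort(sprintf("week index < 1 or missing in row(s) %s",
                         paste(utils::head(bad, 5), collapse = ", ")))
  }
  known <- !is.na(x$age_start)
  if (any(known & is.na(x$age_interval))) {
    rlang::abort("known-age row with missing age interval")
  }
  # age intervals within a stratum must not overlap
  overlaps <- x[known, ] |>
    dplyr::group_by(.data$pop_name, .data$area, .data$year, .data$week, .data$sex) |>
    dplyr::filter(dplyr::n() > 1) |>
    dplyr::arrange(.data$age_start, .by_group = TRUE) |>
    dplyr::summarise(bad = any(.data$age_start[-1] <
                                 (.data$age_start + .data$age_interval)[-dplyr::n()]),
                     .groups = "drop") |>
    dplyr::filter(.data$bad)
  if (nrow(overlaps) > 0) {
    k <- overlaps[1, ]
    rlang::abort(sprintf("overlapping age intervals in stratum (%s, %s, %d, %d, %s)",
                         k$pop_name, k$area, k$year, k$week, k$sex))
  }
  invisible(x)
}

#' Write a raw weekly death-count file
#'
#' Inverse of [read_raw_deaths()]: serializes the long record tibble back to
#' the raw CSV dialect at full precision (lossless round trip).
#'
#' @param x Tibble as returned by [read_raw_deaths()] or the synthetic
#'   generator.
#' @param path Output file path.
#' @param col_names Header spelling, as in [read_raw_deaths()].
#' @return `path`, invisibly.
#' @export
write_raw_deaths <- function(x, path, col_names = stmf_raw_cols()) {
  validate_raw_deaths(x)
  out <- tibble::tibble(
    PopName = x$pop_name, Area = x$area, Year = x$year, Week = x$week,
    Sex = x$sex,
    Age = ifelse(is.na(x$age_start), UNK_AGE, format(x$age_start, trim = TRUE, scientific = FALSE)),
    AgeInterval = ifelse(is.na(x$age_start), ".",
                         ifelse(is.infinite(x$age_interval), OPEN_INTERVAL,
                                format(x$age_interval, trim = TRUE, scientific = FALSE))),
    Type = x$data_type, Access = x$access,
    Deaths = format(x$deaths, trim = TRUE, scientific = FALSE, digits = 15)
  )
  names(out) <- unname(col_names[c("pop_name", "area", "year", "week", "sex",
                                   "age", "age_interval", "type", "access", "deaths")])
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

stmf_out_cols <- function(groups = stmf_age_groups()) {
  g <- gsub("[-+]", "_", groups$age_label)
  g <- sub("_$", "p", g)
  list(deaths = paste0("D", c(g, "Total")), rates = paste0("R", c(g, "Total")))
}

#' Write the harmonized output table
#'
#' Writes the wide harmonized table (one row per country, year, week, sex;
#' death counts and person-week rates for the five standard age groups and
#' all ages; Split / SplitSex / Forecast indicator flags) as CSV at full
#' precision. Records violating the internal invariants (group counts not
#' summing to the all-ages total, non-binary flags) are refused.
#'
#' @param x Wide tibble as produced by [build_stmf()].
#' @param path Output file path.
#' @param long If `TRUE`, write a tidy long variant (one row per age group)
#'   instead of the standard wide layout.
#' @param tol Relative tolerance for the sum-to-total invariant.
#' @return `path`, invisibly.
#' @export
write_stmf <- function(x, path, long = FALSE, tol = 1e-9) {
  validate_stmf_table(x, tol = tol)
  if (long) {
    cols <- stmf_out_cols()
    x <- tidyr::pivot_longer(x, cols = dplyr::all_of(c(cols$deaths, cols$rates)),
                             names_to = "measure", values_to = "value")
  }
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' Read a harmonized output table written by [write_stmf()]
#' @param path CSV file path.
#' @return Wide tibble with the harmonized layout.
#' @export
read_stmf <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    CountryCode = readr::col_character(), Year = readr::col_integer(),
    Week = readr::col_integer(), Sex = readr::col_character(),
    .default = readr::col_double()), progress = FALSE)
}

validate_stmf_table <- function(x, tol = 1e-9) {
  cols <- stmf_out_cols()
  need <- c("CountryCode", "Year", "Week", "Sex", cols$deaths, cols$rates,
            "Split", "SplitSex", "Forecast")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    rlang::abort(sprintf("harmonized table missing column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  grp <- as.matrix(x[, cols$deaths[-length(cols$deaths)]])
  tot <- x[[cols$deaths[length(cols$deaths)]]]
  err <- abs(rowSums(grp) - tot) / pmax(tot, 1)
  if (any(err > tol)) {
    i <- which.max(err)
    rlang::abort(sprintf(
      "age-group deaths do not sum to total for (%s, %d, week %d, %s): rel err %.3g",
      x$CountryCode[i], x$Year[i], x$Week[i], x$Sex[i], err[i]))
  }
  flags <- c("Split", "SplitSex", "Forecast")
  for (f in flags) {
    if (!all(x[[f]] %in% c(0, 1))) rlang::abort(sprintf("flag %s must be 0/1", f))
  }
  invisible(x)
}

#' Read an annual deaths/exposures table
#'
#' Long CSV with one row per (year, sex, age group): annual death counts and
#' person-year exposures, with an optional `Source` column distinguishing
#' observed from forecast years.
#'
#' @param path CSV with columns Year, Sex, Age, AgeInterval, Deaths,
#'   Exposure and optionally Source.
#' @return Tibble with columns `year`, `sex`, `age_start`, `age_interval`,
#'   `deaths`, `exposure`, `source`.
#' @export
read_annual <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("Year", "Sex", "Age", "AgeInterval", "Deaths", "Exposure")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    rlang::abort(sprintf("missing required column(s): %s", paste(missing, collapse = ", ")))
  }
  tibble::tibble(
    year = as.integer(raw$Year),
    sex = normalize_sex(raw$Sex),
    age_start = as.numeric(raw$Age),
    age_interval = suppressWarnings(as.numeric(ifelse(raw$AgeInterval == OPEN_INTERVAL,
                                                      Inf, raw$AgeInterval))),
    deaths = as.numeric(raw$Deaths),
    exposure = as.numeric(raw$Exposure),
    source = if ("Source" %in% names(raw)) tolower(raw$Source) else "observed"
  )
}

#' Write an annual deaths/exposures table
#' @param x Tibble as returned by [read_annual()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annual <- function(x, path) {
  out <- tibble::tibble(
    Year = x$year, Sex = x$sex,
    Age = format(x$age_start, trim = TRUE, scientific = FALSE),
    AgeInterval = ifelse(is.infinite(x$age_interval), OPEN_INTERVAL,
                         format(x$age_interval, trim = TRUE, scientific = FALSE)),
    Deaths = format(x$deaths, trim = TRUE, scientific = FALSE, digits = 15),
    Exposure = format(x$exposure, trim = TRUE, scientific = FALSE, digits = 15),
    Source = if ("source" %in% names(x)) x$source else "observed"
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
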