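#' Week-numbering schemes
#'
#' Weekly death counts are labeled by (year, week). The default scheme is
#' ISO-8601: weeks start on Monday and week 1 is the week containing the
#' year's first Thursday (equivalently, January 4). National statistical
#' offices deviate: in the USA weeks begin on Sunday, in England & Wales and
#' Northern Ireland on Saturday, and in Australia the week count restarts on
#' January 1. For the Sunday- and Saturday-start schemes week 1 is defined,
#' by convention of this package, as the week (starting on the scheme's start
#' day) that contains January 4 — the direct analogue of the ISO rule.
#'
#' @return Character vector of recognized scheme identifiers.
#' @export
week_schemes <- function() {
  c("iso_monday", "sunday_start", "saturday_start", "jan1_start")
}

#' Default country-to-scheme assignment
#'
#' @return Named character vector mapping country codes to scheme ids; any
#'   country not listed uses `iso_monday`.
#' @export
default_week_scheme_map <- function() {
  c(USA = "sunday_start", GBRTENW = "saturday_start", GBR_NIR = "saturday_start",
    AUS = "jan1_start")
}

# weekday as Mon=0 .. Sun=6
wday0 <- function(d) (as.integer(unclass(d)) + 3L) %% 7L

# start-of-week date for a scheme whose weeks begin on weekday `start`
# (Mon=0, Sat=5, Sun=6)
week_start_date <- function(d, start) {
  d - ((wday0(d) - start) %% 7L)
}

#' Map dates to (year, week) labels
#'
#' Assigns every date a statistical (year, week) label under the given
#' scheme. For `iso_monday` this reproduces ISO-8601 week numbering exactly.
#' For `sunday_start` / `saturday_start`, weeks are 7-day blocks beginning on
#' the scheme's start day, with week 1 the block containing January 4. For
#' `jan1_start`, week 1 begins on January 1 and weeks are consecutive 7-day
#' blocks within the calendar year; the final 1-2 day remainder is labeled
#' week 53 and is excluded from the 52-week statistical year by
#' [clamp_to_52()].
#'
#' @param dates A `Date` vector (or something coercible by `as.Date()`).
#' @param scheme One of [week_schemes()].
#' @return A tibble with columns `date`, `year`, `week`.
#' @export
#' @examples
#' date_to_week(as.Date(c("2020-01-01", "2016-01-01")))
date_to_week <- function(dates, scheme = c("iso_monday", "sunday_start",
                                           "saturday_start", "jan1_start")) {
  scheme <- match.arg(scheme)
  d <- as.Date(dates)
  if (anyNA(d)) rlang::abort("invalid date(s) in input")
  if (scheme == "jan1_start") {
    yd <- as.POSIXlt(d)$yday # 0-based day of year
    return(tibble::tibble(date = d,
                          year = as.POSIXlt(d)$year + 1900L,
                          week = yd %/% 7L + 1L))
  }
  start <- switch(scheme, iso_monday = 0L, saturday_start = 5L, sunday_start = 6L)
  ws <- week_start_date(d, start)
  ws_year <- as.POSIXlt(ws)$year + 1900L
  anchor <- function(y) week_start_date(as.Date(paste0(y, "-01-04")), start)
  a_this <- anchor(ws_year)
  a_next <- anchor(ws_year + 1L)
  a_prev <- anchor(ws_year - 1L)
  year <- ifelse(ws >= a_next, ws_year + 1L,
                 ifelse(ws < a_this, ws_year - 1L, ws_year))
  ref <- as.Date(ifelse(ws >= a_next, a_next, ifelse(ws < a_this, a_prev, a_this)),
                 origin = "1970-01-01")
  week <- as.integer((as.integer(unclass(ws)) - as.integer(unclass(ref))) %/% 7L) + 1L
  tibble::tibble(date = d, year = as.integer(year), week = week)
}

#' Look up the week scheme for a country
#' @param country Country/population code.
#' @param scheme_map Named vector as [default_week_scheme_map()].
#' @return A scheme id.
#' @export
country_week_scheme <- function(country, scheme_map = default_week_scheme_map()) {
  if (country %in% names(scheme_map)) unname(scheme_map[[country]]) else "iso_monday"
}

#' Enforce the 52-week statistical year
#'
#' Each statistical year covers exactly 52 weeks. Source data labeled with a
#' week 53 (long ISO years, or the short terminal period of January-1
#' numbering) are merged into week 52 of the same year so that no deaths are
#' lost; alternatively week-53 rows can be dropped. Every merge is recorded
#' in the `clamp_log` attribute of the result.
#'
#' @param x Tibble with at least `year`, `week` and `deaths` columns; any
#'   additional columns define strata that are preserved.
#' @param mode `"merge"` (default; adds week-53 deaths into week 52) or
#'   `"drop"`.
#' @return `x` restricted to weeks 1-52, with attribute `clamp_log` (a tibble
#'   of the year/strata affected and the deaths moved or dropped).
#' @export
clamp_to_52 <- function(x, mode = c("merge", "drop")) {
  mode <- match.arg(mode)
  stopifnot(all(c("year", "week", "deaths") %in% names(x)))
  if (any(x$week > 53)) {
    rlang::abort(sprintf("week index > 53 in year %d",
                         x$year[which(x$week > 53)[1]]))
  }
  if (any(x$week < 1)) rlang::abort("week index < 1")
  w53 <- dplyr::filter(x, .data$week == 53L)
  log <- dplyr::distinct(w53, .data$year) |>
    dplyr::mutate(action = mode,
                  deaths_moved = purrr::map_dbl(.data$year, function(y) {
                    sum(w53$deaths[w53$year == y])
                  }))
  if (mode == "merge") {
    out <- x |>
      dplyr::mutate(week = ifelse(.data$week == 53L, 52L, .data$week)) |>
      dplyr::group_by(dplyr::across(-"deaths")) |>
      dplyr::summarise(deaths = sum(.data$deaths), .groups = "drop")
    out <- out[, names(x)]
  } else {
    out <- dplyr::filter(x, .data$week <= 52L)
  }
  if (nrow(log) > 0) attr(out, "clamp_log") <- log
  out
}
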