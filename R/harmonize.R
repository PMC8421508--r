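#' Aggregate an annual table to a target age grouping
#'
#' Sums annual deaths and exposures into the target groups (each annual row
#' must nest inside exactly one target group) and synthesizes both-sex rows
#' by summing males and females where they are absent.
#'
#' @param annual Annual tibble (`year`, `sex`, `age_start`, `age_interval`,
#'   `deaths`, `exposure`, optionally `source`).
#' @param targets Age-group table, default [stmf_age_groups()].
#' @return Annual tibble at target resolution, including `"b"` rows.
#' @export
aggregate_annual <- function(annual, targets = stmf_age_groups()) {
  idx <- purrr::map_int(seq_len(nrow(annual)), function(i) {
    hit <- which(nests_in(annual$age_start[i], annual$age_interval[i],
                          targets$age_start, targets$age_interval))
    if (length(hit) != 1L) {
      rlang::abort(sprintf(
        "annual age interval %s does not nest in exactly one target group",
        age_label(annual$age_start[i], annual$age_interval[i])))
    }
    hit
  })
  has_source <- "source" %in% names(annual)
  agg <- annual |>
    dplyr::mutate(age_start = targets$age_start[idx],
                  age_interval = targets$age_interval[idx]) |>
    dplyr::group_by(.data$year, .data$sex, .data$age_start, .data$age_interval) |>
    dplyr::summarise(
      deaths = sum(.data$deaths), exposure = sum(.data$exposure),
      source = if (has_source) {
        if (any(.data$source == "forecast")) "forecast" else "observed"
      } else "observed",
      .groups = "drop")
  # both-sex rows from m + f where not already present
  have_b <- dplyr::filter(agg, .data$sex == "b")
  b <- agg |>
    dplyr::filter(.data$sex %in% c("m", "f")) |>
    dplyr::anti_join(have_b, by = c("year", "age_start", "age_interval")) |>
    dplyr::group_by(.data$year, .data$age_start, .data$age_interval) |>
    dplyr::summarise(deaths = sum(.data$deaths), exposure = sum(.data$exposure),
                     source = if (any(.data$source == "forecast")) "forecast" else "observed",
                     .groups = "drop") |>
    dplyr::mutate(sex = "b")
  dplyr::bind_rows(agg, b[, names(agg)]) |>
    dplyr::arrange(.data$year, .data$sex, .data$age_start)
}

#' Redistribute deaths of unknown age
#'
#' Deaths reported with unknown age are allocated proportionally to the
#' known-age counts of the same (population, area, year, week, sex) stratum,
#' conserving the stratum total. If the stratum's known-age counts are all
#' zero, the annual age distribution of the same year and sex is used
#' instead; if that is also unavailable the function errors. Unknown-age
#' deaths are typically a very small share of the total, so this proportional
#' rule has negligible influence on the harmonized series.
#'
#' @param weekly Long weekly tibble (columns of [read_raw_deaths()]);
#'   unknown-age rows have `age_start = NA`.
#' @param annual Optional annual tibble used for the all-zero fallback.
#' @return The weekly tibble without unknown-age rows; attribute
#'   `redistribute_log` records every stratum where the annual fallback was
#'   used.
#' @export
redistribute_unknown_age <- function(weekly, annual = NULL) {
  unk <- is.na(weekly$age_start)
  if (!any(unk)) return(weekly)
  key <- c("pop_name", "area", "year", "week", "sex")
  unk_tab <- weekly[unk, ] |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key))) |>
    dplyr::summarise(unknown_deaths = sum(.data$deaths), .groups = "drop")
  known <- weekly[!unk, ]
  out <- dplyr::left_join(known, unk_tab, by = key) |>
    dplyr::mutate(unknown_deaths = dplyr::coalesce(.data$unknown_deaths, 0))
  fallback_log <- tibble::tibble()
  out <- out |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key))) |>
    dplyr::group_modify(function(g, k) {
      u <- g$unknown_deaths[1]
      if (u == 0) return(dplyr::select(g, -"unknown_deaths"))
      tot <- sum(g$deaths)
      if (tot > 0) {
        g$deaths <- g$deaths + u * g$deaths / tot
      } else {
        if (is.null(annual)) {
          rlang::abort(sprintf(
            "stratum (%s, %d, week %d, %s) has unknown-age deaths but all known counts are zero and no annual table was given",
            k$pop_name, k$year, k$week, k$sex))
        }
        ann <- annual[annual$year == k$year & annual$sex == k$sex, ]
        w <- purrr::map_dbl(seq_len(nrow(g)), function(i) {
          sum(ann$deaths[nests_in(ann$age_start, ann$age_interval,
                                  g$age_start[i], g$age_interval[i])])
        })
        if (sum(w) <= 0) {
          rlang::abort(sprintf(
            "stratum (%s, %d, week %d, %s): unknown-age deaths cannot be redistributed (annual distribution empty)",
            k$pop_name, k$year, k$week, k$sex))
        }
        g$deaths <- g$deaths + u * w / sum(w)
        fallback_log <<- dplyr::bind_rows(fallback_log,
                                          dplyr::mutate(k, unknown_deaths = u))
      }
      dplyr::select(g, -"unknown_deaths")
    }) |>
    dplyr::ungroup()
  out <- out[, names(weekly)]
  attr(out, "redistribute_log") <- fallback_log
  out
}

#' Split broad age intervals into target age groups
#'
#' Disaggregates weekly death counts reported in broad age intervals into the
#' target groups, proportionally to the annual age-specific death counts of
#' the same year and sex (observed or forecast): the estimated count in
#' target group \[x, x+a) nested in source interval \[x, x+b) is the weekly
#' source count times the ratio of annual deaths in \[x, x+a) to annual
#' deaths in \[x, x+b). Within every source interval the split counts sum
#' exactly to the source count, so totals are conserved. The annual age
#' distribution stands in for the within-year weekly one; this is exact when
#' the weekly age distribution is stable across the year and biased when a
#' shock shifts it (e.g. toward old ages).
#'
#' @param weekly Long weekly tibble of known-age records.
#' @param annual Annual tibble covering every target group for the years and
#'   sexes present.
#' @param targets Target age grouping, default [stmf_age_groups()].
#' @return Long weekly tibble on the target groups with an added `split`
#'   column: 1 for every row of a (population, year) in which any source
#'   interval strictly contained more than one target group, else 0.
#' @export
split_age_groups <- function(weekly, annual, targets = stmf_age_groups()) {
  if (anyNA(weekly$age_start)) {
    rlang::abort("unknown-age rows present; run redistribute_unknown_age() first")
  }
  ann_t <- aggregate_annual(annual, targets)
  w <- dplyr::mutate(weekly, .row = dplyr::row_number())
  tg <- dplyr::rename(targets, t_start = "age_start", t_interval = "age_interval")
  cand <- dplyr::cross_join(w, tg) |>
    dplyr::filter(nests_in(.data$t_start, .data$t_interval,
                           .data$age_start, .data$age_interval))
  # every source interval must be exactly tiled by its nested targets
  cover <- cand |>
    dplyr::group_by(.data$.row) |>
    dplyr::summarise(
      n_targets = dplyr::n(),
      width_ok = (is.infinite(.data$age_interval[1]) &&
                    any(is.infinite(.data$t_interval))) ||
        isTRUE(all.equal(sum(.data$t_interval), .data$age_interval[1])),
      .groups = "drop")
  bad <- setdiff(w$.row, cover$.row)
  if (length(bad) > 0 || any(!cover$width_ok)) {
    i <- if (length(bad) > 0) bad[1] else cover$.row[!cover$width_ok][1]
    rlang::abort(sprintf(
      "source interval %s (year %d, week %d, sex %s) is not tiled by the target groups",
      age_label(w$age_start[i], w$age_interval[i]), w$year[i], w$week[i], w$sex[i]))
  }
  cand <- dplyr::left_join(cand,
                           dplyr::select(ann_t, "year", "sex",
                                         t_start = "age_start", t_interval = "age_interval",
                                         ann_deaths = "deaths"),
                           by = c("year", "sex", "t_start", "t_interval"))
  if (anyNA(cand$ann_deaths)) {
    i <- which(is.na(cand$ann_deaths))[1]
    rlang::abort(sprintf("annual table lacks group %s for year %d, sex %s",
                         age_label(cand$t_start[i], cand$t_interval[i]),
                         cand$year[i], cand$sex[i]))
  }
  out <- cand |>
    dplyr::group_by(.data$.row) |>
    dplyr::mutate(denom = sum(.data$ann_deaths)) |>
    dplyr::ungroup()
  zero_denom <- out$denom == 0 & out$deaths > 0
  if (any(zero_denom)) {
    i <- which(zero_denom)[1]
    rlang::abort(sprintf(
      "annual deaths are zero in source interval %s (year %d, sex %s) but weekly deaths are positive",
      age_label(out$age_start[i], out$age_interval[i]), out$year[i], out$sex[i]))
  }
  out <- out |>
    dplyr::mutate(deaths = ifelse(.data$deaths == 0, 0,
                                  .data$deaths * .data$ann_deaths / .data$denom))
  split_flags <- dplyr::left_join(out, dplyr::select(cover, ".row", "n_targets"),
                                  by = ".row") |>
    dplyr::group_by(.data$pop_name, .data$year) |>
    dplyr::summarise(split = as.integer(any(.data$n_targets > 1)), .groups = "drop")
  keep <- setdiff(names(weekly), c("age_start", "age_interval", "deaths"))
  out |>
    dplyr::mutate(age_start = .data$t_start, age_interval = .data$t_interval) |>
    dplyr::select(dplyr::all_of(c(keep, "age_start", "age_interval", "deaths"))) |>
    dplyr::left_join(split_flags, by = c("pop_name", "year")) |>
    dplyr::arrange(.data$pop_name, .data$area, .data$year, .data$week,
                   .data$sex, .data$age_start)
}

#' Split combined-sex weekly counts into males and females
#'
#' Weekly both-sex counts are split using the observed sex ratio of the
#' annual death counts in the same age group and year: the male share of the
#' weekly count equals the male share of the annual count, and the female
#' count is the exact remainder, so male + female reproduces the both-sex
#' total cell by cell. Rows already reported by sex pass through unchanged.
#'
#' @param weekly Long weekly tibble on a fixed age grouping; `sex` values
#'   `"b"` are split, `"m"`/`"f"` pass through.
#' @param annual Annual tibble with male and female rows covering the age
#'   groups present.
#' @return Long weekly tibble with only `"m"`/`"f"` rows and an added
#'   `split_sex` column: 1 for every row of a (population, year) whose input
#'   contained both-sex records, else 0.
#' @export
split_sex <- function(weekly, annual) {
  groups <- dplyr::distinct(weekly, .data$age_start, .data$age_interval)
  # annual m/f deaths summed into each weekly group (annual rows outside the
  # weekly grouping are simply unused)
  shares <- tidyr::expand_grid(groups, year = unique(weekly$year)) |>
    dplyr::mutate(
      m = purrr::pmap_dbl(list(.data$age_start, .data$age_interval, .data$year),
                          function(s, i, y) {
                            a <- annual[annual$sex == "m" & annual$year == y, ]
                            sum(a$deaths[nests_in(a$age_start, a$age_interval, s, i)])
                          }),
      f = purrr::pmap_dbl(list(.data$age_start, .data$age_interval, .data$year),
                          function(s, i, y) {
                            a <- annual[annual$sex == "f" & annual$year == y, ]
                            sum(a$deaths[nests_in(a$age_start, a$age_interval, s, i)])
                          }),
      total = .data$m + .data$f,
      male_share = ifelse(.data$total > 0, .data$m / .data$total, NA_real_))
  flag_years <- weekly |>
    dplyr::group_by(.data$pop_name, .data$year) |>
    dplyr::summarise(split_sex = as.integer(any(.data$sex == "b")), .groups = "drop")
  b <- dplyr::filter(weekly, .data$sex == "b") |>
    dplyr::left_join(dplyr::select(shares, "year", "age_start", "age_interval",
                                   "male_share"),
                     by = c("year", "age_start", "age_interval"))
  bad <- is.na(b$male_share) & b$deaths > 0
  if (any(bad)) {
    i <- which(bad)[1]
    rlang::abort(sprintf(
      "annual both-sex deaths are zero or missing for group %s, year %d, but weekly deaths are positive",
      age_label(b$age_start[i], b$age_interval[i]), b$year[i]))
  }
  b$male_share[is.na(b$male_share)] <- 0
  males <- dplyr::mutate(b, sex = "m", deaths = .data$deaths * .data$male_share)
  females <- dplyr::mutate(b, sex = "f",
                           deaths = .data$deaths - .data$deaths * .data$male_share)
  out <- dplyr::bind_rows(
    dplyr::filter(weekly, .data$sex != "b"),
    dplyr::select(males, -"male_share"),
    dplyr::select(females, -"male_share"))
  out |>
    dplyr::left_join(flag_years, by = c("pop_name", "year")) |>
    dplyr::arrange(.data$pop_name, .data$area, .data$year, .data$week,
                   .data$sex, .data$age_start)
}

#' Harmonize raw weekly records into the standard age groups by sex
#'
#' Applies, in order: redistribution of unknown-age deaths, splitting of
#' broad age intervals into the target groups, and splitting of combined-sex
#' counts — each proportional to annual distributions and each conserving
#' stratum totals. The order (unknown age first, then age, then sex) is
#' fixed; for the proportional operators the age and unknown-age steps
#' commute whenever the annual fallback is not triggered.
#'
#' @param weekly Long weekly tibble from [read_raw_deaths()] (week-clamped
#'   via [clamp_to_52()] if the source uses week 53).
#' @param annual Annual tibble (`year`, `sex`, `age_start`, `age_interval`,
#'   `deaths`, `exposure`, `source`).
#' @param targets Target age grouping, default [stmf_age_groups()].
#' @return Long tibble with one row per (population, area, year, week, sex
#'   m/f, target age group): `deaths` plus the `split` and `split_sex` flag
#'   columns.
#' @export
harmonize <- function(weekly, annual, targets = stmf_age_groups()) {
  weekly |>
    redistribute_unknown_age(annual) |>
    split_age_groups(annual, targets) |>
    split_sex(annual)
}

#' Assemble the wide harmonized output table
#'
#' Combines harmonized male/female weekly counts with annual exposures into
#' the standard wide output: per (country, year, week, sex in m/f/b) the
#' death counts and person-week death rates for each age group and all ages,
#' plus the Split, SplitSex and Forecast indicator columns. Both-sex rows are
#' the sums of the male and female rows; rates divide counts by one week of
#' the annual exposure (exposure / 52). Forecast is 1 for every year whose
#' exposures come from forecast rather than observed annual data.
#'
#' @param harmonized Output of [harmonize()].
#' @param annual Annual tibble with exposures (and a `source` column marking
#'   forecast years).
#' @param targets Age grouping used in `harmonized`.
#' @return Wide tibble (columns `CountryCode`, `Year`, `Week`, `Sex`,
#'   `D<group>`/`DTotal`, `R<group>`/`RTotal`, `Split`, `SplitSex`,
#'   `Forecast`).
#' @export
build_stmf <- function(harmonized, annual, targets = stmf_age_groups()) {
  ann_t <- aggregate_annual(annual, targets)
  b_rows <- harmonized |>
    dplyr::group_by(.data$pop_name, .data$year, .data$week,
                    .data$age_start, .data$age_interval) |>
    dplyr::summarise(deaths = sum(.data$deaths),
                     split = max(.data$split), split_sex = max(.data$split_sex),
                     .groups = "drop") |>
    dplyr::mutate(sex = "b")
  long <- dplyr::bind_rows(
    dplyr::select(harmonized, "pop_name", "year", "week", "sex",
                  "age_start", "age_interval", "deaths", "split", "split_sex"),
    b_rows[, c("pop_name", "year", "week", "sex", "age_start", "age_interval",
               "deaths", "split", "split_sex")])
  long <- long |>
    dplyr::left_join(dplyr::select(ann_t, "year", "sex", "age_start",
                                   "age_interval", "exposure", "source"),
                     by = c("year", "sex", "age_start", "age_interval"))
  if (anyNA(long$exposure)) {
    i <- which(is.na(long$exposure))[1]
    rlang::abort(sprintf("no annual exposure for year %d, sex %s, group %s",
                         long$year[i], long$sex[i],
                         age_label(long$age_start[i], long$age_interval[i])))
  }
  long <- dplyr::mutate(long,
                        rate = weekly_rate(.data$deaths, .data$exposure),
                        age_lab = age_label(.data$age_start, .data$age_interval),
                        forecast = as.integer(.data$source == "forecast"))
  cols <- stmf_out_cols(targets)
  glabs <- targets$age_label
  wide_d <- tidyr::pivot_wider(long,
                               id_cols = c("pop_name", "year", "week", "sex",
                                           "split", "split_sex"),
                               names_from = "age_lab", values_from = "deaths")
  wide_r <- tidyr::pivot_wider(long,
                               id_cols = c("pop_name", "year", "week", "sex"),
                               names_from = "age_lab", values_from = "rate")
  fc <- long |>
    dplyr::group_by(.data$pop_name, .data$year, .data$week, .data$sex) |>
    dplyr::summarise(Forecast = max(.data$forecast), .groups = "drop")
  etot <- long |>
    dplyr::group_by(.data$pop_name, .data$year, .data$week, .data$sex) |>
    dplyr::summarise(e_total = sum(.data$exposure), .groups = "drop")
  dm <- as.matrix(wide_d[, glabs])
  rmat <- as.matrix(wide_r[, glabs])
  out <- tibble::tibble(
    CountryCode = wide_d$pop_name, Year = as.integer(wide_d$year),
    Week = as.integer(wide_d$week), Sex = wide_d$sex)
  for (j in seq_along(glabs)) out[[cols$deaths[j]]] <- dm[, j]
  out[[cols$deaths[length(cols$deaths)]]] <- rowSums(dm)
  for (j in seq_along(glabs)) out[[cols$rates[j]]] <- rmat[, j]
  out[[cols$rates[length(cols$rates)]]] <-
    rowSums(dm) / (etot$e_total[match(paste(out$CountryCode, out$Year, out$Week, out$Sex),
                                      paste(etot$pop_name, etot$year, etot$week, etot$sex))] / 52)
  out$Split <- as.integer(wide_d$split)
  out$SplitSex <- as.integer(wide_d$split_sex)
  out$Forecast <- as.integer(fc$Forecast[match(
    paste(out$CountryCode, out$Year, out$Week, out$Sex),
    paste(fc$pop_name, fc$year, fc$week, fc$sex))])
  dplyr::arrange(out, .data$CountryCode, .data$Year, .data$Week, .data$Sex)
}
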