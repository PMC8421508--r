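#' Fit a Lee-Carter mortality model
#'
#' Fits log m(x,t) = a_x + b_x * k_t to an age-by-year matrix of annual death
#' rates: a_x is the row mean of the log rates, and (b_x, k_t) is the leading
#' singular pair of the row-centered log-rate matrix, normalized so that the
#' age loadings sum to 1 and the period index sums to 0. The drift of the
#' period index, (k_T - k_1) / (T - 1), parameterizes the random-walk-with-
#' drift forecast used by [forecast_rates()]. Zero rates are floored at half
#' a death over the group's exposure before taking logs (or at half the
#' smallest positive rate when no exposures are supplied); every flooring is
#' recorded. No second-stage re-estimation of k against total deaths is
#' performed.
#'
#' @param rates An ages-by-years numeric matrix of annual death rates
#'   (rownames = age labels, colnames = years), or an annual tibble
#'   (`year`, `sex`, `age_start`, `age_interval`, `deaths`, `exposure`) from
#'   which rates = deaths / exposure are taken for one sex.
#' @param sex When `rates` is an annual tibble: which sex to fit
#'   (`"m"`, `"f"` or `"b"`).
#' @param start_year First year of the fitting window (default 2005, chosen
#'   to focus on recent mortality change); years before it are dropped.
#' @param exposure Optional ages-by-years exposure matrix used for the
#'   zero-rate floor when `rates` is a matrix.
#' @return An object of class `lc_fit`: list with `ages`, `years`, `a`, `b`,
#'   `k`, `drift`, `sigma` (innovation SD of the k increments), `floored`
#'   (tibble of floored cells). Has [tidy()], [glance()] and
#'   [autoplot()][ggplot2::autoplot()] methods.
#' @export
fit_lee_carter <- function(rates, sex = "b", start_year = 2005, exposure = NULL) {
  if (is.data.frame(rates)) {
    ann <- dplyr::filter(rates, .data$sex == !!sex)
    if (nrow(ann) == 0 && sex == "b") {
      ann <- rates |>
        dplyr::group_by(.data$year, .data$age_start, .data$age_interval) |>
        dplyr::summarise(deaths = sum(.data$deaths), exposure = sum(.data$exposure),
                         .groups = "drop")
    }
    if (nrow(ann) == 0) rlang::abort(sprintf("no annual rows for sex %s", sex))
    ann <- dplyr::arrange(ann, .data$age_start, .data$year)
    ages <- sort(unique(ann$age_start))
    ag <- dplyr::distinct(ann, .data$age_start, .data$age_interval) |>
      dplyr::arrange(.data$age_start)
    years <- sort(unique(ann$year))
    m <- matrix(NA_real_, length(ages), length(years),
                dimnames = list(age_label(ag$age_start, ag$age_interval), years))
    e <- m
    m[cbind(match(ann$age_start, ages), match(ann$year, years))] <-
      ann$deaths / ann$exposure
    e[cbind(match(ann$age_start, ages), match(ann$year, years))] <- ann$exposure
    rates <- m
    exposure <- e
  }
  if (!is.null(start_year) && !is.null(colnames(rates))) {
    keep <- as.integer(colnames(rates)) >= start_year
    rates <- rates[, keep, drop = FALSE]
    if (!is.null(exposure)) exposure <- exposure[, keep, drop = FALSE]
  }
  if (ncol(rates) < 3) rlang::abort("Lee-Carter fit requires at least 3 years")
  if (nrow(rates) < 2) rlang::abort("Lee-Carter fit requires at least 2 age groups")
  if (anyNA(rates)) rlang::abort("rate matrix contains missing cells")

  floor_mat <- if (!is.null(exposure)) 0.5 / exposure else
    matrix(0.5 * min(rates[rates > 0]), nrow(rates), ncol(rates))
  floored_idx <- which(rates <= 0, arr.ind = TRUE)
  if (any(rowSums(rates > 0) == 0)) {
    rlang::abort("an age row has no positive rates; cannot fit in the log domain")
  }
  rates <- pmax(rates, floor_mat)

  lm_ <- log(rates)
  a <- rowMeans(lm_)
  z <- lm_ - a
  sv <- svd(z, nu = 1, nv = 1)
  b <- sv$u[, 1]
  k <- sv$d[1] * sv$v[, 1]
  # normalization: sum(b) = 1, sum(k) = 0; fix the sign so that sum(b) > 0
  if (sum(b) < 0) { b <- -b; k <- -k }
  k <- k * sum(b)
  b <- b / sum(b)
  a <- a + b * mean(k)
  k <- k - mean(k)
  T_ <- length(k)
  drift <- (k[T_] - k[1]) / (T_ - 1)
  sigma <- if (T_ > 2) stats::sd(diff(k)) else 0
  yrs <- if (!is.null(colnames(lm_))) as.integer(colnames(lm_)) else seq_len(T_)
  structure(list(
    ages = if (!is.null(rownames(lm_))) rownames(lm_) else as.character(seq_len(nrow(lm_))),
    years = yrs, a = unname(a), b = unname(b), k = unname(k),
    drift = drift, sigma = sigma,
    floored = tibble::tibble(
      age = rownames(lm_)[floored_idx[, 1]],
      year = yrs[floored_idx[, 2]])
  ), class = "lc_fit")
}

#' @export
print.lc_fit <- function(x, ...) {
  cat(sprintf("Lee-Carter fit: %d age groups x %d years (%d-%d)\n",
              length(x$ages), length(x$years), min(x$years), max(x$years)))
  cat(sprintf("  drift of k: %.4f   innovation SD: %.4f\n", x$drift, x$sigma))
  if (nrow(x$floored) > 0) cat(sprintf("  %d zero rate(s) floored\n", nrow(x$floored)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Lee-Carter fit
#'
#' @param x An `lc_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per (term, index): terms `a` and `b` indexed
#'   by age, term `k` indexed by year.
#' @method tidy lc_fit
#' @export
tidy.lc_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = "a", index = x$ages, estimate = x$a),
    tibble::tibble(term = "b", index = x$ages, estimate = x$b),
    tibble::tibble(term = "k", index = as.character(x$years), estimate = x$k))
}

#' One-row summary of a Lee-Carter fit
#'
#' @param x An `lc_fit` object.
#' @param ... Unused.
#' @return A tibble with `n_ages`, `n_years`, `drift`, `sigma`, `n_floored`.
#' @method glance lc_fit
#' @export
glance.lc_fit <- function(x, ...) {
  tibble::tibble(n_ages = length(x$ages), n_years = length(x$years),
                 drift = x$drift, sigma = x$sigma, n_floored = nrow(x$floored))
}

#' Forecast death rates from a Lee-Carter fit
#'
#' Projects the period index by a random walk with drift (central path:
#' k at horizon h equals the last fitted k plus h times the drift) and
#' reconstructs rates as exp(a_x + b_x * k). Prediction intervals are not
#' produced; `sigma` from the fit quantifies the innovation scale for users
#' who need them.
#'
#' @param fit An `lc_fit` object.
#' @param horizon Number of years ahead (0 gives an empty result).
#' @return Tibble with columns `year`, `age` (label from the fit), `rate`.
#' @export
forecast_rates <- function(fit, horizon) {
  stopifnot(inherits(fit, "lc_fit"), horizon >= 0)
  if (horizon == 0) {
    return(tibble::tibble(year = integer(), age = character(), rate = double()))
  }
  last_year <- max(fit$years)
  kT <- fit$k[length(fit$k)]
  purrr::map_dfr(seq_len(horizon), function(h) {
    k <- kT + h * fit$drift
    tibble::tibble(year = last_year + h, age = fit$ages,
                   rate = exp(fit$a + fit$b * k))
  })
}

#' Project population exposures under zero migration
#'
#' Cohort bookkeeping from the last observed age-group exposures: within each
#' group the one-year slice at its upper edge (group exposure divided by the
#' group width, under a uniform within-group age distribution) survives with
#' probability exp(-m) and moves into the next group; the remainder survives
#' in place; the open-ended terminal group accumulates and has no outflow;
#' entry into the youngest group is held constant at its last observed
#' level. Projected death counts are rates times projected exposures, and
#' the projected person-years of a year are taken as the projected
#' population itself.
#'
#' @param exposures Tibble with one row per age group: `age_start`,
#'   `age_interval` (last may be `Inf`), `exposure` — the last observed year.
#' @param rates Forecast rates as from [forecast_rates()]: `year`, `age`,
#'   `rate`, with `age` matching `age_label()` of the groups.
#' @param entry Annual inflow into the youngest group; default the youngest
#'   group's exposure divided by its width (0 if the width is infinite).
#' @return Tibble per (forecast year, age group): `year`, `age_start`,
#'   `age_interval`, `exposure`, `deaths`, `source = "forecast"`.
#' @export
project_population <- function(exposures, rates, entry = NULL) {
  g <- dplyr::arrange(exposures, .data$age_start)
  if (!is.infinite(g$age_interval[nrow(g)])) {
    rlang::abort("the terminal age group must be open-ended (age_interval = Inf)")
  }
  labs <- age_label(g$age_start, g$age_interval)
  if (is.null(entry)) {
    entry <- if (is.finite(g$age_interval[1])) g$exposure[1] / g$age_interval[1] else 0
  }
  years <- sort(unique(rates$year))
  E <- g$exposure
  w <- g$age_interval
  out <- purrr::map_dfr(years, function(y) {
    ry <- rates[rates$year == y, ]
    m <- ry$rate[match(labs, ry$age)]
    if (anyNA(m)) rlang::abort(sprintf("forecast rates missing for year %d", y))
    deaths <- m * E
    s <- exp(-m)
    slice <- ifelse(is.finite(w), E / w, 0)
    outflow <- slice * s
    E_next <- (E - slice) * s
    E_next <- E_next + c(entry, outflow[-length(outflow)])
    res <- tibble::tibble(year = y, age_start = g$age_start,
                          age_interval = g$age_interval,
                          exposure = E, deaths = deaths, source = "forecast")
    E <<- E_next
    res
  })
  out
}

#' Extend an annual table with Lee-Carter forecast years
#'
#' For each sex, fits a Lee-Carter model to the observed annual rates
#' (window starting at `start_year`), forecasts rates `horizon` years ahead,
#' projects exposures under zero migration, and appends the forecast rows
#' (flagged `source = "forecast"`) to the annual table.
#'
#' @param annual Observed annual tibble (`year`, `sex` in m/f, `age_start`,
#'   `age_interval`, `deaths`, `exposure`).
#' @param horizon Years to forecast (typically 1-4).
#' @param start_year Lee-Carter fitting window start, default 2005.
#' @return The annual table with forecast years appended, `source` column
#'   set.
#' @export
forecast_annual <- function(annual, horizon, start_year = 2005) {
  if (horizon == 0) return(annual)
  sexes <- intersect(c("m", "f"), unique(annual$sex))
  fc <- purrr::map_dfr(sexes, function(s) {
    fit <- fit_lee_carter(annual, sex = s, start_year = start_year)
    rts <- forecast_rates(fit, horizon)
    last <- dplyr::filter(annual, .data$sex == s, .data$year == max(.data$year))
    project_population(dplyr::select(last, "age_start", "age_interval", "exposure"),
                       rts) |>
      dplyr::mutate(sex = s)
  })
  ann <- annual
  if (!"source" %in% names(ann)) ann$source <- "observed"
  dplyr::bind_rows(ann, fc[, c("year", "sex", "age_start", "age_interval",
                               "deaths", "exposure", "source")])
}

#' Sensitivity of forecast rates to the fitting window
#'
#' Refits the Lee-Carter model with each candidate start year, forecasts the
#' same horizon, and reports the maximum relative change in the final
#' forecast year's rates (hence in the implied weekly rates, which share the
#' same exposures) against the reference start year. A reporting aid, not an
#' assertion: the magnitude depends on the data.
#'
#' @param annual Annual tibble, one sex (or use `sex`).
#' @param start_years Candidate fitting-window start years (>= 2).
#' @param horizon Forecast horizon in years.
#' @param sex Sex to fit, default `"b"`.
#' @param reference Start year compared against; default the first element.
#' @return Tibble with `start_year` and `max_rel_change` (vs reference).
#' @export
lc_sensitivity <- function(annual, start_years, horizon = 3, sex = "b",
                           reference = start_years[1]) {
  if (length(start_years) < 2) {
    return(tibble::tibble(start_year = integer(), max_rel_change = double()))
  }
  final_rates <- function(sy) {
    fit <- fit_lee_carter(annual, sex = sex, start_year = sy)
    r <- forecast_rates(fit, horizon)
    dplyr::filter(r, .data$year == max(.data$year)) |> dplyr::arrange(.data$age)
  }
  ref <- final_rates(reference)
  purrr::map_dfr(start_years, function(sy) {
    r <- final_rates(sy)
    tibble::tibble(start_year = sy,
                   max_rel_change = max(abs(r$rate - ref$rate) / ref$rate))
  })
}
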