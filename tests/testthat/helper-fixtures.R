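# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except where the test is about file I/O.

# a tiny raw weekly tibble in the canonical long layout
make_raw <- function(year = 2020, week = 10, sex = "m",
                     age_start = c(0, 15, 65, 75, 85),
                     age_interval = c(15, 50, 10, 10, Inf),
                     deaths = c(2, 50, 60, 110, 160), pop = "SYN") {
  tibble::tibble(pop_name = pop, area = "", year = as.integer(year),
                 week = as.integer(week), sex = sex,
                 age_start = age_start, age_interval = age_interval,
                 deaths = deaths, data_type = "O", access = "1")
}

# annual table on the standard groups for both sexes, deaths roughly
# proportional to a plausible age pattern
make_annual <- function(years = 2020, m_deaths = c(100, 2600, 11000, 17500, 18000),
                        f_deaths = c(80, 1300, 6800, 15200, 28800),
                        m_exp = c(7.5e5, 3.3e6, 5.5e5, 3.5e5, 1.2e5),
                        f_exp = c(7.1e5, 3.25e6, 6.2e5, 4.6e5, 2.4e5)) {
  g <- weeklymort::stmf_age_groups()
  purrr::map_dfr(years, function(y) {
    dplyr::bind_rows(
      tibble::tibble(year = y, sex = "m", age_start = g$age_start,
                     age_interval = g$age_interval, deaths = m_deaths,
                     exposure = m_exp),
      tibble::tibble(year = y, sex = "f", age_start = g$age_start,
                     age_interval = g$age_interval, deaths = f_deaths,
                     exposure = f_exp))
  }) |>
    dplyr::mutate(source = "observed")
}

# small-country simulation used by the shock-recovery experiments: the
# default population scaled down so a 500-death shock is well inside the
# estimator's resolving power
shock_config <- function(seed, total = 500, weeks = 12:18, scale = 0.05) {
  weeklymort::sim_config(
    years = 2015:2020,
    exposure_m = c(7.5e5, 3.30e6, 5.5e5, 3.5e5, 1.2e5) * scale,
    exposure_f = c(7.1e5, 3.25e6, 6.2e5, 4.6e5, 2.4e5) * scale,
    trend = 0, seasonal_amplitude = 0.15, noise = TRUE,
    shock = list(year = 2020, weeks = weeks, mode = "add", total = total),
    seed = seed)
}

# both-sex all-age weekly rate history from a simulated dataset
sim_history <- function(sim) {
  st <- weeklymort::build_stmf(
    weeklymort::harmonize(sim$raw, sim$annual), sim$annual)
  dplyr::filter(st, Sex == "b") |>
    dplyr::select(year = Year, week = Week, rate = RTotal)
}

total_exposure <- function(config) {
  sum(config$exposure$m + config$exposure$f)
}
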