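# builds a noise-free rate matrix from constrained (a, b, k) ground truth
make_lc_truth <- function(n_age = 5, n_year = 10, seed = 1, drift = -0.6) {
  set.seed(seed)
  b <- runif(n_age)
  b <- b / sum(b)
  k <- cumsum(rnorm(n_year, drift, 0.4))
  k <- k - mean(k)
  a <- log(sort(runif(n_age, 1e-4, 0.2)))
  m <- exp(outer(a, rep(1, n_year)) + outer(b, k))
  dimnames(m) <- list(seq_len(n_age), 2004 + seq_len(n_year))
  list(a = a, b = b, k = k, m = m)
}

test_that("fit recovers constrained parameters from noise-free rates", {
  for (seed in 1:5) {
    tr <- make_lc_truth(seed = seed)
    f <- fit_lee_carter(tr$m, start_year = NULL)
    expect_lt(max(abs(f$a - tr$a)), 1e-8)
    expect_lt(max(abs(f$b - tr$b)), 1e-8)
    expect_lt(max(abs(f$k - tr$k)), 1e-8)
    expect_lt(abs(sum(f$b) - 1), 1e-10)
    expect_lt(abs(sum(f$k)), 1e-10)
  }
})

test_that("degenerate shapes behave as the model implies", {
  # constant rates across years: k identically 0, drift 0
  m <- matrix(rep(c(0.01, 0.05, 0.2), 4), nrow = 3,
              dimnames = list(1:3, 2011:2014))
  f <- fit_lee_carter(m, start_year = NULL)
  expect_equal(f$k, rep(0, 4), tolerance = 1e-12)
  expect_equal(f$drift, 0, tolerance = 1e-12)

  # exactly linear k: drift equals the slope; forecast continues the line
  tr <- make_lc_truth()
  k_lin <- seq(-3, 3, length.out = 10)
  k_lin <- k_lin - mean(k_lin)
  m2 <- exp(outer(tr$a, rep(1, 10)) + outer(tr$b, k_lin))
  dimnames(m2) <- dimnames(tr$m)
  f2 <- fit_lee_carter(m2, start_year = NULL)
  slope <- k_lin[2] - k_lin[1]
  expect_equal(f2$drift, slope, tolerance = 1e-8)
  fc <- forecast_rates(f2, 2)
  want_k <- k_lin[10] + slope * 1:2
  want <- exp(outer(f2$a, rep(1, 2)) + outer(f2$b, want_k))
  got <- matrix(fc$rate, nrow = 5)
  expect_equal(got, want, tolerance = 1e-8)

  # zero loading: forecast rate for that age is constant exp(a)
  f3 <- f2
  f3$b[2] <- 0
  fc3 <- forecast_rates(f3, 3)
  expect_equal(unique(fc3$rate[fc3$age == f3$ages[2]]), exp(f3$a[2]),
               tolerance = 1e-12)

  # guard rails
  expect_error(fit_lee_carter(tr$m[, 1:2, drop = FALSE], start_year = NULL),
               "at least 3 years")
  expect_equal(nrow(forecast_rates(f2, 0)), 0)
})

test_that("refitting on rates regenerated from a fit reproduces the fit (fixed point)", {
  tr <- make_lc_truth(seed = 9)
  f <- fit_lee_carter(tr$m, start_year = NULL)
  m2 <- exp(outer(f$a, rep(1, length(f$k))) + outer(f$b, f$k))
  dimnames(m2) <- dimnames(tr$m)
  f2 <- fit_lee_carter(m2, start_year = NULL)
  expect_equal(f2$a, f$a, tolerance = 1e-9)
  expect_equal(f2$b, f$b, tolerance = 1e-9)
  expect_equal(f2$k, f$k, tolerance = 1e-9)
})

test_that("zero rates are floored at half a death over exposure and logged", {
  tr <- make_lc_truth(n_age = 3, n_year = 5, seed = 3)
  m <- tr$m[, 1:5]
  m[1, 2] <- 0
  e <- matrix(1e5, 3, 5, dimnames = dimnames(m))
  f <- fit_lee_carter(m, start_year = NULL, exposure = e)
  expect_equal(nrow(f$floored), 1)
  expect_equal(f$floored$age, "1")
  # the floored cell entered the fit as 0.5 / exposure
  expect_error(fit_lee_carter(rbind(m * 0, m[2:3, ]), start_year = NULL),
               "no positive rates")
})

test_that("forecast recovers simulated rates within 5% median error under Poisson noise", {
  errs <- purrr::map_dbl(1:100, function(seed) {
    tr <- make_lc_truth(n_age = 5, n_year = 15, seed = seed, drift = -0.4)
    set.seed(seed + 1e4)
    expo <- 1e5
    d <- matrix(stats::rpois(length(tr$m), tr$m * expo), nrow(tr$m))
    m_obs <- d / expo
    dimnames(m_obs) <- dimnames(tr$m)
    f <- fit_lee_carter(m_obs[, 1:12], start_year = NULL,
                        exposure = matrix(expo, 5, 12))
    fc <- forecast_rates(f, 3)
    truth <- as.vector(tr$m[, 13:15])
    stats::median(abs(fc$rate - truth) / truth)
  })
  expect_lt(stats::median(errs), 0.05)
})

test_that("population projection does zero-migration cohort bookkeeping", {
  g <- stmf_age_groups()
  expo <- tibble::tibble(age_start = g$age_start, age_interval = g$age_interval,
                         exposure = c(1000, 5000, 800, 500, 200))
  # zero mortality: cohorts shift, total conserved plus the constant entry
  rates0 <- tibble::tibble(year = 2021, age = g$age_label, rate = 1e-15)
  p0 <- project_population(expo, rates0)
  expect_equal(sum(p0$deaths), 0, tolerance = 1e-9)
  p0b <- project_population(expo, dplyr::mutate(rates0, year = 2022))
  # after one zero-mortality year the 15-64 group gained 0-14's outflow and
  # lost its own top slice (checked via a 2-year run's second-year exposure)
  two <- project_population(expo, dplyr::bind_rows(rates0,
                                                   dplyr::mutate(rates0, year = 2022)))
  y2 <- dplyr::filter(two, year == 2022)
  entry <- expo$exposure[1] / g$age_interval[1]
  expect_equal(y2$exposure[1], expo$exposure[1] - expo$exposure[1] / 15 + entry,
               tolerance = 1e-9)
  expect_equal(y2$exposure[2],
               expo$exposure[2] - expo$exposure[2] / 50 + expo$exposure[1] / 15,
               tolerance = 1e-9)
  expect_equal(sum(y2$exposure), sum(expo$exposure) + entry, tolerance = 1e-9)

  # one open group, m = 0.1: deaths = 100, survivors e^-0.1 * 1000
  one <- tibble::tibble(age_start = 0, age_interval = Inf, exposure = 1000)
  r1 <- tibble::tibble(year = 2021:2022, age = "0+", rate = 0.1)
  p1 <- project_population(one, r1)
  expect_equal(p1$deaths[1], 100)
  expect_equal(p1$exposure[2], exp(-0.1) * 1000)

  # enormous mortality: essentially no survivors leave the group
  r_inf <- tibble::tibble(year = 2021:2022, age = "0+", rate = 50)
  p_inf <- project_population(one, r_inf)
  expect_lt(p_inf$exposure[2], 1e-12)

  expect_error(project_population(dplyr::mutate(expo, age_interval =
                                                  ifelse(is.infinite(age_interval), 15, age_interval)),
                                  rates0), "open-ended")
})

test_that("forecast-extended annual tables flag forecast years and propagate the flag", {
  sim <- simulate_mortality(sim_config(years = 2006:2020, noise = FALSE,
                                       trend = -0.015, seed = 4))
  ann_obs <- dplyr::filter(sim$annual, year <= 2018)
  ann_ext <- forecast_annual(ann_obs, horizon = 2)
  expect_setequal(unique(ann_ext$year[ann_ext$source == "forecast"]), 2019:2020)
  expect_true(all(ann_ext$exposure > 0))
  # projected deaths equal rate x exposure cell-wise by construction
  fitm <- fit_lee_carter(ann_obs, sex = "m", start_year = 2005)
  fcm <- forecast_rates(fitm, 2)
  fc_rows <- dplyr::filter(ann_ext, source == "forecast", sex == "m") |>
    dplyr::mutate(age = age_label(age_start, age_interval)) |>
    dplyr::left_join(fcm, by = c("year", "age"))
  expect_equal(fc_rows$deaths, fc_rows$rate * fc_rows$exposure, tolerance = 1e-12)
  # flag propagates to the output table
  st <- build_stmf(harmonize(sim$raw, ann_ext), ann_ext)
  expect_equal(sort(unique(st$Year[st$Forecast == 1])), 2019:2020)
  expect_equal(unique(st$Forecast[st$Year <= 2018]), 0L)
})

test_that("fit-window sensitivity is zero for identical fits and small for stable mortality", {
  sim <- simulate_mortality(sim_config(years = 2000:2018, noise = FALSE,
                                       trend = -0.01, seed = 8))
  sens <- lc_sensitivity(sim$annual, start_years = c(2005, 2005), horizon = 3,
                         sex = "m")
  expect_equal(sens$max_rel_change, c(0, 0), tolerance = 1e-12)
  # noise-free log-linear mortality: the forecast is window-invariant
  sens2 <- lc_sensitivity(sim$annual, start_years = 2000:2010, horizon = 3,
                          sex = "m")
  expect_true(all(sens2$max_rel_change < 0.005))
  # degenerate input: single candidate window
  expect_equal(nrow(lc_sensitivity(sim$annual, start_years = 2005)), 0)
})
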