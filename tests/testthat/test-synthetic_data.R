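test_that("the noise-free, season-free, shock-free limit is exactly annual/52 per week", {
  cfg <- sim_config(years = 2019:2020, seasonal_amplitude = 0, trend = 0,
                    noise = FALSE, shock = NULL, seed = 1)
  sim <- simulate_mortality(cfg)
  per_week <- sim$truth |>
    dplyr::group_by(year, sex, age_start) |>
    dplyr::summarise(ok = all(abs(deaths - deaths[1]) < 1e-12),
                     annual = sum(deaths), wk = deaths[1], .groups = "drop")
  expect_true(all(per_week$ok))
  expect_equal(per_week$wk, per_week$annual / 52, tolerance = 1e-12)
})

test_that("the generator is bit-reproducible under a fixed seed", {
  cfg <- sim_config(years = 2019:2020, seed = 77)
  a <- simulate_mortality(cfg)
  b <- simulate_mortality(cfg)
  expect_identical(a$raw, b$raw)
  expect_identical(a$annual, b$annual)
  c_ <- simulate_mortality(sim_config(years = 2019:2020, seed = 78))
  expect_false(identical(a$raw$deaths, c_$raw$deaths))
})

test_that("annual tables and official totals are the sums of the fine weekly truth", {
  sim <- simulate_mortality(sim_config(years = 2018:2020, seed = 31))
  resum <- sim$truth |>
    dplyr::group_by(year, sex, age_start) |>
    dplyr::summarise(deaths = sum(deaths), .groups = "drop")
  expect_equal(dplyr::arrange(resum, year, sex, age_start)$deaths,
               dplyr::arrange(sim$annual, year, sex, age_start)$deaths,
               tolerance = 1e-12)
  off_b <- dplyr::filter(sim$official, sex == "b")
  expect_equal(off_b$deaths,
               tapply(sim$truth$deaths, sim$truth$year, sum) |> as.numeric(),
               tolerance = 1e-12)
})

test_that("injected additive shocks are book-kept exactly", {
  cfg <- sim_config(years = 2015:2020, noise = FALSE, trend = 0,
                    shock = list(year = 2020, weeks = 12:18, mode = "add",
                                 total = 500), seed = 5)
  sim <- simulate_mortality(cfg)
  expect_equal(attr(sim$truth, "shock_total"), 500, tolerance = 1e-9)
  expect_equal(sum(sim$truth$lambda - sim$truth$lambda_base), 500,
               tolerance = 1e-9)
  # the shock only touches the configured weeks and year
  touched <- sim$truth |>
    dplyr::filter(lambda != lambda_base) |>
    dplyr::distinct(year, week)
  expect_true(all(touched$year == 2020))
  expect_setequal(touched$week, 12:18)
  # multiplicative mode raises old-age expectations only
  cfg2 <- sim_config(years = 2020, noise = FALSE,
                     shock = list(year = 2020, weeks = 20, mode = "mult",
                                  factor = 2), seed = 5)
  sim2 <- simulate_mortality(cfg2)
  wk20 <- dplyr::filter(sim2$truth, week == 20)
  expect_true(all(wk20$lambda[wk20$age_start == 85] ==
                    2 * wk20$lambda_base[wk20$age_start == 85]))
  expect_true(all(wk20$lambda[wk20$age_start < 65] ==
                    wk20$lambda_base[wk20$age_start < 65]))
})

test_that("coarsening sums exactly, merges sexes, and extracts unknown ages conservatively", {
  sim <- simulate_mortality(sim_config(years = 2020, noise = FALSE, seed = 9))
  broad <- age_group_table(c(0, 65), c(65, Inf))
  co <- coarsen(sim$raw, groups = broad)
  old <- dplyr::filter(co, age_start == 65) |>
    dplyr::group_by(year, week, sex) |>
    dplyr::summarise(d = sum(deaths), .groups = "drop")
  old_fine <- dplyr::filter(sim$raw, age_start >= 65) |>
    dplyr::group_by(year, week, sex) |>
    dplyr::summarise(d = sum(deaths), .groups = "drop")
  expect_equal(old$d, old_fine$d, tolerance = 1e-12)

  cob <- coarsen(sim$raw, combine_sex = TRUE)
  expect_equal(unique(cob$sex), "b")
  expect_equal(sum(cob$deaths), sum(sim$raw$deaths), tolerance = 1e-9)

  cou <- coarsen(sim$raw, unknown_fraction = 0.02)
  expect_equal(sum(cou$deaths), sum(sim$raw$deaths), tolerance = 1e-9)
  unk_share <- sum(cou$deaths[is.na(cou$age_start)]) / sum(cou$deaths)
  expect_equal(unk_share, 0.02, tolerance = 1e-12)
  expect_false(anyNA(coarsen(sim$raw, unknown_fraction = 0)$age_start))

  bad <- age_group_table(c(0, 70), c(70, Inf))
  expect_error(coarsen(sim$raw, groups = bad), "does not nest")
})

test_that("coarsen-then-harmonize reproduces the fine counts in the week-stationary case", {
  sim <- simulate_mortality(sim_config(years = 2019:2020, noise = FALSE,
                                       seasonal_amplitude = 0.15, seed = 12))
  broad <- age_group_table(c(0, 15, 65), c(15, 50, Inf))
  co <- coarsen(sim$raw, groups = broad, combine_sex = TRUE,
                unknown_fraction = 0.01)
  h <- harmonize(co, sim$annual)
  fine <- sim$truth |>
    dplyr::group_by(year, week, sex, age_start) |>
    dplyr::summarise(d = sum(deaths), .groups = "drop")
  cmp <- dplyr::inner_join(h, fine, by = c("year", "week", "sex", "age_start"))
  expect_equal(nrow(cmp), nrow(fine))
  expect_lt(max(abs(cmp$deaths - cmp$d) / pmax(cmp$d, 1e-12)), 1e-9)
})

test_that("every generated dataset passes the internal checks by construction", {
  for (seed in c(1, 2)) {
    sim <- simulate_mortality(sim_config(years = 2019:2020, seed = seed))
    st <- build_stmf(harmonize(sim$raw, sim$annual), sim$annual)
    rep <- check_internal(st, raw = sim$raw)
    expect_true(all(rep$status %in% c("pass", "skipped")))
    expect_true(all(check_external(st, sim$official)$status == "pass"))
  }
})

test_that("invalid simulation configs are rejected", {
  expect_error(sim_config(rates_m = c(-1, 1, 1, 1, 1)), "rates_m")
  expect_error(sim_config(seasonal_amplitude = 1.2), "seasonal_amplitude")
  expect_error(sim_config(shock = list(year = 1999, weeks = 1, total = 10)),
               "year")
  expect_error(coarsen(make_raw(), unknown_fraction = 1), "unknown_fraction")
})
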