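test_that("unknown-age deaths are allocated proportionally to the stratum's known counts", {
  w <- make_raw(age_start = c(0, 65, NA), age_interval = c(65, Inf, NA),
                deaths = c(90, 10, 10))
  out <- redistribute_unknown_age(w)
  expect_equal(out$deaths, c(99, 11))
  expect_equal(sum(out$deaths), sum(w$deaths))

  # no unknown rows: identity
  w2 <- make_raw()
  expect_identical(redistribute_unknown_age(w2), w2)
})

test_that("unknown-age fallback uses the annual distribution, then errors", {
  w <- make_raw(age_start = c(0, 65, NA), age_interval = c(65, Inf, NA),
                deaths = c(0, 0, 8))
  ann <- make_annual(m_deaths = c(10, 40, 10, 20, 20),
                     f_deaths = c(10, 40, 10, 20, 20))
  # annual: 0-64 has 50 deaths, 65+ has 50 -> even split of the 8
  out <- redistribute_unknown_age(w, ann)
  expect_equal(out$deaths, c(4, 4))
  expect_equal(nrow(attr(out, "redistribute_log")), 1)

  expect_error(redistribute_unknown_age(w), "no annual table")
  ann0 <- dplyr::mutate(ann, deaths = 0)
  expect_error(redistribute_unknown_age(w, ann0), "annual distribution empty")
})

test_that("broad age intervals split proportionally to annual deaths and conserve the source count", {
  w <- make_raw(age_start = 65, age_interval = Inf, deaths = 100)
  ann <- make_annual(m_deaths = c(10, 50, 300, 500, 200),
                     f_deaths = c(0, 0, 0, 0, 0))
  out <- split_age_groups(w, ann)
  old <- dplyr::filter(out, age_start >= 65)
  expect_equal(old$deaths, c(30, 50, 20))
  expect_equal(unique(out$split), 1L)
})

test_that("already-standard data pass through the age split unchanged with flag 0", {
  w <- make_raw()
  ann <- make_annual()
  out <- split_age_groups(w, ann)
  expect_equal(out$deaths, w$deaths)
  expect_equal(out$age_start, w$age_start)
  expect_equal(unique(out$split), 0L)
})

test_that("age-split error cases: straddling targets, zero annual denominator", {
  ann <- make_annual()
  # source 0-9 straddles the 0-14 target boundary
  w_bad <- make_raw(age_start = c(0, 10), age_interval = c(10, Inf),
                    deaths = c(5, 5))
  expect_error(split_age_groups(w_bad, ann), "not tiled")
  # zero annual deaths with positive weekly deaths
  w <- make_raw(age_start = 65, age_interval = Inf, deaths = 10)
  ann0 <- dplyr::mutate(ann, deaths = ifelse(age_start >= 65, 0, deaths))
  expect_error(split_age_groups(w, ann0), "annual deaths are zero")
  # but zero weekly deaths give zeros, not an error
  w0 <- make_raw(age_start = 65, age_interval = Inf, deaths = 0)
  out <- split_age_groups(w0, ann0)
  expect_equal(dplyr::filter(out, age_start >= 65)$deaths, c(0, 0, 0))
})

test_that("sex splitting applies the annual sex ratio and conserves cell totals", {
  w <- make_raw(sex = "b", age_start = 75, age_interval = 10, deaths = 100)
  ann <- make_annual(m_deaths = c(10, 50, 300, 4000, 200),
                     f_deaths = c(10, 50, 300, 6000, 200))
  out <- split_sex(w, ann)
  expect_equal(dplyr::filter(out, sex == "m")$deaths, 40)
  expect_equal(dplyr::filter(out, sex == "f")$deaths, 60)
  expect_equal(unique(out$split_sex), 1L)
  # zero weekly deaths -> (0, 0)
  w0 <- make_raw(sex = "b", age_start = 75, age_interval = 10, deaths = 0)
  out0 <- split_sex(w0, ann)
  expect_equal(out0$deaths, c(0, 0))
  # sex-specific input passes through with flag 0
  wm <- make_raw(sex = "m", age_start = 75, age_interval = 10, deaths = 50)
  outm <- split_sex(wm, ann)
  expect_equal(outm$deaths, 50)
  expect_equal(unique(outm$split_sex), 0L)
  # annual total zero with weekly deaths -> error
  ann0 <- dplyr::mutate(ann, deaths = 0)
  expect_error(split_sex(w, ann0), "zero or missing")
})

test_that("every harmonization step conserves stratum totals on random fixtures", {
  set.seed(123)
  sources <- list(
    list(s = c(0, 65), i = c(65, Inf)),
    list(s = c(0, 15, 65), i = c(15, 50, Inf)),
    list(s = c(0, 15, 65, 75, 85), i = c(15, 50, 10, 10, Inf)),
    list(s = 0, i = Inf))
  for (rep in 1:60) {
    src <- sources[[sample(4, 1)]]
    sex <- sample(c("m", "f", "b"), 1)
    deaths <- round(runif(length(src$s), 0, 300), 3)
    w <- make_raw(sex = sex, age_start = src$s, age_interval = src$i,
                  deaths = deaths)
    ann <- make_annual(m_deaths = runif(5, 1, 1000), f_deaths = runif(5, 1, 1000))
    out <- split_age_groups(w, ann)
    expect_equal(sum(out$deaths), sum(w$deaths), tolerance = 1e-12)
    out2 <- split_sex(out, ann)
    expect_equal(sum(out2$deaths), sum(w$deaths), tolerance = 1e-12)
    # male+female reproduces the pre-split cell exactly
    if (sex == "b") {
      cell <- out2 |>
        dplyr::group_by(age_start) |>
        dplyr::summarise(d = sum(deaths), .groups = "drop")
      expect_equal(cell$d, out$deaths, tolerance = 1e-12)
    }
  }
})

test_that("redistribute-then-split equals split-then-redistribute off the fallback path", {
  set.seed(7)
  for (rep in 1:20) {
    known <- round(runif(2, 1, 200), 3)
    unk <- round(runif(1, 0, 20), 3)
    w <- make_raw(age_start = c(0, 65, NA), age_interval = c(65, Inf, NA),
                  deaths = c(known, unk))
    ann <- make_annual(m_deaths = runif(5, 1, 500), f_deaths = runif(5, 1, 500))
    a <- w |> redistribute_unknown_age(ann) |> split_age_groups(ann)
    # split first (unknown rows carried around the split), then redistribute
    b <- w |>
      dplyr::filter(!is.na(age_start)) |>
      split_age_groups(ann) |>
      dplyr::select(-split) |>
      dplyr::bind_rows(dplyr::filter(w, is.na(age_start))) |>
      redistribute_unknown_age(ann)
    expect_equal(a$deaths, b[order(b$age_start), ]$deaths, tolerance = 1e-9)
  }
})

test_that("harmonize sets the flag triple according to what was adjusted", {
  sim <- simulate_mortality(sim_config(years = 2019:2020, noise = FALSE, seed = 2))
  # fully detailed input: no flags
  h0 <- harmonize(sim$raw, sim$annual)
  expect_equal(unique(h0$split), 0L)
  expect_equal(unique(h0$split_sex), 0L)
  st0 <- build_stmf(h0, sim$annual)
  expect_equal(unique(st0$Split), 0L)
  expect_equal(unique(st0$SplitSex), 0L)
  expect_equal(unique(st0$Forecast), 0L)
  # coarsened to broad ages and combined sexes: split flags on
  broad <- age_group_table(c(0, 65), c(65, Inf))
  co <- coarsen(sim$raw, groups = broad, combine_sex = TRUE)
  st1 <- build_stmf(harmonize(co, sim$annual), sim$annual)
  expect_equal(unique(st1$Split), 1L)
  expect_equal(unique(st1$SplitSex), 1L)
  expect_equal(unique(st1$Forecast), 0L)
})
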