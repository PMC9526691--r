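two_year_series <- function(v1, v2, taxon = "Betula") {
  dplyr::bind_rows(make_series(v1, 2018, taxon), make_series(v2, 2019, taxon))
}

test_that("daily climatology averages by calendar day across years", {
  x <- two_year_series(rep(5, 365), rep(5, 365))
  clim <- daily_climatology(x, "Betula")
  expect_equal(nrow(clim), 365)
  expect_true(all(clim$mean_conc == 5))
  expect_true(all(clim$n_years == 2))

  y <- two_year_series(c(10, rep(0, 364)), c(30, rep(0, 364)))
  c2 <- daily_climatology(y, "Betula")
  expect_equal(c2$mean_conc[c2$month == 1 & c2$day == 1], 20)
})

test_that("years missing a day are excluded from that day's mean", {
  a <- make_series(c(10, 10, 10), 2018)     # 1-3 Jan 2018
  b <- make_series(c(40, 40), 2019)         # 1-2 Jan 2019
  clim <- daily_climatology(dplyr::bind_rows(a, b), "Poaceae")
  expect_equal(clim$mean_conc[clim$day == 1], 25)
  expect_equal(clim$mean_conc[clim$day == 3], 10)  # only 2018 contributes
  expect_equal(clim$n_years[clim$day == 3], 1)
})

test_that("climatology requires data and ignores other taxa", {
  x <- make_series(rep(1, 10), taxon = "Alnus")
  expect_error(daily_climatology(x, "Betula"), "no data")
})

test_that("month sections partition days 1-6 ... 25-end", {
  x <- make_series(rep(3, 365))
  clim <- daily_climatology(x, "Poaceae")
  sec <- partition_sections(clim)
  expect_equal(nrow(sec), 60)
  expect_true(all(sec$mean_conc == 3))
  # section 5 lengths: 7 days for 31-day months, 4 for (non-leap) February
  expect_equal(sec$n_days[sec$month == 1 & sec$section == 5], 7L)
  expect_equal(sec$n_days[sec$month == 2 & sec$section == 5], 4L)
  expect_equal(sec$n_days[sec$month == 4 & sec$section == 5], 6L)

  # January with value = day index: section 1 averages days 1-6
  v <- rep(0, 365); v[1:31] <- 1:31
  jan <- daily_climatology(make_series(v), "Poaceae")
  s2 <- partition_sections(jan)
  expect_equal(s2$mean_conc[s2$month == 1 & s2$section == 1], 3.5)
  expect_equal(s2$mean_conc[s2$month == 1 & s2$section == 5], mean(25:31))
})

test_that("section means conserve the climatology annual mean", {
  set.seed(19)
  v <- rgamma(365, 0.6, 0.05)
  clim <- daily_climatology(make_series(v), "Poaceae")
  sec <- partition_sections(clim)
  weighted <- sum(sec$mean_conc * sec$n_days, na.rm = TRUE) / sum(sec$n_days)
  expect_equal(weighted, mean(clim$mean_conc), tolerance = 1e-12)
})

test_that("flowering periods follow the cumulative 0.5/10/90/99.5% rules", {
  v <- c(rep(1, 100), rep(0, 265))
  clim <- daily_climatology(make_series(v), "Poaceae")
  fp <- flowering_periods(clim)
  cls <- as.character(fp$period_class[order(fp$doy)])
  expect_equal(cls[1:9], rep("early", 9))
  expect_equal(cls[10:90], rep("main", 81))
  expect_equal(cls[91:99], rep("late", 9))
  expect_equal(cls[100], "possible")
  expect_true(all(cls[101:365] == "none"))
})

test_that("degenerate climatologies classify sensibly", {
  pt <- rep(0, 365); pt[50] <- 10
  fp <- flowering_periods(daily_climatology(make_series(pt), "Poaceae"))
  expect_equal(sum(fp$period_class == "main"), 1)
  expect_equal(as.character(fp$period_class[fp$doy == 50]), "main")
  expect_true(all(fp$period_class[fp$doy != 50] == "none"))

  z <- flowering_periods(daily_climatology(make_series(c(1, rep(0, 364))),
                                           "Poaceae") |>
                           dplyr::mutate(mean_conc = 0))
  expect_true(all(z$period_class == "none"))
})

test_that("every climatology day receives exactly one class", {
  set.seed(31)
  for (i in 1:10) {
    v <- rgamma(365, 0.5, 0.08) * rbinom(365, 1, 0.6)
    fp <- flowering_periods(daily_climatology(make_series(v), "Poaceae"))
    expect_false(any(is.na(fp$period_class)))
    # main days alone carry at least 80% of the climatological sum
    main_sum <- sum(fp$mean_conc[fp$period_class == "main"])
    expect_gte(main_sum / sum(fp$mean_conc), 0.80)
  }
})

test_that("calendars carry 60 cells per taxon with dominant-class shading", {
  v <- c(rep(1, 100), rep(0, 265))
  clim <- daily_climatology(make_series(v), "Poaceae")
  cal <- build_calendar(list(clim))
  expect_equal(nrow(cal), 60)
  # January sections contain early days 1-9 and main from day 10 on
  expect_equal(as.character(cal$period_class[cal$month == 1 & cal$section == 1]),
               "early")
  expect_equal(as.character(cal$period_class[cal$month == 1 & cal$section == 2]),
               "main")  # days 7-12 include main day 10: main dominates
  expect_equal(as.character(cal$period_class[cal$month == 12 & cal$section == 5]),
               "none")
})

test_that("an all-zero taxon yields 60 cells classed none", {
  clim <- daily_climatology(make_series(rep(1, 365), taxon = "Alnus"),
                            "Alnus") |>
    dplyr::mutate(mean_conc = 0)
  cal <- build_calendar(list(clim))
  expect_equal(nrow(cal), 60)
  expect_true(all(cal$period_class == "none"))
})

test_that("allergenicity is configuration, not data", {
  v <- c(rep(1, 100), rep(0, 265))
  ca <- daily_climatology(make_series(v, taxon = "Betula"), "Betula")
  cb <- daily_climatology(make_series(v, taxon = "Pinus"), "Pinus")
  cal <- build_calendar(list(ca, cb))
  a <- cal[cal$taxon == "Betula", ]
  b <- cal[cal$taxon == "Pinus", ]
  expect_equal(as.character(a$period_class), as.character(b$period_class))
  expect_false(a$allergenicity[1] == b$allergenicity[1])

  expect_error(
    build_calendar(list(daily_climatology(
      make_series(v, taxon = "Nosuchtaxon"), "Nosuchtaxon"))),
    "Nosuchtaxon")
})

test_that("calendar output is invariant to the order years are supplied", {
  set.seed(13)
  y1 <- make_series(rgamma(365, 0.5, 0.05), 2018)
  y2 <- make_series(rgamma(365, 0.5, 0.05), 2019)
  c12 <- build_calendar(list(daily_climatology(dplyr::bind_rows(y1, y2),
                                               "Poaceae")))
  c21 <- build_calendar(list(daily_climatology(dplyr::bind_rows(y2, y1),
                                               "Poaceae")))
  expect_equal(c12, c21)
})

test_that("leap day is averaged only over leap years", {
  leap <- tibble::tibble(site = "t", taxon = "Poaceae",
                         date = seq(as.Date("2020-01-01"),
                                    as.Date("2020-12-31"), by = "day"),
                         conc = 2)
  nonleap <- make_series(rep(4, 365), 2018)
  clim <- daily_climatology(dplyr::bind_rows(leap, nonleap), "Poaceae")
  expect_equal(clim$mean_conc[clim$month == 2 & clim$day == 29], 2)
  expect_equal(clim$n_years[clim$month == 2 & clim$day == 29], 1)
  expect_equal(clim$mean_conc[clim$month == 3 & clim$day == 1], 3)
  expect_equal(nrow(clim), 366)
})
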