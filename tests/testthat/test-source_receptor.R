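test_that("Yamartino sigma evaluates its closed form", {
  expect_equal(yamartino_sigma(rep(123, 50)), 0, tolerance = 1e-5)
  # uniform spread over the four cardinal points attains the upper bound
  expect_equal(yamartino_sigma(c(0, 90, 180, 270)),
               90 * 2 / sqrt(3), tolerance = 1e-10)
  expect_error(yamartino_sigma(numeric(0)), "at least one")
})

test_that("Yamartino sigma is rotation-invariant and bounded", {
  set.seed(101)
  for (i in 1:25) {
    th <- runif(rpois(1, 30) + 2, 0, 360)
    s0 <- yamartino_sigma(th)
    expect_gte(s0, 0)
    expect_lte(s0, 103.93)
    expect_equal(yamartino_sigma(th + runif(1, 0, 360)), s0,
                 tolerance = 1e-9)
  }
})

test_that("Yamartino sigma tracks the two-pass circular SD", {
  set.seed(55)
  for (sdv in c(5, 15, 30, 50, 70)) {
    th <- (rnorm(3000, 210, sdv)) %% 360
    expect_equal(yamartino_sigma(th), circular_sd_2pass(th),
                 tolerance = 0.02)
  }
})

small_wind <- function(n = 40, seed = 9) {
  set.seed(seed)
  tibble::tibble(date = as.Date("2018-06-01") + seq_len(n) - 1,
                 speed = rweibull(n, 2, 8),
                 direction = runif(n, 0, 360),
                 sigma_dir = runif(n, 5, 40))
}

test_that("NWR of a constant concentration is that constant everywhere", {
  w <- small_wind()
  conc <- tibble::tibble(date = w$date, conc = 7)
  g <- nwr_estimate(conc, w, swim_config(n_dir_bins = 24, speed_step = 2))
  vals <- g$values[!is.na(g$values)]
  expect_gt(length(vals), 0)
  expect_true(all(abs(vals - 7) < 1e-9))
})

test_that("a single observation defines the grid only around its own cell", {
  w <- tibble::tibble(date = as.Date("2018-06-01"), speed = 10,
                      direction = 90, sigma_dir = 10)
  conc <- tibble::tibble(date = w$date, conc = 5)
  g <- nwr_estimate(conc, w, swim_config(n_dir_bins = 36, speed_step = 1,
                                         max_speed = 20, min_weight = 0.5))
  # the weighted mean of a single observation is 5 wherever defined, and the
  # defined region is the kernel neighbourhood of (90 degrees, 10 km/h)
  own <- g$values[g$dir_centers == 90,
                  findInterval(10, g$speed_breaks, rightmost.closed = TRUE)]
  expect_equal(own, 5)
  expect_true(all(abs(g$values[!is.na(g$values)] - 5) < 1e-9))
  far <- g$values[g$dir_centers == 270,
                  findInterval(1, g$speed_breaks, rightmost.closed = TRUE)]
  expect_true(is.na(far))
})

test_that("the kernel estimate matches a naive double-loop oracle", {
  w <- small_wind(12, seed = 21)
  conc <- tibble::tibble(date = w$date, conc = rgamma(12, 3, 0.1))
  cfg <- swim_config(n_dir_bins = 12, speed_step = 2, max_speed = 16)
  g <- nwr_estimate(conc, w, cfg)
  expect_equal(g$values, nwr_oracle(conc$conc, w$speed, w$direction, cfg),
               tolerance = 1e-12)
})

test_that("estimates are convex combinations of the concentrations", {
  set.seed(77)
  w <- small_wind(60, seed = 77)
  conc <- tibble::tibble(date = w$date, conc = rgamma(60, 2, 0.05))
  for (g in list(nwr_estimate(conc, w), swim_estimate(conc, w))) {
    v <- g$values[!is.na(g$values)]
    expect_gte(min(v), min(conc$conc) - 1e-9)
    expect_lte(max(v), max(conc$conc) + 1e-9)
  }
})

test_that("rotating all wind directions rotates the grid by whole bins", {
  w <- small_wind(50, seed = 31)
  conc <- tibble::tibble(date = w$date, conc = rgamma(50, 2, 0.1))
  cfg <- swim_config(n_dir_bins = 24, speed_step = 2, max_speed = 16)
  g0 <- nwr_estimate(conc, w, cfg)
  k <- 5  # rotate by 5 bins of 15 degrees
  w2 <- dplyr::mutate(w, direction = (direction + k * 15) %% 360)
  g1 <- nwr_estimate(conc, w2, cfg)
  rotated <- g0$values[((seq_len(24) - 1 - k) %% 24) + 1, ]
  expect_equal(g1$values, rotated, tolerance = 1e-9)
})

test_that("SWIM reduces to NWR when all sigmas are equal", {
  w <- small_wind(40)
  w$sigma_dir <- 12
  conc <- tibble::tibble(date = w$date, conc = rgamma(40, 2, 0.1))
  cfg <- swim_config(n_dir_bins = 24, speed_step = 2)
  expect_equal(swim_estimate(conc, w, cfg)$values,
               nwr_estimate(conc, w, cfg)$values)
})

test_that("sustained winds are up-weighted by mean-sigma over sigma", {
  # two coincident observations with sigma 1 and 2: weights 1.5 and 0.75
  w <- tibble::tibble(date = as.Date("2018-06-01") + 0:1,
                      speed = c(10, 10), direction = c(90, 90),
                      sigma_dir = c(1, 2))
  conc <- tibble::tibble(date = w$date, conc = c(8, 2))
  g <- swim_estimate(conc, w, swim_config(n_dir_bins = 36, speed_step = 1,
                                          max_speed = 20,
                                          min_weight = 1e-12))
  cell <- g$values[g$dir_centers == 90,
                   findInterval(10, g$speed_breaks, rightmost.closed = TRUE)]
  expect_equal(cell, (1.5 * 8 + 0.75 * 2) / 2.25, tolerance = 1e-9)
})

test_that("degenerate sigma and all-zero concentrations are flagged", {
  w <- small_wind(20)
  w$sigma_dir[3] <- 0
  conc <- tibble::tibble(date = w$date, conc = rgamma(20, 2, 0.1))
  expect_warning(swim_estimate(conc, w), "smallest positive")

  w2 <- small_wind(20)
  conc0 <- tibble::tibble(date = w2$date, conc = 0)
  expect_warning(g0 <- swim_estimate(conc0, w2, swim_config(normalize = TRUE)),
                 "zero")
  expect_true(all(g0$values[!is.na(g0$values)] == 0))
})

test_that("pollen and wind records must share dates", {
  w <- small_wind(10)
  conc <- tibble::tibble(date = w$date + 1000, conc = 1)
  expect_error(nwr_estimate(conc, w), "share no dates")
})

test_that("joint-probability roses are histograms summing to one", {
  w <- tibble::tibble(date = as.Date("2018-06-01") + 0:3,
                      speed = c(1, 3, 9, 15),
                      direction = c(0, 90, 180, 270))
  g <- joint_probability_rose(w, n_sectors = 8)
  expect_equal(sum(g$values), 1)
  expect_equal(sort(g$values[g$values > 0]), rep(0.25, 4))

  one <- joint_probability_rose(w[1, ], n_sectors = 8)
  expect_equal(max(one$values), 1)

  set.seed(61)
  wr <- small_wind(300, seed = 61)
  gr <- joint_probability_rose(wr, n_sectors = 16)
  expect_equal(sum(gr$values), 1)
  # oracle: direct binning of one specific cell (E sector, 4-8 km/h)
  manual <- mean(abs(((wr$direction - 90 + 180) %% 360) - 180) <= 11.25 &
                   wr$speed > 4 & wr$speed <= 8)
  expect_equal(gr$values[gr$dir_centers == 90, 3], manual, tolerance = 1e-12)
})

test_that("dominant sector reports the grid maximum with deterministic ties", {
  # uniform grid: tie-break to N and the lowest speed band
  g <- aeropollen:::new_polar_grid((0:7) * 45, c(0, 2, 4, 8, 12),
                                   matrix(1, 8, 4), "concentration")
  d <- dominant_sector(g)
  expect_equal(d$sector, "N")
  expect_equal(d$speed_band, c(0, 2))

  # single hot cell at 200 degrees, 6 km/h: S sector under centred sectors
  v <- matrix(0, 72, 4)
  dirs <- (0:71) * 5
  v[dirs == 200, 3] <- 9
  g2 <- aeropollen:::new_polar_grid(dirs, c(0, 2, 4, 8, 12), v, "concentration")
  d2 <- dominant_sector(g2)
  expect_equal(d2$sector, "S")
  expect_equal(d2$speed_band, c(4, 8))

  g3 <- aeropollen:::new_polar_grid(dirs, c(0, 2), matrix(NA_real_, 72, 1),
                                    "concentration")
  expect_error(dominant_sector(g3), "no defined cells")
})

test_that("a planted plume is recovered in its compass sector", {
  wp <- generate_wind_with_plume(plume_spec(direction = 90), 365, seed = 4)
  d <- dominant_sector(swim_estimate(wp$pollen, wp$wind))
  expect_equal(d$sector, "E")
  expect_lte(angular_distance(d$direction, 90), 15)
})

test_that("polar grids round-trip to delimited text", {
  wp <- generate_wind_with_plume(plume_spec(), 60, seed = 8)
  g <- joint_probability_rose(wp$wind)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_polar_grid(g, tf)
  back <- readr::read_csv(tf, show_col_types = FALSE)
  expect_equal(nrow(back), length(g$dir_centers) *
                 (length(g$speed_breaks) - 1))
  expect_equal(sum(back$value), 1, tolerance = 1e-6)
})
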