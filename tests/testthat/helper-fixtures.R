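# Shared fixtures and independent oracles for the test suite.

# Daily series for one taxon starting 1 Jan of `year`.
make_series <- function(conc, year = 2018, taxon = "Poaceae", site = "test") {
  tibble::tibble(site = site, taxon = taxon,
                 date = as.Date(sprintf("%d-01-01", year)) + seq_along(conc) - 1,
                 conc = conc)
}

# Brute-force MPS oracle: naive cumulative loop over the completed year.
mps_oracle <- function(series, year, lower = 0.05, upper = 0.95) {
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year)), by = "day")
  v <- series$conc[match(dates, series$date)]
  v[is.na(v)] <- 0
  total <- sum(v)
  if (total <= 0) return(list(start = NA, end = NA))
  cum <- 0; start <- NA; end <- NA
  for (i in seq_along(v)) {
    cum <- cum + v[i]
    if (is.na(start) && cum >= lower * total) start <- dates[i]
    if (is.na(end) && cum >= upper * total) { end <- dates[i]; break }
  }
  list(start = start, end = end)
}

# Two-pass circular standard deviation (degrees): RMS of wrapped deviations
# from the circular mean direction.
circular_sd_2pass <- function(directions) {
  th <- directions * pi / 180
  mdir <- Arg(mean(exp(1i * th))) * 180 / pi
  d <- ((directions - mdir + 180) %% 360) - 180
  sqrt(mean(d^2))
}

# Naive double-loop NWR oracle evaluated on the same grid as the package.
nwr_oracle <- function(conc, speed, direction, cfg) {
  nd <- cfg$n_dir_bins
  dir_centers <- (seq_len(nd) - 1) * (360 / nd)
  vmax <- if (is.null(cfg$max_speed)) max(speed) else cfg$max_speed
  sb <- seq(0, vmax + cfg$speed_step, by = cfg$speed_step)
  vc <- (sb[-length(sb)] + sb[-1]) / 2
  vals <- matrix(NA_real_, nd, length(vc))
  for (i in seq_len(nd)) {
    for (j in seq_along(vc)) {
      num <- 0; den <- 0
      for (k in seq_along(conc)) {
        dd <- abs((dir_centers[i] - direction[k]) %% 360)
        dd <- min(dd, 360 - dd)
        w <- exp(-0.5 * (dd / cfg$dir_width)^2) *
          exp(-0.5 * ((vc[j] - speed[k]) / cfg$speed_width)^2)
        num <- num + w * conc[k]; den <- den + w
      }
      if (den >= cfg$min_weight) vals[i, j] <- num / den
    }
  }
  vals
}

# A complete hourly day for one or more days from a 24-vector per day.
make_hourly <- function(day_values, year = 2018, taxon = "Total") {
  rows <- lapply(seq_along(day_values), function(i) {
    d <- as.Date(sprintf("%d-06-01", year)) + i - 1
    tibble::tibble(site = "test", taxon = taxon,
                   datetime = as.POSIXct(paste(d, sprintf("%02d:00:00", 0:23)),
                                         tz = "UTC"),
                   conc = day_values[[i]])
  })
  dplyr::bind_rows(rows)
}
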