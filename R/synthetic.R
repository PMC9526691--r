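# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream (when seed is NULL the ambient stream is used as-is).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of one synthetic taxon season
#'
#' Parameters of the unimodal season curve used by [generate_taxon_year()]:
#' when the season starts, where it peaks, how long it lasts, how much total
#' pollen it carries (target APIn) and how overdispersed the daily counts
#' are around the seasonal mean.
#'
#' @param taxon Taxon name.
#' @param start_doy Day-of-year the season curve begins.
#' @param peak_doy Day-of-year of the curve mode; must satisfy
#'   `start_doy < peak_doy < start_doy + season_length`.
#' @param season_length Length of the curve support in days.
#' @param apin Target noise-free APIn (pollen day/m^3), > 0.
#' @param dispersion Negative-binomial size parameter of the daily noise;
#'   larger is closer to Poisson and `Inf` switches the noise off entirely.
#' @return A list of class `taxon_season_spec`.
#' @export
taxon_season_spec <- function(taxon, start_doy, peak_doy, season_length,
                              apin, dispersion = 5) {
  if (!(start_doy < peak_doy && peak_doy < start_doy + season_length)) {
    stop("need start_doy < peak_doy < start_doy + season_length",
         call. = FALSE)
  }
  if (apin <= 0) stop("`apin` must be > 0", call. = FALSE)
  if (dispersion <= 0) stop("`dispersion` must be > 0", call. = FALSE)
  structure(list(taxon = taxon, start_doy = start_doy, peak_doy = peak_doy,
                 season_length = season_length, apin = apin,
                 dispersion = dispersion),
            class = "taxon_season_spec")
}

# Gamma-shaped daily weights over the season support: right-skewed unimodal
# curve (rapid rise, slower decay) with its mode at the requested peak,
# truncated to the season window and normalised to sum to one.
season_kernel <- function(spec) {
  m <- spec$peak_doy - spec$start_doy
  scale <- max((spec$season_length - m) / 3, 0.5)
  shape <- m / scale + 1
  x <- seq_len(spec$season_length) - 0.5
  w <- stats::dgamma(x, shape = shape, scale = scale)
  w / sum(w)
}

#' Simulate one taxon-year of daily pollen concentrations
#'
#' Builds the noise-free daily mean curve (gamma-shaped kernel scaled so the
#' annual noise-free sum equals the target APIn) and draws daily values from
#' a negative-binomial distribution around it. With `dispersion = Inf` the
#' mean curve itself is returned (the noise-free limit), so the realised
#' APIn equals the target exactly.
#'
#' @param spec A [taxon_season_spec()].
#' @param year Calendar year to simulate.
#' @param site Site label.
#' @param seed Optional seed; given (spec, seed) the output is reproducible.
#' @return A long pollen tibble covering every day of the year (zeros outside
#'   the season). The attribute `truth` records the noise-free ground truth:
#'   `apin`, `peak_doy` and the noise-free MPS `start_date`/`end_date` under
#'   the default 5-95% rule.
#' @export
generate_taxon_year <- function(spec, year, site = "synthetic", seed = NULL) {
  stopifnot(inherits(spec, "taxon_season_spec"))
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year)), by = "day")
  mu <- rep(0, length(dates))
  idx <- spec$start_doy + seq_len(spec$season_length) - 1L
  idx <- idx[idx <= length(dates)]
  mu[idx] <- (spec$apin * season_kernel(spec))[seq_along(idx)]
  conc <- if (is.infinite(spec$dispersion)) mu else {
    with_seed(seed, rnbinom(length(mu), size = spec$dispersion, mu = mu))
  }
  out <- tibble::tibble(site = site, taxon = spec$taxon, date = dates,
                        conc = as.numeric(conc))
  truth_series <- tibble::tibble(site = site, taxon = spec$taxon,
                                 date = dates, conc = mu)
  mps <- main_pollen_season(truth_series, year)
  attr(out, "truth") <- list(apin = spec$apin,
                             peak_doy = spec$peak_doy,
                             start_date = mps$start_date,
                             end_date = mps$end_date)
  out
}

#' Default season specifications emulating a NW-European pollen year
#'
#' A bundle of arboreal (spring) and herbaceous (summer) season specs whose
#' timing and APIn magnitudes follow the typical urban Irish pollen year:
#' an early Alnus season, Fraxinus/Betula peaking in mid-April, Quercus in
#' May, and much larger Poaceae and Urticaceae seasons peaking in June-
#' August, so the summed total series is bimodal with the summer mode higher.
#'
#' @param dispersion Negative-binomial size shared by all specs; default 5.
#' @return Named list of [taxon_season_spec()] objects.
#' @export
default_season_specs <- function(dispersion = 5) {
  sp <- list(
    taxon_season_spec("Alnus",      start_doy = 20,  peak_doy = 46,
                      season_length = 75, apin = 1500, dispersion = dispersion),
    taxon_season_spec("Betula",     start_doy = 85,  peak_doy = 108,
                      season_length = 55, apin = 4900, dispersion = dispersion),
    taxon_season_spec("Fraxinus",   start_doy = 78,  peak_doy = 108,
                      season_length = 60, apin = 1550, dispersion = dispersion),
    taxon_season_spec("Quercus",    start_doy = 112, peak_doy = 140,
                      season_length = 80, apin = 2700, dispersion = dispersion),
    taxon_season_spec("Poaceae",    start_doy = 150, peak_doy = 170,
                      season_length = 70, apin = 17350, dispersion = dispersion),
    taxon_season_spec("Urticaceae", start_doy = 160, peak_doy = 210,
                      season_length = 95, apin = 14780, dispersion = dispersion))
  stats::setNames(sp, vapply(sp, `[[`, character(1), "taxon"))
}

#' Simulate a bimodal multi-taxon pollen year
#'
#' Generates one [generate_taxon_year()] per spec. With the default spec
#' bundle the summed total series shows the characteristic bimodal annual
#' cycle: a spring arboreal mode and a larger summer grass/herb mode.
#'
#' @param specs List of [taxon_season_spec()]; default
#'   [default_season_specs()].
#' @param year Calendar year.
#' @param site Site label.
#' @param seed Optional base seed; taxon i uses `seed + i` so series are
#'   independent yet jointly reproducible.
#' @return A long multi-taxon pollen tibble; per-taxon ground truths in the
#'   `truth` attribute (named list).
#' @export
generate_bimodal_year <- function(specs = default_season_specs(), year = 2018,
                                  site = "synthetic", seed = NULL) {
  if (length(specs) == 0) stop("`specs` must not be empty", call. = FALSE)
  series <- vector("list", length(specs))
  truths <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    s <- generate_taxon_year(specs[[i]], year, site,
                             seed = if (is.null(seed)) NULL else seed + i)
    truths[[i]] <- attr(s, "truth")
    series[[i]] <- s
  }
  out <- dplyr::bind_rows(series)
  names(truths) <- vapply(specs, `[[`, character(1), "taxon")
  attr(out, "truth") <- truths
  out
}

#' Specification of a directional pollen source (plume)
#'
#' @param direction Source direction in degrees (wind blowing FROM there).
#' @param spread Half-width of the source sector in degrees, > 0.
#' @param speed_band `c(lo, hi)` km/h within which the source is advected.
#' @param base Background mean concentration (grains/m^3).
#' @param elevated Mean concentration when the wind samples the source;
#'   must exceed `base`.
#' @return A list of class `plume_spec`.
#' @export
plume_spec <- function(direction = 90, spread = 10, speed_band = c(8, 12),
                       base = 5, elevated = 80) {
  stopifnot(spread > 0, elevated > base, base >= 0,
            length(speed_band) == 2, speed_band[1] < speed_band[2])
  structure(list(direction = direction %% 360, spread = spread,
                 speed_band = speed_band, base = base, elevated = elevated),
            class = "plume_spec")
}

#' Simulate wind records with a planted directional pollen source
#'
#' Wind directions are uniform on the circle and speeds Weibull-distributed
#' (shape 2, scale 8 km/h, a realistic temperate distribution). The daily
#' concentration mean is `elevated` when the wind comes from within `spread`
#' degrees of the source direction at a speed inside the band, `base`
#' otherwise, with negative-binomial noise. A per-day direction standard
#' deviation (`sigma_dir`) is drawn uniformly on 5-45 degrees.
#'
#' @param spec A [plume_spec()].
#' @param n_days Number of days, >= 1.
#' @param year Calendar year the dates are placed in.
#' @param seed Optional seed.
#' @return A list with `wind` (tibble `date`, `speed`, `direction`,
#'   `sigma_dir`), `pollen` (tibble `date`, `conc`) and `truth` (the planted
#'   direction and its 8-point compass sector).
#' @export
generate_wind_with_plume <- function(spec, n_days, year = 2018, seed = NULL) {
  stopifnot(inherits(spec, "plume_spec"))
  if (n_days < 1) stop("`n_days` must be >= 1", call. = FALSE)
  with_seed(seed, {
    dates <- as.Date(sprintf("%d-01-01", year)) + seq_len(n_days) - 1
    direction <- runif(n_days, 0, 360)
    speed <- rweibull(n_days, shape = 2, scale = 8)
    sigma_dir <- runif(n_days, 5, 45)
    in_plume <- angular_distance(direction, spec$direction) <= spec$spread &
      speed >= spec$speed_band[1] & speed <= spec$speed_band[2]
    mu <- ifelse(in_plume, spec$elevated, spec$base)
    conc <- as.numeric(rnbinom(n_days, size = 10, mu = mu))
    list(wind = tibble::tibble(date = dates, speed = speed,
                               direction = direction, sigma_dir = sigma_dir),
         pollen = tibble::tibble(date = dates, conc = conc),
         truth = list(direction = spec$direction,
                      sector = compass_names(8)[sector_index(spec$direction, 8)],
                      n_plume_days = sum(in_plume)))
  })
}

#' Simulate a meteorological covariate with a planted rank association
#'
#' Constructs a daily parameter whose Spearman correlation with the supplied
#' pollen series approximates `rho_target`, via a Gaussian-copula blend of
#' the pollen ranks with independent noise (the Pearson correlation on the
#' normal scale is calibrated as `2 sin(pi rho / 6)`). `rho_target = 1` (or
#' -1) returns an exactly co-monotone (anti-monotone) transform of the
#' series, ties included.
#'
#' @param pollen Pollen tibble (`date`, `conc`); `NA` days get `NA` met too.
#' @param param Name of the generated column; default `"Tmean"`. The values
#'   are affinely mapped to a plausible range for the familiar parameters
#'   (temperature-like by default).
#' @param rho_target Target Spearman correlation in `[-1, 1]`.
#' @param seed Optional seed.
#' @return A meteorology tibble (`date`, `<param>`); the realised Spearman
#'   rho against the pollen series is stored in the `realized_rho` attribute.
#' @export
generate_meteo_with_association <- function(pollen, param = "Tmean",
                                            rho_target, seed = NULL) {
  stopifnot(abs(rho_target) <= 1)
  ok <- !is.na(pollen$conc)
  n <- sum(ok)
  vals <- rep(NA_real_, nrow(pollen))
  with_seed(seed, {
    if (abs(rho_target) == 1) {
      z <- sign(rho_target) * pollen$conc[ok]
    } else {
      r <- rank(pollen$conc[ok], ties.method = "average")
      zp <- qnorm(r / (n + 1))
      rho_p <- 2 * sin(pi * rho_target / 6)
      z <- rho_p * zp + sqrt(1 - rho_p^2) * rnorm(n)
    }
    # map to a plausible temperature-like scale
    vals[ok] <- 10 + 5 * scale(z)[, 1]
  })
  out <- tibble::tibble(date = pollen$date)
  out[[param]] <- vals
  attr(out, "realized_rho") <-
    suppressWarnings(stats::cor(pollen$conc[ok], vals[ok],
                                method = "spearman"))
  out
}

#' Default diurnal template peaking in the early afternoon
#'
#' @param peak_hour Hour of the template maximum; default 14.
#' @param concentration Sharpness of the peak; default 1.5.
#' @return 24 non-negative weights summing to 1.
#' @export
diurnal_template <- function(peak_hour = 14, concentration = 1.5) {
  h <- 0:23
  w <- exp(concentration * cos(2 * pi * (h - peak_hour) / 24))
  w / sum(w)
}

#' Disaggregate daily pollen into synthetic hourly concentrations
#'
#' Allocates each day's (rounded) total across the 24 hours by a multinomial
#' draw with the template as probabilities, so daily sums are preserved up to
#' rounding and the expected hourly shape equals the template.
#'
#' @param daily Single-taxon pollen tibble (`date`, `conc`).
#' @param template 24 non-negative hourly weights; default
#'   [diurnal_template()].
#' @param seed Optional seed.
#' @return An hourly tibble (`site`, `taxon`, `datetime`, `conc`), 24 rows
#'   per observed day.
#' @export
generate_hourly <- function(daily, template = diurnal_template(),
                            seed = NULL) {
  stopifnot(length(template) == 24, all(template >= 0), sum(template) > 0)
  taxon <- if ("taxon" %in% names(daily)) one_taxon(daily) else "Total"
  site <- if ("site" %in% names(daily)) daily$site[1] else "synthetic"
  obs <- daily[!is.na(daily$conc), ]
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(obs)), function(i) {
      total <- round(obs$conc[i])
      cnt <- if (total > 0) {
        as.vector(rmultinom(1, total, prob = template))
      } else rep(0, 24)
      tibble::tibble(
        site = site, taxon = taxon,
        datetime = as.POSIXct(paste(obs$date[i], sprintf("%02d:00:00", 0:23)),
                              tz = "UTC"),
        conc = as.numeric(cnt))
    })
    dplyr::bind_rows(rows)
  })
}
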