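#' Volumetric trap configuration
#'
#' Describes a Hirst-type volumetric sampler well enough to convert raw slide
#' counts into atmospheric concentrations: the pump flow rate, the fraction of
#' the slide surface actually counted under the microscope, and the sampling
#' time represented by one slide.
#'
#' @param flow_rate Air intake in litres per minute. Default 10 L/min, the
#'   standard Hirst trap flow.
#' @param counted_fraction Fraction of the slide surface counted, in (0, 1].
#'   Default 0.125: four horizontal transects typically cover 12-13% of the
#'   slide, and 12.5% is the midpoint of that range.
#' @param sampling_minutes Minutes of air sampling represented by one slide.
#'   Default 1440 (one day).
#'
#' @return A list of class `trap_config`.
#' @examples
#' cfg <- trap_config()
#' raw_count_to_concentration(18, cfg)
#' @export
trap_config <- function(flow_rate = 10, counted_fraction = 0.125,
                        sampling_minutes = 1440) {
  if (!is.numeric(flow_rate) || length(flow_rate) != 1 || flow_rate <= 0) {
    stop("`flow_rate` must be a single positive number (L/min)", call. = FALSE)
  }
  if (!is.numeric(counted_fraction) || length(counted_fraction) != 1 ||
      counted_fraction <= 0 || counted_fraction > 1) {
    stop("`counted_fraction` must be in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(sampling_minutes) || length(sampling_minutes) != 1 ||
      sampling_minutes <= 0) {
    stop("`sampling_minutes` must be a single positive number", call. = FALSE)
  }
  structure(list(flow_rate = flow_rate, counted_fraction = counted_fraction,
                 sampling_minutes = sampling_minutes),
            class = "trap_config")
}

#' Convert a raw slide count to an atmospheric concentration
#'
#' Scales the grains counted on the inspected fraction of the slide up to the
#' whole slide, then divides by the volume of air sampled:
#' `count / counted_fraction / (flow_rate * sampling_minutes / 1000)` m^3.
#'
#' @param count Grains counted (non-negative; vectorised).
#' @param cfg A [trap_config()].
#' @return Concentration in pollen grains/m^3.
#' @examples
#' raw_count_to_concentration(144, trap_config(counted_fraction = 1))
#' @export
raw_count_to_concentration <- function(count, cfg = trap_config()) {
  stopifnot(inherits(cfg, "trap_config"))
  if (any(count < 0, na.rm = TRUE)) {
    stop("`count` must be non-negative", call. = FALSE)
  }
  volume_m3 <- cfg$flow_rate * cfg$sampling_minutes / 1000
  count / cfg$counted_fraction / volume_m3
}

#' Convert wind speed from knots to km/h
#'
#' Meteorological services often report wind speed in knots while polar
#' concentration plots are conventionally drawn in km/h (1 kt = 1.852 km/h).
#'
#' @param speed_kt Speed in knots.
#' @return Speed in km/h.
#' @export
knots_to_kmh <- function(speed_kt) speed_kt * 1.852

# Parse a character date column: primary format first (day-first by default),
# ISO-8601 as fallback. Returns list(dates, failed) where `failed` holds row
# indices that parsed under neither format.
parse_dates <- function(x, date_format = "%d/%m/%Y") {
  x <- as.character(x)
  d <- as.Date(x, format = date_format)
  iso <- as.Date(x, format = "%Y-%m-%d")
  d[is.na(d)] <- iso[is.na(d)]
  list(dates = d, failed = which(is.na(d) & !is.na(x) & nzchar(x)))
}

delim_for <- function(path) {
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a table of daily pollen concentrations
#'
#' Reads a delimited text file (CSV or TSV by extension) holding daily pollen
#' concentrations in grains/m^3, either wide (a `date` column plus one column
#' per taxon) or long (`date`, `taxon`, `conc` columns). Dates are parsed
#' day-first (`DD/MM/YYYY`) by default with ISO-8601 accepted as fallback.
#' Empty cells are missing days (not monitored), distinct from explicit zeros.
#'
#' @param path Path to the delimited file.
#' @param layout `"wide"` or `"long"`.
#' @param site Site identifier attached to every row.
#' @param date_format Primary date format string passed to [as.Date()].
#' @return A tibble with columns `site`, `taxon`, `date`, `conc`, one row per
#'   (taxon, day). Negative values and unparsable dates are rejected with the
#'   offending row numbers; duplicate (date, taxon) pairs are an error.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("date,Poaceae,Betula",
#'              "01/06/2018,12,0",
#'              "02/06/2018,15,1"), tf)
#' read_pollen_table(tf)
#' @export
read_pollen_table <- function(path, layout = c("wide", "long"),
                              site = "site", date_format = "%d/%m/%Y") {
  layout <- match.arg(layout)
  raw <- readr::read_delim(path, delim = delim_for(path),
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  if (nrow(raw) == 0) {
    warning("empty pollen table: ", path, call. = FALSE)
    return(tibble::tibble(site = character(), taxon = character(),
                          date = as.Date(character()), conc = double()))
  }
  if (!"date" %in% names(raw)) {
    stop("pollen table must have a `date` column", call. = FALSE)
  }
  pd <- parse_dates(raw$date, date_format)
  if (length(pd$failed)) {
    stop("unparsable dates in rows: ",
         paste(pd$failed, collapse = ", "), call. = FALSE)
  }
  d <- pd$dates
  if (layout == "wide") {
    long <- tidyr::pivot_longer(
      dplyr::mutate(raw, date = d),
      cols = -"date", names_to = "taxon", values_to = "conc")
  } else {
    if (!all(c("taxon", "conc") %in% names(raw))) {
      stop("long layout needs `taxon` and `conc` columns", call. = FALSE)
    }
    long <- dplyr::mutate(raw[, c("date", "taxon", "conc")], date = d)
  }
  long$conc <- as.numeric(long$conc)
  bad <- which(long$conc < 0)
  if (length(bad)) {
    stop("negative concentrations at (date, taxon): ",
         paste(sprintf("(%s, %s)", long$date[bad], long$taxon[bad]),
               collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(long[, c("date", "taxon")])
  if (any(dup)) {
    d2 <- unique(sprintf("(%s, %s)", long$date[dup], long$taxon[dup]))
    stop("duplicate (date, taxon) pairs: ", paste(d2, collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(site = site, taxon = long$taxon, date = long$date,
                 conc = long$conc)
}

#' Write daily pollen concentrations to delimited text
#'
#' Inverse of [read_pollen_table()]; dates are written ISO-8601.
#'
#' @param x Long pollen tibble (`site`, `taxon`, `date`, `conc`).
#' @param path Output path (`.csv` or `.tsv`).
#' @param layout `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_pollen_table <- function(x, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  stopifnot(all(c("taxon", "date", "conc") %in% names(x)))
  out <- if (layout == "wide") {
    tidyr::pivot_wider(x[, c("date", "taxon", "conc")],
                       names_from = "taxon", values_from = "conc")
  } else {
    x[, c("date", "taxon", "conc")]
  }
  out <- dplyr::arrange(out, .data$date)
  readr::write_delim(out, path, delim = delim_for(path), na = "")
  invisible(path)
}

#' Read a daily meteorology table
#'
#' A wide delimited table: a `date` column plus one numeric column per
#' meteorological parameter (e.g. `Tmean`, `Tmax`, `Tmin`, `Rain`, `Wind_s`,
#' `Wind_d`, `G_rad`, `Rh`, `Sun`). Basic range checks are applied where the
#' parameter semantics are unambiguous.
#'
#' @inheritParams read_pollen_table
#' @return A tibble with `date` plus numeric parameter columns.
#' @export
read_meteo_table <- function(path, date_format = "%d/%m/%Y") {
  raw <- readr::read_delim(path, delim = delim_for(path),
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  if (!"date" %in% names(raw)) {
    stop("meteorology table must have a `date` column", call. = FALSE)
  }
  pd <- parse_dates(raw$date, date_format)
  if (length(pd$failed)) {
    stop("unparsable dates in rows: ",
         paste(pd$failed, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::mutate(raw, date = pd$dates)
  for (nm in setdiff(names(out), "date")) out[[nm]] <- as.numeric(out[[nm]])
  validate_meteo(out)
  tibble::as_tibble(out)
}

validate_meteo <- function(met) {
  if ("Rh" %in% names(met) &&
      any(met$Rh < 0 | met$Rh > 100, na.rm = TRUE)) {
    stop("Rh outside [0, 100]", call. = FALSE)
  }
  if ("Rain" %in% names(met) && any(met$Rain < 0, na.rm = TRUE)) {
    stop("negative Rain", call. = FALSE)
  }
  if ("Wind_d" %in% names(met) &&
      any(met$Wind_d < 0 | met$Wind_d >= 360, na.rm = TRUE)) {
    stop("Wind_d outside [0, 360)", call. = FALSE)
  }
  invisible(met)
}

#' Trailing-window mean of a meteorological parameter
#'
#' Derives a lagged predictor such as "mean temperature over the previous 10
#' days": the value at date `d` is the mean of the parameter over the
#' `window_days` calendar days strictly preceding `d` (the current day is
#' excluded). The value is missing when fewer than `min_obs` of those days
#' have an observation.
#'
#' @param met Meteorology tibble (`date` plus parameter columns).
#' @param param Name of the parameter column.
#' @param window_days Length of the trailing window in days (default 10).
#' @param min_obs Minimum observations required in the window; default half
#'   the window, so a 10-day mean needs at least 5 observed days.
#' @return A tibble with columns `date` and `value`, one row per date present
#'   in `met`.
#' @examples
#' met <- tibble::tibble(date = as.Date("2018-06-01") + 0:14, Tmean = 1:15)
#' lagged_mean(met, "Tmean")  # day 11 gets mean(1:10) = 5.5
#' @export
lagged_mean <- function(met, param, window_days = 10,
                        min_obs = window_days / 2) {
  if (!param %in% names(met)) {
    stop("unknown parameter `", param, "`; available: ",
         paste(setdiff(names(met), "date"), collapse = ", "), call. = FALSE)
  }
  if (window_days < 1) stop("`window_days` must be >= 1", call. = FALSE)
  full <- tibble::tibble(date = seq(min(met$date), max(met$date), by = "day"))
  full <- dplyr::left_join(full, met[, c("date", param)], by = "date")
  v <- full[[param]]
  n <- length(v)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    idx <- seq(max(1L, i - window_days), i - 1L)
    if (i == 1L) next
    w <- v[idx]
    # window must be fully inside the record to hold window_days slots
    if (i - 1L < window_days) w <- c(w, rep(NA_real_, window_days - (i - 1L)))
    if (sum(!is.na(w)) >= min_obs) out[i] <- mean(w, na.rm = TRUE)
  }
  res <- tibble::tibble(date = full$date, value = out)
  res[res$date %in% met$date, ]
}

#' Append trailing-window means as derived meteorology columns
#'
#' Convenience wrapper around [lagged_mean()] adding columns named
#' `<param>_<window_days>` (e.g. `Tmean_10`, `Rain_10`).
#'
#' @inheritParams lagged_mean
#' @param params Character vector of parameter columns to derive.
#' @return `met` with one extra column per entry of `params`.
#' @export
add_lagged_means <- function(met, params, window_days = 10,
                             min_obs = window_days / 2) {
  for (p in params) {
    lg <- lagged_mean(met, p, window_days, min_obs)
    met[[paste0(p, "_", window_days)]] <-
      lg$value[match(met$date, lg$date)]
  }
  met
}
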