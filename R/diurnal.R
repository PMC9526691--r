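#' Mean diurnal (hourly) pollen profile
#'
#' Averages hourly concentrations by hour of day over the days of a period.
#' In `"percent"` mode (the default) each day is first converted to the
#' percentage of its own daily total, so day-to-day abundance swings do not
#' dominate the diurnal shape; days with a zero total are excluded. In
#' `"absolute"` mode raw hourly concentrations are averaged. Only days with
#' at least `min_hours` observed hours qualify.
#'
#' @param hourly Hourly pollen tibble with `datetime` (POSIXct, hour-aligned)
#'   and `conc`; a `taxon` column, if present, must be single-valued.
#' @param period Optional `c(from, to)` Date vector restricting the days.
#' @param mode `"percent"` or `"absolute"`.
#' @param min_hours Minimum observed hours for a day to qualify; default 12.
#' @return A tibble of class `diurnal_profile` with `hour` (0-23), `value`
#'   (% of daily total, or grains/m^3) and `n_days`; the mode is kept in the
#'   `mode` attribute.
#' @export
mean_hourly_profile <- function(hourly, period = NULL,
                                mode = c("percent", "absolute"),
                                min_hours = 12) {
  mode <- match.arg(mode)
  stopifnot(all(c("datetime", "conc") %in% names(hourly)))
  if ("taxon" %in% names(hourly)) one_taxon(hourly)
  x <- hourly[!is.na(hourly$conc), ]
  x$date <- as.Date(x$datetime)
  x$hour <- as.integer(format(x$datetime, "%H"))
  if (!is.null(period)) {
    x <- x[x$date >= period[1] & x$date <= period[2], ]
  }
  counts <- table(x$date)
  keep <- names(counts)[counts >= min_hours]
  x <- x[as.character(x$date) %in% keep, ]
  if (nrow(x) == 0) {
    stop("no days with >= ", min_hours, " observed hours in the period",
         call. = FALSE)
  }
  if (mode == "percent") {
    x <- x |>
      dplyr::group_by(.data$date) |>
      dplyr::mutate(day_total = sum(.data$conc)) |>
      dplyr::ungroup()
    x <- x[x$day_total > 0, ]
    if (nrow(x) == 0) {
      stop("all qualifying days have zero total pollen", call. = FALSE)
    }
    x$value <- 100 * x$conc / x$day_total
  } else {
    x$value <- x$conc
  }
  prof <- x |>
    dplyr::group_by(.data$hour) |>
    dplyr::summarise(value = mean(.data$value),
                     n_days = dplyr::n_distinct(.data$date),
                     .groups = "drop")
  out <- dplyr::left_join(tibble::tibble(hour = 0:23), prof, by = "hour")
  out$n_days[is.na(out$n_days)] <- 0L
  attr(out, "mode") <- mode
  class(out) <- c("diurnal_profile", class(out))
  out
}

#' Peak hour window(s) of a diurnal profile
#'
#' Finds the maximal contiguous hour ranges whose profile value is at least
#' `frac` of the profile maximum. Contiguity wraps across midnight, and a
#' bimodal profile yields two (or more) windows.
#'
#' @param profile Output of [mean_hourly_profile()].
#' @param frac Fraction of the maximum defining "peak"; default 0.8.
#' @return Tibble with one row per window: `start_hour`, `end_hour`
#'   (inclusive, possibly wrapping, e.g. 22 to 2) and `peak_hour` (hour of
#'   the window maximum).
#' @export
peak_window <- function(profile, frac = 0.8) {
  v <- profile$value
  if (all(is.na(v))) stop("profile has no defined hours", call. = FALSE)
  mx <- max(v, na.rm = TRUE)
  hot <- !is.na(v) & v >= frac * mx
  if (all(hot)) {
    return(tibble::tibble(start_hour = 0L, end_hour = 23L,
                          peak_hour = profile$hour[which.max(v)]))
  }
  # runs on the circle: rotate so position 1 is cold, then use rle
  off <- which(!hot)[1]
  idx <- ((seq_along(hot) - 1 + off - 1) %% 24) + 1
  r <- rle(hot[idx])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- lapply(which(r$values), function(k) {
    hrs <- profile$hour[idx[starts[k]:ends[k]]]
    tibble::tibble(start_hour = hrs[1], end_hour = hrs[length(hrs)],
                   peak_hour = hrs[which.max(v[hrs + 1])])
  })
  res <- dplyr::bind_rows(out)
  dplyr::arrange(res, .data$start_hour)
}

#' Write a diurnal profile as 24-row delimited text
#'
#' @param profile Output of [mean_hourly_profile()].
#' @param path Output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_diurnal_profile <- function(profile, path) {
  out <- tibble::as_tibble(profile)
  out$value <- round(out$value, 6)
  readr::write_delim(out, path, delim = delim_for(path), na = "")
  invisible(path)
}
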