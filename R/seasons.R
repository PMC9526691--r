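#' Configuration for the 90% Main Pollen Season method
#'
#' The Main Pollen Season (MPS) is delimited by cumulative quantiles of the
#' annual pollen sum: it starts on the first day the cumulative concentration
#' reaches `lower_quantile` of the annual total and ends on the first day it
#' reaches `upper_quantile`. The defaults (5% and 95%) give the classical
#' "90% method". Taxa whose Annual Pollen Integral reaches `major_threshold`
#' are flagged as major pollen types.
#'
#' @param lower_quantile Lower cumulative fraction, default 0.05.
#' @param upper_quantile Upper cumulative fraction, default 0.95.
#' @param major_threshold APIn (pollen day/m^3) at or above which a taxon is
#'   a major pollen type; default 100.
#' @return A list of class `season_method_config`.
#' @export
season_method_config <- function(lower_quantile = 0.05, upper_quantile = 0.95,
                                 major_threshold = 100) {
  if (!(lower_quantile > 0 && lower_quantile < upper_quantile &&
        upper_quantile < 1)) {
    stop("need 0 < lower_quantile < upper_quantile < 1", call. = FALSE)
  }
  structure(list(lower_quantile = lower_quantile,
                 upper_quantile = upper_quantile,
                 major_threshold = major_threshold),
            class = "season_method_config")
}

#' Season duration from its start and end dates
#'
#' Duration is the calendar-day difference `end - start` (exclusive
#' convention: a season starting and ending on the same day has duration 0).
#' This is the convention used throughout the season table.
#'
#' @param start_date,end_date Date vectors.
#' @return Integer day differences.
#' @examples
#' season_duration(as.Date("2018-02-03"), as.Date("2018-03-31"))  # 56
#' @export
season_duration <- function(start_date, end_date) {
  as.integer(as.Date(end_date) - as.Date(start_date))
}

# Single-taxon check used by season operations.
one_taxon <- function(series) {
  tx <- unique(series$taxon)
  if (length(tx) != 1) {
    stop("expected a single-taxon series, got: ",
         paste(tx, collapse = ", "), call. = FALSE)
  }
  tx
}

year_period <- function(year) {
  c(as.Date(sprintf("%d-01-01", year)), as.Date(sprintf("%d-12-31", year)))
}

# Complete daily grid over [from, to] for one taxon; absent rows become NA
# (day not monitored), which downstream stages treat per their own rules.
complete_days <- function(series, from, to) {
  grid <- tibble::tibble(date = seq(from, to, by = "day"))
  dplyr::left_join(grid, series[, c("date", "conc")], by = "date")
}

#' Annual Pollen Integral
#'
#' Total pollen exposure over a period, in pollen day/m^3. The default follows
#' the recommended aerobiological convention of multiplying the mean observed
#' daily concentration by the number of calendar days in the period, which
#' equals the plain daily sum when no days are missing; `method = "sum"` gives
#' the plain sum over observed days.
#'
#' @param series Single-taxon pollen tibble (`date`, `conc`).
#' @param period A year (single integer) or a length-2 Date vector
#'   `c(from, to)`.
#' @param method `"mean_by_days"` (default) or `"sum"`.
#' @return The APIn as a single number.
#' @examples
#' s <- tibble::tibble(site = "x", taxon = "Poaceae",
#'                     date = as.Date("2018-01-01") + 0:364, conc = 1)
#' annual_pollen_integral(s, 2018)  # 365
#' @export
annual_pollen_integral <- function(series, period,
                                   method = c("mean_by_days", "sum")) {
  method <- match.arg(method)
  if (is.numeric(period) && length(period) == 1) period <- year_period(period)
  stopifnot(inherits(period, "Date"), length(period) == 2)
  obs <- series$conc[series$date >= period[1] & series$date <= period[2]]
  obs <- obs[!is.na(obs)]
  if (length(obs) == 0) {
    stop("no observed days in the requested period", call. = FALSE)
  }
  if (method == "sum") return(sum(obs))
  n_days <- as.integer(period[2] - period[1]) + 1L
  mean(obs) * n_days
}

#' Main Pollen Season by the 90% method
#'
#' Delimits the MPS of one taxon in one year: the start is the first day on
#' which the cumulative daily concentration reaches `lower_quantile` of the
#' annual total, the end the first day it reaches `upper_quantile`, and the
#' duration is the calendar-day difference `end - start`. Days without an
#' observation contribute zero to the cumulative sum (no interpolation); a
#' year with more than 25% of days unmonitored carries a quality warning.
#'
#' @param series Single-taxon pollen tibble (`site`, `taxon`, `date`, `conc`).
#' @param year Calendar year.
#' @param cfg A [season_method_config()].
#' @return One-row tibble with `taxon`, `year`, `start_date`, `end_date`,
#'   `duration_days`, `peak_date` (earliest day of the in-season maximum),
#'   `peak_value`, `apin`, `pct_of_total` (`NA` until filled by
#'   [season_table()]), `is_major`, `season_defined`, `n_missing_days` and
#'   `quality_warning`. A zero annual total yields a row with
#'   `season_defined = FALSE` rather than an error.
#' @export
main_pollen_season <- function(series, year, cfg = season_method_config()) {
  taxon <- one_taxon(series)
  site <- series$site[1]
  per <- year_period(year)
  day <- complete_days(series[series$date >= per[1] & series$date <= per[2], ],
                       per[1], per[2])
  n_missing <- sum(is.na(day$conc))
  qwarn <- n_missing > 0.25 * nrow(day)
  if (qwarn) {
    warning(sprintf("%s %d: %d of %d days unmonitored; season statistics may be truncated",
                    taxon, year, n_missing, nrow(day)), call. = FALSE)
  }
  conc0 <- ifelse(is.na(day$conc), 0, day$conc)
  total <- sum(conc0)
  base <- tibble::tibble(
    site = site, taxon = taxon, year = as.integer(year),
    start_date = as.Date(NA), end_date = as.Date(NA),
    duration_days = NA_integer_, peak_date = as.Date(NA),
    peak_value = NA_real_, apin = NA_real_, pct_of_total = NA_real_,
    is_major = NA, season_defined = FALSE,
    n_missing_days = as.integer(n_missing), quality_warning = qwarn)
  if (total <= 0) return(base)
  cum <- cumsum(conc0)
  start_i <- which(cum >= cfg$lower_quantile * total)[1]
  end_i <- which(cum >= cfg$upper_quantile * total)[1]
  in_season <- seq(start_i, end_i)
  peak_i <- in_season[which.max(conc0[in_season])]
  apin <- annual_pollen_integral(series, year)
  base$start_date <- day$date[start_i]
  base$end_date <- day$date[end_i]
  base$duration_days <- season_duration(day$date[start_i], day$date[end_i])
  base$peak_date <- day$date[peak_i]
  base$peak_value <- conc0[peak_i]
  base$apin <- apin
  base$is_major <- apin >= cfg$major_threshold
  base$season_defined <- TRUE
  base
}

#' Season-parameter table for all taxa of a year
#'
#' Computes [main_pollen_season()] for every taxon plus a synthetic `"Total"`
#' series (the daily sum over taxa, missing only where every taxon is
#' missing). `pct_of_total` is each taxon's APIn as a percentage of the
#' summed APIn over all taxa; rows are sorted by taxon with `Total` last.
#'
#' @param pollen Long multi-taxon pollen tibble.
#' @param year Calendar year.
#' @param cfg A [season_method_config()].
#' @return Tibble of season statistics, one row per taxon plus `Total`.
#' @export
season_table <- function(pollen, year, cfg = season_method_config()) {
  taxa <- sort(unique(pollen$taxon))
  if (length(taxa) == 0) stop("no taxa in `pollen`", call. = FALSE)
  rows <- lapply(taxa, function(tx) {
    main_pollen_season(pollen[pollen$taxon == tx, ], year, cfg)
  })
  tot_series <- pollen |>
    dplyr::group_by(.data$date) |>
    dplyr::summarise(
      conc = if (all(is.na(.data$conc))) NA_real_ else
        sum(.data$conc, na.rm = TRUE),
      .groups = "drop") |>
    dplyr::mutate(site = pollen$site[1], taxon = "Total")
  rows <- c(rows, list(main_pollen_season(tot_series, year, cfg)))
  tbl <- dplyr::bind_rows(rows)
  apin_sum <- sum(tbl$apin[tbl$taxon != "Total"], na.rm = TRUE)
  if (apin_sum > 0) {
    tbl$pct_of_total <- 100 * tbl$apin / apin_sum
    tbl$pct_of_total[tbl$taxon == "Total"] <- NA_real_
  }
  tbl
}

#' Write a season table with the conventional column set
#'
#' Exports the season-parameter table as delimited text with the columns of a
#' standard aerobiological season report: taxon, start and end dates, season
#' duration, maximum daily concentration and its day, APIn, and percentage of
#' total pollen.
#'
#' @param tbl Output of [season_table()].
#' @param path Output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_season_table <- function(tbl, path) {
  out <- tibble::tibble(
    `Pollen Type` = tbl$taxon,
    `Start Date` = format(tbl$start_date, "%d/%m/%Y"),
    `End Date` = format(tbl$end_date, "%d/%m/%Y"),
    `Duration of Season (Days)` = tbl$duration_days,
    `Max Daily Concentration (grains/m3)` = tbl$peak_value,
    `Day of Max Concentration` = format(tbl$peak_date, "%d/%m/%Y"),
    `APIn (Pollen day/m3)` = round(tbl$apin, 1),
    `% of Total Pollen` = round(tbl$pct_of_total, 1))
  readr::write_delim(out, path, delim = delim_for(path), na = "")
  invisible(path)
}
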