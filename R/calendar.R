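#' Multi-year daily climatology of a taxon
#'
#' Averages daily concentrations across years by calendar day (month, day):
#' the mean for 14 April is taken over every year with an observation on
#' 14 April, and `n_years` records how many years contributed. 29 February is
#' averaged only over leap years. Days never observed in any year are absent
#' from the output.
#'
#' @param pollen Long pollen tibble spanning one or more years.
#' @param taxon Taxon to average; must be present in `pollen`.
#' @return Tibble with `taxon`, `month`, `day`, `doy` (leap-reference
#'   day-of-year, 1-366, so 29 Feb = 60), `mean_conc`, `n_years`.
#' @export
daily_climatology <- function(pollen, taxon) {
  x <- pollen[pollen$taxon == taxon & !is.na(pollen$conc), ]
  if (nrow(x) == 0) {
    stop("no data for taxon `", taxon, "`", call. = FALSE)
  }
  x$month <- as.integer(format(x$date, "%m"))
  x$day <- as.integer(format(x$date, "%d"))
  clim <- x |>
    dplyr::group_by(.data$month, .data$day) |>
    dplyr::summarise(mean_conc = mean(.data$conc),
                     n_years = dplyr::n_distinct(format(.data$date, "%Y")),
                     .groups = "drop") |>
    dplyr::arrange(.data$month, .data$day)
  # day-of-year on a leap-year reference so all 366 calendar days are distinct
  ref <- as.Date(sprintf("2000-%02d-%02d", clim$month, clim$day))
  clim$doy <- as.integer(ref - as.Date("2000-01-01")) + 1L
  tibble::tibble(taxon = taxon, clim[, c("month", "day", "doy",
                                         "mean_conc", "n_years")])
}

days_in_month_ref <- c(31L, 29L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

section_of_day <- function(day) pmin((day - 1L) %/% 6L + 1L, 5L)

#' Partition a daily climatology into 5 sections per month
#'
#' Each month is divided into five sections: sections 1-4 cover days 1-6,
#' 7-12, 13-18 and 19-24, and section 5 absorbs the remainder of the month
#' (day 25 to the month end, so 4-7 days depending on the month). The section
#' mean is the mean of the climatology values of the days present in it.
#'
#' @param clim Output of [daily_climatology()] (one taxon).
#' @return Tibble with `taxon`, `month`, `section` (1-5), `mean_conc`
#'   (`NA` when no climatology day falls in the section) and `n_days`
#'   (contributing days).
#' @export
partition_sections <- function(clim) {
  clim$section <- section_of_day(clim$day)
  sec <- clim |>
    dplyr::group_by(.data$taxon, .data$month, .data$section) |>
    dplyr::summarise(mean_conc = mean(.data$mean_conc),
                     n_days = dplyr::n(), .groups = "drop")
  grid <- tidyr::expand_grid(taxon = unique(clim$taxon),
                             month = 1:12, section = 1:5)
  out <- dplyr::left_join(grid, sec, by = c("taxon", "month", "section"))
  out$n_days[is.na(out$n_days)] <- 0L
  dplyr::arrange(out, .data$taxon, .data$month, .data$section)
}

# ordered worst-to-best for cell aggregation: main dominates
period_levels <- c("none", "possible", "early", "late", "main")

#' Flowering-period classification of climatology days
#'
#' Classifies every day of the climatology by the cumulative fraction F(d) of
#' the annual climatological pollen sum reached by day d. The main flowering
#' period begins on the day F reaches 10% and ends on the day it reaches 90%
#' (both days included). Days before the main period with F above 0.5% are
#' early; days after it with F below 99.5% are late; any other day on which
#' pollen was observed (positive climatology mean) is a possible occurrence
#' time; the rest are none. A zero-total climatology classes every day none.
#'
#' @param clim Output of [daily_climatology()] (one taxon).
#' @return `clim` with an added `period_class` factor
#'   (`none < possible < early < late < main`) and `cum_frac` column.
#' @export
flowering_periods <- function(clim) {
  clim <- dplyr::arrange(clim, .data$doy)
  total <- sum(clim$mean_conc)
  cls <- rep("none", nrow(clim))
  f <- if (total > 0) cumsum(clim$mean_conc) / total else rep(0, nrow(clim))
  if (total > 0) {
    main_start <- which(f >= 0.10)[1]
    main_end <- which(f >= 0.90)[1]
    main_idx <- seq(main_start, main_end)
    cls[main_idx] <- "main"
    early <- which(seq_along(f) < main_start & f > 0.005)
    cls[early] <- "early"
    late <- which(seq_along(f) > main_end & f < 0.995)
    cls[late] <- "late"
    rest <- which(cls == "none" & clim$mean_conc > 0)
    cls[rest] <- "possible"
  }
  clim$cum_frac <- f
  clim$period_class <- factor(cls, levels = period_levels, ordered = TRUE)
  clim
}

#' Read the shipped default allergenicity table
#'
#' Allergenicity classes (high / moderate / low) are a literature-based user
#' configuration, not something estimated from the data; the package ships an
#' editable default table covering common northwest-European pollen taxa.
#'
#' @return Tibble with columns `taxon` and `allergenicity`.
#' @export
default_allergenicity <- function() {
  path <- system.file("extdata", "allergenicity.csv", package = "aeropollen")
  readr::read_csv(path, col_types = "cc", progress = FALSE)
}

#' Build a pollen calendar
#'
#' Combines per-taxon daily climatologies into the classical pollen-calendar
#' layout: 12 months x 5 sections = 60 cells per taxon, each carrying the
#' section mean concentration, a flowering-period class and an allergenicity
#' class. A cell's class is the highest-ranked class among its days
#' (main > late > early > possible > none), so any section containing a
#' main-period day displays as main.
#'
#' @param clims A list of [daily_climatology()] outputs (or a single one).
#' @param allergenicity Tibble with `taxon`, `allergenicity` columns; default
#'   the shipped table. Every calendar taxon must have an entry.
#' @return Tibble of class `pollen_calendar`: `taxon`, `month`, `section`,
#'   `mean_conc`, `n_days`, `period_class`, `allergenicity`, 60 rows per
#'   taxon ordered Jan-s1 ... Dec-s5.
#' @export
build_calendar <- function(clims, allergenicity = default_allergenicity()) {
  if (is.data.frame(clims)) clims <- list(clims)
  taxa <- vapply(clims, function(x) x$taxon[1], character(1))
  missing <- setdiff(taxa, allergenicity$taxon)
  if (length(missing)) {
    stop("taxa missing from the allergenicity table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cells <- lapply(clims, function(clim) {
    cl <- flowering_periods(clim)
    cl$section <- section_of_day(cl$day)
    day_cls <- cl |>
      dplyr::group_by(.data$taxon, .data$month, .data$section) |>
      dplyr::summarise(period_class = max(.data$period_class),
                       .groups = "drop")
    sec <- partition_sections(clim)
    out <- dplyr::left_join(sec, day_cls,
                            by = c("taxon", "month", "section"))
    out$period_class[is.na(out$period_class)] <- "none"
    out
  })
  cal <- dplyr::bind_rows(cells)
  cal$allergenicity <-
    allergenicity$allergenicity[match(cal$taxon, allergenicity$taxon)]
  cal <- dplyr::arrange(cal, .data$taxon, .data$month, .data$section)
  class(cal) <- c("pollen_calendar", class(cal))
  cal
}

#' Write a pollen calendar as delimited text
#'
#' @param cal Output of [build_calendar()].
#' @param path Output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_calendar <- function(cal, path) {
  out <- tibble::as_tibble(cal)
  out$period_class <- as.character(out$period_class)
  out$mean_conc <- round(out$mean_conc, 4)
  readr::write_delim(out, path, delim = delim_for(path), na = "")
  invisible(path)
}
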