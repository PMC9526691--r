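#' Yamartino single-pass wind-direction standard deviation
#'
#' Estimates the circular standard deviation of wind direction from a single
#' pass over the data. With s and c the means of sin and cos of the
#' directions and e = sqrt(1 - (s^2 + c^2)), the estimator is
#' `asin(e) * (1 + (2/sqrt(3) - 1) * e^3)`, returned in degrees. It is bounded
#' above by about 103.92 degrees, attained for directions spread uniformly
#' around the circle.
#'
#' @param directions Wind directions in degrees (any real values; reduced
#'   modulo 360). `NA`s are dropped.
#' @return The direction standard deviation in degrees.
#' @examples
#' yamartino_sigma(c(85, 90, 95))
#' yamartino_sigma(c(0, 90, 180, 270))  # ~103.92, the upper bound
#' @export
yamartino_sigma <- function(directions) {
  directions <- directions[!is.na(directions)]
  if (length(directions) == 0) {
    stop("`directions` must contain at least one value", call. = FALSE)
  }
  th <- directions * pi / 180
  sbar <- mean(sin(th))
  cbar <- mean(cos(th))
  eps <- sqrt(max(0, 1 - (sbar^2 + cbar^2)))
  eps <- min(eps, 1)
  sigma <- asin(eps) * (1 + (2 / sqrt(3) - 1) * eps^3)
  sigma * 180 / pi
}

#' Smoothing configuration for NWR / SWIM polar grids
#'
#' @param dir_width Gaussian kernel width (sd) in direction, degrees;
#'   default 15.
#' @param speed_width Gaussian kernel width (sd) in speed, km/h; default 2.
#' @param n_dir_bins Number of direction grid cells tiling the circle;
#'   default 72 (5-degree resolution).
#' @param speed_step Speed grid resolution in km/h; default 0.5.
#' @param max_speed Upper speed of the grid; default the observed maximum.
#' @param min_weight Total kernel weight below which a cell is reported
#'   undefined (`NA`); default 0.1.
#' @param normalize If `TRUE`, [swim_estimate()] divides the grid by its
#'   maximum so values lie in `[0, 1]`.
#' @return A list of class `swim_config`.
#' @export
swim_config <- function(dir_width = 15, speed_width = 2, n_dir_bins = 72,
                        speed_step = 0.5, max_speed = NULL,
                        min_weight = 0.1, normalize = FALSE) {
  stopifnot(dir_width > 0, speed_width > 0, n_dir_bins >= 4, speed_step > 0)
  structure(list(dir_width = dir_width, speed_width = speed_width,
                 n_dir_bins = n_dir_bins, speed_step = speed_step,
                 max_speed = max_speed, min_weight = min_weight,
                 normalize = normalize),
            class = "swim_config")
}

#' Shortest angular distance between directions
#'
#' @param a,b Directions in degrees.
#' @return Wrapped distance in `[0, 180]`.
#' @export
angular_distance <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

new_polar_grid <- function(dir_centers, speed_breaks, values, kind) {
  structure(list(dir_centers = dir_centers, speed_breaks = speed_breaks,
                 values = values, kind = kind),
            class = "polar_grid")
}

#' @export
print.polar_grid <- function(x, ...) {
  cat(sprintf("<polar_grid: %s, %d direction x %d speed cells>\n",
              x$kind, length(x$dir_centers), length(x$speed_breaks) - 1))
  cat(sprintf("  speed range: %s km/h; defined cells: %d; max: %s\n",
              paste(range(x$speed_breaks[is.finite(x$speed_breaks)]),
                    collapse = "-"),
              sum(!is.na(x$values)),
              format(suppressWarnings(max(x$values, na.rm = TRUE)),
                     digits = 4)))
  invisible(x)
}

speed_centers <- function(grid) {
  br <- grid$speed_breaks
  mid <- (br[-length(br)] + br[-1]) / 2
  hi <- is.infinite(mid)
  mid[hi] <- br[-length(br)][hi] + 1  # nominal centre for an open top bin
  mid
}

# Pair daily pollen concentrations with daily wind observations.
pair_conc_wind <- function(pollen, wind) {
  stopifnot(all(c("date", "conc") %in% names(pollen)),
            all(c("date", "speed", "direction") %in% names(wind)))
  m <- dplyr::inner_join(pollen[!is.na(pollen$conc), ], wind, by = "date")
  if (nrow(m) == 0) {
    stop("pollen and wind records share no dates", call. = FALSE)
  }
  m
}

# Kernel-weighted polar estimate shared by NWR and SWIM. obs_weight is a
# per-observation multiplier (1 for plain NWR, mean(sigma)/sigma for SWIM).
polar_kernel_mean <- function(conc, speed, direction, obs_weight, cfg) {
  nd <- cfg$n_dir_bins
  dir_centers <- (seq_len(nd) - 1) * (360 / nd)
  vmax <- if (is.null(cfg$max_speed)) max(speed) else cfg$max_speed
  speed_breaks <- seq(0, vmax + cfg$speed_step, by = cfg$speed_step)
  v_centers <- (speed_breaks[-length(speed_breaks)] + speed_breaks[-1]) / 2
  # [cells x obs] kernel weights: wrapped Gaussian in direction x Gaussian in speed
  dmat <- outer(dir_centers, direction, angular_distance)
  wd <- exp(-0.5 * (dmat / cfg$dir_width)^2)
  vmat <- outer(v_centers, speed, "-")
  wv <- exp(-0.5 * (vmat / cfg$speed_width)^2)
  num <- matrix(0, nd, length(v_centers))
  den <- matrix(0, nd, length(v_centers))
  wc <- obs_weight * conc
  for (j in seq_along(v_centers)) {
    wj <- wd * rep(wv[j, ] * obs_weight, each = nd)
    den[, j] <- rowSums(wj)
    num[, j] <- as.vector(wd %*% (wv[j, ] * wc))
  }
  vals <- num / den
  vals[den < cfg$min_weight] <- NA_real_
  new_polar_grid(dir_centers, speed_breaks, vals, "concentration")
}

#' Non-parametric wind regression (NWR) concentration surface
#'
#' Estimates the expected pollen concentration as a smooth function of wind
#' direction and speed: each grid cell value is the kernel-weighted mean of
#' the daily concentrations, with a wrapped Gaussian kernel in direction and
#' a Gaussian kernel in speed. Cells receiving less total kernel weight than
#' `cfg$min_weight` are reported undefined.
#'
#' @param pollen Tibble with `date`, `conc` (one taxon or a total series).
#' @param wind Tibble with `date`, `speed` (km/h), `direction` (degrees,
#'   direction the wind comes from).
#' @param cfg A [swim_config()].
#' @return A `polar_grid` of estimated concentrations.
#' @export
nwr_estimate <- function(pollen, wind, cfg = swim_config()) {
  m <- pair_conc_wind(pollen, wind)
  polar_kernel_mean(m$conc, m$speed, m$direction,
                    rep(1, nrow(m)), cfg)
}

#' Sustained Wind Incidence Method (SWIM) concentration surface
#'
#' NWR variant that up-weights observations made under sustained (low
#' directional variability) winds: each observation's kernel weight is
#' multiplied by the ratio of the mean direction standard deviation to its
#' own, so steady advection from a source counts more than variable winds.
#' With `cfg$normalize = TRUE` the surface is divided by its maximum, giving
#' a relative source-strength map in `[0, 1]`.
#'
#' @inheritParams nwr_estimate
#' @param wind Must additionally carry `sigma_dir`, the per-period Yamartino
#'   direction standard deviation in degrees. Zero values (perfectly steady
#'   wind) are replaced by the smallest positive sigma observed, with a
#'   warning, to avoid infinite weight.
#' @return A `polar_grid` of estimated (optionally max-normalised)
#'   concentrations.
#' @export
swim_estimate <- function(pollen, wind, cfg = swim_config()) {
  stopifnot("sigma_dir" %in% names(wind))
  m <- pair_conc_wind(pollen, wind)
  sig <- m$sigma_dir
  if (any(sig <= 0)) {
    pos <- sig[sig > 0]
    if (length(pos) == 0) {
      warning("all sigma_dir are zero; sustained-wind weights disabled",
              call. = FALSE)
      sig <- rep(1, length(sig))
    } else {
      warning(sum(sig <= 0), " zero sigma_dir value(s) replaced by the ",
              "smallest positive sigma", call. = FALSE)
      sig[sig <= 0] <- min(pos)
    }
  }
  w <- mean(sig) / sig
  grid <- polar_kernel_mean(m$conc, m$speed, m$direction, w, cfg)
  if (all(m$conc == 0)) {
    warning("all concentrations are zero; max-normalisation skipped",
            call. = FALSE)
    return(grid)
  }
  if (isTRUE(cfg$normalize)) {
    grid$values <- grid$values / max(grid$values, na.rm = TRUE)
  }
  grid
}

compass_names <- function(n) {
  full <- c("N", "NNE", "NE", "ENE", "E", "ESE", "SE", "SSE",
            "S", "SSW", "SW", "WSW", "W", "WNW", "NW", "NNW")
  if (n == 16) full else if (n == 8) full[seq(1, 16, by = 2)]
  else if (n == 4) full[seq(1, 16, by = 4)]
  else as.character(round((seq_len(n) - 1) * 360 / n))
}

# sector index (1 = N) of a direction, sectors centred on compass points
sector_index <- function(direction, n_sectors) {
  w <- 360 / n_sectors
  (floor(((direction + w / 2) %% 360) / w) %% n_sectors) + 1L
}

#' Joint-probability wind rose
#'
#' Bins wind observations into (direction sector, speed band) cells; the cell
#' value is the fraction of observations falling in the cell, so the grid
#' sums to one. Sectors are centred on the compass points (the N sector spans
#' -11.25 to +11.25 degrees with 16 sectors).
#'
#' @param wind Tibble with `speed` (km/h) and `direction` (degrees).
#' @param n_sectors Number of direction sectors; default 16.
#' @param speed_breaks Speed band edges in km/h; default
#'   `c(0, 2, 4, 8, 12, Inf)`, the conventional rose rings.
#' @return A `polar_grid` of probabilities.
#' @export
joint_probability_rose <- function(wind, n_sectors = 16,
                                   speed_breaks = c(0, 2, 4, 8, 12, Inf)) {
  stopifnot(nrow(wind) >= 1)
  si <- sector_index(wind$direction, n_sectors)
  vi <- findInterval(wind$speed, speed_breaks, rightmost.closed = TRUE)
  vi[vi < 1] <- 1L
  vi[vi > length(speed_breaks) - 1] <- length(speed_breaks) - 1L
  counts <- matrix(0, n_sectors, length(speed_breaks) - 1)
  for (k in seq_along(si)) counts[si[k], vi[k]] <- counts[si[k], vi[k]] + 1
  dir_centers <- (seq_len(n_sectors) - 1) * (360 / n_sectors)
  grid <- new_polar_grid(dir_centers, speed_breaks,
                         counts / nrow(wind), "probability")
  grid
}

#' Dominant source sector of a polar grid
#'
#' Locates the grid maximum and reports the compass sector and speed band it
#' falls in. Ties are broken towards the lowest speed band, then the first
#' sector clockwise from North.
#'
#' @param grid A `polar_grid` (from [nwr_estimate()], [swim_estimate()] or
#'   [joint_probability_rose()]).
#' @param n_sectors Number of compass sectors to report; default 8
#'   (N, NE, ..., NW), centred on the compass points.
#' @return A list with `sector` (name), `sector_index`, `direction` (grid
#'   cell centre, degrees), `speed_band` (`c(lo, hi)` km/h) and `value`.
#' @export
dominant_sector <- function(grid, n_sectors = 8) {
  v <- grid$values
  if (all(is.na(v))) stop("grid has no defined cells", call. = FALSE)
  mx <- max(v, na.rm = TRUE)
  hit <- which(v == mx, arr.ind = TRUE)
  # ties: lowest speed band first, then first sector clockwise from N
  sec_of_row <- sector_index(grid$dir_centers[hit[, 1]], n_sectors)
  ord <- order(hit[, 2], sec_of_row)
  best <- hit[ord[1], ]
  si <- sector_index(grid$dir_centers[best[1]], n_sectors)
  list(sector = compass_names(n_sectors)[si],
       sector_index = si,
       direction = grid$dir_centers[best[1]],
       speed_band = c(grid$speed_breaks[best[2]],
                      grid$speed_breaks[best[2] + 1]),
       value = mx)
}

#' Write a polar grid as delimited text
#'
#' One row per (direction, speed) cell: direction centre, speed band edges
#' and value.
#'
#' @param grid A `polar_grid`.
#' @param path Output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_polar_grid <- function(grid, path) {
  ns <- length(grid$speed_breaks) - 1
  out <- tibble::tibble(
    direction = rep(grid$dir_centers, times = ns),
    speed_lo = rep(grid$speed_breaks[-(ns + 1)], each = length(grid$dir_centers)),
    speed_hi = rep(grid$speed_breaks[-1], each = length(grid$dir_centers)),
    value = round(as.vector(grid$values), 8))
  readr::write_delim(out, path, delim = delim_for(path), na = "")
  invisible(path)
}
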