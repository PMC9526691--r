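#' Lilliefors normality test
#'
#' Kolmogorov-Smirnov distance between the empirical CDF and a normal CDF
#' with mean and standard deviation estimated from the same sample. The
#' p-value comes either from the analytic approximation implemented in
#' \pkg{nortest} (default) or from a seeded Monte-Carlo null in which the
#' statistic is recomputed on standard-normal samples of the same size.
#' In this pipeline the test is a screening report: daily pollen data
#' essentially never pass it, which is why the downstream association
#' analysis is rank-based.
#'
#' @param values Numeric sample, `n >= 4`, non-constant. `NA`s dropped.
#' @param method `"analytic"` (nortest) or `"monte-carlo"`.
#' @param n_rep Monte-Carlo replicates (default 2000).
#' @param seed Optional seed for the Monte-Carlo null.
#' @return A list with `statistic`, `p_value`, `n` and `method`.
#' @export
lilliefors_test <- function(values, method = c("analytic", "monte-carlo"),
                            n_rep = 2000, seed = NULL) {
  method <- match.arg(method)
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 4) stop("Lilliefors test needs n >= 4", call. = FALSE)
  if (sd(values) == 0) {
    stop("constant input: standard deviation is zero", call. = FALSE)
  }
  if (method == "analytic") {
    res <- nortest::lillie.test(values)
    return(list(statistic = unname(res$statistic),
                p_value = res$p.value, n = n, method = method))
  }
  d_obs <- lillie_statistic(values)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  d_null <- vapply(seq_len(n_rep),
                   function(i) lillie_statistic(rnorm(n)), numeric(1))
  list(statistic = d_obs,
       p_value = (1 + sum(d_null >= d_obs)) / (n_rep + 1),
       n = n, method = method)
}

# KS distance to the normal with estimated parameters
lillie_statistic <- function(x) {
  n <- length(x)
  x <- sort(x)
  p <- pnorm((x - mean(x)) / sd(x))
  max(seq_len(n) / n - p, p - (seq_len(n) - 1) / n)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Rank correlation between two paired samples: rho is the Pearson
#' correlation of the average ranks (ties share their average rank) and the
#' p-value comes from the t-approximation with n - 2 degrees of freedom.
#' Fewer than 3 complete pairs, or zero rank variance in either variable,
#' yields an undefined (flagged) result rather than an error.
#'
#' @param x,y Paired numeric vectors; incomplete pairs are dropped.
#' @return A list with `rho`, `p_value`, `n` and `defined`.
#' @examples
#' spearman_test(1:5, c(2, 1, 4, 3, 5))  # rho = 0.7
#' @export
spearman_test <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  undef <- list(rho = NA_real_, p_value = NA_real_, n = n, defined = FALSE)
  if (n < 3) return(undef)
  if (sd(rank(x)) == 0 || sd(rank(y)) == 0) return(undef)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n,
       defined = TRUE)
}

met_param_cols <- function(met) {
  setdiff(names(met)[vapply(met, is.numeric, logical(1))], "date")
}

#' Pollen-meteorology correlation matrix restricted to the Main Pollen Season
#'
#' For every taxon with a delimited MPS, computes the Spearman correlation
#' between its daily concentration and each meteorological parameter using
#' only the days inside `[start_date, end_date]` of that taxon's season.
#' Derived trailing-mean parameters already present in `met` (e.g. `Tmean_10`
#' from [add_lagged_means()]) are treated like any other column. Taxa without
#' a delimited season are skipped with a warning.
#'
#' @param pollen Long multi-taxon pollen tibble.
#' @param met Meteorology tibble (`date` plus numeric parameter columns).
#' @param seasons Season table from [season_table()] or rows from
#'   [main_pollen_season()].
#' @param alpha Significance level; default 0.05.
#' @param adjust `"none"` (default, per-pair reporting) or `"BH"` for
#'   Benjamini-Hochberg adjustment across all pairs.
#' @return Tibble with `taxon`, `parameter`, `scope`, `rho`, `p_value`, `n`,
#'   `defined`, `significant`; one row per (taxon, parameter).
#' @export
mps_correlation_matrix <- function(pollen, met, seasons, alpha = 0.05,
                                   adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  params <- met_param_cols(met)
  rows <- list()
  for (i in seq_len(nrow(seasons))) {
    sn <- seasons[i, ]
    if (!isTRUE(sn$season_defined)) {
      warning("no delimited season for ", sn$taxon, " ", sn$year,
              "; skipped", call. = FALSE)
      next
    }
    px <- pollen[pollen$taxon == sn$taxon &
                   pollen$date >= sn$start_date &
                   pollen$date <= sn$end_date, ]
    joined <- dplyr::inner_join(px, met, by = "date")
    for (p in params) {
      st <- spearman_test(joined$conc, joined[[p]])
      rows[[length(rows) + 1]] <- tibble::tibble(
        taxon = sn$taxon, parameter = p,
        scope = paste0("MPS-", sn$year),
        rho = st$rho, p_value = st$p_value, n = st$n, defined = st$defined)
    }
  }
  finish_correlations(dplyr::bind_rows(rows), alpha, adjust)
}

#' Monthly pollen-meteorology correlations
#'
#' Spearman correlations between a (typically total) pollen series and each
#' meteorological parameter, computed separately per calendar month of each
#' year. Months with fewer than `min_days` complete pairs for a parameter
#' are skipped with a warning.
#'
#' @param pollen Single-taxon (or total) pollen tibble.
#' @param met Meteorology tibble.
#' @param alpha Significance level; default 0.05.
#' @param min_days Minimum complete pairs per month; default 10.
#' @param adjust `"none"` or `"BH"`.
#' @return Tibble as in [mps_correlation_matrix()] with `scope` = `"YYYY-MM"`.
#' @export
monthly_correlation <- function(pollen, met, alpha = 0.05, min_days = 10,
                                adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  taxon <- one_taxon(pollen)
  joined <- dplyr::inner_join(pollen[, c("date", "conc")], met, by = "date")
  joined$scope <- format(joined$date, "%Y-%m")
  params <- met_param_cols(met)
  rows <- list()
  for (mo in sort(unique(joined$scope))) {
    sub <- joined[joined$scope == mo, ]
    for (p in params) {
      n_ok <- sum(!is.na(sub$conc) & !is.na(sub[[p]]))
      if (n_ok < min_days) {
        warning(sprintf("%s / %s: only %d paired days (< %d); skipped",
                        mo, p, n_ok, min_days), call. = FALSE)
        next
      }
      st <- spearman_test(sub$conc, sub[[p]])
      rows[[length(rows) + 1]] <- tibble::tibble(
        taxon = taxon, parameter = p, scope = mo,
        rho = st$rho, p_value = st$p_value, n = st$n, defined = st$defined)
    }
  }
  finish_correlations(dplyr::bind_rows(rows), alpha, adjust)
}

finish_correlations <- function(tbl, alpha, adjust) {
  if (nrow(tbl) == 0) {
    return(tibble::tibble(taxon = character(), parameter = character(),
                          scope = character(), rho = double(),
                          p_value = double(), n = integer(),
                          defined = logical(), significant = logical()))
  }
  p <- tbl$p_value
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  tbl$significant <- !is.na(p) & p < alpha
  tbl
}

#' Export a correlation matrix as a taxa x parameters table
#'
#' Writes rho values (rounded to 2 decimals) with a `*` marker on significant
#' pairs, taxa as rows and meteorological parameters as columns, one file per
#' scope value.
#'
#' @param tbl Output of [mps_correlation_matrix()] or [monthly_correlation()].
#' @param path Output path; the scope is interpolated before the extension
#'   when `tbl` spans several scopes.
#' @return Written paths, invisibly.
#' @export
write_correlation_table <- function(tbl, path) {
  scopes <- unique(tbl$scope)
  paths <- character(0)
  for (sc in scopes) {
    sub <- tbl[tbl$scope == sc, ]
    sub$cell <- ifelse(sub$defined,
                       paste0(sprintf("%.2f", sub$rho),
                              ifelse(sub$significant, "*", "")),
                       "")
    wide <- tidyr::pivot_wider(sub[, c("taxon", "parameter", "cell")],
                               names_from = "parameter",
                               values_from = "cell")
    p <- if (length(scopes) == 1) path else
      sub("(\\.[a-z]+)$", paste0("_", sc, "\\1"), path)
    readr::write_delim(wide, p, delim = delim_for(p), na = "")
    paths <- c(paths, p)
  }
  invisible(paths)
}
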