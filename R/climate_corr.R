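#' Align monthly climate to chronology years on a 24-slot month axis
#'
#' For each growth year t the row holds the 12 monthly values of calendar
#' year t-1 (slots 1-12, previous-year January..December) followed by those
#' of year t (slots 13-24). Years without climate coverage stay missing.
#'
#' @param clim A `qwa_climate` object.
#' @param years Chronology years.
#' @return Numeric matrix `length(years)` x 24 with slot labels from
#'   [month_slot_labels()].
#' @export
align_climate <- function(clim, years) {
  stopifnot(inherits(clim, "qwa_climate"))
  m <- matrix(NA_real_, length(years), 24L,
              dimnames = list(years, month_slot_labels()))
  m[, 1:12] <- clim$values[match(years - 1L, clim$years), , drop = FALSE]
  m[, 13:24] <- clim$values[match(years, clim$years), , drop = FALSE]
  if (all(is.na(m))) stop("no overlap between climate and chronology years")
  m
}

# aggregate of the L month slots ending at `end` for every year; rows with
# any missing month, or windows reaching before slot 1, are NA
.window_series <- function(aligned, end, len, aggregate) {
  start <- end - len + 1L
  if (start < 1L) return(rep(NA_real_, nrow(aligned)))
  sub <- aligned[, start:end, drop = FALSE]
  cnt <- rowSums(is.finite(sub))
  v <- if (aggregate == "sum") rowSums(sub) else rowMeans(sub)
  v[cnt < len] <- NA_real_
  v
}

# Pearson r, exact two-tailed t-transform p, and n on pairwise-complete
# observations; optional first-difference filter applied to both series
.cor_cell <- function(x, y, min_n = 10L, filter = "none") {
  if (filter == "first_diff") {
    x <- diff(x)
    y <- diff(y)
  }
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < min_n || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    return(c(r = NA_real_, p = NA_real_, n = n))
  r <- stats::cor(x[ok], y[ok])
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
  }
  c(r = r, p = p, n = n)
}

.default_aggregate <- function(variable) {
  if (variable %in% c("precip", "prec", "precipitation")) "sum" else "mean"
}

# core scan shared by monthly_correlations() and seasonal_scan(), so the
# L = 1 row of the scan reproduces the monthly grid bit for bit
.scan_core <- function(chron, climate, lengths, slots, aggregate, alpha,
                       min_n, filter, p_adjust) {
  stopifnot(is.data.frame(chron), "year" %in% names(chron))
  series_cols <- setdiff(names(chron), "year")
  if (!length(series_cols)) stop("chron needs at least one value column besides `year`")
  if (inherits(climate, "qwa_climate")) {
    climate <- stats::setNames(list(climate), climate$variable)
  }
  out <- list()
  for (v in names(climate)) {
    clim <- climate[[v]]
    agg <- aggregate %||% .default_aggregate(clim$variable)
    aligned <- align_climate(clim, chron$year)
    for (cc in series_cols) {
      for (len in lengths) {
        for (end in slots) {
          w <- .window_series(aligned, end, len, agg)
          cell <- .cor_cell(chron[[cc]], w, min_n, filter)
          out[[length(out) + 1L]] <- data.frame(
            chronology = cc, variable = v, end_slot = end,
            window = .window_label(max(1L, end - len + 1L), end),
            length = len, aggregate = agg,
            r = cell[["r"]], p = cell[["p"]], n = as.integer(cell[["n"]]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  if (p_adjust == "BH") {
    for (key in unique(paste(res$chronology, res$variable))) {
      i <- paste(res$chronology, res$variable) == key
      res$p[i] <- stats::p.adjust(res$p[i], method = "BH")
    }
  }
  res$significant <- !is.na(res$p) & res$p <= alpha
  rownames(res) <- NULL
  res
}

#' Correlations of chronologies with single months of climate
#'
#' Pearson correlation and exact two-tailed p-value of each chronology with
#' each monthly climate slot, on pairwise-complete years. Following common
#' practice in exploratory dendroclimatic screening, no multiple-testing
#' adjustment is applied by default; Benjamini-Hochberg adjustment is
#' available via `p_adjust = "BH"`.
#'
#' @param chron Data frame with a `year` column plus one numeric column per
#'   chronology.
#' @param climate A `qwa_climate` or a named list of them.
#' @param alpha Significance level for the `significant` flag (default
#'   0.05).
#' @param slots Month slots analysed (default previous-March..current-
#'   October, slots 3:22 of [month_slot_labels()]).
#' @param min_n Minimum overlapping years per cell (default 10); cells with
#'   less are reported missing.
#' @param filter `"none"` or `"first_diff"` (difference both series before
#'   correlating, keeping only high-frequency variance).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return Tidy data frame: `chronology`, `variable`, `slot`, `month`, `r`,
#'   `p`, `n`, `significant`.
#' @export
monthly_correlations <- function(chron, climate, alpha = 0.05, slots = 3:22,
                                 min_n = 10L, filter = c("none", "first_diff"),
                                 p_adjust = c("none", "BH")) {
  filter <- match.arg(filter)
  p_adjust <- match.arg(p_adjust)
  res <- .scan_core(chron, climate, lengths = 1L, slots = slots,
                    aggregate = NULL, alpha = alpha, min_n = min_n,
                    filter = filter, p_adjust = p_adjust)
  data.frame(chronology = res$chronology, variable = res$variable,
             slot = res$end_slot, month = res$window, r = res$r, p = res$p,
             n = res$n, significant = res$significant,
             stringsAsFactors = FALSE)
}

#' Seasonal-window correlation scan
#'
#' For every window length L and end slot, the L months ending there are
#' aggregated (totals for precipitation, means for temperature and drought
#' indices) and correlated with the chronology. The L = 1 row reproduces
#' [monthly_correlations()] exactly. Windows reaching before the start of
#' the 24-slot axis are reported missing.
#'
#' @inheritParams monthly_correlations
#' @param lengths Window lengths in months (default 1:19).
#' @param aggregate `NULL` (choose by variable) or `"mean"`/`"sum"`.
#' @return Tidy data frame: `chronology`, `variable`, `end_slot`, `window`,
#'   `length`, `aggregate`, `r`, `p`, `n`, `significant`.
#' @export
seasonal_scan <- function(chron, climate, lengths = 1:19, slots = 3:22,
                          aggregate = NULL, alpha = 0.05, min_n = 10L,
                          filter = c("none", "first_diff"),
                          p_adjust = c("none", "BH")) {
  filter <- match.arg(filter)
  p_adjust <- match.arg(p_adjust)
  stopifnot(all(lengths >= 1L))
  .scan_core(chron, climate, lengths = lengths, slots = slots,
             aggregate = aggregate, alpha = alpha, min_n = min_n,
             filter = filter, p_adjust = p_adjust)
}

#' Optimal season per chronology and climate variable
#'
#' Selects, within each (chronology, variable) group of a seasonal scan, the
#' window maximizing |r| (sign retained). Ties are broken towards the
#' shorter window, then the later end month.
#'
#' @param scan Output of [seasonal_scan()].
#' @return One row per (chronology, variable) with the winning window.
#' @export
best_season <- function(scan) {
  scan <- scan[!is.na(scan$r), , drop = FALSE]
  if (!nrow(scan)) stop("seasonal scan holds no non-missing cells")
  pick <- function(d) {
    d[order(-abs(d$r), d$length, -d$end_slot), , drop = FALSE][1L, , drop = FALSE]
  }
  res <- do.call(rbind, lapply(
    split(scan, paste(scan$chronology, scan$variable)), pick))
  rownames(res) <- NULL
  res
}

#' Critical Pearson correlation at a given significance level
#'
#' Inverts the t-transform of r: r* = sqrt(t*^2 / (t*^2 + n - 2)) with t*
#' the two-tailed Student-t critical value at `alpha` on n - 2 degrees of
#' freedom.
#'
#' @param n Number of paired observations (>= 4).
#' @param alpha Significance level (default 0.05).
#' @return The absolute correlation threshold.
#' @export
#' @examples
#' critical_r(57) # 0.261
critical_r <- function(n, alpha = 0.05) {
  if (n < 4L) stop("need n >= 4")
  tq <- stats::qt(1 - alpha / 2, n - 2)
  sqrt(tq^2 / (tq^2 + n - 2))
}

#' Spatial field correlation of a chronology with gridded climate
#'
#' Correlates one chronology with a seasonal aggregate of a gridded monthly
#' field, cell by cell, returning the correlation map with exact two-tailed
#' p-values and a significance mask. Cells with insufficient overlap are
#' missing.
#'
#' @param chron Data frame with columns `year` and exactly one chronology
#'   column.
#' @param grid A `qwa_grid` object.
#' @param end_slot,win_length Window definition (end slot on the 24-slot
#'   month axis of [month_slot_labels()], and length in months).
#' @param alpha Significance level for the mask.
#' @param aggregate `NULL` (choose by variable) or `"mean"`/`"sum"`.
#' @param min_n Minimum overlapping years per cell.
#' @param filter `"none"` or `"first_diff"`.
#' @return Tidy data frame: `lat`, `lon`, `r`, `p`, `n`, `significant`.
#' @export
spatial_correlation <- function(chron, grid, end_slot, win_length, alpha = 0.05,
                                aggregate = NULL, min_n = 10L,
                                filter = c("none", "first_diff")) {
  filter <- match.arg(filter)
  stopifnot(inherits(grid, "qwa_grid"))
  series_cols <- setdiff(names(chron), "year")
  if (length(series_cols) != 1L)
    stop("chron must have exactly one chronology column")
  agg <- aggregate %||% .default_aggregate(grid$variable)
  x <- chron[[series_cols]]
  out <- vector("list", length(grid$lats) * length(grid$lons))
  k <- 0L
  for (i in seq_along(grid$lats)) {
    for (j in seq_along(grid$lons)) {
      cellclim <- qwa_climate(grid$variable, grid$years,
                              grid$values[, , i, j, drop = TRUE])
      aligned <- align_climate(cellclim, chron$year)
      w <- .window_series(aligned, end_slot, win_length, agg)
      cell <- .cor_cell(x, w, min_n, filter)
      k <- k + 1L
      out[[k]] <- data.frame(lat = grid$lats[i], lon = grid$lons[j],
                             r = cell[["r"]], p = cell[["p"]],
                             n = as.integer(cell[["n"]]))
    }
  }
  res <- do.call(rbind, out)
  res$significant <- !is.na(res$p) & res$p <= alpha
  res
}
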