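#' Mean interseries correlation (Rbar)
#'
#' Arithmetic mean of all pairwise Pearson correlations between tree series,
#' each computed over pairwise-complete years (optionally restricted to a
#' period). Pairs overlapping fewer than `min_overlap` years are excluded
#' with a warning; if every pair is excluded, an error is raised.
#'
#' @param series Numeric matrix, years as rows (rownames = calendar years),
#'   one column per tree.
#' @param period Optional `c(first, last)` year span.
#' @param min_overlap Minimum pairwise overlap in years (default 10).
#' @return The mean interseries correlation.
#' @export
rbar <- function(series, period = NULL, min_overlap = 10L) {
  series <- as.matrix(series)
  if (ncol(series) < 2L) stop("need at least 2 series")
  if (!is.null(period)) {
    yrs <- as.integer(rownames(series))
    if (is.null(rownames(series))) stop("series needs year rownames to apply a period")
    series <- series[yrs >= period[1L] & yrs <= period[2L], , drop = FALSE]
  }
  nc <- ncol(series)
  rs <- c()
  excluded <- 0L
  for (i in seq_len(nc - 1L)) {
    for (j in (i + 1L):nc) {
      ok <- is.finite(series[, i]) & is.finite(series[, j])
      if (sum(ok) < min_overlap) {
        excluded <- excluded + 1L
        next
      }
      rs <- c(rs, stats::cor(series[ok, i], series[ok, j]))
    }
  }
  if (excluded > 0L)
    warning(excluded, " series pair(s) excluded (overlap < ", min_overlap, " years)")
  if (!length(rs)) stop("no series pair with sufficient overlap")
  mean(rs)
}

#' Expressed population signal (EPS)
#'
#' How well a finite-sample mean chronology represents the hypothetical
#' infinite-population chronology, from the mean interseries correlation:
#' EPS = n rbar / (n rbar + (1 - rbar)).
#'
#' @param rbar_value Mean interseries correlation, in (-1, 1].
#' @param n_trees Number of tree series (>= 2).
#' @return EPS in `[0, 1]` for non-negative `rbar_value`.
#' @seealso [snr()]; EPS = SNR/(1 + SNR).
#' @export
#' @examples
#' eps(0.283, 6) # 0.703
eps <- function(rbar_value, n_trees) {
  stopifnot(n_trees >= 2, rbar_value > -1, rbar_value <= 1)
  denom <- n_trees * rbar_value + (1 - rbar_value)
  if (any(denom <= 0)) stop("EPS undefined: n*rbar + (1 - rbar) <= 0")
  n_trees * rbar_value / denom
}

#' Signal-to-noise ratio (SNR)
#'
#' SNR = n rbar / (1 - rbar); satisfies EPS = SNR/(1 + SNR) by construction.
#'
#' @inheritParams eps
#' @return The signal-to-noise ratio (>= 0 for non-negative `rbar_value`).
#' @export
snr <- function(rbar_value, n_trees) {
  stopifnot(n_trees >= 2, rbar_value > -1)
  if (any(rbar_value >= 1)) stop("SNR infinite at rbar = 1")
  n_trees * rbar_value / (1 - rbar_value)
}

#' Lag-1 autocorrelation
#'
#' Pearson correlation of the series with itself shifted by one year, the
#' standard persistence statistic of tree-ring chronologies.
#'
#' @param x Numeric series (length >= 10 after removing missing values from
#'   the ends; internal missing values are not allowed).
#' @return Lag-1 autocorrelation in `[-1, 1]`.
#' @export
ar1 <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 10L) stop("need at least 10 values for ar1")
  if (stats::sd(x) == 0) stop("ar1 undefined for a constant series")
  stats::cor(x[-n], x[-1L])
}

#' Site chronologies per intra-ring sector
#'
#' For each sector, every tree's annual series is z-transformed over the
#' common period and the site chronology is the cross-tree mean of the
#' z-scores per year (arithmetic by default; Tukey biweight optional).
#' Sample depth (trees with data) is recorded per year; a year with no tree
#' is missing, never zero. Trees that are constant or nearly absent over the
#' period are dropped with a warning.
#'
#' @param sm A `qwa_sector_matrix` from [build_sector_matrix()].
#' @param parameter `"ld"` or `"cwt"`.
#' @param method `"arithmetic"` (the convention for anatomical z-scores) or
#'   `"biweight"`.
#' @param period Optional `c(first, last)` scaling period (default: the
#'   matrix's full year span).
#' @return A long data frame of class `qwa_chronology` with columns
#'   `sector`, `year`, `index`, `depth`; attribute `method` and `period`.
#' @export
sector_chronology <- function(sm, parameter = c("ld", "cwt"),
                              method = c("arithmetic", "biweight"),
                              period = NULL) {
  parameter <- match.arg(parameter)
  method <- match.arg(method)
  period <- period %||% range(sm$years)
  labs <- .sector_labels(sm$n_sectors)
  out <- list()
  for (s in seq_len(sm$n_sectors)) {
    X <- sector_series(sm, s, parameter)
    Z <- matrix(NA_real_, nrow(X), ncol(X), dimnames = dimnames(X))
    for (j in seq_len(ncol(X))) {
      zj <- try(ztransform(X[, j], years = sm$years, period = period),
                silent = TRUE)
      if (inherits(zj, "try-error")) {
        warning("tree ", colnames(X)[j], " dropped from sector ", labs[s],
                ": ", attr(zj, "condition")$message)
        next
      }
      Z[, j] <- zj
    }
    depth <- rowSums(is.finite(Z))
    index <- ifelse(depth > 0L,
                    apply(Z, 1L, function(r) {
                      r <- r[is.finite(r)]
                      if (!length(r)) return(NA_real_)
                      if (method == "biweight") biweight_mean(r) else mean(r)
                    }),
                    NA_real_)
    out[[s]] <- data.frame(sector = labs[s], year = sm$years, index = index,
                           depth = as.integer(depth), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "method") <- method
  attr(res, "period") <- period
  class(res) <- c("qwa_chronology", "data.frame")
  res
}

#' Descriptive and signal statistics per sector
#'
#' The standard chronology summary table: per sector the mean and SD of the
#' raw values (micrometers; SD of the annual site means), the lag-1
#' autocorrelation of the mean z-score chronology, the mean interseries
#' correlation (Rbar, pairwise-complete), and EPS and SNR derived from Rbar
#' and the number of trees. A cross-sector `Mean` row holds the arithmetic
#' mean of the per-sector entries.
#'
#' @inheritParams sector_chronology
#' @param min_overlap Minimum pairwise overlap for [rbar()].
#' @return Data frame with columns `sector`, `mean`, `sd`, `ar1`, `rbar`,
#'   `eps`, `snr`, `n_trees`; last row `Mean`.
#' @export
chronology_stats <- function(sm, parameter = c("ld", "cwt"), period = NULL,
                             min_overlap = 10L) {
  parameter <- match.arg(parameter)
  period <- period %||% range(sm$years)
  labs <- .sector_labels(sm$n_sectors)
  inper <- sm$years >= period[1L] & sm$years <= period[2L]
  rows <- list()
  for (s in seq_len(sm$n_sectors)) {
    X <- sector_series(sm, s, parameter)[inper, , drop = FALSE]
    n_trees <- sum(colSums(is.finite(X)) >= 3L)
    rb <- rbar(X, min_overlap = min_overlap)
    Z <- apply(X, 2L, function(col) as.numeric(scale(col)))
    chron <- rowMeans(Z, na.rm = TRUE)
    rows[[s]] <- data.frame(
      sector = labs[s],
      mean = mean(X, na.rm = TRUE),
      sd = stats::sd(rowMeans(X, na.rm = TRUE), na.rm = TRUE),
      ar1 = ar1(chron),
      rbar = rb,
      eps = eps(rb, n_trees),
      snr = snr(rb, n_trees),
      n_trees = n_trees,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  num <- tab[, c("mean", "sd", "ar1", "rbar", "eps", "snr", "n_trees")]
  tab <- rbind(tab, data.frame(sector = "Mean", as.list(colMeans(num)),
                               stringsAsFactors = FALSE))
  rownames(tab) <- NULL
  tab
}

#' Two-group ANOVA around a split year
#'
#' One-way fixed-effects ANOVA comparing the years before the split year
#' (group 1) with the years from the split year onward (group 2); with two
#' groups this equals a pooled-variance two-sample t-test (F = t^2). Used to
#' test for a level shift in a chronology, e.g. a post-warming decline.
#'
#' @param values Annual values.
#' @param years Calendar years (same length).
#' @param split_year First year of group 2 (default 1992).
#' @return A list: `F`, `p`, `means` (named group means), `n` (group sizes),
#'   `split_year`.
#' @export
#' @examples
#' split_group_test(c(1, 2, 3, 4, 5, 6), 1990:1995, 1993) # F = 13.5
split_group_test <- function(values, years, split_year = 1992L) {
  stopifnot(length(values) == length(years))
  ok <- is.finite(values)
  values <- values[ok]
  years <- years[ok]
  g <- factor(ifelse(years < split_year, "group1", "group2"),
              levels = c("group1", "group2"))
  if (any(table(g) < 3L)) stop("each group needs at least 3 years")
  a <- stats::anova(stats::lm(values ~ g))
  list(F = a[["F value"]][1L], p = a[["Pr(>F)"]][1L],
       means = c(tapply(values, g, mean)), n = as.integer(table(g)),
       split_year = split_year)
}
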