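#' z-transform an annual series
#'
#' Standardizes a series to mean 0 and sample standard deviation 1
#' (denominator n - 1) computed over a scaling period; values outside the
#' period are scaled with the period's mean and SD. This removes level and
#' spread differences between trees before averaging them into a site
#' chronology.
#'
#' @param x Numeric series.
#' @param years Calendar years of `x` (required if `period` is given).
#' @param period Optional length-2 year span `c(first, last)` over which
#'   mean and SD are computed; default: all of `x`.
#' @return The z-scored series (same length as `x`).
#' @export
ztransform <- function(x, years = NULL, period = NULL) {
  if (is.null(period)) {
    inper <- rep(TRUE, length(x))
  } else {
    if (is.null(years)) stop("`years` is required when `period` is given")
    stopifnot(length(years) == length(x))
    inper <- years >= period[1L] & years <= period[2L]
  }
  v <- x[inper]
  if (sum(is.finite(v)) < 3L) stop("need at least 3 non-missing values to z-transform")
  m <- mean(v, na.rm = TRUE)
  s <- stats::sd(v, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("cannot z-transform a constant series (SD = 0)")
  (x - m) / s
}

#' First-order differences of an annual series
#'
#' High-pass filter used to strip low-frequency variance before correlation
#' analysis: d_t = x_(t+1) - x_t, labelled with the year of x_(t+1).
#'
#' @param x Numeric series (length >= 2).
#' @param years Optional calendar years; if given, the result carries the
#'   years of the later observation as names.
#' @return Numeric series of length n - 1.
#' @export
first_difference <- function(x, years = NULL) {
  if (length(x) < 2L) stop("need at least 2 values to difference")
  d <- diff(x)
  if (!is.null(years)) names(d) <- years[-1L]
  d
}

#' Tukey biweight robust mean
#'
#' Robust location estimate used for ring-width site chronologies because it
#' discounts outlying trees. Iterated from the median with fixed scale
#' S = median absolute deviation; weights w = (1 - u^2)^2 for |u| < 1 with
#' u = (x - T)/(c S), 0 otherwise, until the estimate changes by less than
#' 1e-6. When S = 0 (e.g. all values identical) the median is returned
#' without iteration.
#'
#' @param x Numeric values (at least one finite).
#' @param c Tuning constant (default 9, the dendrochronological standard).
#' @return The biweight location.
#' @export
biweight_mean <- function(x, c = 9) {
  stopifnot(c > 0)
  x <- x[is.finite(x)]
  if (!length(x)) stop("no finite values")
  S <- stats::mad(x, constant = 1)
  T0 <- stats::median(x)
  if (S == 0) return(T0)
  repeat {
    u <- (x - T0) / (c * S)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    T1 <- sum(w * x) / sum(w)
    if (abs(T1 - T0) < 1e-6) return(T1)
    T0 <- T1
  }
}

#' Variance-stabilizing power transform for ring widths
#'
#' Estimates the optimal power p = 1 - b, where b is the slope of the
#' regression of log local spread |x_t - x_(t-1)| on log local mean
#' (x_t + x_(t-1))/2 over all years with positive spread. The series is
#' returned as x^p (p clamped to [-1, 1]); when |p| < 0.05 the log transform
#' is applied instead. Homogenizes the level-dependence of variance before
#' detrending.
#'
#' @param x Positive ring widths (length >= 10).
#' @return Transformed series with attributes `power` (the clamped p) and
#'   `log` (`TRUE` if log was applied).
#' @export
power_transform <- function(x) {
  if (length(x) < 10L) stop("need at least 10 values")
  if (any(!is.finite(x) | x <= 0)) stop("ring widths must be positive and finite")
  spread <- abs(diff(x))
  level <- (x[-1L] + x[-length(x)]) / 2
  ok <- spread > 0
  if (sum(ok) < 3L) stop("fewer than 3 positive-spread year pairs; cannot estimate power")
  b <- stats::coef(stats::lm(log(spread[ok]) ~ log(level[ok])))[[2L]]
  p <- min(1, max(-1, 1 - b))
  if (abs(p) < 0.05) {
    out <- log(x)
    attr(out, "power") <- p
    attr(out, "log") <- TRUE
  } else {
    out <- x^p
    attr(out, "power") <- p
    attr(out, "log") <- FALSE
  }
  out
}

# Natural cubic smoothing spline on equally spaced points (Reinsch form):
# minimizes sum (y - g)^2 + mu * integral g''^2. Dense solve; series are
# decades-long, not thousands.
.reinsch_smooth <- function(y, mu) {
  n <- length(y)
  if (n < 4L) return(y)
  Q <- matrix(0, n, n - 2L)
  for (j in seq_len(n - 2L)) Q[j:(j + 2L), j] <- c(1, -2, 1)
  R <- diag(2 / 3, n - 2L)
  if (n > 4L) {
    idx <- cbind(seq_len(n - 3L), seq_len(n - 3L) + 1L)
    R[idx] <- 1 / 6
    R[idx[, 2:1, drop = FALSE]] <- 1 / 6
  } else if (n == 4L) {
    R[1, 2] <- R[2, 1] <- 1 / 6
  }
  z <- solve(R + mu * crossprod(Q), crossprod(Q, y))
  as.numeric(y - mu * Q %*% z)
}

# smoothing parameter giving frequency-response amplitude f at wavelength
# lambda (in sample steps)
.spline_mu <- function(lambda, f = 0.5) {
  w0 <- 2 * pi / lambda
  (1 - f) * (2 + cos(w0)) / (12 * f * (1 - cos(w0))^2)
}

#' Cubic-smoothing-spline detrending with a cutoff-frequency parameterization
#'
#' Fits a cubic smoothing spline whose frequency-response amplitude equals
#' `cutoff_amplitude` (default 0.5) at wavelength `stiffness_frac * n` years
#' -- the conventional "66% spline with a 50% cutoff" when
#' `stiffness_frac = 0.66` -- and divides each year's value by the fitted
#' curve, yielding dimensionless growth indices with mean ~ 1. Variance at
#' wavelengths much shorter than the cutoff passes through almost intact;
#' wavelengths much longer (age/size trends) are removed.
#'
#' @param x Numeric series (length >= 10), e.g. ring widths in mm.
#' @param years Optional calendar years (carried into the result).
#' @param stiffness_frac Cutoff wavelength as a fraction of the series
#'   length (default 0.66).
#' @param cutoff_amplitude Frequency-response amplitude at the cutoff
#'   wavelength (default 0.5).
#' @return A list of class `qwa_detrend`: `index` (ratio indices), `fit`
#'   (the spline curve), `years`.
#' @export
spline_detrend <- function(x, years = NULL, stiffness_frac = 0.66,
                           cutoff_amplitude = 0.5) {
  if (length(x) < 10L) stop("need at least 10 values to detrend")
  if (any(!is.finite(x))) stop("series must be complete (no NA) for spline detrending")
  stopifnot(stiffness_frac > 0, stiffness_frac <= 1,
            cutoff_amplitude > 0, cutoff_amplitude < 1)
  n <- length(x)
  mu <- .spline_mu(stiffness_frac * n, cutoff_amplitude)
  fit <- .reinsch_smooth(x, mu)
  if (any(fit <= 0))
    stop("fitted spline is non-positive; apply power_transform() first or ",
         "inspect the series")
  structure(list(index = x / fit, fit = fit,
                 years = years %||% seq_len(n)),
            class = "qwa_detrend")
}

#' Standardized ring-width site chronology
#'
#' Per-core standardization (optional power transform, then
#' cutoff-parameterized spline detrending) followed by a robust site mean.
#' Ratio indices are used on the measurement scale; after a log transform,
#' residuals from the curve (re-centred at 1) replace ratios, since
#' log-scale differences are the ratio analogue. For detrending, estimated
#' powers below 0.05 fall back to the log transform (the Box-Cox limit):
#' a negative power is monotone decreasing and would invert the growth
#' series' orientation. The site chronology uses the Tukey biweight mean by
#' default.
#'
#' @param rwl A `qwa_rwl` long data frame.
#' @param stiffness_frac,cutoff_amplitude Spline parameters, see
#'   [spline_detrend()].
#' @param power Apply [power_transform()] before detrending (default TRUE).
#' @param method `"biweight"` (default) or `"arithmetic"` site mean.
#' @param min_years Cores shorter than this are skipped with a warning.
#' @return A list of class `qwa_rw_chronology`: `indices` (long data frame
#'   `core`, `year`, `index`), `chronology` (data frame `year`, `index`,
#'   `depth`), `powers` (per-core power-transform exponents).
#' @export
rw_chronology <- function(rwl, stiffness_frac = 0.66, cutoff_amplitude = 0.5,
                          power = TRUE, method = c("biweight", "arithmetic"),
                          min_years = 10L) {
  method <- match.arg(method)
  idx <- list()
  powers <- numeric(0)
  for (id in unique(rwl$core)) {
    d <- rwl[rwl$core == id, , drop = FALSE]
    d <- d[order(d$year), , drop = FALSE]
    if (nrow(d) < min_years) {
      warning("core ", id, " has fewer than ", min_years, " years; skipped")
      next
    }
    w <- d$width
    islog <- FALSE
    if (power) {
      w <- power_transform(w)
      p_hat <- attr(w, "power")
      powers[id] <- p_hat
      islog <- isTRUE(attr(w, "log"))
      if (!islog && p_hat < 0.05) {
        # orientation-preserving fallback: x^p with p < 0 is decreasing
        w <- log(d$width)
        islog <- TRUE
      }
    }
    if (islog) {
      mu <- .spline_mu(stiffness_frac * length(w), cutoff_amplitude)
      fit <- .reinsch_smooth(as.numeric(w), mu)
      ind <- as.numeric(w) - fit + 1
    } else {
      ind <- spline_detrend(as.numeric(w), d$year, stiffness_frac,
                            cutoff_amplitude)$index
    }
    idx[[id]] <- data.frame(core = id, year = d$year, index = ind,
                            stringsAsFactors = FALSE)
  }
  if (!length(idx)) stop("no core long enough to standardize")
  indices <- do.call(rbind, idx)
  rownames(indices) <- NULL
  years <- seq(min(indices$year), max(indices$year))
  m <- matrix(NA_real_, length(years), length(idx),
              dimnames = list(years, names(idx)))
  m[cbind(match(indices$year, years), match(indices$core, names(idx)))] <-
    indices$index
  site <- apply(m, 1L, function(r) {
    r <- r[is.finite(r)]
    if (!length(r)) return(NA_real_)
    if (method == "biweight") biweight_mean(r) else mean(r)
  })
  chron <- data.frame(year = years, index = site,
                      depth = rowSums(is.finite(m)))
  structure(list(indices = indices, chronology = chron, powers = powers,
                 method = method),
            class = "qwa_rw_chronology")
}
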