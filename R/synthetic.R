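# monthly climatology of the emulated site: a semi-arid East-Mediterranean
# mountain stand near 2000 m (dry hot summers, snow-fed wet winters)
.TMAX_CLIM <- c(-1, 0, 4, 9, 14, 19, 23, 23, 19, 13, 6, 1)
.PRECIP_CLIM <- c(180, 160, 120, 60, 30, 8, 3, 3, 10, 50, 110, 170)

#' Parameters of the synthetic juniper QWA dataset
#'
#' Bundles every knob of the generator with defaults emulating the study
#' conditions: 6 trees over 1963-2019, 10-14 radial files per ring, ~40
#' cells per file, a decreasing intra-ring lumen profile (22.4 to 3.7 um)
#' with increasing wall thickness (3.1 to 5.2 um), multiplicative
#' (log-scale) climate effects of May precipitation (positive) and
#' April-October maximum temperature (negative) on lumen diameter, a much
#' weaker and mostly idiosyncratic wall-thickness signal, and a post-1992
#' warming trend that drives a ~1 SD lumen decline. See the methods
#' vignette for the calibration of each default.
#'
#' @param years Calendar year span of the rings.
#' @param n_trees Number of trees.
#' @param files_per_ring Length-2 range of radial files measured per ring.
#' @param cells_per_file Mean Poisson cell count per radial file (declines
#'   in drought years).
#' @param base_ld_profile,base_cwt_profile Per-sector baseline means (um).
#' @param beta_precip_may Log-scale lumen response per SD of May
#'   precipitation.
#' @param beta_tmax_summer Log-scale lumen response per SD of April-October
#'   maximum temperature (negative: hotter summers, narrower lumina).
#' @param cwt_beta_scale Factor scaling both betas for wall thickness.
#' @param trend_break_year First year of the warming trend.
#' @param tmax_trend Post-break maximum-temperature trend, degrees C per
#'   decade.
#' @param tree_effect_sd SD of the per-tree log-level offset.
#' @param common_year_sd SD of the year-by-sector effect shared by all
#'   trees (non-climatic common signal).
#' @param noise_sd SD of the idiosyncratic per-tree-per-year log effect.
#' @param cwt_common_sd,cwt_noise_sd Same two components for wall
#'   thickness.
#' @param cell_noise_sd Log-scale SD of individual cells around their
#'   sector target.
#' @param signal_share Optional common-signal variance share s in `[0, 1]`;
#'   when set, the climate betas are zeroed and the common/idiosyncratic
#'   SDs are set to s and 1 - s shares of `signal_total_var`, so the
#'   expected interseries correlation is s exactly.
#' @param signal_total_var Total log-variance used with `signal_share`.
#' @param tmax_anom_sd,tmax_ar1 Monthly maximum-temperature anomaly SD
#'   (degrees C) and lag-1 persistence.
#' @param precip_shape Gamma shape of monthly precipitation.
#' @param spei_lambda Weight of the temperature anomaly in the synthetic
#'   1-month drought index.
#' @param n_cores_rw Ring-width cores generated by [gen_ringwidths()].
#' @param rw_beta_precip Log-scale ring-width response per SD of May-June
#'   precipitation.
#' @param rw_noise_sd Idiosyncratic log-scale ring-width noise SD.
#' @param rw_age_range Cambial-age range (years) of the cores at the first
#'   ring.
#' @param rw_scale,rw_tau,rw_floor Negative-exponential age curve
#'   `rw_scale * exp(-age/rw_tau) + rw_floor` (mm).
#' @param seed Integer seed governing all randomness.
#' @return A validated list of class `qwa_params`.
#' @export
qwa_params <- function(years = 1963:2019,
                       n_trees = 6L,
                       files_per_ring = c(10L, 14L),
                       cells_per_file = 40,
                       base_ld_profile = c(22.4, 19.7, 18.3, 17.3, 16.3,
                                           15.3, 14.3, 12.9, 10.5, 3.7),
                       base_cwt_profile = c(3.1, 3.5, 3.7, 3.9, 4.0,
                                            4.1, 4.3, 4.4, 4.7, 5.2),
                       beta_precip_may = 0.085,
                       beta_tmax_summer = -0.15,
                       cwt_beta_scale = 0.1,
                       trend_break_year = 1992L,
                       tmax_trend = 0.8,
                       tree_effect_sd = 0.10,
                       common_year_sd = 0.02,
                       noise_sd = 0.20,
                       cwt_common_sd = 0.01,
                       cwt_noise_sd = 0.10,
                       cell_noise_sd = 0.12,
                       signal_share = NULL,
                       signal_total_var = 0.04,
                       tmax_anom_sd = 0.9,
                       tmax_ar1 = 0.25,
                       precip_shape = 4,
                       spei_lambda = 0.5,
                       n_cores_rw = 19L,
                       rw_beta_precip = 0.25,
                       rw_noise_sd = 0.2,
                       rw_age_range = c(60, 150),
                       rw_scale = 1.5,
                       rw_tau = 70,
                       rw_floor = 0.3,
                       seed = 42L) {
  p <- as.list(environment())
  stopifnot(length(p$years) >= 3L, all(diff(p$years) == 1L),
            .is_count(p$n_trees),
            length(p$files_per_ring) == 2L,
            p$files_per_ring[1L] >= 1L,
            p$files_per_ring[2L] >= p$files_per_ring[1L],
            p$cells_per_file > 0,
            length(p$base_ld_profile) == length(p$base_cwt_profile),
            all(p$base_ld_profile > 0), all(p$base_cwt_profile > 0),
            p$tree_effect_sd >= 0, p$common_year_sd >= 0, p$noise_sd >= 0,
            p$cwt_common_sd >= 0, p$cwt_noise_sd >= 0, p$cell_noise_sd >= 0,
            p$tmax_anom_sd >= 0, p$precip_shape > 0,
            is.null(p$signal_share) ||
              (p$signal_share >= 0 && p$signal_share <= 1))
  p$seed <- as.integer(p$seed)
  class(p) <- "qwa_params"
  p
}

# stationary AR(1) noise of length n with marginal sd
.ar1_noise <- function(n, phi, sd) {
  if (sd == 0 || n == 0L) return(numeric(n))
  x <- numeric(n)
  x[1L] <- stats::rnorm(1L, 0, sd)
  innov_sd <- sd * sqrt(1 - phi^2)
  for (t in seq_len(n - 1L)) x[t + 1L] <- phi * x[t] + stats::rnorm(1L, 0, innov_sd)
  x
}

#' Generate site monthly climate (Tmax, precipitation, drought index)
#'
#' Maximum temperature is a fixed seasonal climatology plus AR(1) monthly
#' anomalies plus a linear post-break warming trend
#' (`tmax_trend * (year - trend_break_year)/10`). Precipitation is
#' gamma-distributed around a Mediterranean seasonal cycle with dry summers.
#' The 1-month drought index is the per-calendar-month z-score of the
#' precipitation anomaly minus `spei_lambda` times the temperature anomaly,
#' so it has mean 0 and SD 1 in every calendar month and turns negative
#' (drier) as the warming trend proceeds. Climate is generated from one
#' year before the first ring year so previous-year correlation windows are
#' always covered.
#'
#' @param params A [qwa_params()] object.
#' @return Named list of `qwa_climate` objects: `tmax`, `precip`, `spei`.
#' @export
gen_climate <- function(params) {
  stopifnot(inherits(params, "qwa_params"))
  set.seed(params$seed)
  years <- (min(params$years) - 1L):max(params$years)
  ny <- length(years)
  trend <- params$tmax_trend * pmax(0, years - params$trend_break_year) / 10
  anom <- matrix(.ar1_noise(ny * 12L, params$tmax_ar1, params$tmax_anom_sd),
                 ny, 12L, byrow = TRUE)
  tmax_vals <- matrix(.TMAX_CLIM, ny, 12L, byrow = TRUE) + trend + anom
  precip_vals <- matrix(stats::rgamma(ny * 12L, shape = params$precip_shape,
                                      scale = rep(.PRECIP_CLIM, each = ny) /
                                        params$precip_shape),
                        ny, 12L)
  zcol <- function(m) apply(m, 2L, function(col) as.numeric(scale(col)))
  d <- zcol(precip_vals) - params$spei_lambda * zcol(tmax_vals)
  spei_vals <- zcol(d)
  list(tmax = qwa_climate("tmax", years, tmax_vals),
       precip = qwa_climate("precip", years, precip_vals),
       spei = qwa_climate("spei", years, spei_vals))
}

#' Generate a gridded monthly field around the site
#'
#' Replicates the site series across a lat/lon grid with noise whose
#' correlation with the site decays exponentially with great-circle-free
#' planar distance, for exercising spatial field correlations.
#'
#' @param clim A site `qwa_climate` object.
#' @param params A [qwa_params()] object (only the seed is used).
#' @param lats,lons Grid coordinates (degrees).
#' @param site Site coordinates `c(lat, lon)`.
#' @param cor_length Decay length of the site correlation (degrees).
#' @return A `qwa_grid` object.
#' @export
gen_grid <- function(clim, params, lats = seq(30, 38, by = 2),
                     lons = seq(32, 40, by = 2), site = c(34.2, 36.1),
                     cor_length = 10) {
  stopifnot(inherits(clim, "qwa_climate"), inherits(params, "qwa_params"))
  set.seed(params$seed + 3L)
  ny <- length(clim$years)
  mu <- colMeans(clim$values, na.rm = TRUE)
  sig <- apply(clim$values, 2L, stats::sd, na.rm = TRUE)
  anom <- sweep(clim$values, 2L, mu)
  arr <- array(NA_real_, c(ny, 12L, length(lats), length(lons)))
  for (i in seq_along(lats)) {
    for (j in seq_along(lons)) {
      d <- sqrt((lats[i] - site[1L])^2 + (lons[j] - site[2L])^2)
      w <- exp(-d / cor_length)
      noise <- matrix(stats::rnorm(ny * 12L), ny, 12L) %*% diag(sig)
      arr[, , i, j] <- matrix(mu, ny, 12L, byrow = TRUE) +
        w * anom + sqrt(1 - w^2) * noise
    }
  }
  qwa_grid(clim$variable, clim$years, lats, lons, arr)
}

#' Generate climate-driven per-cell tracheid measurements
#'
#' Per tree, year and sector, the target lumen diameter is the baseline
#' sector profile scaled by `exp(beta_p z(May precip) + beta_t z(Apr-Oct
#' Tmax) + tree effect + shared year-sector effect + idiosyncratic
#' tree-year effect)`; the multiplicative (log-scale) form keeps values
#' positive and makes SD-scaled betas interpretable. Wall thickness follows
#' the same structure with betas scaled down by `cwt_beta_scale` and mostly
#' idiosyncratic variance, reproducing the weak common signal of wall
#' measurements. Cells take their sector's target value with lognormal
#' cell-level noise; cell counts per file are Poisson with a mean that
#' shrinks in drought years, so cell-poor latewood rings exercise the
#' empty-sector interpolation path.
#'
#' @param climate Output of [gen_climate()] (must span `params$years`).
#' @param params A [qwa_params()] object.
#' @return A `qwa_cells` data frame.
#' @export
gen_anatomy <- function(climate, params) {
  stopifnot(inherits(params, "qwa_params"))
  years <- params$years
  for (v in c("tmax", "precip", "spei"))
    if (!all(years %in% climate[[v]]$years))
      stop("climate does not span the requested ring years (", v, ")")
  set.seed(params$seed + 1L)
  ny <- length(years)
  nt <- params$n_trees
  S <- length(params$base_ld_profile)
  yi <- match(years, climate$precip$years)
  zP <- as.numeric(scale(climate$precip$values[yi, 5L]))
  zT <- as.numeric(scale(rowMeans(climate$tmax$values[yi, 4:10])))
  zD <- as.numeric(scale(rowMeans(climate$spei$values[yi, 5:9])))
  bp <- params$beta_precip_may
  bt <- params$beta_tmax_summer
  eta_sd <- params$common_year_sd
  eps_sd <- params$noise_sd
  if (!is.null(params$signal_share)) {
    s <- params$signal_share
    bp <- bt <- 0
    eta_sd <- sqrt(s * params$signal_total_var)
    eps_sd <- sqrt((1 - s) * params$signal_total_var)
  }
  tree_eff_ld <- stats::rnorm(nt, 0, params$tree_effect_sd)
  tree_eff_cwt <- stats::rnorm(nt, 0, params$tree_effect_sd / 2)
  eta_ld <- matrix(stats::rnorm(ny * S, 0, eta_sd), ny, S)
  eta_cwt <- matrix(stats::rnorm(ny * S, 0, params$cwt_common_sd), ny, S)
  eps_ld <- matrix(stats::rnorm(nt * ny, 0, eps_sd), nt, ny)
  eps_cwt <- matrix(stats::rnorm(nt * ny, 0, params$cwt_noise_sd), nt, ny)
  climate_ld <- bp * zP + bt * zT
  climate_cwt <- params$cwt_beta_scale * climate_ld
  lambda <- pmax(8, params$cells_per_file * exp(0.15 * pmin(0, zD)))
  rows <- vector("list", nt * ny)
  k <- 0L
  for (t in seq_len(nt)) {
    target_ld <- outer(exp(climate_ld + tree_eff_ld[t] + eps_ld[t, ]),
                       params$base_ld_profile) * exp(eta_ld)
    target_cwt <- outer(exp(climate_cwt + tree_eff_cwt[t] + eps_cwt[t, ]),
                        params$base_cwt_profile) * exp(eta_cwt)
    for (y in seq_len(ny)) {
      nf <- sample(params$files_per_ring[1L]:params$files_per_ring[2L], 1L)
      nc <- pmax(5L, stats::rpois(nf, lambda[y]))
      ncell <- sum(nc)
      file_id <- rep(sprintf("F%02d", seq_len(nf)), nc)
      rank <- sequence(nc)
      pos <- (rank - 0.5) / rep(nc, nc)
      sec <- pmin(S, pmax(1L, floor(pos * S - 1e-9) + 1L))
      noise <- if (params$cell_noise_sd > 0)
        exp(stats::rnorm(2L * ncell, 0, params$cell_noise_sd)) else rep(1, 2L * ncell)
      k <- k + 1L
      rows[[k]] <- data.frame(
        tree = sprintf("T%02d", t), core = sprintf("T%02dA", t),
        year = years[y], file = file_id, rank = rank,
        ld = target_ld[y, sec] * noise[seq_len(ncell)],
        cwt = target_cwt[y, sec] * noise[ncell + seq_len(ncell)],
        stringsAsFactors = FALSE)
    }
  }
  as_qwa_cells(do.call(rbind, rows))
}

#' Generate ring-width series with age trends and a May-June precipitation
#' signal
#'
#' Width = negative-exponential cambial-age curve times
#' `exp(rw_beta_precip * z(May-Jun precip) + noise)`, with per-core age
#' offsets, for exercising power transformation, spline detrending and
#' ring-width chronology statistics.
#'
#' @inheritParams gen_anatomy
#' @return A `qwa_rwl` long data frame.
#' @export
gen_ringwidths <- function(climate, params) {
  stopifnot(inherits(params, "qwa_params"))
  years <- params$years
  if (!all(years %in% climate$precip$years))
    stop("climate does not span the requested ring years")
  set.seed(params$seed + 2L)
  yi <- match(years, climate$precip$years)
  zMJ <- as.numeric(scale(rowSums(climate$precip$values[yi, 5:6])))
  ny <- length(years)
  out <- vector("list", params$n_cores_rw)
  for (cidx in seq_len(params$n_cores_rw)) {
    age0 <- stats::runif(1L, params$rw_age_range[1L], params$rw_age_range[2L])
    age <- age0 + seq_len(ny) - 1L
    base <- params$rw_scale * exp(-age / params$rw_tau) + params$rw_floor
    w <- base * exp(params$rw_beta_precip * zMJ +
                      stats::rnorm(ny, 0, params$rw_noise_sd))
    out[[cidx]] <- data.frame(core = sprintf("JUN%02d", cidx), year = years,
                              width = w, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("qwa_rwl", "data.frame")
  res
}

#' Write a complete synthetic dataset to disk
#'
#' Convenience wrapper producing the file set the pipeline ingests:
#' `cells.csv`, `rw.rwl`, `climate_tmax.txt`, `climate_precip.txt`,
#' `climate_spei.txt` and a `params.yaml` echo.
#'
#' @param params A [qwa_params()] object.
#' @param dir Output directory (created if needed).
#' @param grid Also write `grid_tmax.txt` (long format, see
#'   [read_grid_field()]).
#' @return The directory, invisibly.
#' @export
simulate_dataset <- function(params = qwa_params(), dir, grid = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  climate <- gen_climate(params)
  cells <- gen_anatomy(climate, params)
  rwl <- gen_ringwidths(climate, params)
  write_cell_table(cells, file.path(dir, "cells.csv"))
  write_rwl(rwl, file.path(dir, "rw.rwl"))
  for (v in names(climate))
    write_monthly_climate(climate[[v]], file.path(dir, paste0("climate_", v, ".txt")))
  if (grid) {
    g <- gen_grid(climate$tmax, params)
    long <- expand.grid(year = g$years, month = 1:12, lat = g$lats,
                        lon = g$lons, KEEP.OUT.ATTRS = FALSE)
    long$value <- as.vector(g$values)
    utils::write.table(long, file.path(dir, "grid_tmax.txt"),
                       row.names = FALSE, quote = FALSE)
  }
  pe <- unclass(params)
  pe$signal_share <- pe$signal_share %||% "none"
  pe$years <- paste(range(params$years), collapse = ":")
  yaml::write_yaml(pe, file.path(dir, "params.yaml"))
  invisible(dir)
}
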