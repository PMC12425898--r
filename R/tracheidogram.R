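#' Relative intra-ring positions of cells in a radial file
#'
#' Cells are indexed 1..n from the ring start; cell i is placed at relative
#' position (i - 0.5)/n, the midpoint of its 1/n share of the ring. The
#' positions are strictly increasing, symmetric about 0.5, and never land on
#' a sector boundary s/S (the half-cell offset guarantees this).
#'
#' @param n Number of cells in the radial file (>= 1).
#' @return Numeric vector of n positions in (0, 1).
#' @export
#' @examples
#' assign_relative_positions(4) # 0.125 0.375 0.625 0.875
assign_relative_positions <- function(n) {
  if (!.is_count(n)) stop("radial file must contain at least one cell")
  (seq_len(n) - 0.5) / n
}

#' Remove within-ring measurement outliers by a robust MAD rule
#'
#' Replaces visual outlier screening with a deterministic, auditable rule:
#' within each (tree, year, parameter) group, a cell is removed when its
#' value lies more than `k` scaled median absolute deviations (consistency
#' constant 1.4826) from the group median. A cell flagged for either
#' parameter is dropped entirely, since both measurements come from the same
#' detected cell. When the MAD degenerates to zero although values differ
#' (a majority of exactly tied values), the scaled mean absolute deviation
#' (consistency constant 1.2533) takes its place; all-identical groups are
#' left untouched.
#'
#' With `bins > 1` each ring is additionally stratified by relative
#' intra-ring position (cells compared only to cells in the same position
#' bin of their radial file). This respects the steep earlywood-latewood
#' gradient of conifer tracheidograms: against a whole-ring median, genuine
#' small-lumen latewood cells would be flagged as outliers. The pipeline
#' therefore filters with `bins = n_sectors`; `bins = 1` gives the plain
#' per-ring rule.
#'
#' @param cells A `qwa_cells` data frame.
#' @param k MAD multiplier (> 0; default 3). `Inf` disables removal.
#' @param bins Number of relative-position strata per ring (default 1).
#' @return A list: `cells` (filtered table) and `removed` (audit report
#'   with one row per removed cell and parameter, including the value).
#' @export
filter_outliers <- function(cells, k = 3, bins = 1L) {
  stopifnot(length(k) == 1L, is.numeric(k), k > 0, .is_count(bins))
  cells <- as_qwa_cells(as.data.frame(cells))
  if (bins > 1L) {
    n_in_file <- stats::ave(cells$rank,
                            interaction(cells$tree, cells$core, cells$year,
                                        cells$file, drop = TRUE),
                            FUN = length)
    pos <- (cells$rank - 0.5) / n_in_file
    stratum <- pmin(bins, pmax(1L, floor(pos * bins - 1e-9) + 1L))
    grp <- interaction(cells$tree, cells$year, stratum, drop = TRUE)
  } else {
    grp <- interaction(cells$tree, cells$year, drop = TRUE)
  }
  flag_param <- function(x) {
    med <- stats::ave(x, grp, FUN = stats::median)
    scale_est <- function(v) {
      m <- stats::mad(v, constant = 1.4826)
      if (m > 0) m else 1.2533 * mean(abs(v - stats::median(v)))
    }
    madv <- stats::ave(x, grp, FUN = scale_est)
    madv > 0 & abs(x - med) > k * madv
  }
  out_ld <- flag_param(cells$ld)
  out_cwt <- flag_param(cells$cwt)
  drop <- out_ld | out_cwt
  removed <- rbind(
    if (any(out_ld)) data.frame(cells[out_ld, c("tree", "core", "year", "file", "rank")],
                                parameter = "ld", value = cells$ld[out_ld]),
    if (any(out_cwt)) data.frame(cells[out_cwt, c("tree", "core", "year", "file", "rank")],
                                 parameter = "cwt", value = cells$cwt[out_cwt])
  )
  if (is.null(removed))
    removed <- data.frame(tree = character(), core = character(),
                          year = integer(), file = character(), rank = integer(),
                          parameter = character(), value = numeric())
  rownames(removed) <- NULL
  kept <- cells[!drop, , drop = FALSE]
  rownames(kept) <- NULL
  class(kept) <- c("qwa_cells", "data.frame")
  list(cells = kept, removed = removed)
}

#' Resample one radial file onto equidistant intra-ring sectors
#'
#' The standardized tracheidogram: the ring is divided into `n_sectors`
#' equidistant sectors, sector s covering relative positions
#' ((s-1)/S, s/S], with sector I at the ring start (earlywood) and sector S
#' at the ring end (latewood). A sector's value is the mean of the cells
#' whose positions fall inside it; a sector containing no cell (cell-poor
#' latewood rings) is filled by linear interpolation of the piecewise-linear
#' curve through the (position, value) points, evaluated at the sector
#' midpoint, and flagged.
#'
#' @param values Numeric vector of cell measurements ordered by cell rank.
#' @param n_sectors Number of sectors S (>= 2; default 10).
#' @return A list: `sectors` (S means), `interpolated` (logical flags),
#'   `n_cells`.
#' @export
resample_to_sectors <- function(values, n_sectors = 10L) {
  n <- length(values)
  if (n < 1L) stop("radial file has no cells")
  if (!.is_count(n_sectors) || n_sectors < 2L) stop("n_sectors must be >= 2")
  S <- as.integer(n_sectors)
  pos <- assign_relative_positions(n)
  sec <- pmin(S, pmax(1L, floor(pos * S - 1e-9) + 1L))
  means <- vapply(seq_len(S), function(s) {
    i <- sec == s
    if (any(i)) mean(values[i]) else NA_real_
  }, numeric(1))
  interp <- is.na(means)
  if (any(interp)) {
    mids <- (seq_len(S) - 0.5) / S
    if (n == 1L) {
      means[interp] <- values
    } else {
      means[interp] <- stats::approx(pos, values, xout = mids[interp], rule = 2)$y
    }
  }
  list(sectors = means, interpolated = interp, n_cells = n)
}

#' Average sector profiles of the radial files of one tree ring
#'
#' Per-sector arithmetic mean across the radial files measured for one
#' (tree, year). Replication below `min_files` files (default 10) triggers a
#' warning, with a second, stronger warning below 6 files, the minimum
#' replication recommended for intra-annual tracheid statistics.
#'
#' @param profiles Numeric matrix, one row per radial file, one column per
#'   sector (as produced by stacking [resample_to_sectors()] results).
#' @param min_files Replication threshold for the first warning.
#' @param warn Emit warnings (`FALSE` lets callers aggregate them).
#' @return A list: `sectors` (per-sector means), `depth` (number of files).
#' @export
average_files <- function(profiles, min_files = 10L, warn = TRUE) {
  profiles <- as.matrix(profiles)
  depth <- nrow(profiles)
  if (depth < 1L) stop("no radial-file profiles to average")
  if (warn && depth < 6L)
    warning("only ", depth, " radial files: below the minimum recommended ",
            "number of radial files (6)")
  else if (warn && depth < min_files)
    warning("only ", depth, " radial files: below the requested minimum of ",
            min_files)
  list(sectors = colMeans(profiles), depth = depth)
}

#' Build the tree x year x sector matrix of anatomical means
#'
#' Full per-ring reduction: MAD outlier filtering (stratified by relative
#' intra-ring position, see [filter_outliers()]), resampling of every
#' radial file onto `n_sectors` equidistant sectors, and averaging across
#' files, for both lumen diameter and wall thickness. The result is
#' deterministic and invariant to input row order and to radial-file
#' relabeling. Missing (tree, year) combinations stay missing.
#'
#' @param cells A `qwa_cells` data frame.
#' @param n_sectors Sectors per ring (default 10).
#' @param min_files Radial-file replication below which a ring is counted in
#'   the low-replication summary warning (default 10).
#' @param mad_k MAD multiplier for [filter_outliers()] (default 3).
#' @return An object of class `qwa_sector_matrix`: list with `ld` and `cwt`
#'   (tree x year x sector arrays, micrometers), `depth` (tree x year file
#'   counts), `n_interpolated` (tree x year counts of interpolated sector
#'   values, ld and cwt pooled), `trees`, `years`, `n_sectors`, and the
#'   outlier `removed` report.
#' @export
build_sector_matrix <- function(cells, n_sectors = 10L, min_files = 10L, mad_k = 3) {
  flt <- filter_outliers(cells, k = mad_k, bins = n_sectors)
  cells <- flt$cells
  trees <- sort(unique(cells$tree))
  years <- seq(min(cells$year), max(cells$year))
  S <- as.integer(n_sectors)
  dn <- list(trees, years, .sector_labels(S))
  ld <- array(NA_real_, c(length(trees), length(years), S), dimnames = dn)
  cwt <- ld
  depth <- matrix(NA_integer_, length(trees), length(years),
                  dimnames = list(trees, years))
  n_interp <- depth
  ring_of <- interaction(cells$tree, cells$year, drop = TRUE)
  for (d in split(cells, ring_of)) {
    ti <- match(d$tree[1L], trees)
    yi <- match(d$year[1L], years)
    files <- split(d, interaction(d$core, d$file, drop = TRUE))
    prof_ld <- lapply(files, function(f) resample_to_sectors(f$ld[order(f$rank)], S))
    prof_cwt <- lapply(files, function(f) resample_to_sectors(f$cwt[order(f$rank)], S))
    ld[ti, yi, ] <- average_files(do.call(rbind, lapply(prof_ld, `[[`, "sectors")),
                                  warn = FALSE)$sectors
    cwt[ti, yi, ] <- average_files(do.call(rbind, lapply(prof_cwt, `[[`, "sectors")),
                                   warn = FALSE)$sectors
    depth[ti, yi] <- length(files)
    n_interp[ti, yi] <- sum(vapply(prof_ld, function(p) sum(p$interpolated), 0L)) +
      sum(vapply(prof_cwt, function(p) sum(p$interpolated), 0L))
  }
  low6 <- sum(depth < 6L, na.rm = TRUE)
  lowm <- sum(depth < min_files, na.rm = TRUE)
  if (low6 > 0L)
    warning(low6, " ring(s) have fewer than the minimum recommended ",
            "number of radial files (6)")
  else if (lowm > 0L)
    warning(lowm, " ring(s) have fewer than ", min_files, " radial files")
  structure(list(ld = ld, cwt = cwt, depth = depth, n_interpolated = n_interp,
                 trees = trees, years = years, n_sectors = S,
                 removed = flt$removed),
            class = "qwa_sector_matrix")
}

#' @export
print.qwa_sector_matrix <- function(x, ...) {
  cat("<qwa_sector_matrix> ", length(x$trees), " trees x ",
      length(x$years), " years x ", x$n_sectors, " sectors; ",
      sum(!is.na(x$depth)), " rings (median depth ",
      stats::median(x$depth, na.rm = TRUE), " files); ",
      nrow(x$removed), " outlier removals\n", sep = "")
  invisible(x)
}

#' Year-by-tree matrix of one sector's values
#'
#' Accessor pulling a single sector out of a `qwa_sector_matrix`.
#'
#' @param sm A `qwa_sector_matrix`.
#' @param sector Sector index (1..S) or Roman label.
#' @param parameter `"ld"` or `"cwt"`.
#' @return Numeric matrix, years as rows, trees as columns.
#' @export
sector_series <- function(sm, sector, parameter = c("ld", "cwt")) {
  parameter <- match.arg(parameter)
  if (is.character(sector)) sector <- match(sector, .sector_labels(sm$n_sectors))
  stopifnot(.is_count(sector), sector <= sm$n_sectors)
  a <- sm[[parameter]][, , sector, drop = FALSE]
  t(matrix(a, nrow = length(sm$trees), dimnames = list(sm$trees, sm$years)))
}
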