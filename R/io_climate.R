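#' Construct a monthly climate table
#'
#' @param variable One of `"tmax"`, `"tmean"`, `"tmin"`, `"precip"`,
#'   `"spei"` (units: degrees C for temperatures, mm for precipitation,
#'   dimensionless for the drought index).
#' @param years Integer vector of contiguous calendar years.
#' @param values Numeric year-by-12 matrix (January..December); missing
#'   values must be `NA`, never 0.
#' @return An object of class `qwa_climate`.
#' @export
qwa_climate <- function(variable, years, values) {
  variable <- match.arg(variable, c("tmax", "tmean", "tmin", "precip", "spei"))
  years <- as.integer(years)
  values <- as.matrix(values)
  if (ncol(values) != 12L) stop("climate values must have 12 monthly columns")
  if (nrow(values) != length(years)) stop("years and value rows differ in length")
  if (anyDuplicated(years)) stop("duplicate year in climate table")
  if (length(years) > 1L && any(diff(years) != 1L))
    stop("climate years must be contiguous")
  dimnames(values) <- list(years, month.abb)
  structure(list(variable = variable, years = years, values = values),
            class = "qwa_climate")
}

#' Read a monthly climate table (year x 12 layout)
#'
#' Reads a delimited table whose first column is the calendar year followed
#' by twelve monthly columns. Values equal to the missing-value code are
#' stored as `NA` (and hence excluded from later pairwise-complete
#' correlations). Gap years are inserted as all-missing rows so the year axis
#' is always contiguous; a duplicated year is an error.
#'
#' @param path Path to the file (whitespace- or comma-delimited, header row).
#' @param variable Climate variable name, see [qwa_climate()].
#' @param na Missing-value code used in the file.
#' @param sep Field separator passed to [utils::read.table()] (`""` =
#'   any whitespace).
#' @return A `qwa_climate` object.
#' @export
read_monthly_climate <- function(path, variable, na = -9999, sep = "") {
  if (!file.exists(path)) stop("climate file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(raw) < 13L)
    stop("climate file ", path, " must have a year column plus 12 monthly columns")
  yrs <- as.integer(raw[[1L]])
  if (anyDuplicated(yrs)) {
    stop("duplicate year ", yrs[duplicated(yrs)][1L], " in climate file ", path)
  }
  vals <- as.matrix(raw[, 2:13])
  storage.mode(vals) <- "double"
  vals[vals == na] <- NA_real_
  full <- seq(min(yrs), max(yrs))
  m <- matrix(NA_real_, length(full), 12L)
  m[match(yrs, full), ] <- vals
  qwa_climate(variable, full, m)
}

#' Write a monthly climate table
#'
#' @param clim A `qwa_climate` object.
#' @param path Output path.
#' @param na Missing-value code to write for `NA`.
#' @return The path, invisibly.
#' @export
write_monthly_climate <- function(clim, path, na = -9999) {
  stopifnot(inherits(clim, "qwa_climate"))
  vals <- clim$values
  vals[is.na(vals)] <- na
  df <- data.frame(year = clim$years, vals, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.qwa_climate <- function(x, ...) {
  cat("<qwa_climate> ", x$variable, "; years ", min(x$years), "-",
      max(x$years), "; ", sum(is.na(x$values)), " missing\n", sep = "")
  invisible(x)
}

#' Construct a gridded monthly climate field
#'
#' @param variable Climate variable name, see [qwa_climate()].
#' @param years Contiguous calendar years.
#' @param lats,lons Strictly monotone coordinate vectors (degrees).
#' @param values 4-d array (year, month, lat, lon).
#' @return An object of class `qwa_grid`.
#' @export
qwa_grid <- function(variable, years, lats, lons, values) {
  variable <- match.arg(variable, c("tmax", "tmean", "tmin", "precip", "spei"))
  years <- as.integer(years)
  if (length(years) > 1L && any(diff(years) != 1L)) stop("grid years must be contiguous")
  mono <- function(v) length(v) <= 1L || all(diff(v) > 0) || all(diff(v) < 0)
  if (!mono(lats)) stop("lats must be strictly monotone")
  if (!mono(lons)) stop("lons must be strictly monotone")
  stopifnot(length(dim(values)) == 4L,
            dim(values)[1L] == length(years), dim(values)[2L] == 12L,
            dim(values)[3L] == length(lats), dim(values)[4L] == length(lons))
  structure(list(variable = variable, years = years,
                 lats = as.numeric(lats), lons = as.numeric(lons),
                 values = values),
            class = "qwa_grid")
}

#' Read a gridded monthly field from a long delimited table
#'
#' Plain-text fallback for NetCDF-style fields: columns `year`, `month`,
#' `lat`, `lon`, `value`.
#'
#' @param path Path to the delimited file (header row).
#' @param variable Climate variable name.
#' @param na Missing-value code.
#' @return A `qwa_grid` object.
#' @export
read_grid_field <- function(path, variable, na = -9999) {
  if (!file.exists(path)) stop("grid file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("year", "month", "lat", "lon", "value")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("grid file missing column(s): ", paste(miss, collapse = ", "))
  years <- seq(min(raw$year), max(raw$year))
  lats <- sort(unique(raw$lat))
  lons <- sort(unique(raw$lon))
  arr <- array(NA_real_, c(length(years), 12L, length(lats), length(lons)))
  arr[cbind(match(raw$year, years), raw$month,
            match(raw$lat, lats), match(raw$lon, lons))] <- raw$value
  arr[arr == na] <- NA_real_
  qwa_grid(variable, years, lats, lons, arr)
}

#' Write a sector chronology to a delimited file
#'
#' One row per year with the index value of every sector plus the sample
#' depth (trees contributing to that year), re-readable losslessly to six
#' significant digits with [read_chronology()].
#'
#' @param chron A `qwa_chronology` long data frame from
#'   [sector_chronology()].
#' @param path Output path.
#' @param header Optional character vector of provenance lines written as
#'   `#` comments.
#' @return The path, invisibly.
#' @export
write_chronology <- function(chron, path, header = character()) {
  if (!nrow(chron)) stop("cannot write an empty chronology")
  sectors <- unique(chron$sector)
  years <- sort(unique(chron$year))
  wide <- data.frame(year = years)
  for (s in sectors) {
    d <- chron[chron$sector == s, ]
    wide[[s]] <- signif(d$index[match(years, d$year)], 10)
  }
  d1 <- chron[chron$sector == sectors[1L], ]
  wide$depth <- d1$depth[match(years, d1$year)]
  .write_table(wide, path, header)
}

#' Read a sector chronology written by [write_chronology()]
#'
#' @param path Path to the file.
#' @return A `qwa_chronology` long data frame (`sector`, `year`, `index`,
#'   `depth`).
#' @export
read_chronology <- function(path) {
  wide <- .read_table(path)
  sectors <- setdiff(names(wide), c("year", "depth"))
  out <- do.call(rbind, lapply(sectors, function(s) {
    data.frame(sector = s, year = wide$year, index = wide[[s]],
               depth = wide$depth, stringsAsFactors = FALSE)
  }))
  class(out) <- c("qwa_chronology", "data.frame")
  out
}
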