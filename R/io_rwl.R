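#' Read ring widths from a Tucson (.rwl) decadal file
#'
#' Parses the fixed exchange format used by the ITRDB: an 8-character series
#' id, the decade start year, and up to ten width values per line. Two unit
#' dialects circulate and both are accepted, distinguished by the series
#' terminator: `999` marks values in 0.01 mm, `-9999` marks values in
#' 0.001 mm. Widths are returned in millimetres.
#'
#' @param path Path to the .rwl file.
#' @return A long data frame of class `qwa_rwl` with columns `core`, `year`,
#'   `width` (mm); years are contiguous within each series.
#' @seealso [write_rwl()], [rwl_to_matrix()]
#' @export
read_rwl <- function(path) {
  if (!file.exists(path)) stop("rwl file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) stop("empty rwl file: ", path)
  ids <- trimws(substr(lines, 1L, 8L))
  rest <- substring(lines, 9L)
  out <- list()
  for (id in unique(ids)) {
    sel <- which(ids == id)
    vals <- numeric(0)
    first_year <- NA_integer_
    for (i in sel) {
      toks <- strsplit(trimws(rest[i]), "[ \t]+")[[1L]]
      nums <- suppressWarnings(as.numeric(toks))
      if (anyNA(nums) || length(nums) < 2L)
        stop("line ", lineno[i], ": cannot parse rwl data fields")
      dec <- as.integer(nums[1L])
      if (is.na(first_year)) {
        first_year <- dec
      } else if (dec != first_year + length(vals)) {
        stop("line ", lineno[i], ": non-contiguous or non-monotone decade year ",
             dec, " for series ", id, " (expected ", first_year + length(vals), ")")
      }
      vals <- c(vals, nums[-1L])
    }
    term <- vals[length(vals)]
    if (term == 999) div <- 100 else if (term == -9999) div <- 1000
    else stop("series ", id, ": unknown terminator value ", term,
              " (expected 999 or -9999)")
    w <- vals[-length(vals)] / div
    if (!length(w)) stop("series ", id, ": no data values before terminator")
    if (any(w < 0)) stop("series ", id, ": negative ring width")
    out[[id]] <- data.frame(core = id, year = first_year + seq_along(w) - 1L,
                            width = w, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("qwa_rwl", "data.frame")
  res
}

#' Write ring widths to a Tucson (.rwl) decadal file
#'
#' Emits the 0.01 mm dialect (series terminator `999`), with lines broken at
#' decade boundaries as conventionally produced by measuring software.
#'
#' @param rwl A `qwa_rwl` long data frame (`core`, `year`, `width` in mm).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_rwl <- function(rwl, path) {
  stopifnot(all(c("core", "year", "width") %in% names(rwl)))
  con <- file(path, "w")
  on.exit(close(con))
  for (id in unique(rwl$core)) {
    d <- rwl[rwl$core == id, , drop = FALSE]
    d <- d[order(d$year), , drop = FALSE]
    if (any(diff(d$year) != 1L))
      stop("series ", id, ": years must be contiguous to write Tucson format")
    fields <- sprintf("%6d", as.integer(round(d$width * 100)))
    fields <- c(fields, sprintf("%6d", 999L))
    yrs <- c(d$year, d$year[length(d$year)] + 1L)
    i <- 1L
    while (i <= length(fields)) {
      y <- yrs[i]
      n_in_row <- min(10L - (y %% 10L), length(fields) - i + 1L)
      row <- paste0(formatC(substr(id, 1L, 8L), width = -8L),
                    sprintf("%4d", y),
                    paste(fields[i:(i + n_in_row - 1L)], collapse = ""))
      writeLines(row, con)
      i <- i + n_in_row
    }
  }
  invisible(path)
}

#' Ring-width series as a year-by-core matrix
#'
#' @param rwl A `qwa_rwl` long data frame.
#' @return Numeric matrix with contiguous years as rownames and cores as
#'   columns; years missing from a series are `NA`.
#' @export
rwl_to_matrix <- function(rwl) {
  years <- seq(min(rwl$year), max(rwl$year))
  cores <- unique(rwl$core)
  m <- matrix(NA_real_, length(years), length(cores),
              dimnames = list(years, cores))
  m[cbind(match(rwl$year, years), match(rwl$core, cores))] <- rwl$width
  m
}

#' @export
print.qwa_rwl <- function(x, ...) {
  cat("<qwa_rwl> ", length(unique(x$core)), " series; years ",
      min(x$year), "-", max(x$year), "\n", sep = "")
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}
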