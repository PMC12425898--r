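#' Column-name dialect for per-cell measurement tables
#'
#' Cell-level exports from image-analysis software differ in column naming
#' between versions, so the reader is configured with a dialect: a map from
#' the canonical field names used throughout this package to the column names
#' found in the file.
#'
#' @param sep Field separator ("," for CSV, "\t" for TSV).
#' @param tree,core,year,file,rank,ld,cwt Column names in the file holding,
#'   respectively: tree label, core label, calendar ring year, radial-file
#'   label, 1-based cell position from the ring start, lumen radial diameter
#'   (micrometers), and tangential cell wall thickness (micrometers).
#' @return A named list of class `qwa_dialect`.
#' @export
#' @examples
#' cell_dialect(sep = "\t", ld = "LD.um", cwt = "CWT.um")
cell_dialect <- function(sep = ",", tree = "tree", core = "core", year = "year",
                         file = "file", rank = "rank", ld = "ld", cwt = "cwt") {
  structure(list(sep = sep, tree = tree, core = core, year = year,
                 file = file, rank = rank, ld = ld, cwt = cwt),
            class = "qwa_dialect")
}

#' Validate a data frame of per-cell anatomical measurements
#'
#' Enforces the cell-record contract: positive lumen diameter and wall
#' thickness, cell ranks >= 1 and unique within each radial file, and sorts
#' records by (tree, core, year, file, rank). Violations are reported with
#' row numbers (relative to the incoming order) so they can be traced back to
#' the source file.
#'
#' @param df Data frame with columns `tree`, `core`, `year`, `file`, `rank`,
#'   `ld`, `cwt`.
#' @return The validated, sorted data frame with class `qwa_cells`.
#' @export
as_qwa_cells <- function(df) {
  need <- c("tree", "core", "year", "file", "rank", "ld", "cwt")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cell table is missing required column(s): ", paste(miss, collapse = ", "))
  df <- df[need]
  df$tree <- as.character(df$tree)
  df$core <- as.character(df$core)
  df$file <- as.character(df$file)
  suppressWarnings({
    df$year <- as.integer(df$year)
    df$rank <- as.integer(df$rank)
    df$ld <- as.numeric(df$ld)
    df$cwt <- as.numeric(df$cwt)
  })
  bad <- which(!is.finite(df$ld) | df$ld <= 0)
  if (length(bad))
    stop("non-positive or non-numeric lumen diameter (ld) at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  bad <- which(!is.finite(df$cwt) | df$cwt <= 0)
  if (length(bad))
    stop("non-positive or non-numeric wall thickness (cwt) at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  bad <- which(is.na(df$year) | is.na(df$rank) | df$rank < 1L)
  if (length(bad))
    stop("missing year or invalid cell rank (must be >= 1) at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  key <- paste(df$tree, df$core, df$year, df$file, df$rank, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    k <- strsplit(key[dup[1L]], "\r", fixed = TRUE)[[1L]]
    stop("duplicated cell key (tree=", k[1], ", core=", k[2], ", year=", k[3],
         ", file=", k[4], ", rank=", k[5], ") at row ", dup[1L],
         if (length(dup) > 1L) paste0(" and ", length(dup) - 1L, " more") else "")
  }
  df <- df[order(df$tree, df$core, df$year, df$file, df$rank), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("qwa_cells", "data.frame")
  df
}

#' Read a per-cell anatomical measurement table
#'
#' Reads a delimited table of tracheid measurements (one row per cell) and
#' validates it against the cell-record contract. Malformed rows are rejected
#' with the offending row number, never silently coerced.
#'
#' @param path Path to the delimited file (with a header row).
#' @param dialect A [cell_dialect()] mapping canonical fields to the file's
#'   column names.
#' @return A `qwa_cells` data frame sorted by (tree, core, year, file, rank).
#' @seealso [write_cell_table()], [build_sector_matrix()]
#' @export
read_cell_table <- function(path, dialect = cell_dialect()) {
  if (!file.exists(path)) stop("cell table not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  cols <- unlist(dialect[c("tree", "core", "year", "file", "rank", "ld", "cwt")])
  miss <- setdiff(cols, names(raw))
  if (length(miss))
    stop("cell table ", path, " is missing column(s): ", paste(miss, collapse = ", "))
  df <- data.frame(tree = raw[[dialect$tree]], core = raw[[dialect$core]],
                   year = raw[[dialect$year]], file = raw[[dialect$file]],
                   rank = raw[[dialect$rank]], ld = raw[[dialect$ld]],
                   cwt = raw[[dialect$cwt]], stringsAsFactors = FALSE)
  as_qwa_cells(df)
}

#' Write a per-cell measurement table
#'
#' @param cells A `qwa_cells` data frame (see [as_qwa_cells()]).
#' @param path Output path.
#' @param sep Field separator.
#' @return The path, invisibly.
#' @export
write_cell_table <- function(cells, path, sep = ",") {
  cells <- as_qwa_cells(as.data.frame(cells))
  utils::write.table(cells, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.qwa_cells <- function(x, ...) {
  cat("<qwa_cells> ", nrow(x), " cells; ",
      length(unique(x$tree)), " trees; years ",
      min(x$year), "-", max(x$year), "\n", sep = "")
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}
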