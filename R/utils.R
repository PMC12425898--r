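# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Month-slot labels spanning the previous and current calendar year
#'
#' Dendroclimatic correlation analyses use a 24-slot month axis: slots 1-12
#' are January-December of the year preceding ring formation (labelled
#' `pJan`..`pDec`), slots 13-24 are January-December of the growth year
#' (`Jan`..`Dec`).
#'
#' @return Character vector of 24 slot labels.
#' @export
month_slot_labels <- function() {
  c(paste0("p", month.abb), month.abb)
}

# label for a window of month slots, e.g. "May-Jun" or "pMar-Oct"
.window_label <- function(start_slot, end_slot) {
  lab <- month_slot_labels()
  if (start_slot == end_slot) lab[end_slot]
  else paste(lab[start_slot], lab[end_slot], sep = "-")
}

# Roman sector labels I..X
.sector_labels <- function(n_sectors) as.character(utils::as.roman(seq_len(n_sectors)))

.is_count <- function(x) length(x) == 1L && is.finite(x) && x == round(x) && x >= 1

# write a data.frame with '#'-prefixed header lines carrying run metadata
.write_table <- function(df, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

.read_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = ",", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
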