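#' Write a sweep table as CSV
#'
#' Writes an error-summary table (from [simulate_cell()] or the sweep
#' functions) as an RFC-4180-style CSV with a header row. Numeric columns
#' are serialized at 9 significant digits; seeds and iteration counts are
#' recorded in every row for provenance.
#'
#' @param x a data.frame of error summaries.
#' @param path output file path, or `""` for standard output.
#' @return `x`, invisibly.
#' @export
write_sweep_csv <- function(x, path) {
  stopifnot(is.data.frame(x))
  out <- as.data.frame(x)
  for (col in names(out)) {
    if (is.double(out[[col]])) out[[col]] <- signif(out[[col]], 9)
  }
  utils::write.csv(out, file = path, row.names = FALSE, quote = FALSE)
  invisible(x)
}

#' Read a sweep table written by [write_sweep_csv()]
#'
#' @param path CSV file path.
#' @return A data.frame.
#' @export
read_sweep_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
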