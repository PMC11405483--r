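#' Write a per-nucleus feature table to CSV
#'
#' One row per nucleus, stable column order, all lengths in µm. CSV is used
#' as the interchange format between pipeline stages: it is lossless at the
#' written precision and diff-able.
#'
#' @param records A non-empty data frame (e.g. from [extract_features()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("`records` must be a non-empty data frame", call. = FALSE)
  }
  readr::write_csv(records, path)
  invisible(path)
}

#' Read a feature table written by [write_table()]
#' @param path CSV path.
#' @return A tibble.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
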