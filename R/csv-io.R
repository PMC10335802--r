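#' @title CSV recording
#' @description Plain-text fallback for recordings: one file per stream. An
#'   EEG stream is a CSV with a `timestamp` column followed by one column
#'   per channel (full `%.17g` precision, so values round-trip exactly); a
#'   marker stream is a CSV with columns `timestamp,label,class,phase`.
#' @name csv_io
NULL

#' Write an EEG block to CSV
#' @param block A [sample_block()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_block_csv <- function(block, path) {
  df <- data.frame(timestamp = sprintf("%.17g", block$timestamps))
  for (j in seq_len(ncol(block$values))) {
    df[[block$channel_labels[j]]] <- sprintf("%.17g", block$values[, j])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an EEG block from CSV
#' @param path File written by [write_block_csv()].
#' @param rate Nominal rate to attach (Hz); inferred from the median
#'   timestamp spacing when `NULL`.
#' @return A [sample_block()].
#' @export
read_block_csv <- function(path, rate = NULL) {
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE)
  ts <- as.numeric(df$timestamp)
  vals <- as.matrix(as.data.frame(lapply(df[-1L], as.numeric)))
  if (is.null(rate)) {
    rate <- if (length(ts) > 1L) 1 / stats::median(diff(ts)) else 0
  }
  sample_block(ts, vals, rate = rate,
               channel_labels = colnames(df)[-1L])
}

#' Write markers to CSV
#' @param markers List of [marker_event()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_markers_csv <- function(markers, path) {
  df <- markers_to_df(markers)
  df$timestamp <- sprintf("%.17g", df$timestamp)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read markers from CSV
#' @param path File written by [write_markers_csv()].
#' @return List of [marker_event()].
#' @export
read_markers_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  df$timestamp <- as.numeric(df$timestamp)
  df_to_markers(df)
}
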