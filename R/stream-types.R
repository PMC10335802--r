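#' Stream metadata
#'
#' Describes one logical stream of a session: a regularly sampled EEG stream,
#' an irregular marker stream, or a free-form message stream. This mirrors the
#' metadata header of a lab-streaming style outlet: data only become
#' interpretable together with their name, type, channel labels and nominal
#' rate.
#'
#' @param name Stream identifier (string).
#' @param stream_type One of `"eeg"`, `"markers"`, `"messages"`.
#' @param channel_labels Character vector of channel names. Required and
#'   non-empty for `"eeg"` streams.
#' @param nominal_rate Sampling rate in Hz. Must be `> 0` for EEG streams and
#'   `0` for irregular (marker/message) streams.
#' @param source_id Stable identifier of the producing device/process.
#' @return An object of class `stream_info`.
#' @export
stream_info <- function(name, stream_type = c("eeg", "markers", "messages"),
                        channel_labels = character(), nominal_rate = 0,
                        source_id = name) {
  stream_type <- match.arg(stream_type)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (stream_type == "eeg") {
    if (!(nominal_rate > 0)) {
      stop("eeg streams must declare a positive nominal_rate", call. = FALSE)
    }
    if (length(channel_labels) < 1L) {
      stop("eeg streams need at least one channel label", call. = FALSE)
    }
  } else if (nominal_rate != 0) {
    stop(sprintf("%s streams are irregular: nominal_rate must be 0",
                 stream_type), call. = FALSE)
  }
  structure(
    list(name = name, stream_type = stream_type,
         channel_labels = as.character(channel_labels),
         nominal_rate = as.numeric(nominal_rate),
         source_id = source_id),
    class = "stream_info"
  )
}

#' Timestamped multichannel sample block
#'
#' The unit of data flowing along graph edges: a `[n samples x n channels]`
#' numeric matrix plus per-sample timestamps in seconds on the session clock.
#' Timestamps are strictly increasing; for regular streams their spacing is
#' approximately `1 / rate`. All ingest paths normalise timestamps to seconds
#' (hardware clocks disagree on unit and offset), recording any applied shift
#' in the `offset` field.
#'
#' @param timestamps Numeric vector, strictly increasing, seconds.
#' @param values Numeric matrix with `length(timestamps)` rows.
#' @param rate Nominal sampling rate in Hz (0 = irregular).
#' @param channel_labels Optional channel names; defaults to `ch1..chK`.
#' @param offset Declared clock offset (s) already subtracted at ingest.
#' @return An object of class `sample_block`.
#' @export
sample_block <- function(timestamps, values, rate = 0,
                         channel_labels = NULL, offset = 0) {
  values <- as.matrix(values)
  timestamps <- as.numeric(timestamps)
  n <- length(timestamps)
  if (n == 0L && nrow(values) == 0L) {
    values <- matrix(numeric(0), nrow = 0L,
                     ncol = max(ncol(values), length(channel_labels), 1L))
  }
  if (nrow(values) != n) {
    stop("values must have one row per timestamp", call. = FALSE)
  }
  if (n > 1L && any(diff(timestamps) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(ncol(values)))
  }
  if (length(channel_labels) != ncol(values)) {
    stop("channel_labels length must match channel count", call. = FALSE)
  }
  colnames(values) <- channel_labels
  structure(
    list(timestamps = timestamps, values = values, rate = as.numeric(rate),
         channel_labels = as.character(channel_labels),
         offset = as.numeric(offset)),
    class = "sample_block"
  )
}

#' @export
print.sample_block <- function(x, ...) {
  cat(sprintf("<sample_block: %d samples x %d channels, rate %g Hz",
              n_samples(x), ncol(x$values), x$rate))
  if (n_samples(x) > 0) {
    cat(sprintf(", t = [%.4f, %.4f] s", x$timestamps[1],
                x$timestamps[n_samples(x)]))
  }
  cat(">\n")
  invisible(x)
}

#' Number of samples in a block
#' @param block A `sample_block`.
#' @return Integer sample count.
#' @export
n_samples <- function(block) length(block$timestamps)

#' Duration covered by a block
#'
#' Defined on the half-open sampling convention: `n / rate` for regular
#' streams (each sample owns one sampling period), the timestamp span for
#' irregular ones.
#' @param block A `sample_block`.
#' @return Duration in seconds.
#' @export
block_duration <- function(block) {
  n <- n_samples(block)
  if (n == 0L) return(0)
  if (block$rate > 0) n / block$rate else diff(range(block$timestamps))
}

#' Concatenate sample blocks in time
#' @param ... `sample_block` objects with identical channel layout.
#' @return A single `sample_block`.
#' @export
bind_blocks <- function(...) {
  blocks <- list(...)
  blocks <- blocks[vapply(blocks, n_samples, 1L) > 0L]
  if (length(blocks) == 0L) {
    b <- list(...)[[1L]]
    return(b)
  }
  sample_block(
    timestamps = unlist(lapply(blocks, `[[`, "timestamps")),
    values = do.call(rbind, lapply(blocks, `[[`, "values")),
    rate = blocks[[1L]]$rate,
    channel_labels = blocks[[1L]]$channel_labels
  )
}

#' Slice a block by sample index
#' @param block A `sample_block`.
#' @param idx Integer vector of row indices (kept in order).
#' @return A `sample_block` holding the selected samples.
#' @export
slice_block <- function(block, idx) {
  sample_block(block$timestamps[idx],
               block$values[idx, , drop = FALSE],
               rate = block$rate, channel_labels = block$channel_labels)
}

#' Marker event
#'
#' An irregularly timed stimulus/command event. The payload is a key-value
#' list; `label`, `class` and `phase` are the conventional keys used by the
#' session controllers and the epoching node.
#'
#' @param timestamp Event time in seconds (finite).
#' @param ... Payload entries, e.g. `label = "stim"`, `class = 2L`.
#' @param payload Alternatively, a named list of payload entries.
#' @return An object of class `marker_event`.
#' @export
marker_event <- function(timestamp, ..., payload = NULL) {
  if (is.null(payload)) payload <- list(...)
  stopifnot(is.numeric(timestamp), length(timestamp) == 1L,
            is.finite(timestamp))
  if (length(payload) && is.null(names(payload))) {
    stop("marker payload entries must be named", call. = FALSE)
  }
  structure(list(timestamp = as.numeric(timestamp), payload = payload),
            class = "marker_event")
}

#' @export
print.marker_event <- function(x, ...) {
  kv <- paste(names(x$payload),
              vapply(x$payload, function(v) paste(format(v), collapse = ","),
                     ""),
              sep = "=", collapse = " ")
  cat(sprintf("<marker %.4f s: %s>\n", x$timestamp, kv))
  invisible(x)
}

#' Extract timestamps from a list of markers
#' @param markers List of `marker_event`.
#' @return Numeric vector of timestamps (seconds).
#' @export
marker_times <- function(markers) {
  vapply(markers, `[[`, numeric(1), "timestamp")
}

#' Convert markers to a data frame
#'
#' Flattens the conventional payload keys (`label`, `class`, `phase`) into
#' columns; other keys are dropped (use XDF for full-fidelity payloads).
#' @param markers List of `marker_event`.
#' @return A data frame with columns `timestamp`, `label`, `class`, `phase`.
#' @export
markers_to_df <- function(markers) {
  pick <- function(m, key) {
    v <- m$payload[[key]]
    if (is.null(v)) NA_character_ else as.character(v)
  }
  data.frame(
    timestamp = marker_times(markers),
    label = vapply(markers, pick, "", "label"),
    class = vapply(markers, pick, "", "class"),
    phase = vapply(markers, pick, "", "phase"),
    stringsAsFactors = FALSE
  )
}

#' Rebuild marker events from a data frame
#' @param df Data frame with columns `timestamp`, `label`, `class`, `phase`.
#' @return List of `marker_event`.
#' @export
df_to_markers <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    payload <- list()
    for (key in c("label", "class", "phase")) {
      v <- df[[key]][i]
      if (!is.null(v) && !is.na(v) && nzchar(v)) payload[[key]] <- v
    }
    marker_event(df$timestamp[i], payload = payload)
  })
}
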