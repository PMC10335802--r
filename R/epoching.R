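#' Epoch window specification
#'
#' Defines an extraction window relative to a marker onset, with an optional
#' baseline sub-window. Windows are half-open `[onset + t_min, onset +
#' t_max)`: the boundary sample belongs to the next window, which makes
#' rolling-window counts exact.
#'
#' @param t_min Window start relative to onset, s (negative = pre-stimulus).
#' @param t_max Window end relative to onset, s (`> t_min`).
#' @param baseline Optional `(b0, b1)` baseline window, a sub-interval of
#'   `[t_min, t_max]`.
#' @return An object of class `epoch_spec`.
#' @export
epoch_spec <- function(t_min = -0.2, t_max = 0.8, baseline = NULL) {
  stopifnot(t_max > t_min)
  if (!is.null(baseline)) {
    stopifnot(length(baseline) == 2L, baseline[1] < baseline[2],
              baseline[1] >= t_min, baseline[2] <= t_max)
  }
  structure(list(t_min = t_min, t_max = t_max, baseline = baseline),
            class = "epoch_spec")
}

#' Construct an epoch
#'
#' A fixed-length `channels x samples` matrix tied to an onset time.
#' Streaming blocks are samples-by-channels (appending rows is natural);
#' epochs are channels-by-samples (covariance math wants channels as rows).
#' The orientation conversion happens exactly once, here.
#'
#' @param onset Onset time, s (the marker time for time-locked epochs).
#' @param data Numeric matrix, channels x samples.
#' @param fs Sampling rate, Hz.
#' @param t_min Time of the first sample relative to onset, s.
#' @param label Optional class label (present iff the source marker carried
#'   one).
#' @param meta Named list of extra metadata.
#' @return An object of class `epoch`.
#' @export
new_epoch <- function(onset, data, fs, t_min = 0, label = NULL,
                      meta = list()) {
  data <- as.matrix(data)
  stopifnot(ncol(data) >= 2L, fs > 0)
  structure(list(onset = onset, data = data, fs = fs, t_min = t_min,
                 label = label, meta = meta),
            class = "epoch")
}

#' @export
print.epoch <- function(x, ...) {
  cat(sprintf("<epoch @ %.4f s: %d ch x %d samples%s>\n", x$onset,
              nrow(x$data), ncol(x$data),
              if (is.null(x$label)) "" else paste0(", label ", x$label)))
  invisible(x)
}

#' Sample times of an epoch relative to its onset
#' @param epoch An `epoch`.
#' @return Numeric vector, seconds.
#' @export
epoch_times <- function(epoch) {
  epoch$t_min + (seq_len(ncol(epoch$data)) - 1L) / epoch$fs
}

#' Cut epochs time-locked to markers
#'
#' For each marker, the epoch starts at the first sample whose timestamp is
#' at or after `onset + t_min` (matching by timestamp, not sample index, is
#' robust to marker jitter; alignment error is below one sample period).
#' Markers whose window is not fully covered by the block are skipped and
#' reported with a reason; markers always equal epochs plus skips.
#'
#' @param block A [sample_block()] with `rate > 0`.
#' @param markers List of [marker_event()].
#' @param spec An [epoch_spec()].
#' @return List of `epoch` objects with attribute `"skipped"`, a data frame
#'   of `(marker, reason)` rows for markers that produced no epoch. Labels
#'   are copied from the marker payload key `label` when present.
#' @export
epoch_timelocked <- function(block, markers, spec) {
  fs <- block$rate
  stopifnot(fs > 0)
  n_samp <- round((spec$t_max - spec$t_min) * fs)
  if (n_samp < 2L) stop("epoch window shorter than 2 samples", call. = FALSE)
  n <- n_samples(block)
  epochs <- list()
  skipped <- data.frame(marker = integer(0), reason = character(0),
                        stringsAsFactors = FALSE)
  tol <- 0.5 / max(fs, 1)
  for (i in seq_along(markers)) {
    m <- markers[[i]]
    start <- m$timestamp + spec$t_min
    i0 <- findInterval(start - 1e-9, block$timestamps) + 1L
    if (i0 < 1L || n == 0L || block$timestamps[min(i0, n)] < start - tol) {
      skipped <- rbind(skipped, data.frame(marker = i,
                                           reason = "before stream start"))
      next
    }
    if (i0 + n_samp - 1L > n) {
      skipped <- rbind(skipped, data.frame(marker = i,
                                           reason = "insufficient data"))
      next
    }
    seg <- t(block$values[i0:(i0 + n_samp - 1L), , drop = FALSE])
    ep <- new_epoch(onset = m$timestamp, data = seg, fs = fs,
                    t_min = spec$t_min, label = m$payload$label,
                    meta = m$payload[setdiff(names(m$payload), "label")])
    epochs[[length(epochs) + 1L]] <- ep
  }
  attr(epochs, "skipped") <- skipped
  epochs
}

#' Cut epochs on a rolling window
#'
#' Fixed-length, possibly overlapping windows at a fixed step, used for
#' feedback phases where the mental state is not time-locked to a stimulus.
#' For a stream of duration `T >= length` the count is
#' `floor((T - length) / step) + 1`. Epochs carry no labels.
#'
#' @param block A [sample_block()] with `rate > 0`.
#' @param length Window length, s (`> 0`).
#' @param step Window step, s (`> 0`); `step == length` tiles the stream.
#' @return List of `epoch` objects (empty if the stream is shorter than one
#'   window).
#' @export
epoch_rolling <- function(block, length, step) {
  stopifnot(length > 0, step > 0)
  fs <- block$rate
  stopifnot(fs > 0)
  len_s <- round(length * fs)
  step_s <- max(1L, round(step * fs))
  if (len_s < 2L) stop("window shorter than 2 samples", call. = FALSE)
  n <- n_samples(block)
  if (n < len_s) return(list())
  starts <- seq.int(1L, n - len_s + 1L, by = step_s)
  lapply(starts, function(i0) {
    new_epoch(onset = block$timestamps[i0],
              data = t(block$values[i0:(i0 + len_s - 1L), , drop = FALSE]),
              fs = fs, t_min = 0)
  })
}

#' Baseline-correct an epoch
#'
#' Subtracts, per channel, the mean over the baseline window, resetting the
#' signal to a common starting level at the event onset. The per-channel
#' mean over the window is exactly zero afterwards (to float rounding), the
#' operation is idempotent, and it adds no processing delay since it only
#' uses samples already inside the epoch.
#'
#' @param epoch An `epoch`.
#' @param window `(b0, b1)` relative to onset, a sub-interval of the epoch;
#'   half-open `[b0, b1)` in sample terms.
#' @return The corrected `epoch`.
#' @export
baseline_correct <- function(epoch, window) {
  stopifnot(length(window) == 2L, window[2] > window[1])
  rel <- epoch_times(epoch)
  tol <- 1e-9
  idx <- which(rel >= window[1] - tol & rel < window[2] - tol)
  if (length(idx) == 0L) {
    stop("baseline window contains no samples", call. = FALSE)
  }
  epoch$data <- epoch$data - rowMeans(epoch$data[, idx, drop = FALSE])
  epoch
}
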