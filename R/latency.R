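#' @title Stimulus-to-EEG latency calibration
#' @description Every stimulus chain (graphics pipeline, wireless EEG link)
#'   adds an unknown fixed delay between the logged stimulus marker and the
#'   moment the stimulus reaches the EEG record. A human tapping the headset
#'   in sync with visual flashes creates large artifacts whose offsets from
#'   the flash markers estimate that delay; tap timing noise averages out
#'   over many taps.
#' @name latency_calib
NULL

#' Detect tap artifacts in an EEG block
#'
#' The block is drift-corrected with a causal 1 Hz high-pass (running-mean
#' subtraction over the trailing second — zero lag for a sharp artifact
#' edge, unlike a long FIR high-pass), channels are averaged after
#' rectification, and an onset is declared where the resulting amplitude
#' first exceeds its median by `threshold_sd` robust standard deviations
#' (median absolute deviation scaled); a refractory period suppresses re-triggering on the
#' decay. The reported onset is the midpoint between the last
#' sub-threshold and first supra-threshold sample, an unbiased sub-sample
#' convention.
#'
#' @param block A [sample_block()] with `rate > 0`.
#' @param threshold_sd Threshold multiplier (default 5).
#' @param refractory Minimum spacing between detections, s.
#' @return Sorted numeric vector of onset times (s); possibly empty.
#' @export
detect_tap_artifacts <- function(block, threshold_sd = 5, refractory = 0.25) {
  fs <- block$rate
  stopifnot(fs > 0)
  n <- n_samples(block)
  if (n == 0L) return(numeric(0))
  w <- max(1L, round(fs))
  x <- block$values
  # causal running mean over the trailing w samples, per channel
  cs <- apply(x, 2L, cumsum)
  cs <- rbind(matrix(0, 1L, ncol(x)), cs)
  idx <- seq_len(n)
  lo <- pmax(idx - w, 0L)
  base <- (cs[idx + 1L, , drop = FALSE] - cs[lo + 1L, , drop = FALSE]) /
    (idx - lo)
  amp <- rowMeans(abs(x - base))
  med <- stats::median(amp)
  scale <- stats::mad(amp)
  if (!is.finite(scale)) scale <- 0
  thr <- med + threshold_sd * scale
  if (!is.finite(thr)) return(numeric(0))
  above <- amp > thr
  ab <- which(above)
  if (length(ab) == 0L) return(numeric(0))
  refr_s <- round(refractory * fs)
  edges <- ab[c(TRUE, diff(ab) > 1L)]
  onsets <- numeric(0)
  for (e in edges) {
    prev <- ab[ab < e]
    if (length(prev) > 0L && e - max(prev) <= refr_s) next
    t_cross <- if (e == 1L) block$timestamps[1L] else {
      (block$timestamps[e - 1L] + block$timestamps[e]) / 2
    }
    onsets <- c(onsets, t_cross)
  }
  unique(sort(onsets))
}

#' Estimate a fixed marker-to-artifact latency
#'
#' Each marker is paired with the nearest artifact in `(marker, marker +
#' max_offset]`; each artifact is used at most once and unpaired markers
#' are dropped and counted. Offsets further than 3 robust standard
#' deviations (scaled MAD) from the median are rejected as outliers. The
#' estimate is the mean of the remaining offsets with its standard error.
#'
#' @param marker_times Numeric vector of stimulus marker times, s
#'   (`>= 1`).
#' @param artifact_times Numeric vector of detected artifact onsets, s.
#' @param max_offset Pairing window, s (default 0.5: tap reaction delays
#'   are typically below half a second).
#' @return An object of class `latency_estimate` with `mean_latency` and
#'   `std_error` in milliseconds, `n_pairs`, `n_dropped` and
#'   `outliers_rejected`.
#' @export
estimate_latency <- function(marker_times, artifact_times,
                             max_offset = 0.5) {
  if (length(marker_times) < 1L) stop("need at least one marker",
                                      call. = FALSE)
  marker_times <- sort(marker_times)
  artifact_times <- sort(artifact_times)
  used <- rep(FALSE, length(artifact_times))
  offsets <- numeric(0)
  dropped <- 0L
  for (m in marker_times) {
    ok <- which(!used & artifact_times > m &
                  artifact_times <= m + max_offset)
    if (length(ok) == 0L) {
      dropped <- dropped + 1L
      next
    }
    j <- ok[which.min(artifact_times[ok] - m)]
    used[j] <- TRUE
    offsets <- c(offsets, artifact_times[j] - m)
  }
  if (length(offsets) == 0L) {
    stop("no marker/artifact pairs found within max_offset", call. = FALSE)
  }
  med <- stats::median(offsets)
  scale <- stats::mad(offsets)
  keep <- if (scale > 0) abs(offsets - med) <= 3 * scale else {
    rep(TRUE, length(offsets))
  }
  rejected <- sum(!keep)
  offsets <- offsets[keep]
  n <- length(offsets)
  se <- if (n > 1L) stats::sd(offsets) / sqrt(n) else 0
  structure(
    list(mean_latency = 1000 * mean(offsets), std_error = 1000 * se,
         n_pairs = n, n_dropped = dropped, outliers_rejected = rejected),
    class = "latency_estimate"
  )
}

#' @export
print.latency_estimate <- function(x, ...) {
  cat(sprintf(
    "Latency estimate: %.1f ms (s.e. %.2f ms, n = %d pairs%s%s)\n",
    x$mean_latency, x$std_error, x$n_pairs,
    if (x$n_dropped > 0) sprintf(", %d markers unpaired", x$n_dropped)
    else "",
    if (x$outliers_rejected > 0) sprintf(", %d outliers rejected",
                                         x$outliers_rejected) else ""))
  invisible(x)
}

#' Run tap-artifact latency calibration on a session
#'
#' Convenience wrapper: detect artifacts in the EEG, pair them with the
#' flash markers and estimate the latency.
#'
#' @param eeg A [sample_block()].
#' @param markers List of [marker_event()] (flash markers).
#' @param threshold_sd,refractory Passed to [detect_tap_artifacts()].
#' @param max_offset Passed to [estimate_latency()].
#' @return A `latency_estimate`.
#' @export
calibrate_latency <- function(eeg, markers, threshold_sd = 5,
                              refractory = 0.25, max_offset = 0.5) {
  onsets <- detect_tap_artifacts(eeg, threshold_sd = threshold_sd,
                                 refractory = refractory)
  estimate_latency(marker_times(markers), onsets, max_offset = max_offset)
}

#' Acoustic propagation latency
#'
#' Sound travels at ~343 m/s in dry air at 20 degrees C, i.e. roughly 3 ms
#' per metre between a loudspeaker and the subject's ears.
#'
#' @param distance Speaker-to-ear distance in metres (`>= 0`).
#' @return Latency in milliseconds: `1000 * distance / 343`.
#' @export
#' @examples
#' acoustic_latency(1)   # ~2.92 ms
acoustic_latency <- function(distance) {
  if (any(distance < 0)) stop("distance must be >= 0", call. = FALSE)
  1000 * distance / 343
}

#' Worst-case display refresh jitter
#'
#' A stimulus drawn without synchronisation to the display refresh appears
#' after a uniform random delay between 0 and one refresh period; this
#' returns that worst-case bound in milliseconds (16.7 ms at 60 Hz).
#'
#' @param refresh_rate Display refresh rate, Hz (`> 0`).
#' @return Jitter bound in milliseconds: `1000 / refresh_rate`.
#' @export
#' @examples
#' refresh_jitter_bound(60)   # 16.7 ms
refresh_jitter_bound <- function(refresh_rate) {
  if (any(refresh_rate <= 0)) {
    stop("refresh_rate must be > 0", call. = FALSE)
  }
  1000 / refresh_rate
}
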