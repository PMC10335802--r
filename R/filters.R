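#' FIR filter specification
#'
#' Describes a causal linear-phase FIR filter built by the windowed-sinc
#' construction: take the ideal (non-causal) impulse response, time-shift it
#' by half the filter length and multiply by a Hamming window. The inherent
#' group delay `(order - 1) / (2 fs)` seconds is reported, never silently
#' compensated (compensation would be non-causal).
#'
#' @param kind One of `"bandpass"`, `"highpass"`, `"lowpass"`, `"notch"`.
#' @param band Numeric: `(low, high)` Hz for bandpass/notch, a single edge
#'   for highpass/lowpass.
#' @param order Number of taps; odd, `>= 3` (`order = 1` is the identity
#'   passthrough).
#' @param causal Flag, always `TRUE` here (kept for provenance records).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("bandpass", "highpass", "lowpass", "notch"),
                        band, order = 129L, causal = TRUE) {
  kind <- match.arg(kind)
  order <- as.integer(order)
  if (order < 1L || order %% 2L == 0L) {
    stop("order must be an odd positive integer", call. = FALSE)
  }
  need2 <- kind %in% c("bandpass", "notch")
  if (need2 && length(band) != 2L) {
    stop(sprintf("%s filters need band = c(low, high)", kind), call. = FALSE)
  }
  if (!need2 && length(band) != 1L) {
    stop(sprintf("%s filters need a single band edge", kind), call. = FALSE)
  }
  if (any(band <= 0) || (need2 && band[2] <= band[1])) {
    stop("band edges must be positive and increasing", call. = FALSE)
  }
  structure(list(kind = kind, band = as.numeric(band), order = order,
                 design = "fir-window", causal = isTRUE(causal)),
            class = "filter_spec")
}

hamming_window <- function(n) {
  if (n == 1L) return(1)
  0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
}

# Windowed-sinc lowpass prototype, DC gain normalised to 1.
fir_lowpass <- function(fc, fs, order) {
  m <- (order - 1L) / 2
  x <- seq_len(order) - 1L - m
  h <- ifelse(x == 0, 2 * fc / fs, sin(2 * pi * fc * x / fs) / (pi * x))
  h <- h * hamming_window(order)
  h / sum(h)
}

#' Design a linear-phase FIR filter
#'
#' Windowed-sinc (Hamming) design. Highpass and notch responses are built by
#' spectral inversion of the complementary lowpass/bandpass, which requires
#' an odd tap count.
#'
#' @param spec A [filter_spec()].
#' @param fs Sampling rate, Hz.
#' @return Numeric coefficient vector with attributes `group_delay`
#'   (seconds), `spec` and `fs`.
#' @export
#' @examples
#' h <- design_filter(filter_spec("bandpass", c(8, 30)), fs = 256)
#' group_delay(h)
design_filter <- function(spec, fs) {
  stopifnot(inherits(spec, "filter_spec"), fs > 0)
  if (any(spec$band >= fs / 2)) {
    stop("band edges must lie below the Nyquist frequency", call. = FALSE)
  }
  ord <- spec$order
  if (ord == 1L) {
    h <- 1
  } else {
    h <- switch(spec$kind,
      lowpass = fir_lowpass(spec$band, fs, ord),
      highpass = {
        h0 <- -fir_lowpass(spec$band, fs, ord)
        h0[(ord + 1L) / 2] <- h0[(ord + 1L) / 2] + 1
        h0
      },
      bandpass = fir_lowpass(spec$band[2], fs, ord) -
        fir_lowpass(spec$band[1], fs, ord),
      notch = {
        h0 <- -(fir_lowpass(spec$band[2], fs, ord) -
                  fir_lowpass(spec$band[1], fs, ord))
        h0[(ord + 1L) / 2] <- h0[(ord + 1L) / 2] + 1
        h0
      }
    )
  }
  structure(h, group_delay = (ord - 1L) / (2 * fs), spec = spec, fs = fs)
}

#' Group delay of a designed filter
#' @param coeffs Coefficients from [design_filter()].
#' @return Delay in seconds.
#' @export
group_delay <- function(coeffs) {
  gd <- attr(coeffs, "group_delay")
  if (is.null(gd)) (length(coeffs) - 1L) / 2 else gd
}

#' Frequency response magnitude of FIR taps
#'
#' Direct evaluation of the discrete-time Fourier transform of the
#' coefficient vector.
#' @param coeffs FIR coefficients.
#' @param freqs Frequencies (Hz) at which to evaluate.
#' @param fs Sampling rate, Hz (taken from the coefficients if designed
#'   here).
#' @return Numeric vector of `|H(f)|`.
#' @export
fir_gain <- function(coeffs, freqs, fs = attr(coeffs, "fs")) {
  stopifnot(!is.null(fs))
  k <- seq_along(coeffs) - 1L
  vapply(freqs, function(f) {
    Mod(sum(coeffs * exp(-2i * pi * f * k / fs)))
  }, numeric(1))
}

# Causal FIR on the columns of a matrix, zero initial conditions,
# output aligned with input (y[t] = sum_k h[k+1] x[t-k]).
apply_fir_matrix <- function(h, x) {
  p <- length(h)
  if (p == 1L) return(x * h)
  pad <- matrix(0, nrow = p - 1L, ncol = ncol(x))
  xx <- rbind(pad, x)
  out <- apply(xx, 2L, function(col) {
    stats::filter(col, h, method = "convolution", sides = 1)
  })
  out <- matrix(out, ncol = ncol(x))
  out[-seq_len(p - 1L), , drop = FALSE]
}

#' Streaming causal FIR filtering
#'
#' Applies an FIR filter to a sample block, carrying the filter state (the
#' last `order - 1` input samples) across calls so that chunked application
#' over split blocks is bit-equal to one-shot application on the
#' concatenation. Output at time `t` depends only on inputs at or before
#' `t`.
#'
#' @param coeffs Coefficients from [design_filter()].
#' @param block A [sample_block()].
#' @param state State returned by a previous call, or `NULL` to start from
#'   zero initial conditions.
#' @return A list with elements `block` (filtered samples, same timestamps)
#'   and `state`.
#' @export
apply_causal <- function(coeffs, block, state = NULL) {
  p <- length(coeffs)
  nch <- ncol(block$values)
  if (is.null(state)) {
    state <- list(buffer = matrix(0, nrow = p - 1L, ncol = nch))
  }
  if (nrow(state$buffer) != p - 1L) {
    stop("state does not match the filter order", call. = FALSE)
  }
  if (ncol(state$buffer) != nch) {
    stop("channel count changed mid-stream", call. = FALSE)
  }
  n <- n_samples(block)
  if (n == 0L) return(list(block = block, state = state))
  if (p == 1L) {
    out <- block$values * coeffs
  } else {
    xx <- rbind(state$buffer, block$values)
    out <- apply(xx, 2L, function(col) {
      stats::filter(col, coeffs, method = "convolution", sides = 1)
    })
    out <- matrix(out, ncol = nch)[-seq_len(p - 1L), , drop = FALSE]
    keep <- min(p - 1L, nrow(xx))
    state$buffer <- xx[nrow(xx) - keep + seq_len(keep) - 0L, , drop = FALSE]
    if (keep < p - 1L) {
      state$buffer <- rbind(matrix(0, p - 1L - keep, nch), state$buffer)
    }
  }
  filtered <- sample_block(block$timestamps, out, rate = block$rate,
                           channel_labels = block$channel_labels)
  list(block = filtered, state = state)
}

#' Narrow-band power per channel
#'
#' Electrode-contact proxy: energy in a narrow band around the mains
#' frequency rises when an electrode's impedance is poor. The block is
#' passed through a causal narrow band-pass centred on `f0`; the startup
#' transient (one filter length) is discarded and the mean squared output
#' is returned per channel. The implicit band-pass already removes the
#' sub-1 Hz drift a dedicated high-pass would target.
#'
#' @param block A [sample_block()].
#' @param f0 Centre frequency, Hz.
#' @param bw Bandwidth, Hz (band is `f0 +/- bw/2`).
#' @param order FIR tap count (odd).
#' @return Nonnegative numeric vector, one value per channel, monotone in
#'   the amplitude of an `f0` component.
#' @export
narrowband_power <- function(block, f0 = 50, bw = 4, order = 255L) {
  fs <- block$rate
  stopifnot(fs > 0)
  lo <- f0 - bw / 2
  hi <- f0 + bw / 2
  if (lo <= 1 || hi >= fs / 2) {
    stop("f0 +/- bw/2 must lie inside (1, fs/2)", call. = FALSE)
  }
  h <- design_filter(filter_spec("bandpass", c(lo, hi), order = order), fs)
  y <- apply_fir_matrix(as.numeric(h), block$values)
  drop_n <- min(length(h) - 1L, max(nrow(y) - 1L, 0L))
  if (drop_n > 0L) y <- y[-seq_len(drop_n), , drop = FALSE]
  stats::setNames(colMeans(y^2), block$channel_labels)
}
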