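#' Synthetic EEG generator configuration
#'
#' Bundles every knob of the built-in EEG simulator. Defaults describe a
#' plausible consumer-grade wireless headset: 256 Hz sampling, eight
#' channels, pink (1/f) background normalised to unit standard deviation per
#' channel, mild 50 Hz mains contamination, ~12 blinks/min, a 30 ms hidden
#' hardware latency (mid-range of the 20-40 ms delays reported for Bluetooth
#' headsets) and 5 ms marker timing jitter.
#'
#' Amplitudes are expressed relative to the unit-variance background, so
#' `erp_amp = 1` means an ERP peak equal to one background standard
#' deviation.
#'
#' @param fs Sampling rate, Hz.
#' @param n_channels Number of EEG channels.
#' @param noise_exponent Spectral slope alpha of the 1/f^alpha background.
#' @param line_freq Mains frequency, 50 or 60 Hz.
#' @param line_amp Line-noise sinusoid amplitude (relative units).
#' @param blink_rate Blink transients per minute (Poisson rate).
#' @param blink_amp Peak blink amplitude (relative units).
#' @param erp_amp ERP (P300-like) peak amplitude.
#' @param erp_latency ERP peak latency after the physical stimulus, s.
#' @param erp_width Gaussian ERP template standard deviation, s.
#' @param erd_band Frequency band (low, high) Hz of the motor-imagery
#'   sources.
#' @param erd_attenuation Multiplicative amplitude factor `<= 1` applied to a
#'   class-specific source (event-related desynchronisation).
#' @param hw_latency True (hidden) stimulus-to-EEG delay, s.
#' @param marker_jitter_sd Std. dev. of marker timestamp jitter, s.
#' @param tap_amp Peak amplitude of tap artifacts (relative units).
#' @param seed Integer RNG seed; identical seed + config gives bit-identical
#'   output.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(fs = 256, n_channels = 8, noise_exponent = 1,
                         line_freq = 50, line_amp = 0.2,
                         blink_rate = 12, blink_amp = 5,
                         erp_amp = 1, erp_latency = 0.3, erp_width = 0.05,
                         erd_band = c(8, 30), erd_attenuation = 0.7,
                         hw_latency = 0.03, marker_jitter_sd = 0.005,
                         tap_amp = 20, seed = 1L) {
  stopifnot(fs > 0, n_channels >= 1)
  if (!(erd_attenuation > 0 && erd_attenuation <= 1)) {
    stop("erd_attenuation must lie in (0, 1]", call. = FALSE)
  }
  amps <- c(line_amp, blink_amp, erp_amp, tap_amp)
  if (any(amps < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  if (marker_jitter_sd < 0) stop("marker_jitter_sd must be >= 0",
                                 call. = FALSE)
  stopifnot(length(erd_band) == 2L, erd_band[1] > 0, erd_band[2] > erd_band[1],
            erd_band[2] < fs / 2)
  structure(
    list(fs = fs, n_channels = as.integer(n_channels),
         noise_exponent = noise_exponent, line_freq = line_freq,
         line_amp = line_amp, blink_rate = blink_rate, blink_amp = blink_amp,
         erp_amp = erp_amp, erp_latency = erp_latency, erp_width = erp_width,
         erd_band = erd_band, erd_attenuation = erd_attenuation,
         hw_latency = hw_latency, marker_jitter_sd = marker_jitter_sd,
         tap_amp = tap_amp, seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<synth_config: %g Hz x %d ch, 1/f^%g + %g Hz line (amp %g),\n",
    "  erp amp %g @ %g s (sd %g s), erd %g-%g Hz att %g,\n",
    "  hw latency %g ms, jitter sd %g ms, seed %d>\n"),
    x$fs, x$n_channels, x$noise_exponent, x$line_freq, x$line_amp,
    x$erp_amp, x$erp_latency, x$erp_width, x$erd_band[1], x$erd_band[2],
    x$erd_attenuation, 1000 * x$hw_latency, 1000 * x$marker_jitter_sd,
    x$seed))
  invisible(x)
}
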