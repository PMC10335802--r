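#' @title Synthetic EEG sessions
#' @description Seeded generators for background EEG, oddball (P300)
#'   sessions, motor-imagery sessions and tap-calibration sessions. Every
#'   generator returns data with the statistical structure the downstream
#'   modules assume, together with a `truth` record sufficient to score any
#'   estimate made from the data.
#' @name synth_eeg
NULL

# 1/f^alpha noise by spectral shaping of white noise: one FFT per channel,
# amplitude gain f^(-alpha/2) (clamped below 0.5 Hz to bound drift, DC
# removed), normalised to unit standard deviation. Exactly seedable.
pink_noise_channel <- function(n, fs, alpha) {
  if (n == 0L) return(numeric(0))
  x <- stats::rnorm(n)
  if (alpha == 0) return(x / max(stats::sd(x), .Machine$double.eps))
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k) * fs / n
  g <- (pmax(f, 0.5))^(-alpha / 2)
  g[f == 0] <- 0
  y <- Re(stats::fft(stats::fft(x) * g, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s > 0) y <- y / s
  y
}

# Add a time-localised bump (Gaussian or one-sided exponential) to selected
# channels, in place on a values matrix. Truncated at +/- 5 widths.
add_transient <- function(values, timestamps, center, width, amp, weights,
                          shape = c("gauss", "expdecay")) {
  shape <- match.arg(shape)
  n <- length(timestamps)
  if (n == 0L || amp == 0) return(values)
  lo <- if (shape == "gauss") center - 5 * width else center
  hi <- center + 5 * width
  if (n > 1L) {
    # uniform grid: locate the window arithmetically
    dt <- timestamps[2L] - timestamps[1L]
    i0 <- max(1L, ceiling((lo - timestamps[1L]) / dt - 1e-9) + 1L)
    i1 <- min(n, floor((hi - timestamps[1L]) / dt + 1e-9) + 1L)
    if (i0 > i1) return(values)
    idx <- i0:i1
  } else {
    idx <- which(timestamps >= lo & timestamps <= hi)
    if (length(idx) == 0L) return(values)
  }
  t <- timestamps[idx]
  bump <- switch(shape,
    gauss = amp * exp(-((t - center)^2) / (2 * width^2)),
    expdecay = amp * exp(-(t - center) / width)
  )
  values[idx, ] <- values[idx, ] + outer(bump, weights)
  values
}

# Frontal-weighted blink profile: channel 1 is the most frontal.
blink_weights <- function(n_channels) {
  if (n_channels == 1L) return(1)
  1 - 0.9 * (seq_len(n_channels) - 1) / (n_channels - 1)
}

# Posterior channel subset carrying the ERP (P300 is centro-parietal).
erp_channel_weights <- function(n_channels) {
  w <- numeric(n_channels)
  w[seq.int(n_channels %/% 2 + 1L, n_channels)] <- 1
  w
}

# Background synthesis without touching the seed (sessions manage RNG once).
background_values <- function(n, config, include_blinks = TRUE) {
  values <- matrix(0, nrow = n, ncol = config$n_channels)
  if (n == 0L) return(values)
  t <- (seq_len(n) - 1L) / config$fs
  for (ch in seq_len(config$n_channels)) {
    values[, ch] <- pink_noise_channel(n, config$fs, config$noise_exponent)
    if (config$line_amp > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      values[, ch] <- values[, ch] +
        config$line_amp * sin(2 * pi * config$line_freq * t + phase)
    }
  }
  if (include_blinks && config$blink_rate > 0 && config$blink_amp > 0) {
    duration <- n / config$fs
    n_blinks <- stats::rpois(1, duration * config$blink_rate / 60)
    if (n_blinks > 0) {
      centers <- sort(stats::runif(n_blinks, 0, duration))
      w <- blink_weights(config$n_channels)
      for (c0 in centers) {
        values <- add_transient(values, t, c0, 0.1, config$blink_amp, w,
                                "gauss")
      }
    }
  }
  values
}

#' Generate background EEG
#'
#' Multichannel 1/f^alpha noise (unit standard deviation per channel) plus a
#' line-noise sinusoid with a random phase per channel and, if configured,
#' Poisson-timed frontal-weighted blink transients. Bit-identical for
#' identical seed and configuration.
#'
#' @param duration Length in seconds (`>= 0`); `floor(duration * fs)`
#'   samples are produced.
#' @param config A [synth_config()].
#' @param t0 Timestamp of the first sample, s.
#' @return A [sample_block()].
#' @export
#' @examples
#' bg <- make_background(2, synth_config(n_channels = 4, seed = 7))
#' bg
make_background <- function(duration, config = synth_config(), t0 = 0) {
  if (duration < 0) stop("duration must be >= 0", call. = FALSE)
  n <- floor(duration * config$fs)
  withr::with_seed(config$seed, {
    values <- background_values(n, config)
  })
  sample_block(timestamps = t0 + (seq_len(n) - 1L) / config$fs,
               values = values, rate = config$fs)
}

new_synth_session <- function(eeg, markers, truth) {
  tt <- marker_times(markers)
  if (length(tt) && n_samples(eeg) > 0) {
    span <- range(eeg$timestamps)
    if (any(tt < span[1] | tt > span[2])) {
      stop("internal: marker outside EEG time span", call. = FALSE)
    }
  }
  structure(list(eeg = eeg, markers = markers, truth = truth),
            class = "synth_session")
}

#' @export
print.synth_session <- function(x, ...) {
  cat(sprintf("<synth_session [%s]: %d samples x %d ch, %d markers>\n",
              x$truth$kind, n_samples(x$eeg), ncol(x$eeg$values),
              length(x$markers)))
  invisible(x)
}

#' Generate an oddball (P300) session
#'
#' Stimuli of `n_classes` categories are presented at a fixed
#' inter-stimulus interval. A Gaussian-windowed positive deflection
#' (amplitude `erp_amp`, peak `hw_latency + erp_latency` after the physical
#' stimulus onset, posterior channels only) is added after every
#' target-class stimulus and nowhere else. Marker timestamps are the
#' stimulus onsets corrupted by Gaussian timing jitter
#' (`marker_jitter_sd`), so the recorded markers do not reveal the hidden
#' hardware latency.
#'
#' @param n_classes Number of stimulus categories (`>= 2`).
#' @param n_stimuli Total number of stimuli.
#' @param isi Inter-stimulus interval, s.
#' @param target_class Target (deviant) class id in `1:n_classes`.
#' @param config A [synth_config()].
#' @param policy Stimulus sequencing: `"random"` (default) or
#'   `"round-robin"`. With rapid presentation the 0.8 s analysis epochs
#'   overlap neighbouring stimuli; under a deterministic round-robin
#'   cycle the target's ERP then leaks phase-locked into the epochs of
#'   the always-adjacent classes, which confounds any deviance statistic.
#'   Random sequences break that adjacency, so they are the default.
#' @return A `synth_session` with fields `eeg`, `markers` and `truth`
#'   (`target_class`, per-stimulus `labels`, true onsets, latency).
#' @export
make_oddball_session <- function(n_classes = 4, n_stimuli = 160, isi = 1 / 3,
                                 target_class = 1, config = synth_config(),
                                 policy = c("random", "round-robin")) {
  policy <- match.arg(policy)
  if (n_classes < 2) stop("n_classes must be >= 2", call. = FALSE)
  if (!(target_class %in% seq_len(n_classes))) {
    stop("target_class must be in 1:n_classes", call. = FALSE)
  }
  if (isi < config$erp_width) {
    warning("isi shorter than erp_width: successive ERPs overlap")
  }
  fs <- config$fs
  t0 <- 1
  onsets <- t0 + (seq_len(n_stimuli) - 1L) * isi
  duration <- t0 + (n_stimuli - 1L) * isi + 2
  n <- floor(duration * fs)
  t <- (seq_len(n) - 1L) / fs
  withr::with_seed(config$seed, {
    labels <- switch(policy,
      "round-robin" = rep_len(seq_len(n_classes), n_stimuli),
      "random" = sample(seq_len(n_classes), n_stimuli, replace = TRUE)
    )
    values <- background_values(n, config)
    w <- erp_channel_weights(config$n_channels)
    for (i in which(labels == target_class)) {
      center <- onsets[i] + config$hw_latency + config$erp_latency
      values <- add_transient(values, t, center, config$erp_width,
                              config$erp_amp, w, "gauss")
    }
    jitter <- stats::rnorm(n_stimuli, 0, config$marker_jitter_sd)
  })
  markers <- lapply(seq_len(n_stimuli), function(i) {
    marker_event(onsets[i] + jitter[i], label = "stim",
                 class = labels[i], phase = "stimuli")
  })
  eeg <- sample_block(t, values, rate = fs)
  new_synth_session(eeg, markers, truth = list(
    kind = "oddball", target_class = target_class, labels = labels,
    onsets = onsets, hw_latency = config$hw_latency,
    erp_latency = config$erp_latency, seed = config$seed
  ))
}

# Validate and factor a symmetric positive-definite matrix.
check_spd_input <- function(m, n_channels, what = "covariance") {
  m <- as.matrix(m)
  if (nrow(m) != n_channels || ncol(m) != n_channels) {
    stop(sprintf("%s must be %d x %d", what, n_channels, n_channels),
         call. = FALSE)
  }
  if (max(abs(m - t(m))) > 1e-10) {
    stop(sprintf("%s must be symmetric", what), call. = FALSE)
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop(sprintf("%s must be positive definite", what), call. = FALSE)
  }
  m
}

#' Generate a motor-imagery session
#'
#' Per-class epochs are built by mixing independent band-limited
#' (`erd_band`) unit-variance sources through the Cholesky factor of a
#' class-specific target covariance, so the band-passed channel covariance
#' of class `k` epochs converges to `class_covs[[k]]` as epoch length grows
#' — the generating covariances are the exact recovery target of the
#' downstream classifier. A faint background (amplitude 0.05) keeps the
#' inter-epoch signal non-degenerate without biasing the covariance
#' noticeably.
#'
#' If `class_covs` is `NULL`, two classes are built from the identity
#' covariance with event-related desynchronisation applied to one channel
#' per class: class k has channel k variance scaled by `erd_attenuation^2`.
#'
#' @param n_epochs_per_class Epochs per class.
#' @param class_covs List of symmetric positive-definite matrices, all
#'   `n_channels x n_channels`; or `NULL` for the two-class ERD default.
#' @param config A [synth_config()].
#' @param epoch_duration Length of each imagery epoch, s.
#' @param gap Inter-epoch gap, s.
#' @return A `synth_session`; `truth` records per-epoch `labels`, true
#'   `onsets` and the generating `class_covs`.
#' @export
make_mi_session <- function(n_epochs_per_class = 20, class_covs = NULL,
                            config = synth_config(), epoch_duration = 2,
                            gap = 0.5) {
  fs <- config$fs
  p <- config$n_channels
  if (is.null(class_covs)) {
    class_covs <- lapply(1:2, function(k) {
      m <- diag(p)
      m[k, k] <- config$erd_attenuation^2
      m
    })
  }
  class_covs <- lapply(seq_along(class_covs), function(k) {
    check_spd_input(class_covs[[k]], p, sprintf("class_covs[[%d]]", k))
  })
  n_classes <- length(class_covs)
  if (n_classes < 1) stop("need at least one class covariance", call. = FALSE)
  n_total <- n_epochs_per_class * n_classes
  n_samp <- round(epoch_duration * fs)
  t0 <- 1
  onsets <- t0 + (seq_len(n_total) - 1L) * (epoch_duration + gap)
  duration <- t0 + n_total * (epoch_duration + gap) + 1
  n <- floor(duration * fs)
  h <- design_filter(filter_spec("bandpass", config$erd_band), fs)
  warm <- length(h) - 1L
  h_gain <- sqrt(sum(h^2))  # sd of FIR-filtered unit white noise
  chols <- lapply(class_covs, chol)
  withr::with_seed(config$seed, {
    labels <- sample(rep(seq_len(n_classes), each = n_epochs_per_class))
    values <- 0.05 * background_values(n, config, include_blinks = FALSE)
    for (i in seq_len(n_total)) {
      src <- matrix(stats::rnorm((n_samp + warm) * p), ncol = p)
      src <- apply_fir_matrix(h, src)[-seq_len(warm), , drop = FALSE]
      src <- src / h_gain
      x <- src %*% chols[[labels[i]]]
      i0 <- floor((onsets[i] - 0) * fs) + 1L
      values[i0:(i0 + n_samp - 1L), ] <-
        values[i0:(i0 + n_samp - 1L), ] + x
    }
    jitter <- stats::rnorm(n_total, 0, config$marker_jitter_sd)
  })
  markers <- lapply(seq_len(n_total), function(i) {
    marker_event(onsets[i] + jitter[i], label = labels[i],
                 class = labels[i], phase = "calibration")
  })
  eeg <- sample_block((seq_len(n) - 1L) / fs, values, rate = fs)
  new_synth_session(eeg, markers, truth = list(
    kind = "mi", labels = labels, onsets = onsets,
    class_covs = class_covs, epoch_duration = epoch_duration,
    seed = config$seed
  ))
}

#' Generate a tap-calibration session
#'
#' Visual "flash" markers at a regular cadence; `true_latency +
#' Gaussian(0, tap_sd^2)` seconds after each flash a large sharp-onset
#' artifact (instant rise, exponential decay, all channels) is added to the
#' background — emulating a subject tapping the headset in sync with the
#' flashes. Marker timestamps are exact; the latency is hidden in the data.
#'
#' @param n_taps Number of flash/tap pairs (`>= 1`).
#' @param true_latency True stimulus-to-EEG latency, s.
#' @param tap_sd Std. dev. of human tap timing, s (`>= 0`).
#' @param config A [synth_config()]; `tap_amp` sets artifact amplitude.
#' @param iti Inter-flash interval, s.
#' @return A `synth_session`; `truth` records `true_latency`, flash times
#'   and realised tap times.
#' @export
make_tap_session <- function(n_taps, true_latency = 0.12, tap_sd = 0.03,
                             config = synth_config(), iti = 1) {
  if (n_taps < 1) stop("n_taps must be >= 1", call. = FALSE)
  if (tap_sd < 0) stop("tap_sd must be >= 0", call. = FALSE)
  fs <- config$fs
  t0 <- 2
  flashes <- t0 + (seq_len(n_taps) - 1L) * iti
  duration <- t0 + n_taps * iti + 1
  n <- floor(duration * fs)
  t <- (seq_len(n) - 1L) / fs
  withr::with_seed(config$seed, {
    values <- background_values(n, config, include_blinks = FALSE)
    taps <- flashes + true_latency + stats::rnorm(n_taps, 0, tap_sd)
    for (ta in taps) {
      values <- add_transient(values, t, ta, 0.03, config$tap_amp,
                              rep(1, config$n_channels), "expdecay")
    }
  })
  markers <- lapply(flashes, function(ft) {
    marker_event(ft, label = "flash", phase = "calibration")
  })
  eeg <- sample_block(t, values, rate = fs)
  new_synth_session(eeg, markers, truth = list(
    kind = "tap", true_latency = true_latency, flash_times = flashes,
    tap_times = taps, tap_sd = tap_sd, seed = config$seed
  ))
}
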