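# Filtering, epoching, baselining, narrow-band power.

test_that("designed filters meet their frequency-response contract", {
  h <- design_filter(filter_spec("bandpass", c(8, 30)), 256)
  expect_gte(fir_gain(h, 15), 0.9)
  expect_lte(fir_gain(h, 50), 0.1)
  expect_equal(group_delay(h), 128 / (2 * 256))

  hn <- design_filter(filter_spec("notch", c(46, 54), order = 257L), 256)
  expect_lte(fir_gain(hn, 50), 0.05)
  expect_gte(fir_gain(hn, 40), 0.9)

  # identity passthrough
  h1 <- design_filter(filter_spec("lowpass", 30, order = 1L), 256)
  x <- matrix(rnorm(100), ncol = 2)
  expect_equal(apply_fir_matrix(as.numeric(h1), x), x)

  expect_error(design_filter(filter_spec("lowpass", 200), 256), "Nyquist")
  expect_error(filter_spec("bandpass", c(30, 8)), "increasing")
  expect_error(filter_spec("lowpass", 10, order = 128L), "odd")
})

test_that("causality holds for random FIR specs (impulse oracle)", {
  withr::with_seed(11, {
    for (rep in 1:50) {
      kind <- sample(c("bandpass", "highpass", "lowpass", "notch"), 1)
      edges <- sort(runif(2, 2, 120))
      band <- if (kind %in% c("bandpass", "notch")) edges else edges[1]
      ord <- sample(c(33L, 65L, 129L), 1)
      h <- design_filter(filter_spec(kind, band, order = ord), 256)
      k <- sample(50:150, 1)
      imp <- matrix(0, 300, 1)
      imp[k, 1] <- 1
      y <- apply_fir_matrix(as.numeric(h), imp)
      expect_equal(max(abs(y[seq_len(k - 1L), 1])), 0)
      expect_equal(y[k, 1], as.numeric(h)[1])
    }
  })
})

test_that("chunked filtering equals one-shot filtering", {
  cfg <- quiet_cfg(seed = 3, n_channels = 3)
  blk <- make_background(10, cfg)
  h <- design_filter(filter_spec("bandpass", c(8, 30)), cfg$fs)
  full <- apply_causal(h, blk)$block$values
  withr::with_seed(21, {
    for (rep in 1:5) {
      cuts <- sort(sample(2:(n_samples(blk) - 1),
                          sample(1:8, 1)))
      bounds <- c(0, cuts, n_samples(blk))
      st <- NULL
      parts <- list()
      for (i in seq_len(length(bounds) - 1L)) {
        idx <- (bounds[i] + 1L):bounds[i + 1L]
        r <- apply_causal(h, slice_block(blk, idx), st)
        st <- r$state
        parts[[i]] <- r$block$values
      }
      expect_lt(max(abs(do.call(rbind, parts) - full)), 1e-12)
    }
  })
  # all-zero input stays zero; channel-count change is rejected
  z <- sample_block(blk$timestamps, matrix(0, n_samples(blk), 3),
                    rate = cfg$fs)
  expect_equal(max(abs(apply_causal(h, z)$block$values)), 0)
  st <- apply_causal(h, blk)$state
  two_ch <- slice_block(blk, 1:100)
  two_ch$values <- two_ch$values[, 1:2]
  expect_error(apply_causal(h, sample_block(two_ch$timestamps,
                                            two_ch$values, rate = cfg$fs),
                            st),
               "channel count")
})

test_that("time-locked epoching follows the timestamp convention", {
  cfg <- quiet_cfg(seed = 2, n_channels = 2)
  blk <- make_background(3, cfg)
  spec <- epoch_spec(t_min = -0.2, t_max = 0.8)
  eps <- epoch_timelocked(blk, list(marker_event(1.0, label = "a")), spec)
  expect_length(eps, 1L)
  expect_equal(ncol(eps[[1L]]$data), 256L)
  expect_equal(eps[[1L]]$label, "a")
  # first sample is the first timestamp at/after onset + t_min
  expect_equal(eps[[1L]]$onset + spec$t_min, 0.8, tolerance = 1e-9)
  i0 <- which(blk$timestamps >= 0.8 - 1e-9)[1L]
  expect_equal(unname(eps[[1L]]$data[1, ]),
               unname(blk$values[i0:(i0 + 255L), 1]))

  # marker too close to the end is skipped with a reason
  eps2 <- epoch_timelocked(blk, list(marker_event(2.9), marker_event(1.0)),
                           spec)
  expect_length(eps2, 1L)
  sk <- attr(eps2, "skipped")
  expect_equal(sk$reason, "insufficient data")
  # conservation: markers = epochs + skips
  expect_equal(length(eps2) + nrow(sk), 2L)
})

test_that("epochs align to generator truth within one sample", {
  cfg <- quiet_cfg(seed = 13)
  ses <- make_oddball_session(4, 100, 0.4, 1, cfg)
  spec <- epoch_spec(0, 0.8)
  eps <- epoch_timelocked(ses$eeg, ses$markers, spec)
  expect_equal(length(eps) + nrow(attr(eps, "skipped")), 100L)
  onsets <- vapply(eps, `[[`, numeric(1), "onset")
  starts <- onsets  # t_min = 0
  # each epoch's first sample timestamp is within one period of the marker
  first_ts <- vapply(seq_along(eps), function(i) {
    idx <- which(ses$eeg$timestamps >= starts[i] - 1e-9)[1L]
    ses$eeg$timestamps[idx]
  }, numeric(1))
  expect_true(all(first_ts - starts < 1 / cfg$fs))
})

test_that("rolling-window counts match brute-force enumeration", {
  cfg <- quiet_cfg(seed = 1, n_channels = 1)
  blk <- make_background(10, cfg)
  expect_length(epoch_rolling(blk, 1, 0.5), 19L)
  tiles <- epoch_rolling(blk, 1, 1)
  expect_length(tiles, 10L)
  expect_equal(vapply(tiles, `[[`, numeric(1), "onset"), 0:9)
  expect_length(epoch_rolling(slice_block(blk, 1:100), 1, 0.5), 0L)

  brute_count <- function(n, len_s, step_s) {
    count <- 0L
    i <- 1L
    while (i + len_s - 1L <= n) {
      count <- count + 1L
      i <- i + step_s
    }
    count
  }
  withr::with_seed(31, {
    for (rep in 1:20) {
      dur <- runif(1, 1, 8)
      len <- runif(1, 0.1, 2)
      step <- runif(1, 0.05, 1)
      b <- slice_block(blk, seq_len(floor(dur * cfg$fs)))
      got <- length(epoch_rolling(b, len, step))
      expect_equal(got, brute_count(n_samples(b), round(len * cfg$fs),
                                    max(1L, round(step * cfg$fs))))
    }
  })
})

test_that("baselining zeroes the window mean exactly and is idempotent", {
  cfg <- quiet_cfg(seed = 5, n_channels = 3)
  blk <- make_background(2, cfg)
  ep <- epoch_timelocked(blk, list(marker_event(1.0)),
                         epoch_spec(-0.2, 0.8))[[1L]]
  # constant channel is zeroed entirely
  ep_const <- ep
  ep_const$data[2, ] <- 7
  bc <- baseline_correct(ep_const, c(-0.2, 0))
  expect_equal(max(abs(bc$data[2, ])), 0)
  # defining property + idempotence on random epochs
  rel <- epoch_times(ep)
  idx <- which(rel >= -0.2 & rel < 0)
  b1 <- baseline_correct(ep, c(-0.2, 0))
  expect_lt(max(abs(rowMeans(b1$data[, idx]))), 1e-12)
  b2 <- baseline_correct(b1, c(-0.2, 0))
  expect_equal(b1$data, b2$data)
  # shape preservation: sine + offset
  sine <- sin(2 * pi * 5 * rel)
  ep$data[1, ] <- sine + 5
  bs <- baseline_correct(ep, c(-0.2, 0.8))
  expect_gte(stats::cor(bs$data[1, ], sine), 0.999)
  expect_error(baseline_correct(ep, c(0.9, 1.0)), "window")
})

test_that("narrow-band power scales with the square of the line amplitude", {
  fs <- 256
  t <- (0:(30 * fs - 1)) / fs
  mk <- function(a) sample_block(t, cbind(a * sin(2 * pi * 50 * t)),
                                 rate = fs)
  p1 <- narrowband_power(mk(1), 50, 4)
  p2 <- narrowband_power(mk(2), 50, 4)
  expect_lt(abs(p2 / p1 - 4), 0.2)
  expect_equal(narrowband_power(mk(0), 50, 4), c(ch1 = 0))
  # ranking across channels follows injected amplitude
  two <- sample_block(t, cbind(1 * sin(2 * pi * 50 * t),
                               3 * sin(2 * pi * 50 * t)) +
                        matrix(rnorm(length(t) * 2, sd = 0.5), ncol = 2),
                      rate = fs)
  pw <- narrowband_power(two, 50, 4)
  expect_lt(pw[1], pw[2])
  expect_error(narrowband_power(mk(1), 127, 4), "fs/2")
})
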