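# Generators: determinism, spectral structure, session truth records.

test_that("background blocks honour duration, spacing and the seed", {
  cfg <- quiet_cfg(seed = 4)
  expect_equal(n_samples(make_background(0, cfg)), 0L)
  expect_error(make_background(-1, cfg), "duration")

  bg <- make_background(2, cfg)
  expect_equal(n_samples(bg), floor(2 * cfg$fs))
  expect_true(all(diff(bg$timestamps) > 0))
  expect_equal(diff(bg$timestamps), rep(1 / cfg$fs, n_samples(bg) - 1L))

  bg2 <- make_background(2, cfg)
  expect_identical(bg$values, bg2$values)
  bg3 <- make_background(2, quiet_cfg(seed = 5))
  expect_false(identical(bg$values, bg3$values))
})

test_that("alpha = 0, line_amp = 0 background is spectrally flat", {
  cfg <- quiet_cfg(seed = 2, n_channels = 1, noise_exponent = 0)
  bg <- make_background(60, cfg)
  pg <- stats::spec.pgram(stats::ts(bg$values[, 1], frequency = cfg$fs),
                          taper = 0, plot = FALSE, spans = 15)
  at50 <- mean(pg$spec[abs(pg$freq - 50) < 0.5])
  nearby <- mean(pg$spec[(abs(pg$freq - 45) < 1) | (abs(pg$freq - 55) < 1)])
  expect_lt(at50 / nearby, 3)
  expect_gt(at50 / nearby, 1 / 3)
})

test_that("alpha = 1 background has log-periodogram slope -1 +/- 0.3", {
  cfg <- quiet_cfg(seed = 8, n_channels = 1)
  bg <- make_background(150, cfg)
  pg <- stats::spec.pgram(stats::ts(bg$values[, 1], frequency = cfg$fs),
                          taper = 0, plot = FALSE, spans = 25)
  sel <- pg$freq >= 1 & pg$freq <= 40
  fit <- stats::lm(log(pg$spec[sel]) ~ log(pg$freq[sel]))
  expect_lt(abs(unname(stats::coef(fit)[2]) + 1), 0.3)
})

test_that("line noise shows up at the configured mains frequency", {
  cfg <- quiet_cfg(seed = 2, n_channels = 2, line_amp = 1)
  bg <- make_background(30, cfg)
  pw50 <- narrowband_power(bg, 50, 4)
  pw30 <- narrowband_power(bg, 30, 4)
  expect_true(all(pw50 > 5 * pw30))
})

test_that("oddball sessions: schedules, ERP placement, truth", {
  cfg <- quiet_cfg(seed = 3)
  ses <- make_oddball_session(4, 12, 0.5, target_class = 2, cfg,
                              policy = "round-robin")
  expect_equal(as.integer(table(ses$truth$labels)), rep(3L, 4))
  expect_equal(ses$truth$target_class, 2)
  # every marker lies inside the EEG span
  tt <- marker_times(ses$markers)
  expect_true(all(tt >= ses$eeg$timestamps[1] &
                    tt <= ses$eeg$timestamps[n_samples(ses$eeg)]))
  # determinism
  ses2 <- make_oddball_session(4, 12, 0.5, target_class = 2, cfg,
                               policy = "round-robin")
  expect_identical(ses$eeg$values, ses2$eeg$values)
  expect_identical(marker_times(ses$markers), marker_times(ses2$markers))

  expect_error(make_oddball_session(1, 12, 0.5, 1, cfg), "n_classes")
  expect_error(make_oddball_session(4, 12, 0.5, 9, cfg), "target_class")
  expect_warning(make_oddball_session(4, 8, 0.02, 1, cfg), "overlap")
})

test_that("strong ERP peaks at hw_latency + erp_latency in the class average", {
  cfg <- quiet_cfg(seed = 6, erp_amp = 25, marker_jitter_sd = 0)
  ses <- make_oddball_session(4, 40, 0.9, target_class = 3, cfg)
  eps <- epoch_timelocked(ses$eeg, ses$markers, epoch_spec(0, 0.8))
  cls <- vapply(eps, function(e) e$meta$class, 1)
  avg <- Reduce(`+`, lapply(eps[cls == 3], `[[`, "data")) / sum(cls == 3)
  peak_t <- (which.max(avg[cfg$n_channels, ]) - 1L) / cfg$fs
  expect_lt(abs(peak_t - (cfg$hw_latency + cfg$erp_latency)), 2 / cfg$fs)
})

test_that("erp_amp = 0 leaves target and non-target ensembles alike", {
  # Monte-Carlo: per-seed two-sample t-test on the ERP-window channel means;
  # with no ERP the rejection rate at alpha = 0.05 stays near nominal.
  pvals <- vapply(1:20, function(s) {
    cfg <- quiet_cfg(seed = 100 + s, erp_amp = 0)
    ses <- make_oddball_session(4, 60, 1 / 3, target_class = 1, cfg)
    eps <- epoch_timelocked(ses$eeg, ses$markers, epoch_spec(0, 0.8))
    cls <- vapply(eps, function(e) e$meta$class, 1)
    win <- round((cfg$hw_latency + cfg$erp_latency) * cfg$fs) + (-10:10)
    feat <- vapply(eps, function(e) mean(e$data[cfg$n_channels, win + 1L]),
                   numeric(1))
    stats::t.test(feat[cls == 1], feat[cls != 1])$p.value
  }, numeric(1))
  expect_lte(sum(pvals < 0.05), 5)
  expect_gt(min(pvals), 1e-4)
})

test_that("motor imagery epochs carry the requested covariance", {
  # LLN: one class, cov diag(4, 1), one 60 s epoch
  cfg <- quiet_cfg(seed = 9, n_channels = 2, marker_jitter_sd = 0)
  ses <- make_mi_session(1, list(diag(c(4, 1))), cfg, epoch_duration = 60,
                         gap = 0.5)
  eps <- epoch_timelocked(ses$eeg, ses$markers, epoch_spec(0, 60))
  expect_length(eps, 1L)
  emp <- unclass(epoch_covariance(eps[[1L]], cov_spec(shrinkage = 0)))
  expect_lt(abs(emp[1, 1] - 4) / 4, 0.10)
  expect_lt(abs(emp[2, 2] - 1), 0.10)
  expect_lt(abs(emp[1, 2]), 0.1 * 2)  # 10% of sqrt(4 * 1)
})

test_that("mi sessions validate covariances and are seed-deterministic", {
  cfg <- quiet_cfg(seed = 5, n_channels = 2)
  bad <- matrix(c(1, 2, 2, 1), 2)  # indefinite
  expect_error(make_mi_session(2, list(bad), cfg), "positive definite")
  expect_error(make_mi_session(2, list(diag(3)), cfg), "2 x 2")

  s1 <- make_mi_session(4, NULL, cfg)
  s2 <- make_mi_session(4, NULL, cfg)
  expect_identical(s1$truth$labels, s2$truth$labels)
  expect_identical(s1$eeg$values, s2$eeg$values)
  # truth is sufficient: labels, onsets, generating covariances
  expect_length(s1$truth$labels, 8L)
  expect_length(s1$truth$onsets, 8L)
  expect_length(s1$truth$class_covs, 2L)
})

test_that("tap sessions place artifacts at the stated offsets", {
  cfg <- quiet_cfg(seed = 7)
  ses <- make_tap_session(10, true_latency = 0.12, tap_sd = 0, cfg)
  expect_equal(ses$truth$tap_times, ses$truth$flash_times + 0.12)
  # noiseless taps: the artifact onset sample is within one sample period
  det <- detect_tap_artifacts(ses$eeg)
  expect_length(det, 10L)
  expect_true(all(abs(det - ses$truth$tap_times) <= 1 / cfg$fs))

  expect_error(make_tap_session(0, config = cfg), "n_taps")
  expect_error(make_tap_session(5, tap_sd = -1, config = cfg), "tap_sd")

  # amplitude 0: nothing detectable downstream
  ses0 <- make_tap_session(10, 0.12, 0, quiet_cfg(seed = 7, tap_amp = 0))
  expect_length(detect_tap_artifacts(ses0$eeg), 0L)
})
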