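# Stimulus schedules, session state machines, archiving.

test_that("stimulus sequences respect policy, rate and seed", {
  rr <- make_stimulus_sequence(8, 1:4, "round-robin", rate = 2)
  expect_equal(rr$entries$class, rep(1:4, 2))
  expect_equal(as.integer(table(rr$entries$class)), rep(2L, 4))
  expect_equal(diff(rr$entries$time), rep(0.5, 7))
  expect_true(all(diff(rr$entries$time) > 0))

  r1 <- make_stimulus_sequence(100, 1:3, "random", seed = 5)
  r2 <- make_stimulus_sequence(100, 1:3, "random", seed = 5)
  expect_identical(r1$entries, r2$entries)

  big <- make_stimulus_sequence(4000, 1:4, "random", seed = 2)
  counts <- table(big$entries$class)
  bound <- 3 * sqrt(4000 * 0.25 * 0.75)
  expect_true(all(abs(counts - 1000) <= bound))

  expect_error(make_stimulus_sequence(4, integer(0)), "empty")
  expect_equal(nrow(make_stimulus_sequence(0, 1:2)$entries), 0L)
})

test_that("mi controller walks its transition table deterministically", {
  bk <- broker()
  st <- mi_session_state(make_stimulus_sequence(4, c("left", "right"),
                                                rate = 1))
  expect_equal(st$phase, "idle")
  r <- mi_controller_step(st, "start", bk)
  expect_equal(r$state$phase, "calibration")
  expect_equal(r$markers[[1L]]$payload$phase, "calibration")
  # invalid command names the phase and leaves the state unchanged
  expect_error(mi_controller_step(r$state, "stop"), "calibration")
  # calibration ticks emit the scheduled cues
  st2 <- r$state
  out <- list()
  for (i in 1:6) {
    r2 <- mi_controller_step(st2, list(type = "tick", dt = 1))
    st2 <- r2$state
    out <- c(out, r2$markers)
  }
  expect_length(out, 4L)
  expect_equal(vapply(out, function(m) m$payload$class, ""),
               c("left", "right", "left", "right"))
  # train: exactly one train request, feedback blocked until model-ready
  r3 <- mi_controller_step(st2, "train", bk)
  expect_equal(r3$state$phase, "training")
  expect_length(drain(bk, "train-request"), 1L)
  expect_error(mi_controller_step(r3$state, "stop"), "training")
  r4 <- mi_controller_step(r3$state,
                           list(type = "message", message = "model-ready"))
  expect_equal(r4$state$phase, "feedback")
  r5 <- mi_controller_step(r4$state, "stop")
  expect_equal(r5$state$phase, "done")
})

test_that("scripted calibration yields the scheduled epochs per class", {
  cfg <- quiet_cfg(seed = 9, n_channels = 2)
  blk <- make_background(30, cfg)
  sched <- make_stimulus_sequence(8, c("left", "right"), rate = 0.5)
  st <- mi_controller_step(mi_session_state(sched), "start")$state
  markers <- list()
  for (i in 1:25) {
    r <- mi_controller_step(st, list(type = "tick", dt = 1))
    st <- r$state
    markers <- c(markers, r$markers)
  }
  eps <- epoch_timelocked(blk, markers, epoch_spec(0, 1.5))
  expect_equal(length(eps) + nrow(attr(eps, "skipped")), length(markers))
  labs <- vapply(eps, `[[`, "", "label")
  expect_equal(as.integer(table(labs)), rep(4L, 2))
})

test_that("oddball controller follows the 90 s timeline contract", {
  tl <- oddball_timeline()
  expect_equal(oddball_scheduled_duration(tl), 90)
  st <- oddball_session_state(tl)
  expect_equal(st$phase, "attract")
  r <- oddball_controller_step(st, "start")
  st <- r$state
  expect_equal(st$phase, "instructions")
  stim <- list()
  phases <- character(0)
  for (i in 1:(92 * 10)) {
    r <- oddball_controller_step(st, list(type = "tick", dt = 0.1))
    st <- r$state
    for (m in r$markers) {
      if (identical(m$payload$phase, "stimuli") &&
          identical(m$payload$label, "stim")) {
        stim <- c(stim, list(m))
      } else {
        phases <- c(phases, m$payload$phase)
      }
    }
  }
  expect_equal(st$phase, "done")
  # marker count equals schedule length; rests emit no stimuli
  expect_length(stim, nrow(st$schedule$entries))
  expect_equal(phases, c("rest", "stimuli", "rest", "stimuli", "done"))
  # ticks after done are no-ops
  r <- oddball_controller_step(st, list(type = "tick", dt = 1))
  expect_length(r$markers, 0L)
  expect_equal(r$state$phase, "done")
  # determinism of the full transition table
  expect_error(oddball_controller_step(st, "start"), "done")
})

test_that("archives round-trip, separate configs by digest, fail cleanly", {
  streams <- list(
    list(info = stream_info("eeg", "eeg", channel_labels = c("ch1", "ch2"),
                            nominal_rate = 256),
         block = make_background(1, quiet_cfg(seed = 2, n_channels = 2))),
    list(info = stream_info("stimuli", "markers"),
         markers = list(marker_event(0.5, label = "stim", class = 1))))
  events <- list(marker_event(0, label = "phase:start", phase = "start"))
  dir1 <- file.path(withr::local_tempdir(), "a1")
  archive_session(streams, events, dir1, config = list(seed = 1))
  ar <- load_archive(dir1)
  expect_length(ar$streams, 2L)
  expect_identical(ar$streams[[1L]]$block$values, streams[[1L]]$block$values)
  expect_length(ar$events, 1L)

  # digest changes iff config changes
  dir2 <- file.path(withr::local_tempdir(), "a2")
  archive_session(streams, events, dir2, config = list(seed = 1))
  dir3 <- file.path(withr::local_tempdir(), "a3")
  archive_session(streams, events, dir3, config = list(seed = 2))
  d <- function(p) load_archive(p)$manifest$config_digest
  expect_identical(d(dir1), d(dir2))
  expect_false(identical(d(dir1), d(dir3)))

  # empty session: manifest-only archive
  dir4 <- file.path(withr::local_tempdir(), "a4")
  archive_session(list(), list(), dir4)
  expect_true(file.exists(file.path(dir4, "manifest.json")))
  expect_length(load_archive(dir4)$streams, 0L)

  # unwritable destination: error, no partial archive
  expect_error(archive_session(streams, events,
                               "/nonexistent-root/sub/archive"),
               "cannot write")
})

test_that("app config files round-trip graph specs", {
  doc <- list(graphs = list(list(
    name = "calc", rate = 10,
    nodes = list(list(id = "a", kind = "counter"),
                 list(id = "b", kind = "sink")),
    edges = list(list(source = "a", target = "b"))
  )), synth = list(fs = 128, n_channels = 2, seed = 7))
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  cfg <- read_app_config(path)
  expect_length(cfg$graphs, 1L)
  expect_equal(validate_graph(cfg$graphs[[1L]]), c("a", "b"))
  expect_equal(cfg$synth$fs, 128)
  expect_equal(cfg$synth$seed, 7L)
})
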