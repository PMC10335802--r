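#' @title Session controllers
#' @description Finite-state session controllers for the two demo
#'   applications. The motor-imagery session runs
#'   idle -> calibration -> training -> feedback -> done under admin
#'   commands; the oddball session runs a fixed timeline
#'   attract -> instructions -> rest -> stimuli -> rest -> stimuli -> done
#'   whose scheduled phase durations sum to 90 s by default. Every phase
#'   transition emits a marker with a `phase` payload; every displayed
#'   stimulus emits a class-labelled marker.
#' @name session_apps
NULL

#' Stimulus schedule
#'
#' Ordered `(time, class)` pairs at a fixed presentation rate. Round-robin
#' cycles the classes in a fixed order (class counts differ by at most
#' one); random draws classes i.i.d. uniformly under the seed.
#'
#' @param n Number of stimuli (`>= 0`).
#' @param classes Non-empty vector of class ids.
#' @param policy `"round-robin"` (default) or `"random"`.
#' @param rate Stimuli per second (`> 0`); defaults to 3, a presentation
#'   pace of a few stimuli per second.
#' @param seed Integer seed for the `"random"` policy.
#' @return An object of class `stimulus_schedule` with fields `entries`
#'   (data frame `time`, `class`), `policy`, `rate`, `seed`.
#' @export
make_stimulus_sequence <- function(n, classes,
                                   policy = c("round-robin", "random"),
                                   rate = 3, seed = 1L) {
  policy <- match.arg(policy)
  if (length(classes) == 0L) stop("empty class list", call. = FALSE)
  stopifnot(n >= 0, rate > 0)
  cls <- if (n == 0L) classes[0L] else switch(policy,
    "round-robin" = rep_len(classes, n),
    "random" = withr::with_seed(seed,
                                sample(classes, n, replace = TRUE))
  )
  structure(
    list(entries = data.frame(time = (seq_len(n) - 1L) / rate,
                              class = cls),
         policy = policy, rate = rate, seed = as.integer(seed)),
    class = "stimulus_schedule"
  )
}

#' @export
print.stimulus_schedule <- function(x, ...) {
  cat(sprintf("<stimulus_schedule: %d stimuli @ %g/s, %s>\n",
              nrow(x$entries), x$rate, x$policy))
  invisible(x)
}

phase_marker <- function(time, phase, app) {
  marker_event(time, label = paste0("phase:", phase), phase = phase,
               class = app)
}

# ---- motor imagery controller ---------------------------------------------

mi_transitions <- list(
  idle = c(start = "calibration"),
  calibration = c(train = "training", cancel = "idle", pause = "paused"),
  paused = c(start = "calibration", cancel = "idle"),
  training = c(`model-ready` = "feedback", cancel = "idle"),
  feedback = c(stop = "done", cancel = "idle"),
  done = character(0)
)

#' Initialise a motor-imagery session
#'
#' @param schedule A [make_stimulus_sequence()] of imagery task cues,
#'   replayed during the calibration phase (entry times are offsets from
#'   the calibration start).
#' @param subject Subject identifier.
#' @param session Session number.
#' @return An object of class `mi_session_state`, phase `"idle"`.
#' @export
mi_session_state <- function(schedule, subject = "s01", session = 1L) {
  structure(
    list(app = "mi", phase = "idle", clock = 0, schedule = schedule,
         cue_cursor = 1L, phase_start = 0,
         metadata = list(subject = subject, session = session)),
    class = "mi_session_state"
  )
}

#' Step the motor-imagery controller
#'
#' Inputs are either admin commands (`"start"`, `"train"`, `"pause"`,
#' `"cancel"`, `"stop"`), the Engine message `"model-ready"` (delivered
#' when training finishes, unblocking the feedback phase), or clock ticks
#' `list(type = "tick", dt = seconds)`. Commands invalid in the current
#' phase are rejected with the phase named and leave the state unchanged.
#' During calibration, ticks emit the scheduled task-instruction markers;
#' entering training publishes exactly one train request on the broker
#' topic `"train-request"` (when a broker is supplied).
#'
#' @param state An [mi_session_state()].
#' @param input A command string or `list(type = "tick", dt =)`.
#' @param broker Optional [broker()] for train requests and phase
#'   announcements.
#' @return List with `state` and `markers` (list of emitted
#'   [marker_event()]).
#' @export
mi_controller_step <- function(state, input, broker = NULL) {
  markers <- list()
  if (is.character(input)) {
    allowed <- mi_transitions[[state$phase]]
    if (!(input %in% names(allowed))) {
      stop(sprintf("command '%s' is invalid in phase '%s'", input,
                   state$phase), call. = FALSE)
    }
    state$phase <- allowed[[input]]
    state$phase_start <- state$clock
    markers <- list(phase_marker(state$clock, state$phase, "mi"))
    if (state$phase == "training" && !is.null(broker)) {
      publish(broker, "train-request", "train", timestamp = state$clock)
    }
    if (state$phase == "calibration") state$cue_cursor <- 1L
  } else if (is.list(input) && identical(input$type, "tick")) {
    state$clock <- state$clock + input$dt
    if (state$phase == "calibration") {
      entries <- state$schedule$entries
      while (state$cue_cursor <= nrow(entries) &&
             state$phase_start + entries$time[state$cue_cursor] <=
             state$clock) {
        i <- state$cue_cursor
        markers[[length(markers) + 1L]] <- marker_event(
          state$phase_start + entries$time[i],
          label = entries$class[i], class = entries$class[i],
          phase = "calibration")
        state$cue_cursor <- i + 1L
      }
    }
  } else if (is.list(input) && identical(input$type, "message")) {
    if (identical(input$message, "model-ready") &&
        state$phase == "training") {
      state$phase <- "feedback"
      state$phase_start <- state$clock
      markers <- list(phase_marker(state$clock, "feedback", "mi"))
    }
  } else {
    stop("unrecognised controller input", call. = FALSE)
  }
  list(state = state, markers = markers)
}

# ---- oddball controller ----------------------------------------------------

#' Oddball session timeline configuration
#'
#' Default timeline: 10 s instructions, 5 s rest, 35 s stimulus block,
#' 5 s rest, 35 s stimulus block — 90 s of scheduled session in total,
#' with stimuli at 3/s. All durations are configuration, not constants.
#'
#' @param instruction_dur Instructions phase duration, s.
#' @param rest_dur Rest phase duration, s (applies to every rest).
#' @param block_durs Numeric vector of stimulus-block durations, s.
#' @param stim_rate Stimuli per second within blocks.
#' @param classes Stimulus class ids.
#' @param policy Sequencing policy for [make_stimulus_sequence()].
#' @param seed Seed for the `"random"` policy.
#' @return A list of class `oddball_timeline`.
#' @export
oddball_timeline <- function(instruction_dur = 10, rest_dur = 5,
                             block_durs = c(35, 35), stim_rate = 3,
                             classes = 1:4,
                             policy = "round-robin", seed = 1L) {
  structure(list(instruction_dur = instruction_dur, rest_dur = rest_dur,
                 block_durs = block_durs, stim_rate = stim_rate,
                 classes = classes, policy = policy, seed = seed),
            class = "oddball_timeline")
}

#' Total scheduled duration of an oddball timeline
#' @param timeline An [oddball_timeline()].
#' @return Seconds (90 for the default configuration).
#' @export
oddball_scheduled_duration <- function(timeline) {
  timeline$instruction_dur +
    length(timeline$block_durs) * timeline$rest_dur +
    sum(timeline$block_durs)
}

#' Initialise an oddball session
#'
#' Builds the per-block stimulus schedules (each block holds
#' `floor(block_dur * stim_rate)` stimuli) and starts in the `"attract"`
#' phase, which waits for the `"start"` command.
#'
#' @param timeline An [oddball_timeline()].
#' @param subject Subject identifier.
#' @param session Session number.
#' @return An object of class `oddball_session_state`.
#' @export
oddball_session_state <- function(timeline = oddball_timeline(),
                                  subject = "s01", session = 1L) {
  n_per_block <- floor(timeline$block_durs * timeline$stim_rate)
  schedule <- make_stimulus_sequence(sum(n_per_block), timeline$classes,
                                     policy = timeline$policy,
                                     rate = timeline$stim_rate,
                                     seed = timeline$seed)
  phases <- c("instructions",
              as.vector(rbind(rep("rest", length(timeline$block_durs)),
                              paste0("stimuli", seq_along(timeline$block_durs)))))
  durs <- c(timeline$instruction_dur,
            as.vector(rbind(rep(timeline$rest_dur,
                                length(timeline$block_durs)),
                            timeline$block_durs)))
  structure(
    list(app = "oddball", phase = "attract", clock = 0,
         timeline = timeline, schedule = schedule,
         phases = phases, durs = durs, phase_idx = 0L, phase_start = 0,
         stim_cursor = 1L, n_per_block = n_per_block, block_no = 0L,
         metadata = list(subject = subject, session = session)),
    class = "oddball_session_state"
  )
}

advance_oddball_phase <- function(state) {
  state$phase_idx <- state$phase_idx + 1L
  if (state$phase_idx > length(state$phases)) {
    state$phase <- "done"
  } else {
    state$phase <- sub("[0-9]+$", "", state$phases[state$phase_idx])
    if (startsWith(state$phases[state$phase_idx], "stimuli")) {
      state$block_no <- state$block_no + 1L
    }
  }
  state$phase_start <- state$clock
  state
}

#' Step the oddball controller
#'
#' `"start"` leaves the attract phase; afterwards ticks
#' (`list(type = "tick", dt =)`) drive the fixed timeline. Rest and
#' instruction phases emit no stimulus markers; within stimulus blocks
#' each scheduled stimulus emits one class-labelled marker, so after
#' completion the marker count equals the schedule length. Ticks after
#' `"done"` are no-ops.
#'
#' @param state An [oddball_session_state()].
#' @param input `"start"` or `list(type = "tick", dt =)`.
#' @return List with `state` and `markers`.
#' @export
oddball_controller_step <- function(state, input) {
  markers <- list()
  if (is.character(input)) {
    if (input != "start" || state$phase != "attract") {
      stop(sprintf("command '%s' is invalid in phase '%s'", input,
                   state$phase), call. = FALSE)
    }
    state <- advance_oddball_phase(state)
    markers <- list(phase_marker(state$clock, state$phase, "oddball"))
    return(list(state = state, markers = markers))
  }
  if (!(is.list(input) && identical(input$type, "tick"))) {
    stop("unrecognised controller input", call. = FALSE)
  }
  if (state$phase %in% c("attract", "done")) {
    state$clock <- state$clock + input$dt
    return(list(state = state, markers = markers))
  }
  state$clock <- state$clock + input$dt
  elapsed <- state$clock - state$phase_start
  # stimulus emission inside blocks
  if (startsWith(state$phases[state$phase_idx], "stimuli")) {
    first_in_block <- if (state$block_no > 1L) {
      sum(state$n_per_block[seq_len(state$block_no - 1L)]) + 1L
    } else 1L
    last_in_block <- sum(state$n_per_block[seq_len(state$block_no)])
    entries <- state$schedule$entries
    while (state$stim_cursor <= last_in_block) {
      i <- state$stim_cursor
      t_local <- (i - first_in_block) / state$timeline$stim_rate
      t_abs <- state$phase_start + t_local
      if (t_abs > state$clock) break
      markers[[length(markers) + 1L]] <- marker_event(
        t_abs, label = "stim", class = entries$class[i],
        phase = "stimuli")
      state$stim_cursor <- i + 1L
    }
  }
  if (elapsed >= state$durs[state$phase_idx] - 1e-9) {
    state <- advance_oddball_phase(state)
    markers[[length(markers) + 1L]] <-
      phase_marker(state$clock, state$phase, "oddball")
  }
  list(state = state, markers = markers)
}
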