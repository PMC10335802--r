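#' @title Built-in node kinds
#' @description Node wrappers around the preprocessing and model operations,
#'   registered under the kinds `"source"`, `"bandpass"`, `"highpass"`,
#'   `"lowpass"`, `"notch"`, `"epoch"`, `"window"`, `"baseline"`,
#'   `"linepower"`, `"oddoneout"`, `"training"`, `"inference"` and
#'   `"sink"`, for use in graph configuration files.
#' @name builtin_nodes
NULL

# source: replays a prerecorded/simulated session in real-chunk fashion.
# params: block (sample_block), markers (optional list of marker_event).
# Emits on "out" the samples with timestamps in ((tick-1)/rate, tick/rate]
# and on "markers" the markers in the same interval.
node_source_init <- function(params, ctx) {
  list(block = params$block, markers = params$markers %||% list(),
       cursor = 1L, mcursor = 1L)
}

node_source_update <- function(state, inputs, ctx) {
  t_hi <- ctx$time
  outputs <- list()
  n <- n_samples(state$block)
  i0 <- state$cursor
  if (i0 <= n) {
    i1 <- i0
    while (i1 <= n && state$block$timestamps[i1] <= t_hi) i1 <- i1 + 1L
    if (i1 > i0) {
      outputs$out <- slice_block(state$block, i0:(i1 - 1L))
      state$cursor <- i1
    }
  }
  mm <- state$markers
  j0 <- state$mcursor
  emitted <- list()
  while (j0 <= length(mm) && mm[[j0]]$timestamp <= t_hi) {
    emitted[[length(emitted) + 1L]] <- mm[[j0]]
    j0 <- j0 + 1L
  }
  if (length(emitted) > 0L) {
    outputs$markers <- emitted
    state$mcursor <- j0
  }
  list(state = state, outputs = outputs)
}

# Stateful causal FIR filter node; the design is fixed once the first block
# reveals the sampling rate. params: kind-specific band, order.
make_filter_node <- function(kind) {
  force(kind)
  function(state, inputs, ctx) {
    blk <- inputs$`in`
    if (is.null(blk)) return(list(state = state, outputs = list()))
    if (is.null(state$coeffs)) {
      spec <- filter_spec(kind, ctx$params$band,
                          order = ctx$params$order %||% 129L)
      state$coeffs <- design_filter(spec, blk$rate)
    }
    res <- apply_causal(state$coeffs, blk, state$filter_state)
    state$filter_state <- res$state
    list(state = state, outputs = list(out = res$block))
  }
}

# epoch: buffers data and markers, emits time-locked epochs when their
# window is fully covered. params: t_min, t_max. The buffer is trimmed to
# what pending markers may still need.
node_epoch_init <- function(params, ctx) {
  list(buffer = NULL, pending = list())
}

node_epoch_update <- function(state, inputs, ctx) {
  spec <- epoch_spec(ctx$params$t_min %||% 0,
                     ctx$params$t_max %||% 1)
  blk <- inputs$`in`
  if (!is.null(blk) && n_samples(blk) > 0L) {
    state$buffer <- if (is.null(state$buffer)) blk else {
      bind_blocks(state$buffer, blk)
    }
  }
  if (!is.null(inputs$markers)) {
    state$pending <- c(state$pending, inputs$markers)
  }
  outputs <- list()
  if (!is.null(state$buffer) && length(state$pending) > 0L) {
    buf_end <- state$buffer$timestamps[n_samples(state$buffer)]
    ready <- vapply(state$pending, function(m) {
      m$timestamp + spec$t_max <= buf_end + 1e-9
    }, TRUE)
    if (any(ready)) {
      eps <- epoch_timelocked(state$buffer, state$pending[ready], spec)
      if (length(eps) > 0L) outputs$out <- eps
      state$pending <- state$pending[!ready]
    }
    # trim: keep what the earliest pending marker (or future ones) may need
    horizon <- buf_end + spec$t_min - 1 / max(state$buffer$rate, 1)
    if (length(state$pending) > 0L) {
      horizon <- min(horizon,
                     min(marker_times(state$pending)) + spec$t_min)
    }
    keep <- which(state$buffer$timestamps >= horizon - 1e-9)
    if (length(keep) > 0L && keep[1L] > 1L) {
      state$buffer <- slice_block(state$buffer, keep)
    }
  }
  list(state = state, outputs = outputs)
}

# window: rolling-window epochs. params: length, step.
node_window_init <- function(params, ctx) list(buffer = NULL, emitted = 0L)

node_window_update <- function(state, inputs, ctx) {
  blk <- inputs$`in`
  if (!is.null(blk) && n_samples(blk) > 0L) {
    state$buffer <- if (is.null(state$buffer)) blk else {
      bind_blocks(state$buffer, blk)
    }
  }
  outputs <- list()
  if (!is.null(state$buffer)) {
    len <- ctx$params$length %||% 1
    step <- ctx$params$step %||% len
    fs <- state$buffer$rate
    len_s <- round(len * fs)
    step_s <- max(1L, round(step * fs))
    out <- list()
    while (!is.null(state$buffer) && n_samples(state$buffer) >= len_s) {
      out[[length(out) + 1L]] <- new_epoch(
        onset = state$buffer$timestamps[1L],
        data = t(state$buffer$values[seq_len(len_s), , drop = FALSE]),
        fs = fs, t_min = 0)
      n_left <- n_samples(state$buffer)
      if (n_left > step_s) {
        state$buffer <- slice_block(state$buffer,
                                    seq.int(step_s + 1L, n_left))
      } else {
        state$buffer <- NULL
      }
    }
    if (length(out) > 0L) outputs$out <- out
  }
  list(state = state, outputs = outputs)
}

# baseline: applies baseline_correct to each epoch of the input list.
node_baseline_update <- function(state, inputs, ctx) {
  eps <- inputs$`in`
  if (is.null(eps)) return(list(state = state, outputs = list()))
  win <- ctx$params$window
  out <- lapply(eps, baseline_correct, window = win)
  list(state = state, outputs = list(out = out))
}

# linepower: narrow-band power of each incoming block.
node_linepower_update <- function(state, inputs, ctx) {
  blk <- inputs$`in`
  if (is.null(blk)) return(list(state = state, outputs = list()))
  pw <- narrowband_power(blk, f0 = ctx$params$f0 %||% 50,
                         bw = ctx$params$bw %||% 4,
                         order = ctx$params$order %||% 255L)
  list(state = state, outputs = list(out = pw))
}

# oddoneout: incremental odd-one-out scoring over incoming epochs whose
# meta$class names the stimulus class; publishes each result on the broker
# topic "classification".
node_oddoneout_init <- function(params, ctx) {
  oddoneout_state(params$class_ids,
                  mode = params$mode %||% "avg-then-cov",
                  spec = params$cov_spec %||% cov_spec(),
                  metric = params$metric %||% "airm")
}

node_oddoneout_update <- function(state, inputs, ctx) {
  eps <- inputs$`in`
  if (is.null(eps)) return(list(state = state, outputs = list()))
  result <- NULL
  for (ep in eps) {
    cls <- ep$meta$class %||% ep$label
    upd <- running_update(state, ep, cls)
    state <- upd$state
    result <- upd$result
  }
  if (!is.null(result)) {
    publish(ctx$broker, "classification", result, timestamp = ctx$time)
  }
  list(state = state, outputs = list(out = result))
}

# training: collects labelled epochs; a "train" command on the input port
# "command" (or broker topic "commands") fits an MDM model, saves it to
# params$path and publishes "model-ready" on topic "messages".
node_training_init <- function(params, ctx) list(epochs = list())

node_training_update <- function(state, inputs, ctx) {
  eps <- inputs$`in`
  if (!is.null(eps)) state$epochs <- c(state$epochs, eps)
  cmds <- inputs$command %||%
    lapply(drain(ctx$broker, "train-request"), `[[`, "data")
  if (!is.list(cmds)) cmds <- list(cmds)
  outputs <- list()
  if (any(vapply(cmds, identical, TRUE, "train"))) {
    model <- mdm_fit(state$epochs,
                     spec = ctx$params$cov_spec %||% cov_spec(),
                     metric = ctx$params$metric %||% "airm")
    bundle <- model_bundle(model)
    if (!is.null(ctx$params$path)) save_model(bundle, ctx$params$path)
    publish(ctx$broker, "messages",
            list(type = "model-ready", digest = bundle$digest),
            timestamp = ctx$time)
    state$bundle <- bundle
    outputs$model <- bundle
  }
  list(state = state, outputs = outputs)
}

# inference: classifies incoming epochs with a model taken from the
# "model" input port or loaded from params$path on first use.
node_inference_init <- function(params, ctx) list(bundle = NULL)

node_inference_update <- function(state, inputs, ctx) {
  if (!is.null(inputs$model)) state$bundle <- inputs$model
  if (is.null(state$bundle) && !is.null(ctx$params$path) &&
      file.exists(ctx$params$path)) {
    state$bundle <- load_model(ctx$params$path)
  }
  eps <- inputs$`in`
  if (is.null(eps) || is.null(state$bundle)) {
    return(list(state = state, outputs = list()))
  }
  preds <- lapply(eps, function(ep) mdm_predict(state$bundle$model, ep))
  publish(ctx$broker, "classification", preds, timestamp = ctx$time)
  list(state = state, outputs = list(out = preds))
}

# sink: accumulates everything it receives (inspection/testing).
node_sink_init <- function(params, ctx) list(items = list())

node_sink_update <- function(state, inputs, ctx) {
  if (length(inputs) > 0L) {
    state$items <- c(state$items, unname(inputs))
  }
  list(state = state, outputs = list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

register_builtin_nodes <- function() {
  register_node("source", node_source_update, node_source_init)
  for (kind in c("bandpass", "highpass", "lowpass", "notch")) {
    register_node(kind, make_filter_node(kind), function(params, ctx) list())
  }
  register_node("epoch", node_epoch_update, node_epoch_init)
  register_node("window", node_window_update, node_window_init)
  register_node("baseline", node_baseline_update)
  register_node("linepower", node_linepower_update)
  register_node("oddoneout", node_oddoneout_update, node_oddoneout_init)
  register_node("training", node_training_update, node_training_init)
  register_node("inference", node_inference_update, node_inference_init)
  register_node("sink", node_sink_update, node_sink_init)
}
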