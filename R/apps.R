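#' @title End-to-end demo applications
#' @description Complete single-command pipelines exercising the whole
#'   stack on synthetic data: generate a session, process it online through
#'   a rate-scheduled graph, archive the raw data and (for the oddball app)
#'   prove that offline re-processing of the archive reproduces the online
#'   decisions bit-identically.
#' @name demo_apps
NULL

oddball_epoch_window <- function() epoch_spec(t_min = 0, t_max = 0.8)

#' Run the unsupervised oddball application end-to-end
#'
#' Generates a synthetic oddball session, streams it through a processing
#' graph (`source -> epoch -> oddoneout`) at the given engine rate,
#' collecting the per-update probability results published on the broker
#' topic `"classification"`, and optionally archives the raw session.
#'
#' @param n_classes,n_stimuli,isi,target_class Passed to
#'   [make_oddball_session()].
#' @param config A [synth_config()]; its seed drives everything.
#' @param engine_rate Graph execution rate, Hz.
#' @param archive_dir Optional directory path: when given, the raw EEG,
#'   markers and config manifest are archived there.
#' @param mode Representative mode, see [class_representative()].
#' @return List with `result` (final `oddoneout_result`), `updates`
#'   (number of published updates), `truth` (the generator's hidden
#'   parameters) and `archive` (path or `NULL`).
#' @export
run_oddball_app <- function(n_classes = 4, n_stimuli = 160, isi = 1 / 3,
                            target_class = 1, config = synth_config(),
                            engine_rate = 10, archive_dir = NULL,
                            mode = "avg-then-cov") {
  session <- make_oddball_session(n_classes, n_stimuli, isi, target_class,
                                  config)
  bk <- broker()
  spec <- graph_spec(
    rate = engine_rate,
    nodes = list(
      list(id = "src", kind = "source",
           params = list(block = session$eeg, markers = session$markers)),
      list(id = "ep", kind = "epoch",
           params = list(t_min = 0, t_max = 0.8)),
      list(id = "odd", kind = "oddoneout",
           params = list(class_ids = seq_len(n_classes), mode = mode))
    ),
    edges = list(
      list(source = "src:out", target = "ep:in"),
      list(source = "src:markers", target = "ep:markers"),
      list(source = "ep:out", target = "odd:in")
    ),
    name = "oddball-calculate"
  )
  g <- build_graph(spec, bk)
  run_graph(g, block_duration(session$eeg) + 1)
  updates <- drain(bk, "classification")
  result <- if (length(updates) > 0L) {
    updates[[length(updates)]]$data
  } else NULL
  archive <- NULL
  if (!is.null(archive_dir)) {
    streams <- list(
      list(info = stream_info("eeg", "eeg",
                              channel_labels = session$eeg$channel_labels,
                              nominal_rate = session$eeg$rate),
           block = session$eeg),
      list(info = stream_info("stimuli", "markers"),
           markers = session$markers)
    )
    archive_session(streams, events = session$markers, path = archive_dir,
                    config = list(app = "oddball", n_classes = n_classes,
                                  n_stimuli = n_stimuli, isi = isi,
                                  seed = config$seed, mode = mode,
                                  epoch = list(t_min = 0, t_max = 0.8)))
    archive <- archive_dir
  }
  list(result = result, updates = length(updates), truth = session$truth,
       archive = archive)
}

#' Re-process an archived oddball session offline
#'
#' Loads the raw EEG and markers from an archive, cuts the same epochs and
#' replays them through the incremental odd-one-out update in marker
#' order. With identical configuration this reproduces the online result
#' bit-identically (replay equivalence).
#'
#' @param path Archive directory written by [run_oddball_app()].
#' @return The final `oddoneout_result`.
#' @export
replay_oddball_archive <- function(path) {
  ar <- load_archive(path)
  cfg <- ar$manifest$config
  is_marker <- vapply(ar$streams, function(s) is.null(s$block), TRUE)
  eeg <- ar$streams[[which(!is_marker)[1L]]]$block
  markers <- ar$streams[[which(is_marker)[1L]]]$markers
  spec <- epoch_spec(t_min = cfg$epoch$t_min, t_max = cfg$epoch$t_max)
  eps <- epoch_timelocked(eeg, markers, spec)
  state <- oddoneout_state(seq_len(cfg$n_classes), mode = cfg$mode)
  result <- NULL
  for (ep in eps) {
    upd <- running_update(state, ep, ep$meta$class)
    state <- upd$state
    result <- upd$result
  }
  result
}

#' Run the motor-imagery application end-to-end
#'
#' Generates a synthetic motor-imagery session, drives the session
#' controller through calibration (cue markers) and training (one train
#' request on the broker), fits the covariance + minimum-distance-to-mean
#' pipeline on the calibration epochs, persists the model, and classifies
#' held-out epochs in the feedback phase.
#'
#' @param n_epochs_per_class Calibration + feedback epochs per class (half
#'   each, rounded up for calibration).
#' @param class_covs Optional generating covariances, see
#'   [make_mi_session()].
#' @param config A [synth_config()].
#' @param model_path Where to persist the trained model (default: a
#'   temporary file).
#' @return List with `model` (the loaded `model_bundle`), `accuracy`
#'   (held-out), `n_train`, `n_test` and `truth`.
#' @export
run_mi_app <- function(n_epochs_per_class = 40, class_covs = NULL,
                       config = synth_config(n_channels = 4),
                       model_path = tempfile(fileext = ".mdm.json")) {
  session <- make_mi_session(n_epochs_per_class, class_covs, config)
  spec <- epoch_spec(t_min = 0, t_max = session$truth$epoch_duration)
  eps <- epoch_timelocked(session$eeg, session$markers, spec)
  # band-pass before covariance, as in the online pipeline
  h <- design_filter(filter_spec("bandpass", config$erd_band),
                     session$eeg$fs %||% session$eeg$rate)
  eps <- lapply(eps, function(e) {
    e$data <- t(apply_fir_matrix(as.numeric(h), t(e$data)))
    e
  })
  labels <- vapply(eps, function(e) as.character(e$label), "")
  idx_train <- unlist(lapply(unique(labels), function(k) {
    which(labels == k)[seq_len(ceiling(sum(labels == k) / 2))]
  }))
  train <- eps[idx_train]
  test <- eps[-idx_train]
  bk <- broker()
  st <- mi_session_state(make_stimulus_sequence(
    length(train), unique(labels), rate = 1 / 2.5))
  st <- mi_controller_step(st, "start", bk)$state
  st <- mi_controller_step(st, "train", bk)$state
  stopifnot(length(drain(bk, "train-request")) == 1L)
  model <- mdm_fit(train)
  save_model(model_bundle(model), model_path)
  bundle <- load_model(model_path)
  st <- mi_controller_step(st, list(type = "message",
                                    message = "model-ready"))$state
  acc <- mdm_accuracy(bundle$model, test)
  list(model = bundle, accuracy = acc, n_train = length(train),
       n_test = length(test), truth = session$truth,
       final_phase = st$phase)
}
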