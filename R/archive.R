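#' Archive a session to disk
#'
#' Writes the raw (pre-filter) EEG, all markers and the state-transition
#' log under `path`, plus a `manifest.json` recording configuration
#' digests and seeds sufficient to re-run the whole pipeline offline. The
#' archive is assembled in a temporary directory and moved into place, so
#' an unwritable destination fails before any partial archive is left
#' behind.
#'
#' @param streams Named list of stream entries (as for [write_xdf()]):
#'   each a list with `info` and `block` or `markers`. May be empty.
#' @param events List of [marker_event()] state-transition/stimulus
#'   events (written to `events.csv`).
#' @param path Destination directory (must not exist).
#' @param config Named list of configuration to record in the manifest
#'   (seeds, generator settings, graph specs); serialised as JSON.
#' @param format `"xdf"` (default) writes a single `session.xdf`;
#'   `"csv"` writes one CSV per stream.
#' @return `path`, invisibly. The manifest digest changes iff `config`
#'   changes.
#' @export
archive_session <- function(streams, events, path, config = list(),
                            format = c("xdf", "csv")) {
  format <- match.arg(format)
  if (file.exists(path)) {
    stop(sprintf("archive path '%s' already exists", path), call. = FALSE)
  }
  parent <- dirname(path)
  if (!dir.exists(parent) || file.access(parent, 2L) != 0L) {
    stop(sprintf("cannot write archive under '%s'", parent), call. = FALSE)
  }
  staging <- tempfile("archive-")
  dir.create(staging)
  files <- character(0)
  if (length(streams) > 0L) {
    if (format == "xdf") {
      write_xdf(file.path(staging, "session.xdf"), streams)
      files <- "session.xdf"
    } else {
      for (i in seq_along(streams)) {
        s <- streams[[i]]
        fn <- sprintf("%s.csv", s$info$name)
        if (is.null(s$markers)) {
          write_block_csv(s$block, file.path(staging, fn))
        } else {
          write_markers_csv(s$markers, file.path(staging, fn))
        }
        files <- c(files, fn)
      }
    }
  }
  if (length(events) > 0L) {
    write_markers_csv(events, file.path(staging, "events.csv"))
    files <- c(files, "events.csv")
  }
  config_json <- as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                               digits = NA))
  tf <- tempfile()
  writeLines(config_json, tf)
  digest <- unname(tools::md5sum(tf))
  unlink(tf)
  manifest <- list(format = "bcistream-archive", version = "1",
                   created_at = format(Sys.time(), tz = "UTC"),
                   storage = format, files = as.list(files),
                   config_digest = digest, config = config)
  jsonlite::write_json(manifest, file.path(staging, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!file.rename(staging, path)) {
    # cross-device fallback: copy then remove
    dir.create(path)
    ok <- file.copy(list.files(staging, full.names = TRUE), path,
                    recursive = TRUE)
    unlink(staging, recursive = TRUE)
    if (!all(ok)) {
      unlink(path, recursive = TRUE)
      stop(sprintf("failed to write archive to '%s'", path), call. = FALSE)
    }
  }
  invisible(path)
}

#' Load an archived session
#'
#' @param path Directory written by [archive_session()].
#' @return List with `streams`, `events` and `manifest`.
#' @export
load_archive <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) {
    stop(sprintf("'%s' is not a session archive (no manifest)", path),
         call. = FALSE)
  }
  manifest <- jsonlite::read_json(mf)
  streams <- list()
  if (identical(manifest$storage, "xdf") &&
      file.exists(file.path(path, "session.xdf"))) {
    streams <- read_xdf(file.path(path, "session.xdf"))
  } else if (identical(manifest$storage, "csv")) {
    for (fn in setdiff(unlist(manifest$files), "events.csv")) {
      full <- file.path(path, fn)
      head <- readLines(full, n = 1L)
      if (identical(head, "\"timestamp\",\"label\",\"class\",\"phase\"")) {
        streams[[length(streams) + 1L]] <-
          list(info = stream_info(sub("[.]csv$", "", fn), "markers"),
               markers = read_markers_csv(full))
      } else {
        blk <- read_block_csv(full)
        streams[[length(streams) + 1L]] <-
          list(info = stream_info(sub("[.]csv$", "", fn), "eeg",
                                  channel_labels = blk$channel_labels,
                                  nominal_rate = blk$rate),
               block = blk)
      }
    }
  }
  events <- if (file.exists(file.path(path, "events.csv"))) {
    read_markers_csv(file.path(path, "events.csv"))
  } else list()
  list(streams = streams, events = events, manifest = manifest)
}
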