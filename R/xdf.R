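#' @title XDF recording
#' @description Minimal reader/writer for the extensible data format (XDF
#'   1.0), the multi-stream container used by lab-streaming recorders: a
#'   `"XDF:"` magic, then length-prefixed chunks (FileHeader, StreamHeader,
#'   Samples, StreamFooter). EEG streams are stored as 64-bit floats with
#'   per-sample double timestamps, so a round trip is lossless for metadata
#'   and lossless-to-float-precision for data. Marker payloads are stored as
#'   a single JSON string channel, preserving arbitrary keys.
#' @name xdf_io
NULL

xdf_write_varlen <- function(con, n) {
  # length field: 1 byte count-of-bytes (we always use 8), then the value
  writeBin(as.raw(8L), con)
  lo <- n %% 2^32
  hi <- n %/% 2^32
  writeBin(as.integer(lo %% 2^16), con, size = 2L, endian = "little")
  writeBin(as.integer(lo %/% 2^16), con, size = 2L, endian = "little")
  writeBin(as.integer(hi %% 2^16), con, size = 2L, endian = "little")
  writeBin(as.integer(hi %/% 2^16), con, size = 2L, endian = "little")
}

xdf_chunk <- function(con, tag, payload) {
  stopifnot(is.raw(payload))
  xdf_write_varlen(con, length(payload) + 2)
  writeBin(as.integer(tag), con, size = 2L, endian = "little")
  writeBin(payload, con)
}

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

stream_header_xml <- function(info, channel_format) {
  chans <- paste0(vapply(info$channel_labels, function(l) {
    sprintf("<channel><label>%s</label></channel>", xml_escape(l))
  }, ""), collapse = "")
  sprintf(paste0(
    "<?xml version=\"1.0\"?><info><name>%s</name><type>%s</type>",
    "<channel_count>%d</channel_count><nominal_srate>%.17g</nominal_srate>",
    "<channel_format>%s</channel_format><source_id>%s</source_id>",
    "<desc><channels>%s</channels></desc></info>"),
    xml_escape(info$name), xml_escape(info$stream_type),
    max(length(info$channel_labels), 1L), info$nominal_rate,
    channel_format, xml_escape(info$source_id), chans)
}

string_to_raw <- function(s) charToRaw(enc2utf8(s))

raw_string_sample <- function(s) {
  b <- string_to_raw(s)
  # string value: varint length (1-byte count + value) + bytes
  n <- length(b)
  c(as.raw(4L), writeBin(as.integer(n), raw(), size = 4L,
                         endian = "little"), b)
}

#' Write streams to an XDF file
#'
#' @param path Output file path.
#' @param streams List of stream entries. Each entry is a list with `info`
#'   (a [stream_info()]) and either `block` (a [sample_block()], for EEG)
#'   or `markers` (a list of [marker_event()]).
#' @return `path`, invisibly.
#' @export
write_xdf <- function(path, streams) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("XDF:"), con)
  header <- string_to_raw("<?xml version=\"1.0\"?><info><version>1.0</version></info>")
  xdf_chunk(con, 1L, header)
  for (i in seq_along(streams)) {
    s <- streams[[i]]
    stopifnot(inherits(s$info, "stream_info"))
    sid <- writeBin(as.integer(i), raw(), size = 4L, endian = "little")
    fmt <- if (is.null(s$markers)) "double64" else "string"
    xdf_chunk(con, 2L, c(sid, string_to_raw(
      stream_header_xml(s$info, fmt))))
    if (is.null(s$markers)) {
      blk <- s$block
      if (ncol(blk$values) != length(s$info$channel_labels)) {
        stop("block channel count disagrees with stream_info",
             call. = FALSE)
      }
      n <- n_samples(blk)
      if (n > 0L) {
        body <- raw(0)
        rows <- lapply(seq_len(n), function(r) {
          c(as.raw(8L),
            writeBin(blk$timestamps[r], raw(), size = 8L,
                     endian = "little"),
            writeBin(as.numeric(blk$values[r, ]), raw(), size = 8L,
                     endian = "little"))
        })
        body <- c(as.raw(4L),
                  writeBin(as.integer(n), raw(), size = 4L,
                           endian = "little"),
                  do.call(c, rows))
        xdf_chunk(con, 3L, c(sid, body))
      }
      first_t <- if (n > 0) blk$timestamps[1] else 0
      last_t <- if (n > 0) blk$timestamps[n] else 0
    } else {
      mm <- s$markers
      n <- length(mm)
      if (n > 0L) {
        rows <- lapply(mm, function(m) {
          c(as.raw(8L),
            writeBin(m$timestamp, raw(), size = 8L, endian = "little"),
            raw_string_sample(as.character(
              jsonlite::toJSON(m$payload, auto_unbox = TRUE))))
        })
        body <- c(as.raw(4L),
                  writeBin(as.integer(n), raw(), size = 4L,
                           endian = "little"),
                  do.call(c, rows))
        xdf_chunk(con, 3L, c(sid, body))
      }
      tt <- marker_times(mm)
      first_t <- if (n > 0) min(tt) else 0
      last_t <- if (n > 0) max(tt) else 0
    }
    footer <- sprintf(paste0(
      "<?xml version=\"1.0\"?><info><first_timestamp>%.17g",
      "</first_timestamp><last_timestamp>%.17g</last_timestamp>",
      "<sample_count>%d</sample_count></info>"), first_t, last_t, n)
    xdf_chunk(con, 6L, c(sid, string_to_raw(footer)))
  }
  invisible(path)
}

xdf_format_error <- function(msg, offset) {
  stop(structure(class = c("xdf_format_error", "error", "condition"),
                 list(message = sprintf("%s (byte offset %d)", msg, offset),
                      call = NULL, offset = offset)))
}

read_exact <- function(con, n, what, offset) {
  b <- readBin(con, "raw", n = n)
  if (length(b) < n) {
    xdf_format_error(sprintf("truncated file while reading %s", what),
                     offset + length(b))
  }
  b
}

raw_to_int <- function(b) {
  sum(as.numeric(b) * 256^(seq_along(b) - 1L))
}

xml_field <- function(xml, tag) {
  m <- regmatches(xml, regexec(sprintf("<%s>(.*?)</%s>", tag, tag), xml))
  if (length(m[[1L]]) < 2L) NA_character_ else m[[1L]][2L]
}

#' Read an XDF file
#'
#' @param path File written by [write_xdf()] (or any single-segment XDF
#'   file using double64/string formats and 8-byte timestamps).
#' @return List of stream entries mirroring the [write_xdf()] input:
#'   `info` plus `block` or `markers`. Truncated or malformed files raise
#'   an `xdf_format_error` carrying the byte offset.
#' @export
read_xdf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  offset <- 0L
  magic <- readBin(con, "raw", n = 4L)
  if (length(magic) < 4L || !identical(rawToChar(magic), "XDF:")) {
    xdf_format_error("missing XDF magic", 0L)
  }
  offset <- 4L
  streams <- list()
  repeat {
    nb <- readBin(con, "raw", n = 1L)
    if (length(nb) == 0L) break
    nlb <- as.integer(nb)
    if (!(nlb %in% c(1L, 4L, 8L))) {
      xdf_format_error("invalid chunk length field", offset)
    }
    len_raw <- read_exact(con, nlb, "chunk length", offset + 1L)
    len <- raw_to_int(len_raw)
    tag_raw <- read_exact(con, 2L, "chunk tag", offset + 1L + nlb)
    tag <- raw_to_int(tag_raw)
    content <- read_exact(con, len - 2, "chunk content",
                          offset + 3L + nlb)
    offset <- offset + 1L + nlb + len
    if (tag %in% c(2L, 3L, 6L)) {
      sid <- raw_to_int(content[1:4])
      body <- content[-(1:4)]
      key <- as.character(sid)
      if (tag == 2L) {
        xml <- rawToChar(body)
        fmt <- xml_field(xml, "channel_format")
        stype <- xml_field(xml, "type")
        labels <- regmatches(xml,
                             gregexpr("<label>(.*?)</label>", xml))[[1L]]
        labels <- gsub("</?label>", "", labels)
        rate <- as.numeric(xml_field(xml, "nominal_srate"))
        streams[[key]] <- list(
          info = stream_info(xml_field(xml, "name"), stype,
                             channel_labels = if (fmt == "string")
                               character(0) else labels,
                             nominal_rate = rate,
                             source_id = xml_field(xml, "source_id")),
          format = fmt,
          n_channels = as.integer(xml_field(xml, "channel_count")),
          timestamps = numeric(0), rows = list(), markers = list())
      } else if (tag == 3L) {
        st <- streams[[key]]
        if (is.null(st)) xdf_format_error("samples before header", offset)
        pos <- 1L
        nvb <- as.integer(body[pos]); pos <- pos + 1L
        nsamp <- raw_to_int(body[pos:(pos + nvb - 1L)]); pos <- pos + nvb
        for (r in seq_len(nsamp)) {
          tb <- as.integer(body[pos]); pos <- pos + 1L
          ts <- NA_real_
          if (tb == 8L) {
            ts <- readBin(body[pos:(pos + 7L)], "double", size = 8L,
                          endian = "little")
            pos <- pos + 8L
          }
          if (st$format == "double64") {
            nc <- st$n_channels
            vals <- readBin(body[pos:(pos + 8L * nc - 1L)], "double",
                            n = nc, size = 8L, endian = "little")
            pos <- pos + 8L * nc
            st$timestamps <- c(st$timestamps, ts)
            st$rows[[length(st$rows) + 1L]] <- vals
          } else {
            slb <- as.integer(body[pos]); pos <- pos + 1L
            slen <- raw_to_int(body[pos:(pos + slb - 1L)])
            pos <- pos + slb
            s <- if (slen > 0) rawToChar(body[pos:(pos + slen - 1L)]) else ""
            pos <- pos + slen
            payload <- jsonlite::fromJSON(s, simplifyVector = TRUE)
            st$markers[[length(st$markers) + 1L]] <-
              marker_event(ts, payload = as.list(payload))
          }
        }
        streams[[key]] <- st
      }
    }
  }
  lapply(unname(streams), function(st) {
    if (st$format == "double64") {
      values <- if (length(st$rows) > 0L) do.call(rbind, st$rows) else {
        matrix(numeric(0), 0L, st$n_channels)
      }
      list(info = st$info,
           block = sample_block(st$timestamps, values,
                                rate = st$info$nominal_rate,
                                channel_labels = st$info$channel_labels))
    } else {
      list(info = st$info, markers = st$markers)
    }
  })
}
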