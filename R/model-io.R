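MODEL_FORMAT <- "bcistream-mdm"
MODEL_VERSION <- "1"

# Canonical full-precision digest of the model parameters: any change to
# class ids, metric, shrinkage or a mean matrix changes the digest.
model_digest <- function(model) {
  canon <- c(
    model$metric, model$cov_spec$estimator,
    sprintf("%.17g", model$cov_spec$shrinkage),
    unlist(lapply(model$class_ids, function(k) {
      c(k, sprintf("%.17g", as.numeric(model$means[[k]])))
    }))
  )
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(canon, tf)
  unname(tools::md5sum(tf))
}

encode_doubles <- function(x) {
  jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8L,
                                endian = "little"))
}

decode_doubles <- function(s, n) {
  r <- jsonlite::base64_dec(s)
  if (length(r) != 8L * n) {
    stop("corrupt model file: array payload has wrong length",
         call. = FALSE)
  }
  readBin(r, "double", n = n, size = 8L, endian = "little")
}

#' Wrap a fitted model for persistence
#' @param model An `mdm_model`.
#' @return An object of class `model_bundle` carrying the model, a
#'   creation timestamp, a full-precision parameter digest and the format
#'   version.
#' @export
model_bundle <- function(model) {
  stopifnot(inherits(model, "mdm_model"))
  structure(list(model = model,
                 created_at = format(Sys.time(), tz = "UTC"),
                 digest = model_digest(model),
                 version = MODEL_VERSION),
            class = "model_bundle")
}

#' Save a model bundle to disk
#'
#' Single-file JSON container: human-readable metadata (format, version,
#' digest, class ids, metric, estimator settings) plus the mean matrices as
#' base64-encoded little-endian 64-bit floats, so that
#' `load_model(save_model(b))` reproduces predictions bit-identically. The
#' file is written atomically (temp file + rename): a failed write leaves no
#' partial model behind.
#'
#' @param bundle A [model_bundle()] (a bare `mdm_model` is wrapped).
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(bundle, path) {
  if (inherits(bundle, "mdm_model")) bundle <- model_bundle(bundle)
  stopifnot(inherits(bundle, "model_bundle"))
  model <- bundle$model
  p <- model$provenance$n_channels
  doc <- list(
    format = MODEL_FORMAT, version = bundle$version,
    created_at = bundle$created_at, digest = bundle$digest,
    metric = model$metric,
    cov_spec = list(estimator = model$cov_spec$estimator,
                    shrinkage = model$cov_spec$shrinkage),
    n_channels = p,
    class_ids = as.list(model$class_ids),
    provenance = model$provenance,
    means = lapply(model$class_ids, function(k) {
      list(class = k, data = encode_doubles(model$means[[k]]))
    })
  )
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(doc, tmp, auto_unbox = TRUE, digits = NA)
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    stop(sprintf("cannot write model to '%s'", path), call. = FALSE)
  }
  invisible(path)
}

#' Load a model bundle from disk
#'
#' @param path File written by [save_model()].
#' @return A `model_bundle`; its digest is recomputed and verified against
#'   the stored one.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("model file '%s' does not exist", path), call. = FALSE)
  }
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) {
                    stop(sprintf("corrupt model file '%s': %s", path,
                                 conditionMessage(e)), call. = FALSE)
                  })
  if (!identical(doc$format, MODEL_FORMAT)) {
    stop("not a model file (unknown format tag)", call. = FALSE)
  }
  if (!identical(doc$version, MODEL_VERSION)) {
    stop(sprintf("model format version mismatch: file %s, supported %s",
                 doc$version, MODEL_VERSION), call. = FALSE)
  }
  p <- doc$n_channels
  class_ids <- as.character(unlist(doc$class_ids))
  means <- list()
  for (entry in doc$means) {
    m <- matrix(decode_doubles(entry$data, p * p), p, p)
    means[[entry$class]] <- as_spd(m)
  }
  if (!setequal(names(means), class_ids)) {
    stop("corrupt model file: class ids and means disagree", call. = FALSE)
  }
  model <- structure(
    list(class_ids = class_ids, means = means[class_ids],
         metric = doc$metric,
         cov_spec = cov_spec(doc$cov_spec$estimator,
                             doc$cov_spec$shrinkage),
         provenance = doc$provenance),
    class = "mdm_model"
  )
  digest <- model_digest(model)
  if (!identical(digest, doc$digest)) {
    stop("corrupt model file: digest mismatch", call. = FALSE)
  }
  structure(list(model = model, created_at = doc$created_at,
                 digest = digest, version = doc$version),
            class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("<model_bundle v%s, digest %s, created %s>\n", x$version,
              substr(x$digest, 1, 8), x$created_at))
  print(x$model)
  invisible(x)
}
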