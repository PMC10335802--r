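#' Fit a minimum-distance-to-mean classifier
#'
#' Computes one Riemannian mean covariance per class from labelled epochs.
#' An epoch is classified by the nearest class mean on the SPD manifold.
#'
#' @param epochs List of labelled `epoch` objects (label on every epoch,
#'   `>= 2` distinct classes, `>= 1` epoch per class).
#' @param spec A [cov_spec()] used for per-epoch covariance estimation.
#' @param metric `"airm"` (default) or `"logeuclid"`.
#' @return An object of class `mdm_model` with fields `class_ids` (sorted,
#'   as characters), `means`, `metric`, `cov_spec` and `provenance`.
#' @export
mdm_fit <- function(epochs, spec = cov_spec(),
                    metric = c("airm", "logeuclid")) {
  metric <- match.arg(metric)
  labels <- lapply(epochs, `[[`, "label")
  if (any(vapply(labels, is.null, TRUE))) {
    stop("all epochs must carry a label", call. = FALSE)
  }
  labels <- as.character(unlist(labels))
  class_ids <- sort(unique(labels))
  if (length(class_ids) < 2L) {
    stop("need at least 2 classes", call. = FALSE)
  }
  covs <- lapply(epochs, epoch_covariance, spec = spec)
  means <- lapply(class_ids, function(k) {
    riemannian_mean(covs[labels == k], metric = metric)
  })
  names(means) <- class_ids
  structure(
    list(class_ids = class_ids, means = means, metric = metric,
         cov_spec = spec,
         provenance = list(
           n_epochs = as.list(table(labels)),
           n_channels = nrow(means[[1L]]),
           fitted_at = format(Sys.time(), tz = "UTC")
         )),
    class = "mdm_model"
  )
}

#' @export
print.mdm_model <- function(x, ...) {
  cat(sprintf("<mdm_model: %d classes (%s), %d channels, metric %s>\n",
              length(x$class_ids), paste(x$class_ids, collapse = ", "),
              x$provenance$n_channels, x$metric))
  invisible(x)
}

#' Classify an epoch with an MDM model
#'
#' The predicted class is the argmin over class means of the manifold
#' distance to the epoch covariance; ties break towards the first class id.
#' Scores are `softmax(-distance)` with unit temperature and sum to one.
#'
#' @param model An `mdm_model`.
#' @param epoch An `epoch` (or channels-by-samples matrix) with the model's
#'   channel count, or an `spd` covariance directly.
#' @return A list with `class` (predicted id, character), `scores` (named
#'   numeric, sums to 1) and `distances` (named numeric).
#' @export
mdm_predict <- function(model, epoch) {
  cov <- if (inherits(epoch, "spd")) epoch else {
    epoch_covariance(epoch, model$cov_spec)
  }
  if (nrow(cov) != model$provenance$n_channels) {
    stop("epoch channel count does not match the model", call. = FALSE)
  }
  d <- vapply(model$means, function(m) spd_distance(cov, m, model$metric),
              numeric(1))
  names(d) <- model$class_ids
  z <- exp(-(d - min(d)))
  scores <- z / sum(z)
  list(class = model$class_ids[which.min(d)], scores = scores, distances = d)
}

#' Classification accuracy of an MDM model on labelled epochs
#' @param model An `mdm_model`.
#' @param epochs List of labelled `epoch` objects.
#' @return Fraction of epochs whose predicted class equals their label.
#' @export
mdm_accuracy <- function(model, epochs) {
  pred <- vapply(epochs, function(e) mdm_predict(model, e)$class, "")
  truth <- vapply(epochs, function(e) as.character(e$label), "")
  mean(pred == truth)
}
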