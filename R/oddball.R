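#' @title Unsupervised oddball target identification
#' @description In an oddball session the target (deviant) stimulus class
#'   elicits a P300-like response, but no labels say which class is the
#'   target. Epochs are grouped by stimulus class, each group is reduced to a
#'   representative SPD covariance, and the class whose representative is
#'   furthest from the others (largest summed pairwise manifold distance) is
#'   reported as the target, with per-class probabilities.
#' @name oddball_unsupervised
NULL

#' Representative covariance of a class ensemble
#'
#' Two reductions are implemented. `"avg-then-cov"` (default) averages the
#' epochs pointwise and takes the covariance of the averaged epoch:
#' averaging enhances the time-locked ERP against the non-time-locked
#' background, which is exactly the deviance the statistic looks for.
#' `"cov-then-mean"` takes the Riemannian mean of per-epoch covariances.
#' Both modes agree on a single-epoch ensemble.
#'
#' @param epochs Non-empty list of `epoch` objects of identical shape (all
#'   epochs of one stimulus class).
#' @param mode `"avg-then-cov"` or `"cov-then-mean"`.
#' @param spec A [cov_spec()].
#' @param metric Metric for the `"cov-then-mean"` Riemannian mean.
#' @return An `spd` matrix.
#' @export
class_representative <- function(epochs,
                                 mode = c("avg-then-cov", "cov-then-mean"),
                                 spec = cov_spec(),
                                 metric = c("airm", "logeuclid")) {
  mode <- match.arg(mode)
  metric <- match.arg(metric)
  if (length(epochs) == 0L) stop("empty ensemble", call. = FALSE)
  dims <- vapply(epochs, function(e) dim(e$data), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("epochs in an ensemble must share one shape", call. = FALSE)
  }
  if (mode == "avg-then-cov") {
    acc <- Reduce(`+`, lapply(epochs, `[[`, "data")) / length(epochs)
    epoch_covariance(acc, spec)
  } else {
    riemannian_mean(lapply(epochs, epoch_covariance, spec = spec),
                    metric = metric)
  }
}

new_oddoneout_result <- function(scores, counts, low_confidence) {
  total <- sum(scores)
  probabilities <- if (total > 0) {
    scores / total
  } else {
    rep(1 / length(scores), length(scores))
  }
  names(probabilities) <- names(scores)
  structure(
    list(scores = scores, probabilities = probabilities,
         predicted_target = names(scores)[which.max(probabilities)],
         n_epochs_used = counts, low_confidence = low_confidence),
    class = "oddoneout_result"
  )
}

#' @export
print.oddoneout_result <- function(x, ...) {
  cat(sprintf("<odd-one-out: target '%s'%s>\n", x$predicted_target,
              if (x$low_confidence) " (low confidence)" else ""))
  print(round(x$probabilities, 4))
  invisible(x)
}

#' Odd-one-out scores from class representatives
#'
#' Score of class `k` is the sum of its pairwise manifold distances to all
#' other classes; probabilities are the proportionally normalised scores
#' (all-zero scores give the uniform distribution). With two classes the
#' single pairwise distance makes both scores equal — the statistic is
#' uninformative at `K = 2` by construction.
#'
#' @param reps Named list (class id -> `spd` representative), `>= 2`
#'   entries.
#' @param metric `"airm"` or `"logeuclid"`.
#' @param counts Optional named per-class epoch counts, reported in the
#'   result; classes with fewer than 3 epochs flag the result
#'   low-confidence.
#' @return An `oddoneout_result` with `scores`, `probabilities`
#'   (nonnegative, summing to 1), `predicted_target` (argmax) and
#'   `n_epochs_used`.
#' @export
oddoneout_scores <- function(reps, metric = c("airm", "logeuclid"),
                             counts = NULL) {
  metric <- match.arg(metric)
  k <- length(reps)
  if (k < 2L) stop("need at least 2 classes", call. = FALSE)
  ids <- names(reps)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("reps must be a named list of class representatives", call. = FALSE)
  }
  dims <- vapply(reps, nrow, 1L)
  if (any(dims != dims[1])) stop("dimension mismatch", call. = FALSE)
  d <- matrix(0, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      d[i, j] <- d[j, i] <- spd_distance(reps[[i]], reps[[j]], metric)
    }
  }
  scores <- rowSums(d)
  if (is.null(counts)) counts <- stats::setNames(rep(NA_integer_, k), ids)
  low_conf <- any(is.na(counts)) || any(counts < 3L)
  new_oddoneout_result(scores, counts, low_conf)
}

#' Initialise incremental odd-one-out state
#'
#' @param class_ids Character/integer vector of all stimulus classes.
#' @param mode,spec,metric As in [class_representative()].
#' @return An `oddoneout_state` accumulating per-class epoch sums (or
#'   covariance lists) so that incremental re-scoring equals the batch
#'   computation on the same epochs.
#' @export
oddoneout_state <- function(class_ids,
                            mode = c("avg-then-cov", "cov-then-mean"),
                            spec = cov_spec(),
                            metric = c("airm", "logeuclid")) {
  mode <- match.arg(mode)
  metric <- match.arg(metric)
  ids <- as.character(class_ids)
  stopifnot(length(ids) >= 2L, !anyDuplicated(ids))
  structure(
    list(class_ids = ids, mode = mode, spec = spec, metric = metric,
         sums = stats::setNames(vector("list", length(ids)), ids),
         covs = stats::setNames(rep(list(list()), length(ids)), ids),
         counts = stats::setNames(integer(length(ids)), ids)),
    class = "oddoneout_state"
  )
}

# Representatives for all classes seen so far (NULL when a class is empty).
state_representatives <- function(state) {
  lapply(stats::setNames(state$class_ids, state$class_ids), function(k) {
    if (state$counts[[k]] == 0L) return(NULL)
    if (state$mode == "avg-then-cov") {
      epoch_covariance(state$sums[[k]] / state$counts[[k]], state$spec)
    } else {
      riemannian_mean(state$covs[[k]], metric = state$metric)
    }
  })
}

score_state <- function(state) {
  ids <- state$class_ids
  k <- length(ids)
  present <- ids[state$counts > 0L]
  if (length(present) < 2L) {
    scores <- stats::setNames(rep(0, k), ids)
    return(new_oddoneout_result(scores, state$counts, TRUE))
  }
  reps <- state_representatives(state)[present]
  partial <- oddoneout_scores(reps, metric = state$metric,
                              counts = state$counts[present])
  # Absent classes are held at the uniform prior weight 1/K; the remaining
  # probability mass is split over the present classes in score proportion.
  probabilities <- stats::setNames(rep(1 / k, k), ids)
  probabilities[present] <-
    partial$probabilities * (1 - (k - length(present)) / k)
  scores <- stats::setNames(rep(0, k), ids)
  scores[present] <- partial$scores
  structure(
    list(scores = scores, probabilities = probabilities,
         predicted_target = ids[which.max(probabilities)],
         n_epochs_used = state$counts,
         low_confidence = any(state$counts < 3L)),
    class = "oddoneout_result"
  )
}

#' Incremental odd-one-out update
#'
#' Accumulates one epoch into its class ensemble and re-scores. The result
#' after `n` updates equals the batch computation on the same `n` epochs;
#' classes with no epochs yet are held at the uniform prior weight. The
#' result is flagged `low_confidence` until every class has at least 3
#' epochs.
#'
#' @param state An [oddoneout_state()].
#' @param new_epoch An `epoch`.
#' @param class_id Stimulus class of the epoch (must be a known class).
#' @return A list with updated `state` and the current `result`.
#' @export
running_update <- function(state, new_epoch, class_id) {
  stopifnot(inherits(state, "oddoneout_state"))
  k <- as.character(class_id)
  if (!(k %in% state$class_ids)) {
    stop(sprintf("unknown class id '%s'", k), call. = FALSE)
  }
  if (state$mode == "avg-then-cov") {
    state$sums[[k]] <- if (is.null(state$sums[[k]])) new_epoch$data else {
      state$sums[[k]] + new_epoch$data
    }
  } else {
    state$covs[[k]] <- c(state$covs[[k]],
                         list(epoch_covariance(new_epoch, state$spec)))
  }
  state$counts[[k]] <- state$counts[[k]] + 1L
  list(state = state, result = score_state(state))
}

#' Batch odd-one-out analysis of an epoched oddball session
#'
#' Groups labelled epochs by class, builds representatives and scores them.
#'
#' @param epochs List of `epoch` objects whose `meta$class` (or, failing
#'   that, `label`) is the stimulus class.
#' @param class_ids Optional full class list (defaults to the labels seen).
#' @param mode,spec,metric As in [class_representative()].
#' @return An `oddoneout_result`.
#' @export
oddoneout_batch <- function(epochs, class_ids = NULL,
                            mode = c("avg-then-cov", "cov-then-mean"),
                            spec = cov_spec(),
                            metric = c("airm", "logeuclid")) {
  mode <- match.arg(mode)
  metric <- match.arg(metric)
  labels <- vapply(epochs, function(e) {
    as.character(e$meta$class %||% e$label)
  }, "")
  if (is.null(class_ids)) class_ids <- sort(unique(labels))
  class_ids <- as.character(class_ids)
  reps <- list()
  counts <- stats::setNames(integer(length(class_ids)), class_ids)
  for (k in class_ids) {
    members <- epochs[labels == k]
    counts[[k]] <- length(members)
    if (length(members) > 0L) {
      reps[[k]] <- class_representative(members, mode = mode, spec = spec,
                                        metric = metric)
    }
  }
  if (length(reps) < length(class_ids)) {
    state <- oddoneout_state(class_ids, mode = mode, spec = spec,
                             metric = metric)
    for (i in seq_along(epochs)) {
      state <- running_update(state, epochs[[i]], labels[i])$state
    }
    return(score_state(state))
  }
  oddoneout_scores(reps, metric = metric, counts = counts)
}
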