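#' Publish/subscribe broker
#'
#' Mediates communication between graphs: named topics holding FIFO queues
#' of `(timestamp, data)` items. Publishing never blocks on subscribers;
#' draining a topic returns all pending items in publication order and
#' empties the queue. Topics are auto-created on first use.
#'
#' @return An object of class `broker` (an environment).
#' @export
broker <- function() {
  env <- new.env(parent = emptyenv())
  env$topics <- list()
  env$published <- integer(0)
  env$drained <- integer(0)
  class(env) <- "broker"
  env
}

#' @export
print.broker <- function(x, ...) {
  cat(sprintf("<broker: %d topics, %d pending>\n", length(x$topics),
              sum(vapply(x$topics, length, 1L))))
  invisible(x)
}

#' Publish an item on a topic
#' @param broker A [broker()].
#' @param topic Topic name (string).
#' @param data Arbitrary payload.
#' @param timestamp Publication time, s.
#' @return The broker, invisibly.
#' @export
publish <- function(broker, topic, data, timestamp = NA_real_) {
  stopifnot(inherits(broker, "broker"), is.character(topic))
  q <- broker$topics[[topic]]
  if (is.null(q)) q <- list()
  q[[length(q) + 1L]] <- list(timestamp = timestamp, data = data)
  broker$topics[[topic]] <- q
  cnt <- broker$published[topic]
  broker$published[topic] <- if (is.na(cnt)) 1L else cnt + 1L
  invisible(broker)
}

#' Drain a topic
#'
#' @param broker A [broker()].
#' @param topic Topic name; unknown topics yield an empty list.
#' @return List of `(timestamp, data)` items in publication order; the
#'   queue is emptied (a second drain returns nothing).
#' @export
drain <- function(broker, topic) {
  stopifnot(inherits(broker, "broker"))
  q <- broker$topics[[topic]]
  if (is.null(q)) return(list())
  broker$topics[[topic]] <- list()
  cnt <- broker$drained[topic]
  broker$drained[topic] <- if (is.na(cnt)) length(q) else cnt + length(q)
  q
}

#' Pending item count per topic
#' @param broker A [broker()].
#' @param topic Topic name.
#' @return Integer count of undelivered items.
#' @export
pending <- function(broker, topic) {
  length(broker$topics[[topic]])
}
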