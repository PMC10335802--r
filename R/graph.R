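#' Processing graph specification
#'
#' A declarative description of one rate-scheduled processing graph: an
#' execution frequency, a list of nodes (unique id, registered kind,
#' parameter list) and directed edges between node ports. Edge endpoints
#' are written `"node"` or `"node:port"`; the default ports are `"out"`
#' (source side) and `"in"` (target side). The edge relation must be
#' acyclic: one tick executes every node exactly once, in an order
#' compatible with all edges.
#'
#' @param rate Execution rate, Hz (`> 0`).
#' @param nodes List of `list(id =, kind =, params = list(...))`.
#' @param edges List of `list(source =, target =)` endpoint strings.
#' @param name Optional graph name.
#' @return An object of class `graph_spec`.
#' @export
graph_spec <- function(rate, nodes, edges = list(), name = "graph") {
  stopifnot(rate > 0)
  parse_endpoint <- function(s, default_port) {
    parts <- strsplit(s, ":", fixed = TRUE)[[1L]]
    if (length(parts) == 1L) parts <- c(parts, default_port)
    list(node = parts[1L], port = parts[2L])
  }
  nodes <- lapply(nodes, function(nd) {
    stopifnot(!is.null(nd$id), !is.null(nd$kind))
    if (is.null(nd$params)) nd$params <- list()
    nd
  })
  edges <- lapply(edges, function(e) {
    list(source = parse_endpoint(e$source, "out"),
         target = parse_endpoint(e$target, "in"))
  })
  structure(list(rate = rate, nodes = nodes, edges = edges, name = name),
            class = "graph_spec")
}

# Depth-first search for one directed cycle among the given adjacency.
find_cycle <- function(ids, adj) {
  color <- stats::setNames(rep(0L, length(ids)), ids)  # 0 new 1 open 2 done
  stack <- character(0)
  result <- NULL
  visit <- function(v) {
    if (!is.null(result)) return()
    color[v] <<- 1L
    stack <<- c(stack, v)
    for (w in adj[[v]]) {
      if (color[w] == 1L) {
        i <- match(w, stack)
        result <<- c(stack[i:length(stack)], w)
        return()
      }
      if (color[w] == 0L) visit(w)
      if (!is.null(result)) return()
    }
    color[v] <<- 2L
    stack <<- stack[-length(stack)]
  }
  for (v in ids) if (color[v] == 0L) visit(v)
  result
}

#' Validate a graph and return its execution order
#'
#' Checks node-id uniqueness and edge endpoints, rejects input-port
#' collisions, and topologically sorts the nodes (Kahn's algorithm,
#' breaking ties by declaration order, so re-validation returns the same
#' order). A cyclic spec raises a `graph_cycle_error` naming one offending
#' cycle.
#'
#' @param spec A [graph_spec()].
#' @return Character vector of node ids in execution order.
#' @export
validate_graph <- function(spec) {
  stopifnot(inherits(spec, "graph_spec"))
  ids <- vapply(spec$nodes, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate node id '%s'", ids[duplicated(ids)][1L]),
         call. = FALSE)
  }
  adj <- stats::setNames(rep(list(character(0)), length(ids)), ids)
  indeg <- stats::setNames(rep(0L, length(ids)), ids)
  seen_inputs <- character(0)
  for (e in spec$edges) {
    for (end in c(e$source$node, e$target$node)) {
      if (!(end %in% ids)) {
        stop(structure(class = c("invalid_spec_error", "error", "condition"),
                       list(message = sprintf(
                         "edge endpoint '%s' is not a node", end),
                         call = NULL)))
      }
    }
    key <- paste0(e$target$node, ":", e$target$port)
    if (key %in% seen_inputs) {
      stop(structure(class = c("invalid_spec_error", "error", "condition"),
                     list(message = sprintf(
                       "input port '%s' has more than one in-edge", key),
                       call = NULL)))
    }
    seen_inputs <- c(seen_inputs, key)
    adj[[e$source$node]] <- c(adj[[e$source$node]], e$target$node)
    indeg[e$target$node] <- indeg[e$target$node] + 1L
  }
  order <- character(0)
  remaining <- ids
  deg <- indeg
  while (length(remaining) > 0L) {
    ready <- remaining[deg[remaining] == 0L]
    if (length(ready) == 0L) {
      cyc <- find_cycle(ids, adj)
      stop(structure(class = c("graph_cycle_error", "error", "condition"),
                     list(message = sprintf(
                       "graph contains a cycle: %s",
                       paste(cyc, collapse = " -> ")), call = NULL)))
    }
    v <- ready[1L]  # declaration order: `remaining` preserves it
    order <- c(order, v)
    remaining <- setdiff(remaining, v)
    for (w in adj[[v]]) deg[w] <- deg[w] - 1L
  }
  order
}

# ---- node registry ---------------------------------------------------------

.node_registry <- new.env(parent = emptyenv())

#' Register a node kind
#'
#' A node kind is a pair of functions: `init(params, ctx)` returning the
#' node's initial state, and `update(state, inputs, ctx)` returning
#' `list(state =, outputs = list(port = value))`. `inputs` is a named list
#' (input port -> value produced upstream this tick; absent if the upstream
#' produced nothing). `ctx` carries `tick`, `time`, `rate`, `broker` and
#' the node `params`.
#'
#' @param kind Node kind name (string).
#' @param init Initialiser, or `NULL` for stateless nodes.
#' @param update Update function, called once per tick.
#' @return `kind`, invisibly.
#' @export
register_node <- function(kind, update, init = NULL) {
  stopifnot(is.character(kind), is.function(update))
  assign(kind, list(init = init, update = update), envir = .node_registry)
  invisible(kind)
}

#' List registered node kinds
#' @return Character vector.
#' @export
node_kinds <- function() sort(ls(.node_registry))

#' Instantiate a runtime graph
#'
#' @param spec A [graph_spec()].
#' @param broker A [broker()] shared across graphs (created if missing).
#' @return An object of class `runtime_graph` (an environment) holding node
#'   states, the execution order and tick counters.
#' @export
build_graph <- function(spec, broker = NULL) {
  order <- validate_graph(spec)
  if (is.null(broker)) broker <- broker()
  nodes <- stats::setNames(spec$nodes, vapply(spec$nodes, `[[`, "", "id"))
  g <- new.env(parent = emptyenv())
  g$spec <- spec
  g$order <- order
  g$broker <- broker
  g$tick <- 0L
  g$states <- list()
  g$outputs <- list()
  for (id in order) {
    nd <- nodes[[id]]
    impl <- .node_registry[[nd$kind]]
    if (is.null(impl)) {
      stop(sprintf("unknown node kind '%s' (node '%s')", nd$kind, id),
           call. = FALSE)
    }
    ctx <- list(tick = 0L, time = 0, rate = spec$rate, broker = broker,
                params = nd$params)
    g$states[[id]] <- if (is.null(impl$init)) NULL else {
      impl$init(nd$params, ctx)
    }
  }
  class(g) <- "runtime_graph"
  g
}

#' Execute one tick of a graph
#'
#' Calls each node's update exactly once, in topological order; outputs
#' produced this tick are visible to downstream nodes within the same
#' tick. If a node's update fails, the tick aborts with the node id
#' attached and the remaining nodes are not touched that tick.
#'
#' @param graph A [build_graph()] result.
#' @return The graph, invisibly.
#' @export
tick_graph <- function(graph) {
  stopifnot(inherits(graph, "runtime_graph"))
  graph$tick <- graph$tick + 1L
  time <- graph$tick / graph$spec$rate
  nodes <- stats::setNames(graph$spec$nodes,
                           vapply(graph$spec$nodes, `[[`, "", "id"))
  tick_outputs <- list()
  for (id in graph$order) {
    nd <- nodes[[id]]
    inputs <- list()
    for (e in graph$spec$edges) {
      if (e$target$node != id) next
      up <- tick_outputs[[e$source$node]]
      if (!is.null(up) && e$source$port %in% names(up)) {
        inputs[[e$target$port]] <- up[[e$source$port]]
      }
    }
    impl <- .node_registry[[nd$kind]]
    ctx <- list(tick = graph$tick, time = time, rate = graph$spec$rate,
                broker = graph$broker, params = nd$params)
    res <- tryCatch(
      impl$update(graph$states[[id]], inputs, ctx),
      error = function(e) {
        stop(structure(
          class = c("node_update_error", "error", "condition"),
          list(message = sprintf("node '%s' failed on tick %d: %s", id,
                                 graph$tick, conditionMessage(e)),
               call = NULL, node = id)))
      })
    graph$states[[id]] <- res$state
    tick_outputs[[id]] <- res$outputs
  }
  graph$outputs <- tick_outputs
  invisible(graph)
}

#' Run a graph over simulated time
#'
#' Executes exactly `floor(duration * rate)` ticks on the simulated clock;
#' no wall-clock dependence.
#'
#' @param graph A [build_graph()] result.
#' @param duration Simulated duration, s.
#' @return The graph, invisibly.
#' @export
run_graph <- function(graph, duration) {
  n_ticks <- floor(duration * graph$spec$rate)
  for (i in seq_len(n_ticks)) tick_graph(graph)
  invisible(graph)
}

#' @export
print.runtime_graph <- function(x, ...) {
  cat(sprintf("<runtime_graph '%s': %d nodes @ %g Hz, tick %d>\n",
              x$spec$name, length(x$order), x$spec$rate, x$tick))
  invisible(x)
}
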