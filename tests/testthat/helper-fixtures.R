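# Shared fixtures: small synthetic configurations and brute-force oracles.

quiet_cfg <- function(seed = 1L, n_channels = 4L, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_channels = n_channels, blink_rate = 0,
         line_amp = 0),
    list(...))
  do.call(synth_config, args)
}

# All permutations of a small vector (brute-force enumeration oracle).
all_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_permutations(v[-i])) {
      out[[length(out) + 1L]] <- c(v[i], rest)
    }
  }
  out
}

# Does `order` satisfy every edge (source before target)?
order_satisfies_edges <- function(order, edges) {
  pos <- stats::setNames(seq_along(order), order)
  all(vapply(edges, function(e) {
    pos[[e$source$node]] < pos[[e$target$node]]
  }, TRUE))
}

# Brute-force set of all valid topological orders of a graph_spec.
valid_orders_bruteforce <- function(spec) {
  ids <- vapply(spec$nodes, `[[`, "", "id")
  Filter(function(p) order_satisfies_edges(p, spec$edges),
         all_permutations(ids))
}

# Random DAG on n nodes: edges only from lower to higher random rank, then
# ids shuffled so declaration order carries no information.
random_dag_spec <- function(n, p_edge = 0.4, rate = 10) {
  ids <- sample(paste0("n", seq_len(n)))
  rank <- sample(n)
  edges <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      a <- which(rank == i)
      b <- which(rank == j)
      if (stats::runif(1) < p_edge) {
        edges[[length(edges) + 1L]] <-
          list(source = paste0(ids[a], ":out"),
               target = paste0(ids[b], ":", ids[a]))  # unique in-ports
      }
    }
  }
  graph_spec(rate = rate,
             nodes = lapply(ids, function(id) list(id = id, kind = "probe")),
             edges = edges)
}

# "probe" node: records the global update sequence number at each tick.
probe_log <- new.env()

register_node("probe",
  update = function(state, inputs, ctx) {
    probe_log$seq <- probe_log$seq + 1L
    state$calls <- c(state$calls, probe_log$seq)
    list(state = state, outputs = list(out = probe_log$seq))
  },
  init = function(params, ctx) list(calls = integer(0)))

register_node("counter",
  update = function(state, inputs, ctx) {
    state$count <- state$count + 1L
    list(state = state, outputs = list(out = state$count))
  },
  init = function(params, ctx) list(count = 0L))

register_node("const",
  update = function(state, inputs, ctx) {
    list(state = state, outputs = list(out = ctx$params$value))
  })

register_node("doubler",
  update = function(state, inputs, ctx) {
    out <- if (is.null(inputs$`in`)) NULL else 2 * inputs$`in`
    list(state = state,
         outputs = if (is.null(out)) list() else list(out = out))
  })

register_node("failer",
  update = function(state, inputs, ctx) stop("boom"))

# Deterministic SPD fixture.
seeded_spd <- function(p, seed) {
  withr::with_seed(seed, random_spd(p))
}
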