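#' Read an application configuration file
#'
#' One JSON document per application, listing processing graphs (each with
#' `rate`, `nodes`, `edges`), an optional session timeline and optional
#' synthetic-generator parameters. Mirrors the usual one-file-per-app
#' graph layout of stream-processing frameworks; JSON is used as the
#' document format.
#'
#' @param path JSON file.
#' @return List with `graphs` (list of [graph_spec()]), `session` (raw
#'   list or `NULL`) and `synth` (a [synth_config()] or `NULL`).
#' @export
read_app_config <- function(path) {
  doc <- jsonlite::read_json(path)
  graphs <- lapply(doc$graphs, function(g) {
    graph_spec(rate = g$rate,
               nodes = lapply(g$nodes, function(nd) {
                 list(id = nd$id, kind = nd$kind,
                      params = nd$params %||% list())
               }),
               edges = lapply(g$edges, function(e) {
                 list(source = e$source, target = e$target)
               }),
               name = g$name %||% "graph")
  })
  synth <- NULL
  if (!is.null(doc$synth)) {
    synth <- do.call(synth_config, lapply(doc$synth, function(v) {
      if (is.list(v)) unlist(v) else v
    }))
  }
  list(graphs = graphs, session = doc$session, synth = synth)
}
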