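# Import/export helpers: spike rasters and weight matrices as CSV, chain
# graphs as edge-list CSV or DOT.

#' Write / read a spike raster as CSV
#'
#' Columns: `source_id`, `time_ms`, and `label` when present.
#'
#' @param raster A `spike_raster` (or any data.frame with `source`, `time`).
#' @param path Output file.
#' @export
write_raster_csv <- function(raster, path) {
  df <- data.frame(source_id = raster$source, time_ms = raster$time)
  if (!is.null(raster$label)) df$label <- as.character(raster$label)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_raster_csv
#' @param n_sources,duration Raster attributes to restore (inferred from the
#'   data when omitted).
#' @export
read_raster_csv <- function(path, n_sources = NULL, duration = NULL) {
  df <- utils::read.csv(path)
  out <- data.frame(source = df$source_id, time = df$time_ms)
  if (!is.null(df$label)) {
    out$label <- factor(df$label, levels = c("pattern", "carrier", "background"))
  }
  structure(out, class = c("spike_raster", "data.frame"),
            n_sources = n_sources %||% max(df$source_id),
            duration = duration %||% max(df$time_ms))
}

#' Write a weight matrix as a long-format CSV
#'
#' @param w Matrix (rows = presynaptic source, columns = postsynaptic
#'   neuron).
#' @param path Output file.
#' @param source_name Column name for the row index.
#' @export
write_weights_csv <- function(w, path, source_name = "src_id") {
  idx <- which(w != 0, arr.ind = TRUE)
  df <- data.frame(src = idx[, 1], neuron_id = idx[, 2], weight = w[idx])
  names(df)[1] <- source_name
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a chain graph
#'
#' Writes the strengthened-lateral-synapse graph as an edge-list CSV or a
#' Graphviz DOT file (accepting neurons drawn with a double border, as is
#' conventional for accepting states of finite automata).
#'
#' @param graph A [extract_chain_graph()] result.
#' @param path Output file.
#' @export
write_chain_edges_csv <- function(graph, path) {
  utils::write.csv(graph$edges, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_chain_edges_csv
#' @export
write_chain_dot <- function(graph, path) {
  lines <- c("digraph chain {", "  rankdir=LR;")
  for (m in graph$members) {
    shape <- if (m %in% graph$accepting) "doublecircle" else "circle"
    lines <- c(lines, sprintf("  n%d [label=\"%d\", shape=%s];", m, m, shape))
  }
  if (nrow(graph$edges)) {
    lines <- c(lines, sprintf("  n%d -> n%d [penwidth=%.2f];",
                              graph$edges$src, graph$edges$dst,
                              0.5 + 3 * graph$edges$weight / graph$wl_max))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
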