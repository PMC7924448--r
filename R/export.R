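# Graph and trace serialization: Graphviz DOT and a JSON run trace.

dot_escape <- function(x) gsub('"', '\\\\"', x)

#' Export the task graph as Graphviz DOT
#'
#' One DOT node per task, labelled with its id, name, role
#' (task/copy/select, uncertain/speculative flags) and current activation;
#' one DOT edge per dependency. Output is deterministic for a fixed graph.
#'
#' @param rt an `stf_runtime`.
#' @param file optional path; when given the DOT text is also written there.
#' @return the DOT source as a single character string.
#' @export
export_dot <- function(rt, file = NULL) {
  stopifnot(inherits(rt, "stf_runtime"))
  nodes <- graph_nodes(rt)
  lines <- c("digraph stf {", "  rankdir=TB;")
  if (nrow(nodes) > 0) {
    role_of <- function(i) {
      r <- nodes$role[i]
      if (r == "task" && nodes$uncertain[i] && !nodes$speculative[i]) r <- "uncertain"
      if (nodes$speculative[i]) r <- "speculative"
      r
    }
    shape <- c(task = "box", uncertain = "diamond", speculative = "ellipse",
               copy = "note", select = "invtrapezium")
    col <- c(ENABLED = "black", DISABLED = "gray60")
    for (i in seq_len(nrow(nodes))) {
      r <- role_of(i)
      lines <- c(lines, sprintf(
        '  t%d [label="%d: %s\\n%s, %s", shape=%s, color=%s];',
        nodes$id[i], nodes$id[i], dot_escape(nodes$name[i]), r,
        nodes$activation[i], shape[[r]], col[[nodes$activation[i]]]))
    }
  }
  edges <- graph_edges(rt)
  if (nrow(edges) > 0) {
    o <- order(edges$from, edges$to)
    lines <- c(lines, sprintf("  t%d -> t%d;", edges$from[o], edges$to[o]))
  }
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(file)) writeLines(txt, file)
  invisible(txt)
}

#' Export the run trace as JSON
#'
#' A list of records `{task id, name, role, worker, start, end, activation,
#' group, group_state, group_failed}` in abstract time units, plus the
#' makespan.
#'
#' @param rt an `stf_runtime` (executed or not; unexecuted tasks have null
#'   times).
#' @param file optional path to write the JSON to.
#' @return the JSON string, invisibly.
#' @export
export_trace_json <- function(rt, file = NULL) {
  tr <- run_trace(rt)
  txt <- jsonlite::toJSON(list(makespan = tr$makespan, records = tr$records),
                          dataframe = "rows", na = "null", auto_unbox = TRUE,
                          digits = NA, pretty = TRUE)
  if (!is.null(file)) writeLines(txt, file)
  invisible(as.character(txt))
}
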