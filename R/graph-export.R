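#' Export a similarity graph
#'
#' Serializes a similarity graph deterministically.  DOT output styles
#' solid/dotted edges accordingly and labels each edge
#' `"<avg_rmsd> A / <avg_length> nt / <label_pct>%"`; GraphML carries the
#' same attributes as typed keys; JSON is a faithful round-trippable dump
#' (see [read_graph_json()]).
#'
#' @param g a `similarity_graph`.
#' @param path output path.
#' @param format `"DOT"`, `"GraphML"` or `"JSON"`.
#' @return (invisibly) the path.
#' @export
export_graph <- function(g, path, format = c("DOT", "GraphML", "JSON")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) abort(paste0(
                       "unknown graph format: ", format[1],
                       " (use DOT, GraphML or JSON)")))
  switch(format,
         DOT = export_graph_dot(g, path),
         GraphML = export_graph_graphml(g, path),
         JSON = export_graph_json(g, path))
  invisible(path)
}

edge_label <- function(e) {
  sprintf("%.2f A / %.1f nt / %.1f%%", e$avg_rmsd, e$avg_length, e$label_pct)
}

export_graph_dot <- function(g, path) {
  nodes <- arrange(g$nodes, .data$family)
  edges <- arrange(g$edges, .data$family_a, .data$family_b)
  lines <- c(
    sprintf("graph motif_similarity_%s {", g$mode),
    sprintf("  // rmsd_cutoff=%g pct_threshold=%g",
            g$parameters$rmsd_cutoff, g$parameters$pct_threshold),
    sprintf("  \"%s\" [label=\"%s\\n(%d)\"];", nodes$family, nodes$family,
            nodes$n_instances),
    if (nrow(edges) > 0L)
      sprintf("  \"%s\" -- \"%s\" [style=%s, label=\"%s\"];",
              edges$family_a, edges$family_b,
              ifelse(edges$status == "solid", "solid", "dashed"),
              edge_label(edges)),
    "}"
  )
  writeLines(lines, path)
}

export_graph_graphml <- function(g, path) {
  nodes <- arrange(g$nodes, .data$family)
  edges <- arrange(g$edges, .data$family_a, .data$family_b)
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
    "  <key id=\"n\" for=\"node\" attr.name=\"n_instances\" attr.type=\"int\"/>",
    "  <key id=\"rmsd\" for=\"edge\" attr.name=\"avg_rmsd\" attr.type=\"double\"/>",
    "  <key id=\"len\" for=\"edge\" attr.name=\"avg_length\" attr.type=\"double\"/>",
    "  <key id=\"pct\" for=\"edge\" attr.name=\"label_pct\" attr.type=\"double\"/>",
    "  <key id=\"status\" for=\"edge\" attr.name=\"status\" attr.type=\"string\"/>",
    sprintf("  <graph id=\"motif_similarity_%s\" edgedefault=\"undirected\">",
            g$mode),
    sprintf("    <node id=\"%s\"><data key=\"n\">%d</data></node>",
            esc(nodes$family), nodes$n_instances),
    if (nrow(edges) > 0L)
      sprintf(paste0("    <edge source=\"%s\" target=\"%s\">",
                     "<data key=\"rmsd\">%.6g</data>",
                     "<data key=\"len\">%.6g</data>",
                     "<data key=\"pct\">%.6g</data>",
                     "<data key=\"status\">%s</data></edge>"),
              esc(edges$family_a), esc(edges$family_b), edges$avg_rmsd,
              edges$avg_length, edges$label_pct, edges$status),
    "  </graph>",
    "</graphml>"
  )
  writeLines(lines, path)
}

export_graph_json <- function(g, path) {
  obj <- list(
    mode = g$mode,
    parameters = g$parameters,
    nodes = arrange(g$nodes, .data$family),
    edges = arrange(g$edges, .data$family_a, .data$family_b)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
}

#' Read a similarity graph from its JSON export
#'
#' @param path a JSON file written by [export_graph()].
#' @return a `similarity_graph`.
#' @export
read_graph_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- as_tibble(obj$edges)
  if (nrow(edges) == 0L) {
    edges <- tibble(family_a = character(), family_b = character(),
                    n_pairs = integer(), avg_rmsd = numeric(),
                    avg_length = numeric(), pct_a = numeric(),
                    pct_b = numeric(), label_pct = numeric(),
                    status = character())
  } else {
    edges$n_pairs <- as.integer(edges$n_pairs)
  }
  nodes <- as_tibble(obj$nodes)
  nodes$n_instances <- as.integer(nodes$n_instances)
  structure(list(nodes = nodes, edges = edges, mode = obj$mode,
                 parameters = obj$parameters),
            class = "similarity_graph")
}
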