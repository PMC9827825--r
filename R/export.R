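# Plain-text network exports: GraphML for graph tooling, an edge-list CSV
# for spreadsheets, and a JSON dump that round-trips through
# read_network_json() (node structures serialized as SMILES). All writers
# are deterministic for a given network so repeated runs are byte-identical.

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

.num_attr <- function(x) {
  ifelse(is.na(x), "", sprintf("%.10g", x))
}

#' Export a reaction network as GraphML
#'
#' Nodes carry key, formula, SMILES and flags; edges carry barriers, heat of
#' reaction, step label, co-products and conformer statistics. Output is
#' deterministic (byte-identical across runs on the same network).
#'
#' @param network a `reaction_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(network, path) {
  n <- network$nodes
  e <- network$edges
  node_keys <- c(formula = "string", smiles = "string", seed = "boolean",
                 explored = "boolean", excluded_reason = "string")
  edge_keys <- c(ers_label = "string", co_products = "string",
                 delta_h = "double", delta_g_forward = "double",
                 delta_g_backward = "double", best_delta_g = "double",
                 range_delta_g = "double", n_intended = "int",
                 source = "string")
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
    sprintf("  <key id=\"n_%s\" for=\"node\" attr.name=\"%s\" attr.type=\"%s\"/>",
            names(node_keys), names(node_keys), node_keys),
    sprintf("  <key id=\"e_%s\" for=\"edge\" attr.name=\"%s\" attr.type=\"%s\"/>",
            names(edge_keys), names(edge_keys), edge_keys),
    "  <graph id=\"reaction_network\" edgedefault=\"undirected\">")
  id_of <- stats::setNames(sprintf("v%d", seq_len(nrow(n))), n$key)
  for (r in seq_len(nrow(n))) {
    vals <- c(formula = n$formula[r], smiles = n$smiles[r],
              seed = tolower(as.character(n$seed[r])),
              explored = tolower(as.character(n$explored[r])),
              excluded_reason = if (is.na(n$excluded_reason[r])) "" else n$excluded_reason[r])
    lines <- c(lines,
               sprintf("    <node id=\"%s\">", id_of[[n$key[r]]]),
               sprintf("      <data key=\"n_key\">%s</data>", .xml_escape(n$key[r])),
               sprintf("      <data key=\"n_%s\">%s</data>", names(vals),
                       .xml_escape(ifelse(is.na(vals), "", vals))),
               "    </node>")
  }
  for (r in seq_len(nrow(e))) {
    vals <- c(ers_label = e$ers_label[r], co_products = e$co_products[r],
              delta_h = .num_attr(e$delta_h[r]),
              delta_g_forward = .num_attr(e$delta_g_forward[r]),
              delta_g_backward = .num_attr(e$delta_g_backward[r]),
              best_delta_g = .num_attr(e$best_delta_g[r]),
              range_delta_g = .num_attr(e$range_delta_g[r]),
              n_intended = as.character(e$n_intended[r]),
              source = e$source[r])
    lines <- c(lines,
               sprintf("    <edge source=\"%s\" target=\"%s\">",
                       id_of[[e$from[r]]], id_of[[e$to[r]]]),
               sprintf("      <data key=\"e_%s\">%s</data>", names(vals),
                       .xml_escape(ifelse(is.na(vals), "", vals))),
               "    </edge>")
  }
  lines <- c(lines, "  </graph>", "</graphml>")
  writeLines(lines, path)
  invisible(path)
}

#' Export the network edge list as CSV
#'
#' @param network a `reaction_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edgelist_csv <- function(network, path) {
  utils::write.csv(network$edges, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Dump / restore a reaction network as JSON
#'
#' The JSON dump carries nodes (with SMILES), edges, the funnel stage log
#' and the configuration scalars; node structures are rebuilt from SMILES on
#' reading. Characterization records are not included (archive them with
#' [write_ts_records()]).
#'
#' @param network a `reaction_network`.
#' @param path file path.
#' @return `path` invisibly for the writer; a `reaction_network` (without
#'   records) for the reader.
#' @export
write_network_json <- function(network, path) {
  payload <- list(
    format = "ersnet-network", version = 1L,
    nodes = network$nodes, edges = network$edges,
    stage_counts = network$stage_counts,
    config = network$config[c("dh_threshold", "dg_low_threshold", "k_conformers",
                              "max_iterations", "min_heavy_atoms", "seed")]
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  if (!identical(x$format, "ersnet-network")) .stop2("not an ersnet network dump")
  nodes <- tibble::as_tibble(x$nodes)
  if (!"excluded_reason" %in% names(nodes)) nodes$excluded_reason <- NA_character_
  edges <- tibble::as_tibble(x$edges)
  graphs <- list()
  for (r in seq_len(nrow(nodes))) {
    if (!is.na(nodes$smiles[r])) {
      graphs[[nodes$key[r]]] <- parse_smiles(nodes$smiles[r])
    }
  }
  structure(list(nodes = nodes, edges = edges, records = .empty_records(),
                 graphs = graphs,
                 stage_counts = tibble::as_tibble(x$stage_counts),
                 config = x$config),
            class = "reaction_network")
}
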