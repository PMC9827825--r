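# Canonical graph keys. Species identity throughout the package -- candidate
# deduplication, IRC endpoint matching, network node identity -- is the
# canonical key of the molecular graph, so isomorphic graphs (and hence
# stereoisomers, which the graph model does not distinguish) collapse to one
# species.
#
# Bond orders are encoded by subdividing every bond with an auxiliary vertex
# colored by the order; canonical labeling of the colored auxiliary graph
# (BLISS, via igraph) then respects both elements and bond orders. The key is
# the adjacency serialization under the canonical atom order, prefixed with
# the Hill formula.

.key_cache <- new.env(parent = emptyenv())

.element_color <- c(H = 1L, C = 2L, N = 3L, O = 4L, S = 5L, P = 6L)

#' Canonical key of a connected or disconnected molecular graph
#'
#' Returns a deterministic string identical for isomorphic graphs and
#' distinct for non-isomorphic ones: atom-permutation invariant by canonical
#' labeling of an element/bond-order colored graph. For graphs with several
#' components the component keys are sorted and joined, so the key of a
#' species set does not depend on component order (see [species_key()]).
#'
#' @param graph a `molgraph`.
#' @return character canonical key.
#' @export
#' @examples
#' canonical_key(parse_smiles("CCO")) == canonical_key(parse_smiles("OCC")) # TRUE
#' canonical_key(parse_smiles("CCO")) == canonical_key(parse_smiles("COC")) # FALSE
canonical_key <- function(graph) {
  comps <- split_components(graph)
  if (length(comps) == 1) return(.component_key(comps[[1]]))
  paste(sort(vapply(comps, .component_key, character(1))), collapse = "+")
}

#' Set-level canonical key of a species set
#'
#' Alias of [canonical_key()] emphasising the species-set reading: the key of
#' a multi-fragment graph is the sorted join of its component keys and is
#' invariant under component reordering.
#'
#' @param graph a `molgraph` (possibly disconnected) or a list of `molgraph`
#'   components.
#' @return character key.
#' @export
species_key <- function(graph) {
  if (inherits(graph, "molgraph")) return(canonical_key(graph))
  paste(sort(vapply(graph, canonical_key, character(1))), collapse = "+")
}

.component_key <- function(g) {
  raw <- paste0(paste(g$elements, collapse = ","), ";",
                paste(t(bond_list(g)), collapse = ","))
  hit <- .key_cache[[raw]]
  if (!is.null(hit)) return(hit)
  n <- n_atoms(g)
  bl <- bond_list(g)
  nb <- nrow(bl)
  key <- if (n == 1) {
    paste0(molecular_formula(g), "|", g$elements[1])
  } else {
    # auxiliary graph: atoms 1..n, one subdivision vertex per bond
    edges <- integer(0)
    colors <- c(.element_color[g$elements], 6L + bl[, 3])
    if (nb > 0) {
      aux <- n + seq_len(nb)
      edges <- as.integer(t(cbind(c(bl[, 1], bl[, 2]), c(aux, aux))))
    }
    ig <- igraph::make_empty_graph(n + nb, directed = FALSE)
    if (length(edges)) ig <- igraph::add_edges(ig, edges)
    perm <- igraph::canonical_permutation(ig, colors = colors)$labeling
    # rank of atoms among themselves under the canonical labeling
    atom_rank <- rank(perm[seq_len(n)])
    inv <- order(atom_rank) # inv[k] = original atom at canonical position k
    el_canon <- g$elements[inv]
    if (nb > 0) {
      ci <- atom_rank[bl[, 1]]
      cj <- atom_rank[bl[, 2]]
      lo <- pmin(ci, cj); hi <- pmax(ci, cj)
      ord <- order(lo, hi)
      edge_str <- paste(sprintf("%d-%d:%d", lo[ord], hi[ord], bl[ord, 3]),
                        collapse = ",")
    } else {
      edge_str <- ""
    }
    paste0(molecular_formula(g), "|", paste(el_canon, collapse = "."),
           "/", edge_str)
  }
  .key_cache[[raw]] <- key
  key
}
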