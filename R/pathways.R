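# Minimax (bottleneck) pathway analysis: the most kinetically favorable
# pathway between two species is the one whose largest single barrier is
# smallest. Each undirected network edge is traversed with its directed
# barrier: the stored forward barrier in the reactant-to-product direction,
# the thermochemistry-consistent backward barrier (forward - dH) the other
# way.

.directed_edges <- function(network) {
  e <- network$edges
  fwd <- tibble::tibble(from = e$from, to = e$to, barrier = e$delta_g_forward,
                        edge_row = seq_len(nrow(e)), direction = "forward")
  bwd <- tibble::tibble(from = e$to, to = e$from, barrier = e$delta_g_backward,
                        edge_row = seq_len(nrow(e)), direction = "backward")
  d <- dplyr::bind_rows(fwd, bwd)
  # a fragmentation edge also connects the reactant to each co-product (same
  # barrier: it is one reaction); the reverse step implies the co-fragments
  co_rows <- which(nzchar(e$co_products) & !is.na(e$co_products))
  for (r in co_rows) {
    for (ck in strsplit(e$co_products[r], " + ", fixed = TRUE)[[1]]) {
      d <- dplyr::bind_rows(
        d,
        tibble::tibble(from = e$from[r], to = ck, barrier = e$delta_g_forward[r],
                       edge_row = r, direction = "forward"),
        tibble::tibble(from = ck, to = e$from[r], barrier = e$delta_g_backward[r],
                       edge_row = r, direction = "backward"))
    }
  }
  d[!is.na(d$barrier), , drop = FALSE]
}

# Bottleneck Dijkstra from `source`: minimal over paths of the maximal
# directed barrier, to every reachable node. Returns list(bottleneck, steps)
# named by node key.
.bottleneck_search <- function(dir_edges, source) {
  keys <- sort(unique(c(dir_edges$from, dir_edges$to, source)))
  bneck <- stats::setNames(rep(Inf, length(keys)), keys)
  steps <- stats::setNames(rep(Inf, length(keys)), keys)
  done <- stats::setNames(rep(FALSE, length(keys)), keys)
  bneck[source] <- 0
  steps[source] <- 0
  adj <- split(seq_len(nrow(dir_edges)), dir_edges$from)
  repeat {
    open <- which(!done & is.finite(bneck))
    if (!length(open)) break
    # deterministic extraction: smallest (bottleneck, steps, key)
    o <- open[order(bneck[open], steps[open], names(bneck)[open])][1]
    u <- names(bneck)[o]
    done[o] <- TRUE
    for (r in adj[[u]]) {
      v <- dir_edges$to[r]
      nb <- max(bneck[u], dir_edges$barrier[r])
      ns <- steps[u] + 1
      if (nb < bneck[v] || (nb == bneck[v] && ns < steps[v])) {
        bneck[v] <- nb
        steps[v] <- ns
      }
    }
  }
  list(bottleneck = bneck, steps = steps)
}

#' Minimax (lowest-maximum-barrier) pathway between two species
#'
#' Among all simple paths from `source_key` to `target_key`, finds one
#' minimizing the maximum directed barrier along it; ties are broken by
#' fewer edges, then by lexicographic node keys. Returns `NULL` when the
#' target is unreachable.
#'
#' @param network a `reaction_network`.
#' @param source_key,target_key canonical node keys.
#' @return `NULL`, or a list with `path` (node-key vector), `edges` (tibble
#'   of traversed directed edges with barriers) and `bottleneck` (kcal/mol).
#' @export
minimax_pathway <- function(network, source_key, target_key) {
  if (!source_key %in% network$nodes$key) .stop2("unknown node key: ", source_key)
  if (!target_key %in% network$nodes$key) .stop2("unknown node key: ", target_key)
  if (source_key == target_key) {
    return(list(path = source_key, edges = .directed_edges(network)[0, ],
                bottleneck = 0))
  }
  de <- .directed_edges(network)
  if (!nrow(de)) return(NULL)
  bs <- .bottleneck_search(de, source_key)
  bstar <- bs$bottleneck[target_key]
  if (is.na(bstar) || !is.finite(bstar)) return(NULL)
  # restrict to edges not above the optimal bottleneck, then take the
  # fewest-hop path with lexicographic tie-breaking via ordered BFS
  sub <- de[de$barrier <= bstar + 1e-9, , drop = FALSE]
  sub <- sub[order(sub$from, sub$to), , drop = FALSE]
  parent <- list()
  dist <- list()
  dist[[source_key]] <- 0L
  queue <- source_key
  while (length(queue)) {
    u <- queue[[1]]
    queue <- queue[-1]
    out <- sub[sub$from == u, , drop = FALSE]
    for (r in seq_len(nrow(out))) {
      v <- out$to[r]
      if (is.null(dist[[v]])) {
        dist[[v]] <- dist[[u]] + 1L
        parent[[v]] <- u
        queue <- c(queue, v)
      }
    }
  }
  if (is.null(dist[[target_key]])) return(NULL)
  path <- target_key
  while (path[1] != source_key) path <- c(parent[[path[1]]], path)
  used <- lapply(seq_len(length(path) - 1), function(i) {
    hit <- sub[sub$from == path[i] & sub$to == path[i + 1], , drop = FALSE]
    hit[which.min(hit$barrier), , drop = FALSE]
  })
  used <- dplyr::bind_rows(used)
  list(path = path, edges = used, bottleneck = unname(max(used$barrier)))
}

#' Rank reachable species by minimax bottleneck barrier
#'
#' Computes the minimax bottleneck from `source_key` to every reachable node
#' and returns those at or below `cutoff`, ascending (the source itself has
#' bottleneck 0). This is the "most kinetically favorable products" view of
#' a network.
#'
#' @param network a `reaction_network`.
#' @param source_key canonical key of the starting species.
#' @param cutoff barrier cap in kcal/mol (default `Inf`: all reachable).
#' @return tibble with `key`, `bottleneck`, `n_steps`, sorted by bottleneck.
#' @export
kinetically_favorable_products <- function(network, source_key, cutoff = Inf) {
  if (!source_key %in% network$nodes$key) .stop2("unknown node key: ", source_key)
  de <- .directed_edges(network)
  if (!nrow(de)) {
    return(tibble::tibble(key = source_key, bottleneck = 0, n_steps = 0L))
  }
  bs <- .bottleneck_search(de, source_key)
  reach <- names(bs$bottleneck)[is.finite(bs$bottleneck)]
  out <- tibble::tibble(key = reach,
                        bottleneck = unname(bs$bottleneck[reach]),
                        n_steps = as.integer(bs$steps[reach]))
  if (!source_key %in% out$key) {
    out <- dplyr::bind_rows(out, tibble::tibble(key = source_key, bottleneck = 0,
                                                n_steps = 0L))
  }
  out <- out[out$bottleneck <= cutoff, , drop = FALSE]
  dplyr::arrange(out, .data$bottleneck, .data$n_steps, .data$key)
}

#' Energy-diagram table for a pathway
#'
#' Cumulative reaction-energy profile along a minimax pathway: per step the
#' traversed barrier, the step reaction energy and the running cumulative
#' energy relative to the source species.
#'
#' @param network a `reaction_network`.
#' @param pathway result of [minimax_pathway()].
#' @return tibble with one row per step.
#' @export
pathway_energy_table <- function(network, pathway) {
  if (is.null(pathway) || length(pathway$path) < 2) {
    return(tibble::tibble(step = integer(), from = character(), to = character(),
                          barrier = numeric(), delta_h = numeric(),
                          cumulative_h = numeric()))
  }
  e <- network$edges
  steps <- pathway$edges
  dh <- vapply(seq_len(nrow(steps)), function(i) {
    row <- e[steps$edge_row[i], , drop = FALSE]
    if (steps$direction[i] == "forward") row$delta_h else -row$delta_h
  }, numeric(1))
  tibble::tibble(step = seq_len(nrow(steps)), from = steps$from, to = steps$to,
                 barrier = steps$barrier, delta_h = dh,
                 cumulative_h = cumsum(ifelse(is.na(dh), 0, dh)))
}
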