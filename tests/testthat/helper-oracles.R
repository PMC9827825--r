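# Shared test helpers: independent brute-force oracles and fixture builders.

# Relabel the atoms of a graph by a permutation: atom i of the result is atom
# perm[i] of the input.
permute_graph <- function(g, perm) {
  molgraph(g$elements[perm], g$bonds[perm, perm, drop = FALSE], label = g$label)
}

# Allowed valences, restated independently of the package internals.
.oracle_valences <- list(H = 1L, C = 4L, N = 3L, O = 2L, S = c(2L, 4L, 6L),
                         P = c(3L, 5L))

.oracle_valence_ok <- function(elements, bonds) {
  v <- rowSums(bonds)
  all(vapply(seq_along(v), function(i) v[i] %in% .oracle_valences[[elements[i]]],
             logical(1)))
}

# All multisets of size k over 1..n as a list of index vectors.
.multisets <- function(n, k) {
  out <- list()
  recurse <- function(start, left, acc) {
    if (left == 0) {
      out[[length(out) + 1]] <<- acc
      return()
    }
    if (start > n) return()
    for (i in start:n) recurse(i, left - 1, c(acc, i))
  }
  if (n >= 1) recurse(1, k, integer(0))
  out
}

# Naive brute-force ERS enumerator: every multiset of n_break bond units x
# every multiset of n_form formed units over all atom pairs, applied blindly,
# keeping valence-valid non-identity products; returns the set of distinct
# product canonical keys. No pruning; deduplication is post hoc.
naive_enumerate_keys <- function(graph, n_break = 2, n_form = 2) {
  bl <- bond_list(graph)
  units <- bl[rep(seq_len(nrow(bl)), bl[, 3]), 1:2, drop = FALSE]
  n <- n_atoms(graph)
  pairs <- t(utils::combn(seq_len(n), 2))
  rkey <- canonical_key(graph)
  keys <- character(0)
  break_sets <- .multisets(nrow(units), n_break)
  # drop break multisets taking more units than a bond has
  break_sets <- Filter(function(bs) {
    tab <- table(paste(units[bs, 1], units[bs, 2]))
    all(vapply(names(tab), function(u) {
      ij <- as.integer(strsplit(u, " ")[[1]])
      tab[[u]] <= graph$bonds[ij[1], ij[2]]
    }, logical(1)))
  }, break_sets)
  form_sets <- .multisets(nrow(pairs), n_form)
  for (bs in break_sets) {
    b2 <- graph$bonds
    for (r in bs) {
      i <- units[r, 1]; j <- units[r, 2]
      b2[i, j] <- b2[i, j] - 1L
      b2[j, i] <- b2[i, j]
    }
    for (fs in form_sets) {
      b3 <- b2
      for (p in fs) {
        i <- pairs[p, 1]; j <- pairs[p, 2]
        b3[i, j] <- b3[i, j] + 1L
        b3[j, i] <- b3[i, j]
      }
      if (max(b3) > 3) next
      if (!.oracle_valence_ok(graph$elements, b3)) next
      k <- canonical_key(molgraph(graph$elements, b3, check = FALSE))
      if (k != rkey) keys <- c(keys, k)
    }
  }
  sort(unique(keys))
}

# Exhaustive minimax oracle: enumerate all simple paths over directed edges
# (data frame from/to/barrier) and return the best (bottleneck, hops), or
# NULL if the target is unreachable.
brute_minimax <- function(dir_edges, source, target) {
  best <- NULL
  recurse <- function(node, visited, bneck, hops) {
    if (node == target) {
      if (is.null(best) || bneck < best$bottleneck ||
          (bneck == best$bottleneck && hops < best$hops)) {
        best <<- list(bottleneck = bneck, hops = hops)
      }
      return()
    }
    out <- dir_edges[dir_edges$from == node, , drop = FALSE]
    for (r in seq_len(nrow(out))) {
      v <- out$to[r]
      if (v %in% visited) next
      recurse(v, c(visited, v), max(bneck, out$barrier[r]), hops + 1)
    }
  }
  recurse(source, source, -Inf, 0)
  if (is.null(best)) return(NULL)
  if (best$bottleneck == -Inf) best$bottleneck <- 0
  best
}

# Random small reaction network for pathway tests.
random_toy_network <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  keys <- sprintf("N%02d", seq_len(n_nodes))
  from <- sample(keys, n_edges, replace = TRUE)
  to <- sample(keys, n_edges, replace = TRUE)
  keep <- from != to
  from <- from[keep]; to <- to[keep]
  dup <- duplicated(paste(pmin(from, to), pmax(from, to)))
  from <- from[!dup]; to <- to[!dup]
  as_reaction_network(tibble::tibble(
    from = from, to = to,
    delta_g_forward = round(stats::runif(length(from), 10, 100), 1),
    delta_h = round(stats::runif(length(from), -30, 30), 1)))
}

# Pool of valence-valid graphs: fixture molecules plus their b2f2 products.
candidate_graph_pool <- function(names = c("ethanol", "khp", "ethene")) {
  pool <- list()
  for (nm in names) {
    g <- fixture_molecules(nm)
    pool[[length(pool) + 1]] <- g
    cands <- enumerate_candidates(g)
    for (pg in cands$product_graph) pool[[length(pool) + 1]] <- pg
  }
  pool
}
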