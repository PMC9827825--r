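# Recursive reaction-network exploration. Each iteration runs the full
# funnel for every eligible unexplored reactant: ERS enumeration ->
# enthalpy pre-pruning -> low-level characterization and barrier
# down-selection -> high-level characterization -> IRC classification ->
# unintended-channel mining -> expansion of the reactant pool. Nodes are
# species (canonical keys); edges are validated reactions between a reactant
# and one product species, annotated with co-products for fragmentations.

#' Exploration configuration
#'
#' @param ers list of [ers_spec()] step classes to enumerate (default b2f2).
#' @param dh_threshold enthalpy pre-pruning cap (endothermicity), kcal/mol.
#'   The conventional default is 80 kJ/mol.
#' @param dg_low_threshold down-selection cap on the best low-level barrier,
#'   kcal/mol (default 50).
#' @param k_conformers conformer attempt slots per candidate and level
#'   (default 4).
#' @param max_iterations exploration rounds (default 2: seeds, then their
#'   products).
#' @param min_heavy_atoms smallest product expanded in later rounds
#'   (default 3 non-hydrogen atoms; small molecules like water are terminal).
#' @param expansion_barrier_cutoff optional kinetic-relevance cap: a product
#'   joins the next reactant pool only if its formation barrier is below
#'   this (default `NULL`, expand all eligible products).
#' @param seed integer seed forwarded to the default backend.
#' @return an object of class `explore_config`.
#' @export
explore_config <- function(ers = list(ers_spec()),
                           dh_threshold = kj_to_kcal(80),
                           dg_low_threshold = 50,
                           k_conformers = 4L,
                           max_iterations = 2L,
                           min_heavy_atoms = 3L,
                           expansion_barrier_cutoff = NULL,
                           seed = 1L) {
  if (inherits(ers, "ers_spec")) ers <- list(ers)
  stopifnot(dh_threshold > 0 || is.infinite(dh_threshold),
            dg_low_threshold > 0, k_conformers >= 1L, max_iterations >= 1L)
  structure(list(ers = ers, dh_threshold = dh_threshold,
                 dg_low_threshold = dg_low_threshold,
                 k_conformers = as.integer(k_conformers),
                 max_iterations = as.integer(max_iterations),
                 min_heavy_atoms = as.integer(min_heavy_atoms),
                 expansion_barrier_cutoff = expansion_barrier_cutoff,
                 seed = as.integer(seed)),
            class = "explore_config")
}

.empty_nodes <- function() {
  tibble::tibble(key = character(), formula = character(), smiles = character(),
                 seed = logical(), explored = logical(),
                 excluded_reason = character())
}

# representative product fragment of a reaction: most atoms, ties broken by
# lexicographically smallest key
.main_component <- function(comps, keys) {
  sizes <- vapply(comps, n_atoms, integer(1))
  cand <- which(sizes == max(sizes))
  cand[order(keys[cand])][1]
}

.empty_edges <- function() {
  tibble::tibble(from = character(), to = character(), ers_label = character(),
                 co_products = character(), delta_h = numeric(),
                 delta_g_forward = numeric(), delta_g_backward = numeric(),
                 best_delta_g = numeric(), range_delta_g = numeric(),
                 n_intended = integer(), source = character())
}

#' Explore a reaction network from seed molecules
#'
#' Runs up to `max_iterations` rounds of the exploration funnel starting
#' from the seed species. Every reaction validated by at least one intended
#' high-level record becomes a set of edges (one per product fragment, each
#' carrying the full reaction's thermochemistry and its co-products);
#' unintended converged records whose IRC endpoint matches a pool reactant
#' are mined into additional edges. Products are expanded in the next round
#' when they have at least `min_heavy_atoms` heavy atoms, satisfy the
#' optional barrier cutoff, and have not been explored; later rounds are
#' unimolecular only (cross reactions between intermediates are neglected).
#' The result is fully deterministic given seeds, config and backend.
#'
#' @param seeds a `molgraph` or list of `molgraph` seed species.
#' @param config an [explore_config()].
#' @param backend characterization backend (default: surrogate seeded from
#'   the config).
#' @return an object of class `reaction_network` with elements `nodes`,
#'   `edges`, `records` (all tibbles), `graphs` (named list of `molgraph` by
#'   key), `stage_counts` (per-reactant funnel log) and `config`.
#' @export
#' @examples
#' net <- explore_network(parse_smiles("CC"), explore_config(max_iterations = 1))
#' net$edges$delta_g_forward
explore_network <- function(seeds, config = explore_config(),
                            backend = surrogate_backend(seed = config$seed)) {
  if (inherits(seeds, "molgraph")) seeds <- list(seeds)
  graphs <- list()
  nodes <- .empty_nodes()
  edges <- .empty_edges()
  all_records <- list()
  stage_counts <- list()

  register_node <- function(key, graph = NULL, seed_flag = FALSE) {
    if (!key %in% nodes$key) {
      smiles <- if (!is.null(graph)) to_smiles(graph) else NA_character_
      formula <- if (!is.null(graph)) molecular_formula(graph) else NA_character_
      nodes <<- dplyr::bind_rows(nodes, tibble::tibble(
        key = key, formula = formula, smiles = smiles,
        seed = seed_flag, explored = FALSE, excluded_reason = NA_character_))
    }
    if (!is.null(graph) && is.null(graphs[[key]])) graphs[[key]] <<- graph
    invisible(key)
  }

  for (g in seeds) {
    if (!valence_valid(g)) .stop2("seed graph is not valence-valid")
    for (comp in split_components(g)) register_node(canonical_key(comp), comp,
                                                    seed_flag = TRUE)
  }

  add_edge <- function(from, to, label, co_products, dh, dgf, best, rng,
                       n_int, source) {
    pid <- reaction_pair_id(from, to)
    dup <- which(reaction_pair_id(edges$from, edges$to) == pid &
                   edges$ers_label == label)
    row <- tibble::tibble(
      from = from, to = to, ers_label = label, co_products = co_products,
      delta_h = dh, delta_g_forward = dgf,
      delta_g_backward = dgf - dh,
      best_delta_g = best, range_delta_g = rng,
      n_intended = n_int, source = source)
    if (length(dup)) {
      # keep the lower-barrier representative of a duplicated (pair, label)
      if (isTRUE(row$delta_g_forward < edges$delta_g_forward[dup[1]])) {
        edges[dup[1], ] <<- row
      }
    } else {
      edges <<- dplyr::bind_rows(edges, row)
    }
  }

  for (iter in seq_len(config$max_iterations)) {
    # frontier eligibility: unexplored, not excluded, structure known, and
    # (for non-seeds) at least min_heavy_atoms heavy atoms
    for (k in nodes$key[!nodes$explored & is.na(nodes$excluded_reason) & !nodes$seed]) {
      g <- graphs[[k]]
      if (!is.null(g) && n_heavy_atoms(g) < config$min_heavy_atoms) {
        nodes$excluded_reason[nodes$key == k] <- "small_molecule"
      }
    }
    frontier <- nodes$key[!nodes$explored & is.na(nodes$excluded_reason) &
                            nodes$key %in% names(graphs)]
    frontier <- sort(frontier)
    if (!length(frontier)) break
    for (rk in frontier) {
      nodes$explored[nodes$key == rk] <- TRUE
      graph <- graphs[[rk]]
      if (is.null(graph)) next
      cands <- lapply(config$ers, function(sp) enumerate_candidates(graph, sp))
      rg <- attr(cands[[1]], "reactant_graph")
      cands <- dplyr::bind_rows(cands)
      cands <- cands[!duplicated(cands$product_key), , drop = FALSE]
      attr(cands, "reactant_graph") <- rg
      n_enum <- nrow(cands)
      cands <- estimate_reaction_enthalpy(cands)
      cands <- filter_by_enthalpy(cands, config$dh_threshold)
      n_dh <- nrow(cands)
      low <- characterize_candidates(cands, config$k_conformers, backend, "low")
      best_low <- dplyr::summarise(
        dplyr::group_by(low, .data$product_key),
        best = if (any(.data$converged)) min(.data$delta_g_act[.data$converged]) else Inf,
        .groups = "drop")
      pass_keys <- best_low$product_key[best_low$best < config$dg_low_threshold]
      kept <- cands[cands$product_key %in% pass_keys, , drop = FALSE]
      attr(kept, "reactant_graph") <- rg
      n_low <- nrow(kept)
      high <- characterize_candidates(kept, config$k_conformers, backend, "high")
      high <- classify_outcomes(high)
      all_records[[length(all_records) + 1]] <- low
      all_records[[length(all_records) + 1]] <- high
      summ <- aggregate_conformers(high)
      stage_counts[[length(stage_counts) + 1]] <- tibble::tibble(
        iteration = iter, reactant_key = rk, enumerated = n_enum,
        dh_passed = n_dh, low_passed = n_low,
        intended_reactions = sum(summ$n_intended > 0))
      # validated (intended) reactions -> one edge per reaction, drawn from
      # the reactant to the largest product fragment; co-products are
      # annotated on the edge and still registered as nodes
      for (r in seq_len(nrow(kept))) {
        pk <- kept$product_key[r]
        s <- summ[summ$product_key == pk, , drop = FALSE]
        if (!nrow(s) || s$n_intended == 0) next
        comps <- split_components(kept$product_graph[[r]])
        ckeys <- vapply(comps, canonical_key, character(1))
        for (ci in seq_along(comps)) register_node(ckeys[ci], comps[[ci]])
        main <- .main_component(comps, ckeys)
        add_edge(rk, ckeys[main], kept$ers_label[r],
                 co_products = paste(sort(ckeys[-main]), collapse = " + "),
                 dh = kept$delta_h[r], dgf = s$best_delta_g,
                 best = s$best_delta_g, rng = s$range_delta_g,
                 n_int = s$n_intended, source = "intended")
        # kinetic-relevance cap on expansion of the product fragments
        if (!is.null(config$expansion_barrier_cutoff) &&
            s$best_delta_g > config$expansion_barrier_cutoff) {
          hit <- nodes$key %in% ckeys & !nodes$explored & is.na(nodes$excluded_reason)
          nodes$excluded_reason[hit] <- "barrier_cap"
        }
      }
      # mined unintended channels
      known <- reaction_pair_id(edges$from, edges$to)
      mined <- mine_unintended(high, pool_keys = nodes$key,
                               known_pairs = known, candidates = kept)
      for (r in seq_len(nrow(mined))) {
        pk <- mined$product_key[r]
        pg <- graphs[[pk]]
        if (is.null(pg)) {
          # endpoint species not yet registered with a structure; find it in
          # the enumerated candidates if possible
          hit <- which(cands$product_key == pk)
          if (length(hit)) pg <- cands$product_graph[[hit[1]]]
        }
        to_key <- pk
        co <- ""
        if (!is.null(pg)) {
          comps <- split_components(pg)
          ckeys <- vapply(comps, canonical_key, character(1))
          for (ci in seq_along(comps)) register_node(ckeys[ci], comps[[ci]])
          main <- .main_component(comps, ckeys)
          to_key <- ckeys[main]
          co <- paste(sort(ckeys[-main]), collapse = " + ")
        } else {
          register_node(pk)
        }
        add_edge(mined$reactant_key[r], to_key,
                 ifelse(is.na(mined$ers_label[r]), "unintended", mined$ers_label[r]),
                 co_products = co, dh = NA_real_,
                 dgf = mined$delta_g_act[r], best = mined$delta_g_act[r],
                 rng = NA_real_, n_int = 0L, source = "mined")
      }
    }
    if (iter == config$max_iterations) {
      small <- !nodes$explored & is.na(nodes$excluded_reason) & !nodes$seed &
        vapply(nodes$key, function(k) {
          g <- graphs[[k]]
          !is.null(g) && n_heavy_atoms(g) < config$min_heavy_atoms
        }, logical(1))
      nodes$excluded_reason[small] <- "small_molecule"
      rest <- !nodes$explored & is.na(nodes$excluded_reason)
      nodes$excluded_reason[rest] <- "max_depth"
    }
  }
  records <- if (length(all_records)) dplyr::bind_rows(all_records) else .empty_records()
  structure(list(nodes = nodes, edges = edges, records = records,
                 graphs = graphs,
                 stage_counts = dplyr::bind_rows(stage_counts),
                 config = config),
            class = "reaction_network")
}

#' Build a reaction network from an edge table
#'
#' Constructs a `reaction_network` directly from reactions given as an edge
#' table -- useful for pathway analysis over externally supplied barrier
#' data (e.g. literature values) without running an exploration. Missing
#' columns are filled with defaults; `delta_g_backward` defaults to
#' `delta_g_forward - delta_h` (or the forward barrier when `delta_h` is
#' absent, i.e. a thermoneutral assumption).
#'
#' @param edges data frame with at least `from`, `to`, `delta_g_forward`;
#'   optional `delta_h`, `delta_g_backward`, `ers_label`, `co_products`.
#' @param seed_keys node keys flagged as seeds (default: none).
#' @return a `reaction_network`.
#' @export
#' @examples
#' toy <- as_reaction_network(tibble::tibble(
#'   from = "S", to = "T", delta_g_forward = 40))
#' minimax_pathway(toy, "S", "T")$bottleneck
as_reaction_network <- function(edges, seed_keys = character()) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("from", "to", "delta_g_forward") %in% names(edges)))
  has <- function(col) col %in% names(edges)
  if (!has("delta_h")) edges$delta_h <- 0
  if (!has("delta_g_backward")) {
    edges$delta_g_backward <- edges$delta_g_forward -
      ifelse(is.na(edges$delta_h), 0, edges$delta_h)
  }
  if (!has("ers_label")) edges$ers_label <- "b2f2"
  if (!has("co_products")) edges$co_products <- ""
  if (!has("best_delta_g")) edges$best_delta_g <- edges$delta_g_forward
  if (!has("range_delta_g")) edges$range_delta_g <- NA_real_
  if (!has("n_intended")) edges$n_intended <- 1L
  if (!has("source")) edges$source <- "intended"
  keys <- sort(unique(c(edges$from, edges$to,
                        unlist(strsplit(edges$co_products[nzchar(edges$co_products)],
                                        " + ", fixed = TRUE)))))
  nodes <- tibble::tibble(key = keys, formula = NA_character_,
                          smiles = NA_character_, seed = keys %in% seed_keys,
                          explored = FALSE, excluded_reason = NA_character_)
  structure(list(nodes = nodes, edges = edges[, names(.empty_edges())],
                 records = .empty_records(), graphs = list(),
                 stage_counts = tibble::tibble(), config = NULL),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> %d nodes, %d edges (%d intended, %d mined), %d records\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$source == "intended"),
              sum(x$edges$source == "mined"), nrow(x$records)))
  invisible(x)
}
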