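# Elementary-reaction-step (bNfM) product enumeration. An ERS removes
# n_break bond-order units and adds n_form units; candidates whose product
# satisfies the closed-shell valence condition are kept and deduplicated by
# the canonical key of the product species set. b2f2 is the workhorse step;
# b3f3 covers concerted multi-bond rearrangements.

#' Specify an elementary reaction step class
#'
#' @param n_break number of bond-order units to remove (>= 1).
#' @param n_form number of bond-order units to add (>= 1).
#' @param intermolecular_required bimolecular mode: require at least one
#'   formed unit to join atoms of different input fragments, and drop
#'   candidates whose change set touches a single fragment only.
#' @param exclude_identity drop candidates whose product species set has the
#'   same canonical key as the reactants (default TRUE). Degenerate
#'   rearrangements that regenerate the reactant graph are excluded under
#'   this flag; turn it off to count every distinct enumerated product graph
#'   including the reactant itself.
#' @param constraint optional predicate `function(broken, formed)` applied to
#'   each minimal change set; candidates failing it are dropped. Used for
#'   constrained step classes such as cyclic b3f3 (see [cyclic_constraint()]).
#' @return an object of class `ers_spec`.
#' @export
#' @examples
#' ers_spec()            # b2f2
#' ers_spec(3, 3)        # b3f3
ers_spec <- function(n_break = 2L, n_form = 2L, intermolecular_required = FALSE,
                     exclude_identity = TRUE, constraint = NULL) {
  n_break <- as.integer(n_break)
  n_form <- as.integer(n_form)
  stopifnot(n_break >= 1L, n_form >= 1L)
  structure(list(n_break = n_break, n_form = n_form,
                 intermolecular_required = isTRUE(intermolecular_required),
                 exclude_identity = isTRUE(exclude_identity),
                 constraint = constraint),
            class = "ers_spec")
}

#' @export
print.ers_spec <- function(x, ...) {
  cat(sprintf("<ers_spec> b%df%d%s%s%s\n", x$n_break, x$n_form,
              if (x$intermolecular_required) " (intermolecular required)" else "",
              if (!x$exclude_identity) " (identity retained)" else "",
              if (!is.null(x$constraint)) " (constrained)" else ""))
  invisible(x)
}

#' Constraint for the cyclic-b3f3 step class
#'
#' Returns a predicate requiring the break/form units to form a single closed
#' alternating cycle (every atom touched by the change set has equal broken
#' and formed incidence and the change set is connected). This is a
#' provisional reading of the constrained b3f3 class; counts derived from it
#' should be treated as indicative only.
#'
#' @return a function usable as the `constraint` of [ers_spec()].
#' @export
cyclic_constraint <- function() {
  function(broken, formed) {
    units <- rbind(broken, formed)
    if (!nrow(units)) return(FALSE)
    atoms <- sort(unique(as.vector(units)))
    inc_b <- table(factor(as.vector(broken), levels = atoms))
    inc_f <- table(factor(as.vector(formed), levels = atoms))
    if (!all(inc_b == inc_f)) return(FALSE)
    # connectivity of the change multigraph
    adj <- lapply(atoms, function(a) {
      hits <- units[, 1] == a | units[, 2] == a
      setdiff(unique(as.vector(units[hits, , drop = FALSE])), a)
    })
    names(adj) <- as.character(atoms)
    seen <- atoms[1]
    queue <- atoms[1]
    while (length(queue)) {
      a <- queue[[1]]; queue <- queue[-1]
      nb <- setdiff(adj[[as.character(a)]], seen)
      seen <- c(seen, nb)
      queue <- c(queue, nb)
    }
    length(seen) == length(atoms)
  }
}

#' Minimal bNfM label of a change set
#'
#' Cancels units that appear in both the broken and formed lists (breaking
#' and re-forming the same pair is not a net change) and labels the remainder
#' `b{n}f{m}`.
#'
#' @param broken,formed integer unit matrices (columns `i`, `j`) as in
#'   [graph_diff()].
#' @return character label such as `"b2f2"`; `"b0f0"` for a no-op.
#' @export
classify_ers <- function(broken, formed) {
  key <- function(m) {
    if (!nrow(m)) return(character())
    paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]), sep = "-")
  }
  kb <- key(broken)
  kf <- key(formed)
  for (u in unique(kb)) {
    k <- min(sum(kb == u), sum(kf == u))
    if (k > 0) {
      kb <- kb[-which(kb == u)[seq_len(k)]]
      kf <- kf[-which(kf == u)[seq_len(k)]]
    }
  }
  sprintf("b%df%d", length(kb), length(kf))
}

# Multisets of `size` units over rows of `bl` (bond list), multiplicity
# capped by bond order. Returns list of integer index-count pairs.
.break_multisets <- function(bl, size) {
  out <- list()
  nb <- nrow(bl)
  recurse <- function(start, left, acc) {
    if (left == 0) {
      out[[length(out) + 1]] <<- acc
      return()
    }
    if (start > nb) return()
    for (b in start:nb) {
      cap <- min(bl[b, 3], left)
      for (k in seq_len(cap)) {
        recurse(b + 1, left - k, c(acc, rep(b, k)))
      }
    }
  }
  if (nb > 0) recurse(1, size, integer(0))
  out
}

# Multisets of `size` formed units over candidate atom pairs, with per-atom
# capacity caps. pairs: 2-col matrix; cap: named capacity per atom.
.form_multisets <- function(pairs, size, cap) {
  out <- list()
  np <- nrow(pairs)
  if (np == 0) return(out)
  recurse <- function(start, left, acc, cap) {
    if (left == 0) {
      out[[length(out) + 1]] <<- acc
      return()
    }
    if (start > np) return()
    for (p in start:np) {
      i <- pairs[p, 1]; j <- pairs[p, 2]
      kmax <- min(left, cap[[as.character(i)]], cap[[as.character(j)]])
      if (kmax < 1) next
      for (k in seq_len(kmax)) {
        cap2 <- cap
        cap2[[as.character(i)]] <- cap2[[as.character(i)]] - k
        cap2[[as.character(j)]] <- cap2[[as.character(j)]] - k
        recurse(p + 1, left - k, c(acc, rep(p, k)), cap2)
      }
    }
  }
  recurse(1, size, integer(0), cap)
  out
}

#' Enumerate elementary-reaction-step product candidates
#'
#' Exhaustively applies the bNfM step class of `spec` to one reactant graph
#' (or the disjoint union of two, for bimolecular enumeration): every
#' multiset of `n_break` removable bond units is combined with every multiset
#' of `n_form` formed units that returns all atoms to an allowed valence.
#' Valence-valid, non-identity products are kept and deduplicated by the
#' canonical key of the product species set (first-found change set retained
#' as representative); output rows are sorted by product key.
#'
#' @param reactants a `molgraph`, or a list of one or two `molgraph` objects
#'   (two graphs trigger bimolecular enumeration on their disjoint union).
#' @param spec an [ers_spec()].
#' @return a tibble with one row per candidate: `reactant_key`,
#'   `product_key`, `ers_label`, `product_smiles`, `n_products`, `delta_h`
#'   (NA until estimated), and list-columns `broken`, `formed`,
#'   `product_graph`. The combined reactant graph is attached as the
#'   `reactant_graph` attribute.
#' @export
#' @examples
#' enumerate_candidates(parse_smiles("CC"), ers_spec()) # ethane -> ethene + H2
enumerate_candidates <- function(reactants, spec = ers_spec()) {
  if (inherits(reactants, "molgraph")) reactants <- list(reactants)
  stopifnot(length(reactants) %in% c(1L, 2L))
  if (length(reactants) == 2) {
    graph <- graph_union(reactants[[1]], reactants[[2]])
  } else {
    graph <- reactants[[1]]
    if (is.null(attr(graph, "fragment"))) {
      attr(graph, "fragment") <- rep(1L, n_atoms(graph))
    }
  }
  if (!valence_valid(graph)) .stop2("reactant graph is not valence-valid")
  frag <- attr(graph, "fragment")
  rkey <- canonical_key(graph)
  n <- n_atoms(graph)
  els <- graph$elements
  maxval <- vapply(els, function(e) max(.ALLOWED_VALENCES[[e]]), integer(1))
  bl <- bond_list(graph)

  hits <- new.env(parent = emptyenv())
  rows <- list()

  for (bm in .break_multisets(bl, spec$n_break)) {
    broken <- bl[bm, 1:2, drop = FALSE]
    bonds2 <- graph$bonds
    for (r in seq_len(nrow(broken))) {
      i <- broken[r, 1]; j <- broken[r, 2]
      bonds2[i, j] <- bonds2[i, j] - 1L
      bonds2[j, i] <- bonds2[i, j]
    }
    v2 <- as.integer(rowSums(bonds2))
    # atoms that can still accept bond units
    open <- which(v2 < maxval)
    if (length(open) < 2) next
    pairs <- t(utils::combn(open, 2))
    # order cap: no bond beyond triple
    keep <- bonds2[pairs] < 3L
    pairs <- pairs[keep, , drop = FALSE]
    if (!nrow(pairs)) next
    cap <- as.list(maxval[open] - v2[open])
    names(cap) <- as.character(open)
    for (fm in .form_multisets(pairs, spec$n_form, cap)) {
      formed <- pairs[fm, , drop = FALSE]
      bonds3 <- bonds2
      bad_order <- FALSE
      for (r in seq_len(nrow(formed))) {
        i <- formed[r, 1]; j <- formed[r, 2]
        bonds3[i, j] <- bonds3[i, j] + 1L
        if (bonds3[i, j] > 3L) { bad_order <- TRUE; break }
        bonds3[j, i] <- bonds3[i, j]
      }
      if (bad_order) next
      v3 <- as.integer(rowSums(bonds3))
      ok <- TRUE
      for (a in unique(c(as.vector(broken), as.vector(formed)))) {
        if (!(v3[a] %in% .ALLOWED_VALENCES[[els[a]]])) { ok <- FALSE; break }
      }
      if (!ok) next
      colnames(broken) <- colnames(formed) <- c("i", "j")
      # minimal change set (cancel break+form of the same pair)
      product <- molgraph(els, bonds3, label = "", check = FALSE)
      diff <- graph_diff(graph, product)
      if (spec$intermolecular_required && length(unique(frag)) > 1) {
        touched <- unique(frag[unique(c(as.vector(diff$broken), as.vector(diff$formed)))])
        inter_formed <- nrow(diff$formed) > 0 &&
          any(frag[diff$formed[, 1]] != frag[diff$formed[, 2]])
        if (length(touched) < 2 || !inter_formed) next
      }
      if (!is.null(spec$constraint) && !spec$constraint(diff$broken, diff$formed)) next
      pkey <- canonical_key(product)
      if (spec$exclude_identity && pkey == rkey) next
      n_units <- nrow(diff$broken) + nrow(diff$formed)
      prev <- hits[[pkey]]
      if (!is.null(prev)) {
        # keep the representative with the minimal change set, so the bNfM
        # label of a product is its smallest discovered step class
        prev_units <- nrow(rows[[prev]]$broken[[1]]) + nrow(rows[[prev]]$formed[[1]])
        if (n_units >= prev_units) next
      }
      comps <- split_components(product)
      row <- tibble::tibble(
        reactant_key = rkey,
        product_key = pkey,
        ers_label = classify_ers(diff$broken, diff$formed),
        product_smiles = to_smiles(product),
        n_products = length(comps),
        delta_h = NA_real_,
        broken = list(diff$broken),
        formed = list(diff$formed),
        product_graph = list(product)
      )
      if (!is.null(prev)) {
        rows[[prev]] <- row
      } else {
        rows[[length(rows) + 1]] <- row
        hits[[pkey]] <- length(rows)
      }
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
    reactant_key = character(), product_key = character(),
    ers_label = character(), product_smiles = character(),
    n_products = integer(), delta_h = numeric(),
    broken = list(), formed = list(), product_graph = list()
  )
  out <- dplyr::arrange(out, .data$product_key)
  attr(out, "reactant_graph") <- graph
  out
}

#' Count distinct enumerated product graphs
#'
#' The enumeration-stage product count: the number of distinct product
#' species sets reachable by the step class, counting the reactant graph
#' itself when degenerate rearrangement channels regenerate it. This is the
#' quantity conventionally reported as "distinct enumerated products" for a
#' reactant; reaction-level identity exclusion happens later in the pipeline.
#'
#' @param reactants as in [enumerate_candidates()].
#' @param spec an [ers_spec()]; its `exclude_identity` flag is ignored here.
#' @return integer count of distinct product keys.
#' @export
#' @examples
#' \donttest{
#' count_enumerated_products(parse_smiles("OCC(O)C(O)C(O)C(O)C=O")) # 264
#' }
count_enumerated_products <- function(reactants, spec = ers_spec()) {
  spec$exclude_identity <- FALSE
  nrow(enumerate_candidates(reactants, spec))
}
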