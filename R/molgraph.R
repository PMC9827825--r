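# Molecular-graph data model: atoms plus a symmetric integer bond-order
# matrix. Only neutral closed-shell species are representable: every atom's
# total bond order must sit in its element's allowed-valence list, so charges
# and radicals are excluded by construction.

# Allowed total bond orders per supported element. S and P are polyvalent.
.ALLOWED_VALENCES <- list(
  H = 1L,
  C = 4L,
  N = 3L,
  O = 2L,
  S = c(2L, 4L, 6L),
  P = c(3L, 5L)
)

#' Allowed valences for the supported elements
#'
#' The package models neutral closed-shell molecules over H, C, N, O, S and P.
#' Each element has a fixed list of permitted total bond orders; sulfur and
#' phosphorus are polyvalent (hypervalent states are legal).
#'
#' @param element optional element symbol; if given, returns that element's
#'   allowed valences, otherwise the full named list.
#' @return integer vector or named list of integer vectors.
#' @export
#' @examples
#' allowed_valences("S")
allowed_valences <- function(element = NULL) {
  if (is.null(element)) return(.ALLOWED_VALENCES)
  v <- .ALLOWED_VALENCES[[element]]
  if (is.null(v)) .stop2("unsupported element: ", element)
  v
}

#' Construct a molecular graph
#'
#' A `molgraph` is a list of atoms (element symbols) together with a symmetric
#' non-negative integer bond-order matrix with zero diagonal. The graph may be
#' disconnected (a species set); [split_components()] separates it.
#'
#' @param elements character vector of element symbols (H, C, N, O, S, P).
#' @param bonds symmetric integer matrix of bond orders, zero diagonal.
#' @param label free-text provenance label.
#' @param check validate symmetry/diagonal and element support (default TRUE).
#' @return an object of class `molgraph`.
#' @export
#' @examples
#' h2 <- molgraph(c("H", "H"), matrix(c(0L, 1L, 1L, 0L), 2))
#' valence_valid(h2)
molgraph <- function(elements, bonds, label = "", check = TRUE) {
  elements <- as.character(elements)
  n <- length(elements)
  bonds <- matrix(as.integer(bonds), n, n)
  if (check) {
    bad <- setdiff(unique(elements), names(.ALLOWED_VALENCES))
    if (length(bad)) .stop2("unsupported element(s): ", paste(bad, collapse = ", "))
    if (n > 0) {
      if (!isTRUE(all.equal(bonds, t(bonds)))) .stop2("bond matrix must be symmetric")
      if (any(diag(bonds) != 0L)) .stop2("bond matrix must have zero diagonal")
      if (any(bonds < 0L)) .stop2("bond orders must be non-negative")
    }
  }
  structure(list(elements = elements, bonds = bonds, label = label),
            class = "molgraph")
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph> %s (%d atoms, %d bonds)%s\n",
              molecular_formula(x), n_atoms(x), nrow(bond_list(x)),
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' Number of atoms in a molecular graph
#' @param graph a `molgraph`.
#' @return integer atom count.
#' @export
n_atoms <- function(graph) length(graph$elements)

#' Number of heavy (non-hydrogen) atoms
#' @param graph a `molgraph`.
#' @return integer count of non-H atoms.
#' @export
n_heavy_atoms <- function(graph) sum(graph$elements != "H")

#' Total bond order (valence) of every atom
#' @param graph a `molgraph`.
#' @return integer vector of per-atom total bond orders.
#' @export
atom_valences <- function(graph) {
  if (n_atoms(graph) == 0) return(integer())
  as.integer(rowSums(graph$bonds))
}

#' Is every atom at an allowed valence?
#'
#' The closed-shell condition: each atom's total bond order must be a member
#' of its element's allowed-valence list.
#'
#' @param graph a `molgraph`.
#' @return logical scalar.
#' @export
valence_valid <- function(graph) {
  v <- atom_valences(graph)
  all(vapply(seq_along(v), function(i) {
    v[i] %in% .ALLOWED_VALENCES[[graph$elements[i]]]
  }, logical(1)))
}

#' List the bonds of a graph
#'
#' @param graph a `molgraph`.
#' @return integer matrix with columns `i`, `j`, `order` (i < j), one row per
#'   bonded pair, ordered by (i, j).
#' @export
bond_list <- function(graph) {
  n <- n_atoms(graph)
  if (n < 2) return(matrix(integer(), 0, 3, dimnames = list(NULL, c("i", "j", "order"))))
  idx <- which(upper.tri(graph$bonds) & graph$bonds > 0, arr.ind = TRUE)
  out <- cbind(i = idx[, 1], j = idx[, 2], order = graph$bonds[idx])
  out <- out[order(out[, 1], out[, 2]), , drop = FALSE]
  storage.mode(out) <- "integer"
  out
}

#' Molecular formula in Hill order
#'
#' @param graph a `molgraph`.
#' @return character scalar, e.g. `"C6H12O6"`.
#' @export
molecular_formula <- function(graph) {
  tab <- table(graph$elements)
  els <- names(tab)
  hill <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(vapply(hill, function(e) {
    k <- tab[[e]]
    if (k == 1) e else paste0(e, k)
  }, character(1)), collapse = "")
}

#' Split a graph into connected components
#'
#' A disconnected `molgraph` represents a set of species (for example the
#' products acetaldehyde + formic acid of a fragmentation). Atom count is
#' conserved: the component atom counts sum to the input's.
#'
#' @param graph a `molgraph`.
#' @return list of connected `molgraph` objects, each with an `atom_map`
#'   attribute giving the original atom indices.
#' @export
split_components <- function(graph) {
  n <- n_atoms(graph)
  if (n == 0) return(list())
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      a <- queue[[1]]
      queue <- queue[-1]
      nb <- which(graph$bonds[a, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  lapply(seq_len(cur), function(k) {
    keep <- which(comp == k)
    g <- molgraph(graph$elements[keep],
                  graph$bonds[keep, keep, drop = FALSE],
                  label = graph$label, check = FALSE)
    attr(g, "atom_map") <- keep
    g
  })
}

#' Disjoint union of two molecular graphs
#'
#' Used to set up bimolecular enumeration: the two reactants become one
#' (disconnected) graph and a fragment id records which input each atom came
#' from.
#'
#' @param a,b `molgraph` objects.
#' @return a `molgraph` with a `fragment` attribute (integer vector of 1/2).
#' @export
graph_union <- function(a, b) {
  na <- n_atoms(a); nb <- n_atoms(b)
  bonds <- matrix(0L, na + nb, na + nb)
  bonds[seq_len(na), seq_len(na)] <- a$bonds
  bonds[na + seq_len(nb), na + seq_len(nb)] <- b$bonds
  g <- molgraph(c(a$elements, b$elements), bonds,
                label = paste(a$label, b$label, sep = "+"), check = FALSE)
  attr(g, "fragment") <- rep(c(1L, 2L), c(na, nb))
  g
}

#' Bond-change difference between two graphs on the same atoms
#'
#' Computes the multiset of bond-order units present in `a` but not `b`
#' (`broken`) and the converse (`formed`), under an atom correspondence.
#' Applying the result to `a` with [apply_bond_changes()] reproduces `b`
#' exactly. A unit is one step of integer bond order, so breaking the pi bond
#' of an alkene is one broken unit.
#'
#' @param a,b `molgraph` objects with the same number of atoms.
#' @param mapping integer vector: `mapping[i]` is the atom of `b` matched to
#'   atom `i` of `a` (default identity).
#' @return list with integer matrices `broken` and `formed` (columns `i`,
#'   `j`), one row per unit, indexed in `a`'s atom numbering.
#' @export
#' @examples
#' ethane <- parse_smiles("CC")
#' d <- graph_diff(ethane, ethane)
#' nrow(d$broken) # 0
graph_diff <- function(a, b, mapping = seq_len(n_atoms(a))) {
  if (n_atoms(a) != n_atoms(b)) .stop2("graphs differ in atom count")
  if (!identical(a$elements, b$elements[mapping])) {
    .stop2("element mismatch under the given atom mapping")
  }
  delta <- b$bonds[mapping, mapping, drop = FALSE] - a$bonds
  unit_rows <- function(sel) {
    idx <- which(upper.tri(delta) & sel, arr.ind = TRUE)
    if (!nrow(idx)) {
      return(matrix(integer(), 0, 2, dimnames = list(NULL, c("i", "j"))))
    }
    reps <- abs(delta[idx])
    out <- idx[rep(seq_len(nrow(idx)), reps), , drop = FALSE]
    colnames(out) <- c("i", "j")
    storage.mode(out) <- "integer"
    out[order(out[, 1], out[, 2]), , drop = FALSE]
  }
  list(broken = unit_rows(delta < 0), formed = unit_rows(delta > 0))
}

#' Apply a bond-change set to a graph
#'
#' Decrements one bond-order unit per row of `changes$broken` and increments
#' one per row of `changes$formed`, then reports whether the result satisfies
#' the closed-shell valence condition.
#'
#' @param graph a `molgraph`.
#' @param changes list with `broken` and `formed` unit matrices as produced by
#'   [graph_diff()].
#' @return list with elements `graph` (the updated `molgraph`) and `valid`
#'   (logical: valence-valid result).
#' @export
apply_bond_changes <- function(graph, changes) {
  bonds <- graph$bonds
  br <- changes$broken
  fm <- changes$formed
  if (nrow(br)) {
    for (r in seq_len(nrow(br))) {
      i <- br[r, 1]; j <- br[r, 2]
      if (bonds[i, j] < 1L) {
        .stop2(sprintf("cannot break a bond unit between atoms %d and %d: no bond left", i, j))
      }
      bonds[i, j] <- bonds[i, j] - 1L
      bonds[j, i] <- bonds[i, j]
    }
  }
  if (nrow(fm)) {
    for (r in seq_len(nrow(fm))) {
      i <- fm[r, 1]; j <- fm[r, 2]
      if (i == j) .stop2("cannot form a bond from an atom to itself")
      bonds[i, j] <- bonds[i, j] + 1L
      bonds[j, i] <- bonds[i, j]
    }
  }
  out <- molgraph(graph$elements, bonds, label = graph$label, check = FALSE)
  list(graph = out, valid = valence_valid(out))
}
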