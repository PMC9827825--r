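# SMILES-subset reader/writer. The accepted dialect is deliberately narrow:
# Kekule structures over H, C, N, O, S, P with single/double/triple bonds,
# branches and ring-closure digits. No aromatic lowercase, charges, isotopes,
# stereo descriptors or radical centres -- those species are outside the
# neutral closed-shell scope of the graph model.

#' Parse a SMILES-subset string into a molecular graph
#'
#' Supports the elements H, C, N, O, S, P; bond symbols `-`, `=`, `#`;
#' branches `(...)`; ring-closure digits `1`-`9`; dot-separated fragments;
#' and bracket atoms with an optional hydrogen count (`[H]`, `[SH2]`). Input
#' must be Kekule (no aromatic lowercase) with no charges or stereochemistry.
#' Implicit hydrogens are added to every non-bracket atom to reach the lowest
#' allowed valence not below its explicit bond count; bracket atoms get
#' exactly the hydrogen count they declare.
#'
#' @param text a single SMILES-subset string.
#' @param label provenance label stored on the graph (defaults to `text`).
#' @return a valence-valid `molgraph` with all hydrogens explicit.
#' @export
#' @examples
#' parse_smiles("CC(=O)C")           # propan-2-one
#' molecular_formula(parse_smiles("OCC(O)C(O)C(O)C(O)C=O")) # "C6H12O6"
parse_smiles <- function(text, label = text) {
  stopifnot(is.character(text), length(text) == 1)
  chars <- strsplit(text, "")[[1]]
  elements <- character(0)
  fixed_h <- integer(0) # -1 = implicit completion; >= 0 = declared H count
  bonds <- list() # list of c(i, j, order)
  stack <- integer(0) # open-branch anchors
  prev <- NA_integer_
  pending <- 1L
  rings <- list() # digit -> c(atom, order)
  i <- 1
  add_atom <- function(sym, h_count) {
    if (!sym %in% names(.ALLOWED_VALENCES)) {
      .stop2("unsupported element token in SMILES: '", sym, "'")
    }
    elements[[length(elements) + 1]] <<- sym
    fixed_h[[length(fixed_h) + 1]] <<- h_count
    idx <- length(elements)
    if (!is.na(prev)) bonds[[length(bonds) + 1]] <<- c(prev, idx, pending)
    prev <<- idx
    pending <<- 1L
  }
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% c("H", "C", "N", "O", "S", "P")) {
      add_atom(ch, -1L)
    } else if (ch == "[") {
      j <- i + 1
      body <- ""
      while (j <= length(chars) && chars[j] != "]") {
        body <- paste0(body, chars[j])
        j <- j + 1
      }
      if (j > length(chars)) .stop2("unterminated bracket atom in SMILES")
      m <- regmatches(body, regexec("^([A-Z])(H([0-9]?))?$", body))[[1]]
      if (!length(m)) {
        .stop2("unsupported bracket-atom token (charge/stereo/isotope?): '[", body, "]'")
      }
      h_count <- if (m[3] == "") 0L else if (m[4] == "") 1L else as.integer(m[4])
      if (m[2] == "H" && m[3] != "") .stop2("unsupported bracket-atom token: '[", body, "]'")
      add_atom(m[2], h_count)
      i <- j
    } else if (ch == "-") {
      pending <- 1L
    } else if (ch == "=") {
      pending <- 2L
    } else if (ch == "#") {
      pending <- 3L
    } else if (ch == "(") {
      if (is.na(prev)) .stop2("branch with no preceding atom in SMILES")
      stack <- c(stack, prev)
    } else if (ch == ")") {
      if (!length(stack)) .stop2("unbalanced ')' in SMILES")
      prev <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
    } else if (grepl("[1-9]", ch)) {
      if (is.na(prev)) .stop2("ring-closure digit with no preceding atom")
      if (is.null(rings[[ch]])) {
        rings[[ch]] <- c(prev, pending)
      } else {
        open <- rings[[ch]]
        ord <- max(open[2], pending) # bond symbol may sit on either end
        bonds[[length(bonds) + 1]] <- c(open[1], prev, ord)
        rings[[ch]] <- NULL
      }
      pending <- 1L
    } else if (ch == ".") {
      prev <- NA_integer_
      pending <- 1L
    } else {
      .stop2("unsupported SMILES token: '", ch, "'")
    }
    i <- i + 1
  }
  if (length(stack)) .stop2("unbalanced '(' in SMILES")
  if (length(Filter(Negate(is.null), rings))) .stop2("unclosed ring bond in SMILES")

  n <- length(elements)
  mat <- matrix(0L, n, n)
  for (b in bonds) {
    if (b[1] == b[2]) .stop2("self-bond in SMILES")
    mat[b[1], b[2]] <- mat[b[1], b[2]] + as.integer(b[3])
    mat[b[2], b[1]] <- mat[b[1], b[2]]
  }

  # hydrogen completion: implicit atoms to lowest allowed valence, bracket
  # atoms to their declared count
  deg <- if (n > 0) as.integer(rowSums(mat)) else integer()
  n_h <- integer(n)
  for (a in seq_len(n)) {
    if (fixed_h[a] >= 0L) {
      n_h[a] <- fixed_h[a]
      next
    }
    av <- .ALLOWED_VALENCES[[elements[a]]]
    tgt <- av[av >= deg[a]]
    if (!length(tgt)) {
      .stop2(sprintf("valence unsatisfiable for atom %d (%s, explicit bond order %d)",
                     a, elements[a], deg[a]))
    }
    n_h[a] <- min(tgt) - deg[a]
  }
  tot_h <- sum(n_h)
  if (tot_h > 0) {
    big <- matrix(0L, n + tot_h, n + tot_h)
    big[seq_len(n), seq_len(n)] <- mat
    h <- n
    for (a in seq_len(n)) {
      k <- n_h[a]
      while (k > 0) {
        h <- h + 1L
        big[a, h] <- 1L
        big[h, a] <- 1L
        k <- k - 1L
      }
    }
    mat <- big
    elements <- c(elements, rep("H", tot_h))
  }
  g <- molgraph(elements, mat, label = label)
  if (!valence_valid(g)) {
    v <- atom_valences(g)
    bad <- which(!vapply(seq_along(v), function(k) {
      v[k] %in% .ALLOWED_VALENCES[[elements[k]]]
    }, logical(1)))
    .stop2("valence error: atom(s) ", paste(bad, collapse = ", "),
           " (", paste(elements[bad], collapse = ", "), ") not at an allowed valence")
  }
  g
}

#' Write a molecular graph as a SMILES-subset string
#'
#' Hydrogens bonded to heavy atoms are suppressed where implicit-H completion
#' recovers them, otherwise written as a bracket H count; hydrogen-only
#' fragments use bracket atoms (`[H][H]`). Disconnected components are joined
#' with `.`. The output round-trips through [parse_smiles()] to an isomorphic
#' graph; it is deterministic in the atom order but not canonical (use
#' [canonical_key()] for identity).
#'
#' @param graph a `molgraph`.
#' @return character SMILES-subset string.
#' @export
#' @examples
#' to_smiles(parse_smiles("C=C"))
to_smiles <- function(graph) {
  comps <- split_components(graph)
  paste(vapply(comps, .component_smiles, character(1)), collapse = ".")
}

.component_smiles <- function(g) {
  n <- n_atoms(g)
  heavy <- which(g$elements != "H")
  if (!length(heavy)) {
    return(paste(rep("[H]", n), collapse = ""))
  }
  suppress <- g$elements == "H" & vapply(seq_len(n), function(a) {
    nb <- which(g$bonds[a, ] > 0)
    length(nb) == 1 && g$elements[nb] != "H"
  }, logical(1))
  keep <- which(!suppress)
  sub <- g$bonds[keep, keep, drop = FALSE]
  els <- g$elements[keep]
  m <- length(keep)
  order_sym <- function(o) c("", "=", "#")[o]

  # spanning tree + back edges by deterministic DFS
  seen <- logical(m)
  parent <- rep(NA_integer_, m)
  tree <- matrix(FALSE, m, m)
  stack <- list(1L)
  seen[1] <- TRUE
  while (length(stack)) {
    a <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    for (b in rev(which(sub[a, ] > 0))) {
      if (!seen[b]) {
        seen[b] <- TRUE
        parent[b] <- a
        tree[a, b] <- tree[b, a] <- TRUE
        stack <- c(stack, list(b))
      }
    }
  }
  is_back <- sub > 0 & !tree
  be <- which(upper.tri(is_back) & is_back, arr.ind = TRUE)
  digits_at <- vector("list", m)
  if (nrow(be)) {
    if (nrow(be) > 9) .stop2("SMILES writer supports at most 9 ring closures per component")
    for (r in seq_len(nrow(be))) {
      i <- be[r, 1]; j <- be[r, 2]
      digits_at[[i]] <- c(digits_at[[i]], list(c(j, sub[i, j], r)))
      digits_at[[j]] <- c(digits_at[[j]], list(c(i, sub[i, j], r)))
    }
  }

  atom_token <- function(a) {
    nh <- sum(g$bonds[keep[a], ] > 0 & suppress)
    el <- els[a]
    expl <- sum(sub[a, ])
    av <- .ALLOWED_VALENCES[[el]]
    cand <- av[av >= expl]
    default_h <- if (length(cand)) min(cand) - expl else -1L
    if (el != "H" && default_h == nh) {
      el
    } else if (nh == 0) {
      paste0("[", el, "]")
    } else {
      paste0("[", el, "H", if (nh > 1) nh else "", "]")
    }
  }

  written <- logical(m)
  write_atom <- function(a, incoming_order) {
    out <- character(0)
    if (incoming_order > 1) out <- c(out, order_sym(incoming_order))
    out <- c(out, atom_token(a))
    written[a] <<- TRUE
    for (d in digits_at[[a]]) {
      out <- c(out, if (d[2] > 1 && !written[d[1]]) order_sym(d[2]) else "",
               as.character(d[3]))
    }
    kids <- sort(which(tree[a, ] & !written))
    for (k in seq_along(kids)) {
      b <- kids[k]
      body <- write_atom(b, sub[a, b])
      out <- if (k < length(kids)) c(out, "(", body, ")") else c(out, body)
    }
    paste(out, collapse = "")
  }
  write_atom(1L, 1L)
}
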