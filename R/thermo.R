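# Heat-of-reaction estimation behind a pluggable thermochemistry interface.
# The packaged estimator is a bond-increment model over standard mean bond
# energies: breaking a unit of bond order costs the per-unit increment for
# that element pair and order, forming one releases it. It is a coarse
# surrogate for a proper component-increment or quantum thermochemistry
# backend, adequate for exercising the enthalpy pre-pruning stage.

#' Load a bond-increment energy table
#'
#' The table maps (element pair, bond order) to the mean energy of that
#' bond-order *unit* in kJ/mol: entry (C, C, 2) is the increment from a
#' single to a double carbon-carbon bond, not the full double-bond energy.
#' The packaged default covers all element pairs over H, C, N, O, S, P that
#' occur in the shipped fixture molecules.
#'
#' @param path CSV file with columns `elem1,elem2,order,energy_kJ`; `NULL`
#'   loads the packaged default table.
#' @return a tibble of class `bond_increment_table`.
#' @export
bond_increment_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "bond_energies.csv", package = "ersnet",
                        mustWork = TRUE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("elem1", "elem2", "order", "energy_kJ")
  if (!all(need %in% names(tab))) {
    .stop2("bond table must have columns ", paste(need, collapse = ", "))
  }
  if (any(tab$energy_kJ <= 0)) .stop2("bond energies must be positive")
  tab <- tibble::as_tibble(tab)
  attr(tab, "source") <- path
  class(tab) <- c("bond_increment_table", class(tab))
  tab
}

.bond_energy_lookup <- function(table) {
  env <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(table))) {
    pair <- sort(c(table$elem1[r], table$elem2[r]))
    env[[paste(pair[1], pair[2], table$order[r], sep = ":")]] <- table$energy_kJ[r]
  }
  env
}

# Energy (kJ/mol) of the bond units in `units` (2-col atom-index matrix)
# taken from graph `g`, where each repeated pair consumes successive order
# levels starting from the order in `g` and going down (breaking) or from
# order+1 going up (forming).
.units_energy <- function(units, g, lookup, direction = c("break", "form")) {
  direction <- match.arg(direction)
  if (!nrow(units)) return(0)
  key <- paste(pmin(units[, 1], units[, 2]), pmax(units[, 1], units[, 2]))
  total <- 0
  for (u in unique(key)) {
    rows <- which(key == u)
    i <- units[rows[1], 1]; j <- units[rows[1], 2]
    m <- length(rows)
    base <- g$bonds[i, j]
    orders <- if (direction == "break") base - seq_len(m) + 1L else base + seq_len(m)
    pair <- sort(c(g$elements[i], g$elements[j]))
    for (o in orders) {
      e <- lookup[[paste(pair[1], pair[2], o, sep = ":")]]
      if (is.null(e)) {
        .stop2(sprintf("no bond-increment energy for %s-%s order %d",
                       pair[1], pair[2], o))
      }
      total <- total + e
    }
  }
  total
}

#' Estimate heats of reaction for enumerated candidates
#'
#' Bond-increment estimate: `dH = sum(E(broken units)) - sum(E(formed
#' units))`, evaluated in kJ/mol against the table and stored on the
#' candidates in kcal/mol (1 kcal = 4.184 kJ). Positive values are
#' endothermic.
#'
#' @param candidates tibble from [enumerate_candidates()] (must carry the
#'   `reactant_graph` attribute).
#' @param table a [bond_increment_table()].
#' @return the candidates with the `delta_h` column filled (kcal/mol).
#' @export
estimate_reaction_enthalpy <- function(candidates, table = bond_increment_table()) {
  graph <- attr(candidates, "reactant_graph")
  if (is.null(graph)) .stop2("candidates are missing the reactant_graph attribute")
  lookup <- .bond_energy_lookup(table)
  dh <- vapply(seq_len(nrow(candidates)), function(r) {
    e_break <- .units_energy(candidates$broken[[r]], graph, lookup, "break")
    # formed units are indexed against the product: their final orders are in
    # the product graph; equivalently, form from the post-break graph upward
    g_broken <- apply_bond_changes(graph, list(broken = candidates$broken[[r]],
                                               formed = matrix(integer(), 0, 2)))$graph
    e_form <- .units_energy(candidates$formed[[r]], g_broken, lookup, "form")
    (e_break - e_form) * KCAL_PER_KJ
  }, numeric(1))
  candidates$delta_h <- dh
  candidates
}

#' Filter candidates by an enthalpy threshold
#'
#' Retains candidates whose estimated heat of reaction does not exceed the
#' threshold (an endothermicity cap: every exothermic candidate passes).
#' Order is preserved.
#'
#' @param candidates candidate tibble with `delta_h` filled (kcal/mol).
#' @param threshold cap on `delta_h`.
#' @param unit `"kcal"` (default) or `"kJ"` for the threshold's unit.
#' @return the retained candidates, with a `n_dropped` attribute.
#' @export
#' @examples
#' # an infinite threshold is the identity filter
filter_by_enthalpy <- function(candidates, threshold = kj_to_kcal(80),
                               unit = c("kcal", "kJ")) {
  unit <- match.arg(unit)
  if (unit == "kJ") threshold <- kj_to_kcal(threshold)
  if (nrow(candidates) && anyNA(candidates$delta_h)) {
    .stop2("candidates carry missing delta_h estimates; run estimate_reaction_enthalpy() first")
  }
  keep <- candidates$delta_h <= threshold
  out <- candidates[keep, , drop = FALSE]
  attr(out, "reactant_graph") <- attr(candidates, "reactant_graph")
  attr(out, "n_dropped") <- sum(!keep)
  out
}
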