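# broom-style accessors for the fitted/explored objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a reaction network into its edge table
#'
#' @param x a `reaction_network`.
#' @param ... unused.
#' @return the edges tibble (one row per reaction edge).
#' @export
tidy.reaction_network <- function(x, ...) x$edges

#' One-row summary of a reaction network
#'
#' @param x a `reaction_network`.
#' @param ... unused.
#' @return one-row tibble with node/edge counts, edge provenance split and
#'   barrier range.
#' @export
glance.reaction_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_intended_edges = sum(x$edges$source == "intended"),
    n_mined_edges = sum(x$edges$source == "mined"),
    n_seeds = sum(x$nodes$seed),
    n_explored = sum(x$nodes$explored),
    n_records = nrow(x$records),
    min_barrier = if (nrow(x$edges)) min(x$edges$delta_g_forward, na.rm = TRUE) else NA_real_,
    max_barrier = if (nrow(x$edges)) max(x$edges$delta_g_forward, na.rm = TRUE) else NA_real_
  )
}

#' Tidy network statistics into the per-reactant table
#'
#' @param x a `network_statistics` object.
#' @param ... unused.
#' @return per-reactant statistics tibble.
#' @export
tidy.network_statistics <- function(x, ...) x$per_reactant

#' One-row summary of network statistics
#'
#' @param x a `network_statistics` object.
#' @param ... unused.
#' @return the one-row summary tibble.
#' @export
glance.network_statistics <- function(x, ...) x$summary
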