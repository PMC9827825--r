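# Performance statistics for an exploration run, computed over high-level
# characterization records. Four headline numbers: success rate (fraction of
# attempted products with at least one converged high-level TS), intended
# rate (same, requiring an intended TS -- bounded above by the success
# rate), total gradient calls (GC), and gradient calls per intended product
# (GCPI). Denominators are distinct products by canonical key, not conformer
# attempts.

#' Compute exploration performance statistics
#'
#' @param records records tibble; rows with `level == "high"` are used
#'   (classified on the fly if the `outcome` column is absent).
#' @return object of class `network_statistics`: a list with `summary`
#'   (one-row tibble: `n_products_attempted`, `n_converged_products`,
#'   `n_intended_products`, `success_rate`, `intended_rate`, `total_gc`,
#'   `gcpi`), `per_reactant` (same statistics keyed by reactant) and
#'   `ranges` (per-reaction conformer barrier summaries from
#'   [aggregate_conformers()]).
#' @export
#' @examples
#' spec <- fixture_spec(n_products = 20, seed = 42)
#' compute_statistics(generate_fixture_records(spec))
compute_statistics <- function(records) {
  high <- records[records$level == "high", , drop = FALSE]
  if (!nrow(high)) .stop2("no high-level records: statistics are undefined")
  if (!"outcome" %in% names(high)) high <- classify_outcomes(high)
  per_product <- dplyr::summarise(
    dplyr::group_by(high, .data$reactant_key, .data$product_key),
    converged = any(.data$converged),
    intended = any(.data$outcome == "intended"),
    gc = sum(.data$gradient_calls),
    .groups = "drop")
  summarize_block <- function(pp, gc_total) {
    n_att <- nrow(pp)
    n_conv <- sum(pp$converged)
    n_int <- sum(pp$intended)
    tibble::tibble(
      n_products_attempted = n_att,
      n_converged_products = n_conv,
      n_intended_products = n_int,
      success_rate = n_conv / n_att,
      intended_rate = n_int / n_att,
      total_gc = gc_total,
      gcpi = if (n_int > 0) gc_total / n_int else NA_real_)
  }
  # product identity for the headline numbers is the distinct product key
  dp <- dplyr::summarise(
    dplyr::group_by(per_product, .data$product_key),
    converged = any(.data$converged), intended = any(.data$intended),
    .groups = "drop")
  summary <- summarize_block(dp, sum(high$gradient_calls))
  per_reactant <- dplyr::group_modify(
    dplyr::group_by(per_product, .data$reactant_key),
    function(d, g) summarize_block(d, sum(d$gc)))
  per_reactant <- dplyr::ungroup(per_reactant)
  structure(list(summary = summary, per_reactant = per_reactant,
                 ranges = aggregate_conformers(high)),
            class = "network_statistics")
}

#' @export
print.network_statistics <- function(x, ...) {
  s <- x$summary
  cat("<network_statistics>\n")
  cat(sprintf("  products attempted (high level): %d\n", s$n_products_attempted))
  cat(sprintf("  success rate:  %.3f\n", s$success_rate))
  cat(sprintf("  intended rate: %.3f\n", s$intended_rate))
  cat(sprintf("  total gradient calls: %d\n", s$total_gc))
  cat(sprintf("  gradient calls per intended product: %s\n",
              if (is.na(s$gcpi)) "undefined" else sprintf("%.1f", s$gcpi)))
  invisible(x)
}

#' Write statistics tables as CSV
#'
#' Writes the one-row summary to `path` and, when `per_reactant_path` is
#' given, the per-reactant breakdown alongside it.
#'
#' @param stats a `network_statistics` object.
#' @param path summary CSV path.
#' @param per_reactant_path optional per-reactant CSV path.
#' @return `path`, invisibly.
#' @export
write_statistics_csv <- function(stats, path, per_reactant_path = NULL) {
  utils::write.csv(stats$summary, path, row.names = FALSE)
  if (!is.null(per_reactant_path)) {
    utils::write.csv(stats$per_reactant, per_reactant_path, row.names = FALSE)
  }
  invisible(path)
}
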