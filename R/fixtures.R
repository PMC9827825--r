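# Packaged fixture molecules and the seeded fixture-record generator. The
# generator emits schema-valid high-level characterization records with
# controlled convergence and intended rates, so the statistics layer can be
# exercised (and its estimators checked for parameter recovery) without any
# characterization engine.

#' Packaged fixture molecules
#'
#' A small set of benchmark reactants shipped as SMILES-subset strings:
#' simple calibration molecules (water, methane, ethane, ethene, ethanol),
#' the unimolecular degradation benchmarks gamma-ketohydroperoxide (`khp`,
#' 3-hydroperoxypropanal), propylene carbonate and methyl butanoate, the
#' open-chain aldohexose form of glucose, and butadiene + ethene as a classic
#' bimolecular (Diels-Alder) pair.
#'
#' @param name optional fixture name; if given, the parsed `molgraph` is
#'   returned instead of the table.
#' @return a tibble with `name` and `smiles`, or a `molgraph`.
#' @export
#' @examples
#' fixture_molecules()
#' fixture_molecules("khp")
fixture_molecules <- function(name = NULL) {
  path <- system.file("extdata", "molecules.smi", package = "ersnet",
                      mustWork = TRUE)
  rows <- strsplit(readLines(path, warn = FALSE), "\\s+")
  tab <- tibble::tibble(name = vapply(rows, `[[`, character(1), 1),
                        smiles = vapply(rows, `[[`, character(1), 2))
  if (is.null(name)) return(tab)
  hit <- which(tab$name == name)
  if (!length(hit)) .stop2("unknown fixture molecule: ", name)
  parse_smiles(tab$smiles[hit], label = name)
}

#' Specification of a synthetic record stream
#'
#' @param n_products number of distinct products in the stream.
#' @param intended_prob probability that a product has an intended high-level
#'   TS. Coupled to convergence (intended implies converged), so the
#'   effective intended rate is `min(intended_prob, converged_prob)`.
#' @param converged_prob probability that a product has at least one
#'   converged high-level record.
#' @param gc_range inclusive integer range of gradient calls per attempt.
#' @param barrier_range barrier range in kcal/mol.
#' @param k_conformers conformer slots per product.
#' @param seed RNG seed (stream is byte-identical for a fixed seed).
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_products = 500L, intended_prob = 0.6,
                         converged_prob = 0.9, gc_range = c(4L, 15L),
                         barrier_range = c(20, 80), k_conformers = 4L,
                         seed = 1L) {
  stopifnot(n_products >= 1, intended_prob >= 0, intended_prob <= 1,
            converged_prob >= 0, converged_prob <= 1,
            length(gc_range) == 2, gc_range[1] <= gc_range[2],
            length(barrier_range) == 2, barrier_range[1] <= barrier_range[2],
            k_conformers >= 1)
  structure(list(n_products = as.integer(n_products),
                 intended_prob = intended_prob, converged_prob = converged_prob,
                 gc_range = as.integer(gc_range), barrier_range = barrier_range,
                 k_conformers = as.integer(k_conformers),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic characterization-record stream
#'
#' One product's fate is decided by a single uniform draw `u`: it converges
#' when `u < converged_prob` and is intended when `u < intended_prob` (so
#' intended products are a subset of converged ones and the intended rate
#' can never exceed the success rate, mirroring the real pipeline's bound).
#' The first conformer slot carries the product-level outcome; the remaining
#' slots converge with probability 0.8 given a converged product and share
#' its intended/unintended fate. Records are schema-valid for the replay
#' backend and byte-identical for a fixed seed.
#'
#' @param spec a [fixture_spec()].
#' @return records tibble (all `level == "high"`).
#' @export
generate_fixture_records <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  .with_local_seed(spec$seed, {
    n <- spec$n_products
    k <- spec$k_conformers
    p_int <- min(spec$intended_prob, spec$converged_prob)
    u <- stats::runif(n)
    conv <- u < spec$converged_prob
    int <- u < p_int
    base_barrier <- stats::runif(n, spec$barrier_range[1], spec$barrier_range[2])
    rk <- "FIXTURE-REACTANT"
    pk <- sprintf("FIXTURE-P%04d", seq_len(n))
    # long format: n products x k conformer slots; the first slot carries the
    # product-level outcome, later slots converge with prob 0.8 given a
    # converged product and share its intended/unintended fate
    pi_ <- rep(seq_len(n), each = k)
    slot <- rep(seq_len(k) - 1L, n)
    conf_conv <- ifelse(slot == 0L, conv[pi_],
                        conv[pi_] & stats::runif(n * k) < 0.8)
    dg <- ifelse(conf_conv, base_barrier[pi_] + stats::runif(n * k, 0, 5),
                 NA_real_)
    # every attempted slot costs gradient calls, converged or not
    gc <- sample(seq(spec$gc_range[1], spec$gc_range[2]), n * k, replace = TRUE)
    tibble::tibble(
      reactant_key = rk, product_key = pk[pi_],
      conformer_index = slot, level = "high",
      converged = conf_conv, delta_g_act = dg,
      gradient_calls = as.integer(gc),
      irc_reactant_key = ifelse(conf_conv, rk, NA_character_),
      irc_product_key = ifelse(conf_conv,
                               ifelse(int[pi_], pk[pi_],
                                      paste0(pk[pi_], "-REROUTED")),
                               NA_character_)
    )
  })
}
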