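# Internal helpers shared across modules.

KCAL_PER_KJ <- 1 / 4.184

#' Convert kJ/mol to kcal/mol
#'
#' Barriers and heats of reaction are handled internally in kcal/mol;
#' bond-increment tables and enthalpy thresholds are conventionally quoted in
#' kJ/mol, so conversion happens at the configuration boundary.
#'
#' @param x numeric vector of energies in kJ/mol.
#' @return energies in kcal/mol.
#' @export
kj_to_kcal <- function(x) x * KCAL_PER_KJ

# Deterministic, platform-independent string hash (polynomial rolling hash
# modulo the Mersenne prime 2^31 - 1). Used by the surrogate backend and the
# fixture generator so that record streams are reproducible across runs
# without touching R's global RNG.
.str_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  h
}

# Uniform deviate in [0, 1) derived from a string and a tag. Independent
# tags give (practically) independent deviates from the same string.
.hash_unit <- function(s, tag) {
  .str_hash(paste0(s, "\r", tag)) / 2147483647
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.
.with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

.stop2 <- function(...) stop(..., call. = FALSE)
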