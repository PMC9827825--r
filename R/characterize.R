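# Transition-state characterization bookkeeping. The package does no quantum
# chemistry: a backend object answers "characterize conformer c of this
# candidate at this level" with a TransitionStateRecord, and everything else
# -- conformer slots, intended/unintended classification from IRC endpoint
# keys, unintended-channel mining, conformer aggregation -- is bookkeeping
# over those records. Two backends ship: a deterministic surrogate (for
# pipeline exercise and statistics) and a replay backend over archived
# JSON-lines records.

.empty_records <- function() {
  tibble::tibble(
    reactant_key = character(), product_key = character(),
    conformer_index = integer(), level = character(),
    converged = logical(), delta_g_act = numeric(),
    gradient_calls = integer(),
    irc_reactant_key = character(), irc_product_key = character()
  )
}

.failed_record <- function(rkey, pkey, conformer, level) {
  tibble::tibble(
    reactant_key = rkey, product_key = pkey,
    conformer_index = as.integer(conformer), level = level,
    converged = FALSE, delta_g_act = NA_real_, gradient_calls = 0L,
    irc_reactant_key = NA_character_, irc_product_key = NA_character_
  )
}

#' Characterize candidates over conformer attempt slots
#'
#' Requests `k_conformers` transition-state records per candidate from the
#' backend at the given level. Reaction conformers are abstract attempt
#' slots: the backend decides convergence, barrier, gradient-call cost and
#' IRC endpoints per slot. A backend failure yields an unconverged record,
#' never an error escaping the pipeline.
#'
#' @param candidates candidate tibble ([enumerate_candidates()] output, with
#'   `delta_h` estimates for the surrogate backend).
#' @param k_conformers attempt slots per candidate (>= 1).
#' @param backend a backend object; see [surrogate_backend()] and
#'   [replay_backend()].
#' @param level `"low"` or `"high"`.
#' @return a records tibble: one row per (candidate, conformer) with
#'   `reactant_key`, `product_key`, `conformer_index`, `level`, `converged`,
#'   `delta_g_act` (kcal/mol, NA unless converged), `gradient_calls`,
#'   `irc_reactant_key`, `irc_product_key`.
#' @export
characterize_candidates <- function(candidates, k_conformers = 4L, backend,
                                    level = c("low", "high")) {
  level <- match.arg(level)
  k_conformers <- as.integer(k_conformers)
  stopifnot(k_conformers >= 1L)
  if (!nrow(candidates)) return(.empty_records())
  out <- vector("list", nrow(candidates) * k_conformers)
  idx <- 0L
  for (r in seq_len(nrow(candidates))) {
    cand <- candidates[r, , drop = FALSE]
    # sibling products of the same reactant: the alternative channels a
    # rerouted (unintended) TS may land on
    sibs <- setdiff(candidates$product_key[candidates$reactant_key == cand$reactant_key],
                    cand$product_key)
    for (conf in seq_len(k_conformers) - 1L) {
      idx <- idx + 1L
      out[[idx]] <- tryCatch(
        ts_characterize(backend, cand, conf, level, alternatives = sibs),
        error = function(e) {
          warning("backend failure for ", cand$product_key, " conformer ",
                  conf, ": ", conditionMessage(e), call. = FALSE)
          .failed_record(cand$reactant_key, cand$product_key, conf, level)
        }
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Backend contract for transition-state characterization
#'
#' Generic dispatched on the backend object: given one candidate row, a
#' conformer slot and a level, return a one-row records tibble (see
#' [characterize_candidates()] for the schema).
#'
#' @param backend backend object.
#' @param candidate one-row candidate tibble.
#' @param conformer_index attempt slot, 0-based.
#' @param level `"low"` or `"high"`.
#' @param alternatives product keys of sibling channels from the same
#'   reactant (used by backends that model unintended rerouting).
#' @return one-row records tibble.
#' @export
ts_characterize <- function(backend, candidate, conformer_index, level,
                            alternatives = character()) {
  UseMethod("ts_characterize")
}

#' Deterministic surrogate characterization backend
#'
#' A non-physical stand-in for a quantum-chemistry characterization stack,
#' built so the pipeline's bookkeeping and statistics can be exercised
#' deterministically. The low-level barrier is
#' `max(delta_h, 0) + base_barrier + J` with `J` a hash-derived jitter in
#' `[0, jitter_range)` per (candidate, conformer); the high-level barrier
#' adds a hash-derived offset in `[-high_offset, +high_offset)`; gradient
#' calls are hash-drawn integers in `gc_range`. IRC endpoints default to the
#' putative reaction (all intended); `unintended_fraction` reroutes a
#' deterministic subset of candidates to a hash-selected sibling channel,
#' and `fail_fraction` makes a deterministic subset of conformer attempts
#' unconverged. Identical inputs and seed give byte-identical record streams.
#'
#' @param seed integer folded into every hash.
#' @param base_barrier intrinsic barrier floor, kcal/mol (default 30).
#' @param jitter_range conformer jitter width, kcal/mol (default 20).
#' @param high_offset half-width of the low-to-high barrier shift (default 5).
#' @param gc_range inclusive integer range of gradient calls per attempt.
#' @param unintended_fraction fraction of candidates rerouted to a sibling
#'   product (given any sibling exists).
#' @param fail_fraction fraction of conformer attempts that fail to converge.
#' @return backend object of class `surrogate_backend`.
#' @export
surrogate_backend <- function(seed = 1L, base_barrier = 30, jitter_range = 20,
                              high_offset = 5, gc_range = c(4L, 15L),
                              unintended_fraction = 0, fail_fraction = 0) {
  stopifnot(unintended_fraction >= 0, unintended_fraction <= 1,
            fail_fraction >= 0, fail_fraction <= 1,
            length(gc_range) == 2, gc_range[1] >= 1)
  structure(list(seed = as.integer(seed), base_barrier = base_barrier,
                 jitter_range = jitter_range, high_offset = high_offset,
                 gc_range = as.integer(gc_range),
                 unintended_fraction = unintended_fraction,
                 fail_fraction = fail_fraction),
            class = c("surrogate_backend", "ts_backend"))
}

#' @export
ts_characterize.surrogate_backend <- function(backend, candidate,
                                              conformer_index, level,
                                              alternatives = character()) {
  rkey <- candidate$reactant_key
  pkey <- candidate$product_key
  tag <- paste(rkey, pkey, conformer_index, backend$seed, sep = "|")
  if (.hash_unit(tag, "fail") < backend$fail_fraction) {
    return(.failed_record(rkey, pkey, conformer_index, level))
  }
  dh <- candidate$delta_h
  if (is.null(dh) || is.na(dh)) dh <- 0
  dg_low <- max(dh, 0) + backend$base_barrier +
    backend$jitter_range * .hash_unit(tag, "jitter")
  dg <- if (level == "high") {
    dg_low + backend$high_offset * (2 * .hash_unit(tag, "offset") - 1)
  } else {
    dg_low
  }
  gc <- backend$gc_range[1] +
    floor(.hash_unit(tag, paste0("gc", level)) *
            (backend$gc_range[2] - backend$gc_range[1] + 1L))
  irc_p <- pkey
  cand_tag <- paste(rkey, pkey, backend$seed, sep = "|")
  if (length(alternatives) &&
      .hash_unit(cand_tag, "route") < backend$unintended_fraction) {
    pick <- 1L + floor(.hash_unit(cand_tag, "alt") * length(alternatives))
    irc_p <- sort(alternatives)[pick]
  }
  tibble::tibble(
    reactant_key = rkey, product_key = pkey,
    conformer_index = as.integer(conformer_index), level = level,
    converged = TRUE, delta_g_act = dg, gradient_calls = as.integer(gc),
    irc_reactant_key = rkey, irc_product_key = irc_p
  )
}

#' Replay backend over archived characterization records
#'
#' Serves records from a JSON-lines archive (see [write_ts_records()]),
#' matched by (reactant key, product key, conformer index, level). Requested
#' slots with no archived record come back as unconverged placeholder
#' records with a warning, so partial archives replay cleanly.
#'
#' @param path JSONL records file.
#' @return backend object of class `replay_backend`.
#' @export
replay_backend <- function(path) {
  records <- read_ts_records(path)
  index <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(records))) {
    k <- paste(records$reactant_key[r], records$product_key[r],
               records$conformer_index[r], records$level[r], sep = "|")
    index[[k]] <- records[r, , drop = FALSE]
  }
  structure(list(path = path, index = index, n = nrow(records)),
            class = c("replay_backend", "ts_backend"))
}

#' @export
ts_characterize.replay_backend <- function(backend, candidate, conformer_index,
                                           level, alternatives = character()) {
  k <- paste(candidate$reactant_key, candidate$product_key,
             conformer_index, level, sep = "|")
  hit <- backend$index[[k]]
  if (is.null(hit)) {
    warning("no archived record for ", candidate$product_key, " conformer ",
            conformer_index, " (", level, "); emitting a failed placeholder",
            call. = FALSE)
    return(.failed_record(candidate$reactant_key, candidate$product_key,
                          conformer_index, level))
  }
  hit
}

#' Classify record outcomes from IRC endpoints
#'
#' A record is `failed` if unconverged; `intended` if its IRC endpoint keys
#' equal the candidate's reactant/product keys as an unordered pair (a TS
#' traversed in either orientation confirms the putative reaction); otherwise
#' `unintended`.
#'
#' @param records records tibble.
#' @return the records with an `outcome` factor column added.
#' @export
classify_outcomes <- function(records) {
  outcome <- rep("failed", nrow(records))
  conv <- records$converged
  same <- conv &
    ((records$irc_reactant_key == records$reactant_key &
        records$irc_product_key == records$product_key) |
       (records$irc_reactant_key == records$product_key &
          records$irc_product_key == records$reactant_key))
  outcome[conv & same] <- "intended"
  outcome[conv & !same] <- "unintended"
  records$outcome <- factor(outcome, levels = c("intended", "unintended", "failed"))
  records
}

#' Mine unintended channels for new reaction candidates
#'
#' Unsuccessful-in-intent TS searches still localize real transition states;
#' when one IRC endpoint of an unintended converged record matches a known
#' reactant, the record reveals a reaction channel from that reactant to the
#' other endpoint. Each such channel is emitted once (deduplicated against
#' `known_pairs` and within the mined set by reactant/product key pair),
#' carrying the record's barrier; the bNfM label is taken from the matching
#' enumerated candidate when one is supplied, otherwise left NA.
#'
#' @param records classified records tibble (see [classify_outcomes()]).
#' @param pool_keys canonical keys of the known reactant pool.
#' @param known_pairs character vector of "reactant_key -> product_key"
#'   pairs already present in the network (see [reaction_pair_id()]).
#' @param candidates optional candidate tibble used to look up change sets
#'   and labels for mined channels.
#' @return tibble of mined channels: `reactant_key`, `product_key`,
#'   `ers_label`, `delta_g_act`, `n_records`, plus `n_dropped` attribute for
#'   records whose endpoints matched no pool reactant.
#' @export
mine_unintended <- function(records, pool_keys, known_pairs = character(),
                            candidates = NULL) {
  if (!"outcome" %in% names(records)) records <- classify_outcomes(records)
  un <- records[records$outcome == "unintended", , drop = FALSE]
  mined <- list()
  dropped <- 0L
  if (nrow(un)) {
    for (r in seq_len(nrow(un))) {
      ends <- c(un$irc_reactant_key[r], un$irc_product_key[r])
      hit <- which(ends %in% pool_keys)
      if (!length(hit)) {
        dropped <- dropped + 1L
        next
      }
      rk <- ends[hit[1]]
      pk <- ends[-hit[1]][1]
      if (is.na(pk) || pk == rk) {
        dropped <- dropped + 1L
        next
      }
      mined[[length(mined) + 1]] <- tibble::tibble(
        reactant_key = rk, product_key = pk,
        delta_g_act = un$delta_g_act[r]
      )
    }
  }
  if (!length(mined)) {
    out <- tibble::tibble(reactant_key = character(), product_key = character(),
                          ers_label = character(), delta_g_act = numeric(),
                          n_records = integer())
    attr(out, "n_dropped") <- dropped
    return(out)
  }
  out <- dplyr::bind_rows(mined)
  out <- dplyr::summarise(
    dplyr::group_by(out, .data$reactant_key, .data$product_key),
    delta_g_act = min(.data$delta_g_act),
    n_records = dplyr::n(),
    .groups = "drop"
  )
  out$ers_label <- NA_character_
  if (!is.null(candidates) && nrow(candidates)) {
    m <- match(paste(out$reactant_key, out$product_key),
               paste(candidates$reactant_key, candidates$product_key))
    out$ers_label <- candidates$ers_label[m]
  }
  out <- out[!reaction_pair_id(out$reactant_key, out$product_key) %in% known_pairs, ,
             drop = FALSE]
  out <- out[, c("reactant_key", "product_key", "ers_label", "delta_g_act",
                 "n_records")]
  attr(out, "n_dropped") <- dropped
  out
}

#' Canonical identifier of an (unordered) reaction pair
#'
#' @param rkey,pkey reactant and product canonical keys.
#' @return character vector of direction-independent pair ids.
#' @export
reaction_pair_id <- function(rkey, pkey) {
  paste(pmin(rkey, pkey), pmax(rkey, pkey), sep = " <> ")
}

#' Aggregate conformer records into per-reaction barrier summaries
#'
#' For each (reactant, product, level) the best barrier is the minimum
#' activation free energy over *intended* conformer records and the range is
#' max - min over the same set; reactions with no intended record get an NA
#' summary. The spread of barriers across reaction conformers measures how
#' much conformational sampling matters for that reaction.
#'
#' @param records classified records tibble.
#' @return tibble with `reactant_key`, `product_key`, `level`,
#'   `best_delta_g`, `range_delta_g`, `n_intended`, `n_converged`,
#'   `n_attempted`.
#' @export
aggregate_conformers <- function(records) {
  if (!"outcome" %in% names(records)) records <- classify_outcomes(records)
  dplyr::summarise(
    dplyr::group_by(records, .data$reactant_key, .data$product_key, .data$level),
    best_delta_g = if (any(.data$outcome == "intended")) {
      min(.data$delta_g_act[.data$outcome == "intended"])
    } else NA_real_,
    range_delta_g = if (any(.data$outcome == "intended")) {
      diff(range(.data$delta_g_act[.data$outcome == "intended"]))
    } else NA_real_,
    n_intended = sum(.data$outcome == "intended"),
    n_converged = sum(.data$converged),
    n_attempted = dplyr::n(),
    .groups = "drop"
  )
}
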