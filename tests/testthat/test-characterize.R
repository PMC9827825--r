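cands_khp <- function() {
  estimate_reaction_enthalpy(enumerate_candidates(fixture_molecules("khp")))
}

test_that("surrogate backend fills every conformer slot deterministically", {
  cands <- cands_khp()
  rec1 <- characterize_candidates(cands, 4, surrogate_backend(seed = 3), "low")
  rec2 <- characterize_candidates(cands, 4, surrogate_backend(seed = 3), "low")
  expect_identical(rec1, rec2)
  expect_equal(nrow(rec1), 4 * nrow(cands))
  expect_true(all(rec1$converged))
  expect_true(all(rec1$gradient_calls >= 4 & rec1$gradient_calls <= 15))
  # different seeds give different barrier streams
  rec3 <- characterize_candidates(cands, 4, surrogate_backend(seed = 4), "low")
  expect_false(identical(rec1$delta_g_act, rec3$delta_g_act))
})

test_that("surrogate barrier is floored at the intrinsic base for exothermic channels", {
  cands <- cands_khp()
  exo <- cands[cands$delta_h < 0, , drop = FALSE][1, ]
  rec <- characterize_candidates(exo, 1, surrogate_backend(seed = 1), "low")
  # dH clamped at zero: barrier in [30, 50)
  expect_gte(rec$delta_g_act, 30)
  expect_lt(rec$delta_g_act, 50)
  endo <- cands[cands$delta_h > 0, , drop = FALSE][1, ]
  rec2 <- characterize_candidates(endo, 1, surrogate_backend(seed = 1), "low")
  expect_gte(rec2$delta_g_act, endo$delta_h + 30)
})

test_that("high-level barriers sit within the offset band around low-level ones", {
  cands <- cands_khp()[1:5, ]
  lo <- characterize_candidates(cands, 4, surrogate_backend(seed = 1), "low")
  hi <- characterize_candidates(cands, 4, surrogate_backend(seed = 1), "high")
  expect_true(all(abs(hi$delta_g_act - lo$delta_g_act) <= 5))
})

test_that("replay backend serves archived records and pads missing slots", {
  cands <- cands_khp()[1, ]
  rec <- characterize_candidates(cands, 3, surrogate_backend(seed = 1), "high")
  tmp <- withr::local_tempfile(fileext = ".jsonl")
  write_ts_records(rec, tmp)
  backend <- replay_backend(tmp)
  expect_warning(
    out <- characterize_candidates(cands, 4, backend, "high"),
    "failed placeholder")
  expect_equal(nrow(out), 4L)
  expect_equal(sum(out$converged), 3L)
  expect_false(out$converged[out$conformer_index == 3])
  # served records match the archive exactly
  expect_equal(out$delta_g_act[1:3], rec$delta_g_act)
})

test_that("records survive a JSONL round-trip byte-exactly", {
  cands <- cands_khp()[1:4, ]
  rec <- characterize_candidates(cands, 2, surrogate_backend(seed = 9), "high")
  tmp <- withr::local_tempfile(fileext = ".jsonl")
  write_ts_records(rec, tmp)
  back <- read_ts_records(tmp)
  expect_equal(as.data.frame(back), as.data.frame(rec))
  # versioned header is enforced
  tmp2 <- withr::local_tempfile(fileext = ".jsonl")
  writeLines('{"format":"something-else","version":1}', tmp2)
  expect_error(read_ts_records(tmp2), "not an ersnet records file")
})

test_that("outcomes classify by unordered IRC endpoint comparison", {
  base <- tibble::tibble(
    reactant_key = "R", product_key = "P", conformer_index = 0L,
    level = "high", converged = TRUE, delta_g_act = 40,
    gradient_calls = 5L, irc_reactant_key = "R", irc_product_key = "P")
  expect_equal(as.character(classify_outcomes(base)$outcome), "intended")
  # reverse orientation still intended
  rev <- base
  rev$irc_reactant_key <- "P"; rev$irc_product_key <- "R"
  expect_equal(as.character(classify_outcomes(rev)$outcome), "intended")
  # unconverged -> failed
  fail <- base
  fail$converged <- FALSE; fail$delta_g_act <- NA_real_
  fail$irc_reactant_key <- NA_character_; fail$irc_product_key <- NA_character_
  expect_equal(as.character(classify_outcomes(fail)$outcome), "failed")
  # a stray endpoint -> unintended
  un <- base
  un$irc_product_key <- "X"
  expect_equal(as.character(classify_outcomes(un)$outcome), "unintended")
})

test_that("unintended rerouting produces classifiable and minable records", {
  cands <- cands_khp()
  backend <- surrogate_backend(seed = 5, unintended_fraction = 0.4)
  rec <- classify_outcomes(characterize_candidates(cands, 2, backend, "high"))
  expect_true(any(rec$outcome == "unintended"))
  expect_true(any(rec$outcome == "intended"))
  rkey <- cands$reactant_key[1]
  mined <- mine_unintended(rec, pool_keys = rkey, candidates = cands)
  expect_gt(nrow(mined), 0)
  # mined channels start at the pool reactant and carry the sibling's label
  expect_true(all(mined$reactant_key == rkey))
  expect_true(all(mined$ers_label == "b2f2"))
  # never re-emit known reactions
  known <- reaction_pair_id(mined$reactant_key, mined$product_key)
  mined2 <- mine_unintended(rec, pool_keys = rkey, known_pairs = known,
                            candidates = cands)
  expect_equal(nrow(mined2), 0L)
})

test_that("mining drops records whose endpoints match no pool reactant", {
  rec <- tibble::tibble(
    reactant_key = "R", product_key = "P", conformer_index = 0L,
    level = "high", converged = TRUE, delta_g_act = 33,
    gradient_calls = 5L, irc_reactant_key = "A", irc_product_key = "B")
  mined <- mine_unintended(classify_outcomes(rec), pool_keys = "R")
  expect_equal(nrow(mined), 0L)
  expect_equal(attr(mined, "n_dropped"), 1L)
  # all-intended record streams mine nothing
  ok <- rec
  ok$irc_reactant_key <- "R"; ok$irc_product_key <- "P"
  expect_equal(nrow(mine_unintended(classify_outcomes(ok), pool_keys = "R")), 0L)
})

test_that("conformer aggregation takes best/range over intended records only", {
  rec <- tibble::tibble(
    reactant_key = "R", product_key = "P",
    conformer_index = 0:2, level = "high",
    converged = c(TRUE, TRUE, FALSE),
    delta_g_act = c(40.0, 43.7, NA),
    gradient_calls = c(5L, 6L, 2L),
    irc_reactant_key = c("R", "R", NA), irc_product_key = c("P", "P", NA))
  s <- aggregate_conformers(rec)
  expect_equal(s$best_delta_g, 40.0)
  expect_equal(s$range_delta_g, 3.7)
  expect_equal(s$n_intended, 2L)
  # single intended conformer: zero range
  s1 <- aggregate_conformers(rec[1, ])
  expect_equal(s1$range_delta_g, 0)
  # unintended barriers are excluded from best
  mixed <- rec
  mixed$converged <- TRUE
  mixed$delta_g_act <- c(50, 30, 45)
  mixed$irc_reactant_key <- "R"
  mixed$irc_product_key <- c("P", "X", "X")
  s2 <- aggregate_conformers(mixed)
  expect_equal(s2$best_delta_g, 50)
  expect_equal(s2$n_intended, 1L)
})

test_that("a crashing backend yields failed records, not errors", {
  broken_backend <- structure(list(), class = c("broken_backend", "ts_backend"))
  assign("ts_characterize.broken_backend",
         function(backend, candidate, conformer_index, level, alternatives) {
           stop("boom")
         }, envir = globalenv())
  withr::defer(rm("ts_characterize.broken_backend", envir = globalenv()))
  cands <- cands_khp()[1, ]
  w <- capture_warnings(rec <- characterize_candidates(cands, 2, broken_backend, "low"))
  expect_length(w, 2)
  expect_match(w, "backend failure", all = TRUE)
  expect_equal(nrow(rec), 2L)
  expect_false(any(rec$converged))
})
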