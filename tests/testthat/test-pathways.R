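test_that("minimax pathway on a single edge returns that edge", {
  toy <- as_reaction_network(tibble::tibble(from = "S", to = "T",
                                            delta_g_forward = 40, delta_h = 0))
  pw <- minimax_pathway(toy, "S", "T")
  expect_equal(pw$path, c("S", "T"))
  expect_equal(pw$bottleneck, 40)
})

test_that("the two-step route beats the direct high-barrier reaction", {
  # methyl-butanoate-style toy: direct isomerization at 106.0 kcal/mol vs a
  # two-step route over the enol intermediate at 68.2 then 44.2 kcal/mol
  toy <- as_reaction_network(tibble::tibble(
    from = c("MB", "MB", "ENOL"), to = c("MA", "ENOL", "MA"),
    delta_g_forward = c(106.0, 68.2, 44.2), delta_h = 0))
  pw <- minimax_pathway(toy, "MB", "MA")
  expect_equal(pw$path, c("MB", "ENOL", "MA"))
  expect_equal(pw$bottleneck, 68.2)
  fav <- kinetically_favorable_products(toy, "MB", cutoff = 70)
  expect_true("MA" %in% fav$key)
  expect_equal(fav$bottleneck[fav$key == "MA"], 68.2)
})

test_that("minimax equals exhaustive simple-path search on random networks", {
  for (s in 1:50) {
    net <- random_toy_network(n_nodes = sample(4:8, 1), n_edges = sample(5:14, 1),
                              seed = 1000 + s)
    de <- ersnet:::.directed_edges(net)
    keys <- net$nodes$key
    src <- keys[1]
    for (tgt in keys[-1]) {
      oracle <- brute_minimax(de, src, tgt)
      got <- minimax_pathway(net, src, tgt)
      if (is.null(oracle)) {
        expect_null(got, label = paste("seed", s, tgt))
      } else {
        expect_equal(got$bottleneck, oracle$bottleneck,
                     label = paste("seed", s, tgt))
        expect_equal(length(got$path) - 1, oracle$hops,
                     label = paste("seed", s, "hops", tgt))
      }
    }
  }
})

test_that("bottleneck values are monotone and bounded by direct edges", {
  net <- random_toy_network(8, 14, seed = 99)
  src <- net$nodes$key[1]
  fav <- kinetically_favorable_products(net, src)
  de <- ersnet:::.directed_edges(net)
  direct <- de[de$from == src, , drop = FALSE]
  for (r in seq_len(nrow(direct))) {
    b <- fav$bottleneck[fav$key == direct$to[r]]
    expect_lte(b, direct$barrier[r])
  }
  # any prefix of a minimax path has a bottleneck no larger than the whole
  tgt <- fav$key[nrow(fav)]
  pw <- minimax_pathway(net, src, tgt)
  if (!is.null(pw) && length(pw$path) > 2) {
    for (mid in pw$path[-c(1, length(pw$path))]) {
      expect_lte(minimax_pathway(net, src, mid)$bottleneck, pw$bottleneck)
    }
  }
})

test_that("cutoff filtering keeps only the source under all barriers", {
  toy <- as_reaction_network(tibble::tibble(
    from = c("S", "A"), to = c("A", "B"),
    delta_g_forward = c(50, 60), delta_h = 0))
  fav <- kinetically_favorable_products(toy, "S", cutoff = 10)
  expect_equal(fav$key, "S")
  all_fav <- kinetically_favorable_products(toy, "S")
  expect_setequal(all_fav$key, c("S", "A", "B"))
  expect_false(is.unsorted(all_fav$bottleneck))
})

test_that("unknown node keys error; disconnected targets return NULL", {
  toy <- as_reaction_network(tibble::tibble(from = "S", to = "T",
                                            delta_g_forward = 40))
  expect_error(minimax_pathway(toy, "S", "nope"), "unknown node")
  expect_error(kinetically_favorable_products(toy, "nope"), "unknown node")
  two <- as_reaction_network(tibble::tibble(
    from = c("S", "X"), to = c("T", "Y"), delta_g_forward = c(40, 50)))
  expect_null(minimax_pathway(two, "S", "Y"))
})

test_that("co-product fragments are reachable through their fragmentation edge", {
  cfg <- explore_config(max_iterations = 1, dh_threshold = Inf,
                        dg_low_threshold = Inf)
  net <- explore_network(parse_smiles("CC"), cfg)
  h2 <- net$nodes$key[net$nodes$formula == "H2"]
  src <- net$nodes$key[net$nodes$seed]
  pw <- minimax_pathway(net, src, h2)
  expect_false(is.null(pw))
  expect_equal(pw$bottleneck, net$edges$delta_g_forward[1])
})

test_that("pathway energy tables accumulate step reaction energies", {
  toy <- as_reaction_network(tibble::tibble(
    from = c("S", "A"), to = c("A", "T"),
    delta_g_forward = c(50, 60), delta_h = c(-10, 5)))
  pw <- minimax_pathway(toy, "S", "T")
  tab <- pathway_energy_table(toy, pw)
  expect_equal(tab$cumulative_h, c(-10, -5))
  expect_equal(tab$barrier, c(50, 60))
})
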