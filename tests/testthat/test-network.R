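test_that("single-seed exploration of ethane builds the expected network", {
  cfg <- explore_config(max_iterations = 1, dh_threshold = Inf,
                        dg_low_threshold = Inf)
  net <- explore_network(parse_smiles("CC"), cfg)
  expect_setequal(net$nodes$formula, c("C2H6", "C2H4", "H2"))
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$ers_label, "b2f2")
  # the fragmentation edge points at the larger fragment, co-product annotated
  expect_equal(net$nodes$formula[match(net$edges$to, net$nodes$key)], "C2H4")
  expect_match(net$edges$co_products, "H2")
})

test_that("water gives a single-node network and small products are not expanded", {
  net <- explore_network(parse_smiles("O"), explore_config(max_iterations = 1))
  expect_equal(nrow(net$nodes), 1L)
  expect_equal(nrow(net$edges), 0L)

  cfg <- explore_config(max_iterations = 2, dh_threshold = Inf,
                        dg_low_threshold = Inf)
  net2 <- explore_network(parse_smiles("CC"), cfg)
  # ethene and H2 have < 3 heavy atoms: excluded, pool empties after round 1
  small <- net2$nodes[net2$nodes$formula %in% c("C2H4", "H2"), ]
  expect_true(all(small$excluded_reason == "small_molecule"))
  expect_false(any(small$explored))
})

test_that("exploration respects the enthalpy threshold", {
  # ethane dehydrogenation is +127 kJ/mol endothermic: the conventional
  # 80 kJ/mol pre-pruning cap removes it and the network stays trivial
  net <- explore_network(parse_smiles("CC"), explore_config(max_iterations = 1))
  expect_equal(nrow(net$edges), 0L)
})

test_that("two-iteration KHP exploration grows, stays conserved and can mine", {
  cfg <- explore_config(max_iterations = 2, seed = 1)
  net <- explore_network(fixture_molecules("khp"), cfg)
  expect_gt(nrow(net$edges), 10)
  expect_gt(sum(net$nodes$explored), 1)
  # every edge endpoint is a node; no duplicate (pair, label) edges
  expect_true(all(net$edges$from %in% net$nodes$key))
  expect_true(all(net$edges$to %in% net$nodes$key))
  eid <- paste(reaction_pair_id(net$edges$from, net$edges$to), net$edges$ers_label)
  expect_false(any(duplicated(eid)))
  # all barriers positive
  expect_true(all(net$edges$delta_g_forward > 0, na.rm = TRUE))
  # unexplored nodes carry machine-readable exclusion reasons
  un <- net$nodes[!net$nodes$explored, ]
  expect_true(all(un$excluded_reason %in% c("small_molecule", "barrier_cap",
                                            "max_depth")))
  # node count never decreases: 1-iteration run is a subset
  net1 <- explore_network(fixture_molecules("khp"),
                          explore_config(max_iterations = 1, seed = 1))
  expect_true(all(net1$nodes$key %in% net$nodes$key))
  expect_gte(nrow(net$nodes), nrow(net1$nodes))
})

test_that("unintended rerouting feeds mined edges into the network", {
  cfg <- explore_config(max_iterations = 1, seed = 1)
  backend <- surrogate_backend(seed = 1, unintended_fraction = 0.5)
  net <- explore_network(fixture_molecules("khp"), cfg, backend)
  expect_gt(sum(net$edges$source == "mined"), 0)
})

test_that("exploration is reproducible end to end", {
  cfg <- explore_config(max_iterations = 2, seed = 7)
  a <- explore_network(fixture_molecules("khp"), cfg)
  b <- explore_network(fixture_molecules("khp"), cfg)
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$edges, b$edges)
  expect_identical(a$records, b$records)
})

test_that("barrier cutoff marks products as excluded for expansion", {
  cfg <- explore_config(max_iterations = 2, seed = 1,
                        expansion_barrier_cutoff = 0.1)
  net <- explore_network(fixture_molecules("khp"), cfg)
  expect_true(any(net$nodes$excluded_reason == "barrier_cap", na.rm = TRUE))
})

test_that("tidiers and exports produce consistent tables", {
  cfg <- explore_config(max_iterations = 1, seed = 1)
  net <- explore_network(fixture_molecules("khp"), cfg)
  expect_identical(tidy(net), net$edges)
  g <- glance(net)
  expect_equal(g$n_nodes, nrow(net$nodes))
  expect_equal(g$n_edges, nrow(net$edges))

  tmp_gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, tmp_gml)
  parsed <- xml2::read_xml(tmp_gml)
  expect_equal(length(xml2::xml_find_all(parsed, ".//d1:node",
                                         xml2::xml_ns(parsed))),
               nrow(net$nodes))
  expect_equal(length(xml2::xml_find_all(parsed, ".//d1:edge",
                                         xml2::xml_ns(parsed))),
               nrow(net$edges))

  tmp_json <- withr::local_tempfile(fileext = ".json")
  write_network_json(net, tmp_json)
  back <- read_network_json(tmp_json)
  expect_equal(back$nodes$key, net$nodes$key)
  expect_equal(back$edges$delta_g_forward, net$edges$delta_g_forward)
  # node structures rebuilt from SMILES agree with the stored keys
  for (k in names(back$graphs)) {
    expect_identical(canonical_key(back$graphs[[k]]), k)
  }
})
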