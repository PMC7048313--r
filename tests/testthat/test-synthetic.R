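test_that("generator is deterministic and validates its spec", {
  spec <- synthetic_spec(n_background = 200, n_communities = 3,
                         proteins_per_community = 6, seed = 9)
  g1 <- suppressMessages(generate_global_graph(spec))
  g2 <- suppressMessages(generate_global_graph(spec))
  expect_identical(g1$graph$edges, g2$graph$edges)
  expect_identical(g1$ground_truth, g2$ground_truth)

  expect_error(synthetic_spec(p_member_hub = 1.2), "probability")
  expect_error(synthetic_spec(n_background = 0), ">= 1")
  expect_error(synthetic_spec(proteins_per_community = c(3, 3)),
               "per community")
})

test_that("no communities means a pure background graph", {
  spec <- synthetic_spec(n_background = 300, n_communities = 0, seed = 2)
  sg <- suppressMessages(generate_global_graph(spec))
  expect_equal(sg$graph$n, 300L)
  expect_false(any(sg$graph$nodes$is_protein))
  expect_equal(nrow(sg$ground_truth), 0L)
})

test_that("arc counts sit within three binomial standard deviations", {
  spec <- synthetic_spec(seed = 12)
  sg <- suppressMessages(generate_global_graph(spec))
  edges <- sg$graph$edges
  lay <- list(proteins = sg$ground_truth$node_id, hubs = sg$hubs$hub_id)
  bg <- setdiff(sg$graph$nodes$node_id, c(lay$proteins, lay$hubs))
  nb <- length(bg)
  n_bg <- sum(edges$from %in% bg & edges$to %in% bg)
  exp_bg <- nb * (nb - 1) * spec$p_background_edge
  expect_lt(abs(n_bg - exp_bg), 3 * sqrt(exp_bg))
  n_cross <- sum(edges$from %in% lay$proteins & edges$to %in% bg)
  exp_cross <- length(lay$proteins) * nb * spec$p_cross
  expect_lt(abs(n_cross - exp_cross), 3 * sqrt(exp_cross))
  n_hub_arcs <- sum(edges$from %in% lay$proteins & edges$to %in% lay$hubs)
  exp_hub <- length(lay$proteins) * spec$hubs_per_community * spec$p_member_hub
  expect_lt(abs(n_hub_arcs - exp_hub), 3 * sqrt(exp_hub * (1 - spec$p_member_hub)) + 1)
})

test_that("every planted hub is one step from its community", {
  sg <- default_graph()
  edges <- sg$graph$edges
  for (i in seq_len(nrow(sg$hubs))) {
    hub <- sg$hubs$hub_id[i]
    members <- sg$ground_truth$node_id[
      sg$ground_truth$community_id == sg$hubs$community_id[i]]
    expect_true(any(edges$from %in% members & edges$to == hub))
  }
})

test_that("recovery degrades as hub attachment weakens", {
  ari <- vapply(c(0.9, 0.6, 0.3), function(p) {
    spec <- synthetic_spec(p_member_hub = p, seed = 5)
    sg <- suppressMessages(generate_global_graph(spec))
    res <- suppressMessages(run_pipeline(sg))
    # score coverage as well as agreement: unclustered proteins count against
    cl <- res$clustering$communities
    truth <- sg$ground_truth
    found <- cl$community_id[match(truth$node_id, cl$node_id)]
    found[is.na(found)] <- -(seq_len(sum(is.na(found)))) # singletons
    mclust::adjustedRandIndex(found, truth$community_id)
  }, numeric(1))
  expect_true(all(diff(ari) <= 1e-9)) # non-increasing trend
})

test_that("snapshot pairs: identity limit and determinism", {
  spec <- synthetic_spec(n_background = 300, n_communities = 4,
                         proteins_per_community = 8, seed = 21)
  pair0 <- suppressMessages(
    generate_snapshot_pair(spec, rewire_hub_frac = 0, rewire_direct_frac = 0,
                           growth = 1))
  expect_identical(pair0$old$graph$edges, pair0$new$graph$edges)

  p1 <- suppressMessages(generate_snapshot_pair(spec))
  p2 <- suppressMessages(generate_snapshot_pair(spec))
  expect_identical(p1$new$graph$edges, p2$new$graph$edges)
  # old snapshot equals the plain generator under the same seed
  solo <- suppressMessages(generate_global_graph(spec))
  expect_identical(p1$old$graph$edges, solo$graph$edges)

  expect_error(generate_snapshot_pair(spec, rewire_hub_frac = 2), "probability")
  expect_error(generate_snapshot_pair(spec, growth = 0.5), ">= 1")
})

test_that("growth extends communities and their labels", {
  spec <- synthetic_spec(n_background = 300, n_communities = 4,
                         proteins_per_community = 10, seed = 8)
  pair <- suppressMessages(
    generate_snapshot_pair(spec, rewire_hub_frac = 0, rewire_direct_frac = 0,
                           growth = 1.2))
  expect_equal(nrow(pair$new$ground_truth), 48L)
  expect_gt(pair$new$graph$n, pair$old$graph$n)
  # new members are flagged proteins with symbols
  new_ids <- setdiff(pair$new$ground_truth$node_id, pair$old$ground_truth$node_id)
  expect_true(all(pair$new$graph$nodes$is_protein[new_ids + 1L]))
})
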