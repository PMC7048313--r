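mini_nodes <- function(titles, protein_flags) {
  data.frame(node_id = seq_along(titles) - 1L, title = titles,
             is_protein = protein_flags, symbol = NA)
}

test_that("mediating pages are found along oriented length-2 paths", {
  # A(0) -> T(2) -> B(1); hidden link A -> B
  nodes <- mini_nodes(c("A", "B", "T"), c(TRUE, TRUE, FALSE))
  g <- hl_graph(data.frame(from = c(0, 2), to = c(2, 1)), n = 3, nodes = nodes)
  fn <- build_friendship_network(g, c(0, 1), data.frame(from = 0, to = 1))
  expect_equal(fn$associated_nodes, 2L)
  expect_equal(nrow(fn$edges), 2L)
  expect_true(all(paste(fn$edges$from, fn$edges$to) %in% c("0 2", "2 1")))

  # no mediating path at all
  g2 <- hl_graph(data.frame(from = 0, to = 2), n = 3, nodes = nodes)
  fn2 <- build_friendship_network(g2, c(0, 1), data.frame(from = 0, to = 1))
  expect_length(fn2$associated_nodes, 0L)

  expect_error(build_friendship_network(g, integer(), data.frame(from = 0, to = 1)),
               "empty")
})

test_that("every associated node is certified by a mediating path", {
  res <- default_run()
  sg <- default_graph()
  cid <- res$clustering$communities$community_id[1]
  members <- res$clustering$communities$node_id[
    res$clustering$communities$community_id == cid]
  links <- res$hidden$edges[res$hidden$edges$from %in% members &
                              res$hidden$edges$to %in% members, ]
  fn <- build_friendship_network(sg$graph, members, links)
  keys <- paste(sg$graph$edges$from, sg$graph$edges$to)
  for (v in fn$associated_nodes) {
    p <- fn$paths[fn$paths$via == v, ][1, ]
    expect_true(paste(p$from, p$via) %in% keys)
    expect_true(paste(p$via, p$to) %in% keys)
  }
})

test_that("labels pick the most connected associated page, ties by title", {
  nodes <- mini_nodes(c("A", "B", "C", "Zinc", "Apoptosis"),
                      c(TRUE, TRUE, TRUE, FALSE, FALSE))
  # two mediators with equal degree: label must be the lexicographic first
  edges <- data.frame(from = c(0, 3, 0, 4), to = c(3, 1, 4, 1))
  g <- hl_graph(edges, n = 5, nodes = nodes)
  fn <- build_friendship_network(g, 0:2, data.frame(from = 0, to = 1))
  lab <- label_community(fn, nodes)
  expect_equal(lab$label, "Apoptosis")
  expect_false(lab$self_labeled)
  expect_equal(nrow(lab$candidates), 2L)

  # no associated nodes: self-labeled by the best-connected member
  g2 <- hl_graph(data.frame(from = 0, to = 1), n = 5, nodes = nodes)
  fn2 <- build_friendship_network(g2, 0:1, data.frame(from = 0, to = 1))
  lab2 <- label_community(fn2, nodes)
  expect_true(lab2$self_labeled)
  expect_true(lab2$label %in% c("A", "B"))
})

test_that("planted topic hubs name their communities", {
  res <- default_run()
  sg <- default_graph()
  expect_true(all(grepl("^Topic_", res$labels$label)))
  # each recovered community is named by its own planted hub
  truth_label <- function(cid) {
    members <- res$clustering$communities$node_id[
      res$clustering$communities$community_id == cid]
    planted <- sg$ground_truth$community_id[match(members, sg$ground_truth$node_id)]
    sprintf("Topic_%d", unique(planted))
  }
  for (cid in res$labels$community_id) {
    expect_equal(res$labels$label[res$labels$community_id == cid],
                 truth_label(cid))
  }
})

test_that("inter-community abstraction counts hidden arcs between groups", {
  cl <- structure(list(communities = tibble::tibble(
    community_id = c(1L, 1L, 2L, 2L), node_id = c(0L, 1L, 2L, 3L))),
    class = "mcl_clustering")
  hidden <- data.frame(from = c(0, 1, 2, 0), to = c(1, 2, 3, 3))
  cg <- community_graph(cl, hidden)
  expect_equal(cg$n_hidden_links[cg$comm_a == 1 & cg$comm_b == 2], 2L)
})

test_that("shortest-path histograms: direct, mediated, unreachable", {
  nodes <- mini_nodes(c("A", "B", "T", "X"), c(TRUE, TRUE, FALSE, FALSE))
  g <- hl_graph(data.frame(from = c(0, 2, 1), to = c(2, 1, 0)), n = 4,
                nodes = nodes)
  h <- sampled_shortest_paths(g, pairs = data.frame(from = c(1, 0, 0),
                                                    to = c(0, 1, 3)))
  df <- as.data.frame(h)
  expect_equal(df$n[df$length == 1], 1L) # direct arc 1 -> 0
  expect_equal(df$n[df$length == 2], 1L) # 0 -> 2 -> 1
  expect_equal(df$n[is.infinite(df$length)], 1L) # 3 unreachable
  expect_equal(sum(df$n), 3L)
  expect_error(sampled_shortest_paths(g, pair_kind = "random_any", n_pairs = 0),
               "n_pairs")
})

test_that("hidden-link endpoints sit closer than random protein pairs", {
  res <- default_run()
  sg <- default_graph()
  h_hidden <- sampled_shortest_paths(sg$graph, pair_kind = "hidden_link_endpoints",
                                     hidden = res$hidden, n_pairs = 200, seed = 1)
  h_random <- sampled_shortest_paths(sg$graph, pair_kind = "random_protein",
                                     n_pairs = 400, seed = 1)
  expect_equal(modal_path_length(h_hidden), 2)
  expect_gte(modal_path_length(h_random), 3)
  expect_equal(sum(h_hidden$n), attr(h_hidden, "n_pairs"))
  expect_equal(sum(h_random$n), attr(h_random, "n_pairs"))
})
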