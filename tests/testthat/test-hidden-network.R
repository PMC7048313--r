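# brute-force oracle: try every distinct weight as the inclusion level and
# return the kept arcs whose LCC ratio is closest to the target
brute_force_cutoff <- function(W, ratio_target) {
  diag(W) <- 0
  ws <- sort(unique(W[W > 0]), decreasing = TRUE)
  best <- NULL
  for (w in ws) {
    idx <- which(W >= w, arr.ind = TRUE)
    arcs <- data.frame(from = idx[, "col"] - 1L, to = idx[, "row"] - 1L)
    ratio <- graph_lcc(arcs)$ratio
    dev <- abs(ratio - ratio_target)
    if (is.null(best) || dev < best$dev) best <- list(w = w, dev = dev, arcs = arcs)
  }
  best
}

toy_regomax_matrix <- function(W, ids = seq_len(nrow(W)) - 1L) {
  dimnames(W) <- list(as.character(ids), as.character(ids))
  W
}

test_that("all-equal weights leave a single nontrivial candidate", {
  W <- matrix(0.2, 3, 3)
  direct <- data.frame(from = c(0, 1, 2), to = c(1, 2, 0)) # ratio 1.0
  hn <- suppressMessages(select_cutoff(toy_regomax_matrix(W), direct))
  # everything kept: one candidate level, cutoff sits below it
  expect_equal(nrow(hn$edges), 6L)
  expect_equal(hn$cutoff, 0)
  expect_true(all(hn$edges$weight > hn$cutoff))
})

test_that("weak extra arc is excluded to match the direct ratio", {
  # weighted 3-cycle (node 3 attached by one weak arc) vs a 3-cycle direct net
  W <- matrix(0, 4, 4)
  W[2, 1] <- 0.5; W[3, 2] <- 0.4; W[1, 3] <- 0.45 # cycle 0->1->2->0
  W[4, 1] <- 0.01                                 # weak 0->3
  direct <- data.frame(from = c(0, 1, 2), to = c(1, 2, 0))
  hn <- suppressMessages(select_cutoff(toy_regomax_matrix(W), direct))
  expect_equal(hn$lcc_ratio_hidden, 1.0)
  expect_equal(nrow(hn$edges), 3L)
  expect_false(any(hn$edges$to == 3))
  oracle <- brute_force_cutoff(W, graph_lcc(direct)$ratio)
  expect_equal(nrow(hn$edges), nrow(oracle$arcs))
})

test_that("sweep equals the brute-force scan on random weight matrices", {
  for (seed in 1:5) {
    W <- withr::with_seed(seed, {
      W <- matrix(stats::rexp(15 * 15), 15, 15) * 1e-3
      W[W < stats::median(W)] <- 0
      W
    })
    direct <- random_graph(15, 30, seed = seed + 50)$edges
    hn <- suppressMessages(select_cutoff(toy_regomax_matrix(W), direct))
    oracle <- brute_force_cutoff(W, graph_lcc(direct)$ratio)
    keys_got <- paste(hn$edges$from, hn$edges$to)
    keys_want <- paste(oracle$arcs$from, oracle$arcs$to)
    expect_setequal(keys_got, keys_want)
  }
})

test_that("raising the cutoff never grows the network", {
  res <- default_run()
  W <- res$regomax$G_qr
  diag(W) <- 0
  levels <- stats::quantile(W[W > 1e-12], c(0.5, 0.8, 0.95, 0.99))
  edge_counts <- vapply(levels, function(l) sum(W > l), integer(1))
  lcc_sizes <- vapply(levels, function(l) {
    idx <- which(W > l, arr.ind = TRUE)
    graph_lcc(data.frame(from = idx[, "col"], to = idx[, "row"]))$n_nodes
  }, integer(1))
  expect_true(all(diff(edge_counts) <= 0))
  expect_true(all(diff(lcc_sizes) <= 0))
})

test_that("pipeline hidden network matches the direct connectivity regime", {
  res <- default_run()
  expect_lt(abs(res$hidden$lcc_ratio_hidden - res$hidden$lcc_ratio_direct) /
              res$hidden$lcc_ratio_direct, 0.10)
})

test_that("asymmetric hidden paths reciprocate less than imported direct links", {
  spec <- synthetic_spec(p_member_hub = 0.5, p_direct_reciprocal = 0.95, seed = 7)
  sg <- suppressMessages(generate_global_graph(spec))
  res <- suppressMessages(run_pipeline(sg))
  expect_lt(bidirectional_fraction(res$hidden),
            bidirectional_fraction(res$direct))
})

test_that("arc-level overlap counts and failure modes", {
  direct <- data.frame(from = c(0, 1), to = c(1, 2))
  hidden <- suppressMessages(select_cutoff(
    toy_regomax_matrix(matrix(c(0, 0, 0.3, 0.4, 0, 0, 0, 0.2, 0), 3, 3,
                              byrow = TRUE)),
    direct))
  stats_id <- link_overlap_stats(hidden, hidden)
  expect_equal(stats_id$frac_direct_also_hidden, 1)
  expect_equal(stats_id$direct_only, 0L)

  # direct {a->b, b->c}, hidden {b->c, c->a}: one shared arc
  d2 <- data.frame(from = c(0, 1), to = c(1, 2))
  h2 <- data.frame(from = c(1, 2), to = c(2, 0))
  st <- link_overlap_stats(d2, h2, subset = 0:2)
  expect_equal(st$direct_and_hidden, 1L)
  expect_equal(st$frac_direct_also_hidden, 0.5)

  disjoint <- link_overlap_stats(data.frame(from = 0, to = 1),
                                 data.frame(from = 1, to = 2), subset = 0:2)
  expect_equal(disjoint$direct_and_hidden, 0L)

  expect_error(link_overlap_stats(data.frame(from = 5, to = 6), h2, subset = 0:2),
               "same node subset")
})

test_that("degenerate inputs are rejected", {
  W <- matrix(0, 3, 3)
  expect_error(suppressMessages(
    select_cutoff(toy_regomax_matrix(W), data.frame(from = 0, to = 1))),
    "no positive")
  expect_error(suppressMessages(
    select_cutoff(toy_regomax_matrix(matrix(0.1, 3, 3)),
                  data.frame(from = integer(), to = integer()))),
    "zero edges|no edges")
})
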