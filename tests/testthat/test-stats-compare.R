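# explicit hypergeometric tail by summation, the enumeration oracle for the
# one-sided Fisher test on a pair universe
hyper_tail <- function(k, n_ref, n_wiki, universe) {
  kk <- k:min(n_ref, n_wiki)
  sum(exp(lchoose(n_ref, kk) + lchoose(universe - n_ref, n_wiki - kk) -
            lchoose(universe, n_wiki)))
}

make_pairs <- function(symbols, pair_idx) {
  combs <- utils::combn(symbols, 2)
  data.frame(symbol_a = combs[1, pair_idx], symbol_b = combs[2, pair_idx],
             type = "link")
}

test_that("full overlap on a 20-pair universe hits the exact point mass", {
  # |universe| = choose(20, 2)? No: the example universe is 20 pairs exactly,
  # so we force universe_n = 20 with 10 wiki = 10 ref = 10 matched pairs
  syms <- paste0("G", 1:10)
  wiki <- make_pairs(syms, 1:10)
  ref <- make_pairs(syms, 1:10)
  res <- overlap_and_fisher(wiki[, 1:2], ref, universe_n = 20)
  expect_equal(res$n_matched, 10L)
  expect_equal(res$p, 1 / choose(20, 10), tolerance = 1e-12)
})

test_that("no overlap in a large universe is not significant", {
  wiki <- data.frame(symbol_a = c("A", "B"), symbol_b = c("B", "C"))
  ref <- data.frame(symbol_a = "A", symbol_b = "C", type = "x")
  res <- overlap_and_fisher(wiki, ref, universe_n = 1e4)
  expect_gt(res$p, 0.99)
})

test_that("Fisher p equals explicit enumeration on small universes", {
  for (seed in 1:5) {
    cfg <- withr::with_seed(seed, {
      syms <- paste0("G", 1:12) # 66 unordered pairs
      list(wiki = make_pairs(syms, sample(66, 20)),
           ref = make_pairs(syms, sample(66, 15)))
    })
    res <- overlap_and_fisher(cfg$wiki[, 1:2], cfg$ref)
    expect_equal(res$p,
                 hyper_tail(res$n_matched, res$n_ref, res$n_wiki, res$universe_n),
                 tolerance = 1e-12)
    # agrees with R's own Fisher test on the 2x2 table
    tab <- matrix(c(res$n_matched, res$n_wiki - res$n_matched,
                    res$n_ref - res$n_matched,
                    res$universe_n - res$n_wiki - res$n_ref + res$n_matched),
                  2, 2)
    expect_equal(res$p, stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("degree correlations: exact values and the hand-computed case", {
  net <- data.frame(a = c("X", "Y", "Z", "X"), b = c("Y", "Z", "W", "Z"))
  expect_equal(degree_correlation(net, net), 1.0)

  # degrees (1,2,3) vs (3,2,1) and (1,2,3) vs (1,2,4), via explicit stubs
  chain <- function(counts, who) {
    # build a network in which node i has total degree counts[i]
    stubs <- rep(who, counts)
    data.frame(a = stubs, b = paste0("pad", seq_along(stubs)))
  }
  who <- c("P", "Q", "R")
  expect_equal(degree_correlation(chain(c(1, 2, 3), who),
                                  chain(c(3, 2, 1), who), shared_nodes = who),
               -1.0)
  r <- degree_correlation(chain(c(1, 2, 3), who), chain(c(1, 2, 4), who),
                          shared_nodes = who)
  # hand-evaluated Pearson sums: r = 5 / sqrt(2 * 14/3 * 3) -> 0.98198...
  expect_equal(r, 0.981980506, tolerance = 1e-8)

  expect_error(degree_correlation(chain(c(2, 2, 2), who), chain(c(1, 2, 3), who),
                                  shared_nodes = who), "constant")
})

test_that("relative type fractions normalize over retained types", {
  wiki <- data.frame(symbol_a = c("A", "A"), symbol_b = c("B", "C"))
  ref <- data.frame(symbol_a = c("A", "A", "A", "A", "B", "B", "B", "B", "B", "C"),
                    symbol_b = c("B", "C", "D", "E", "C", "D", "E", "F", "G", "D"),
                    type = c("t1", "t1", "t1", "t1", "t2", "t2", "t2", "t2", "t2", "t2"))
  # restricted to shared proteins {A,B,C}: t1 has {AB, AC}, t2 has {BC, CD?..}
  res <- suppressMessages(relative_type_fractions(wiki, ref))
  expect_equal(sum(res$f_rel), 1, tolerance = 1e-12)
  expect_equal(res$f[res$type == "t1"], 1) # both t1 pairs matched
  # f = (1, 0) -> f_rel = (1, 0)
  expect_equal(res$f_rel[res$type == "t1"], 1)

  one <- suppressMessages(relative_type_fractions(
    wiki, data.frame(symbol_a = "A", symbol_b = "B", type = "only")))
  expect_equal(one$f_rel, 1)
})

test_that("community enrichment: point mass, filters, BH monotonicity", {
  universe <- paste0("G", 1:1000)
  nodes <- data.frame(node_id = 0:19, title = paste0("T", 1:20),
                      is_protein = TRUE, symbol = paste0("G", 1:20))
  cl <- structure(list(communities = tibble::tibble(
    community_id = 1L, node_id = 0:19)), class = "mcl_clustering")
  sets <- list(exact_match = paste0("G", 1:20),
               half = paste0("G", c(1:4, 500:505)),
               unrelated = paste0("G", 900:940))
  res <- enrich_communities(cl, sets, universe, nodes)
  pm <- res[res$term == "exact_match", ]
  expect_equal(pm$p, exp(-lchoose(1000, 20)), tolerance = 1e-9)
  expect_true(pm$selected)
  # overlap 4 < 5 is never selected, whatever its p
  expect_false(res$selected[res$term == "half"])
  # BH q non-decreasing along sorted p
  srt <- res[order(res$p), ]
  expect_true(all(diff(srt$q) >= -1e-15))
  expect_true(all(res$q >= res$p - 1e-15))

  expect_error(enrich_communities(cl, list(), universe, nodes), "empty")
})

test_that("planted gene sets are recovered as the top term", {
  res <- default_run()
  sg <- default_graph()
  nodes <- sg$graph$nodes
  truth <- sg$ground_truth
  universe <- nodes$symbol[nodes$is_protein]
  sets <- lapply(split(truth$node_id, truth$community_id), function(ids) {
    nodes$symbol[ids + 1L]
  })
  names(sets) <- paste0("planted_", names(sets))
  enr <- enrich_communities(res$clustering, sets, universe, nodes)
  top1 <- enr |>
    dplyr::group_by(community_id) |>
    dplyr::slice_min(p, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  # the top term of (nearly) every recovered community is its planted set
  hits <- vapply(seq_len(nrow(top1)), function(i) {
    members <- res$clustering$communities$node_id[
      res$clustering$communities$community_id == top1$community_id[i]]
    planted <- unique(truth$community_id[match(members, truth$node_id)])
    top1$term[i] == paste0("planted_", planted)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("title-to-symbol arc mapping drops unmapped endpoints", {
  nodes <- data.frame(node_id = 0:2, title = c("A", "B", "C"),
                      is_protein = TRUE, symbol = c("GA", "GB", NA))
  out <- suppressMessages(
    map_arcs_to_symbols(data.frame(from = c(0, 1), to = c(1, 2)), nodes))
  expect_equal(nrow(out), 1L)
  expect_equal(attr(out, "n_unmapped_arcs"), 1L)
  expect_equal(out$symbol_a, "GA")
})
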