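#' Link persistence between two snapshots
#'
#' Fraction of the old snapshot's arcs, restricted to nodes present in both
#' snapshots, that are still present in the new snapshot. The denominator is
#' the old link set: the statistic reads "how many existing links did not
#' change".
#'
#' @param net_old,net_new arcs (`from`, `to` data frames, graphs, or hidden
#'   networks).
#' @param shared_nodes node ids present in both snapshots; defaults to the
#'   union of endpoints seen in both arc sets.
#' @param undirected collapse arcs to unordered links before comparing.
#'   Default FALSE (arcs).
#' @return Fraction in `[0, 1]`.
#' @export
link_persistence <- function(net_old, net_new, shared_nodes = NULL,
                             undirected = FALSE) {
  old <- edges_of(net_old)
  new <- edges_of(net_new)
  shared_nodes <- shared_nodes %||%
    intersect(unique(c(old$from, old$to)), unique(c(new$from, new$to)))
  old <- old[old$from %in% shared_nodes & old$to %in% shared_nodes, ]
  new <- new[new$from %in% shared_nodes & new$to %in% shared_nodes, ]
  if (nrow(old) == 0L) abort("old snapshot has no arcs among the shared nodes.")
  key <- function(e) {
    if (undirected) unique(pair_keys(e$from, e$to, directed = FALSE))
    else unique(paste(e$from, e$to, sep = "\r"))
  }
  ok <- key(old)
  mean(ok %in% key(new))
}

#' PageRank-rank fold changes between snapshots
#'
#' Compares the rank index `K` (1 = most probable) of each node across two
#' PageRank vectors. A node *improved* when `K_old / K_new > fold` (it moved
#' up the ranking) and *worsened* when `K_new / K_old > fold`. Nodes missing
#' from either snapshot are excluded with a message. Folds on the
#' probabilities instead of the ranks are available with `on = "prob"`.
#'
#' @param pr_old,pr_new [pagerank()] results, [reduced_pagerank()] tibbles,
#'   or any data frames with `node_id`, `k` (and `p` for `on = "prob"`).
#' @param fold fold-change threshold (> 1). Default 2.
#' @param on `"rank"` (default) or `"prob"`.
#' @return Tibble `node_id`, `k_old`, `k_new`, `ratio`, `status`
#'   (`"improved"`, `"worsened"`, `"stable"`), with attribute `n_excluded`.
#' @export
rank_fold_changes <- function(pr_old, pr_new, fold = 2, on = c("rank", "prob")) {
  on <- match.arg(on)
  if (!is.numeric(fold) || fold <= 1) abort("`fold` must be > 1.")
  tab <- function(x) if (inherits(x, "pagerank")) x$table else as_tibble(x)
  old <- tab(pr_old)
  new <- tab(pr_new)
  joined <- inner_join(old, new, by = "node_id", suffix = c("_old", "_new"))
  n_excluded <- nrow(old) + nrow(new) - 2L * nrow(joined)
  if (n_excluded > 0L) {
    inform(sprintf("excluded %d node(s) missing from one of the snapshots", n_excluded))
  }
  ratio <- if (on == "rank") joined$k_old / joined$k_new
  else joined$p_new / joined$p_old
  out <- tibble(node_id = joined$node_id,
                k_old = joined$k_old, k_new = joined$k_new, ratio = ratio,
                status = ifelse(ratio > fold, "improved",
                                ifelse(1 / ratio > fold, "worsened", "stable")))
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Match communities across snapshots by reciprocal-best Jaccard
#'
#' Jaccard index `J(a, b) = |a n b| / |a u b|` over the nodes shared by the
#' two snapshots; a pair is matched iff `J(a, b)` is strictly the maximum of
#' row `a` *and* of column `b` (ties yield no match, conservatively) and the
#' intersection holds at least `min_intersection` nodes — the
#' reciprocal-best-hit rule used for orthologs.
#'
#' @param cl_old,cl_new [mcl_cluster()] results (or tibbles `community_id`,
#'   `node_id`).
#' @param min_intersection minimum shared members per match. Default 3.
#' @return Tibble `old`, `new`, `jaccard`, `intersection` (both judged over
#'   the shared nodes), `size_old`, `size_new` (full community sizes).
#' @export
match_communities <- function(cl_old, cl_new, min_intersection = 3L) {
  min_intersection <- assert_count(min_intersection, "min_intersection", min = 1L)
  memb <- function(x) {
    if (inherits(x, "mcl_clustering")) x$communities else as_tibble(x)
  }
  old <- memb(cl_old)
  new <- memb(cl_new)
  if (nrow(old) == 0L || nrow(new) == 0L) abort("empty clustering.")
  size_old_full <- table(old$community_id)
  size_new_full <- table(new$community_id)
  # similarity is judged on the nodes both snapshots know; reported sizes
  # are the full community sizes, so growth is visible
  shared <- intersect(old$node_id, new$node_id)
  old <- old[old$node_id %in% shared, ]
  new <- new[new$node_id %in% shared, ]
  olds <- split(old$node_id, old$community_id)
  news <- split(new$node_id, new$community_id)
  J <- matrix(0, length(olds), length(news),
              dimnames = list(names(olds), names(news)))
  I <- J
  for (a in seq_along(olds)) {
    for (b in seq_along(news)) {
      inter <- length(intersect(olds[[a]], news[[b]]))
      I[a, b] <- inter
      J[a, b] <- inter / length(union(olds[[a]], news[[b]]))
    }
  }
  matches <- list()
  for (a in seq_len(nrow(J))) {
    row_max <- max(J[a, ])
    if (row_max == 0) next
    b_best <- which(J[a, ] == row_max)
    if (length(b_best) != 1L) next      # tied row maximum: no match
    col_max <- max(J[, b_best])
    if (J[a, b_best] < col_max) next
    if (sum(J[, b_best] == col_max) != 1L) next # tied column maximum
    if (I[a, b_best] < min_intersection) next
    matches[[length(matches) + 1L]] <- tibble(
      old = as.integer(rownames(J)[a]),
      new = as.integer(colnames(J)[b_best]),
      jaccard = J[a, b_best], intersection = as.integer(I[a, b_best]),
      size_old = as.integer(size_old_full[[names(olds)[a]]]),
      size_new = as.integer(size_new_full[[names(news)[b_best]]]))
  }
  if (length(matches) == 0L) {
    return(tibble(old = integer(), new = integer(), jaccard = numeric(),
                  intersection = integer(), size_old = integer(),
                  size_new = integer()))
  }
  bind_rows(matches)
}

#' Full two-snapshot comparison
#'
#' Bundles link persistence (direct and hidden), PageRank-rank fold
#' changes, and reciprocal-Jaccard community matching between the pipeline
#' results of two snapshots of the same graph.
#'
#' @param res_old,res_new [run_pipeline()] results for the old/new snapshot.
#' @param fold rank fold-change threshold. Default 2.
#' @param min_intersection community-match threshold. Default 3.
#' @return An object of class `snapshot_comparison`: `persistence` (named
#'   list `direct`, `hidden`), `rank_folds` tibble, `matches` tibble.
#' @export
compare_snapshots <- function(res_old, res_new, fold = 2, min_intersection = 3L) {
  stopifnot(inherits(res_old, "pipeline_result"),
            inherits(res_new, "pipeline_result"))
  shared <- intersect(res_old$subset, res_new$subset)
  persistence <- list(
    direct = link_persistence(res_old$direct, res_new$direct, shared),
    hidden = link_persistence(res_old$hidden, res_new$hidden, shared)
  )
  pr_old <- reduced_pagerank(res_old$regomax)
  pr_new <- reduced_pagerank(res_new$regomax)
  folds <- suppressMessages(
    rank_fold_changes(pr_old[pr_old$node_id %in% shared, ],
                      pr_new[pr_new$node_id %in% shared, ], fold = fold))
  matches <- match_communities(res_old$clustering, res_new$clustering,
                               min_intersection = min_intersection)
  structure(list(persistence = persistence, rank_folds = folds,
                 matches = matches),
            class = "snapshot_comparison")
}

#' @export
print.snapshot_comparison <- function(x, ...) {
  cat(sprintf("<snapshot_comparison> persistence: direct %.3f, hidden %.3f\n",
              x$persistence$direct, x$persistence$hidden))
  cat(sprintf("  %d improved / %d worsened node(s); %d matched community pair(s)\n",
              sum(x$rank_folds$status == "improved"),
              sum(x$rank_folds$status == "worsened"), nrow(x$matches)))
  invisible(x)
}

#' Write a snapshot comparison report
#'
#' JSON report (persistence, improved/worsened counts, matches) plus an
#' optional TSV of per-node rank folds.
#'
#' @param sc a [compare_snapshots()] result.
#' @param json_path destination JSON.
#' @param folds_path optional TSV of rank folds.
#' @export
write_snapshot_comparison <- function(sc, json_path, folds_path = NULL) {
  stopifnot(inherits(sc, "snapshot_comparison"))
  jsonlite::write_json(
    list(persistence = sc$persistence,
         n_improved = sum(sc$rank_folds$status == "improved"),
         n_worsened = sum(sc$rank_folds$status == "worsened"),
         matches = sc$matches),
    json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(folds_path)) {
    utils::write.table(sc$rank_folds, folds_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(sc)
}
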