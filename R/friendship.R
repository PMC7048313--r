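#' Augmented ("friendship") network of a community
#'
#' For every hidden link `a -> b` inside a community, collects all pages `v`
#' of the global graph mediating an oriented length-2 path `a -> v -> b`.
#' Mediators outside the community become *associated* nodes; the arcs
#' `a -> v` and `v -> b` of every mediating path, plus any direct arcs
#' `a -> b` between community members, form the augmented network. The
#' degree ranking of the associated nodes is what names the community.
#'
#' @param g the global [hl_graph()].
#' @param community integer vector of member node ids.
#' @param hidden_links data frame `from`, `to` of hidden arcs, endpoints
#'   inside `community`.
#' @return An object of class `friendship_network`: `protein_nodes`,
#'   `associated_nodes`, `edges` (tibble `from`, `to`, subset of the global
#'   arcs), `degree` (tibble `node_id`, `degree`, `role`), `paths` (tibble
#'   `from`, `via`, `to`, one row per mediating path).
#' @export
build_friendship_network <- function(g, community, hidden_links) {
  stopifnot(inherits(g, "hlgraph"))
  community <- as.integer(community)
  if (length(community) == 0L) abort("`community` is empty.")
  hidden_links <- edges_of(hidden_links)
  if (!all(c(hidden_links$from, hidden_links$to) %in% community)) {
    abort("hidden link endpoints must lie inside the community.")
  }
  out_nb <- split(g$edges$to, factor(g$edges$from, levels = community))
  in_nb <- split(g$edges$from, factor(g$edges$to, levels = community))
  paths <- purrr::pmap_dfr(hidden_links[, c("from", "to")], function(from, to) {
    via <- intersect(out_nb[[as.character(from)]], in_nb[[as.character(to)]])
    via <- setdiff(via, c(from, to))
    if (length(via) == 0L) return(NULL)
    tibble(from = from, via = via, to = to)
  })
  if (nrow(paths) == 0L) {
    paths <- tibble(from = integer(), via = integer(), to = integer())
  }
  direct <- g$edges[g$edges$from %in% community & g$edges$to %in% community, ]
  dk <- semi_join(direct, hidden_links, by = c("from", "to"))
  path_edges <- bind_rows(
    tibble(from = paths$from, to = paths$via),
    tibble(from = paths$via, to = paths$to),
    dk
  )
  edges <- distinct(path_edges, .data$from, .data$to)
  associated <- sort(setdiff(unique(paths$via), community))
  all_nodes <- sort(unique(c(community, associated)))
  deg <- tabulate(match(edges$from, all_nodes), nbins = length(all_nodes)) +
    tabulate(match(edges$to, all_nodes), nbins = length(all_nodes))
  degree <- tibble(node_id = all_nodes, degree = deg,
                   role = ifelse(all_nodes %in% community, "protein", "associated"))
  structure(
    list(protein_nodes = sort(community), associated_nodes = associated,
         edges = edges, degree = degree, paths = paths),
    class = "friendship_network"
  )
}

#' @export
print.friendship_network <- function(x, ...) {
  cat(sprintf("<friendship_network> %d protein + %d associated node(s), %d arcs\n",
              length(x$protein_nodes), length(x$associated_nodes), nrow(x$edges)))
  invisible(x)
}

#' Label a community from its friendship network
#'
#' The community label is the title of the most connected associated page in
#' the augmented network; the top `top_k` candidates are returned to support
#' manual overrides. Degree ties break lexicographically by title. A
#' community with no associated pages is labeled by its most connected
#' member and flagged as self-labeled.
#'
#' @param fn a [build_friendship_network()] result.
#' @param nodes node table (as in [hl_graph()]) carrying titles.
#' @param top_k number of ranked candidates to return. Default 10.
#' @return A list: `label`, `candidates` (tibble `node_id`, `title`,
#'   `degree`, `is_protein`), `self_labeled`.
#' @export
label_community <- function(fn, nodes, top_k = 10L) {
  stopifnot(inherits(fn, "friendship_network"))
  nodes <- validate_node_table(nodes, nrow(as_tibble(nodes)))
  pool_role <- if (length(fn$associated_nodes) > 0L) "associated" else "protein"
  pool <- fn$degree[fn$degree$role == pool_role, , drop = FALSE]
  pool <- left_join(pool, nodes[, c("node_id", "title", "is_protein")],
                    by = "node_id")
  pool <- arrange(pool, desc(.data$degree), .data$title)
  cand <- head(pool, top_k)
  list(label = cand$title[1L],
       candidates = select(cand, "node_id", "title", "degree", "is_protein"),
       self_labeled = pool_role == "protein")
}

#' Build, label, and summarize all communities of a clustering
#'
#' Convenience wrapper: one friendship network and label per community.
#'
#' @param g the global [hl_graph()] (its node table provides titles).
#' @param cl a [mcl_cluster()] result.
#' @param hidden a [select_cutoff()] result supplying the hidden arcs.
#' @param top_k candidates kept per community.
#' @return Tibble `community_id`, `label`, `n_proteins`, `n_hidden_links`,
#'   `n_associated`, `self_labeled`.
#' @export
label_communities <- function(g, cl, hidden, top_k = 10L) {
  stopifnot(inherits(cl, "mcl_clustering"))
  hidden_edges <- edges_of(hidden)
  purrr::map_dfr(unique(cl$communities$community_id), function(cid) {
    members <- cl$communities$node_id[cl$communities$community_id == cid]
    links <- hidden_edges[hidden_edges$from %in% members &
                            hidden_edges$to %in% members, , drop = FALSE]
    fn <- build_friendship_network(g, members, links)
    lab <- label_community(fn, g$nodes, top_k = top_k)
    tibble(community_id = cid, label = lab$label,
           n_proteins = length(members), n_hidden_links = nrow(links),
           n_associated = length(fn$associated_nodes),
           self_labeled = lab$self_labeled)
  })
}

#' Abstracted community-of-communities graph
#'
#' Counts the oriented hidden arcs running between members of different
#' communities, yielding the abstracted map of inter-community connections.
#'
#' @param cl a [mcl_cluster()] result.
#' @param hidden a [select_cutoff()] result (thresholded hidden arcs).
#' @return Tibble `comm_a`, `comm_b`, `n_hidden_links` (arcs from members of
#'   `comm_a` to members of `comm_b`, `comm_a != comm_b`).
#' @export
community_graph <- function(cl, hidden) {
  stopifnot(inherits(cl, "mcl_clustering"))
  hidden_edges <- edges_of(hidden)
  lut <- setNames(cl$communities$community_id, cl$communities$node_id)
  ca <- lut[as.character(hidden_edges$from)]
  cb <- lut[as.character(hidden_edges$to)]
  keep <- !is.na(ca) & !is.na(cb) & ca != cb
  if (!any(keep)) return(tibble(comm_a = integer(), comm_b = integer(),
                                n_hidden_links = integer()))
  count(tibble(comm_a = as.integer(ca[keep]), comm_b = as.integer(cb[keep])),
        .data$comm_a, .data$comm_b, name = "n_hidden_links")
}

#' Shortest oriented path lengths over sampled node pairs
#'
#' Breadth-first search from each source in the global directed graph;
#' unreachable targets land in a separate `Inf` bin. Pairs are either given
#' explicitly or sampled: endpoints of hidden links, random marked
#' (protein) pairs, or random page pairs.
#'
#' @param g the global [hl_graph()].
#' @param pairs explicit pairs (`from`, `to` data frame) for
#'   `pair_kind = "explicit"`.
#' @param pair_kind one of `"explicit"`, `"random_protein"`, `"random_any"`,
#'   `"hidden_link_endpoints"`.
#' @param n_pairs number of sampled pairs (ignored for explicit pairs).
#' @param seed sampling seed. Default 42.
#' @param hidden a [select_cutoff()] result, required for
#'   `"hidden_link_endpoints"`.
#' @return An object of class `path_histogram`: tibble `length` (numeric,
#'   `Inf` for unreachable), `n`, with attributes `n_pairs` and `pair_kind`.
#' @export
sampled_shortest_paths <- function(g, pairs = NULL,
                                   pair_kind = c("explicit", "random_protein",
                                                 "random_any",
                                                 "hidden_link_endpoints"),
                                   n_pairs = 1000L, seed = 42L, hidden = NULL) {
  stopifnot(inherits(g, "hlgraph"))
  pair_kind <- match.arg(pair_kind)
  if (pair_kind != "explicit") n_pairs <- assert_count(n_pairs, "n_pairs", min = 1L)
  pairs <- switch(
    pair_kind,
    explicit = {
      if (is.null(pairs)) abort("explicit `pairs` required.")
      as_tibble(pairs)[, c("from", "to")]
    },
    random_protein = with_seed(seed, {
      prot <- protein_nodes(g)
      tibble(from = sample(prot, n_pairs, replace = TRUE),
             to = sample(prot, n_pairs, replace = TRUE))
    }),
    random_any = with_seed(seed, {
      tibble(from = sample.int(g$n, n_pairs, replace = TRUE) - 1L,
             to = sample.int(g$n, n_pairs, replace = TRUE) - 1L)
    }),
    hidden_link_endpoints = {
      if (is.null(hidden)) abort("`hidden` network required for hidden_link_endpoints.")
      he <- edges_of(hidden)
      with_seed(seed, he[sample.int(nrow(he), min(n_pairs, nrow(he))), c("from", "to")])
    }
  )
  pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  if (nrow(pairs) == 0L) abort("no valid (distinct-endpoint) pairs to measure.")
  gi <- as_igraph_edges(g$edges, node_ids = seq_len(g$n) - 1L)
  lens <- numeric(nrow(pairs))
  for (src in unique(pairs$from)) {
    rows <- which(pairs$from == src)
    targets <- unique(pairs$to[rows])
    d <- igraph::distances(gi, v = as.character(src),
                           to = as.character(targets), mode = "out")
    lens[rows] <- d[1L, match(as.character(pairs$to[rows]), colnames(d))]
  }
  hist <- count(tibble(length = lens), .data$length, name = "n")
  structure(hist, class = c("path_histogram", class(hist)),
            n_pairs = nrow(pairs), pair_kind = pair_kind)
}

#' Modal shortest-path length of a histogram
#'
#' @param hist a [sampled_shortest_paths()] result.
#' @return The most frequent path length (ties break toward the shorter
#'   length); may be `Inf` when most pairs are unreachable.
#' @export
modal_path_length <- function(hist) {
  stopifnot(inherits(hist, "path_histogram"))
  hist$length[which.max(hist$n)]
}
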