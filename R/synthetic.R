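#' Specification of a synthetic Wikipedia-like graph
#'
#' Defines the generative model used for end-to-end validation: a sparse
#' random background of "ordinary pages", plus planted protein communities.
#' Each community owns one or more background "topic hub" pages; members
#' link to their hubs and hubs back to members, creating oriented length-2
#' protein -> hub -> protein paths (the substrate of hidden links). Members
#' are also connected by sparser direct arcs, partially reciprocated to
#' emulate interaction lists imported as unordered pairs. Hubs link to other
#' hubs, which gives distinct communities finite (length >= 3) oriented
#' paths between their members and a community-of-communities structure.
#' Proteins additionally emit arcs into the random background.
#'
#' @param n_background number of background pages. Default 2000.
#' @param n_communities number of planted communities. Default 12.
#' @param proteins_per_community members per community (single count or one
#'   count per community). Default 10.
#' @param hubs_per_community topic hubs per community. Default 1.
#' @param p_member_hub probability of each member -> hub and hub -> member
#'   arc (drawn independently). Default 0.9.
#' @param p_direct probability of each ordered direct member -> member arc.
#'   Default 0.15.
#' @param p_background_edge probability of each ordered background ->
#'   background arc. Default 0.002.
#' @param p_cross probability of each protein -> background arc.
#'   Default 0.01.
#' @param p_hub_hub probability of each ordered hub -> hub arc. Default 0.3.
#' @param p_direct_reciprocal probability that a drawn direct arc also gets
#'   its reciprocal. Default 0.5.
#' @param seed integer seed; the generator consumes one private stream fully
#'   determined by it. Default 42.
#' @return A validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_background = 2000L, n_communities = 12L,
                           proteins_per_community = 10L,
                           hubs_per_community = 1L,
                           p_member_hub = 0.9, p_direct = 0.15,
                           p_background_edge = 0.002, p_cross = 0.01,
                           p_hub_hub = 0.3, p_direct_reciprocal = 0.5,
                           seed = 42L) {
  n_background <- assert_count(n_background, "n_background", min = 1L)
  n_communities <- assert_count(n_communities, "n_communities", min = 0L)
  hubs_per_community <- assert_count(hubs_per_community, "hubs_per_community", min = 1L)
  seed <- assert_count(seed, "seed")
  if (length(proteins_per_community) == 1L) {
    proteins_per_community <- rep(as.integer(proteins_per_community), n_communities)
  }
  if (length(proteins_per_community) != n_communities ||
      (n_communities > 0L && any(proteins_per_community < 1L))) {
    abort("`proteins_per_community` must give one positive count per community.")
  }
  for (p in c("p_member_hub", "p_direct", "p_background_edge", "p_cross",
              "p_hub_hub", "p_direct_reciprocal")) {
    assert_prob(get(p), p)
  }
  structure(list(n_background = n_background, n_communities = n_communities,
                 proteins_per_community = proteins_per_community,
                 hubs_per_community = hubs_per_community,
                 p_member_hub = p_member_hub, p_direct = p_direct,
                 p_background_edge = p_background_edge, p_cross = p_cross,
                 p_hub_hub = p_hub_hub,
                 p_direct_reciprocal = p_direct_reciprocal, seed = seed),
            class = "synthetic_spec")
}

# sample m ordered pairs without replacement from the (n_from x n_to) pair
# space excluding the diagonal when `from` and `to` index the same set
sample_pairs <- function(from_ids, to_ids, p, same_set = FALSE) {
  nf <- length(from_ids)
  nt <- length(to_ids)
  total <- nf * nt - if (same_set) nf else 0L
  if (total <= 0L || p == 0) return(tibble(from = integer(), to = integer()))
  m <- stats::rbinom(1L, total, p)
  if (m == 0L) return(tibble(from = integer(), to = integer()))
  idx <- sample.int(total, m) - 1L
  if (same_set) {
    # index the n*(n-1) off-diagonal cells row-wise
    i <- idx %/% (nt - 1L)
    j <- idx %% (nt - 1L)
    j <- ifelse(j >= i, j + 1L, j)
  } else {
    i <- idx %/% nt
    j <- idx %% nt
  }
  tibble(from = from_ids[i + 1L], to = to_ids[j + 1L])
}

synthetic_layout <- function(spec) {
  P <- sum(spec$proteins_per_community)
  H <- spec$n_communities * spec$hubs_per_community
  N <- P + H + spec$n_background
  comm_of_protein <- rep(seq_len(spec$n_communities), spec$proteins_per_community)
  list(P = P, H = H, N = N,
       proteins = seq_len(P) - 1L,
       hubs = if (H > 0L) P + seq_len(H) - 1L else integer(),
       background = if (spec$n_background > 0L) P + H + seq_len(spec$n_background) - 1L
       else integer(),
       comm_of_protein = comm_of_protein,
       comm_of_hub = rep(seq_len(spec$n_communities),
                         each = spec$hubs_per_community))
}

synthetic_nodes <- function(spec, lay) {
  tibble(
    node_id = seq_len(lay$N) - 1L,
    title = c(sprintf("Protein_%04d", lay$proteins),
              sprintf("Topic_%d", seq_along(lay$hubs)),
              sprintf("Page_%05d", seq_along(lay$background))),
    is_protein = c(rep(TRUE, lay$P), rep(FALSE, lay$H + spec$n_background)),
    symbol = c(sprintf("GENE%04d", lay$proteins),
               rep(NA_character_, lay$H + spec$n_background))
  )
}

draw_member_hub <- function(members, hubs, p) {
  grid <- expand.grid(m = members, h = hubs)
  to_hub <- grid[stats::runif(nrow(grid)) < p, , drop = FALSE]
  from_hub <- grid[stats::runif(nrow(grid)) < p, , drop = FALSE]
  bind_rows(tibble(from = to_hub$m, to = to_hub$h),
            tibble(from = from_hub$h, to = from_hub$m))
}

draw_direct <- function(members, p, p_recip) {
  arcs <- sample_pairs(members, members, p, same_set = TRUE)
  recip <- arcs[stats::runif(nrow(arcs)) < p_recip, c("to", "from")]
  names(recip) <- c("from", "to")
  bind_rows(arcs, recip)
}

#' Generate a synthetic global graph with planted communities
#'
#' Draws one graph from a [synthetic_spec()] model: deterministic under the
#' spec's seed, with ground-truth labels for every protein node and a known
#' hub (titled `Topic_<community>`) per community.
#'
#' @param spec a [synthetic_spec()].
#' @return An object of class `synthetic_graph`: `graph` (a [hl_graph()]
#'   with node table), `ground_truth` (tibble `node_id`, `community_id`),
#'   `hubs` (tibble `community_id`, `hub_id`, `title`), `spec`.
#' @export
generate_global_graph <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, generate_graph_impl(spec))
}

generate_graph_impl <- function(spec, lay = synthetic_layout(spec)) {
  parts <- list(
    sample_pairs(lay$background, lay$background, spec$p_background_edge,
                 same_set = TRUE),
    sample_pairs(lay$proteins, lay$background, spec$p_cross)
  )
  if (spec$n_communities > 0L) {
    for (c_id in seq_len(spec$n_communities)) {
      members <- lay$proteins[lay$comm_of_protein == c_id]
      hubs <- lay$hubs[lay$comm_of_hub == c_id]
      parts[[length(parts) + 1L]] <- draw_member_hub(members, hubs, spec$p_member_hub)
      parts[[length(parts) + 1L]] <- draw_direct(members, spec$p_direct,
                                                 spec$p_direct_reciprocal)
    }
    parts[[length(parts) + 1L]] <- sample_pairs(lay$hubs, lay$hubs,
                                                spec$p_hub_hub, same_set = TRUE)
  }
  edges <- bind_rows(parts)
  nodes <- synthetic_nodes(spec, lay)
  graph <- hl_graph(edges, n = lay$N, nodes = nodes)
  if (spec$n_communities > 0L) {
    n_protein_arcs <- sum(graph$edges$from %in% lay$proteins |
                            graph$edges$to %in% lay$proteins)
    if (n_protein_arcs == 0L) abort("spec produced a graph with zero protein arcs.")
  }
  structure(
    list(graph = graph,
         ground_truth = tibble(node_id = lay$proteins,
                               community_id = lay$comm_of_protein),
         hubs = tibble(community_id = lay$comm_of_hub, hub_id = lay$hubs,
                       title = nodes$title[lay$hubs + 1L]),
         spec = spec),
    class = "synthetic_graph"
  )
}

#' @export
print.synthetic_graph <- function(x, ...) {
  cat(sprintf("<synthetic_graph> %d communities planted in a %d-node graph\n",
              x$spec$n_communities, x$graph$n))
  print(x$graph)
  invisible(x)
}

#' Generate a pair of evolving snapshots
#'
#' Produces an old snapshot from the spec and a new one derived from it by
#' (i) rewiring a fraction of the hub-incident arcs (retargeting them into
#' the random background — the "associated pages" churn), (ii) rewiring a
#' smaller fraction of the direct protein arcs, and (iii) growing each
#' community by a factor `growth` with new members wired like original ones.
#' Both snapshots and the perturbation are drawn from one stream determined
#' by the spec's seed; the old snapshot is identical to
#' [generate_global_graph()] on the same spec.
#'
#' @param spec a [synthetic_spec()].
#' @param rewire_hub_frac fraction of hub-incident arcs rewired. Default 0.3.
#' @param rewire_direct_frac fraction of direct protein arcs rewired.
#'   Default 0.05.
#' @param growth community size multiplier (>= 1). Default 1.2.
#' @return A list of class `snapshot_pair`: `old` and `new`
#'   ([generate_global_graph()]-style objects) and `params`.
#' @export
generate_snapshot_pair <- function(spec, rewire_hub_frac = 0.3,
                                   rewire_direct_frac = 0.05, growth = 1.2) {
  stopifnot(inherits(spec, "synthetic_spec"))
  assert_prob(rewire_hub_frac, "rewire_hub_frac")
  assert_prob(rewire_direct_frac, "rewire_direct_frac")
  if (!is.numeric(growth) || growth < 1) abort("`growth` must be >= 1.")
  with_seed(spec$seed, {
    lay <- synthetic_layout(spec)
    old <- generate_graph_impl(spec, lay)
    new <- perturb_snapshot(old, lay, rewire_hub_frac, rewire_direct_frac, growth)
    structure(list(old = old, new = new,
                   params = list(rewire_hub_frac = rewire_hub_frac,
                                 rewire_direct_frac = rewire_direct_frac,
                                 growth = growth)),
              class = "snapshot_pair")
  })
}

perturb_snapshot <- function(old, lay, rewire_hub_frac, rewire_direct_frac,
                             growth) {
  spec <- old$spec
  edges <- old$graph$edges
  is_hub_arc <- edges$from %in% lay$hubs | edges$to %in% lay$hubs
  is_direct <- edges$from %in% lay$proteins & edges$to %in% lay$proteins
  rewire <- function(edges, which_rows, frac) {
    n_rw <- round(frac * length(which_rows))
    if (n_rw == 0L) return(edges)
    rows <- sample(which_rows, n_rw)
    # retarget into the random background, keeping the source
    edges$to[rows] <- sample(lay$background, n_rw, replace = TRUE)
    edges
  }
  edges <- rewire(edges, which(is_hub_arc), rewire_hub_frac)
  edges <- rewire(edges, which(is_direct), rewire_direct_frac)

  # community growth: append new members, wired like the originals
  truth <- old$ground_truth
  hubs <- old$hubs
  nodes <- old$graph$nodes
  next_id <- old$graph$n
  new_rows <- list()
  if (growth > 1 && spec$n_communities > 0L) {
    for (c_id in seq_len(spec$n_communities)) {
      members <- truth$node_id[truth$community_id == c_id]
      n_new <- round((growth - 1) * length(members))
      if (n_new == 0L) next
      ids <- next_id + seq_len(n_new) - 1L
      next_id <- next_id + n_new
      chubs <- hubs$hub_id[hubs$community_id == c_id]
      all_members <- c(members, ids)
      new_rows[[length(new_rows) + 1L]] <- bind_rows(
        draw_member_hub(ids, chubs, spec$p_member_hub),
        draw_direct_growth(ids, all_members, spec$p_direct,
                           spec$p_direct_reciprocal),
        sample_pairs(ids, lay$background, spec$p_cross)
      )
      truth <- bind_rows(truth, tibble(node_id = ids, community_id = c_id))
      nodes <- bind_rows(nodes,
                         tibble(node_id = ids,
                                title = sprintf("Protein_%04d", ids),
                                is_protein = TRUE,
                                symbol = sprintf("GENE%04d", ids)))
    }
  }
  edges <- bind_rows(c(list(edges), new_rows))
  nodes <- arrange(nodes, .data$node_id)
  nodes$node_id <- seq_len(nrow(nodes)) - 1L # ids were already dense, appended at the end
  graph <- hl_graph(edges, n = next_id, nodes = nodes)
  structure(list(graph = graph, ground_truth = truth, hubs = hubs, spec = spec),
            class = "synthetic_graph")
}

# direct arcs touching at least one new member
draw_direct_growth <- function(new_ids, all_members, p, p_recip) {
  old_ids <- setdiff(all_members, new_ids)
  arcs <- bind_rows(
    sample_pairs(new_ids, old_ids, p),
    sample_pairs(old_ids, new_ids, p),
    sample_pairs(new_ids, new_ids, p, same_set = TRUE)
  )
  recip <- arcs[stats::runif(nrow(arcs)) < p_recip, c("to", "from")]
  names(recip) <- c("from", "to")
  bind_rows(arcs, recip)
}

#' Write the ground truth of a synthetic graph
#'
#' @param sg a [generate_global_graph()] result.
#' @param path destination TSV (`node_id`, `community_id`).
#' @export
write_ground_truth <- function(sg, path) {
  stopifnot(inherits(sg, "synthetic_graph"))
  utils::write.table(sg$ground_truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(sg)
}
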