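#' Hidden-link network by connectivity-matched thresholding
#'
#' Extracts the network of strong hidden links from the indirect component
#' `G_qr` of a reduced Google matrix. Entries below every candidate cutoff
#' are swept (descending through the distinct off-diagonal weights) and, at
#' each cutoff, the connectivity ratio — nodes divided by edges — of the
#' largest weakly connected component is computed incrementally. The returned
#' cutoff is the one whose ratio is closest to the same ratio of the direct
#' network's largest component; ties break toward the larger cutoff (fewer
#' edges). This calibrates the hidden network to the same sparsity regime as
#' the direct one without fixing an arbitrary weight scale.
#'
#' Tiny negative `G_qr` entries (numerical round-off) and weights below
#' `1e-12` are clamped to zero before candidate enumeration; the clamped mass
#' is recorded. The diagonal is excluded unless `keep_diagonal = TRUE`
#' (self-transitions are not connections between distinct proteins).
#'
#' @param rg a [reduce_google_matrix()] result (its `G_qr` is thresholded),
#'   or a bare non-negative matrix with node ids as dimnames.
#' @param direct arcs of the direct network on the same subset: a
#'   [hl_graph()], a hidden network, or a `from`/`to` data frame.
#' @param keep_diagonal keep self-weights as candidate links. Default FALSE.
#' @return An object of class `hidden_network`: `edges`
#'   (tibble `from`, `to`, `weight`, all weights > `cutoff`), `cutoff`,
#'   `lcc_ratio_direct`, `lcc_ratio_hidden`, `clamped_mass`, `subset`,
#'   `provenance = "hidden"`.
#' @export
select_cutoff <- function(rg, direct, keep_diagonal = FALSE) {
  if (inherits(rg, "regomax")) {
    W <- rg$G_qr
    subset <- rg$subset
  } else {
    W <- as.matrix(rg)
    if (is.null(rownames(W))) abort("matrix input needs node ids as dimnames.")
    subset <- as.integer(rownames(W))
  }
  nr <- nrow(W)
  clamped <- sum(abs(W[W < 1e-12]))
  W[W < 1e-12] <- 0
  if (clamped > 0) {
    inform(sprintf("clamped %.3e of (near-)zero or negative G_qr mass before thresholding",
                   clamped))
  }
  if (!keep_diagonal) diag(W) <- 0
  direct_edges <- edges_of(direct)
  if (nrow(direct_edges) == 0L) abort("direct network has no edges; its LCC ratio is undefined.")
  ratio_direct <- graph_lcc(direct_edges)$ratio

  idx <- which(W > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) abort("G_qr has no positive off-diagonal entries.")
  # arcs W[i, j] mean j -> i in Google-matrix orientation
  arcs <- tibble(from = subset[idx[, "col"]], to = subset[idx[, "row"]],
                 weight = W[idx])
  arcs <- arrange(arcs, desc(.data$weight), .data$from, .data$to)

  sweep <- lcc_ratio_sweep(arcs, nr)
  distinct_w <- sweep$distinct_w
  # keeping weights >= distinct_w[k] equals "weight > cutoff_k" with the
  # cutoff at the next lower distinct weight (0 below the smallest)
  cutoffs <- c(distinct_w[-1L], 0)
  dev <- abs(sweep$ratio - ratio_direct)
  best <- which(dev == min(dev))[1L] # sweep is descending: first hit = larger cutoff
  cutoff <- cutoffs[best]
  edges <- arcs[arcs$weight > cutoff, , drop = FALSE]
  structure(
    list(edges = edges, cutoff = cutoff,
         lcc_ratio_direct = ratio_direct,
         lcc_ratio_hidden = sweep$ratio[best],
         clamped_mass = clamped, subset = subset,
         provenance = "hidden"),
    class = "hidden_network"
  )
}

# Incremental union-find sweep: after inserting each distinct-weight group of
# arcs (descending), report the nodes/edges ratio of the current largest weak
# component (ties -> component holding the smallest node id).
lcc_ratio_sweep <- function(arcs, n_nodes) {
  ids <- sort(unique(c(arcs$from, arcs$to)))
  pos <- match(c(arcs$from, arcs$to), ids)
  u <- pos[seq_len(nrow(arcs))]
  v <- pos[-seq_len(nrow(arcs))]
  parent <- seq_along(ids)
  size <- rep(1L, length(ids))
  m_in <- rep(0L, length(ids)) # arcs inside each root's component
  min_id <- ids
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  groups <- cumsum(!duplicated(arcs$weight)) # runs of equal weight, descending
  distinct_w <- arcs$weight[!duplicated(arcs$weight)]
  idx_by_group <- split(seq_len(nrow(arcs)), groups)
  n_groups <- length(idx_by_group)
  ratio <- numeric(n_groups)
  for (g in seq_len(n_groups)) {
    for (e in idx_by_group[[g]]) {
      ru <- find(u[e])
      rv <- find(v[e])
      if (ru == rv) {
        m_in[ru] <- m_in[ru] + 1L
      } else {
        if (size[ru] < size[rv]) { tmp <- ru; ru <- rv; rv <- tmp }
        parent[rv] <- ru
        size[ru] <- size[ru] + size[rv]
        m_in[ru] <- m_in[ru] + m_in[rv] + 1L
        min_id[ru] <- min(min_id[ru], min_id[rv])
      }
    }
    roots <- which(parent == seq_along(parent))
    biggest <- roots[size[roots] == max(size[roots])]
    if (length(biggest) > 1L) biggest <- biggest[which.min(min_id[biggest])]
    ratio[g] <- size[biggest] / m_in[biggest]
  }
  list(distinct_w = distinct_w, ratio = ratio)
}

#' @export
print.hidden_network <- function(x, ...) {
  cat(sprintf("<hidden_network> %d arcs above cutoff %.4e\n",
              nrow(x$edges), x$cutoff))
  cat(sprintf("  LCC nodes/edges ratio: direct %.4f, hidden %.4f\n",
              x$lcc_ratio_direct, x$lcc_ratio_hidden))
  invisible(x)
}

#' Write a hidden network to TSV plus a JSON sidecar
#'
#' @param hn a [select_cutoff()] result.
#' @param edges_path destination TSV (`source`, `target`, `weight`).
#' @param json_path optional sidecar with cutoff and LCC ratios.
#' @export
write_hidden_network <- function(hn, edges_path, json_path = NULL) {
  stopifnot(inherits(hn, "hidden_network"))
  out <- hn$edges
  names(out) <- c("source", "target", "weight")
  utils::write.table(out, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(cutoff = hn$cutoff, lcc_ratio_direct = hn$lcc_ratio_direct,
           lcc_ratio_hidden = hn$lcc_ratio_hidden, n_edges = nrow(hn$edges)),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(hn)
}

#' Arc-level overlap between the direct and hidden networks
#'
#' Classifies every arc on the shared subset as direct-only, hidden-only, or
#' direct+hidden, and reports the fraction of direct links that are also
#' hidden.
#'
#' @param direct direct arcs (graph, network, or `from`/`to` data frame).
#' @param hidden a [select_cutoff()] result (or arcs with a known subset via
#'   the `subset` argument).
#' @param subset node universe; defaults to the hidden network's subset.
#' @return A one-row tibble: `n_direct`, `n_hidden`, `direct_only`,
#'   `hidden_only`, `direct_and_hidden`, `frac_direct_also_hidden`.
#' @export
link_overlap_stats <- function(direct, hidden, subset = NULL) {
  direct_edges <- edges_of(direct)
  hidden_edges <- edges_of(hidden)
  subset <- subset %||% (if (inherits(hidden, "hidden_network")) hidden$subset)
  if (is.null(subset)) abort("provide `subset` when `hidden` is a bare edge table.")
  all_ids <- unique(c(direct_edges$from, direct_edges$to,
                      hidden_edges$from, hidden_edges$to))
  if (!all(all_ids %in% subset)) {
    abort("direct and hidden networks are not defined on the same node subset.")
  }
  n <- max(subset) + 1
  dk <- arc_key(direct_edges$from, direct_edges$to, n)
  hk <- arc_key(hidden_edges$from, hidden_edges$to, n)
  both <- sum(dk %in% hk)
  tibble(n_direct = length(dk), n_hidden = length(hk),
         direct_only = length(dk) - both,
         hidden_only = length(hk) - both,
         direct_and_hidden = both,
         frac_direct_also_hidden = both / length(dk))
}
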