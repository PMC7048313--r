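#' Markov clustering of a weighted network
#'
#' In-package Markov Clustering (MCL) of the hidden-link network into
#' communities. The directed weighted network is symmetrized (each unordered
#' pair keeps the larger of its two arc weights), every node receives a
#' self-loop equal to its largest incident weight, and columns are
#' normalized to a stochastic matrix. The iteration then alternates
#' *expansion* (matrix power `expansion`) and *inflation* (elementwise power
#' `inflation` followed by column renormalization), pruning entries below
#' `prune`, until the largest entrywise change drops below `tol`. Clusters
#' are the weakly connected components of the non-zero attractor structure
#' of the limit matrix; communities smaller than `min_size` are discarded
#' (their count and members are retained in the result). The procedure is
#' fully deterministic.
#'
#' @param net a [select_cutoff()] result or a data frame `from`, `to`,
#'   `weight` (missing `weight` means unit weights).
#' @param inflation elementwise power (> 1). Default 2.
#' @param expansion integer matrix power (>= 2). Default 2.
#' @param min_size smallest community size kept. Default 4.
#' @param prune entries below this are dropped each iteration. Default 1e-5.
#' @param tol convergence tolerance on the max entrywise change. Default 1e-8.
#' @param max_iter iteration cap; exceeding it is an error. Default 200.
#' @return An object of class `mcl_clustering`: `communities` (tibble
#'   `community_id`, `node_id`; ids 1..k ordered by decreasing size),
#'   `sizes`, `n_iterations`, `n_discarded`, `discarded_nodes`, `params`,
#'   `max_colsum_dev` (largest deviation of any column sum from 1 seen
#'   during the iteration).
#' @examples
#' tri2 <- data.frame(from = c(0, 1, 2, 3, 4, 5), to = c(1, 2, 0, 4, 5, 3))
#' mcl_cluster(tri2, min_size = 1)$communities
#' @export
mcl_cluster <- function(net, inflation = 2, expansion = 2L, min_size = 4L,
                        prune = 1e-5, tol = 1e-8, max_iter = 200L) {
  edges <- edges_of(net)
  if (nrow(edges) == 0L) abort("network is empty.")
  if (!is.numeric(inflation) || inflation <= 1) abort("`inflation` must be > 1.")
  expansion <- assert_count(expansion, "expansion", min = 2L)
  min_size <- assert_count(min_size, "min_size", min = 1L)
  if (!"weight" %in% names(edges)) edges$weight <- 1
  ids <- sort(unique(c(edges$from, edges$to)))
  nn <- length(ids)
  i <- match(edges$to, ids)
  j <- match(edges$from, ids)
  A <- Matrix::sparseMatrix(i = i, j = j, x = edges$weight, dims = c(nn, nn))
  A <- pmax_sparse(A, Matrix::t(A))          # symmetrize: max of both directions
  loop <- apply_max_incident(A)              # self-loop = max incident weight
  Matrix::diag(A) <- loop
  M <- normalize_cols(A)
  max_dev <- 0
  it <- 0L
  repeat {
    it <- it + 1L
    M_new <- M
    for (e in seq_len(expansion - 1L)) M_new <- M_new %*% M
    M_new@x <- M_new@x^inflation
    M_new@x[M_new@x < prune] <- 0
    M_new <- normalize_cols(Matrix::drop0(M_new))
    max_dev <- max(max_dev, max(abs(Matrix::colSums(M_new) - 1)))
    diff <- max(abs(M_new - M))
    M <- M_new
    if (diff < tol) break
    if (it >= max_iter) {
      abort(sprintf("MCL did not converge in %d iterations (last max change %.3e).",
                    max_iter, diff))
    }
  }
  # clusters: weak components of the non-zero attractor structure
  nz <- which(as.matrix(M) > 0, arr.ind = TRUE)
  gi <- igraph::graph_from_edgelist(cbind(nz[, 1L], nz[, 2L]), directed = FALSE)
  if (igraph::vcount(gi) < nn) {
    gi <- igraph::add_vertices(gi, nn - igraph::vcount(gi))
  }
  member <- igraph::components(gi)$membership[seq_len(nn)]
  comm <- tibble(node_id = ids, cluster = member)
  sizes_all <- table(comm$cluster)
  keep <- names(sizes_all)[sizes_all >= min_size]
  discarded <- comm$node_id[!(comm$cluster %in% keep)]
  n_discarded <- length(unique(comm$cluster)) - length(keep)
  comm <- comm[comm$cluster %in% keep, , drop = FALSE]
  if (nrow(comm) > 0L) {
    ord <- names(sort(table(comm$cluster), decreasing = TRUE))
    comm$community_id <- match(as.character(comm$cluster), ord)
    comm <- arrange(select(comm, "community_id", "node_id"),
                    .data$community_id, .data$node_id)
  } else {
    comm <- tibble(community_id = integer(), node_id = integer())
  }
  structure(
    list(communities = comm,
         sizes = as.integer(table(comm$community_id)),
         n_iterations = it, n_discarded = n_discarded,
         discarded_nodes = discarded,
         params = list(inflation = inflation, expansion = expansion,
                       prune_threshold = prune, min_size = min_size),
         max_colsum_dev = max_dev),
    class = "mcl_clustering"
  )
}

pmax_sparse <- function(A, B) {
  # elementwise max of two non-negative sparse matrices
  D <- A - B
  D@x <- pmax(D@x, 0)
  Matrix::drop0(B + D)
}

apply_max_incident <- function(A) {
  # per-node largest incident weight of a symmetric sparse matrix
  At <- as(A, "TsparseMatrix")
  w <- numeric(nrow(A))
  if (length(At@x) > 0L) {
    agg <- tapply(At@x, At@i + 1L, max)
    w[as.integer(names(agg))] <- agg
  }
  w[w == 0] <- 1 # isolated self only: give it unit mass
  w
}

normalize_cols <- function(M) {
  cs <- Matrix::colSums(M)
  cs[cs == 0] <- 1
  M %*% Matrix::Diagonal(x = 1 / cs)
}

#' @export
print.mcl_clustering <- function(x, ...) {
  cat(sprintf("<mcl_clustering> %d communities (size >= %d) over %d nodes; %d iterations\n",
              length(x$sizes), x$params$min_size, nrow(x$communities),
              x$n_iterations))
  if (x$n_discarded > 0L) {
    cat(sprintf("  %d community(ies) below min size discarded (%d nodes)\n",
                x$n_discarded, length(x$discarded_nodes)))
  }
  invisible(x)
}

#' Write a clustering to TSV plus a JSON parameter sidecar
#'
#' @param cl a [mcl_cluster()] result.
#' @param path destination TSV (`community_id`, `node_id`).
#' @param json_path optional parameters sidecar.
#' @export
write_clustering <- function(cl, path, json_path = NULL) {
  stopifnot(inherits(cl, "mcl_clustering"))
  utils::write.table(cl$communities, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  if (!is.null(json_path)) {
    jsonlite::write_json(cl$params, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(cl)
}

#' Agreement of a clustering with planted labels
#'
#' Adjusted Rand Index between recovered communities and a ground-truth
#' labeling, computed over the nodes present in both (nodes dropped by
#' thresholding or the minimum community size are not scored).
#'
#' @param cl a [mcl_cluster()] result.
#' @param truth data frame `node_id`, `community_id` (planted labels).
#' @return ARI in `[-1, 1]`.
#' @export
recovery_ari <- function(cl, truth) {
  stopifnot(inherits(cl, "mcl_clustering"))
  truth <- as_tibble(truth)
  joined <- inner_join(cl$communities, truth, by = "node_id",
                       suffix = c("_found", "_true"))
  if (nrow(joined) == 0L) abort("clustering and ground truth share no nodes.")
  mclust::adjustedRandIndex(joined$community_id_found, joined$community_id_true)
}
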