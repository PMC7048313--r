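#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname pagerank
#' @param x a `pagerank` object.
#' @param ... unused.
#' @method tidy pagerank
#' @export
tidy.pagerank <- function(x, ...) x$table

#' @rdname pagerank
#' @method glance pagerank
#' @export
glance.pagerank <- function(x, ...) {
  tibble(n = nrow(x$table), iterations = x$iterations,
         residual = x$residual, alpha = x$alpha)
}

#' Long tibble of reduced-matrix weights
#'
#' One row per ordered subset pair and component, in Google-matrix arc
#' orientation (`from` = column node, `to` = row node).
#'
#' @param x a `regomax` object.
#' @param component which matrix to tidy. Default `"G_qr"`.
#' @param ... unused.
#' @method tidy regomax
#' @export
tidy.regomax <- function(x, component = c("G_qr", "G_R", "G_rr", "G_pr"), ...) {
  component <- match.arg(component)
  M <- x[[component]]
  tibble(from = rep(x$subset, each = length(x$subset)),
         to = rep(x$subset, times = length(x$subset)),
         component = component,
         weight = as.vector(t(M)))
}

#' @rdname tidy.regomax
#' @method glance regomax
#' @export
glance.regomax <- function(x, ...) {
  tibble(n_r = length(x$subset), method = x$method, lambda_c = x$lambda_c,
         series_terms = x$series_terms,
         max_colsum_dev = max(abs(colSums(x$G_R) - 1)))
}

#' @rdname mcl_cluster
#' @param x an `mcl_clustering` object.
#' @param ... unused.
#' @method tidy mcl_clustering
#' @export
tidy.mcl_clustering <- function(x, ...) x$communities

#' @rdname mcl_cluster
#' @method glance mcl_clustering
#' @export
glance.mcl_clustering <- function(x, ...) {
  tibble(n_communities = length(x$sizes),
         n_nodes_clustered = nrow(x$communities),
         mean_size = mean(x$sizes), median_size = stats::median(x$sizes),
         max_size = if (length(x$sizes)) max(x$sizes) else NA_integer_,
         n_iterations = x$n_iterations, n_discarded = x$n_discarded)
}

#' @rdname compare_snapshots
#' @param x a `snapshot_comparison` object.
#' @param ... unused.
#' @method tidy snapshot_comparison
#' @export
tidy.snapshot_comparison <- function(x, ...) x$matches

#' @rdname compare_snapshots
#' @method glance snapshot_comparison
#' @export
glance.snapshot_comparison <- function(x, ...) {
  tibble(persistence_direct = x$persistence$direct,
         persistence_hidden = x$persistence$hidden,
         n_improved = sum(x$rank_folds$status == "improved"),
         n_worsened = sum(x$rank_folds$status == "worsened"),
         n_matched = nrow(x$matches),
         mean_size_old = mean(x$matches$size_old),
         mean_size_new = mean(x$matches$size_new))
}
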