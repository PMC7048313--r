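#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_abline
#'   scale_x_log10 scale_y_log10 labs theme_minimal
#' @export
ggplot2::autoplot

#' Bar chart of a shortest-path-length histogram
#'
#' @param object a [sampled_shortest_paths()] result.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot path_histogram
#' @export
autoplot.path_histogram <- function(object, ...) {
  df <- as_tibble(object)
  df$length <- factor(ifelse(is.infinite(df$length), "unreachable",
                             as.character(df$length)),
                      levels = c(sort(unique(df$length[is.finite(df$length)])),
                                 "unreachable"))
  ggplot(df, aes(x = .data$length, y = .data$n)) +
    geom_col(fill = "steelblue") +
    labs(x = "shortest oriented path length", y = "pairs",
         title = sprintf("Path lengths (%s pairs)", attr(object, "pair_kind"))) +
    theme_minimal()
}

#' PageRank probability against rank index
#'
#' @param object a [pagerank()] result.
#' @param ... unused.
#' @return A ggplot (log-log).
#' @method autoplot pagerank
#' @export
autoplot.pagerank <- function(object, ...) {
  ggplot(object$table, aes(x = .data$k, y = .data$p)) +
    geom_point(size = 0.6, alpha = 0.6) +
    scale_x_log10() + scale_y_log10() +
    labs(x = "PageRank index K", y = "PageRank probability P") +
    theme_minimal()
}

#' Community size distribution of a clustering
#'
#' @param object a [mcl_cluster()] result.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot mcl_clustering
#' @export
autoplot.mcl_clustering <- function(object, ...) {
  df <- tibble(community_id = seq_along(object$sizes), size = object$sizes)
  ggplot(df, aes(x = .data$community_id, y = .data$size)) +
    geom_col(fill = "darkorange") +
    labs(x = "community (by decreasing size)", y = "members") +
    theme_minimal()
}

#' Matched community sizes across two snapshots
#'
#' Scatter of old vs new sizes of the reciprocal-Jaccard-matched
#' communities; points above the diagonal grew.
#'
#' @param object a [compare_snapshots()] result.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot snapshot_comparison
#' @export
autoplot.snapshot_comparison <- function(object, ...) {
  ggplot(object$matches, aes(x = .data$size_old, y = .data$size_new)) +
    geom_point(alpha = 0.7) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    labs(x = "community size (old snapshot)",
         y = "community size (new snapshot)") +
    theme_minimal()
}
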