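#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis. Defaults follow the
#' standard choices for this analysis: damping 0.85, MCL inflation 2 /
#' expansion 2, minimum community size 4, community-match intersection 3,
#' enrichment overlap 5 at q <= 1e-8.
#'
#' @param alpha damping factor. Default 0.85.
#' @param pr_tol,pr_max_iter PageRank convergence control.
#' @param regomax_eps series truncation tolerance. Default 1e-12.
#' @param regomax_max_terms series cap; `NULL` uses the lambda_c-based
#'   default of [reduce_google_matrix()].
#' @param inflation,expansion,min_size,prune MCL parameters.
#' @param keep_diagonal keep G_qr self-weights when thresholding.
#' @param min_intersection community matching threshold. Default 3.
#' @param enrich_min_overlap,enrich_q_max enrichment summary filters.
#' @param label_top_k candidates kept when labeling communities.
#' @param path_seed seed for shortest-path pair sampling. Default 42.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha = 0.85, pr_tol = 1e-12, pr_max_iter = 1000L,
                            regomax_eps = 1e-12, regomax_max_terms = 10000L,
                            inflation = 2, expansion = 2L, min_size = 4L,
                            prune = 1e-5, keep_diagonal = FALSE,
                            min_intersection = 3L, enrich_min_overlap = 5L,
                            enrich_q_max = 1e-8, label_top_k = 10L,
                            path_seed = 42L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full hidden-network analysis pipeline
#'
#' Executes, in order: Google matrix -> PageRank -> reduced Google matrix
#' (projector series) -> direct subnetwork -> connectivity-matched hidden
#' network -> Markov clustering -> community labeling via friendship
#' networks. Any stage failure aborts with the stage name; outputs computed
#' so far are written when `output_dir` is given.
#'
#' @param g a [hl_graph()] (with node table) or a
#'   [generate_global_graph()] result.
#' @param subset 0-based node ids to reduce onto; defaults to the marked
#'   protein pages.
#' @param config a [pipeline_config()].
#' @param output_dir optional directory; when given, every stage's TSV/JSON
#'   output plus a run manifest are written there.
#' @return An object of class `pipeline_result`: `graph`, `subset`,
#'   `pagerank`, `regomax`, `direct` (arcs), `hidden`, `clustering`,
#'   `labels`, `manifest`.
#' @export
run_pipeline <- function(g, subset = NULL, config = pipeline_config(),
                         output_dir = NULL) {
  if (inherits(g, "synthetic_graph")) g <- g$graph
  stopifnot(inherits(g, "hlgraph"), inherits(config, "pipeline_config"))
  subset <- subset %||% protein_nodes(g)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)))
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }
  gm <- stage("google_matrix", google_matrix(g, alpha = config$alpha))
  pr <- stage("pagerank", pagerank(gm, tol = config$pr_tol,
                                   max_iter = config$pr_max_iter))
  rg <- stage("regomax", reduce_google_matrix(
    gm, subset, method = "projector_series", eps = config$regomax_eps,
    max_terms = config$regomax_max_terms))
  direct <- stage("direct_subnetwork", direct_subnetwork(g, subset))
  hidden <- stage("hidden_cutoff", suppressMessages(
    select_cutoff(rg, direct, keep_diagonal = config$keep_diagonal)))
  cl <- stage("mcl", mcl_cluster(hidden, inflation = config$inflation,
                                 expansion = config$expansion,
                                 min_size = config$min_size,
                                 prune = config$prune))
  labels <- if (!is.null(g$nodes)) {
    stage("labels", label_communities(g, cl, hidden, top_k = config$label_top_k))
  } else NULL
  manifest <- list(
    package_version = as.character(utils::packageVersion("hiddennet")),
    n_nodes = g$n, n_edges = nrow(g$edges), n_subset = length(subset),
    parameters = unclass(config),
    lambda_c = rg$lambda_c, series_terms = rg$series_terms,
    cutoff = hidden$cutoff,
    n_hidden_edges = nrow(hidden$edges),
    n_communities = length(cl$sizes),
    stages_completed = names(timings), timings_sec = timings,
    outputs = character()
  )
  res <- structure(
    list(graph = g, subset = subset, pagerank = pr, regomax = rg,
         direct = direct, hidden = hidden, clustering = cl, labels = labels,
         manifest = manifest),
    class = "pipeline_result"
  )
  if (!is.null(output_dir)) res <- write_pipeline_outputs(res, output_dir)
  res
}

write_pipeline_outputs <- function(res, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(output_dir, ...)
  outputs <- c("pagerank.tsv", "hidden_edges.tsv", "hidden_meta.json",
               "communities.tsv", "mcl_params.json",
               "gr_matrix.tsv", "gqr_matrix.tsv", "gpr_matrix.tsv",
               "regomax_meta.json", "manifest.json")
  pr_out <- res$pagerank$table
  names(pr_out) <- c("node_id", "P", "K")
  utils::write.table(pr_out, p("pagerank.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_hidden_network(res$hidden, p("hidden_edges.tsv"), p("hidden_meta.json"))
  write_clustering(res$clustering, p("communities.tsv"), p("mcl_params.json"))
  mats <- c(G_R = "gr_matrix.tsv", G_qr = "gqr_matrix.tsv",
            G_pr = "gpr_matrix.tsv")
  for (comp in names(mats)) {
    utils::write.table(res$regomax[[comp]], p(mats[[comp]]), sep = "\t",
                       quote = FALSE, row.names = TRUE, col.names = NA)
  }
  jsonlite::write_json(
    list(subset = res$regomax$subset, lambda_c = res$regomax$lambda_c,
         series_terms = res$regomax$series_terms, method = res$regomax$method),
    p("regomax_meta.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(res$labels)) {
    utils::write.table(res$labels, p("community_map.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, "community_map.tsv")
  }
  res$manifest$outputs <- outputs
  jsonlite::write_json(res$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  graph: %d nodes, %d arcs; subset: %d nodes\n",
              x$graph$n, nrow(x$graph$edges), length(x$subset)))
  cat(sprintf("  hidden network: %d arcs above cutoff %.3e\n",
              nrow(x$hidden$edges), x$hidden$cutoff))
  cat(sprintf("  communities: %d (sizes %s)\n", length(x$clustering$sizes),
              paste(x$clustering$sizes, collapse = ", ")))
  invisible(x)
}
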