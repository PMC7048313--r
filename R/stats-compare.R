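#' Read a reference interaction network
#'
#' TSV with header `symbol_a	symbol_b	type` (pathway-database export
#' style). Symbols must be nonempty.
#'
#' @param path file path.
#' @return Tibble `symbol_a`, `symbol_b`, `type`.
#' @export
read_reference_network <- function(path) {
  if (!file.exists(path)) abort(sprintf("reference network not found: %s", path))
  ref <- as_tibble(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE))
  if (!all(c("symbol_a", "symbol_b", "type") %in% names(ref))) {
    abort("reference network needs columns `symbol_a`, `symbol_b`, `type`.")
  }
  if (any(ref$symbol_a == "" | ref$symbol_b == "")) abort("empty symbols in reference network.")
  ref
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file (tab-separated: set name, description, symbols...).
#' @return Named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("GMT file not found: %s", path))
  sets <- fgsea::gmtPathways(path)
  if (length(sets) == 0L) abort("GMT file contains no gene sets.")
  sets
}

#' Map arcs between node ids to gene-symbol pairs
#'
#' @param edges arcs (`from`, `to`) over node ids.
#' @param nodes node table carrying `symbol`.
#' @return Tibble `symbol_a`, `symbol_b`; arcs with an unmapped endpoint are
#'   dropped with a message and counted in attribute `n_unmapped_arcs`.
#' @export
map_arcs_to_symbols <- function(edges, nodes) {
  edges <- edges_of(edges)
  nodes <- as_tibble(nodes)
  lut <- setNames(nodes$symbol, nodes$node_id)
  sa <- lut[as.character(edges$from)]
  sb <- lut[as.character(edges$to)]
  keep <- !is.na(sa) & !is.na(sb)
  if (any(!keep)) {
    inform(sprintf("dropped %d arc(s) with an unmapped endpoint", sum(!keep)))
  }
  out <- tibble(symbol_a = unname(sa[keep]), symbol_b = unname(sb[keep]))
  attr(out, "n_unmapped_arcs") <- sum(!keep)
  out
}

pair_keys <- function(a, b, directed) {
  if (directed) paste(a, b, sep = "\r") else
    paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Overlap of a hyperlink-derived network with a reference network
#'
#' Restricts both networks to their shared proteins, matches links (as
#' unordered symbol pairs by default, since reference databases mix directed
#' and undirected semantics), and tests the overlap with a one-sided
#' Fisher's exact test on the 2x2 table over the universe of all pairs of
#' matched proteins — the null being that any two shared proteins could be
#' connected.
#'
#' @param wiki arcs as symbol pairs (`symbol_a`, `symbol_b`), e.g. from
#'   [map_arcs_to_symbols()].
#' @param ref a [read_reference_network()] tibble.
#' @param universe_n override for the number of pairs in the universe;
#'   defaults to `choose(m, 2)` (unordered) or `m * (m - 1)` (directed) over
#'   the `m` shared proteins.
#' @param directed match arcs with orientation. Default FALSE.
#' @return One-row tibble: `n_shared_proteins`, `n_wiki`, `n_ref`,
#'   `n_matched`, `universe_n`, `p` (one-sided Fisher / hypergeometric
#'   upper tail).
#' @export
overlap_and_fisher <- function(wiki, ref, universe_n = NULL, directed = FALSE) {
  wiki <- as_tibble(wiki)
  ref <- as_tibble(ref)
  shared <- intersect(unique(c(wiki$symbol_a, wiki$symbol_b)),
                      unique(c(ref$symbol_a, ref$symbol_b)))
  if (length(shared) == 0L) abort("no proteins shared between the two networks.")
  wk <- wiki[wiki$symbol_a %in% shared & wiki$symbol_b %in% shared, ]
  rf <- ref[ref$symbol_a %in% shared & ref$symbol_b %in% shared, ]
  wp <- unique(pair_keys(wk$symbol_a, wk$symbol_b, directed))
  rp <- unique(pair_keys(rf$symbol_a, rf$symbol_b, directed))
  m <- length(shared)
  universe_n <- universe_n %||%
    (if (directed) m * (m - 1) else choose(m, 2))
  n_matched <- sum(wp %in% rp)
  p <- phyper(n_matched - 1, length(rp), universe_n - length(rp), length(wp),
              lower.tail = FALSE)
  tibble(n_shared_proteins = m, n_wiki = length(wp), n_ref = length(rp),
         n_matched = n_matched, universe_n = universe_n, p = p)
}

#' Degree correlation between two networks on their shared nodes
#'
#' Pearson correlation of the total (in + out) degrees of the shared nodes.
#'
#' @param net_a,net_b arcs as data frames (node-id or symbol columns, the
#'   first two columns are used).
#' @param shared_nodes nodes/symbols to compare on; defaults to those
#'   present in both networks.
#' @return Pearson r.
#' @export
degree_correlation <- function(net_a, net_b, shared_nodes = NULL) {
  deg <- function(net, who) {
    net <- as_tibble(net)
    ends <- c(net[[1L]], net[[2L]])
    tab <- table(ends)
    out <- rep(0, length(who))
    hit <- match(names(tab), as.character(who))
    out[hit[!is.na(hit)]] <- as.numeric(tab[!is.na(hit)])
    out
  }
  a <- as_tibble(net_a); b <- as_tibble(net_b)
  shared_nodes <- shared_nodes %||%
    intersect(unique(c(a[[1L]], a[[2L]])), unique(c(b[[1L]], b[[2L]])))
  if (length(shared_nodes) < 3L) abort("need at least 3 shared nodes.")
  da <- deg(a, shared_nodes)
  db <- deg(b, shared_nodes)
  if (length(unique(da)) == 1L || length(unique(db)) == 1L) {
    abort("constant degree vector; Pearson correlation undefined.")
  }
  cor(da, db)
}

#' Relative link-type fractions matched in a reference network
#'
#' For each interaction type `t` of the reference, `f_t` is the fraction of
#' that type's links (restricted to proteins shared with the query network)
#' that the query network matches; `f_t_rel = f_t / sum_t f_t` compares the
#' profile across types. Types with no reference links among the shared
#' proteins are dropped with a message.
#'
#' @inheritParams overlap_and_fisher
#' @return Tibble `type`, `n_ref`, `n_matched`, `f`, `f_rel`
#'   (`sum(f_rel) == 1`).
#' @export
relative_type_fractions <- function(wiki, ref, directed = FALSE) {
  wiki <- as_tibble(wiki)
  ref <- as_tibble(ref)
  shared <- intersect(unique(c(wiki$symbol_a, wiki$symbol_b)),
                      unique(c(ref$symbol_a, ref$symbol_b)))
  wk <- wiki[wiki$symbol_a %in% shared & wiki$symbol_b %in% shared, ]
  wp <- unique(pair_keys(wk$symbol_a, wk$symbol_b, directed))
  rf <- ref[ref$symbol_a %in% shared & ref$symbol_b %in% shared, ]
  if (nrow(rf) == 0L) abort("no reference links among shared proteins.")
  res <- rf |>
    mutate(key = pair_keys(.data$symbol_a, .data$symbol_b, directed)) |>
    group_by(.data$type) |>
    summarise(n_ref = dplyr::n_distinct(.data$key),
              n_matched = sum(unique(.data$key) %in% wp), .groups = "drop") |>
    filter(.data$n_ref > 0L)
  dropped <- setdiff(unique(ref$type), res$type)
  if (length(dropped) > 0L) {
    inform(sprintf("dropped type(s) with no reference links among shared proteins: %s",
                   paste(dropped, collapse = ", ")))
  }
  res <- mutate(res, f = .data$n_matched / .data$n_ref)
  if (all(res$f == 0)) return(mutate(res, f_rel = 0))
  mutate(res, f_rel = .data$f / sum(.data$f))
}

#' Hypergeometric gene-set enrichment of communities
#'
#' For every community x gene set, the upper-tail hypergeometric probability
#' of the observed overlap given the symbol universe, with
#' Benjamini-Hochberg correction across all sets within each community.
#' Summary rows require an overlap of at least `min_overlap` genes and a
#' q-value of at most `q_max`; the full table is returned with a `selected`
#' flag. Community members without a mapped symbol in the universe are
#' excluded and counted.
#'
#' @param cl a [mcl_cluster()] result.
#' @param gene_sets named list of symbol vectors (see [read_gmt()]).
#' @param universe character vector of all testable symbols.
#' @param nodes node table mapping `node_id` to `symbol`.
#' @param min_overlap minimum overlap for the summary. Default 5.
#' @param q_max q-value ceiling for the summary. Default 1e-8.
#' @return Tibble `community_id`, `term`, `overlap_k`, `set_size`,
#'   `community_size`, `universe_size`, `p`, `q`, `selected`, with attribute
#'   `n_unmapped` (community members not mappable into the universe).
#' @export
enrich_communities <- function(cl, gene_sets, universe, nodes,
                               min_overlap = 5L, q_max = 1e-8) {
  stopifnot(inherits(cl, "mcl_clustering"))
  if (length(gene_sets) == 0L) abort("empty gene-set collection.")
  nodes <- as_tibble(nodes)
  universe <- unique(universe)
  sets <- lapply(gene_sets, function(s) intersect(unique(s), universe))
  lut <- setNames(nodes$symbol, nodes$node_id)
  n_unmapped <- 0L
  res <- purrr::map_dfr(unique(cl$communities$community_id), function(cid) {
    members <- cl$communities$node_id[cl$communities$community_id == cid]
    syms <- lut[as.character(members)]
    mapped <- intersect(syms[!is.na(syms)], universe)
    n_unmapped <<- n_unmapped + (length(members) - length(mapped))
    if (length(mapped) == 0L) return(NULL)
    k <- vapply(sets, function(s) length(intersect(s, mapped)), integer(1))
    sizes <- lengths(sets)
    p <- phyper(k - 1, sizes, length(universe) - sizes, length(mapped),
                lower.tail = FALSE)
    tibble(community_id = cid, term = names(sets), overlap_k = unname(k),
           set_size = unname(sizes), community_size = length(mapped),
           universe_size = length(universe), p = unname(p),
           q = unname(p.adjust(p, method = "BH")))
  })
  if (nrow(res) == 0L) abort("no community could be mapped into the universe.")
  res <- mutate(res, selected = .data$overlap_k >= min_overlap & .data$q <= q_max)
  attr(res, "n_unmapped") <- n_unmapped
  res
}
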