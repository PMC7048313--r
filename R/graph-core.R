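#' Directed hyperlink graphs
#'
#' A `hlgraph` holds a directed graph over `n` nodes with dense 0-based ids,
#' together with an optional node table carrying the page title, the marked
#' ("protein") flag, and an optional gene symbol per node. Edges are stored as
#' a tibble of ordered `(from, to)` arcs: `from -> to` means page `from` cites
#' page `to`. Duplicate arcs are collapsed and self-loops dropped at
#' construction; the number of dropped self-loops is retained.
#'
#' @param edges data frame with integer columns `from` and `to` (0-based ids).
#' @param n node count; defaults to `max(id) + 1` over edges and node table.
#' @param nodes optional node table with columns `node_id`, `title`,
#'   `is_protein`, `symbol` (`symbol` may be `NA`).
#' @return An object of class `hlgraph` with fields `n`, `edges` (tibble),
#'   `nodes` (tibble or `NULL`), and `n_self_loops_dropped`.
#' @examples
#' g <- hl_graph(data.frame(from = c(0, 0, 1), to = c(1, 1, 0)), n = 2)
#' g$edges
#' @export
hl_graph <- function(edges, n = NULL, nodes = NULL) {
  edges <- as_tibble(edges)
  if (!all(c("from", "to") %in% names(edges))) {
    abort("`edges` must have columns `from` and `to`.")
  }
  edges$from <- as.integer(edges$from)
  edges$to <- as.integer(edges$to)
  if (anyNA(edges$from) || anyNA(edges$to)) {
    abort("`edges` contains non-integer or missing node ids.")
  }
  if (is.null(n)) {
    n <- max(c(edges$from, edges$to, -1L), nodes$node_id %||% -1L) + 1L
  }
  n <- assert_count(n, "n", min = 0L)
  bad <- which(edges$from >= n | edges$to >= n | edges$from < 0L | edges$to < 0L)
  if (length(bad) > 0L) {
    abort(sprintf("edge %d references node %d but the graph has N = %d nodes (ids 0..%d).",
                  bad[1L], max(edges$from[bad[1L]], edges$to[bad[1L]]), n, n - 1L))
  }
  loops <- edges$from == edges$to
  n_loops <- sum(loops)
  if (n_loops > 0L) {
    inform(sprintf("dropped %d self-loop(s) at load time", n_loops))
    edges <- edges[!loops, , drop = FALSE]
  }
  edges <- distinct(edges, from, to)
  if (!is.null(nodes)) {
    nodes <- validate_node_table(nodes, n)
  }
  structure(
    list(n = n, edges = edges, nodes = nodes, n_self_loops_dropped = n_loops),
    class = "hlgraph"
  )
}

validate_node_table <- function(nodes, n) {
  nodes <- as_tibble(nodes)
  required <- c("node_id", "title", "is_protein")
  if (!all(required %in% names(nodes))) {
    abort("node table must have columns `node_id`, `title`, `is_protein`.")
  }
  if (!"symbol" %in% names(nodes)) nodes$symbol <- NA_character_
  nodes$node_id <- as.integer(nodes$node_id)
  nodes$is_protein <- as.logical(nodes$is_protein)
  nodes$symbol <- as.character(nodes$symbol)
  nodes$symbol[!is.na(nodes$symbol) & nodes$symbol == ""] <- NA_character_
  nodes <- nodes[order(nodes$node_id), c("node_id", "title", "is_protein", "symbol")]
  if (!identical(nodes$node_id, seq_len(nrow(nodes)) - 1L) || nrow(nodes) != n) {
    abort(sprintf("node ids must be dense 0..N-1 with N = %d.", n))
  }
  if (anyDuplicated(nodes$title)) abort("node titles must be unique.")
  sym <- nodes$symbol[!is.na(nodes$symbol)]
  if (anyDuplicated(sym)) abort("each gene symbol may be attached to one node only.")
  nodes
}

#' @export
print.hlgraph <- function(x, ...) {
  cat(sprintf("<hlgraph> %d nodes, %d arcs", x$n, nrow(x$edges)))
  if (!is.null(x$nodes)) {
    cat(sprintf(", %d marked protein pages", sum(x$nodes$is_protein)))
  }
  cat("\n")
  invisible(x)
}

#' Marked (protein) node ids of a graph
#'
#' @param g a [hl_graph()] with a node table.
#' @return Integer vector of 0-based ids of nodes flagged `is_protein`.
#' @export
protein_nodes <- function(g) {
  stopifnot(inherits(g, "hlgraph"))
  if (is.null(g$nodes)) abort("graph has no node table; protein flags unknown.")
  g$nodes$node_id[g$nodes$is_protein]
}

#' Read a directed graph from an edge-list file
#'
#' The edge list is a headerless two-column TSV (`source`, `target`; `#`
#' comments allowed); the node table is a TSV with header
#' `node_id title is_protein symbol`. Duplicate rows collapse to one arc and
#' self-loops are dropped with a message.
#'
#' @param edges_path path to the edge-list TSV.
#' @param nodes_path optional path to the node table TSV.
#' @return A [hl_graph()].
#' @export
read_edgelist <- function(edges_path, nodes_path = NULL) {
  if (!file.exists(edges_path)) abort(sprintf("edge file not found: %s", edges_path))
  lines <- readLines(edges_path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (length(rows) == 0L) {
    edges <- tibble(from = integer(), to = integer())
  } else {
    parts <- strsplit(lines[keep], "\t", fixed = TRUE)
    ok <- lengths(parts) >= 2L
    if (!all(ok)) {
      abort(sprintf("malformed edge row at line %d: %s",
                    rows[which(!ok)[1L]], lines[keep][which(!ok)[1L]]))
    }
    from <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 1L)))
    to <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
    bad <- which(is.na(from) | is.na(to))
    if (length(bad) > 0L) {
      abort(sprintf("malformed edge row at line %d: %s",
                    rows[bad[1L]], lines[keep][bad[1L]]))
    }
    edges <- tibble(from = from, to = to)
  }
  nodes <- NULL
  if (!is.null(nodes_path)) {
    if (!file.exists(nodes_path)) abort(sprintf("node table not found: %s", nodes_path))
    nodes <- utils::read.delim(nodes_path, sep = "\t", stringsAsFactors = FALSE,
                               na.strings = c("NA", ""))
  }
  hl_graph(edges, nodes = nodes)
}

#' Write a graph back to the edge-list format
#'
#' @param g a [hl_graph()].
#' @param edges_path destination for the two-column TSV edge list.
#' @param nodes_path optional destination for the node table TSV.
#' @return `g`, invisibly.
#' @export
write_edgelist <- function(g, edges_path, nodes_path = NULL) {
  stopifnot(inherits(g, "hlgraph"))
  utils::write.table(g$edges, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(nodes_path)) {
    if (is.null(g$nodes)) abort("graph has no node table to write.")
    utils::write.table(g$nodes, nodes_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "")
  }
  invisible(g)
}

edges_of <- function(x) {
  if (inherits(x, "hlgraph")) return(x$edges)
  if (inherits(x, "hidden_network")) return(x$edges)
  x <- as_tibble(x)
  if (!all(c("from", "to") %in% names(x))) {
    abort("expected a graph, a hidden network, or a data frame with `from`/`to`.")
  }
  x
}

as_igraph_edges <- function(edges, node_ids = NULL) {
  node_ids <- node_ids %||% sort(unique(c(edges$from, edges$to)))
  igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$from), to = as.character(edges$to)),
    directed = TRUE,
    vertices = data.frame(name = as.character(node_ids))
  )
}

#' Largest weakly connected component and its connectivity ratio
#'
#' Components are weak (arc orientation ignored). The connectivity ratio is
#' the number of nodes of the largest component divided by the number of arcs
#' with both endpoints inside it; ties for "largest" break toward the
#' component containing the smallest node id.
#'
#' @param x a [hl_graph()], a hidden network, or an edge data frame.
#' @param node_ids node universe; defaults to all graph nodes for a `hlgraph`
#'   and to the endpoint set for a bare edge table.
#' @return A list with `node_ids` (members, ascending), `n_nodes`, `n_edges`,
#'   and `ratio` = `n_nodes / n_edges`.
#' @export
graph_lcc <- function(x, node_ids = NULL) {
  edges <- edges_of(x)
  if (nrow(edges) == 0L) abort("graph has zero edges; connectivity ratio undefined.")
  if (is.null(node_ids) && inherits(x, "hlgraph")) node_ids <- seq_len(x$n) - 1L
  node_ids <- node_ids %||% sort(unique(c(edges$from, edges$to)))
  comp <- igraph::components(as_igraph_edges(edges, node_ids), mode = "weak")
  member <- comp$membership
  sizes <- comp$csize
  biggest <- which(sizes == max(sizes))
  if (length(biggest) > 1L) {
    # deterministic tie-break: component holding the smallest node id
    smallest_id <- vapply(biggest, function(k) {
      min(as.integer(names(member)[member == k]))
    }, integer(1))
    biggest <- biggest[which.min(smallest_id)]
  }
  ids <- sort(as.integer(names(member)[member == biggest]))
  m <- sum(edges$from %in% ids & edges$to %in% ids)
  list(node_ids = ids, n_nodes = length(ids), n_edges = m,
       ratio = length(ids) / m)
}

#' Fraction of reciprocated arcs
#'
#' The share of arcs `j -> i` whose reciprocal `i -> j` is also present. In
#' hyperlink protein networks this separates link sets imported as unordered
#' interaction lists (high reciprocity) from asymmetric indirect links.
#'
#' @inheritParams graph_lcc
#' @return A single number in `[0, 1]`.
#' @export
bidirectional_fraction <- function(x) {
  edges <- edges_of(x)
  if (nrow(edges) == 0L) abort("graph has zero edges.")
  n <- max(edges$from, edges$to) + 1
  keys <- arc_key(edges$from, edges$to, n)
  rev_keys <- arc_key(edges$to, edges$from, n)
  mean(rev_keys %in% keys)
}

#' Flag marked nodes without any links
#'
#' Marked (protein) pages with neither outgoing nor incoming links are
#' candidates for removal before analysis. Both counting conventions are
#' exposed: links to/from any page (`scope = "any"`, the default) or only
#' links among the marked subset (`scope = "protein"`).
#'
#' @param g a [hl_graph()] with a node table.
#' @param scope `"any"` or `"protein"`.
#' @return Tibble `node_id`, `title`, `n_out`, `n_in`, `unlinked` for the
#'   marked nodes.
#' @export
flag_unlinked <- function(g, scope = c("any", "protein")) {
  scope <- match.arg(scope)
  prot <- protein_nodes(g)
  edges <- g$edges
  if (scope == "protein") {
    edges <- edges[edges$from %in% prot & edges$to %in% prot, , drop = FALSE]
  }
  n_out <- tabulate(edges$from + 1L, nbins = g$n)[prot + 1L]
  n_in <- tabulate(edges$to + 1L, nbins = g$n)[prot + 1L]
  tibble(node_id = prot,
         title = g$nodes$title[prot + 1L],
         n_out = n_out, n_in = n_in,
         unlinked = n_out + n_in == 0L)
}

#' Restrict a graph to the arcs among a node subset
#'
#' @param g a [hl_graph()].
#' @param subset integer vector of 0-based node ids.
#' @return Tibble of arcs `from`, `to` with both endpoints in `subset`.
#' @export
direct_subnetwork <- function(g, subset) {
  stopifnot(inherits(g, "hlgraph"))
  edges <- g$edges
  edges[edges$from %in% subset & edges$to %in% subset, , drop = FALSE]
}
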