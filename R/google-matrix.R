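#' Google matrix of a directed graph
#'
#' Builds the column-stochastic Google matrix
#' `G = alpha * S + (1 - alpha) / N`, where `S[i, j] = A[i, j] / k_out(j)` is
#' the Markov transition matrix of the link structure and a dangling column
#' `j` (no outgoing links) is replaced by the uniform column `1/N`. The two
#' rank-one parts (dangling columns, teleportation) are never materialized:
#' the object stores the sparse non-dangling part of `S`, the dangling set,
#' and `alpha`, and applies the rest analytically inside matrix-vector
#' products, so memory stays O(N + number of links).
#'
#' @param g a [hl_graph()].
#' @param alpha damping factor in (0, 1); the probability of following a link
#'   rather than teleporting. Default 0.85.
#' @return An object of class `google_matrix` with fields `S` (sparse
#'   `dgCMatrix`, dangling columns all-zero), `dangling` (logical), `alpha`,
#'   `n`.
#' @examples
#' g <- hl_graph(data.frame(from = c(0, 1), to = c(1, 0)), n = 2)
#' G <- google_matrix(g, alpha = 0.85)
#' as.matrix(G)
#' @export
google_matrix <- function(g, alpha = 0.85) {
  stopifnot(inherits(g, "hlgraph"))
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie strictly between 0 and 1.")
  }
  n <- g$n
  k_out <- tabulate(g$edges$from + 1L, nbins = n)
  dangling <- k_out == 0L
  S <- Matrix::sparseMatrix(
    i = g$edges$to + 1L, j = g$edges$from + 1L,
    x = 1 / k_out[g$edges$from + 1L],
    dims = c(n, n)
  )
  structure(list(S = S, dangling = dangling, alpha = alpha, n = n),
            class = "google_matrix")
}

#' @export
print.google_matrix <- function(x, ...) {
  cat(sprintf("<google_matrix> N = %d, alpha = %g, %d dangling node(s)\n",
              x$n, x$alpha, sum(x$dangling)))
  invisible(x)
}

#' Dense Google matrix (small graphs only)
#'
#' Materializes the full `N x N` matrix; intended for oracle checks and tiny
#' examples, not for production graphs.
#'
#' @param x a [google_matrix()].
#' @param ... unused.
#' @export
as.matrix.google_matrix <- function(x, ...) {
  n <- x$n
  Sd <- as.matrix(x$S)
  Sd[, x$dangling] <- 1 / n
  x$alpha * Sd + (1 - x$alpha) / n
}

# y = G %*% v without densifying: sparse part + dangling mass + teleport mass.
g_matvec <- function(gm, v) {
  mass <- sum(v[gm$dangling])
  gm$alpha * as.numeric(gm$S %*% v) + gm$alpha * mass / gm$n +
    (1 - gm$alpha) * sum(v) / gm$n
}

#' PageRank by power iteration
#'
#' Iterates `v <- G v` from the uniform vector until the L1 change drops
#' below `tol`. Teleportation guarantees a unique positive stationary vector;
#' rank ties (equal probabilities) break by ascending node id.
#'
#' @param gm a [google_matrix()].
#' @param tol L1 convergence tolerance (> 0). Default `1e-12`.
#' @param max_iter iteration cap; exceeding it is an error carrying the last
#'   residual. Default 1000.
#' @return An object of class `pagerank`: tibble accessor via [tidy()], with
#'   fields `table` (`node_id`, `p`, `k`), `iterations`, `residual`, `alpha`.
#' @examples
#' g <- hl_graph(data.frame(from = c(0, 1), to = c(1, 0)), n = 2)
#' pr <- pagerank(google_matrix(g))
#' tidy(pr)
#' @export
pagerank <- function(gm, tol = 1e-12, max_iter = 1000L) {
  stopifnot(inherits(gm, "google_matrix"))
  if (!is.numeric(tol) || tol <= 0) abort("`tol` must be > 0.")
  v <- rep(1 / gm$n, gm$n)
  it <- 0L
  repeat {
    it <- it + 1L
    v_new <- g_matvec(gm, v)
    v_new <- v_new / sum(v_new)
    res <- sum(abs(v_new - v))
    v <- v_new
    if (res < tol) break
    if (it >= max_iter) {
      abort(sprintf("PageRank did not converge in %d iterations (last L1 residual %.3e).",
                    max_iter, res))
    }
  }
  k <- integer(gm$n)
  k[order(-v, seq_len(gm$n))] <- seq_len(gm$n)
  structure(
    list(table = tibble(node_id = seq_len(gm$n) - 1L, p = v, k = k),
         iterations = it, residual = res, alpha = gm$alpha),
    class = "pagerank"
  )
}

#' @export
print.pagerank <- function(x, ...) {
  cat(sprintf("<pagerank> N = %d, %d iterations, final L1 residual %.2e\n",
              nrow(x$table), x$iterations, x$residual))
  print(head(arrange(x$table, .data$k), 5L))
  invisible(x)
}
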