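# Fixture builders and an independent dense reference implementation of the
# Google-matrix algebra, used as oracles against the package's sparse paths.

# random directed graph with no self-loops, possibly with dangling nodes
random_graph <- function(n, n_edges, seed) {
  withr::with_seed(seed, {
    from <- sample.int(n, n_edges * 2L, replace = TRUE) - 1L
    to <- sample.int(n, n_edges * 2L, replace = TRUE) - 1L
    keep <- from != to
    edges <- unique(data.frame(from = from[keep], to = to[keep]))[seq_len(n_edges), ]
    edges <- edges[!is.na(edges$from), , drop = FALSE]
    hl_graph(edges, n = n)
  })
}

# dense Google matrix built from first principles (independent of the
# package's sparse representation)
dense_google <- function(g, alpha = 0.85) {
  n <- g$n
  A <- matrix(0, n, n)
  A[cbind(g$edges$to + 1L, g$edges$from + 1L)] <- 1
  k_out <- colSums(A)
  S <- sweep(A, 2L, pmax(k_out, 1), "/")
  S[, k_out == 0] <- 1 / n
  alpha * S + (1 - alpha) / n
}

# dense reduced matrix by direct block solve (the exact formula, written
# independently of the package internals)
dense_reduce <- function(Gd, subset0) {
  r <- subset0 + 1L
  s <- setdiff(seq_len(nrow(Gd)), r)
  Gd[r, r, drop = FALSE] +
    Gd[r, s, drop = FALSE] %*%
    solve(diag(length(s)) - Gd[s, s, drop = FALSE], Gd[s, r, drop = FALSE])
}

# plain dense MCL reference: textbook iteration on a ready-made stochastic
# matrix, no pruning tricks, used to cross-check the sparse implementation
dense_mcl_reference <- function(M, inflation = 2, expansion = 2L,
                                iter = 100L) {
  for (i in seq_len(iter)) {
    M <- M
    E <- diag(nrow(M))
    for (k in seq_len(expansion)) E <- E %*% M
    E <- E^inflation
    E <- sweep(E, 2L, colSums(E), "/")
    if (max(abs(E - M)) < 1e-10) return(E)
    M <- E
  }
  M
}

# shared expensive fixtures, built once per test run
.cache <- new.env(parent = emptyenv())

default_run <- function() {
  if (is.null(.cache$default_run)) {
    sg <- suppressMessages(generate_global_graph(synthetic_spec()))
    .cache$default_graph <- sg
    .cache$default_run <- suppressMessages(run_pipeline(sg))
  }
  .cache$default_run
}

default_graph <- function() {
  default_run()
  .cache$default_graph
}
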