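#' Reduced Google matrix of a node subset
#'
#' Computes the `N_r x N_r` reduced Google matrix `G_R` summarizing all direct
#' and indirect transitions of the full Google matrix among a chosen subset
#' of nodes, and decomposes it as `G_R = G_rr + G_pr + G_qr`:
#'
#' * `G_rr` — the subset block of `G` itself (direct links plus their
#'   teleportation floor);
#' * `G_pr` — the projector part dominated by the PageRank of the complement;
#'   each of its columns is close to the reduced PageRank vector and carries
#'   little link-specific information;
#' * `G_qr` — the nontrivial indirect part, accumulating all pathways that
#'   leave the subset, wander through the complement, and return. Its large
#'   entries define the hidden links used downstream.
#'
#' Two algebraically equivalent routes are provided. `"exact"` densifies `G`,
#' partitions it into subset (`r`) and complement (`s`) blocks and evaluates
#' `G_R = G_rr + G_rs (1 - G_ss)^{-1} G_sr` by a direct linear solve — the
#' reference for small graphs. `"projector_series"` never forms an
#' `N_s x N_s` dense matrix: the leading left/right eigenvectors of `G_ss`
#' (eigenvalue `lambda_c < 1`) are obtained by power iteration, the spectral
#' projector `P_c` and its complement `Q_c = 1 - P_c` are applied as rank-one
#' updates, `G_pr = G_rs P_c G_sr / (1 - lambda_c)`, and
#' `G_qr = G_rs [sum_l (Q_c G_ss Q_c)^l] Q_c G_sr` is summed until the added
#' term's max-norm falls below `eps`.
#'
#' The reduced matrix is column-stochastic and preserves the global PageRank
#' probabilities of the subset up to one normalization constant.
#'
#' @param gm a [google_matrix()].
#' @param subset integer vector of 0-based node ids (order is kept and fixes
#'   the row/column order of all returned matrices).
#' @param method `"projector_series"` (default; scalable) or `"exact"`
#'   (dense oracle for small `N`).
#' @param eps series truncation tolerance on the max-norm of the added term.
#'   Default `1e-12`.
#' @param max_terms series length cap; defaults to
#'   `max(1000, ceiling(10 / (1 - lambda_c)))`, capped at 10000. Exceeding it
#'   without reaching `eps` is an error.
#' @param power_tol L1 tolerance of the eigenvector power iterations.
#'   Default `1e-14`.
#' @param power_max_iter power-iteration cap. Default 100000.
#' @return An object of class `regomax`: `subset`, dense matrices `G_R`,
#'   `G_rr`, `G_pr`, `G_qr` (rows/cols ordered as `subset`), `lambda_c`,
#'   `series_terms`, `method`.
#' @export
reduce_google_matrix <- function(gm, subset,
                                 method = c("projector_series", "exact"),
                                 eps = 1e-12, max_terms = NULL,
                                 power_tol = 1e-14, power_max_iter = 100000L) {
  stopifnot(inherits(gm, "google_matrix"))
  method <- match.arg(method)
  subset <- as.integer(subset)
  if (length(subset) == 0L) abort("`subset` is empty.")
  if (anyDuplicated(subset)) abort("`subset` has duplicate node ids.")
  if (any(subset < 0L | subset >= gm$n)) abort("`subset` ids must lie in 0..N-1.")
  if (!is.numeric(eps) || eps <= 0) abort("`eps` must be > 0.")
  if (method == "exact") {
    reduce_exact_impl(gm, subset)
  } else {
    if (length(subset) >= gm$n) {
      abort("projector series requires a non-empty complement; use method = \"exact\".")
    }
    reduce_series_impl(gm, subset, eps, max_terms, power_tol, power_max_iter)
  }
}

new_regomax <- function(subset, G_R, G_rr, G_pr, G_qr, lambda_c, series_terms,
                        method) {
  ids <- as.character(subset)
  dimnames(G_R) <- dimnames(G_rr) <- dimnames(G_pr) <- dimnames(G_qr) <-
    list(ids, ids)
  structure(list(subset = subset, G_R = G_R, G_rr = G_rr, G_pr = G_pr,
                 G_qr = G_qr, lambda_c = lambda_c,
                 series_terms = series_terms, method = method),
            class = "regomax")
}

#' @export
print.regomax <- function(x, ...) {
  cat(sprintf("<regomax> N_r = %d, method = %s, lambda_c = %s, %s series term(s)\n",
              length(x$subset), x$method,
              ifelse(is.na(x$lambda_c), "NA", format(x$lambda_c, digits = 6)),
              ifelse(is.na(x$series_terms), "-", x$series_terms)))
  cat(sprintf("  column-sum deviation of G_R from 1: %.2e\n",
              max(abs(colSums(x$G_R) - 1))))
  invisible(x)
}

reduce_exact_impl <- function(gm, subset) {
  Gd <- as.matrix(gm)
  r <- subset + 1L
  s <- setdiff(seq_len(gm$n), r)
  G_rr <- Gd[r, r, drop = FALSE]
  if (length(s) == 0L) {
    z <- matrix(0, length(r), length(r))
    return(new_regomax(subset, G_rr, G_rr, z, z,
                       lambda_c = NA_real_, series_terms = NA_integer_,
                       method = "exact"))
  }
  G_ss <- Gd[s, s, drop = FALSE]
  G_rs <- Gd[r, s, drop = FALSE]
  G_sr <- Gd[s, r, drop = FALSE]
  ns <- length(s)
  G_R <- G_rr + G_rs %*% solve(diag(ns) - G_ss, G_sr)
  # leading eigenpair of G_ss fixes the projector split of the indirect part
  er <- eigen(G_ss)
  i_max <- which.max(Re(er$values))
  lambda_c <- Re(er$values[i_max])
  psi_r <- Re(er$vectors[, i_max])
  el <- eigen(t(G_ss))
  j_max <- which.max(Re(el$values))
  psi_l <- Re(el$vectors[, j_max])
  if (sum(psi_r) < 0) psi_r <- -psi_r
  if (sum(psi_l) < 0) psi_l <- -psi_l
  denom <- sum(psi_l * psi_r)
  G_pr <- (G_rs %*% psi_r) %*% (crossprod(psi_l, G_sr)) / (denom * (1 - lambda_c))
  G_qr <- G_R - G_rr - G_pr
  new_regomax(subset, G_R, G_rr, G_pr, G_qr, lambda_c,
              series_terms = NA_integer_, method = "exact")
}

reduce_series_impl <- function(gm, subset, eps, max_terms, power_tol,
                               power_max_iter) {
  n <- gm$n
  alpha <- gm$alpha
  r <- subset + 1L
  s <- setdiff(seq_len(n), r)
  ns <- length(s)
  nr <- length(r)
  S_ss <- gm$S[s, s, drop = FALSE]
  S_rs <- gm$S[r, s, drop = FALSE]
  S_sr <- gm$S[s, r, drop = FALSE]
  S_rr <- gm$S[r, r, drop = FALSE]
  d_s <- gm$dangling[s]
  d_r <- gm$dangling[r]
  tele <- (1 - alpha) / n

  # implicit block products; V is a dense (ns x k) matrix
  gss_mult <- function(V) {
    extra <- alpha * colSums(V[d_s, , drop = FALSE]) / n + tele * colSums(V)
    out <- alpha * as.matrix(S_ss %*% V)
    sweep(out, 2L, extra, `+`)
  }
  gss_tmult <- function(W) {
    tot <- colSums(W)
    out <- alpha * as.matrix(Matrix::crossprod(S_ss, W))
    out <- sweep(out, 2L, tele * tot, `+`)
    out[d_s, ] <- out[d_s, , drop = FALSE] +
      matrix(alpha * tot / n, sum(d_s), length(tot), byrow = TRUE)
    out
  }
  grs_mult <- function(V) {
    extra <- alpha * colSums(V[d_s, , drop = FALSE]) / n + tele * colSums(V)
    out <- alpha * as.matrix(S_rs %*% V)
    sweep(out, 2L, extra, `+`)
  }

  # dense ns x nr and nr x nr blocks of the full G
  col_const_sr <- alpha * d_r / n + tele
  G_sr <- alpha * as.matrix(S_sr)
  G_sr <- sweep(G_sr, 2L, col_const_sr, `+`)
  G_rr <- alpha * as.matrix(S_rr)
  G_rr <- sweep(G_rr, 2L, col_const_sr, `+`)

  # leading right/left eigenvectors of G_ss by power iteration
  power_iter <- function(mult) {
    v <- rep(1 / ns, ns)
    lam <- NA_real_
    for (it in seq_len(power_max_iter)) {
      w <- mult(matrix(v, ncol = 1L))[, 1L]
      lam <- sum(abs(w))
      w <- w / lam
      if (sum(abs(w - v)) < power_tol) return(list(vec = w, lambda = lam, it = it))
      v <- w
    }
    abort(sprintf("power iteration for the complement eigenvector did not converge in %d iterations.",
                  power_max_iter))
  }
  right <- power_iter(gss_mult)
  left <- power_iter(gss_tmult)
  lambda_c <- right$lambda
  psi_r <- right$vec
  psi_l <- left$vec
  denom <- sum(psi_l * psi_r)

  pc_mult <- function(V) psi_r %o% (as.numeric(crossprod(psi_l, V)) / denom)
  qc_mult <- function(V) V - pc_mult(V)

  G_pr <- grs_mult(pc_mult(G_sr)) / (1 - lambda_c)

  if (is.null(max_terms)) {
    # heuristic cap: generous floor plus a lambda_c-scaled allowance, since
    # the series' true rate is set by the complement's subleading spectrum
    max_terms <- min(10000L, max(1000L, as.integer(ceiling(10 / (1 - lambda_c)))))
  }
  V <- qc_mult(G_sr)
  G_qr <- matrix(0, nr, nr)
  terms <- 0L
  repeat {
    term <- grs_mult(V)
    G_qr <- G_qr + term
    terms <- terms + 1L
    if (max(abs(term)) < eps) break
    if (terms >= max_terms) {
      abort(sprintf(paste0("indirect-pathway series not converged after %d terms ",
                           "(last term max-norm %.3e, lambda_c = %.6f); ",
                           "raise `max_terms` or relax `eps`."),
                    terms, max(abs(term)), lambda_c))
    }
    V <- qc_mult(gss_mult(V))
  }
  G_R <- G_rr + G_pr + G_qr
  new_regomax(subset, G_R, G_rr, G_pr, G_qr, lambda_c, terms,
              method = "projector_series")
}

#' Reduced PageRank of a regomax object
#'
#' PageRank of the reduced matrix `G_R`, computed by dense power iteration.
#' By construction it equals the global PageRank restricted to the subset and
#' renormalized to sum 1.
#'
#' @param rg a [reduce_google_matrix()] result.
#' @param tol,max_iter convergence control as in [pagerank()].
#' @return Tibble `node_id`, `p`, `k` over the subset.
#' @export
reduced_pagerank <- function(rg, tol = 1e-14, max_iter = 10000L) {
  stopifnot(inherits(rg, "regomax"))
  nr <- length(rg$subset)
  v <- rep(1 / nr, nr)
  for (it in seq_len(max_iter)) {
    w <- as.numeric(rg$G_R %*% v)
    w <- w / sum(w)
    if (sum(abs(w - v)) < tol) {
      k <- integer(nr)
      k[order(-w, seq_len(nr))] <- seq_len(nr)
      return(tibble(node_id = rg$subset, p = w, k = k))
    }
    v <- w
  }
  abort("reduced PageRank power iteration did not converge.")
}
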