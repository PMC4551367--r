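# Mutual-information network baselines: ARACNE (relevance network pruned by
# the data-processing inequality) and MRNET (maximum relevance / minimum
# redundancy forward selection), plus time-delayed variants that score each
# pair by the maximum MI over source lags and orient edges by the best lag.

#' Pairwise mutual information matrix
#'
#' Two estimators are provided. `"binned"` (default) discretizes each gene
#' into `ceiling(sqrt(T))` equal-frequency bins and applies the
#' Miller-Madow bias correction (clamped at zero). `"gaussian"` uses the
#' closed form `-1/2 log(1 - cor^2)` and exists mainly for tests against the
#' bivariate-normal formula; its diagonal is capped at the value for
#' `|cor| = 1 - 1e-12` to stay finite.
#'
#' @param expr Expression matrix (genes x time), `T >= 4`.
#' @param estimator `"binned"` or `"gaussian"`.
#' @return An `mi_matrix`: an n x n numeric matrix (nats) with attribute
#'   `estimator`; symmetric; zero-lag.
#' @export
mi_matrix <- function(expr, estimator = c("binned", "gaussian")) {
  estimator <- match.arg(estimator)
  check_expression(expr)
  if (ncol(expr) < 4) gn_stop("need at least 4 time points", "gn_format_error")
  cons <- apply(expr, 1, function(r) var(r) == 0)
  if (any(cons))
    gn_warn(sprintf("%d constant gene(s); their MI rows are zero", sum(cons)))
  M <- if (estimator == "gaussian") gaussian_mi(expr, expr)
       else binned_mi(expr, expr)
  if (any(cons)) { M[cons, ] <- 0; M[, cons] <- 0 }
  dimnames(M) <- list(rownames(expr), rownames(expr))
  structure(M, estimator = estimator, class = c("mi_matrix", "matrix"))
}

#' @noRd
gaussian_mi <- function(A, B) {
  r <- suppressWarnings(cor(t(A), t(B)))
  r[is.na(r)] <- 0
  r <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  -0.5 * log(1 - r^2)
}

# equal-frequency discretization of each row into ceiling(sqrt(T)) bins
#' @noRd
discretize_rows <- function(A) {
  Tn <- ncol(A)
  nb <- ceiling(sqrt(Tn))
  D <- t(apply(A, 1, function(r)
    ceiling(rank(r, ties.method = "first") * nb / Tn)))
  list(D = D, nb = nb)
}

# cross MI between rows of A and rows of B (same number of columns),
# Miller-Madow corrected, clamped at zero; vectorized over all pairs via
# per-bin indicator cross-products
#' @noRd
binned_mi <- function(A, B) {
  da <- discretize_rows(A); db <- discretize_rows(B)
  Tn <- ncol(A); nb <- max(da$nb, db$nb)
  Ia <- lapply(seq_len(nb), function(a) (da$D == a) * 1)
  Ib <- lapply(seq_len(nb), function(b) (db$D == b) * 1)
  pa <- vapply(Ia, rowMeans, numeric(nrow(A)))
  pb <- vapply(Ib, rowMeans, numeric(nrow(B)))
  MI <- matrix(0, nrow(A), nrow(B))
  Kj <- matrix(0, nrow(A), nrow(B))   # occupied joint cells
  for (a in seq_len(nb)) {
    if (all(pa[, a] == 0)) next
    for (b in seq_len(nb)) {
      if (all(pb[, b] == 0)) next
      pj <- tcrossprod(Ia[[a]], Ib[[b]]) / Tn
      pos <- pj > 0
      Kj <- Kj + pos
      den <- outer(pa[, a], pb[, b])
      MI[pos] <- MI[pos] + pj[pos] * log(pj[pos] / den[pos])
    }
  }
  Ka <- rowSums(pa > 0); Kb <- rowSums(pb > 0)
  MI <- MI + (outer(Ka, Kb, "+") - Kj - 1) / (2 * Tn)
  pmax(MI, 0)
}

#' Time-delayed mutual information matrix
#'
#' `values[i, j]` is the maximum over lags `1..max_lag` of the MI between
#' the source series `x_i` shifted back by the lag and the target `x_j`;
#' `best_lag[i, j]` records the arg-max (ties resolved to the smallest lag).
#' The result is directional (not symmetric in general).
#'
#' @inheritParams mi_matrix
#' @param max_lag Largest source lag scanned, `T > max_lag + 3`.
#' @return An `mi_matrix` with attributes `best_lag` (integer matrix) and
#'   `estimator`.
#' @export
time_delayed_mi_matrix <- function(expr, max_lag,
                                   estimator = c("binned", "gaussian")) {
  estimator <- match.arg(estimator)
  check_expression(expr)
  Tn <- ncol(expr)
  if (Tn <= max_lag + 3)
    gn_stop("need T > max_lag + 3", "gn_format_error")
  n <- nrow(expr)
  vals <- matrix(-Inf, n, n)
  best <- matrix(NA_integer_, n, n)
  for (lag in seq_len(max_lag)) {
    A <- expr[, 1:(Tn - lag), drop = FALSE]        # source leads ...
    B <- expr[, (1 + lag):Tn, drop = FALSE]        # ... target follows
    M <- if (estimator == "gaussian") gaussian_mi(A, B) else binned_mi(A, B)
    upd <- M > vals                                # strict: ties keep the smaller lag
    vals[upd] <- M[upd]
    best[upd] <- lag
  }
  dimnames(vals) <- list(rownames(expr), rownames(expr))
  dimnames(best) <- dimnames(vals)
  structure(vals, estimator = estimator, best_lag = best,
            class = c("mi_matrix", "matrix"))
}

# shared post-processing: symmetrize a TD matrix, remember orientation
#' @noRd
mi_prepare <- function(mi) {
  bl <- attr(mi, "best_lag")
  M <- unclass(mi)
  attributes(M) <- list(dim = dim(mi), dimnames = dimnames(mi))
  if (!is.null(bl)) {
    sym <- pmax(M, t(M))
    fwd <- M >= t(M)       # TRUE: orient i -> j
    list(M = sym, td = TRUE, fwd = fwd)
  } else {
    list(M = M, td = FALSE, fwd = NULL)
  }
}

# turn a symmetric score matrix into an edge ranking; undirected pairs are
# emitted in both directions unless a TD orientation is supplied
#' @noRd
mi_ranking <- function(M, keep, prep, label) {
  idx <- which(keep & upper.tri(M), arr.ind = TRUE)
  ids <- rownames(M)
  if (nrow(idx) == 0)
    return(new_ranking(character(0), character(0), numeric(0),
                       method_label = label))
  sc <- M[idx]
  if (prep$td) {
    f <- prep$fwd[idx]
    src <- ifelse(f, idx[, 1], idx[, 2])
    tgt <- ifelse(f, idx[, 2], idx[, 1])
    new_ranking(ids[src], ids[tgt], sc, method_label = label)
  } else {
    new_ranking(c(ids[idx[, 1]], ids[idx[, 2]]),
                c(ids[idx[, 2]], ids[idx[, 1]]),
                c(sc, sc), method_label = label)
  }
}

#' ARACNE relevance network with DPI pruning
#'
#' In every triangle of the MI graph the weakest edge is removed when it is
#' smaller than both others minus `dpi_epsilon` (the data-processing
#' inequality: such an edge is consistent with an indirect interaction).
#' Surviving edges are ranked by MI. With a time-delayed input matrix the
#' surviving pairs are oriented by the recorded best lag; otherwise both
#' directions are emitted.
#'
#' @param mi An `mi_matrix` from [mi_matrix()] or
#'   [time_delayed_mi_matrix()].
#' @param dpi_epsilon DPI tolerance (default 0: strict-inequality removal).
#' @return An `edge_ranking`.
#' @export
aracne <- function(mi, dpi_epsilon = 0) {
  prep <- mi_prepare(mi)
  M <- prep$M
  diag(M) <- 0
  removed <- dpi_mask_cpp(M, dpi_epsilon)
  keep <- (M > 0) & !removed
  mi_ranking(M, keep, prep, if (prep$td) "td-aracne" else "aracne")
}

#' MRNET maximum-relevance minimum-redundancy network
#'
#' For each target gene, predictors are selected greedily by relevance minus
#' mean redundancy against the already-selected set while the best score
#' stays positive; the edge score of a pair is the larger of its two
#' directional selection scores. Time-delayed input is symmetrized and
#' oriented by best lag as in [aracne()].
#'
#' @param mi An `mi_matrix`.
#' @return An `edge_ranking`.
#' @export
mrnet <- function(mi) {
  prep <- mi_prepare(mi)
  M <- prep$M
  diag(M) <- 0
  S <- mrnet_scores_cpp(M)
  E <- pmax(S, t(S))
  dimnames(E) <- dimnames(M)
  mi_ranking(E, E > 0, prep, if (prep$td) "td-mrnet" else "mrnet")
}
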