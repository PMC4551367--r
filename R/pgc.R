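# Pairwise (bivariate) Granger causality: for every ordered gene pair
# (i -> j) the full bivariate VAR(p) on {i, j} is compared against the
# univariate autoregression of j alone through an F-test.

#' F-test comparing full and reduced Granger regressions
#'
#' Computes `F = ((RSS_reduced - RSS_full)/p) / (RSS_full/(m - 2p))`, which
#' under independence of the two series follows the `F(p, m - 2p)`
#' distribution (`m = T - p` stacked equations). Negative numerators, which
#' can only arise through ill-conditioning since the reduced model is nested,
#' are clamped to zero with a warning.
#'
#' @param rss_full RSS of the bivariate (full) model; must be > 0.
#' @param rss_reduced RSS of the univariate (reduced) model.
#' @param p Model order.
#' @param m Number of stacked equations (T - p); must exceed `2p`.
#' @return A list with `f_score`, `dof1` (= p), `dof2` (= m - 2p) and
#'   `p_value` (upper tail).
#' @export
f_score_test <- function(rss_full, rss_reduced, p, m) {
  if (m <= 2 * p)
    gn_stop(sprintf("insufficient data: m=%d must exceed 2p=%d", m, 2 * p),
            "gn_insufficient_data_error")
  if (rss_full <= 0)
    gn_stop("degenerate fit: full-model RSS is zero", "gn_degenerate_error")
  f <- ((rss_reduced - rss_full) / p) / (rss_full / (m - 2 * p))
  if (f < 0) {
    gn_warn("negative F numerator clamped to 0 (ill-conditioned fit)")
    f <- 0
  }
  list(f_score = f, dof1 = p, dof2 = m - 2L * p,
       p_value = pf(f, p, m - 2 * p, lower.tail = FALSE))
}

#' Pairwise Granger causality over all ordered gene pairs
#'
#' Fits, for every ordered pair (i, j), the bivariate VAR(p) of genes i and j
#' predicting j (full model) and the univariate autoregression of j (reduced
#' model), and scores the edge i -> j by the upper-tail F-test p-value.
#' Scores are `-log10(p)`; ties are broken by larger F, then lexicographic
#' (source, target). A Benjamini-Hochberg adjusted p-value column is included
#' as auxiliary output; no thresholding is applied.
#'
#' @param expr Expression matrix (genes x time), `T > 2p + 1`.
#' @param p Model order.
#' @return An `edge_ranking` with `n*(n-1)` rows and columns `source`,
#'   `target`, `score`, `p_value`, `f_score`, `p_adjusted`.
#' @export
pgc_all_pairs <- function(expr, p) {
  check_expression(expr)
  n <- nrow(expr); Tn <- ncol(expr)
  m <- Tn - p
  if (m <= 2 * p)
    gn_stop(sprintf("T=%d too short for pairwise GC at p=%d (need T > 3p)",
                    Tn, p), "gn_insufficient_data_error")
  d <- build_design(expr, p)
  G <- crossprod(d$X)            # (np x np) lag cross-products
  V <- crossprod(d$X, d$Y)       # (np x n)
  yty <- colSums(d$Y^2)
  fmat <- pgc_f_matrix_cpp(G, V, yty, n, p, m)
  src <- rep(seq_len(n), times = n)
  tgt <- rep(seq_len(n), each = n)
  keep <- src != tgt
  src <- src[keep]; tgt <- tgt[keep]
  f <- fmat[cbind(src, tgt)]
  f[f < 0] <- 0
  pv <- pf(f, p, m - 2 * p, lower.tail = FALSE)
  ids <- rownames(expr)
  r <- new_ranking(ids[src], ids[tgt], score = -log10(pv), p_value = pv,
                   extra = list(f_score = f), tie_score = f,
                   method_label = "pgc")
  r$p_adjusted <- stats::p.adjust(r$p_value, method = "BH")
  r
}
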