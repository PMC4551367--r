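# Edge rankings and their evaluation against golden-standard edge sets:
# precision-recall curves (step-interpolated AUPRC), F1 at a rank cutoff and
# top-k overlap counts. The evaluation universe is the set of all ordered
# non-self gene pairs; rankings shorter than a requested cutoff are padded
# with zero-score edges in lexicographic order so every prefix is defined.

#' @noRd
new_ranking <- function(source, target, score, p_value = NULL, extra = NULL,
                        tie_score = NULL, method_label = NA_character_,
                        sort = TRUE) {
  df <- data.frame(source = as.character(source),
                   target = as.character(target),
                   score = as.numeric(score), stringsAsFactors = FALSE)
  if (!is.null(p_value)) df$p_value <- p_value
  if (!is.null(extra)) for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  if (any(df$source == df$target))
    gn_stop("self-edges are not allowed in a ranking", "gn_format_error")
  if (sort && nrow(df) > 0) {
    ts <- if (is.null(tie_score)) rep(0, nrow(df)) else tie_score
    df <- df[order(-df$score, -ts, df$source, df$target), , drop = FALSE]
    rownames(df) <- NULL
  }
  structure(df, method_label = method_label,
            class = c("edge_ranking", "data.frame"))
}

#' Rank edges from a VAR coefficient matrix
#'
#' Scores the edge i -> j by aggregating `|B|` over its p lag entries
#' (`max` by default; `sum` and `l2` are alternatives), excludes the
#' autoregressive diagonal, and sorts by score with deterministic
#' lexicographic (source, target) tie-breaking.
#'
#' @param B Coefficient matrix ((n*p) x n, lag-major blocks) or a `gc_fit`.
#' @param gene_ids Gene identifiers (length n).
#' @param aggregation `"max"`, `"sum"` or `"l2"`.
#' @param method_label Optional label stored on the ranking.
#' @return An `edge_ranking` with `n*(n-1)` rows.
#' @export
rank_from_coefficients <- function(B, gene_ids,
                                   aggregation = c("max", "sum", "l2"),
                                   method_label = NA_character_) {
  aggregation <- match.arg(aggregation)
  if (is.list(B) && !is.null(B$B)) B <- B$B
  n <- length(gene_ids)
  p <- nrow(B) / n
  if (p != round(p))
    gn_stop("nrow(B) is not a multiple of length(gene_ids)", "gn_shape_error")
  p <- as.integer(p)
  A <- abs(B)
  S <- switch(aggregation,
              max = {
                acc <- A[1:n, , drop = FALSE]
                for (l in seq_len(p - 1))
                  acc <- pmax(acc, A[(l * n + 1):((l + 1) * n), , drop = FALSE])
                acc
              },
              sum = {
                acc <- A[1:n, , drop = FALSE]
                for (l in seq_len(p - 1))
                  acc <- acc + A[(l * n + 1):((l + 1) * n), , drop = FALSE]
                acc
              },
              l2 = {
                acc <- A[1:n, , drop = FALSE]^2
                for (l in seq_len(p - 1))
                  acc <- acc + A[(l * n + 1):((l + 1) * n), , drop = FALSE]^2
                sqrt(acc)
              })
  src <- rep(seq_len(n), times = n)
  tgt <- rep(seq_len(n), each = n)
  keep <- src != tgt
  new_ranking(gene_ids[src[keep]], gene_ids[tgt[keep]], S[cbind(src, tgt)][keep],
              method_label = method_label)
}

#' @noRd
gold_keys <- function(gold) {
  edges <- if (inherits(gold, "gold_standard")) gold$edges else gold
  unique(paste0(edges$source, "\r", edges$target))
}

#' @noRd
ranking_keys <- function(ranking) paste0(ranking$source, "\r", ranking$target)

# lexicographically-first (k - nrow) ordered non-self pairs over `ids` not
# already in the ranking, used to pad short rankings with zero-score edges
#' @noRd
pad_hits <- function(ranking, gold_set, k, ids) {
  extra <- k - nrow(ranking)
  if (extra <= 0 || is.null(ids)) return(0L)
  g <- expand.grid(target = sort(ids), source = sort(ids),
                   stringsAsFactors = FALSE)[, c("source", "target")]
  g <- g[g$source != g$target, ]
  key <- paste0(g$source, "\r", g$target)
  key <- setdiff(key, ranking_keys(ranking))
  sum(head(key, extra) %in% gold_set)
}

#' Precision, recall and F1 at a rank cutoff
#'
#' Evaluates the top-`k` prefix of a ranking against the golden standard.
#' At `k = |gold|`, precision, recall and F1 coincide. If the ranking has
#' fewer than `k` entries it is padded with zero-score edges over the
#' `universe` gene set in lexicographic order (with a warning); without a
#' universe the full list is used as-is.
#'
#' @param ranking An `edge_ranking`.
#' @param gold A `gold_standard` or a data frame with `source`, `target`.
#' @param k Rank cutoff, >= 1.
#' @param universe Optional character vector of gene ids defining the
#'   all-ordered-pairs evaluation universe used for padding.
#' @return A list with `precision`, `recall`, `f1`, `hits` and `k`.
#' @export
f1_at_k <- function(ranking, gold, k, universe = NULL) {
  if (k < 1) gn_stop("k must be >= 1", "gn_parameter_error")
  gset <- gold_keys(gold)
  if (length(gset) == 0) gn_stop("golden standard is empty", "gn_parameter_error")
  hits <- sum(head(ranking_keys(ranking), k) %in% gset)
  denom <- k
  if (k > nrow(ranking)) {
    gn_warn(sprintf("ranking has %d < k=%d edges; padding with zero-score edges",
                    nrow(ranking), k))
    hits <- hits + pad_hits(ranking, gset, k, universe)
    if (is.null(universe)) denom <- nrow(ranking)
  }
  precision <- if (denom > 0) hits / denom else 0
  recall <- hits / length(gset)
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1, hits = hits, k = k)
}

#' Number of golden-standard edges among the top k
#'
#' @inheritParams f1_at_k
#' @return Integer overlap count.
#' @export
topk_overlap <- function(ranking, gold, k, universe = NULL) {
  gset <- gold_keys(gold)
  if (length(gset) == 0) return(0L)
  hits <- sum(head(ranking_keys(ranking), k) %in% gset)
  if (k > nrow(ranking)) hits <- hits + pad_hits(ranking, gset, k, universe)
  as.integer(hits)
}

#' Precision-recall curve and AUPRC
#'
#' Sweeps every prefix of the ranking, recording precision and recall, and
#' integrates by step interpolation: AUPRC = sum over gold hits of the
#' precision at the hit's rank divided by |gold|. Gold edges never ranked
#' simply cap the attainable recall.
#'
#' @inheritParams f1_at_k
#' @return A `prc_curve` list with `points` (data frame `rank`, `recall`,
#'   `precision`) and `auprc`.
#' @export
prc <- function(ranking, gold) {
  gset <- gold_keys(gold)
  if (length(gset) == 0) gn_stop("golden standard is empty", "gn_parameter_error")
  hit <- ranking_keys(ranking) %in% gset
  if (!any(hit))
    gn_warn("no golden-standard edge appears in the ranking")
  cum <- cumsum(hit)
  kk <- seq_along(hit)
  precision <- cum / kk
  recall <- cum / length(gset)
  auprc <- sum(precision[hit]) / length(gset)
  structure(list(points = data.frame(rank = kk, recall = recall,
                                     precision = precision),
                 auprc = auprc),
            class = "prc_curve")
}

#' Summaries of log10 p-value distributions by scenario
#'
#' Given a named list of rankings (or data frames) carrying `p_value`
#' columns, returns per-scenario quantile summaries of log10 p, the layout
#' used to contrast e.g. random pairs against golden-standard pairs.
#'
#' @param rankings Named list; each element needs a `p_value` column.
#' @param probs Quantile probabilities.
#' @return Data frame with one row per scenario: `n`, `median_log10_p` and
#'   one column per requested quantile.
#' @export
pvalue_distribution_report <- function(rankings,
                                       probs = c(0.05, 0.25, 0.5, 0.75, 0.95)) {
  if (is.null(names(rankings)) || any(!nzchar(names(rankings))))
    gn_stop("rankings must be a named list", "gn_parameter_error")
  rows <- lapply(names(rankings), function(nm) {
    pv <- rankings[[nm]]$p_value
    if (is.null(pv)) gn_stop(sprintf("scenario '%s' has no p_value column", nm),
                             "gn_parameter_error")
    lp <- log10(pmax(pv, .Machine$double.xmin))
    q <- quantile(lp, probs, names = FALSE)
    out <- data.frame(scenario = nm, n = length(lp),
                      median_log10_p = stats::median(lp))
    for (i in seq_along(probs)) out[[sprintf("q%02d", round(100 * probs[i]))]] <- q[i]
    out
  })
  do.call(rbind, rows)
}
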