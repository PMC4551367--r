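# CGC-2SPR: conditional Granger causality with a two-step prior-knowledge
# ridge regularization.
#
# Step 1 fits an ordinary ridge VAR, giving a preliminary coefficient matrix
# B*. Step 2 builds a prior weight matrix W from a pairwise association
# graph (tiled across the p lag blocks), flips the sign of each W entry to
# match B* (prior magnitudes carry no sign information, but regulation can be
# repressive), and solves
#
#   min_B 1/2 ||Y - XB||_F^2 + 1/2 lambda1 ||B - lambda2 W||_F^2
#
# whose stationarity condition gives the closed form
#
#   B = (X'X + lambda1 I)^{-1} (X'Y + lambda1 lambda2 W).
#
# lambda2 = "auto" balances data and prior scales as max|B*| / max|W|.

#' Configuration for a CGC-2SPR fit
#'
#' @param lambda1 Ridge penalty, > 0 (reused for step 1 and step 2).
#' @param lambda2 Prior target scale, >= 0, or `"auto"` to resolve as
#'   `max|B*| / max|W|` after step 1.
#' @param p Model order.
#' @param mapping Prior weight mapping: `"linear"` rescales continuous
#'   weights so the largest magnitude is 1; `"binary"` maps presence to 1.
#' @param aggregation Lag aggregation used when extracting edge scores.
#' @return An `spr_config` list.
#' @export
spr_config <- function(lambda1, lambda2 = "auto", p,
                       mapping = c("linear", "binary"),
                       aggregation = c("max", "sum", "l2")) {
  if (!is.numeric(lambda1) || lambda1 <= 0)
    gn_stop("lambda1 must be > 0", "gn_parameter_error")
  if (!(identical(lambda2, "auto") || (is.numeric(lambda2) && lambda2 >= 0)))
    gn_stop("lambda2 must be >= 0 or \"auto\"", "gn_parameter_error")
  structure(list(lambda1 = lambda1, lambda2 = lambda2, p = as.integer(p),
                 mapping = match.arg(mapping),
                 aggregation = match.arg(aggregation)),
            class = "spr_config")
}

#' Build the tiled prior weight matrix W
#'
#' Maps a pairwise prior graph onto the (n*p) x n coefficient layout: an
#' n x n block W' is filled from the prior edge weights (zero where the prior
#' is silent; prior nodes absent from `gene_ids` are dropped with a message),
#' then stacked p times -- the prior carries no lag information, so every lag
#' block receives the same weights.
#'
#' @param prior An `edge_list` (directed; symmetrize undirected input at read
#'   time via [read_edge_list()]).
#' @param gene_ids Ordered gene universe of the expression matrix.
#' @param p Model order.
#' @param mapping `"linear"` (divide by the maximum weight, so max entry is
#'   1) or `"binary"` (any edge becomes 1).
#' @return A `prior_weight_matrix` list with `W` ((n*p) x n, unsigned),
#'   `signed = FALSE`, `mapping` and `dropped` (count of out-of-universe
#'   prior edges).
#' @export
build_prior_matrix <- function(prior, gene_ids, p,
                               mapping = c("linear", "binary")) {
  mapping <- match.arg(mapping)
  if (anyDuplicated(gene_ids))
    gn_stop("gene_ids must be unique", "gn_format_error")
  n <- length(gene_ids)
  si <- match(prior$source, gene_ids)
  ti <- match(prior$target, gene_ids)
  keep <- !is.na(si) & !is.na(ti)
  dropped <- sum(!keep)
  if (dropped > 0)
    message(sprintf("build_prior_matrix: dropped %d prior edge(s) outside the gene universe",
                    dropped))
  Wp <- matrix(0, n, n, dimnames = list(gene_ids, gene_ids))
  if (any(keep)) {
    w <- prior$weight[keep]
    if (any(w < 0))
      gn_stop("prior weights must be non-negative", "gn_format_error")
    w <- if (mapping == "binary") as.numeric(w != 0) else w / max(w)
    Wp[cbind(si[keep], ti[keep])] <- w
  } else if (nrow(prior) > 0) {
    gn_warn("all prior edges fall outside the gene universe; prior matrix is zero")
  }
  W <- do.call(rbind, rep(list(Wp), p))
  rownames(W) <- paste0(rep(gene_ids, p), "_lag", rep(seq_len(p), each = n))
  structure(list(W = W, signed = FALSE, mapping = mapping, n = n, p = p,
                 dropped = dropped),
            class = "prior_weight_matrix")
}

#' Sign-adjust a prior weight matrix by a preliminary estimate
#'
#' Entrywise, `W[k, j] <- sign(B*[k, j]) * |W[k, j]|`; entries where the
#' preliminary coefficient is exactly zero keep their positive sign. The
#' adjustment has per-lag resolution because B* does.
#'
#' @param pw A `prior_weight_matrix` with `signed = FALSE`.
#' @param b_star Preliminary coefficient matrix ((n*p) x n), typically the
#'   step-one ridge estimate.
#' @return The sign-adjusted `prior_weight_matrix` (`signed = TRUE`).
#' @export
sign_adjust <- function(pw, b_star) {
  if (is.list(b_star) && !is.null(b_star$B)) b_star <- b_star$B
  if (!all(dim(pw$W) == dim(b_star)))
    gn_stop(sprintf("shape mismatch: W is %dx%d, B* is %dx%d",
                    nrow(pw$W), ncol(pw$W), nrow(b_star), ncol(b_star)),
            "gn_shape_error")
  if (isTRUE(pw$signed))
    gn_stop("prior weight matrix is already signed", "gn_parameter_error")
  s <- sign(b_star)
  s[s == 0] <- 1
  pw$W <- s * abs(pw$W)
  pw$signed <- TRUE
  pw
}

#' Fit CGC-2SPR: two-step prior-knowledge ridge Granger causality
#'
#' Step 1 runs ordinary ridge at `cfg$lambda1` to obtain `B*`; step 2 builds
#' the tiled prior matrix, sign-adjusts it by `B*`, resolves
#' `lambda2 = "auto"` to `max|B*| / max|W|`, and evaluates the closed-form
#' solution of the prior-target ridge objective. When the prior is empty (or
#' `lambda2` resolves to 0), the fit degrades gracefully to ordinary ridge
#' with a warning.
#'
#' @param design A `var_design` from [build_design()] (its `p` must match
#'   `cfg$p`).
#' @param prior An `edge_list` prior graph.
#' @param cfg An `spr_config`.
#' @return A list with `result` (a `gc_fit` carrying `B`, residuals, RSS),
#'   `signed_W` (the sign-adjusted `prior_weight_matrix`),
#'   `resolved_lambda2`, and `b_star` (the step-one ridge coefficients).
#' @export
fit_cgc_2spr <- function(design, prior, cfg) {
  if (!inherits(cfg, "spr_config")) gn_stop("cfg must be an spr_config", "gn_parameter_error")
  if (cfg$p != design$p)
    gn_stop(sprintf("cfg$p=%d does not match design p=%d", cfg$p, design$p),
            "gn_parameter_error")
  X <- design$X; Y <- design$Y
  sv <- design_svd(X)
  Bstar <- ridge_coef_svd(sv, Y, cfg$lambda1)
  dimnames(Bstar) <- list(colnames(X), colnames(Y))

  pw <- build_prior_matrix(prior, design$gene_ids, design$p, cfg$mapping)
  maxW <- max(abs(pw$W))
  lambda2 <- cfg$lambda2
  if (identical(lambda2, "auto")) {
    if (maxW == 0) {
      gn_warn("prior matrix is zero; lambda2 \"auto\" falls back to 0 (ordinary ridge)")
      lambda2 <- 0
    } else {
      lambda2 <- max(abs(Bstar)) / maxW
    }
  }
  pw <- sign_adjust(pw, Bstar)

  if (lambda2 == 0 || maxW == 0) {
    B <- Bstar
  } else {
    # closed form, split so the X'Y part reuses the numerically stable ridge
    # recombination and the W part uses
    # (X'X + l1 I)^{-1} W = V diag(1/(d^2+l1)) V'W + (W - V V'W)/l1
    W <- pw$W
    VtW <- crossprod(sv$v, W)
    prior_part <- cfg$lambda1 * lambda2 * (sv$v %*% ((1 / (sv$d^2 + cfg$lambda1)) * VtW)) +
      lambda2 * (W - sv$v %*% VtW)
    B <- Bstar + prior_part
  }
  dimnames(B) <- list(colnames(X), colnames(Y))
  res <- finish_fit(B, X, Y, method = "cgc2spr", lambda1 = cfg$lambda1)
  res$lambda2 <- lambda2
  list(result = res, signed_W = pw, resolved_lambda2 = lambda2, b_star = Bstar)
}
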