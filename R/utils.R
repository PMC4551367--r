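# Internal helpers shared across modules.

#' @noRd
gn_stop <- function(msg, class) {
  stop(structure(class = c(class, "grangernet_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' @noRd
gn_warn <- function(msg, class = "grangernet_warning") {
  warning(structure(class = c(class, "warning", "condition"),
                    list(message = msg, call = sys.call(-1))))
}

# Deterministic 31-bit hash of a string, used to derive per-edge seeds so that
# identical edges always receive identical permutation streams.
#' @noRd
string_seed <- function(s, base_seed = 0L) {
  h <- as.double(base_seed %% 2147483587)
  for (c in utf8ToInt(s)) h <- (h * 131 + c) %% 2147483587
  as.integer(h)
}

#' @noRd
check_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr))
    gn_stop("expression data must be a numeric matrix (genes x time)",
            "gn_format_error")
  if (is.null(rownames(expr)))
    gn_stop("expression matrix must carry gene identifiers as row names",
            "gn_format_error")
  if (anyDuplicated(rownames(expr)))
    gn_stop(sprintf("duplicate gene identifier(s): %s",
                    paste(unique(rownames(expr)[duplicated(rownames(expr))]),
                          collapse = ", ")), "gn_format_error")
  if (anyNA(expr) || any(!is.finite(expr)))
    gn_stop("expression matrix contains missing or non-finite values",
            "gn_format_error")
  if (ncol(expr) < 2)
    gn_stop("expression matrix needs at least 2 time points", "gn_format_error")
  invisible(expr)
}

# Population (1/T) z-scoring of each row; constant rows are centred only.
#' @noRd
zscore_rows <- function(x) {
  mu <- rowMeans(x)
  xc <- x - mu
  s <- sqrt(rowMeans(xc^2))
  s[s == 0] <- 1
  xc / s
}
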