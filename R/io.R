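# On-disk formats: tab-separated expression matrices, edge lists (priors and
# golden standards), edge rankings (TSV and SIF dialects) and run configs.
# All loaders validate strictly and report the offending location; nothing is
# silently dropped or imputed.

#' Read a gene x time expression matrix
#'
#' The expected layout is tab-separated text with a header row of time labels,
#' gene identifiers in the first column and one numeric column per time point
#' (the usual orientation of GEO series-matrix exports). Genes are returned in
#' file order.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix (genes in rows, time in columns) with gene
#'   identifiers as row names and time labels as column names.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' m <- matrix(rnorm(6), 2, 3, dimnames = list(c("g1", "g2"), paste0("t", 1:3)))
#' write_expression(m, f)
#' x <- read_expression(f)
#' stopifnot(all.equal(x, m))
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) gn_stop(paste0("file not found: ", path), "gn_io_error")
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", quote = "", comment.char = "")
  if (ncol(tab) < 3)
    gn_stop(sprintf("%s: fewer than 2 time columns", path), "gn_format_error")
  ids <- tab[[1]]
  if (anyDuplicated(ids))
    gn_stop(sprintf("%s: duplicate gene identifier(s): %s", path,
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")),
            "gn_format_error")
  vals <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    gn_stop(sprintf("%s: non-numeric or missing value at gene '%s', column %d",
                    path, ids[bad[1]], bad[2] + 1L), "gn_format_error")
  }
  rownames(vals) <- ids
  check_expression(vals)
  vals
}

#' Write an expression matrix as tab-separated text
#'
#' @param expr Numeric matrix, genes in rows, gene ids as row names.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(expr, path) {
  check_expression(expr)
  labs <- colnames(expr)
  if (is.null(labs)) labs <- paste0("t", seq_len(ncol(expr)))
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", labs)
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) gn_stop(paste0("cannot write: ", path), "gn_io_error")
  invisible(path)
}

#' Read a weighted edge list
#'
#' Lines are `source<TAB>target[<TAB>weight]`; the weight defaults to 1.
#' For `directed = FALSE` every stored pair implies its reverse with the same
#' weight, and the returned object contains both directions explicitly.
#' Nodes are opaque strings; no filtering against any gene universe is done
#' here (see [build_prior_matrix()]).
#'
#' @param path Path to a TSV edge list.
#' @param directed Whether the file records directed edges.
#' @return An `edge_list`: a data frame with columns `source`, `target`,
#'   `weight` and attribute `directed`.
#' @export
read_edge_list <- function(path, directed = TRUE) {
  if (!file.exists(path)) gn_stop(paste0("file not found: ", path), "gn_io_error")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(edge_list(character(), character(), numeric(), directed))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfld <- lengths(parts)
  bad <- which(nfld < 2 | nfld > 3)
  if (length(bad))
    gn_stop(sprintf("%s: malformed line %d (expected 2 or 3 tab-separated fields)",
                    path, bad[1]), "gn_format_error")
  src <- vapply(parts, `[[`, "", 1)
  tgt <- vapply(parts, `[[`, "", 2)
  w <- vapply(parts, function(p) if (length(p) == 3) p[[3]] else "1", "")
  wn <- suppressWarnings(as.numeric(w))
  if (anyNA(wn) || any(!is.finite(wn)))
    gn_stop(sprintf("%s: non-numeric weight on line %d", path,
                    which(is.na(wn) | !is.finite(wn))[1]), "gn_format_error")
  edge_list(src, tgt, wn, directed)
}

#' Construct an edge list object
#'
#' @param source,target Character vectors of node ids.
#' @param weight Numeric weights (recycled scalar allowed; default 1).
#' @param directed If `FALSE` the reverse of each pair is added with equal
#'   weight and the result is marked undirected.
#' @return An `edge_list` data frame.
#' @export
edge_list <- function(source, target, weight = 1, directed = TRUE) {
  source <- as.character(source); target <- as.character(target)
  weight <- rep_len(as.numeric(weight), length(source))
  if (any(!is.finite(weight))) gn_stop("edge weights must be finite", "gn_format_error")
  df <- data.frame(source = source, target = target, weight = weight,
                   stringsAsFactors = FALSE)
  if (!directed && nrow(df) > 0) {
    rev <- data.frame(source = df$target, target = df$source, weight = df$weight,
                      stringsAsFactors = FALSE)
    df <- rbind(df, rev)
    df <- df[!duplicated(paste0(df$source, "\r", df$target)), , drop = FALSE]
    rownames(df) <- NULL
  }
  structure(df, directed = directed, class = c("edge_list", "data.frame"))
}

#' Write an edge list as tab-separated text
#'
#' @param edges An `edge_list` or data frame with `source`, `target`, `weight`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(edges, path) {
  write.table(edges[, c("source", "target", "weight")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an edge ranking
#'
#' The default dialect is tab-separated with a header and columns
#' `rank`, `source`, `target`, `score`, `p_value` (the latter left empty when
#' the method carries no p-values). `format = "sif"` writes the simple
#' interaction format `source<TAB>gc<TAB>target` understood by network
#' viewers.
#'
#' @param ranking An `edge_ranking` (see [rank_from_coefficients()]).
#' @param path Output path.
#' @param format `"tsv"` (default) or `"sif"`.
#' @return Invisibly, `path`.
#' @export
write_ranking <- function(ranking, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  ok <- tryCatch({
    if (format == "sif") {
      df <- data.frame(source = ranking$source, interaction = "gc",
                       target = ranking$target)
      write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE)
    } else {
      pv <- if (is.null(ranking$p_value)) rep(NA_real_, nrow(ranking)) else ranking$p_value
      df <- data.frame(rank = seq_len(nrow(ranking)), source = ranking$source,
                       target = ranking$target,
                       score = formatC(ranking$score, digits = 15, format = "g"),
                       p_value = ifelse(is.na(pv), "",
                                        formatC(pv, digits = 15, format = "g")))
      write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    TRUE
  }, error = function(e) FALSE)
  if (!ok) gn_stop(paste0("cannot write: ", path), "gn_io_error")
  invisible(path)
}

#' Read back an edge ranking written by [write_ranking()]
#'
#' @param path Path to a TSV ranking.
#' @return An `edge_ranking` data frame.
#' @export
read_ranking <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE,
                    colClasses = c("integer", "character", "character",
                                   "numeric", "character"))
  pv <- suppressWarnings(as.numeric(tab$p_value))
  new_ranking(tab$source, tab$target, tab$score,
              p_value = if (all(is.na(pv))) NULL else pv, sort = FALSE)
}

#' Read a run configuration (YAML or JSON)
#'
#' Recognised keys: `model_order`, `lambda1`, `lambda2`, `seed`, `top_k`,
#' `mcse_replicates`. Unknown keys are kept verbatim.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) gn_stop(paste0("file not found: ", path), "gn_io_error")
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
}
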