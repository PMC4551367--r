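# Benchmark simulator: a modularized hierarchical golden-standard network,
# linear time-series expression generated from it, and a clique
# prior-knowledge graph over the surviving module members.
#
# The network is built from repeats of a three-layer 1 -> 3 -> 9 regulatory
# module (13 genes, 12 edges: one master regulator, three mid-level
# effectors, nine leaves), connected by random cross-module perturbation
# edges. Master regulators are stochastically activated; activation
# propagates downstream along edges, unactivated genes are filtered out (as
# an expressed-gene filter would do), and the surviving genes are padded
# with isolated background genes showing the same periodic dynamics.

MODULE_SIZE <- 13L
MODULE_EDGES <- 12L

#' Simulation configuration
#'
#' Defaults reproduce the benchmark conditions: 60 module repeats (780 base
#' genes), padding to 1000 total genes, 20 time points, lags drawn from
#' 1..3, per-edge coefficients from U(-1, 1), decay factors from
#' U(0.95, 1) and N(0, 1) innovation noise. `perturbation_edges = 700` is
#' the package's calibrated default for the number of random cross-module
#' edges added before activation filtering, chosen so that the surviving
#' network is of the order of 650 genes and ~1080 retained edges.
#'
#' @param module_repeats Number of 13-gene module copies.
#' @param perturbation_edges Random cross-module directed edges added before
#'   filtering.
#' @param activation_rate Probability that each master regulator is
#'   activated.
#' @param total_nodes Final gene count after isolated-node padding.
#' @param T Number of time points.
#' @param max_lag Maximum regulatory lag (model order of the generator).
#' @param noise_sigma Standard deviation of the Gaussian innovation noise.
#' @param decay_range Range of the per-gene AR(2) decay factor.
#' @param coeff_range Range of the per-edge regulatory coefficient.
#' @param ar2_form `"oscillatory"` uses the period-12 recursion
#'   `x_t = sqrt(3) d x_(t-1) - d^2 x_(t-2) + e`; `"printed"` uses a plus
#'   sign on the second term (explosive; kept for comparison).
#' @param seed Integer seed; the same seed yields a bit-identical network,
#'   expression matrix and prior.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(module_repeats = 60L, perturbation_edges = 700L,
                              activation_rate = 0.5, total_nodes = 1000L,
                              T = 20L, max_lag = 3L, noise_sigma = 1,
                              decay_range = c(0.95, 1),
                              coeff_range = c(-1, 1),
                              ar2_form = c("oscillatory", "printed"),
                              seed = 1L) {
  if (T <= max_lag) gn_stop("T must exceed max_lag", "gn_parameter_error")
  if (activation_rate <= 0 || activation_rate > 1)
    gn_stop("activation_rate must be in (0, 1]", "gn_parameter_error")
  structure(list(module_repeats = as.integer(module_repeats),
                 perturbation_edges = as.integer(perturbation_edges),
                 activation_rate = activation_rate,
                 total_nodes = as.integer(total_nodes),
                 T = as.integer(T), max_lag = as.integer(max_lag),
                 noise_sigma = noise_sigma, decay_range = decay_range,
                 coeff_range = coeff_range, ar2_form = match.arg(ar2_form),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# static edge template of one 1 -> 3 -> 9 module, 1-based node offsets
#' @noRd
module_edge_template <- function() {
  rbind(cbind(1L, 2:4),
        cbind(rep(2:4, each = 3L), 5:13))
}

#' Generate the golden-standard regulatory network
#'
#' Builds `module_repeats` copies of the 13-gene module, adds random
#' cross-module perturbation edges (never targeting a master, so masters
#' remain unregulated), activates each master with probability
#' `activation_rate`, propagates activation downstream along all edges to a
#' fixed point, retains only activated genes and the edges among them, and
#' pads with isolated background genes up to `total_nodes`. Each retained
#' edge receives a lag drawn uniformly from `1..max_lag` and a coefficient
#' from `coeff_range`.
#'
#' @param cfg A `simulation_config`.
#' @return A `gold_standard` list: `edges` (data frame `source`, `target`,
#'   `lag`, `coefficient`), `nodes` (all gene ids, surviving module genes
#'   first), `roles` (named vector: master / effector / isolated), `module`
#'   (named vector of module indices, `NA` for isolated genes) and `config`.
#' @export
generate_network <- function(cfg) {
  withr::with_seed(cfg$seed, {
    nb <- cfg$module_repeats * MODULE_SIZE
    tmpl <- module_edge_template()
    src <- integer(0); tgt <- integer(0)
    for (k in seq_len(cfg$module_repeats)) {
      off <- (k - 1L) * MODULE_SIZE
      src <- c(src, tmpl[, 1] + off)
      tgt <- c(tgt, tmpl[, 2] + off)
    }
    module_of <- rep(seq_len(cfg$module_repeats), each = MODULE_SIZE)
    is_master <- rep(c(TRUE, rep(FALSE, MODULE_SIZE - 1L)), cfg$module_repeats)

    # cross-module perturbation edges; masters stay unregulated
    have <- new.env(hash = TRUE)
    for (e in seq_along(src)) assign(paste(src[e], tgt[e]), TRUE, envir = have)
    np <- 0L
    while (np < cfg$perturbation_edges) {
      u <- sample.int(nb, 1L); v <- sample.int(nb, 1L)
      if (module_of[u] == module_of[v] || is_master[v]) next
      key <- paste(u, v)
      if (!is.null(have[[key]])) next
      assign(key, TRUE, envir = have)
      src <- c(src, u); tgt <- c(tgt, v); np <- np + 1L
    }

    # activation: masters by coin flip, then downstream propagation along
    # any edge until a fixed point
    active <- logical(nb)
    active[is_master] <- runif(sum(is_master)) < cfg$activation_rate
    repeat {
      newly <- active[src] & !active[tgt]
      if (!any(newly)) break
      active[unique(tgt[newly])] <- TRUE
    }
    n_active <- sum(active)
    if (n_active == 0)
      gn_stop("activation left zero genes; increase activation_rate",
              "gn_degenerate_error")
    if (n_active > cfg$total_nodes)
      gn_stop(sprintf("surviving genes (%d) exceed total_nodes (%d)",
                      n_active, cfg$total_nodes), "gn_degenerate_error")

    keep_edge <- active[src] & active[tgt]
    esrc <- src[keep_edge]; etgt <- tgt[keep_edge]

    # final gene universe: surviving module genes, then isolated padding
    width <- max(4L, nchar(as.character(cfg$total_nodes)))
    mod_ids <- sprintf("G%0*d", width, seq_len(nb))
    surv <- which(active)
    n_iso <- cfg$total_nodes - n_active
    iso_ids <- if (n_iso > 0) sprintf("ISO%0*d", width, seq_len(n_iso)) else character(0)
    nodes <- c(mod_ids[surv], iso_ids)
    roles <- c(ifelse(is_master[surv], "master", "effector"),
               rep("isolated", n_iso))
    names(roles) <- nodes
    module <- c(module_of[surv], rep(NA_integer_, n_iso))
    names(module) <- nodes

    edges <- data.frame(source = mod_ids[esrc], target = mod_ids[etgt],
                        lag = sample.int(cfg$max_lag, length(esrc), replace = TRUE),
                        coefficient = runif(length(esrc), cfg$coeff_range[1],
                                            cfg$coeff_range[2]),
                        stringsAsFactors = FALSE)
    structure(list(edges = edges, nodes = nodes, roles = roles,
                   module = module, config = cfg),
              class = "gold_standard")
  })
}

#' Periodic AR(2) oscillator series
#'
#' The master-regulator / background process
#' `x_t = sqrt(3) d x_(t-1) - d^2 x_(t-2) + e_t` has characteristic roots
#' `d exp(+-i pi/6)`, so at `d = 1` and zero noise every trajectory repeats
#' with period 12. `form = "printed"` flips the second term's sign (real,
#' explosive roots).
#'
#' @param T Series length.
#' @param d Decay factor.
#' @param noise_sigma Innovation standard deviation.
#' @param init Initial values (at least 2; defaults to N(0, 1) draws).
#' @param form `"oscillatory"` or `"printed"`.
#' @return Numeric vector of length `T`.
#' @export
ar2_master_series <- function(T, d = 1, noise_sigma = 0,
                              init = rnorm(2),
                              form = c("oscillatory", "printed")) {
  form <- match.arg(form)
  b <- if (form == "oscillatory") -d^2 else d^2
  x <- numeric(T)
  ni <- min(length(init), T)
  x[seq_len(ni)] <- init[seq_len(ni)]
  if (T > ni)
    for (t in (ni + 1):T)
      x[t] <- sqrt(3) * d * x[t - 1] + b * x[t - 2] +
        (if (noise_sigma > 0) rnorm(1, 0, noise_sigma) else 0)
  x
}

#' Generate time-series expression from a golden standard
#'
#' The first `max_lag` time points of every gene are N(0, 1). Afterwards,
#' master regulators and isolated genes follow the periodic AR(2) oscillator
#' with a per-gene decay factor drawn from `decay_range`, while effectors
#' are linear combinations of their golden-standard parents at the edge lags
#' plus innovation noise. Each gene is finally z-scored across time
#' (population variance).
#'
#' @param gold A `gold_standard` from [generate_network()].
#' @param cfg A `simulation_config` (its `T`, `max_lag`, `noise_sigma`,
#'   `decay_range`, `ar2_form` are used).
#' @param seed Seed for the expression draw; defaults to `cfg$seed + 1` so a
#'   single configuration seed determines the whole dataset.
#' @param normalize If `FALSE`, skip the final per-gene z-scoring and return
#'   the raw linear-model trajectories.
#' @return Expression matrix (genes x time) with `gold$nodes` as row names.
#' @export
generate_expression <- function(gold, cfg, seed = cfg$seed + 1L,
                                normalize = TRUE) {
  withr::with_seed(seed, {
    nodes <- gold$nodes
    n <- length(nodes); Tn <- cfg$T; L <- cfg$max_lag
    roles <- gold$roles[nodes]
    ar2 <- roles %in% c("master", "isolated")
    d <- runif(n, cfg$decay_range[1], cfg$decay_range[2])
    bsign <- if (cfg$ar2_form == "oscillatory") -1 else 1
    x <- matrix(0, n, Tn, dimnames = list(nodes, paste0("t", seq_len(Tn))))
    x[, seq_len(L)] <- rnorm(n * L)
    eidx <- match(gold$edges$target, nodes)
    pidx <- match(gold$edges$source, nodes)
    noise <- matrix(if (cfg$noise_sigma > 0) rnorm(n * (Tn - L), 0, cfg$noise_sigma) else 0,
                    n, Tn - L)
    for (t in (L + 1):Tn) {
      xt <- numeric(n)
      xt[ar2] <- sqrt(3) * d[ar2] * x[ar2, t - 1] +
        bsign * d[ar2]^2 * x[ar2, t - 2]
      if (nrow(gold$edges) > 0) {
        contrib <- gold$edges$coefficient *
          x[cbind(pidx, t - gold$edges$lag)]
        inc <- rowsum(contrib, eidx)
        xt[as.integer(rownames(inc))] <- xt[as.integer(rownames(inc))] + inc[, 1]
      }
      x[, t] <- xt + noise[, t - L]
    }
    if (normalize) zscore_rows(x) else x
  })
}

#' Generate the clique prior-knowledge graph
#'
#' For every module, all ordered pairs among the module's surviving members
#' become prior edges of weight 1 (a bidirectional clique). Cross-module
#' perturbation edges are never part of the prior, and members lost to the
#' activation filter leave their clique edges behind -- so the prior is both
#' noisy (most clique pairs are not true regulations) and incomplete.
#'
#' @param gold A `gold_standard`.
#' @param cfg A `simulation_config` (unused fields are ignored; kept so the
#'   three generator calls share one signature).
#' @return A directed `edge_list` of prior edges, weight 1.
#' @export
generate_prior_clique <- function(gold, cfg = gold$config) {
  mods <- split(names(gold$module)[!is.na(gold$module)],
                gold$module[!is.na(gold$module)])
  src <- character(0); tgt <- character(0)
  for (members in mods) {
    s <- length(members)
    if (s < 2) next
    g <- expand.grid(source = members, target = members,
                     stringsAsFactors = FALSE)
    g <- g[g$source != g$target, ]
    src <- c(src, g$source); tgt <- c(tgt, g$target)
  }
  edge_list(src, tgt, 1, directed = TRUE)
}

#' Generate a complete simulated benchmark dataset
#'
#' Convenience wrapper: network, expression and clique prior from one
#' configuration.
#'
#' @param cfg A `simulation_config`.
#' @return A list with `gold`, `expr`, `prior` and `config`.
#' @export
simulate_dataset <- function(cfg = simulation_config()) {
  gold <- generate_network(cfg)
  list(gold = gold, expr = generate_expression(gold, cfg),
       prior = generate_prior_clique(gold, cfg), config = cfg)
}

#' Accuracy of a prior graph against a golden standard
#'
#' Fraction of prior edges that are true golden-standard directed edges.
#'
#' @param prior An `edge_list`.
#' @param gold A `gold_standard`.
#' @return Numeric scalar in \[0, 1\].
#' @export
prior_accuracy <- function(prior, gold) {
  if (nrow(prior) == 0) return(NA_real_)
  gk <- paste0(gold$edges$source, "\r", gold$edges$target)
  mean(paste0(prior$source, "\r", prior$target) %in% gk)
}
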