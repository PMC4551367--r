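# grangernet

Granger-causality inference of directed gene regulatory networks from
**short** time-series expression data — the regime where the number of genes
far exceeds the number of time points (n ≫ T), which breaks both the
classical pairwise F-test (random coincidences dominate) and the conditional
multivariate model (it needs T ≥ (n+1)p).

The package is built around **CGC-2SPR**, a conditional Granger causality
model with a two-step prior-knowledge ridge regularization. The order-p VAR
`Y = XB + E` (Y: m×n responses, X: m×np lagged predictors, m = T−p) is fitted
by minimizing

    1/2 ||Y − XB||²_F  +  1/2 λ₁ ||B − λ₂W||²_F

where W is an (np×n) weight matrix tiled from a pairwise prior-knowledge
graph (protein interactions, TF-binding scores, association networks).
Step 1 fits ordinary ridge to get a preliminary estimate B\*; step 2 flips
the sign of each W entry to match B\* (priors carry magnitude, not
regulatory sign) and evaluates the closed form

    B̂ = (XᵀX + λ₁I)⁻¹ (XᵀY + λ₁λ₂W),

with λ₂ = max|B\*| / max|W| by default, so the data-driven estimate and the
prior target live on the same scale. Edges are ranked by |B̂| (max over
lags), and per-edge significance in the n ≫ T regime comes from **MCSE**, a
Monte Carlo permutation test that permutes the source gene's series in time
while keeping every other gene fixed as conditioning context.

Also included, for controlled comparison on the same interfaces:

- pairwise Granger causality with exact F(p, m−2p) tests (`pgc_all_pairs`),
- ridge / lasso / elastic-net VAR fits with cross-validated penalties
  (`ridge_fit`, `lasso_fit`, `enet_fit`, `cross_validate`),
- mutual-information baselines ARACNE and MRNET plus their time-delayed,
  lag-oriented variants (`mi_matrix`, `time_delayed_mi_matrix`, `aracne`,
  `mrnet`),
- a modularized hierarchical benchmark simulator (1→3→9 regulatory modules,
  stochastic activation, clique prior graph; `simulate_dataset`),
- precision–recall / F1 evaluation against golden-standard edge lists
  (`f1_at_k`, `prc`, `topk_overlap`) and a one-command benchmark harness
  (`run_benchmark`).

## Worked example

```r
library(grangernet)

# simulate a small benchmark: 10 modules, padded to 150 genes, 20 time points
cfg <- simulation_config(module_repeats = 10, perturbation_edges = 60,
                         total_nodes = 150, seed = 42)
ds <- simulate_dataset(cfg)

# ordinary ridge vs the prior-guided two-step fit, both at the same penalty
design <- build_design(ds$expr, p = 3)
lam <- cross_validate(ds$expr, 3, penalty_config("ridge"), seed = 1)$best_lambda1
ridge <- ridge_fit(design, lam)
cgc <- fit_cgc_2spr(design, ds$prior,
                    spr_config(lambda1 = lam, lambda2 = "auto", p = 3))

k <- nrow(ds$gold$edges)
r_ridge <- rank_from_coefficients(ridge, rownames(ds$expr))
r_cgc <- rank_from_coefficients(cgc$result, rownames(ds$expr))
f1_at_k(r_ridge, ds$gold, k)$f1
f1_at_k(r_cgc, ds$gold, k)$f1

# permutation significance of the top-ranked edge
top <- c(r_cgc$source[1], r_cgc$target[1])
mcse_edge(ds$expr, ds$prior, spr_config(lam, "auto", 3), top, R = 99, seed = 7)
```

Output:

```
genes: 150  time points: 20  gold edges: 69  prior edges: 568
prior accuracy: 8.5%
lambda1 (CV): 100   resolved lambda2: 0.04975
F1@69  ridge: 0.159   cgc2spr: 0.203
top edge G0016 -> G0021: score 0.090, MCSE p = 0.010
```

Reading it: the clique prior is only 8.5% accurate on its own, yet pulling
the ridge solution toward it lifts F1 at the |gold| cutoff from 0.159 to
0.203 — the prior contributes *group* information (which genes belong
together) that the data alone, with 20 time points, cannot resolve. The
top-ranked edge reaches the smallest p-value attainable at R = 99
permutations (1/100).

At full benchmark scale (1000 genes, `run_benchmark()` with defaults) the
prior-guided fit scores a mean F1@|gold| around 0.17 against roughly 0.10
for lasso, 0.05–0.06 for pairwise GC and ridge, and effectively zero for
the mutual-information methods.

A thin command-line wrapper over the same functions ships at
`inst/cli/grangernet.R` (subcommands: simulate, pgc, fit, cgc2spr, mi,
mcse, evaluate, benchmark).

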