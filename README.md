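# herdnet

Proximity-based social networks and separable temporal ERGMs for dairy
herds.

Housed dairy cows wearing ultra-wideband positioning tags produce one
(x, y) fix per second. **herdnet** turns those tracks into daily social
networks and models their day-to-day dynamics:

1. **Trajectories** — read per-second positions, fill gaps with modified
   Akima (makima) interpolation, assign each fix to a functional area of
   the barn (resting vs feeding) from polygon geometry.
2. **Contact networks** — count, per dyad and per area, the seconds two
   cows spend within 2.5 m of each other (two adjacent 1.25 m cubicles),
   and keep dyads with at least 600 s per day as edges of a binary daily
   network.
3. **Dyadic covariates** — additive genetic relationship from pedigree
   (tabular method), the "kindergarten" indicator (born within 7 d on the
   same birth farm) and parity classes (1 / 2 / 3+).
4. **STERGM** — separable temporal exponential random graph model: the
   transition from day *t* to *t* + 1 factorises into a *formation* phase
   (ties appearing, an ERGM on the union network y⁺ = yᵗ ∪ yᵗ⁺¹) and a
   *persistence* phase (ties surviving, on the intersection
   y⁻ = yᵗ ∩ yᵗ⁺¹). Each phase is a logistic regression of dyad states on
   change statistics (edges, parity endpoint/homophily terms, kinship,
   kindergarten, and — in variant M2 — triangles), pooled over the 4
   transitions of a 5-day sliding window; for the dyad-independent M1
   terms this maximum pseudolikelihood is the exact conditional MLE.
5. **Prediction and evaluation** — simulate 100 next-day networks per
   scenario (exact per-dyad draws for M1, Metropolis–Hastings toggles for
   M2), score them against the observed day by graph correlation (Pearson
   on dyad vectors) and Spearman correlations of degree / betweenness /
   eigenvector centralities, and compare with a naive baseline that
   randomly permutes animal identities 100 times.

A synthetic-data generator (herds with structured pedigrees, network
series from known coefficients, per-second trajectories that re-extract a
target network exactly) makes the entire pipeline testable without any
farm data.

## Worked example

```r
library(herdnet)

herd <- generate_herd(n_cows = 75, n_founder_pairs = 10, seed = 1)
cov  <- build_dyad_covariates(herd$pedigree, herd$herd, herd$herd$cow_id)
series <- generate_network_series(herd, cov, n_days = 14, seed = 1,
                                  area = "resting")
series[[1]]
#> Daily network: 75 cows, 283 edges (density 0.102), day 1, resting area

pairwise_correlogram(series)
#> Graph-correlation correlogram over 91 day pairs
#>  lag mean_correlation n_pairs
#>    1            0.183      13
#>    2            0.039      12
#>    3            0.005      11
#>  ...
```

Consecutive days correlate (~0.18) and the signal decays within a few
days — the motivation for short sliding windows. Fit the exogenous model
on days 1–5:

```r
fit <- fit_mple(as_transitions(series[1:5]), model_spec("M1"), cov)
summary(fit)
#> STERGM (M1) -- converged
#>
#> Formation phase:
#>              Estimate Std. Error z value Pr(>|z|)
#> edges         -2.6054     0.0837  -31.13  < 2e-16 ***
#> parity2        0.0326     0.0605    0.54    0.591
#> parity3plus    0.1198     0.0583    2.05    0.040 *
#> parity_match   0.3101     0.0748    4.14  3.4e-05 ***
#> kinship        0.6776     0.2763    2.45    0.014 *
#> kindergarten   0.5159     0.2462    2.10    0.036 *
#> ...
```

Related, familiar and same-parity cows form (and keep) contacts at higher
rates. Predict day 6 and compare with the naive permutation baseline:

```r
sims <- simulate(fit, nsim = 100, seed = 2, cov = cov, y_prev = series[[5]])
obs  <- series[[6]]
mean(sapply(sims, graph_correlation, b = obs))
#> 0.040
naive_baseline(series[[5]], obs, n_perm = 100, seed = 3)
#> Accuracy over 100 networks
#>   graph_corr       mean  0.001  sd 0.020
#>   degree_rho       mean  0.007  sd 0.116
#>   ...
```

The model recovers dyad-level structure (graph correlation 0.040, about
the square of the day-to-day correlation, as expected when one day of
history carries the signal) while the naive baseline sits at zero.

The full experiment — groups × areas × sliding windows × {M1, M2}, with
correlograms, per-scenario accuracy tables, a convergence ledger and a
run manifest — is one call:

```r
report <- run_pipeline(list(synthetic = list(n_cows = 75, n_founder_pairs = 10,
                                             n_days = 14),
                            seed = 1))
write_report(report, "results/")
```

`run_pipeline()` also accepts a YAML config file, and can start from
position CSVs plus a barn-geometry YAML instead of a synthetic spec. See
`vignettes/herdnet-methods.Rmd` for the model, its assumptions and all
numerical choices.

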