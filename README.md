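# ordinet

Regularized partial-correlation networks for ordinal questionnaire data.

`ordinet` is for researchers who analyze symptom-level survey data — for
example, how individual intolerance-of-uncertainty (IU) components relate
to individual problematic-smartphone-use (PSU) symptoms — as a network
rather than as scale sum scores. It implements the standard
network-psychometrics workflow end to end:

* **Data**: 5-point Likert item tables from CSV, attention-check filtering,
  Table-1-style descriptives (mean, SD, skewness g1, excess kurtosis g2),
  McDonald's omega from a one-factor fit.
* **Estimation**: Spearman correlations (tie-corrected), positive-
  semidefinite repair, and a Gaussian graphical model fitted by the
  graphical lasso (C++ block coordinate descent) with EBIC model selection:

  edge weights ρᵢⱼ = −Θᵢⱼ/√(Θᵢᵢ Θⱼⱼ) from the L1-penalized precision
  matrix Θ̂ = argmax log det Θ − tr(SΘ) − λ Σ|Θᵢⱼ|, with λ chosen by
  EBIC(γ) = −2L + E log n + 4 γ E log p over a 100-point path (γ = 0.5 by
  default).

* **Centrality**: one-step expected influence (EI, the signed sum of a
  node's edge weights) and bridge expected influence (BEI, the same sum
  restricted to edges crossing two pre-defined clusters), z-scored, with a
  blind 85th-percentile cutoff that flags exactly 3 of 21 nodes as central
  and 3 as bridge.
* **Accuracy & stability**: nonparametric bootstrap edge CIs, bootstrapped
  difference tests for edges and centralities, and the case-dropping
  correlation-stability (CS) coefficient (acceptable ≥ 0.25, ideal ≥ 0.5).
* **Synthetic data**: a latent-Gaussian + threshold generator with a known
  ground-truth network (default: 12 + 9 items, n = 1,849, ~66% edge
  density, anchor edges 0.43 / 0.31 / 0.11 / −0.05), so the whole pipeline
  is testable without access to raw survey data.

See `vignettes/network-analysis.Rmd` for the model, the tunable
parameters, and the validation design.

## Worked example

```r
library(ordinet)

# simulate the default two-cluster profile and analyze it
cfg <- run_config(n = 1849, seed = 1,
                  boot = bootstrap_spec(B = 100, seed = 1),
                  out = "run1")
bundle <- run_pipeline(cfg)

print(bundle$summary)
#> 21 nodes; 102 of 210 possible edges (49%); 102 positive, 0 negative
#> weights in [0.001, 0.343]
#> strongest within-cluster edges:
#>  node_a node_b weight
#>     IU1    IU2  0.343
#>     IU9   IU10  0.196
#>    PSU2   PSU3  0.192
#> strongest between-cluster edges:
#>  node_a node_b weight
#>     IU2   PSU8 0.1177
#>     IU7   PSU8 0.0665
#>     IU1   PSU8 0.0600

subset(bundle$centrality, is_central | is_bridge,
       select = c(node, cluster, ei_z, bei_z, is_central, is_bridge))
#>    node cluster       ei_z     bei_z is_central is_bridge
#> 1   IU1      IU  2.7557278 0.9905347       TRUE     FALSE
#> 2   IU2      IU  1.5927692 1.5617465       TRUE      TRUE
#> 7   IU7      IU -0.3953796 1.2505351      FALSE      TRUE
#> 20 PSU8     PSU  0.8729583 2.8132602       TRUE      TRUE

bundle$cs
#> $ei
#> [1] 0.75
#> $bei
#> [1] 0.55
```

Reading the output: the estimator keeps 102 regularized partial
correlations among the 210 possible item pairs (EBIC at γ = 0.5 prunes
the rest), the strongest within-cluster edge is IU1–IU2 and the strongest
bridge edge IU2–PSU8 — the anchors planted by the generator, attenuated by
discretization and L1 shrinkage. IU2 and PSU8 are flagged as both central
and bridge nodes; a CS-coefficient of 0.75 for expected influence means up
to 75% of respondents can be dropped while 95% of subsamples still
correlate ≥ 0.7 with the full-sample values (0.75 is the grid maximum).
All artifacts — edge list, centrality table, bootstrap CIs, stability
long table, layout, figure, JSON manifest — are written to `run1/`.

A thin CLI over the same functions ships in
`inst/scripts/ordinet-cli.R` (subcommands `simulate` and `analyze`).

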