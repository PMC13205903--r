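# successr

Microbial succession, maternal transmission, and community assembly analysis
for longitudinal microbiome cohorts.

## The problem

Studies that follow gut communities across developmental stages — maternal
(MA), juvenile (JU), adult (AD) — under a two-group design (e.g. control vs
antibiotic-exposed dams) need a recurring set of analyses that no single R
package covers:

* **Compositional diversity** — CLR transform with multiplicative zero
  replacement, Aitchison distance, PCoA, PERMANOVA, Shannon/Simpson/Chao1.
* **Turnover vs nestedness** — Baselga's partition of Sørensen dissimilarity,
  β_sor = β_sim + β_sne, with the contrast-level turnover proportion
  mean(β_sim/β_sor) tested by label-shuffling permutation.
* **Niche breadth** — Levins B = 1/Σp² (with the Shannon variant
  exp(−Σ p ln p) as a robustness companion).
* **Differential prevalence and abundance** — stage-specific prevalence
  floors (50% maternal, 30% later stages, with a guard against marginal
  contrasts such as 2-vs-1 positives), a two-class rank-test + LDA effect
  size abundance screen, and cross-stage direction-consistent feature sets.
* **Colonization patterns and trajectories** — per-taxon binomial tests of
  adult prevalence against the juvenile baseline classify taxa as
  early / persistent / late colonizers; paired signed-rank comparison of
  (ΔABX, ΔCON) prevalence-change coordinates detects accelerated maturation.
* **Source tracking** — an expectation–maximization decomposition of each
  sink community into known source profiles plus an unknown source
  (x_sink ~ Multinomial(Σ_k α_k γ_k + α_u γ_u)), replicated runs, and a
  BH-adjusted Wilcoxon group contrast per stage transition.
* **Strain sharing** — normalized phylogenetic distances
  nGD = patristic distance / total branch length on per-taxon strain trees;
  a mother–offspring pair with nGD < 0.03 is a strain-sharing event.
* **Assembly processes** — abundance-weighted βMNTD with tip-shuffling
  nulls gives βNTI; richness- and abundance-constrained randomization of
  Bray–Curtis gives RC_Bray; pairs are classified as heterogeneous /
  homogeneous selection, dispersal limitation, homogenizing dispersal, or
  undominated by the standard ±2 / ±0.95 thresholds.
* **Neutral community model** — Sloan's occupancy–abundance fit
  F(p̄) = 1 − Beta(d; Nm·p̄, Nm(1−p̄)) estimates the migration rate m, Nm,
  and R², and flags taxa above/below the neutral band (dispersal-shifted
  taxa feed a |ρ| > 0.8 Spearman co-occurrence network).

Every generator ships with an explicit ground-truth object
(`neutral_sim_truth()`, `mixture_truth()`, `succession_truth()`), so each
estimator is validated by parameter recovery rather than against fixed
snapshots.

## Worked example

Simulate neutrally assembled communities with a known migration rate, rarefy,
and fit the neutral model:

```r
library(successr)

truth  <- neutral_sim_truth(n_taxa = 300, m = 0.1, N = 1000, n_samples = 40)
counts <- simulate_neutral_communities(truth, seed = 7)
fit    <- counts |> rarefy("min", seed = 1) |> fit_ncm()
fit
#> <ncm_fit> m = 0.1329, N = 1000, Nm = 132.9, R2 = 0.967 (207 taxa, 40 samples)
#>   states: above=29, below=6, neutral=172
```

The fit recovers the planted migration rate (m̂ = 0.13 vs true 0.1; the
canonical threshold-detection fit runs slightly high) with R² = 0.97 — the
community is correctly judged neutral. `tidy(fit)` returns the per-taxon
occupancy table, `glance(fit)` the one-row summary, `autoplot(fit)` the
occupancy–abundance curve with its confidence band.

Classify colonization patterns on a cohort with planted early / persistent /
late taxa (prevalence gaps 0.8, n = 20 + 20):

```r
tru    <- succession_truth(rep(c("early", "persistent", "late"), each = 10),
                           p_JU = rep(c(0.9, 0.5, 0.1), each = 10),
                           p_AD = rep(c(0.1, 0.5, 0.9), each = 10))
cohort <- simulate_succession_cohort(tru, n_JU = 20, n_AD = 20, seed = 3)
calls  <- classify_colonization(cohort$table, cohort$design, group = "A")
colonization_proportions(calls)
#> # A tibble: 3 × 3
#>   class          n proportion
#>   <chr>      <int>      <dbl>
#> 1 early         12      0.4
#> 2 late          11      0.367
#> 3 persistent     7      0.233
```

All 10 planted early and 10 late colonizers are recovered; the extra
early/late calls are persistent taxa crossing the lenient p < 0.1 threshold,
the expected behavior of the plug-in binomial test (see the methods
vignette).

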