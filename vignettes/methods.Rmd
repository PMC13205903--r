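---
title: "Models and methods in successr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in successr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(successr)
```

successr analyzes longitudinal microbiome cohorts spanning maternal (MA),
juvenile (JU) and adult (AD) stages under a two-group design. This vignette
explains the statistical models behind each analysis, the parameters that
matter, what the synthetic-data generators do and do not emulate, and the
numerical choices made where the design was genuinely open.

## Data model

The core container is a `feature_table`: a non-negative features-by-samples
matrix declared as `counts` (integer reads) or `relative` (columns summing
to 1). A study design tibble maps each sample to `group`, `stage`,
`subject_id`, a source/sink `role` and an optional mother–offspring
`pair_id`. Count-based null models (Raup–Crick, the neutral fit) require
even sequencing depth, so `rarefy()` subsamples columns without replacement
(multivariate hypergeometric) to a common depth. Without-replacement
subsampling preserves count support: it can never invent a taxon absent from
a sample, and the rarefied column sums hit the requested depth exactly.

## Compositional statistics

Zeros are replaced multiplicatively before the CLR transform: every zero
becomes 0.65 × the smallest nonzero relative abundance in the whole table,
and columns are renormalized. The factor 0.65 is the common multiplicative
replacement convention and is exposed as `zero_factor`; the replacement
value is global rather than per-sample so that identical compositions at
different depths transform identically. The CLR value ln(x/g(x)) makes each
column sum to zero, Aitchison distance is Euclidean distance between CLR
columns, and PCoA is classical double-centered MDS (negative eigenvalues are
reported, not hidden, so embedding quality can be judged). PERMANOVA is
delegated to `vegan::adonis2` (single factor), with the permutation p-value
(1 + #{F_perm ≥ F_obs}) / (1 + n_perm).

## Turnover and nestedness

For presence/absence profiles with `a` shared features and `b`, `c` unique
ones, total Sørensen dissimilarity β_sor = (b+c)/(2a+b+c) splits into
turnover β_sim = min(b,c)/(a+min(b,c)) and nestedness β_sne = β_sor − β_sim.
The contrast statistic is the mean of β_sim/β_sor over between-group pairs;
pairs with β_sor = 0 have an undefined ratio and are excluded (logged in the
result). Significance comes from shuffling group labels (999 by default);
the p-value is two-sided, 2 × min(tail probabilities) with the
(1+k)/(1+n) estimator so p is never zero. Whether the summary averages
between-group pairs only (default) or all pairs is a `pairs` argument, since
either convention is defensible for stage-level summaries.

## Differential prevalence rules

A feature is differentially prevalent at a stage when one group clears the
prevalence floor while the other has at most one positive sample. Floors are
50% of the group at the directly exposed maternal stage and 30% at later
stages, applied as ceiling(rate × n). The juvenile stage activates a guard
against marginal contrasts: with 0 positives in the low group the high group
needs ≥ 2, with 1 positive it needs ≥ 3. The guard minima are the complete
requirement for the guarded stage — at n = 7 a ceiling floor of 3 would make
the "absent → ≥ 2 suffices" clause unreachable, so the guard replaces rather
than augments the floor. A stricter at-threshold sub-rule used for broad,
low-specificity feature classes (a group sitting exactly at the floor
tolerates no positives on the other side) is available as
`exact_floor_strict`; floors themselves are plain numbers in
`prevalence_rule()`, so the relaxed 25%/15% variants used for functional
pathways are a configuration, not a code path.

The abundance screen is the two-class core of the LDA-effect-size
procedure: a two-sided Wilcoxon rank-sum test on relative abundances plus an
effect-size gate. With two classes and one feature the discriminant axis is
the feature itself, so the effect size reduces to the class-mean difference
on the counts-per-million scale, reported as log10(1 + |Δ mean CPM|). On
this scale the conventional LDA > 2 gate corresponds to a > 100-CPM shift; a
2-fold change of a moderately abundant taxon scores ≈ 4–5 and passes, which
is the behavior the screen is meant to have. This is a reimplementation of
the two-class reduction, not the original multi-class tool.

## Colonization patterns and trajectories

For each feature detected at least once in JU or AD, the AD positive count
k_AD is tested against the JU prevalence with a two-sided exact binomial
test; the null proportion is clamped to [1/(2n_JU), 1 − 1/(2n_JU)] so it is
never 0 or 1. Features with p < 0.1 are classed early (prevalence falls) or
late (prevalence rises); everything else is persistent. Two properties of
this plug-in test are worth knowing. First, its realized type-I error
exceeds the nominal level — the JU prevalence is estimated, not known, and
exact enumeration over (k_JU, k_AD) at n = 20/20, p = 0.5 puts the false
shift-call rate near 0.25 at α = 0.1. The test suite checks the empirical
rate against that enumerated value rather than against α. Second, power for
large planted gaps (≥ 0.4 at n = 20/20) is excellent: early/late labels are
recovered at ≥ 90%.

Trajectory comparison pairs each shared feature's prevalence change
(AD − JU, ×100) in the exposed group (x) with the control group (y). Under
concordant development points sit on y = x; points above the diagonal are
taxa already at adult-like prevalence in the exposed juveniles —
"accelerated in exposed". A two-sided paired Wilcoxon signed-rank test
summarizes the overall displacement. Rank tests use `stats::wilcox.test`
(exact where sample size and ties permit, mid-rank normal approximation
otherwise).

## Source tracking

Each sink is modeled as a multinomial mixture of K known source profiles
plus one unknown source. Known profiles are fixed at empirical source
frequencies with pseudocount 1 (a joint re-estimation mode exists behind
`update_sources`); mixing proportions start uniform over K + 1; EM stops at
a log-likelihood gain below 1e-8 or 1000 iterations, and monotonicity of the
likelihood is asserted every step.

The unknown-source profile is re-estimated each M-step **on the orphan
support only** — taxa with zero total source count. This is an
identifiability requirement, not a convenience: a fully free unknown profile
makes the model degenerate (any sink is a one-component mixture of itself),
and in recovery experiments the free variant drifts, absorbing ~25% of the
mass when the true unknown contribution is zero. Restricted to orphan taxa,
the decomposition recovers planted (0.6, 0.3, 0.1, 0) mixtures to within
0.005 at depth 1e5. The cost is that an unknown source sharing taxa with
known sources has its overlapping mass credited to them — an ambiguity no
mixture decomposition escapes; the `unknown_support = "free"` flag restores
the unrestricted behavior if wanted.

Replicated runs (default 10) resample each sink multinomially at its own
depth, so the repeat spread measures estimation stability. The group
contrast defaults to per-sink units (each sink's mean contribution across
runs, Wilcoxon between groups, BH across transitions): per-run group means
re-use the same sinks in every run, so a run-level test is pseudo-replicated
and rejects under the null far too often. Per-run comparison remains
available (`compare = "per_run"`) for descriptive use.

## Strain sharing

Strain trees are consumed, not built. nGD is the patristic distance between
two samples' tips divided by the tree's total branch length, making it
invariant to uniform branch-length scaling. A sharing event is a
mother–offspring pair with nGD strictly below 0.03. Unpaired background
comparisons enumerate all cross-pair maternal × offspring combinations
within a group (capped at 10,000 with a seeded subsample) rather than one
random draw, which stabilizes the background distribution.

## Assembly processes

βMNTD is abundance-weighted: each taxon's relative abundance multiplies its
distance to the nearest taxon of the partner community (a presence/absence
mode exists). Nulls shuffle tip labels over the regional pool — every
feature observed anywhere in the analyzed table — because the z-score
should measure departure from regional phylogenetic structure; βNTI is
(obs − null mean)/null sd. Pairs whose null standard deviation is zero
(e.g. a star tree, where every cross-taxon distance is equal) are flagged
undefined and excluded from classification rather than silently dropped.

RC_Bray builds null communities that keep each sample's observed richness
(taxa drawn without replacement, weighted by regional occurrence frequency,
one individual seeded each) and total abundance (remaining individuals
multinomial on regional relative abundance restricted to the drawn taxa);
RC = 2[P(null < obs) + ½P(null = obs)] − 1 ∈ [−1, 1]. Both weighting
vectors are arguments in spirit — they are recomputed from the analyzed
table. Note that samples which are simple multinomial draws from one
profile at high depth are *more* similar than this null ensemble and score
RC ≈ −1; that is the index detecting homogenization. Calibration (|RC| ≤
0.95 for ~95% of pairs) holds when observations are exchangeable with the
null's own generative process, which is how the calibration suite builds
its fixture.

Process labels follow the standard thresholds exactly: βNTI > +2
heterogeneous selection, < −2 homogeneous selection; otherwise RC > +0.95
dispersal limitation, RC < −0.95 homogenizing dispersal, |RC| ≤ 0.95
undominated. |βNTI| > 2 is the deterministic fraction.

## Neutral community model

With local community size N (the common rarefied depth) and migration rate
m, the expected occurrence frequency of a taxon with mean relative abundance
p̄ is 1 − Beta(d; Nm·p̄, Nm(1 − p̄)) at detection limit d = 1/N (one read).
m̂ minimizes the sum of squared frequency residuals by Brent optimization on
(1e-6, 1]; the search runs on five log-spaced subintervals and keeps the
best SSE as a guard against multimodality (none has been observed). R² =
1 − SSR/SST is deliberately unclamped: negative values mean the neutral
curve fits worse than a constant and are the model's failure signal.
Per-taxon 95% Wilson score intervals around the predicted frequency (with
the sample count as n) classify taxa as above / neutral / below the band.

Two honest caveats, both verified by simulation. The threshold-detection
approximation biases m̂ upward by roughly 20–35% at N = 1000 (the exact
beta-binomial zero-probability removes the bias but is not the canonical
fit, so it is not used). And the nominal 95% band under-covers: on exactly
neutral simulations ~15% of taxa fall outside, because p̄ is itself
estimated from the same samples; the band should be read as a screening
device for dispersal-shifted taxa, not an exact test. Dispersal-state
shifts order below < neutral < above and compare shared taxa between two
fits; the co-occurrence step keeps Spearman edges at |ρ| > 0.8, p < 0.05,
with positive and negative edge sets separated.

## Synthetic data: what it emulates, and what it does not

`simulate_tree()` is a pure-birth (Yule) process: exponential waits with
rate equal to the lineage count, a uniformly chosen lineage splits, and a
final wait extends tips to the present, giving ultrametric trees with
expected depth Σ_{k=2..n} 1/k.

`simulate_neutral_communities()` defaults to sampling the stationary law of
Hubbell local dynamics with immigration — composition π ~ Dirichlet(Nm·p)
over the metacommunity profile p, then counts ~ Multinomial(N, π) — which
is exactly the distribution whose beta marginals the occupancy–abundance
fit assumes, so planted migration rates are recoverable (±50% tolerance is
comfortably met; observed error ~25–35%). The intuitive sequential urn
(each recruit immigrates with probability m, else copies a resident) is
available as `scheme = "urn"`; its copy amplification makes communities
over-dispersed relative to the stationary law, and fitted migration rates
come out ~2–3× low. The default metacommunity is a geometric series
(k = 0.97), chosen for the rare-taxon tail that exercises the low-abundance
end of the occupancy curve.

`simulate_source_sink()` draws sources and mixture sinks multinomially from
planted profiles; `simulate_transmission_cohort()` assembles the two-group
maternal/adult layout with the environmental (unknown) contribution on a
disjoint taxon block, which is the regime where maternal contributions are
cleanly identifiable. `simulate_succession_cohort()` plants Bernoulli
presence per stage prevalence with log-normal read counts for present
features (only the presence structure carries signal downstream).

None of the generators emulate compositional sequencing artifacts —
amplification bias, contamination, batch effects, variable library sizes —
nor phylogenetic signal in community membership (community assembly in the
βNTI fixtures is deliberately independent of the tree, which is what makes
them null calibrations). Passing tests therefore demonstrate statistical
correctness of the estimators under their assumed models, not robustness to
real-data pathologies.

## Problem sizes and determinism

The validation suite uses the study-scale conditions throughout: NCM
recovery at N = 1000, 60 samples, 500 taxa; mixture recovery at depth 1e5;
colonization cohorts at n = 20/20 with prevalence gaps 0.8; βNTI nulls at
n_null = 200 over ≥ 100 pairs; RC calibration over 300 independent pairs;
200-replicate uniformity checks for PERMANOVA and trajectory p-values; and
a 50-replicate null-calibration experiment for the replicated
source-tracking contrast. Every stochastic function takes an integer seed,
runs in a private RNG stream, and restores the caller's RNG state, so
results are bit-reproducible and library calls never perturb user
randomness.
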