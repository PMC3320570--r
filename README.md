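# synclust

Probabilistic clustering of genetic-perturbation effects on synaptic
neurotransmitter release.

## The problem

Functional studies of presynaptic genes report how a perturbation (knockout,
overexpression, point mutant, pharmacological treatment) changes a handful of
synaptic release variables measured in autaptic neuron cultures:

| variable | meaning | typical unit |
|---|---|---|
| `A` | evoked EPSC amplitude | nA |
| `RRP` | readily releasable vesicle pool (hypertonic sucrose charge) | pC |
| `Pv` | vesicular release probability | % |
| `F` | spontaneous (miniature) release frequency | Hz |

These data are poorly standardized: absolute wild-type values differ by
orders of magnitude across labs, most papers report only a subset of the
variables, and effect sizes differ wildly between perturbation types. Direct
comparison across studies is impossible, yet the *direction* of a
perturbation's effect in log space carries its functional signature: by the
quantal release model

```
A = RRP · Pv · q            (q = quantal size, assumed unchanged)
log2 A = log2 RRP + log2 Pv
```

a pure priming perturbation moves along the RRP axis, a pure fusion
perturbation along the Pv axis, and so on.

`synclust` normalizes every perturbation to a control group from the same
study, log2-transforms, and clusters the *orientations* of the resulting
effect vectors in (RRP, Pv, A) space with a mixture of origin-anchored
rank-1 probabilistic principal component analyzers (MPPCA): component `k` is
a zero-mean Gaussian with covariance

```
C_k = w_k w_kᵀ + σ²_k I
```

— a noisy line through the origin (the no-effect point). Missing variables
are handled exactly, by marginalizing each vector's likelihood to its
observed coordinates and using expected sufficient statistics in the M-step.
Because EM is stochastic, clustering is stabilized by consensus: many
restarts across a range of cluster numbers K, a co-occurrence matrix per
run, averaged per K and across K, ordered by optimal leaf ordering, with a
block-structure score proposing K. Clusters are then interpreted
geometrically (unit vectors projected onto the release-model circle,
fixed-orientation orthogonal regression at 0°/45°/90°/135° with an
error-reduction statistic and a permutation null) and statistically
(assignment entropy, RMS effect size, per-gene summaries, a weighted
contingency randomization test for gain- vs loss-of-function enrichment, and
a correlation screen over wild-type control experiments).

A synthetic database generator with known ground truth
(`generate_database()`, `paperlike_config()`) emulates the curated
perturbation database's composition — 378 experimental groups in 56 studies,
121 analyzable perturbations of 27 genes from 39 studies, heterogeneous
per-study missing-variable patterns, heavy-tailed effect sizes — so the
whole pipeline is testable without any external data.

## Worked example

```r
library(synclust)

sim <- generate_database(paperlike_config(), seed = 42)  # synthetic, known truth
res <- analyze_perturbations(sim$database, K_values = 2:6, restarts = 10,
                             seed = 42, n_perm = 500, n_rand = 1999,
                             K_star = 3)
print(res)
```

```
Perturbation orientation-clustering analysis
  378 database rows -> 121 perturbations after the >=2-variable filter (27 genes, 39 studies)
  12 perturbations with >10-fold effects (kept in all analyses)
  K* = 3, cluster sizes 94 / 17 / 10
  cluster unit vectors (RRP, Pv, A):
      [,1]   [,2]   [,3]
RRP -0.016  0.710 -0.705
Pv   0.710 -0.012  0.709
A    0.704  0.704 -0.007
  error reduction from clustering: 90.2%
  proportional-model permutation p = 0.001996 (500 permutations)
  GOF/LOF contingency: chi-square 2.821, randomization p = 0.0375
  control correlations: 1 of 6 pairs significant at Bonferroni 0.0083
```

Reading the output: the three recovered unit vectors are (up to sign) the
fusion direction (0, 0.71, 0.70): Pv and A co-change, RRP untouched; the
priming direction (0.71, 0, 0.70): RRP and A co-change; and the
anti-correlated direction (0.71, −0.71, 0): RRP up, Pv down, A unchanged —
exactly the three orientations the synthetic truth was built on. Clustering
reduces the summed weighted orthogonal regression error by 90% relative to
fitting one orientation to all perturbations; the proportional (45°) model
beats all 500 within-column permutations of the data matrix (p ≈ 0.002);
and gain-of-function perturbations are significantly enriched in the
anti-correlated cluster (randomization p = 0.038).

Individual stages are available as plain functions — `read_database()`,
`normalize_to_controls()`, `filter_min_variables()`, `mppca()`,
`consensus_cluster()`, `orientation_fit()`, `weighted_contingency_test()`,
… — and `mppca()` returns a classed model object with `print`, `summary`,
`coef`, `predict`, `logLik`, `simulate`, `residuals` and `plot` methods. A
thin command-line wrapper lives in `inst/cli/synclust`
(`simulate | normalize | cluster | analyze | all`).

## Method vignette

`vignettes/orientation-clustering.Rmd` documents the model and its
assumptions, the numerical choices (initialization, collapse handling,
tolerances, tie-breaks), what the synthetic generator does and does not
emulate, and known limitations.
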