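---
title: "Connectivity-based parcellation with the streamline infinite relational model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity-based parcellation with the streamline infinite relational model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The model

Structural brain networks can be parcellated under two distinct notions of a
cluster. *Community-based* clusters are sets of regions that are densely
connected to each other and sparsely connected to everything else.
*Profile-based* clusters are sets of regions that connect to the *same
targets*, whether or not they connect to each other — the pattern typical of
hub ("rich club") regions. The stochastic block model subsumes both: edge
probability depends only on the cluster memberships of the two endpoints,
so a strong diagonal of the block probability matrix $\rho$ produces
communities while structure in the off-diagonal entries captures shared
connection profiles.

`sirm` implements a nonparametric, multi-subject version of this idea.
For $N$ regions and $M$ subjects the generative model is

$$
\begin{aligned}
Z &\sim \mathrm{CRP}(\xi) \\
\rho^{(m)}_{ab} &\sim \mathrm{Beta}(\alpha,\beta) \\
a^{(m)}_{ij} \mid Z, \rho^{(m)} &\sim
  \mathrm{Bernoulli}\!\left(\rho^{(m)}_{z_i z_j}\right) \\
s^{(m)}_{i\cdot} \mid a^{(m)}_{i\cdot} &\sim
  \mathrm{DirMul}\!\left(\delta_T\, a^{(m)}_{i\cdot} +
  \delta_F\,(1 - a^{(m)}_{i\cdot})\right),
\end{aligned}
$$

where $Z$ is a partition of the regions *shared across subjects*, each
subject has its own symmetric binary connectome $A^{(m)}$ and block
probabilities $\rho^{(m)}$, and $s^{(m)}_{i\cdot}$ is the row of observed
streamline counts seeded at region $i$ (row totals $T_i$ are fixed by the
tractography, and the counts $s_{ij}$ and $s_{ji}$ may differ even though
$A$ is undirected). The Chinese-restaurant-process prior makes the number
of clusters $K$ part of the posterior rather than a tuning constant.

The Dirichlet-multinomial forward model encodes the working assumption of
probabilistic tractography: streamlines concentrate on true structural
connections (pseudo-count $\delta_T$ per connected target) but false
connections still attract occasional streamlines (pseudo-count
$\delta_F < \delta_T$). Fitting the combined model ("sIRM" mode) therefore
needs no streamline threshold; thresholded binary input can instead be
clustered directly ("birm" mode), and connectivity can be estimated without
any clustering assumption under a flat prior $P(A) \propto 1$ ("flat"
mode). The two-stage pipeline — flat-prior MAP connectomes, then block-model
clustering — is what `mode = "birm"` runs automatically when it is handed
count data.

## Hyperparameters

| parameter | meaning | default | why |
|---|---|---|---|
| $\xi$ | CRP concentration (unitless); prior expected $K$ is $\sum_{i<N} \xi/(\xi+i)$ | 1 | weakly favours few clusters; posterior $K$ is data-driven |
| $\alpha,\beta$ | Beta prior on each block probability | 1, 1 | uniform: no preference for dense or sparse blocks |
| $\delta_T$ | Dirichlet pseudo-count of a true connection | 1.0 | order-one mass per true target |
| $\delta_F$ | pseudo-count of a false connection | 0.05 | a false target attracts $\sim$5% of the mass of a true one, matching the "mostly but not perfectly reliable" reading of tractography |

$\delta_T \ge \delta_F$ is enforced; setting them *equal* switches the
streamline likelihood off (the Dirichlet-multinomial becomes symmetric in
the adjacency), which is exactly the switch used by the prior-recovery test
below.

## Inference

All inference is by block Gibbs sampling with the block probabilities
$\rho$ integrated out analytically (Beta–Bernoulli conjugacy): sampler
state is only $(Z, \{A^{(m)}\})$, which mixes faster and leaves nothing to
tune. `posterior_rho()` is a read-out of the Beta posterior means at any
state, not part of the sampler.

One sweep updates every edge dyad of every subject (subject-major,
lexicographic) and then every node assignment in a fresh random
permutation. The edge update resamples $a_{ij}$ from its exact conditional:
collapsed block-prior odds $(\alpha + n_1^-)/(\beta + n_0^-)$ of the dyad's
block with the dyad removed, times the Dirichlet-multinomial likelihood
ratio of *both* affected seed rows (rows $i$ and $j$ carry separate
observations $s_{ij}$ and $s_{ji}$). The node update removes the node,
deletes its cluster if emptied, and reassigns by CRP predictive weight
times the change in collapsed block likelihood of reinsertion, including a
fresh-cluster candidate evaluated under the analytic prior predictive.
Any fixed scan order leaves the stationary distribution unchanged; the
implementation's correctness is checked against brute-force enumeration of
all 52 partitions of a 5-node graph and all 8 adjacency states of a 3-node
instance.

Numerical choices:

* everything is computed in log space with `lgamma`/`lbeta`; no factorials
  are formed. Per-dyad likelihood ratios use precomputed tables of
  $\log\Gamma(\delta+s_{ij})$ and of the row pseudo-count totals over all
  possible degrees, so an edge update is O(1);
* within-cluster blocks count unordered dyads $i<j$ once, off-diagonal
  blocks pool $(a,b)$ with $(b,a)$, and the diagonal of $A$ is excluded
  everywhere (regions are not self-connected; input matrices with nonzero
  diagonals are zeroed with a warning). The self-entry is likewise excluded
  from each Dirichlet-multinomial row, which has $N-1$ categories;
* the multinomial coefficient is kept in `dirmul_row_loglik()` so the pmf
  normalizes exactly (it cancels in every sampling ratio but matters for
  the normalization tests and honest joint densities);
* the MAP estimate is the retained sample with the highest joint
  log-posterior, earliest on ties;
* cluster ids are canonicalized (numbered by first appearance) whenever a
  partition is stored or written, making chains comparable across label
  switching.

**Initialization.** The partition starts from the fully split state, one
cluster per node, and the connectomes from a greedy flat-prior pass over
the dyads. Collapsed Gibbs merges clusters far more easily than it splits
them (a split must pass through improbable intermediate states one node at
a time), so a coarse random start — e.g. a CRP draw, whose expected $K$ is
only $\log N$ — under-splits and traps chains; starting fully split makes
every move towards the posterior a merge. A CRP-draw or any custom start
remains available through the `partition` argument.

**Defaults.** 2000 sweeps, 1000 burn-in, thinning 2, all overridable via
`sirm_control()` and recorded in the fitted object. For the problem sizes
the package targets (tens to a few hundred regions) these defaults give
stable MAP estimates; the chain's log-posterior trace (`plot()`) is the
first thing to inspect when in doubt.

## Uncertainty read-outs

Because cluster labels switch and $K$ varies across samples, posterior
uncertainty is summarized through the co-assignment matrix
$M = Z^\top Z$: `coassignment()` returns $E[M]$, whose entry $(i,j)$ is the
posterior probability that regions $i$ and $j$ share a cluster. A row of
this matrix (`cluster_probability_map()`) is the cluster probability map of
one region; `interpolate_colors()` blends MAP cluster colors by
co-assignment weight, $c_i = \sum_j m_{ij}\hat c_j / \sum_j m_{ij}$, so
confidently assigned regions keep their cluster color and ambiguous ones
shade between the alternatives. `credible_interval_K()` gives equal-tailed
empirical intervals on the number of clusters, rounded outward to
integers.

## Evaluation statistics

`ami()` implements adjusted mutual information with the hypergeometric
(fixed-marginal) expected-MI correction and the max-entropy denominator,
$\mathrm{AMI} = (\mathrm{MI}-\mathrm{EMI})/(\max(H_1,H_2)-\mathrm{EMI})$.
The expected-MI term is validated against a permutation Monte-Carlo oracle.
When both partitions are a single cluster the measure is 0/0; the package
returns 1 (they are identical) with a message. One trivial partition
against a non-trivial one scores 0.

`community_ratio()` computes, per cluster, the fraction of its incident
streamlines that stay within the cluster, on the symmetrized count matrix
$S' = S + S^\top$ with each unordered pair counted once. Values near 1 mark
communities; values near 0 mark profile-based clusters and hubs. A
singleton cluster carrying streamlines scores 0 (it cannot be a community);
a cluster with no incident streamlines at all is `NA` — "no data" rather
than "pure hub". Whether to use raw or symmetrized counts is a genuine
choice; symmetrized counts are used so that the ratio does not depend on
which of the two seeding directions produced a streamline.

## The synthetic-data generator

`sample_partition()`, `sample_network()` and `sample_streamlines()` draw
from the three stages of the generative model exactly as factorized above,
and `make_toy()`/`simulate_study()` compose them: twelve nodes in three
clusters of four for the toy regimes, with block probabilities 0.9/0.05
(community: 0.9 on the diagonal; profile: 0.9 off the diagonal), and
planted-partition studies of any size. Default row totals are $T_i = 1000$
streamlines per seed region — a round, realistic order for region-level
probabilistic tractography; each generator takes an explicit seed.

What the generator emulates is the model's own world: exchangeable regions
within clusters, independent dyads given the blocks, and
Dirichlet-multinomial streamline noise. Real tractography data violate all
three in ways the generator deliberately does not mimic — distance- and
curvature-dependent streamline loss, spatially correlated false positives
from crossing fibres, inhomogeneous seeding, and region sizes that vary by
an order of magnitude. Passing recovery tests on synthetic data therefore
demonstrates the correctness of the inference machinery, not the adequacy
of the model for any particular dataset.

## Problem sizes used by the test-suite experiments

The package's verification experiments are sized to be exhaustive where
enumeration is possible and modest where sampling is required: CRP
normalization over all 4140 partitions of 8 nodes; Dirichlet-multinomial
normalization over all compositions with 3 targets and totals up to 4;
sampler-versus-enumeration comparisons at $N=5$ (52 partitions, 50k
sweeps) and $N=3$ (8 adjacency states); prior recovery at $N=20$;
planted-partition recovery at $N=24$ with 4 clusters and 10 replicate
datasets; regime separation over 100 paired toy draws.

## Known limitations

* **Joint MAP can merge weakly separated clusters.** The MAP is taken over
  the *joint* space $(Z, \{A^{(m)}\})$. When two clusters are only
  moderately distinguished by a single subject's network, a merged
  partition with a slightly adapted connectome can attain higher joint
  density than the planted truth — not a sampler failure (the merged
  state's density genuinely exceeds the best density attainable with the
  true partition) but a property of joint point estimation in a model with
  latent discrete structure. Multi-subject data sharpen the partition
  posterior and suppress this; with a single subject, inspect the
  co-assignment matrix rather than trusting the MAP alone.
* Gibbs sampling over partitions has no split–merge or tempering moves;
  multimodal posteriors at large $N$ may need several chains (compare MAP
  log-posteriors across seeds).
* The forward model conditions on row totals $T_i$; it does not model the
  absolute streamline yield of a region, and a Poisson-count variant is
  out of scope.
* Directed, degree-corrected, weighted, overlapping and hierarchical block
  models are out of scope, as is any handling of neuroimaging file formats:
  input is plain delimited text.

## A worked example

```{r, eval = FALSE}
library(sirm)
toy <- make_toy("community", seed = 1)
counts <- sample_streamlines(toy$adjacency, delta_t = 1, delta_f = 0.05,
                             row_totals = 1000, seed = 101)
fit <- sirm(counts, mode = "sirm",
            control = sirm_control(seed = 2001))
summary(fit)
ami(map_estimate(fit)$partition, toy$partition)
```
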