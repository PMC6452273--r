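---
title: "Detecting correlated evolution of binary genome traits"
author: "cooccurphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting correlated evolution of binary genome traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Prokaryotic genomes gain and lose whole functional systems — CRISPR-Cas
immune systems, DNA double-strand-break repair (DSB-RS) pathways, and the
like — on evolutionary time scales. When two such systems interact
(synergistically or antagonistically), their presence/absence patterns
across genomes become statistically associated: they co-occur more, or less,
than their individual frequencies predict. `cooccurphylo` implements a
two-stage screen for such associations over a genomes × traits binary
matrix and a phylogeny of the genomes:

1. a **phylogeny-naive screen**: 2×2 contingency tables for every
   (system, cas) trait pair, the Φ association coefficient, a comparison of
   |Φ| against frequency-matched background "control genes", Fisher exact
   tests, and a Bonferroni correction;
2. a **phylogenetic correction**: for every pair passing stage 1, a
   likelihood-ratio test of correlated evolution on the tree (independent
   vs dependent continuous-time Markov models of the joint trait states),
   repeated over a set of bootstrap trees with a median decision rule.

Stage 2 exists because genomes are not independent observations. A trait
pair gained once each on the stem of the same large clade can produce a
tiny Fisher p-value from a single pair of evolutionary events; the
tree-aware test asks instead whether the *rates* of gain and loss of one
trait depend on the state of the other, which requires repeated, associated
transitions to attain significance.

## The screening statistics

For a pair of binary traits with joint counts *a* (both present), *b*
(first only), *c* (second only), *d* (both absent):

$$\Phi = \frac{ad - bc}{\sqrt{(a+b)(c+d)(a+c)(b+d)}},$$

which is identical to the Pearson correlation of the two 0/1 indicator
vectors (the test suite uses this identity as an oracle). Φ is undefined
when a margin is zero; such pairs are reported untestable rather than
scored 0, because imputing 0 would bias the aggregate test below. Traits
present in ≤1% or ≥99% of genomes are excluded up front (strict
inequalities): their tables are so unbalanced that Φ and the Fisher test
carry almost no information.

**Control genes.** Because most repair components are frequent, their Φ
values with any frequent partner tend to be positive. To ask whether the
focal family of traits is *more* associated with the partner family than
arbitrary genes are, each system trait is compared against `k_controls = 10`
background traits sampled uniformly (without replacement) among controls
whose genome frequency lies within ±1% (absolute) of the focal trait's; the
margin widens in +1% steps when the pool is thin, and each widening is
logged. ΔΦ for a pair is |Φ| of the pair minus the mean |Φ| of its matched
controls with the same partner; a one-sample, one-sided t-test over all
pairs tests H0: mean ΔΦ ≤ 0. Zero-variance input (possible in tiny
simulations) degenerates to p ∈ {0, 1} with a warning.

**Fisher and Bonferroni.** Pair-level significance uses the two-sided
Fisher exact test under the minimum-likelihood convention (the sum of
hypergeometric probabilities of all margin-preserving tables no more
probable than the observed one), as implemented in `stats::fisher.test`.
The Bonferroni threshold is α/m with m = the number of pairs actually
tested *in the current run* — m varies with the input matrix and the
frequency filter, so it is recorded in every output rather than fixed.

## The correlated-evolution model

Joint states of a trait pair (X, Y) are ordered 1 = (0,0), 2 = (0,1),
3 = (1,0), 4 = (1,1). Both models are continuous-time Markov chains on
these four states in which only one trait may change at an instant
(double-transition rates are structurally 0):

* **independent** (4 free rates): X gains at α₁ and is lost at β₁
  regardless of Y, and symmetrically for Y (α₂, β₂);
* **dependent** (8 free rates): q₁₂, q₁₃, q₂₁, q₂₄, q₃₁, q₃₄, q₄₂, q₄₃,
  so each trait's gain/loss rate may differ according to the partner's
  state. The independent model is the nested special case
  q₁₃ = q₂₄ = α₁, q₃₁ = q₄₂ = β₁, q₁₂ = q₃₄ = α₂, q₂₁ = q₄₃ = β₂.

The likelihood of the tip patterns is computed by Felsenstein's pruning
algorithm over the four joint states, with per-branch transition matrices
exp(Q·t). The likelihood-ratio statistic 2(lnL_dep − lnL_indep) is referred
to χ² with 4 degrees of freedom — the difference in free-rate counts.
A pair is called significant after phylogenetic correction iff the median
LRT p-value across the supplied bootstrap trees is strictly below 0.01
(the even-count median is the mean of the two central order statistics).
The median rule makes the call robust to uncertainty in any single tree
estimate.

### Numerical choices

* **Root prior**: uniform (¼ per joint state) by default — the common
  default in discrete-character ML software; a stationary-distribution
  prior is available (`root_prior = "stationary"`). Under a reversible
  model with the stationary prior the likelihood is invariant to the root
  position, which the suite verifies by re-rooting.
* **Optimization** is over log-rates with bounds [1e−8, 1e3], because the
  likelihood is flat near zero rates on the natural scale. `n_starts`
  starting points are used: a moment-based initialization (each trait's
  stationary frequency matched to its tip frequency, total rate ≈ 2 events
  per mean root-to-tip depth), seeded log-normal perturbations of it, and —
  for the dependent model — the *embedded independent maximum-likelihood
  rates*, which guarantees lnL_dep ≥ lnL_indep up to optimizer tolerance.
  Bootstrap-tree fits are additionally warm-started at the main-tree MLE.
* The LRT statistic is clipped at 0 (small negative values are optimizer
  noise under nesting); zero-length branches use an identity transition
  matrix exactly; impossible data under a frozen chain yield −∞ rather
  than an error.
* Inside the C++ pruning kernel, Q is eigendecomposed once per likelihood
  evaluation and each branch's exp(Q·t) is reconstructed from the
  spectrum, falling back to a Padé matrix exponential per branch whenever
  the spectral reconstruction does not reproduce exp(Q·t) to 1e−9 (the
  generator can be defective). Rows of every transition matrix sum to 1
  within 1e−10; partial likelihoods are rescaled in post-order to avoid
  underflow.

## The signed matrix and clustering

Each (system, cas) pair receives a call in {−1, 0, +1}: nonzero only if it
passed *both* the Fisher/Bonferroni screen and the median-LRT rule, with
the sign of Φ (the joint-presence cell convention makes +1 mean
co-occurrence and −1 avoidance). Rows (cas) and columns (system) with no
nonzero entry are dropped. Rows and columns are then ordered independently
by agglomerative single-linkage ("nearest neighbour") hierarchical
clustering on Euclidean distances — the default of the clustered-heatmap
routines this output is destined for. The output is the leaf orders plus
the merge tables, not a rendered figure. Because single-linkage
merge heights between two leaves equal the minimax path between them,
cophenetic distances are invariant to tie-breaking; the test suite uses
this to compare against a brute-force O(n³) oracle.

## The synthetic benchmark

Nothing in the pipeline depends on where the trait matrix comes from, so
all tests run on simulated data:

* **Trees** are pure-birth (Yule): while k lineages are active the next
  split arrives at rate k·λ and a uniform lineage splits; after the n-th
  tip the tree is extended by one final exponential epoch, making the
  expected root-to-tip height Σ_{k=2..n} 1/(kλ). Yule rather than
  birth–death keeps a single parameter; real trees are inputs, not
  something this package estimates.
* **Trait pairs** evolve by sampling the 4-state chain down the tree from
  a root state (uniform, stationary, or fixed).
* **Control genes** are i.i.d. Bernoulli columns by default — a
  deliberately phylogeny-free null that lets tests separate the
  (phylogeny-naive) Φ screen from the tree-aware stage. An `on_tree` mode
  evolves controls as two-state chains with stationary frequency equal to
  the target, for experiments that need phylogenetically structured
  controls.
* **Bootstrap trees** are emulated by multiplying each branch length by an
  independent log-normal factor with mean 1 and coefficient of variation
  `length_cv` (default 0.2); topology is unchanged. Real bootstrap trees
  vary in topology too, so this stand-in exercises only the
  branch-length-uncertainty part of the median rule.

**Benchmark conditions.** The calibration experiments use 200-tip trees
with birth rate 1.2 (expected height ≈ 4.1) and gain/loss rates of order 1,
i.e. a trait turns over a handful of times along a root-to-tip path. This
is the informative regime for this test: much faster turnover saturates
the chain (tips forget the tree and the dependent model gains nothing);
much slower turnover freezes whole clades (few events to estimate rates
from). The planted dependency used for power experiments makes the partner
trait's gain 5× faster and its loss 5× slower when the other trait is
present. Under these conditions the suite checks that the LRT's type-I
error at p < 0.05 stays within [0.01, 0.10] (the χ²₄ reference is only
asymptotically exact), that the median rule at 0.01 is conservative
(≤ 3% false calls), and that power at p < 0.01 exceeds 80%.

Replicate counts (200 for type-I, 100 for power and for the ΔΦ
experiments, 40 full pipeline runs) were chosen to keep Monte-Carlo error
a few percent while the whole suite stays comfortably runnable on a
laptop.

## Reproducibility

Every stochastic function takes a `seed`; the pipeline takes one master
seed and derives a per-stage substream with `derive_seed(master, tag)` (a
deterministic fold of the tag into [1, 2³¹−2]), so stages can be re-run in
isolation and whole runs are byte-identical — the suite asserts identical
output files across repeated runs. Output logs record package and R
versions, the seed, and every parameter.

## What passing tests do and do not show

The synthetic generator matches the *statistical assumptions* of the
method (binary traits, Markovian gain/loss, a known tree). Real data
violate several of these: detection of a system in a genome is itself
error-prone, trees are estimated (topology error is larger than the
branch-length jitter emulated here), traits within an epistatic group are
mutually exclusive by construction, and horizontal transfer couples gains
across lineages in non-Markovian ways. Passing the suite shows the
statistics are computed correctly and behave as designed under the model —
not that the model captures everything in real genome collections.

## Known limitations

* Only pairs of binary traits; no joint models of >2 traits, hidden rate
  classes, or ancestral-state output.
* ML fitting only (the decision rule consumes likelihood-ratio p-values);
  no Bayesian (RJ-MCMC) variant.
* The χ²₄ reference for the LRT is asymptotic; at small tip counts it can
  be conservative or mildly anti-conservative, which is why the median
  rule uses the stringent 0.01 threshold.
* With a single testable pair the ΔΦ t-test is undefined and reported as
  NA.
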