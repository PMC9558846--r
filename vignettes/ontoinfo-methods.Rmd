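---
title: "Measuring Bayesian phylogenetic information and dissonance of ontology-annotated character subsets"
author: "ontoinfo package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic information and dissonance of ontology-annotated subsets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontoinfo)
```

## The question and the quantities

Morphological character matrices carry dependencies: characters describing
related anatomical structures may evolve in a concerted way, either because
they track the same phylogenetic history or because they respond jointly to
convergent selective pressures. `ontoinfo` asks whether the structure of an
anatomy ontology — which groups characters into nested anatomical concepts —
predicts the phylogenetic behaviour of the character subsets it defines.

The package works with three quantities, all defined on posterior
distributions over **unrooted, fully resolved tree topologies**:

* **Bayesian phylogenetic information (BPI).** With a discrete uniform prior
  over the $(2n-5)!!$ topologies on $n$ taxa, the prior entropy is
  $H_0 = \ln (2n-5)!!$. A data subset with posterior entropy $H$ carries
  information $I = H_0 - H$ nats, reported as a percentage of $H_0$. $I\%$
  is 0 when the data leave all topologies equiprobable and 100 when the
  posterior is a point mass.

* **Posterior coverage ($\varphi$).** The estimated fraction of total
  posterior probability represented by the distinct topologies actually
  present in a finite MCMC sample. Low coverage warns that the sample (and
  hence any entropy estimate) describes only part of the posterior.

* **Phylogenetic dissonance ($D$).** For $K$ posterior distributions,
  $D = H(\bar p) - \overline{H(p_k)}$: the entropy of their equal-weight
  mixture minus their mean entropy — a Jensen–Shannon-type divergence in
  natural log units, with $0 \le D \le \ln K$. Congruent subsets give
  $D \approx 0$; subsets concentrating on disjoint tree sets approach the
  maximum.

Because the prior depends only on the number of taxa, BPI from different
subsets of one matrix is directly comparable.

## Estimating the posterior: the conditional clade distribution

A finite topology sample underestimates the support of a diffuse posterior,
so relative frequencies ("plug-in" estimation) are biased. The package's
default estimator is the **conditional clade distribution (CCD)**: every
sampled tree is rooted at the first canonical taxon, and for each observed
clade the relative frequencies of its observed child splits are recorded.
The probability of any topology is the product of its conditional split
frequencies, which extends positive probability to unsampled topologies
assembled from sampled splits.

Two CCD properties the package relies on, both enforced by tests against
explicit enumeration at $n \le 6$:

* the entropy over the CCD's full support can be computed without
  enumeration, as $\sum_c m(c)\, H(q(\cdot\mid c))$ with $m(c)$ the clade's
  marginal probability (computed top-down from the root clade) and
  $q(\cdot\mid c)$ its conditional split distribution;
* the uniform prior itself factorises exactly as a CCD with conditionals
  $q_0(a, s-a) = R(a)R(s-a)/R(s)$, where $R(k) = (2k-3)!!$ counts rooted
  topologies on $k$ leaves.

The second property yields the **clade-specific decomposition** of
information: $I = \sum_c m(c)\, \mathrm{KL}(q(\cdot\mid c)\,\|\,
q_0(\cdot\mid c))$. Each clade's component is non-negative and the
components sum to $I$ exactly (a conservation contract asserted to
$10^{-9}$), so the share of a subset's information attributable to each
clade of a reference species tree can be read off directly.

Coverage is the CCD mass on the distinct sampled topologies. The plug-in
estimator is retained (`estimator = "plugin"`) as an oracle and for the
exact mixture identities below.

## Dissonance conventions

For plug-in distributions the identity $H(\text{merged}) = \overline{H} + D$
holds to machine precision and is asserted at $10^{-12}$. For CCD inputs the
merged distribution is the CCD built from the **pooled samples** — pooling
is what concatenating MCMC runs does, whereas averaging CCD parameters would
estimate a different object.

The literature reports dissonance "as a percentage of maximum" without
fixing the maximum, and back-calculation from published tables is ambiguous,
so the denominator is configurable: the merged entropy (default), the mean
entropy, or $\ln K$ (the strict Jensen–Shannon bound). All internal
entropies are in nats; percentages are scale-free.

## The Mk(v)+$\Gamma$ sampler

So the pipeline runs end to end without external software, the package
includes a single-chain Metropolis–Hastings sampler over (topology, branch
lengths, gamma shape) under the symmetric $k$-state Mk model with
discrete-gamma rate variation:

* transition probability $P(\text{same}) = 1/k + \frac{k-1}{k}
  e^{-k\beta t}$ with $\beta = 1/(k-1)$, so branch lengths are in expected
  changes per character;
* four rate categories by default, mean-per-category discretisation of a
  Gamma(shape $\alpha$, rate $\alpha$) distribution;
* priors: uniform on topology, i.i.d. Exponential(10) on branch lengths,
  Exponential(1) on $\alpha$ — the conventional settings for morphological
  matrices of this kind;
* `coding = "variable"` applies the Mkv ascertainment correction, dividing
  each character's likelihood by the probability of being variable (the
  correction renormalises the variable patterns to sum to one, which is
  asserted by enumeration at $n = 4$, $k = 2$);
* moves: nearest-neighbour interchange on a random internal edge (40%),
  a branch-length multiplier (40%), a gamma-shape multiplier (20%);
  proposals violating monophyly constraints are auto-rejected, which
  implements constrained analyses such as enforcing a clade of interest;
* chains start from a neighbour-joining topology on mean Hamming distances
  (with prior-scale branch lengths); a random start is used for prior
  sampling (no data) and when the NJ tree violates the constraints.
  Starting near the centre of the data's support shortens burn-in
  substantially at these problem sizes; the stationary distribution is
  unaffected.

Design divergences from common MCMC practice, chosen deliberately: no
Metropolis coupling (a mixing optimisation, not a correctness requirement at
~10 taxa), and one shared (topology, lengths, $\alpha$) across the
characters of a subset, matching per-subset analyses. The likelihood itself
is validated three ways: a closed form at two taxa, brute-force summation
over internal states on all 15 five-taxon topologies ($<10^{-10}$), and an
independent pruning implementation on binary data with gamma rates.

Sampler calibration is tested by sampling the prior (a zero-character
matrix): the topology frequencies must pass a chi-square uniformity test
over the 15 five-taxon topologies, and $I\%$ must be near zero.

## Ontology handling and semantic similarity

OBO flat files are parsed into a typed term graph (`is_a`,
`relationship:` edges, obsolete flags). Closures default to
{`is_a`, `part_of`} jointly, and the relation set is a first-class argument
everywhere, so subsumption-only or parthood-only analyses are one keyword
away — relevant because mixing relation types can cluster concepts that are
structurally unrelated (subtypes of a common class in different body
regions).

Two similarity metrics are provided: **Jaccard** overlap of reflexive
ancestor closures, and **Resnik** information content of the most
informative common ancestor. The Resnik IC corpus is the annotation table
itself ($IC(a) = -\ln(n_a/N)$ over annotated characters), which keeps the
measure self-contained and reproducible rather than dependent on an
external knowledgebase. Similarities are converted to distances as
$d = 1 - s/s_{\max}$ and clustered with average linkage (UPGMA) by default;
labels are sorted before clustering so tie-breaking is deterministic and
permutation-invariant. The linkage is configurable since no single linkage
is canonical for semantic distances.

A **dissonance dendrogram** applies the same clustering to the matrix of
pairwise dissonance percentages between subset posteriors. Comparing it
with the semantic-similarity dendrogram is the package's central device:
*semantic signal* exists where the two agree.

## Subsets, node maps and resampling

* `buildSubsetsAll()` makes one subset per annotated term with at least
  `minChars` characters (default 3 — one- or two-character subsets carry
  near-prior posteriors and mostly add noise; the threshold is exposed).
  Annotation propagation along the ontology is off by default (a subset is
  "characters annotated to this term"), with an opt-in closure mode for
  analyses of the "everything under this concept" kind.
* `buildSubsetsProfile()` implements curated term groups; `infoTable()`
  reports per-run and mean coverage/information per subset (the subset-level
  dissonance column is the among-run convergence diagnostic) plus per-group
  rows giving the merged-posterior information and among-subset dissonance
  within each run.
* `nodeInfoMap()` walks a term dendrogram and reports, for every internal
  node, the merged-posterior information and the among-subset dissonance of
  the subtended subsets, normalised by across-node means (relative values
  average 1).
* `cladeSupportMatrix()` scores every subset's marginal posterior for each
  clade of a reference topology; the "supporting proportion" uses a 0.95
  posterior-probability threshold by default (no canonical value exists;
  it is a parameter).
* `resampleSubsets()` draws size-matched random character sets (without
  replacement within a replicate, independently across replicates), and
  `compareResampled()` frames each ontology-based subset's statistic
  relative to the resampled median — above 1 means the ontology grouping
  carries more signal than a random set of the same size.

## The synthetic study generator

`makeFixtureStudy()` builds the package's test world: a toy fish-anatomy
ontology (jaw bones under a dermatocranium concept, fins under a paired-fin
concept), a random species tree, and an alternative tree sharing no
non-trivial splits with it. Jaw-term character blocks are simulated under
Mk+$\Gamma$ on the species tree; fin-term blocks are simulated **jointly on
the alternative tree**, emulating concerted convergence: anatomically
related characters that agree with each other but not with the species
phylogeny. Defaults are 8 taxa, 20 binary characters per term, gamma shape
1, mean branch length 0.1 — small enough that a full analysis runs in
seconds per subset, large enough that the convergent block is detectable.
Per-character rates are drawn from the discrete-gamma category means, so the
simulation matches the inference discretisation exactly.

What passing the end-to-end test shows: with this generator the pipeline
reports lower within-group than between-group dissonance, the dissonance
dendrogram separates the two groups, and the convergent group's posterior
supports the alternative tree's clades. What it does not show: behaviour on
real matrices with heterogeneous state spaces, correlated noise,
non-stationary evolution, or ontologies whose granularity varies across the
anatomy — none of which the generator emulates.

## Numerical choices and degenerate inputs

* Entropies in nats throughout; percentages make the base irrelevant.
* CCD entropy may exceed the prior entropy by floating-point error only;
  overshoot is clipped at $10^{-9}$ relative tolerance and larger overshoot
  is an error (it signals estimator failure).
* Topologies are canonicalised as sorted split sets (each split stored as
  the side containing the first taxon in sorted label order); the topology
  id is the sorted concatenation, invariant to rotation, rooting and branch
  lengths. Polytomies are rejected by default (the information measures
  assume resolved topologies) and accepted behind an explicit flag.
* Burn-in is `ceiling(burnin * N)` samples per run; readers of external
  tree files drop it at read time, the built-in sampler flags it on the
  returned sample and downstream statistics drop it automatically.
* `countTopologies()` returns exact values as doubles up to $n = 20$
  (beyond 2^53 exactness would need big integers; every analysis in scope
  is near $n = 10$, where reliable BPI estimation is feasible at all).
* Degenerate cases: zero-length branches with conflicting states are
  legitimate (small probability, not an error); an all-zero information
  vector makes relative information undefined and returns flagged NaNs; a
  dendrogram node subtending fewer than two sampled subsets is skipped with
  a warning.

## Problem sizes used by the test suite

The shipped tests and the acceptance script run entirely on synthetic data:
enumeration oracles at 5–6 taxa (15 and 105 topologies), sampler
calibration on 5 taxa, recovery on 10 taxa with 500 characters and two
seeded replicates, and the convergence study on 8 taxa with 7 subsets of 20
characters. These sizes were chosen to exercise every code path at full
statistical strength while keeping a complete run in minutes on one core.
Recovery fixtures draw generating edge lengths uniformly in [0.05, 0.3]:
with shorter edges the generating topology is not reliably identifiable and
"posterior mode equals the generating tree" stops being a property of the
sampler (near-ties between one-split neighbours appear), which is the
estimand those tests target.

## Known limitations

* No significance testing for BPI or dissonance differences — the
  statistics are descriptive, mirroring the framework they implement.
* The sampler is meant for small matrices (~10 taxa); for published-scale
  reanalyses, import MrBayes tree files with `readMrBayesTrees()` instead.
* CCD estimates are biased upward in coverage when the sample is very small
  relative to the posterior spread; the low-coverage warning threshold
  (50%) follows common practice.
* A single dendrogram cannot represent all relations in an ontology graph;
  relation filtering mitigates but does not remove this.
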