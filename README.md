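# ontoinfo

Quantifies how much phylogenetic information discrete morphological
characters carry about tree topology, and whether that information is
structured by anatomy-ontology knowledge. It is aimed at morphological
systematists who annotate character matrices with anatomy ontology terms
(HAO, Uberon, and the like) and want to know which anatomical concepts are
phylogenetically informative, which agree with each other, and which
betray concerted convergence.

## The statistics

All quantities are defined on posterior distributions over unrooted,
resolved tree topologies on *n* taxa, with the uniform prior over the
(2n−5)!! topologies:

* **Bayesian phylogenetic information (BPI)**
  *I = H₀ − H*, the prior entropy *H₀ = ln (2n−5)!!* minus the posterior
  entropy *H*, reported as a percentage of *H₀* (0% = no signal,
  100% = a single topology).
* **Posterior coverage (φ)** — the estimated fraction of total posterior
  probability represented by the distinct topologies present in a finite
  MCMC sample.
* **Phylogenetic dissonance (D)** — for K subset posteriors,
  *D = H(mean distribution) − mean(H)*, a Jensen–Shannon-type divergence
  (0 for congruent subsets, ≤ ln K).

Posteriors are estimated from tree samples with **conditional clade
distributions (CCDs)**: trees are rooted at a reference taxon and each
clade's child-split frequencies recorded, which extends probability to
unsampled topologies assembled from sampled splits and allows exact entropy
computation without enumeration. The same factorisation decomposes a
subset's BPI into non-negative **clade-specific components** that sum to
the total exactly.

Character subsets are built from a character→term annotation table (one
subset per annotated term, or curated term "profiles"), ontologies are read
from OBO files, and subsets are related through **Jaccard** or **Resnik**
semantic similarity dendrograms. Comparing the semantic-similarity
dendrogram with a **dissonance dendrogram** (clustering subsets by pairwise
posterior dissonance) tests whether ontology structure carries phylogenetic
information. A lightweight Mk(v)+Γ Metropolis–Hastings sampler makes the
whole pipeline self-contained; MrBayes-style `.t` files can be imported
instead for full-scale analyses.

## Worked example

A complete synthetic study: a toy fish anatomy (jaw bones + fins), a
species tree, and an alternative tree on which the fin characters evolve
jointly — the concerted-convergence scenario.

```r
library(ontoinfo)

fx <- makeFixtureStudy(nTaxa = 8, charsPerTerm = 20, seed = 42)
subsets <- buildSubsetsAll(fx$annotations, minChars = 3)

samples <- list()
for (j in seq_along(subsets)) {
  id <- names(subsets)[j]
  runs <- runMkMcmc(subsetCharacters(fx$matrix, subsets[[id]]$chars),
                    mkModel(coding = "variable"),
                    mcmcConfig(nGenerations = 3000, sampleEvery = 10,
                               nRuns = 2L, seed = 100 + j),
                    subsetId = id)
  samples[[id]] <- lapply(runs, dropBurnin)
}

tab <- infoTable(samples)
tab[tab$run == "mean", c("subset", "coverage_pct", "information_pct",
                         "dissonance_pct")]
#>        subset coverage_pct information_pct dissonance_pct
#>  FISH:0000011         86.8            60.7           7.55
#>  FISH:0000012         90.5            60.9           3.99
#>  FISH:0000013         89.0            53.7           3.18
#>  FISH:0000014         74.1            46.0           5.76
#>  FISH:0000021         93.9            62.5           6.18
#>  FISH:0000022         95.5            62.2           3.55
#>  FISH:0000023         87.6            58.4           9.01
```

Each subset row gives the mean posterior coverage and information across
the two runs; the dissonance column is the among-run dissonance, a
topology-convergence diagnostic (a few percent here, consistent with
converged chains). Terms `FISH:0000011–14` are the jaw bones (premaxilla,
maxilla, dentary, infraorbital; simulated on the species tree);
`FISH:0000021–23` are the fins (simulated on the alternative tree).

Clustering the subsets by pairwise posterior dissonance separates the two
blocks:

```r
merged <- lapply(samples, mergeTreeSamples)   # pool the two runs per subset
dd <- dissonanceDendrogram(merged)
dendrogramToNewick(dd$dendrogram)
#> ((FISH-0000021,(FISH-0000022,FISH-0000023)),(FISH-0000011,(FISH-0000014,(FISH-0000012,FISH-0000013))));
```

(heights omitted for readability — fins cluster with fins, jaws with jaws).
Finally, the clade decomposition of one jaw subset's information against
its own posterior:

```r
cc <- cladeInfoComponents(buildCCD(merged[[1]]))
head(cc$table, 3)
#>      clade size posteriorProb infoComponent
#> 1 01111111    7         1.000         2.641
#> 2 00111101    5         0.671         0.867
#> 3 00101101    4         0.584         0.607
cc$totalI       # 5.32 nats of the prior entropy ln(10395) = 9.249
```

The components are per-clade Kullback–Leibler terms against the analytic
uniform-prior CCD and sum to the subset's total information exactly.

A command-line surface over the same functions is provided as
`exec/ontoinfo` (subcommands `fixture`, `subsets`, `sample`, `import`,
`info`, `dissonance`, `semdendro`, `dissdendro`, `nodemap`, `cladeinfo`,
`compare-resampled`); every run writes a JSON manifest with its merged
configuration.

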