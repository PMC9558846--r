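#' @import methods
#' @importFrom stats as.dist hclust qgamma pgamma runif rexp setNames
#' @importFrom utils read.delim write.table combn head tail
NULL

## Split/clade masks are "0"/"1" strings over the canonical (sorted) taxon
## order; a split mask always contains the first taxon, a clade mask never
## contains it (clades arise from rooting at the first taxon).

#' Unrooted tree topology
#'
#' A canonical, branch-length-free representation of an unrooted (binary or
#' multifurcating) tree topology: the sorted taxon label set plus the set of
#' non-trivial bipartitions, each encoded as a bitmask string over the
#' canonical taxon order for the side containing the first taxon. The
#' \code{id} is the sorted concatenation of split masks, so it is invariant
#' to rotation, rooting and branch lengths.
#'
#' @slot taxa character vector of taxon labels, sorted (canonical order).
#' @slot splits character vector of split masks ("0"/"1" strings), sorted.
#' @slot id character scalar identifying the topology.
#' @export
setClass("Topology", representation(
  taxa = "character", splits = "character", id = "character"
))

setValidity("Topology", function(object) {
  n <- length(object@taxa)
  if (anyDuplicated(object@taxa)) return("duplicate taxon labels")
  if (is.unsorted(object@taxa)) return("taxa must be in sorted canonical order")
  if (length(object@splits) && any(nchar(object@splits) != n))
    return("split masks must have one bit per taxon")
  if (length(object@splits) && any(substr(object@splits, 1, 1) != "1"))
    return("split masks must contain the first canonical taxon")
  TRUE
})

#' Posterior sample of tree topologies
#'
#' An ordered sample of \linkS4class{Topology} objects from one MCMC run (or
#' an i.i.d. synthetic draw), all on one taxon set. \code{burninFraction}
#' records the proportion of the stored sample that still needs to be
#' discarded as burn-in (\code{\link{dropBurnin}}); readers that already
#' discard burn-in set it to 0.
#'
#' @slot taxa canonical taxon labels.
#' @slot splits list of character vectors: the split set of each sampled tree.
#' @slot ids character vector of topology ids, parallel to \code{splits}.
#' @slot runId,subsetId character labels for provenance.
#' @slot burninFraction numeric in [0,1).
#' @export
setClass("TreeSample", representation(
  taxa = "character", splits = "list", ids = "character",
  runId = "character", subsetId = "character", burninFraction = "numeric"
))

setValidity("TreeSample", function(object) {
  if (length(object@splits) != length(object@ids))
    return("splits and ids must have equal length")
  if (length(object@ids) == 0L) return("empty tree sample")
  if (object@burninFraction < 0 || object@burninFraction >= 1)
    return("burninFraction must be in [0, 1)")
  TRUE
})

#' Explicit distribution over tree topologies
#'
#' Probabilities attached to explicitly listed topology ids. The plug-in
#' (relative frequency) estimator produces distributions summing to one over
#' the listed ids; a CCD-derived distribution restricted to listed ids may
#' sum to less than one.
#'
#' @slot taxa canonical taxon labels.
#' @slot probs named numeric vector, names are topology ids.
#' @slot estimator one of "plugin", "ccd", "analytic".
#' @export
setClass("TopologyDistribution", representation(
  taxa = "character", probs = "numeric", estimator = "character"
))

setValidity("TopologyDistribution", function(object) {
  if (is.null(names(object@probs))) return("probs must be named by topology id")
  if (any(object@probs < -1e-12)) return("negative probabilities")
  if (object@estimator == "plugin" && abs(sum(object@probs) - 1) > 1e-9)
    return("plugin distribution must sum to 1")
  TRUE
})

#' Conditional clade distribution (CCD)
#'
#' Factorised estimator of the posterior over tree topologies: sampled trees
#' are rooted at the first canonical taxon and, for every observed clade, the
#' relative frequencies of its observed child splits are recorded. The CCD
#' extends positive probability to unsampled topologies assembled from
#' sampled conditional splits.
#'
#' @slot taxa canonical taxon labels; the first is the rooting taxon.
#' @slot cladeTable named list: clade mask -> named numeric vector of child
#'   split keys ("maskA|maskB") -> conditional frequency (sums to 1).
#' @slot sampleSize number of trees the CCD was built from.
#' @export
setClass("CladeDistribution", representation(
  taxa = "character", cladeTable = "list", sampleSize = "numeric"
))

setValidity("CladeDistribution", function(object) {
  for (q in object@cladeTable) {
    if (abs(sum(q) - 1) > 1e-9) return("conditional split frequencies must sum to 1")
    if (any(q < 0)) return("negative conditional frequency")
  }
  TRUE
})

#' Per-subset information summary
#'
#' Posterior coverage, posterior entropy, Bayesian phylogenetic information
#' (prior entropy minus posterior entropy, in nats) and its percentage of the
#' prior entropy for one tree sample.
#'
#' @slot coveragePhi fraction of posterior probability covered by the
#'   distinct sampled topologies.
#' @slot entropyH posterior entropy (nats).
#' @slot informationI information in nats; \code{informationPct} as percent
#'   of the uniform-prior entropy.
#' @slot nTaxa,subsetId,runId provenance.
#' @export
setClass("InfoSummary", representation(
  coveragePhi = "numeric", entropyH = "numeric", informationI = "numeric",
  informationPct = "numeric", nTaxa = "integer",
  subsetId = "character", runId = "character"
))

#' Phylogenetic dissonance result
#'
#' Jensen-Shannon-type divergence among K topology distributions: entropy of
#' the equal-weight merged distribution minus the mean of the per-distribution
#' entropies (natural log). The percentage denominator is configurable
#' because only "percent of maximum" is well defined up to convention.
#'
#' @slot entropies per-distribution entropies (nats).
#' @slot meanEntropy,mergedEntropy,dissonanceD nats.
#' @slot dissonancePct percent of the configured maximum.
#' @slot k number of distributions; \code{denominator} one of "merged",
#'   "mean", "logk".
#' @export
setClass("DissonanceResult", representation(
  entropies = "numeric", meanEntropy = "numeric", mergedEntropy = "numeric",
  dissonanceD = "numeric", dissonancePct = "numeric", k = "integer",
  denominator = "character"
))

#' Ontology term graph
#'
#' Terms and typed directed relations (child -> parent) of an anatomy
#' ontology read from an OBO flat file. Closures are taken over a
#' configurable relation set; obsolete terms are excluded from closures.
#'
#' @slot terms data.frame with columns id, name, obsolete.
#' @slot edges data.frame with columns child, parent, relation.
#' @export
setClass("TermGraph", representation(terms = "data.frame", edges = "data.frame"))

setValidity("TermGraph", function(object) {
  need <- c("id", "name", "obsolete")
  if (!all(need %in% names(object@terms))) return("terms needs id/name/obsolete")
  if (!all(c("child", "parent", "relation") %in% names(object@edges)))
    return("edges needs child/parent/relation")
  known <- object@terms$id
  if (nrow(object@edges) &&
      !all(c(object@edges$child, object@edges$parent) %in% known))
    return("edge endpoint not a known term")
  TRUE
})

#' Discrete morphological character matrix
#'
#' Taxa-by-characters matrix of discrete state tokens. Cells are strings of
#' state symbols: "0", "1", ... ; "?" (or "-") for missing; multi-symbol
#' strings such as "01" for polymorphic/ambiguous observations. Each
#' character carries its own state-space size (its declared alphabet).
#'
#' @slot taxa canonical taxon labels (rows).
#' @slot codes character matrix (taxa x characters) of state tokens.
#' @slot nStates integer vector, per-character number of states k.
#' @export
setClass("CharacterMatrix", representation(
  taxa = "character", codes = "matrix", nStates = "integer"
))

setValidity("CharacterMatrix", function(object) {
  if (nrow(object@codes) != length(object@taxa)) return("row/taxa mismatch")
  if (ncol(object@codes) != length(object@nStates)) return("col/nStates mismatch")
  if (any(object@nStates < 2)) return("characters need at least 2 states")
  TRUE
})

#' Mk+Gamma model settings
#'
#' Symmetric k-state Markov model for discrete morphology with discrete-gamma
#' rate variation. \code{coding = "variable"} applies the ascertainment
#' correction for matrices that exclude constant characters (Mkv).
#'
#' @slot nRateCategories number of discrete gamma categories (default 4).
#' @slot coding "all" or "variable".
#' @slot blRate exponential prior rate on branch lengths (default 10).
#' @slot shapeRate exponential prior rate on the gamma shape (default 1).
#' @export
setClass("MkModel", representation(
  nRateCategories = "integer", coding = "character",
  blRate = "numeric", shapeRate = "numeric"
))

#' @rdname MkModel-class
#' @param nRateCategories,coding,blRate,shapeRate see slots.
#' @return an \code{MkModel}.
#' @export
mkModel <- function(nRateCategories = 4L, coding = c("variable", "all"),
                    blRate = 10, shapeRate = 1) {
  coding <- match.arg(coding)
  new("MkModel", nRateCategories = as.integer(nRateCategories),
      coding = coding, blRate = blRate, shapeRate = shapeRate)
}

#' MCMC run configuration
#'
#' @slot nGenerations total proposals per run.
#' @slot sampleEvery thinning interval.
#' @slot burninFraction proportion flagged as burn-in (default 0.25).
#' @slot nRuns number of independent runs (default 2).
#' @slot seed integer seed.
#' @slot constraints list of clade label vectors that every sampled topology
#'   must contain (monophyly constraints).
#' @export
setClass("McmcConfig", representation(
  nGenerations = "numeric", sampleEvery = "numeric", burninFraction = "numeric",
  nRuns = "integer", seed = "integer", constraints = "list"
))

#' @rdname McmcConfig-class
#' @param nGenerations,sampleEvery,burninFraction,nRuns,seed,constraints see slots.
#' @return an \code{McmcConfig}.
#' @export
mcmcConfig <- function(nGenerations = 20000, sampleEvery = 20,
                       burninFraction = 0.25, nRuns = 2L, seed = 1L,
                       constraints = list()) {
  new("McmcConfig", nGenerations = nGenerations, sampleEvery = sampleEvery,
      burninFraction = burninFraction, nRuns = as.integer(nRuns),
      seed = as.integer(seed), constraints = constraints)
}

## ---- show methods ----

setMethod("show", "Topology", function(object) {
  cat(sprintf("Topology: %d taxa, %d non-trivial splits\n  id: %s\n",
              length(object@taxa), length(object@splits),
              substr(object@id, 1, 60)))
})

setMethod("show", "TreeSample", function(object) {
  cat(sprintf(
    "TreeSample: %d trees, %d taxa, %d distinct topologies\n  subset: %s  run: %s  burnin flagged: %.0f%%\n",
    length(object@ids), length(object@taxa), length(unique(object@ids)),
    object@subsetId, object@runId, 100 * object@burninFraction))
})

setMethod("show", "TopologyDistribution", function(object) {
  cat(sprintf("TopologyDistribution (%s): %d topologies, mass %.4f\n",
              object@estimator, length(object@probs), sum(object@probs)))
})

setMethod("show", "CladeDistribution", function(object) {
  cat(sprintf("CladeDistribution: %d taxa, %d clades, built from %d trees\n",
              length(object@taxa), length(object@cladeTable), object@sampleSize))
})

setMethod("show", "InfoSummary", function(object) {
  cat(sprintf(
    "InfoSummary [%s / %s]: phi = %.4f, H = %.4f nats, I = %.4f nats (%.2f%%)\n",
    object@subsetId, object@runId, object@coveragePhi, object@entropyH,
    object@informationI, object@informationPct))
})

setMethod("show", "DissonanceResult", function(object) {
  cat(sprintf(
    "Dissonance over %d distributions: D = %.4f nats (%.2f%% of %s)\n",
    object@k, object@dissonanceD, object@dissonancePct, object@denominator))
})

setMethod("show", "TermGraph", function(object) {
  cat(sprintf("TermGraph: %d terms (%d obsolete), %d edges (%s)\n",
              nrow(object@terms), sum(object@terms$obsolete), nrow(object@edges),
              paste(unique(object@edges$relation), collapse = ", ")))
})

setMethod("show", "CharacterMatrix", function(object) {
  cat(sprintf("CharacterMatrix: %d taxa x %d characters, k in {%s}\n",
              length(object@taxa), ncol(object@codes),
              paste(sort(unique(object@nStates)), collapse = ",")))
})

## ---- accessors ----

#' Accessors for core classes
#'
#' @param x an object.
#' @return \code{taxonLabels}: character vector of taxon labels;
#'   \code{topologyID}: topology id string; \code{topologySplits}: split
#'   masks; \code{nTrees}: number of sampled trees.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("taxonLabels", function(x) standardGeneric("taxonLabels"))
#' @rdname accessors
#' @export
setMethod("taxonLabels", "Topology", function(x) x@taxa)
#' @rdname accessors
#' @export
setMethod("taxonLabels", "TreeSample", function(x) x@taxa)
#' @rdname accessors
#' @export
setMethod("taxonLabels", "TopologyDistribution", function(x) x@taxa)
#' @rdname accessors
#' @export
setMethod("taxonLabels", "CladeDistribution", function(x) x@taxa)
#' @rdname accessors
#' @export
setMethod("taxonLabels", "CharacterMatrix", function(x) x@taxa)

#' @rdname accessors
#' @export
topologyID <- function(x) {
  stopifnot(is(x, "Topology"))
  x@id
}

#' @rdname accessors
#' @export
topologySplits <- function(x) {
  stopifnot(is(x, "Topology"))
  x@splits
}

#' @rdname accessors
#' @export
nTrees <- function(x) {
  stopifnot(is(x, "TreeSample"))
  length(x@ids)
}

#' @rdname accessors
#' @export
topologyIDs <- function(x) {
  stopifnot(is(x, "TreeSample"))
  x@ids
}

#' @rdname accessors
#' @export
topologyProbs <- function(x) {
  stopifnot(is(x, "TopologyDistribution"))
  x@probs
}
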