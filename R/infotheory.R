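## Estimators of the posterior distribution over tree topologies and the
## information-theoretic statistics computed from them: posterior coverage,
## entropy, Bayesian phylogenetic information (BPI), phylogenetic dissonance
## and clade-specific information components.
##
## Entropies are in nats throughout; reported percentages are relative to
## the relevant maximum, so the log base cancels.

## ---- prior ----

#' Entropy of the uniform prior over unrooted topologies
#'
#' \code{ln((2n - 5)!!)}, computed in log space so it is exact for any n.
#'
#' @param n taxon count, >= 4.
#' @return prior entropy in nats.
#' @examples
#' priorEntropy(5)   # log(15)
#' @export
priorEntropy <- function(n) {
  if (n < 4) stop("n must be >= 4")
  sum(log(seq(1, 2 * n - 5, by = 2)))
}

## number of rooted binary topologies on k leaves, R(k) = (2k - 3)!!
nRootedTopologies <- function(k) {
  if (k <= 2) return(1)
  prod(seq(1, 2 * k - 3, by = 2))
}

## analytic prior conditional probability that a clade of size a + b splits
## into a given unordered pair of sizes (a, b)
priorSplitProb <- function(a, b) {
  exp(log(nRootedTopologies(a)) + log(nRootedTopologies(b)) -
        log(nRootedTopologies(a + b)))
}

## ---- plug-in estimator ----

#' Plug-in (relative frequency) topology distribution
#'
#' @param sample a \linkS4class{TreeSample} (burn-in already removed).
#' @return a \linkS4class{TopologyDistribution} with estimator "plugin".
#' @export
pluginDistribution <- function(sample) {
  stopifnot(is(sample, "TreeSample"))
  tab <- table(sample@ids)
  probs <- as.numeric(tab) / length(sample@ids)
  names(probs) <- names(tab)
  new("TopologyDistribution", taxa = sample@taxa, probs = probs,
      estimator = "plugin")
}

#' Shannon entropy of an explicit topology distribution
#'
#' @param dist a \linkS4class{TopologyDistribution}.
#' @return entropy in nats over the listed ids.
#' @export
distributionEntropy <- function(dist) {
  p <- dist@probs[dist@probs > 0]
  -sum(p * log(p))
}

## ---- conditional clade distribution ----

#' Build a conditional clade distribution from a tree sample
#'
#' Each sampled (fully resolved) tree is rooted at the first canonical
#' taxon; for every observed clade the relative frequencies of its observed
#' child splits are recorded.
#'
#' @param sample a \linkS4class{TreeSample} (burn-in already removed).
#' @return a \linkS4class{CladeDistribution}.
#' @export
buildCCD <- function(sample) {
  stopifnot(is(sample, "TreeSample"))
  n <- length(sample@taxa)
  counts <- new.env(parent = emptyenv())
  for (spl in sample@splits) {
    if (length(spl) != n - 3)
      stop("CCD requires fully resolved topologies")
    cm <- rootedChildMap(spl, n)
    for (clade in names(cm)) {
      kids <- cm[[clade]]
      if (length(kids) != 2) stop("CCD requires binary clades")
      key <- paste(sort(kids), collapse = "|")
      cur <- counts[[clade]]
      if (is.null(cur)) cur <- numeric(0)
      cur[key] <- (if (is.na(cur[key])) 0 else cur[key]) + 1
      counts[[clade]] <- cur
    }
  }
  cladeTable <- lapply(as.list(counts), function(x) x / sum(x))
  new("CladeDistribution", taxa = sample@taxa, cladeTable = cladeTable,
      sampleSize = length(sample@ids))
}

#' Analytic CCD of the uniform prior
#'
#' The conditional probability that a clade of size s splits into given
#' subsets of sizes (a, s - a) is R(a) R(s-a) / R(s) with R(k) = (2k-3)!!
#' the number of rooted topologies on k leaves. Enumerates every clade, so
#' intended for small n (tests, oracles).
#'
#' @param taxa canonical taxon labels (sorted).
#' @return a \linkS4class{CladeDistribution} that assigns exactly
#'   \code{1 / countTopologies(n)} to every resolved topology.
#' @export
priorCCD <- function(taxa) {
  taxa <- sort(taxa)
  n <- length(taxa)
  if (n < 4 || n > 12) stop("priorCCD is for 4 <= n <= 12")
  idxAll <- 2:n
  cladeTable <- list()
  for (sz in 2:(n - 1)) {
    sets <- utils::combn(idxAll, sz, simplify = FALSE)
    if (sz == n - 1) sets <- list(idxAll)
    for (s in sets) {
      q <- numeric(0)
      others <- s[-1]
      combnList <- function(x, m)
        if (m == 0) list(integer(0)) else utils::combn(x, m, simplify = FALSE)
      for (asz in 1:(length(s) - 1)) {
        ## child containing the smallest member of s, of size asz
        for (aRest in combnList(others, asz - 1)) {
          a <- c(s[1], aRest)
          b <- setdiff(s, a)
          va <- rep(FALSE, n); va[a] <- TRUE
          vb <- rep(FALSE, n); vb[b] <- TRUE
          key <- paste(sort(c(maskFromLogical(va), maskFromLogical(vb))),
                       collapse = "|")
          q[key] <- priorSplitProb(length(a), length(b))
        }
      }
      v <- rep(FALSE, n); v[s] <- TRUE
      cladeTable[[maskFromLogical(v)]] <- q
    }
  }
  new("CladeDistribution", taxa = taxa, cladeTable = cladeTable,
      sampleSize = 0)
}

#' CCD probability of a single topology
#'
#' Product over the clades of the topology (rooted at the first canonical
#' taxon) of the conditional split frequencies; 0 if any clade or split was
#' never observed.
#'
#' @param ccd a \linkS4class{CladeDistribution}.
#' @param topology a \linkS4class{Topology} on the same taxon set.
#' @return a probability.
#' @export
ccdTopologyProb <- function(ccd, topology) {
  stopifnot(identical(ccd@taxa, topology@taxa))
  n <- length(ccd@taxa)
  cm <- rootedChildMap(topology@splits, n)
  p <- 1
  for (clade in names(cm)) {
    q <- ccd@cladeTable[[clade]]
    if (is.null(q)) return(0)
    key <- paste(sort(cm[[clade]]), collapse = "|")
    qi <- q[key]
    if (is.na(qi)) return(0)
    p <- p * qi
  }
  unname(p)
}

## clade marginals m(c) computed top-down from the root clade
ccdCladeMarginals <- function(ccd) {
  n <- length(ccd@taxa)
  clades <- names(ccd@cladeTable)
  sizes <- vapply(clades, function(m) sum(logicalFromMask(m)), 0)
  ord <- order(sizes, decreasing = TRUE)
  clades <- clades[ord]
  m <- stats::setNames(numeric(length(clades)), clades)
  rootClade <- maskFromLogical(c(FALSE, rep(TRUE, n - 1)))
  m[rootClade] <- 1
  for (clade in clades) {
    mc <- m[clade]
    if (mc == 0) next
    q <- ccd@cladeTable[[clade]]
    for (i in seq_along(q)) {
      kids <- strsplit(names(q)[i], "|", fixed = TRUE)[[1]]
      for (kid in kids) {
        if (!is.null(ccd@cladeTable[[kid]]))
          m[kid] <- m[kid] + mc * q[i]
      }
    }
  }
  m
}

#' Entropy of a CCD without enumerating topologies
#'
#' Uses the factorisation of the CCD: the entropy over its full support is
#' the sum over clades of the clade's marginal probability times the entropy
#' of its conditional split distribution.
#'
#' @param ccd a \linkS4class{CladeDistribution}.
#' @return entropy in nats.
#' @export
ccdEntropy <- function(ccd) {
  m <- ccdCladeMarginals(ccd)
  h <- 0
  for (clade in names(ccd@cladeTable)) {
    q <- ccd@cladeTable[[clade]]
    q <- q[q > 0]
    h <- h + m[clade] * (-sum(q * log(q)))
  }
  unname(h)
}

#' Posterior coverage of a tree sample
#'
#' The CCD-estimated total posterior probability of the distinct topologies
#' actually present in the sample.
#'
#' @param sample a \linkS4class{TreeSample}.
#' @param ccd optional \linkS4class{CladeDistribution}; built from
#'   \code{sample} when missing.
#' @return coverage phi in (0, 1].
#' @export
posteriorCoverage <- function(sample, ccd = NULL) {
  if (is.null(ccd)) ccd <- buildCCD(sample)
  firstIdx <- !duplicated(sample@ids)
  tops <- sample@splits[firstIdx]
  phi <- 0
  for (spl in tops) {
    top <- new("Topology", taxa = sample@taxa, splits = spl,
               id = topologyIdFromSplits(spl))
    phi <- phi + ccdTopologyProb(ccd, top)
  }
  min(phi, 1)
}

## ---- information ----

#' Bayesian phylogenetic information from a posterior entropy
#'
#' I = prior entropy minus posterior entropy; also returned as a percentage
#' of the prior entropy. Tiny estimator overshoot above the prior entropy is
#' clipped; larger overshoot signals estimator failure and errors.
#'
#' @param entropyH posterior entropy in nats.
#' @param n taxon count.
#' @return list with \code{informationI} (nats) and \code{informationPct}.
#' @export
phyloInformation <- function(entropyH, n) {
  h0 <- priorEntropy(n)
  if (entropyH > h0 * (1 + 1e-9) + 1e-12)
    stop("posterior entropy exceeds prior entropy: estimator failure")
  entropyH <- min(entropyH, h0)
  i <- h0 - entropyH
  list(informationI = i, informationPct = 100 * i / h0)
}

#' Per-sample information summary
#'
#' Builds the chosen posterior estimator and returns coverage, entropy,
#' information and information percentage for one tree sample.
#'
#' @param sample a \linkS4class{TreeSample}; flagged burn-in is removed.
#' @param estimator "ccd" (default) or "plugin". Coverage is always
#'   CCD-based (it is defined relative to the CCD mass).
#' @return an \linkS4class{InfoSummary}.
#' @export
infoSummary <- function(sample, estimator = c("ccd", "plugin")) {
  estimator <- match.arg(estimator)
  sample <- dropBurnin(sample)
  n <- length(sample@taxa)
  ccd <- buildCCD(sample)
  h <- if (estimator == "ccd") ccdEntropy(ccd)
       else distributionEntropy(pluginDistribution(sample))
  info <- phyloInformation(h, n)
  new("InfoSummary", coveragePhi = posteriorCoverage(sample, ccd),
      entropyH = min(h, priorEntropy(n)),
      informationI = info$informationI, informationPct = info$informationPct,
      nTaxa = as.integer(n), subsetId = sample@subsetId, runId = sample@runId)
}

## ---- dissonance ----

#' Pool tree samples (e.g. independent runs) into one sample
#'
#' Concatenates the topology sequences; this is the merged distribution
#' used for profile-level information and for CCD-based dissonance.
#'
#' @param samples list of \linkS4class{TreeSample} objects on one taxon set.
#' @return a \linkS4class{TreeSample}.
#' @export
mergeTreeSamples <- function(samples) {
  taxa <- samples[[1]]@taxa
  for (s in samples) if (!identical(s@taxa, taxa)) stop("mismatched taxa")
  new("TreeSample", taxa = taxa,
      splits = do.call(c, lapply(samples, function(s) s@splits)),
      ids = do.call(c, lapply(samples, function(s) s@ids)),
      runId = "merged", subsetId = samples[[1]]@subsetId, burninFraction = 0)
}

mergeDistributions <- function(dists) {
  taxa <- dists[[1]]@taxa
  for (d in dists) if (!identical(d@taxa, taxa)) stop("mismatched taxa")
  ids <- unique(unlist(lapply(dists, function(d) names(d@probs))))
  acc <- stats::setNames(numeric(length(ids)), ids)
  for (d in dists) acc[names(d@probs)] <- acc[names(d@probs)] + d@probs
  new("TopologyDistribution", taxa = taxa, probs = acc / length(dists),
      estimator = dists[[1]]@estimator)
}

#' Phylogenetic dissonance among topology distributions
#'
#' Jensen-Shannon-type divergence with natural logs: the entropy of the
#' equal-weight merged distribution minus the mean per-distribution entropy.
#' For \linkS4class{TreeSample} inputs with the CCD estimator, the merged
#' distribution is the CCD of the pooled samples (pooling is what
#' concatenating runs does); for plug-in inputs the probability vectors are
#' averaged.
#'
#' @param x list of K >= 2 \linkS4class{TreeSample} or
#'   \linkS4class{TopologyDistribution} objects on one taxon set.
#' @param denominator scaling of the reported percentage: "merged" (default,
#'   percent of the merged-distribution entropy), "mean", or "logk"
#'   (percent of ln K, the JSD maximum).
#' @param estimator "ccd" (default) or "plugin"; only used for tree samples.
#' @return a \linkS4class{DissonanceResult}.
#' @export
dissonance <- function(x, denominator = c("merged", "mean", "logk"),
                       estimator = c("ccd", "plugin")) {
  denominator <- match.arg(denominator)
  estimator <- match.arg(estimator)
  if (length(x) < 2) stop("need at least 2 distributions")
  if (is(x[[1]], "TreeSample")) {
    x <- lapply(x, dropBurnin)
    if (estimator == "ccd") {
      hs <- vapply(x, function(s) ccdEntropy(buildCCD(s)), 0)
      hm <- ccdEntropy(buildCCD(mergeTreeSamples(x)))
    } else {
      dists <- lapply(x, pluginDistribution)
      hs <- vapply(dists, distributionEntropy, 0)
      hm <- distributionEntropy(mergeDistributions(dists))
    }
  } else if (is(x[[1]], "TopologyDistribution")) {
    hs <- vapply(x, distributionEntropy, 0)
    hm <- distributionEntropy(mergeDistributions(x))
  } else stop("x must be a list of TreeSample or TopologyDistribution")
  k <- length(x)
  d <- max(hm - mean(hs), 0)
  den <- switch(denominator, merged = hm, mean = mean(hs), logk = log(k))
  pct <- if (den <= 0) 0 else 100 * d / den
  new("DissonanceResult", entropies = hs, meanEntropy = mean(hs),
      mergedEntropy = hm, dissonanceD = d,
      dissonancePct = min(pct, 100), k = as.integer(k),
      denominator = denominator)
}

#' Among-run dissonance (topology convergence diagnostic)
#'
#' Dissonance between the posteriors of two MCMC runs of the same data
#' subset; values near zero indicate topological convergence.
#'
#' @param run1,run2 \linkS4class{TreeSample} objects from the same subset.
#' @inheritParams dissonance
#' @return a \linkS4class{DissonanceResult}.
#' @export
amongRunDissonance <- function(run1, run2,
                               denominator = c("merged", "mean", "logk"),
                               estimator = c("ccd", "plugin")) {
  dissonance(list(run1, run2), denominator = denominator,
             estimator = estimator)
}

## ---- clade-level statistics ----

#' Clade-specific information components
#'
#' Decomposes the CCD-estimated information I = prior entropy - posterior
#' entropy over the observed clades: each clade contributes its marginal
#' probability times the Kullback-Leibler divergence of its posterior
#' conditional split distribution from the analytic prior conditional
#' (sizes-based, R(a)R(b)/R(s)). Components are non-negative and sum to the
#' total information exactly.
#'
#' @param ccd a \linkS4class{CladeDistribution}.
#' @return a list with \code{table} (data.frame: clade mask, size, posterior
#'   probability, information component in nats) and \code{totalI} (nats).
#' @export
cladeInfoComponents <- function(ccd) {
  m <- ccdCladeMarginals(ccd)
  clades <- names(ccd@cladeTable)
  comp <- numeric(length(clades))
  size <- integer(length(clades))
  for (i in seq_along(clades)) {
    q <- ccd@cladeTable[[clades[i]]]
    size[i] <- sum(logicalFromMask(clades[i]))
    kl <- 0
    for (j in seq_along(q)) {
      if (q[j] == 0) next
      kids <- strsplit(names(q)[j], "|", fixed = TRUE)[[1]]
      a <- sum(logicalFromMask(kids[1]))
      b <- sum(logicalFromMask(kids[2]))
      kl <- kl + q[j] * (log(q[j]) - log(priorSplitProb(a, b)))
    }
    comp[i] <- m[clades[i]] * kl
  }
  tab <- data.frame(clade = clades, size = size,
                    posteriorProb = unname(m[clades]),
                    infoComponent = comp, stringsAsFactors = FALSE)
  tab <- tab[order(-tab$infoComponent), ]
  rownames(tab) <- NULL
  list(table = tab, totalI = sum(comp))
}

#' Marginal posterior probability of a clade
#'
#' The probability that the bipartition induced by the given clade appears
#' in a tree drawn from the distribution (for samples: the relative
#' frequency of the split).
#'
#' @param x a \linkS4class{TreeSample} or \linkS4class{TopologyDistribution}.
#' @param clade character vector of taxon labels, or a bitmask string over
#'   the canonical taxon order.
#' @return a probability.
#' @export
cladePosterior <- function(x, clade) {
  taxa <- taxonLabels(x)
  n <- length(taxa)
  mask <- if (length(clade) == 1 && grepl("^[01]+$", clade) &&
              nchar(clade) == n) clade else maskFromLabels(clade, taxa)
  sz <- sum(logicalFromMask(mask))
  if (sz < 2 || sz > n - 2) stop("trivial clade (size < 2 or > n - 2)")
  split <- canonicalSplit(logicalFromMask(mask))
  if (is(x, "TreeSample")) {
    hits <- vapply(x@splits, function(s) split %in% s, FALSE)
    mean(hits)
  } else if (is(x, "TopologyDistribution")) {
    hit <- vapply(names(x@probs), function(id) {
      split %in% strsplit(id, ";", fixed = TRUE)[[1]]
    }, FALSE)
    sum(x@probs[hit])
  } else stop("unsupported input")
}
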