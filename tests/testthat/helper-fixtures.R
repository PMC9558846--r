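## Shared test fixtures, all built in code.

taxa5 <- letters[1:5]
taxa6 <- letters[1:6]

## cached enumerations (cheap, reused across files)
TOPS5 <- enumerateTopologies(taxa5)
TOPS6 <- enumerateTopologies(taxa6)

## a skewed but full-support distribution over the 15 five-taxon topologies
skewedProbs5 <- function() {
  p <- exp(-0.4 * seq_len(15))
  p / sum(p)
}

## random resolved topology as Topology
randomTopology <- function(n) {
  topologyFromPhylo(ape::rtree(n, tip.label = sample(paste0("t", seq_len(n)))))
}

## random plugin distribution over made-up ids
randomPlugin <- function(nIds = 6, taxa = taxa5) {
  p <- stats::rexp(nIds)
  new("TopologyDistribution", taxa = taxa,
      probs = stats::setNames(p / sum(p), paste0("id", seq_len(nIds))),
      estimator = "plugin")
}

pointMass <- function(id = "id1", taxa = taxa5) {
  new("TopologyDistribution", taxa = taxa,
      probs = stats::setNames(1, id), estimator = "plugin")
}

## independent CCD-probability oracle: tally conditional clade splits by
## rooting each sampled tree at the first taxon with ape and walking the
## rooted node structure (a different code path from buildCCD)
oracleCcdProbs <- function(sample, topologies) {
  taxa <- sample@taxa
  counts <- list()
  tally <- function(phy) {
    ## phy: rooted at taxon 1 (drop that tip, root the rest)
    nwk <- topologyToNewick(new("Topology", taxa = taxa,
                                splits = phy, id = "x"))
    tr <- ape::read.tree(text = nwk)
    tr <- ape::root(tr, outgroup = taxa[1], resolve.root = TRUE)
    tr <- ape::drop.tip(tr, taxa[1])
    pp <- ape::prop.part(tr)
    cladeSets <- lapply(pp, function(idx) sort(attr(pp, "labels")[idx]))
    nodeOf <- function(set) {
      key <- paste(set, collapse = ",")
      keys <- vapply(cladeSets, paste, "", collapse = ",")
      which(keys == key)
    }
    for (i in seq_along(cladeSets)) {
      set <- cladeSets[[i]]
      if (length(set) < 2) next
      node <- length(tr$tip.label) + i
      kids <- tr$edge[tr$edge[, 1] == node, 2]
      kidSets <- lapply(kids, function(kid) {
        if (kid <= length(tr$tip.label)) tr$tip.label[kid]
        else cladeSets[[kid - length(tr$tip.label)]]
      })
      key <- paste(set, collapse = ",")
      skey <- paste(sort(vapply(kidSets, function(s)
        paste(sort(s), collapse = ","), "")), collapse = "|")
      if (is.null(counts[[key]])) counts[[key]] <<- numeric(0)
      cur <- counts[[key]][skey]
      counts[[key]][skey] <<- (if (is.na(cur)) 0 else cur) + 1
    }
  }
  for (spl in sample@splits) tally(spl)
  freqs <- lapply(counts, function(x) x / sum(x))
  vapply(topologies, function(top) {
    tr <- ape::read.tree(text = topologyToNewick(top))
    tr <- ape::root(tr, outgroup = taxa[1], resolve.root = TRUE)
    tr <- ape::drop.tip(tr, taxa[1])
    pp <- ape::prop.part(tr)
    cladeSets <- lapply(pp, function(idx) sort(attr(pp, "labels")[idx]))
    p <- 1
    for (i in seq_along(cladeSets)) {
      set <- cladeSets[[i]]
      if (length(set) < 2) next
      node <- length(tr$tip.label) + i
      kids <- tr$edge[tr$edge[, 1] == node, 2]
      kidSets <- lapply(kids, function(kid) {
        if (kid <= length(tr$tip.label)) tr$tip.label[kid]
        else cladeSets[[kid - length(tr$tip.label)]]
      })
      key <- paste(set, collapse = ",")
      skey <- paste(sort(vapply(kidSets, function(s)
        paste(sort(s), collapse = ","), "")), collapse = "|")
      q <- freqs[[key]][skey]
      if (is.null(freqs[[key]]) || is.na(q)) return(0)
      p <- p * q
    }
    p
  }, 0)
}

## brute-force Mk likelihood: explicit sum over internal-node states
bruteMkLogLik <- function(cm, tree, rate = 1) {
  po <- stats::reorder(tree, "postorder")
  nTip <- length(po$tip.label)
  nNode <- max(po$edge)
  internal <- (nTip + 1):nNode
  total <- 0
  for (ch in seq_len(ncol(cm@codes))) {
    k <- cm@nStates[ch]
    grid <- expand.grid(rep(list(seq_len(k)), length(internal)))
    s <- 0
    tipState <- as.integer(cm@codes[match(po$tip.label, cm@taxa), ch]) + 1L
    for (g in seq_len(nrow(grid))) {
      st <- integer(nNode)
      st[seq_len(nTip)] <- tipState
      st[internal] <- as.integer(grid[g, ])
      p <- 1 / k
      for (e in seq_len(nrow(po$edge))) {
        t <- rate * po$edge.length[e]
        pSame <- 1 / k + (k - 1) / k * exp(-k * t / (k - 1))
        same <- st[po$edge[e, 1]] == st[po$edge[e, 2]]
        p <- p * if (same) pSame else (1 - pSame) / (k - 1)
      }
      s <- s + p
    }
    total <- total + log(s)
  }
  total
}

## tiny hand-written OBO text for parser tests
miniOboText <- function() {
  c("format-version: 1.2", "",
    "[Term]", "id: X:1", "name: root", "",
    "[Term]", "id: X:2", "name: mid", "is_a: X:1", "",
    "[Term]", "id: X:3", "name: leaf", "is_a: X:2",
    "relationship: part_of X:1", "",
    "[Term]", "id: X:4", "name: old", "is_obsolete: true", "is_a: X:1")
}

## equal-weight mixture of plugin distributions (independent of package
## internals)
mergeDistributionsForTest <- function(dists) {
  ids <- unique(unlist(lapply(dists, function(d) names(topologyProbs(d)))))
  acc <- stats::setNames(numeric(length(ids)), ids)
  for (d in dists) {
    p <- topologyProbs(d)
    acc[names(p)] <- acc[names(p)] + p
  }
  new("TopologyDistribution", taxa = dists[[1]]@taxa,
      probs = acc / length(dists), estimator = "plugin")
}
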