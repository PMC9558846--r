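## Tree input/output and canonical topology representation.
##
## All downstream statistics are over unrooted, branch-length-free
## topologies; this file owns the reduction from Newick/NEXUS trees to the
## canonical split-set encoding and back.

## ---- mask helpers (internal) ----

maskFromLogical <- function(v) paste(ifelse(v, "1", "0"), collapse = "")

logicalFromMask <- function(m) strsplit(m, "", fixed = TRUE)[[1]] == "1"

maskFromLabels <- function(labels, taxa) {
  idx <- match(labels, taxa)
  if (anyNA(idx)) stop("unknown taxon label(s): ",
                       paste(labels[is.na(idx)], collapse = ", "))
  v <- rep(FALSE, length(taxa))
  v[idx] <- TRUE
  maskFromLogical(v)
}

labelsFromMask <- function(mask, taxa) taxa[logicalFromMask(mask)]

## canonical split orientation: the side containing the first canonical taxon
canonicalSplit <- function(v) {
  if (!v[1]) v <- !v
  maskFromLogical(v)
}

topologyIdFromSplits <- function(splits) paste(sort(splits), collapse = ";")

newTopology <- function(taxa, splits) {
  splits <- sort(splits)
  new("Topology", taxa = taxa, splits = splits,
      id = topologyIdFromSplits(splits))
}

## ---- phylo -> Topology ----

#' Reduce an ape phylo to a canonical Topology
#'
#' Branch lengths, internal labels and the root position are discarded;
#' rooted inputs are unrooted. By default only fully resolved topologies
#' (exactly n - 3 non-trivial splits) are accepted.
#'
#' @param phy an \code{ape::phylo}.
#' @param taxa optional canonical taxon set the tree must match.
#' @param polytomies "error" (default) or "accept".
#' @return a \linkS4class{Topology}.
#' @export
topologyFromPhylo <- function(phy, taxa = NULL, polytomies = c("error", "accept")) {
  polytomies <- match.arg(polytomies)
  if (anyDuplicated(phy$tip.label)) stop("duplicate taxon labels in tree")
  if (is.null(taxa)) {
    taxa <- sort(phy$tip.label)
  } else if (!setequal(taxa, phy$tip.label)) {
    stop("tree labels do not match the expected taxon set")
  }
  n <- length(taxa)
  if (n < 3) stop("need at least 3 taxa")
  phy <- ape::unroot(phy)
  tipIdx <- match(phy$tip.label, taxa)
  parts <- ape::prop.part(phy)
  splits <- character(0)
  for (p in parts) {
    sz <- length(p)
    if (sz < 2 || sz > n - 2) next
    v <- rep(FALSE, n)
    v[tipIdx[p]] <- TRUE
    splits <- c(splits, canonicalSplit(v))
  }
  splits <- unique(splits)
  if (polytomies == "error" && length(splits) != n - 3)
    stop("topology is not fully resolved (", length(splits),
         " of ", n - 3, " splits); set polytomies = \"accept\" to allow")
  newTopology(taxa, splits)
}

#' Parse a Newick string into a canonical Topology
#'
#' @param text a single Newick string.
#' @inheritParams topologyFromPhylo
#' @return a \linkS4class{Topology}.
#' @examples
#' t1 <- parseNewick("((A,B),(C,D));")
#' topologySplits(t1)  # the single non-trivial split AB|CD
#' @export
parseNewick <- function(text, taxa = NULL, polytomies = c("error", "accept")) {
  phy <- ape::read.tree(text = text)
  if (is.null(phy)) stop("invalid Newick string")
  if (inherits(phy, "multiPhylo")) phy <- phy[[1]]
  topologyFromPhylo(phy, taxa, polytomies)
}

## ---- rooted clade decomposition (shared by CCD and the Newick writer) ----

## Root the split set at the first canonical taxon. Returns, for each
## non-singleton clade (mask over taxa, first-taxon bit 0), the masks of its
## child clades (2 for binary trees). The root clade is all taxa but the
## first.
rootedChildMap <- function(splits, n) {
  rootClade <- maskFromLogical(c(FALSE, rep(TRUE, n - 1)))
  clades <- character(0)
  for (s in splits) {
    v <- logicalFromMask(s)  # contains taxon 1; clade is the complement
    clades <- c(clades, maskFromLogical(!v))
  }
  clades <- unique(clades)
  clades <- clades[clades != rootClade]
  sizes <- vapply(clades, function(m) sum(logicalFromMask(m)), 0)
  ord <- order(sizes)
  clades <- clades[ord]
  ## singleton leaf clades for taxa 2..n
  avail <- vapply(2:n, function(i) {
    v <- rep(FALSE, n); v[i] <- TRUE; maskFromLogical(v)
  }, "")
  availMat <- vapply(avail, logicalFromMask, logical(n))
  colnames(availMat) <- avail
  children <- list()
  for (cl in c(clades, rootClade)) {
    cv <- logicalFromMask(cl)
    isSub <- apply(availMat, 2, function(x) all(!x | cv))
    children[[cl]] <- colnames(availMat)[isSub]
    availMat <- cbind(availMat[, !isSub, drop = FALSE], cv)
    colnames(availMat)[ncol(availMat)] <- cl
  }
  children
}

## ---- Topology -> Newick ----

#' Write a Topology as a Newick string
#'
#' The tree is written unrooted (basal trifurcation at the first canonical
#' taxon), without branch lengths.
#'
#' @param topology a \linkS4class{Topology}.
#' @return a Newick string.
#' @export
topologyToNewick <- function(topology) {
  taxa <- topology@taxa
  n <- length(taxa)
  if (length(topology@splits) == 0) {
    return(paste0("(", paste(taxa, collapse = ","), ");"))
  }
  children <- rootedChildMap(topology@splits, n)
  render <- function(mask) {
    v <- logicalFromMask(mask)
    if (sum(v) == 1) return(taxa[which(v)])
    kids <- children[[mask]]
    paste0("(", paste(vapply(kids, render, ""), collapse = ","), ")")
  }
  rootClade <- maskFromLogical(c(FALSE, rep(TRUE, n - 1)))
  kids <- children[[rootClade]]
  paste0("(", taxa[1], ",",
         paste(vapply(kids, render, ""), collapse = ","), ");")
}

#' @rdname topologyToNewick
#' @return \code{phyloFromTopology}: an \code{ape::phylo}.
#' @export
phyloFromTopology <- function(topology) {
  ape::read.tree(text = topologyToNewick(topology))
}

## ---- TreeSample construction and readers ----

treeSampleFromTopologies <- function(topologies, runId = "run1",
                                     subsetId = "all", burninFraction = 0) {
  taxa <- topologies[[1]]@taxa
  for (t in topologies) {
    if (!identical(t@taxa, taxa)) stop("mixed taxon sets in tree sample")
  }
  new("TreeSample", taxa = taxa,
      splits = unname(lapply(topologies, function(t) t@splits)),
      ids = unname(vapply(topologies, function(t) t@id, "")),
      runId = runId, subsetId = subsetId, burninFraction = burninFraction)
}

#' Build a TreeSample from a list of trees
#'
#' @param trees a list of \code{phylo} objects, a \code{multiPhylo}, or a
#'   list of \linkS4class{Topology} objects.
#' @param taxa optional canonical taxon set.
#' @param runId,subsetId provenance labels.
#' @param burninFraction proportion of the sample flagged as burn-in.
#' @param polytomies passed to \code{\link{topologyFromPhylo}}.
#' @return a \linkS4class{TreeSample}.
#' @export
treeSample <- function(trees, taxa = NULL, runId = "run1", subsetId = "all",
                       burninFraction = 0, polytomies = "error") {
  if (inherits(trees, "multiPhylo")) {
    if (!is.null(attr(trees, "TipLabel")))
      trees <- ape::.uncompressTipLabel(trees)
    trees <- unclass(trees)
  }
  if (length(trees) == 0) stop("empty tree list")
  if (is(trees[[1]], "Topology")) {
    tops <- trees
  } else {
    if (is.null(taxa)) taxa <- sort(trees[[1]]$tip.label)
    tops <- lapply(trees, topologyFromPhylo, taxa = taxa,
                   polytomies = polytomies)
  }
  treeSampleFromTopologies(tops, runId, subsetId, burninFraction)
}

#' Read a MrBayes-style NEXUS tree file
#'
#' Applies the translate table, drops the first \code{ceiling(burnin * N)}
#' trees, and reduces the rest to canonical topologies in sample order.
#'
#' @param file path to a NEXUS trees file (MrBayes .t dialect).
#' @param burnin fraction of initial samples to discard (default 0.25).
#' @param runId,subsetId provenance labels.
#' @param polytomies passed to \code{\link{topologyFromPhylo}}.
#' @return a \linkS4class{TreeSample} (burn-in already removed).
#' @export
readMrBayesTrees <- function(file, burnin = 0.25, runId = "run1",
                             subsetId = "all", polytomies = "error") {
  trees <- ape::read.nexus(file)
  if (inherits(trees, "phylo")) trees <- list(trees)
  nAll <- length(trees)
  drop <- ceiling(burnin * nAll)
  if (drop >= nAll) stop("no trees left after burn-in")
  trees <- trees[(drop + 1):nAll]
  treeSample(trees, runId = runId, subsetId = subsetId, burninFraction = 0,
             polytomies = polytomies)
}

#' Read a plain one-tree-per-line Newick file
#'
#' @inheritParams readMrBayesTrees
#' @return a \linkS4class{TreeSample}.
#' @export
readNewickTrees <- function(file, burnin = 0, runId = "run1", subsetId = "all",
                            polytomies = "error") {
  trees <- ape::read.tree(file)
  if (inherits(trees, "phylo")) trees <- list(trees)
  nAll <- length(trees)
  drop <- ceiling(burnin * nAll)
  if (drop >= nAll) stop("no trees left after burn-in")
  treeSample(trees[(drop + 1):nAll], runId = runId, subsetId = subsetId)
}

#' Write a TreeSample as a MrBayes-compatible NEXUS tree file
#'
#' @param sample a \linkS4class{TreeSample}.
#' @param file output path.
#' @export
writeMrBayesTrees <- function(sample, file) {
  taxa <- sample@taxa
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("#NEXUS", con)
  writeLines("begin trees;", con)
  writeLines("   translate", con)
  tr <- paste0("      ", seq_along(taxa), " ", taxa,
               ifelse(seq_along(taxa) < length(taxa), ",", ";"))
  writeLines(tr, con)
  for (i in seq_along(sample@ids)) {
    top <- new("Topology", taxa = taxa, splits = sample@splits[[i]],
               id = sample@ids[i])
    nwk <- topologyToNewick(top)
    for (j in seq_along(taxa)) {
      nwk <- gsub(paste0("(?<=[(,])", taxa[j], "(?=[,)])"), as.character(j),
                  nwk, perl = TRUE)
    }
    writeLines(sprintf("   tree gen.%d = [&U] %s", i, nwk), con)
  }
  writeLines("end;", con)
  invisible(file)
}

#' Remove flagged burn-in from a TreeSample
#'
#' @param sample a \linkS4class{TreeSample}.
#' @return a \linkS4class{TreeSample} with the first
#'   \code{ceiling(burninFraction * N)} trees removed and
#'   \code{burninFraction} reset to 0.
#' @export
dropBurnin <- function(sample) {
  b <- sample@burninFraction
  if (b == 0) return(sample)
  nAll <- length(sample@ids)
  drop <- ceiling(b * nAll)
  if (drop >= nAll) stop("no trees left after burn-in")
  keep <- (drop + 1):nAll
  new("TreeSample", taxa = sample@taxa, splits = sample@splits[keep],
      ids = sample@ids[keep], runId = sample@runId,
      subsetId = sample@subsetId, burninFraction = 0)
}

## ---- counting ----

#' Number of unrooted binary topologies
#'
#' \code{(2n - 5)!!}, the number of distinct fully resolved unrooted
#' labelled topologies on n taxa. Exact as a double for n <= 20 (the result
#' stays below 2^53); all analyses in scope use n around 10.
#'
#' @param n taxon count, >= 3.
#' @return a numeric count.
#' @examples
#' countTopologies(5)   # 15
#' countTopologies(10)  # 2027025
#' @export
countTopologies <- function(n) {
  if (n < 3) stop("n must be >= 3")
  if (n == 3) return(1)
  prod(seq(1, 2 * n - 5, by = 2))
}
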