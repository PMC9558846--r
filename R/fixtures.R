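## Synthetic-data generators: toy ontologies, Mk-simulated character
## matrices on known trees (including concerted-convergence scenarios where
## a block of anatomically related characters tracks an alternative tree),
## and posterior samples with known entropy. Everything is seeded and
## deterministic, so the whole pipeline is testable without downloads.

#' Enumerate all resolved unrooted topologies
#'
#' Recursive enumeration via the rooted decomposition at the first
#' canonical taxon; intended for small n (the count is (2n-5)!!).
#'
#' @param taxa taxon labels (3 to 8 of them).
#' @return list of \linkS4class{Topology} objects, one per topology.
#' @export
enumerateTopologies <- function(taxa) {
  taxa <- sort(taxa)
  n <- length(taxa)
  if (n < 3 || n > 8) stop("enumeration supported for 3 <= n <= 8")
  ## rooted trees on index set s: list of clade index-sets (each tree is the
  ## list of its non-singleton clades, including s itself)
  rooted <- function(s) {
    if (length(s) == 1) return(list(list()))
    out <- list()
    others <- s[-1]
    for (asz in seq_len(length(s) - 1)) {
      combs <- if (asz == 1) list(integer(0))
               else utils::combn(others, asz - 1, simplify = FALSE)
      for (aRest in combs) {
        a <- c(s[1], aRest)
        b <- setdiff(s, a)
        for (ta in rooted(a)) for (tb in rooted(b)) {
          out[[length(out) + 1]] <- c(list(s), ta, tb)
        }
      }
    }
    out
  }
  lapply(rooted(2:n), function(clades) {
    ## non-trivial unrooted splits: clades of size 2..n-2 (excluding the
    ## root clade), complemented onto the side containing taxon 1
    splits <- character(0)
    for (cl in clades) {
      if (length(cl) < 2 || length(cl) > n - 2) next
      v <- rep(TRUE, n)
      v[cl] <- FALSE
      splits <- c(splits, maskFromLogical(v))
    }
    newTopology(taxa, splits)
  })
}

#' Synthetic posterior sample with known distribution
#'
#' I.i.d. draws from an explicit distribution over topologies, rendered as
#' a \linkS4class{TreeSample}; the generating entropy is known in closed
#' form, which makes this the estimator-calibration fixture.
#'
#' @param topologies list of \linkS4class{Topology} objects.
#' @param probs matching probabilities (must sum to 1).
#' @param nDraws sample size.
#' @param seed integer seed.
#' @param runId,subsetId provenance labels.
#' @return a \linkS4class{TreeSample}.
#' @export
makeSyntheticPosterior <- function(topologies, probs, nDraws, seed = 1,
                                   runId = "run1", subsetId = "synthetic") {
  if (abs(sum(probs) - 1) > 1e-9) stop("probs must sum to 1")
  if (length(probs) != length(topologies)) stop("length mismatch")
  set.seed(seed)
  idx <- sample.int(length(probs), nDraws, replace = TRUE, prob = probs)
  treeSampleFromTopologies(topologies[idx], runId = runId,
                           subsetId = subsetId)
}

#' Deterministic toy ontology with regular shape
#'
#' A rooted tree-shaped ontology of given depth and branching factor:
#' 1 + b + b^2 + ... + b^depth terms, every non-root term linked to its
#' parent by \code{part_of} (and, optionally, a proportion of extra
#' \code{is_a} edges to the root to mix relation types).
#'
#' @param depth tree depth below the root.
#' @param branching children per term.
#' @param relation relation type for the tree edges (default "part_of").
#' @param file optional path: also write the ontology as OBO.
#' @return a \linkS4class{TermGraph}.
#' @export
makeToyOntology <- function(depth = 2, branching = 3, relation = "part_of",
                            file = NULL) {
  if (depth < 1 || branching < 1) stop("invalid shape parameters")
  ids <- "TOY:0000001"
  nms <- "whole organism"
  ech <- character(0); epa <- character(0)
  level <- ids
  counter <- 1
  for (d in seq_len(depth)) {
    nxt <- character(0)
    for (p in level) {
      for (b in seq_len(branching)) {
        counter <- counter + 1
        id <- sprintf("TOY:%07d", counter)
        ids <- c(ids, id)
        nms <- c(nms, sprintf("part %d.%d of %s", d, b, p))
        ech <- c(ech, id); epa <- c(epa, p)
        nxt <- c(nxt, id)
      }
    }
    level <- nxt
  }
  g <- new("TermGraph",
           terms = data.frame(id = ids, name = nms, obsolete = FALSE,
                              stringsAsFactors = FALSE),
           edges = data.frame(child = ech, parent = epa,
                              relation = relation, stringsAsFactors = FALSE))
  if (!is.null(file)) writeOBO(g, file)
  g
}

## hand-built fish-flavoured toy anatomy used by the fixture study
fishToyOntology <- function() {
  spec <- list(
    c("FISH:0000001", "organism", NA, NA),
    c("FISH:0000002", "skeleton", "FISH:0000001", "part_of"),
    c("FISH:0000010", "dermatocranium", "FISH:0000002", "part_of"),
    c("FISH:0000011", "premaxilla", "FISH:0000010", "part_of"),
    c("FISH:0000012", "maxilla", "FISH:0000010", "part_of"),
    c("FISH:0000013", "dentary", "FISH:0000010", "part_of"),
    c("FISH:0000014", "infraorbital", "FISH:0000010", "part_of"),
    c("FISH:0000020", "paired fin", "FISH:0000001", "part_of"),
    c("FISH:0000021", "pectoral fin", "FISH:0000020", "is_a"),
    c("FISH:0000022", "pelvic fin", "FISH:0000020", "is_a"),
    c("FISH:0000023", "dorsal fin", "FISH:0000020", "is_a")
  )
  terms <- data.frame(id = vapply(spec, `[`, "", 1),
                      name = vapply(spec, `[`, "", 2),
                      obsolete = FALSE, stringsAsFactors = FALSE)
  hasEdge <- !is.na(vapply(spec, `[`, "", 3))
  edges <- data.frame(child = terms$id[hasEdge],
                      parent = vapply(spec[hasEdge], `[`, "", 3),
                      relation = vapply(spec[hasEdge], `[`, "", 4),
                      stringsAsFactors = FALSE)
  new("TermGraph", terms = terms, edges = edges)
}

## random resolved topology on taxa with exponential branch lengths
randomTreeWithLengths <- function(taxa, blMean = 0.1) {
  phy <- ape::unroot(ape::rtree(length(taxa), tip.label = sample(taxa)))
  phy$edge.length <- stats::rexp(nrow(phy$edge), rate = 1 / blMean)
  phy
}

#' Generate a complete synthetic study (convergence scenario)
#'
#' Builds a toy fish anatomy ontology, a species tree, and an alternative
#' ("convergence") tree sharing no non-trivial splits with it, then
#' simulates per-term character blocks under Mk+Gamma: jaw terms
#' (premaxilla, maxilla, dentary, infraorbital) on the species tree, fin
#' terms (pectoral, pelvic, dorsal fin) jointly on the alternative tree —
#' the concerted-convergence scenario in which anatomically related
#' characters agree with each other but not with the species phylogeny.
#' Optional noise characters evolve on independent random trees.
#'
#' @param nTaxa number of taxa (default 8).
#' @param charsPerTerm characters per term block (default 20).
#' @param noiseChars characters simulated on independent random trees
#'   (annotated to the root term; default 0).
#' @param blMean mean branch length of the generating trees (default 0.1).
#' @param seed integer seed; output is fully determined by it.
#' @param outDir optional directory: write matrix.nex, annotations.tsv,
#'   ontology.obo, species_tree.nwk, alternative_tree.nwk, manifest.json.
#' @return list: matrix (\linkS4class{CharacterMatrix}), annotations
#'   (data.frame), ontology (\linkS4class{TermGraph}), speciesTree and
#'   alternativeTree (\code{phylo}), manifest (list recording which terms
#'   were generated on which tree).
#' @export
makeFixtureStudy <- function(nTaxa = 8, charsPerTerm = 20, noiseChars = 0,
                             blMean = 0.1, seed = 1, outDir = NULL) {
  set.seed(seed)
  taxa <- sort(sprintf("sp%02d", seq_len(nTaxa)))
  species <- randomTreeWithLengths(taxa, blMean)
  spId <- topologyFromPhylo(species)@id
  spSplits <- topologyFromPhylo(species)@splits
  ## alternative tree sharing no non-trivial splits with the species tree
  alt <- NULL
  for (i in 1:200) {
    cand <- randomTreeWithLengths(taxa, blMean)
    cs <- topologyFromPhylo(cand)@splits
    if (!length(intersect(cs, spSplits))) { alt <- cand; break }
  }
  if (is.null(alt)) stop("could not draw a disjoint alternative topology")
  ontology <- fishToyOntology()
  jawTerms <- c("FISH:0000011", "FISH:0000012", "FISH:0000013", "FISH:0000014")
  finTerms <- c("FISH:0000021", "FISH:0000022", "FISH:0000023")
  blocks <- list(); annChar <- integer(0); annTerm <- character(0)
  addBlock <- function(term, tree) {
    cmB <- simulateCharacters(tree, charsPerTerm, nStates = 2, alpha = 1,
                              model = mkModel(coding = "variable"))
    start <- sum(vapply(blocks, function(b) ncol(b@codes), 0L))
    blocks[[length(blocks) + 1]] <<- cmB
    annChar <<- c(annChar, start + seq_len(charsPerTerm))
    annTerm <<- c(annTerm, rep(term, charsPerTerm))
  }
  for (tm in jawTerms) addBlock(tm, species)
  for (tm in finTerms) addBlock(tm, alt)
  if (noiseChars > 0) {
    for (i in seq_len(noiseChars)) {
      addBlockTree <- randomTreeWithLengths(taxa, blMean)
      cmB <- simulateCharacters(addBlockTree, 1, nStates = 2, alpha = 1,
                                model = mkModel(coding = "variable"))
      start <- sum(vapply(blocks, function(b) ncol(b@codes), 0L))
      blocks[[length(blocks) + 1]] <- cmB
      annChar <- c(annChar, start + 1L)
      annTerm <- c(annTerm, "FISH:0000001")
    }
  }
  codes <- do.call(cbind, lapply(blocks, function(b) b@codes))
  cm <- characterMatrix(codes, taxa = taxa,
                        nStates = unlist(lapply(blocks, function(b) b@nStates)))
  annotations <- data.frame(
    character = annChar, term = annTerm,
    label = ontology@terms$name[match(annTerm, ontology@terms$id)],
    stringsAsFactors = FALSE)
  manifest <- list(
    seed = seed, nTaxa = nTaxa, charsPerTerm = charsPerTerm,
    noiseChars = noiseChars, blMean = blMean,
    speciesTreeId = spId, alternativeTreeId = topologyFromPhylo(alt)@id,
    termTree = c(stats::setNames(rep("species", length(jawTerms)), jawTerms),
                 stats::setNames(rep("alternative", length(finTerms)), finTerms)))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeNexusMatrix(cm, file.path(outDir, "matrix.nex"))
    utils::write.table(
      data.frame(character_index = annotations$character - 1L,
                 term_id = annotations$term, term_label = annotations$label),
      file.path(outDir, "annotations.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    writeOBO(ontology, file.path(outDir, "ontology.obo"))
    ape::write.tree(species, file.path(outDir, "species_tree.nwk"))
    ape::write.tree(alt, file.path(outDir, "alternative_tree.nwk"))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(matrix = cm, annotations = annotations, ontology = ontology,
       speciesTree = species, alternativeTree = alt, manifest = manifest)
}
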