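## Ontology parsing, semantic similarity and term dendrograms.
##
## Closures are taken over a configurable relation set; the default
## {is_a, part_of} treats subsumption and parthood jointly, and restricting
## to one of them supports subsumption-only / parthood-only analyses.

DEFAULT_RELATIONS <- c("is_a", "part_of")

#' Read an OBO flat file
#'
#' Parses [Term] stanzas of an OBO 1.2/1.4 file: term ids and names,
#' \code{is_a} edges, typed \code{relationship:} edges, and obsolete flags.
#'
#' @param file path to an OBO file.
#' @param dangling "drop" (default; warn and drop edges to unknown terms) or
#'   "error".
#' @return a \linkS4class{TermGraph}.
#' @export
readOBO <- function(file, dangling = c("drop", "error")) {
  dangling <- match.arg(dangling)
  lines <- readLines(file, warn = FALSE)
  ids <- character(0); nms <- character(0); obs <- logical(0)
  ech <- character(0); epa <- character(0); erel <- character(0)
  cur <- NULL; inTerm <- FALSE
  flush <- function() {
    if (!is.null(cur) && nzchar(cur$id)) {
      ids <<- c(ids, cur$id); nms <<- c(nms, cur$name); obs <<- c(obs, cur$obs)
      if (length(cur$parents)) {
        ech <<- c(ech, rep(cur$id, length(cur$parents)))
        epa <<- c(epa, cur$parents); erel <<- c(erel, cur$rels)
      }
    }
  }
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)  # strip comments
    ln <- trimws(ln)
    if (ln == "[Term]") { flush(); cur <- list(id = "", name = "", obs = FALSE,
                                               parents = character(0),
                                               rels = character(0))
                          inTerm <- TRUE; next }
    if (grepl("^\\[", ln)) { flush(); cur <- NULL; inTerm <- FALSE; next }
    if (!inTerm || !nzchar(ln)) next
    if (grepl("^id:", ln)) cur$id <- trimws(sub("^id:", "", ln))
    else if (grepl("^name:", ln)) cur$name <- trimws(sub("^name:", "", ln))
    else if (grepl("^is_obsolete:", ln))
      cur$obs <- grepl("true", ln, fixed = TRUE)
    else if (grepl("^is_a:", ln)) {
      cur$parents <- c(cur$parents, trimws(sub("^is_a:", "", ln)))
      cur$rels <- c(cur$rels, "is_a")
    } else if (grepl("^relationship:", ln)) {
      parts <- strsplit(trimws(sub("^relationship:", "", ln)), "[[:space:]]+")[[1]]
      if (length(parts) < 2) stop("malformed relationship line: ", ln)
      cur$parents <- c(cur$parents, parts[2])
      cur$rels <- c(cur$rels, parts[1])
    }
  }
  flush()
  if (anyDuplicated(ids)) stop("duplicate term ids in OBO file")
  known <- epa %in% ids
  if (!all(known)) {
    msg <- paste("dangling edge target(s):",
                 paste(unique(epa[!known]), collapse = ", "))
    if (dangling == "error") stop(msg)
    warning(msg, "; dropped")
    ech <- ech[known]; epa <- epa[known]; erel <- erel[known]
  }
  new("TermGraph",
      terms = data.frame(id = ids, name = nms, obsolete = obs,
                         stringsAsFactors = FALSE),
      edges = data.frame(child = ech, parent = epa, relation = erel,
                         stringsAsFactors = FALSE))
}

#' Write a TermGraph as an OBO flat file
#'
#' @param graph a \linkS4class{TermGraph}.
#' @param file output path.
#' @export
writeOBO <- function(graph, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (i in seq_len(nrow(graph@terms))) {
    id <- graph@terms$id[i]
    writeLines(c("", "[Term]", paste0("id: ", id),
                 paste0("name: ", graph@terms$name[i])), con)
    if (graph@terms$obsolete[i]) writeLines("is_obsolete: true", con)
    e <- graph@edges[graph@edges$child == id, , drop = FALSE]
    for (j in seq_len(nrow(e))) {
      if (e$relation[j] == "is_a")
        writeLines(paste0("is_a: ", e$parent[j]), con)
      else
        writeLines(paste0("relationship: ", e$relation[j], " ", e$parent[j]), con)
    }
  }
  invisible(file)
}

checkTerm <- function(graph, term) {
  if (!term %in% graph@terms$id) stop("unknown term: ", term)
}

## edges restricted to the chosen relations and non-obsolete endpoints
activeEdges <- function(graph, relations) {
  e <- graph@edges[graph@edges$relation %in% relations, , drop = FALSE]
  obsolete <- graph@terms$id[graph@terms$obsolete]
  e[!(e$child %in% obsolete) & !(e$parent %in% obsolete), , drop = FALSE]
}

#' Ancestor closure of a term
#'
#' Reflexive transitive closure over the chosen relation types; obsolete
#' terms are excluded.
#'
#' @param graph a \linkS4class{TermGraph}.
#' @param term a term id.
#' @param relations relation types to traverse (default is_a + part_of).
#' @return character vector of term ids, including \code{term}.
#' @export
termAncestors <- function(graph, term, relations = DEFAULT_RELATIONS) {
  checkTerm(graph, term)
  e <- activeEdges(graph, relations)
  seen <- term
  frontier <- term
  while (length(frontier)) {
    nxt <- unique(e$parent[e$child %in% frontier])
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Terms subsumed by a query term
#'
#' All terms whose relation closure contains the query (i.e. the query
#' itself plus its descendants under the chosen relations).
#'
#' @inheritParams termAncestors
#' @param term the query term id.
#' @return character vector of term ids.
#' @export
termsUnder <- function(graph, term, relations = DEFAULT_RELATIONS) {
  checkTerm(graph, term)
  e <- activeEdges(graph, relations)
  seen <- term
  frontier <- term
  while (length(frontier)) {
    nxt <- unique(e$child[e$parent %in% frontier])
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Jaccard semantic similarity
#'
#' Overlap of reflexive ancestor closures:
#' |anc(t1) intersect anc(t2)| / |anc(t1) union anc(t2)|.
#'
#' @inheritParams termAncestors
#' @param t1,t2 term ids.
#' @return similarity in [0, 1].
#' @export
jaccardSimilarity <- function(graph, t1, t2, relations = DEFAULT_RELATIONS) {
  a1 <- termAncestors(graph, t1, relations)
  a2 <- termAncestors(graph, t2, relations)
  length(intersect(a1, a2)) / length(union(a1, a2))
}

## characters annotated to a term or any of its descendants
annotationCount <- function(graph, annotations, term, relations) {
  under <- termsUnder(graph, term, relations)
  length(unique(annotations$character[annotations$term %in% under]))
}

#' Resnik semantic similarity
#'
#' Information content of the most informative common ancestor (MICA), with
#' IC(a) = -ln(n_a / N): n_a the number of characters annotated to a or any
#' descendant, N the total number of annotated characters. The annotation
#' table itself is the IC corpus, keeping the measure self-contained.
#'
#' @inheritParams jaccardSimilarity
#' @param annotations an annotation table (see \code{\link{readAnnotations}}).
#' @return similarity >= 0 (0, with a warning, if no common ancestor).
#' @export
resnikSimilarity <- function(graph, annotations, t1, t2,
                             relations = DEFAULT_RELATIONS) {
  common <- intersect(termAncestors(graph, t1, relations),
                      termAncestors(graph, t2, relations))
  if (!length(common)) {
    warning("no common ancestor for ", t1, " and ", t2)
    return(0)
  }
  N <- length(unique(annotations$character))
  ic <- vapply(common, function(a) {
    na <- annotationCount(graph, annotations, a, relations)
    if (na == 0) 0 else -log(na / N)
  }, 0)
  max(ic)
}

#' Pairwise semantic similarity and distance matrices
#'
#' Distances are d = 1 - s / s_max with s_max = 1 for Jaccard and the
#' maximum observed IC for Resnik.
#'
#' @inheritParams resnikSimilarity
#' @param terms character vector of >= 2 term ids.
#' @param metric "jaccard" (default) or "resnik".
#' @return \code{similarityMatrix}: symmetric similarity matrix;
#'   \code{semanticDistanceMatrix}: the corresponding distance matrix with
#'   zero diagonal.
#' @export
similarityMatrix <- function(graph, terms, metric = c("jaccard", "resnik"),
                             relations = DEFAULT_RELATIONS,
                             annotations = NULL) {
  metric <- match.arg(metric)
  if (length(terms) < 2) stop("need at least 2 terms")
  if (metric == "resnik" && is.null(annotations))
    stop("resnik similarity needs an annotation corpus")
  k <- length(terms)
  s <- matrix(0, k, k, dimnames = list(terms, terms))
  for (i in seq_len(k)) for (j in i:k) {
    v <- if (metric == "jaccard")
      jaccardSimilarity(graph, terms[i], terms[j], relations)
    else
      resnikSimilarity(graph, annotations, terms[i], terms[j], relations)
    s[i, j] <- v; s[j, i] <- v
  }
  s
}

#' @rdname similarityMatrix
#' @export
semanticDistanceMatrix <- function(graph, terms,
                                   metric = c("jaccard", "resnik"),
                                   relations = DEFAULT_RELATIONS,
                                   annotations = NULL) {
  metric <- match.arg(metric)
  s <- similarityMatrix(graph, terms, metric, relations, annotations)
  smax <- if (metric == "jaccard") 1 else max(s)
  if (smax <= 0) smax <- 1
  d <- 1 - s / smax
  diag(d) <- 0
  d
}

#' Agglomerative clustering of a distance matrix
#'
#' Average linkage (UPGMA) by default. Labels are sorted before clustering
#' so that tie-breaking is deterministic and invariant to input order.
#'
#' @param distances square symmetric distance matrix with zero diagonal and
#'   row/column names.
#' @param linkage an \code{stats::hclust} method (default "average").
#' @return an \code{hclust} object.
#' @export
clusterDendrogram <- function(distances, linkage = "average") {
  if (any(is.na(distances))) stop("NaN/NA distances")
  if (!isSymmetric(unname(distances))) stop("distance matrix must be symmetric")
  ord <- order(rownames(distances))
  distances <- distances[ord, ord, drop = FALSE]
  stats::hclust(stats::as.dist(distances), method = linkage)
}

#' Dissonance dendrogram over data subsets
#'
#' Clusters subsets by their pairwise phylogenetic dissonance (percent),
#' i.e. by the congruence of their posterior topology distributions rather
#' than by ontology structure.
#'
#' @param samples named list of \linkS4class{TreeSample} or
#'   \linkS4class{TopologyDistribution} objects (one per subset).
#' @inheritParams dissonance
#' @param linkage clustering linkage (default "average").
#' @return list with \code{dendrogram} (hclust) and \code{distances} (the
#'   pairwise dissonance-percent matrix).
#' @export
dissonanceDendrogram <- function(samples,
                                 denominator = c("merged", "mean", "logk"),
                                 estimator = c("ccd", "plugin"),
                                 linkage = "average") {
  denominator <- match.arg(denominator)
  estimator <- match.arg(estimator)
  if (length(samples) < 2) stop("need at least 2 subsets")
  labs <- names(samples)
  if (is.null(labs) || any(!nzchar(labs))) stop("samples must be named")
  k <- length(samples)
  d <- matrix(0, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    dr <- dissonance(samples[c(i, j)], denominator = denominator,
                     estimator = estimator)
    d[i, j] <- dr@dissonancePct; d[j, i] <- dr@dissonancePct
  }
  list(dendrogram = clusterDendrogram(d, linkage), distances = d)
}

#' Export a dendrogram as Newick with node heights
#'
#' @param dendro an \code{hclust} object.
#' @return a Newick string.
#' @export
dendrogramToNewick <- function(dendro) {
  ape::write.tree(ape::as.phylo(dendro))
}

#' Read a character-to-term annotation table
#'
#' Expects a TSV with columns \code{character_index} (0-based column index
#' into the character matrix, following the convention of annotation
#' exports), \code{term_id}, and optionally \code{term_label}. Returned
#' with 1-based \code{character} indices for use in R.
#'
#' @param file path to a TSV file.
#' @param graph optional \linkS4class{TermGraph} to validate term ids against.
#' @param nChars optional matrix width to validate indices against.
#' @return data.frame with columns \code{character} (1-based) and
#'   \code{term} (plus \code{label} if present).
#' @export
readAnnotations <- function(file, graph = NULL, nChars = NULL) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("character_index", "term_id") %in% names(tab)))
    stop("annotation TSV needs character_index and term_id columns")
  out <- data.frame(character = tab$character_index + 1L,
                    term = tab$term_id, stringsAsFactors = FALSE)
  if ("term_label" %in% names(tab)) out$label <- tab$term_label
  if (!is.null(graph) && !all(out$term %in% graph@terms$id))
    stop("annotation term(s) missing from ontology: ",
         paste(setdiff(out$term, graph@terms$id), collapse = ", "))
  if (!is.null(nChars) && any(out$character < 1 | out$character > nChars))
    stop("character index out of matrix bounds")
  out
}
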