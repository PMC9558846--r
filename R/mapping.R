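## Study-level analyses: subset construction from annotations, Table-style
## information summaries, dendrogram-node information/dissonance maps,
## clade-support matrices against a reference tree, and resampling
## comparisons.

## A subset is a plain list: subsetId, label, chars (sorted unique 1-based
## character indices), mode ("ALL", "PROFILE", "RESAMPLED"), and optionally
## group (profile name).

makeSubset <- function(subsetId, label, chars, mode, group = NA_character_) {
  chars <- sort(unique(as.integer(chars)))
  if (!length(chars)) stop("empty subset: ", subsetId)
  list(subsetId = subsetId, label = label, chars = chars, mode = mode,
       group = group)
}

#' Build one data subset per annotated ontology term (ALL mode)
#'
#' One subset per term with at least \code{minChars} directly annotated
#' characters. With \code{propagate = TRUE}, characters annotated to
#' descendant terms (under \code{relations}) also count towards a term's
#' subset, so parent subsets contain their children's characters.
#'
#' @param annotations annotation table (see \code{\link{readAnnotations}}).
#' @param minChars minimum subset size (default 3; one- or two-character
#'   subsets carry near-prior posteriors and mostly add noise).
#' @param graph \linkS4class{TermGraph}, required when \code{propagate}.
#' @param propagate propagate annotations up the ontology (default FALSE).
#' @param relations relations used for propagation.
#' @return named list of subsets.
#' @export
buildSubsetsAll <- function(annotations, minChars = 3, graph = NULL,
                            propagate = FALSE,
                            relations = DEFAULT_RELATIONS) {
  terms <- unique(annotations$term)
  out <- list()
  for (tm in terms) {
    chars <- if (propagate) {
      if (is.null(graph)) stop("propagate = TRUE needs a TermGraph")
      under <- termsUnder(graph, tm, relations)
      unique(annotations$character[annotations$term %in% under])
    } else {
      unique(annotations$character[annotations$term == tm])
    }
    if (length(chars) >= minChars) {
      lab <- if ("label" %in% names(annotations)) {
        annotations$label[match(tm, annotations$term)]
      } else tm
      out[[tm]] <- makeSubset(tm, lab, chars, "ALL")
    }
  }
  if (!length(out)) stop("no term has >= minChars annotated characters")
  out
}

#' Build profile subsets from curated term groups
#'
#' One subset per listed term, tagged with its profile (group) name; the
#' grouping metadata drives the per-profile merged rows of
#' \code{\link{infoTable}}. Terms with no annotated characters are dropped
#' with a warning.
#'
#' @param annotations annotation table.
#' @param profile named list: profile name -> character vector of term ids.
#' @return named list of subsets.
#' @export
buildSubsetsProfile <- function(annotations, profile) {
  out <- list()
  for (grp in names(profile)) {
    for (tm in profile[[grp]]) {
      chars <- unique(annotations$character[annotations$term == tm])
      if (!length(chars)) {
        warning("profile term with no annotated characters dropped: ", tm)
        next
      }
      out[[tm]] <- makeSubset(tm, tm, chars, "PROFILE", group = grp)
    }
  }
  if (!length(out)) stop("no profile term has annotated characters")
  out
}

#' Randomly resampled subsets of fixed size
#'
#' Characters are drawn without replacement within each replicate and
#' independently (with replacement) across replicates.
#'
#' @param nChars width of the character matrix (or a
#'   \linkS4class{CharacterMatrix}).
#' @param size subset size.
#' @param reps number of replicates.
#' @param seed integer seed.
#' @param label prefix for subset ids.
#' @return named list of subsets with mode "RESAMPLED".
#' @export
resampleSubsets <- function(nChars, size, reps = 100, seed = 1,
                            label = "resample") {
  if (is(nChars, "CharacterMatrix")) nChars <- ncol(nChars@codes)
  if (size > nChars) stop("size exceeds matrix width")
  if (reps < 1) stop("reps must be >= 1")
  set.seed(seed)
  out <- list()
  for (r in seq_len(reps)) {
    id <- sprintf("%s_%03d", label, r)
    out[[id]] <- makeSubset(id, id, sample.int(nChars, size), "RESAMPLED")
  }
  out
}

## ---- Table-style information summaries ----

#' Per-subset and per-profile information table
#'
#' For each subset: per-run coverage and information percentages plus a
#' mean row whose dissonance column is the among-run dissonance (the
#' topology-convergence diagnostic). For each profile group (when subsets
#' carry a \code{group}): per-run rows with the information of the
#' equal-weight merged distribution across the group's subsets and the
#' among-subset dissonance within that run, plus their mean.
#'
#' @param samplesBySubset named list: subset id -> list of
#'   \linkS4class{TreeSample} runs (burn-in flags respected).
#' @param subsets optional named list of subsets (for group metadata).
#' @param denominator,estimator passed to \code{\link{dissonance}} /
#'   \code{\link{infoSummary}}.
#' @return data.frame with columns group, subset, run, coverage_pct,
#'   information_pct, dissonance_pct.
#' @export
infoTable <- function(samplesBySubset, subsets = NULL,
                      denominator = c("merged", "mean", "logk"),
                      estimator = c("ccd", "plugin")) {
  denominator <- match.arg(denominator)
  estimator <- match.arg(estimator)
  rows <- list()
  addRow <- function(group, subset, run, cov, info, diss) {
    rows[[length(rows) + 1]] <<- data.frame(
      group = group, subset = subset, run = run, coverage_pct = cov,
      information_pct = info, dissonance_pct = diss,
      stringsAsFactors = FALSE)
  }
  groupOf <- function(id) {
    if (!is.null(subsets) && !is.null(subsets[[id]])) subsets[[id]]$group
    else NA_character_
  }
  for (id in names(samplesBySubset)) {
    runs <- lapply(samplesBySubset[[id]], dropBurnin)
    sums <- lapply(runs, infoSummary, estimator = estimator)
    for (i in seq_along(sums)) {
      addRow(groupOf(id), id, paste0("run", i), 100 * sums[[i]]@coveragePhi,
             sums[[i]]@informationPct, NA_real_)
    }
    amongRun <- if (length(runs) >= 2) {
      dissonance(runs, denominator = denominator,
                 estimator = estimator)@dissonancePct
    } else NA_real_
    addRow(groupOf(id), id, "mean",
           mean(vapply(sums, function(s) 100 * s@coveragePhi, 0)),
           mean(vapply(sums, function(s) s@informationPct, 0)), amongRun)
  }
  ## per-profile merged rows
  groups <- unique(stats::na.omit(vapply(names(samplesBySubset), groupOf, "")))
  for (grp in groups) {
    ids <- names(samplesBySubset)[vapply(names(samplesBySubset),
                                         function(i) identical(groupOf(i), grp),
                                         FALSE)]
    if (length(ids) < 2) next
    nRuns <- min(vapply(samplesBySubset[ids], length, 0L))
    runRows <- list()
    for (r in seq_len(nRuns)) {
      perRun <- lapply(ids, function(i) dropBurnin(samplesBySubset[[i]][[r]]))
      merged <- mergeTreeSamples(perRun)
      msum <- infoSummary(merged, estimator = estimator)
      dss <- dissonance(perRun, denominator = denominator,
                        estimator = estimator)
      runRows[[r]] <- c(100 * msum@coveragePhi, msum@informationPct,
                        dss@dissonancePct)
      addRow(grp, paste0("profile:", grp), paste0("run", r),
             runRows[[r]][1], runRows[[r]][2], runRows[[r]][3])
    }
    m <- colMeans(do.call(rbind, runRows))
    addRow(grp, paste0("profile:", grp), "mean", m[1], m[2], m[3])
  }
  do.call(rbind, rows)
}

## ---- dendrogram node mapping ----

## leaves subtended by each internal node of an hclust
hclustLeafSets <- function(h) {
  nInt <- nrow(h$merge)
  sets <- vector("list", nInt)
  for (i in seq_len(nInt)) {
    kids <- h$merge[i, ]
    s <- character(0)
    for (kid in kids) {
      s <- c(s, if (kid < 0) h$labels[-kid] else sets[[kid]])
    }
    sets[[i]] <- s
  }
  sets
}

#' Information and dissonance mapped to dendrogram nodes
#'
#' For every internal node of a term dendrogram, the information of the
#' equal-weight merged posterior over the subtended subsets and the
#' among-subset dissonance, plus the same quantities relative to their
#' across-node means (relative values average 1 across usable nodes).
#'
#' @param dendro an \code{hclust} over subset ids.
#' @param samples named list: subset id -> \linkS4class{TreeSample} (or
#'   \linkS4class{TopologyDistribution}).
#' @param denominator,estimator passed to \code{\link{dissonance}}.
#' @return data.frame with one row per usable internal node: node index,
#'   height, nSubsets, information_pct, dissonance_pct, rel_information,
#'   rel_dissonance, subtended (comma-joined ids).
#' @export
nodeInfoMap <- function(dendro, samples,
                        denominator = c("merged", "mean", "logk"),
                        estimator = c("ccd", "plugin")) {
  denominator <- match.arg(denominator)
  estimator <- match.arg(estimator)
  sets <- hclustLeafSets(dendro)
  rows <- list()
  for (i in seq_along(sets)) {
    ids <- intersect(sets[[i]], names(samples))
    if (length(ids) < 2) {
      warning("dendrogram node ", i, " subtends < 2 subsets with samples; skipped")
      next
    }
    xs <- samples[ids]
    if (is(xs[[1]], "TreeSample")) {
      xs <- lapply(xs, dropBurnin)
      merged <- mergeTreeSamples(xs)
      msum <- infoSummary(merged, estimator = estimator)
      infoPct <- msum@informationPct
    } else {
      merged <- mergeDistributions(xs)
      h <- distributionEntropy(merged)
      infoPct <- phyloInformation(h, length(merged@taxa))$informationPct
    }
    dss <- dissonance(xs, denominator = denominator, estimator = estimator)
    rows[[length(rows) + 1]] <- data.frame(
      node = i, height = dendro$height[i], nSubsets = length(ids),
      information_pct = infoPct, dissonance_pct = dss@dissonancePct,
      subtended = paste(ids, collapse = ","), stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no dendrogram node subtends >= 2 subsets")
  tab <- do.call(rbind, rows)
  relOf <- function(v) if (mean(v) > 0) v / mean(v) else rep(NaN, length(v))
  tab$rel_information <- relOf(tab$information_pct)
  tab$rel_dissonance <- relOf(tab$dissonance_pct)
  tab[, c("node", "height", "nSubsets", "information_pct", "dissonance_pct",
          "rel_information", "rel_dissonance", "subtended")]
}

## ---- reference-tree clade support ----

#' Posterior support of reference-tree clades across subsets
#'
#' Cell (s, c) is the marginal posterior probability, under subset s's
#' distribution, of clade c of the reference topology; the supporting
#' proportion of a clade is the fraction of subsets whose support reaches
#' the threshold.
#'
#' @param samples named list: subset id -> \linkS4class{TreeSample} or
#'   \linkS4class{TopologyDistribution}.
#' @param reference a \linkS4class{Topology} on the same taxon set.
#' @param threshold posterior probability counting as support
#'   (default 0.95).
#' @return list with \code{matrix} (subsets x clades), \code{supporting}
#'   (per-clade proportion), \code{clades} (data.frame: label, mask,
#'   taxa), \code{threshold}.
#' @export
cladeSupportMatrix <- function(samples, reference, threshold = 0.95) {
  taxa <- reference@taxa
  masks <- reference@splits
  sizes <- vapply(masks, function(m) {
    v <- logicalFromMask(m)
    min(sum(v), sum(!v))
  }, 0)
  masks <- masks[order(sizes, masks)]
  labs <- paste0("N", seq_along(masks))
  m <- matrix(0, length(samples), length(masks),
              dimnames = list(names(samples), labs))
  for (i in seq_along(samples)) {
    x <- samples[[i]]
    if (is(x, "TreeSample")) x <- dropBurnin(x)
    if (!identical(taxonLabels(x), taxa)) stop("taxon set mismatch")
    for (j in seq_along(masks)) m[i, j] <- cladePosterior(x, masks[j])
  }
  clades <- data.frame(
    label = labs, mask = masks,
    taxa = vapply(masks, function(mk) {
      v <- logicalFromMask(mk)
      side <- if (sum(v) <= sum(!v)) v else !v
      paste(taxa[side], collapse = ",")
    }, ""), stringsAsFactors = FALSE, row.names = NULL)
  list(matrix = m, supporting = colMeans(m >= threshold),
       clades = clades, threshold = threshold)
}

## ---- relative information and resampling comparison ----

#' Relative information across subsets
#'
#' Each subset's information percentage divided by the mean across
#' subsets; the outputs average 1. All-zero inputs are undefined and
#' return NaN.
#'
#' @param infos numeric vector of information percentages, or a list of
#'   \linkS4class{InfoSummary} objects.
#' @return named numeric vector.
#' @export
relativeInformation <- function(infos) {
  if (is.list(infos))
    infos <- vapply(infos, function(s) s@informationPct,
                    0, USE.NAMES = TRUE)
  if (!length(infos)) stop("need at least one subset")
  m <- mean(infos)
  if (m == 0) {
    warning("all-zero information: relative values undefined")
    return(stats::setNames(rep(NaN, length(infos)), names(infos)))
  }
  infos / m
}

#' Compare ontology-based subsets against resampled subsets
#'
#' Frames each term's statistic relative to the median of its resampled
#' counterparts (values above 1 mean the ontology-based subset carries more
#' information, or more dissonance, than a typical random subset of the
#' same size).
#'
#' @param standardInfo named numeric: information percent per term
#'   (ontology-based subsets).
#' @param resampledInfo named list of numeric vectors: per-term information
#'   percentages of the resampled replicates.
#' @param standardDiss optional named numeric: pairwise dissonance percent
#'   of each term's subset against the reference term's subset.
#' @param resampledDiss optional named list of numeric vectors: resampled
#'   counterparts of \code{standardDiss}.
#' @return data.frame per term: standard value, resampled quartiles, and
#'   the standard-to-median ratio, for information (and dissonance when
#'   given).
#' @export
compareResampled <- function(standardInfo, resampledInfo,
                             standardDiss = NULL, resampledDiss = NULL) {
  terms <- names(standardInfo)
  if (!all(terms %in% names(resampledInfo)))
    stop("resampledInfo missing terms: ",
         paste(setdiff(terms, names(resampledInfo)), collapse = ", "))
  qs <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  out <- data.frame(term = terms, standard_info = unname(standardInfo),
                    stringsAsFactors = FALSE)
  qi <- t(vapply(resampledInfo[terms], qs, numeric(3)))
  out$resampled_info_q25 <- qi[, 1]
  out$resampled_info_median <- qi[, 2]
  out$resampled_info_q75 <- qi[, 3]
  out$rel_info <- ifelse(out$resampled_info_median > 0,
                         out$standard_info / out$resampled_info_median, NaN)
  if (!is.null(standardDiss)) {
    keep <- intersect(terms, names(standardDiss))
    out$standard_diss <- standardDiss[match(out$term, names(standardDiss))]
    qd <- t(vapply(resampledDiss[terms], function(v)
      if (is.null(v)) rep(NA_real_, 3) else qs(v), numeric(3)))
    out$resampled_diss_q25 <- qd[, 1]
    out$resampled_diss_median <- qd[, 2]
    out$resampled_diss_q75 <- qd[, 3]
    out$rel_diss <- ifelse(out$resampled_diss_median > 0,
                           out$standard_diss / out$resampled_diss_median, NaN)
  }
  out
}
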