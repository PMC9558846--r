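## Lightweight Bayesian MCMC over unrooted topologies under the Mk(v)+Gamma
## model, plus the matching simulation engine. This makes the pipeline
## runnable end to end without external phylogenetics software; importing
## externally generated tree samples (readMrBayesTrees) is equally
## supported and is the route for reproducing published MrBayes analyses.

## ---- character matrices ----

#' Construct a CharacterMatrix
#'
#' @param codes character matrix (taxa x characters) of state tokens:
#'   single symbols "0","1",..., "?" or "-" for missing, multi-symbol
#'   strings like "01" for polymorphic observations.
#' @param taxa taxon labels (defaults to rownames); stored sorted.
#' @param nStates per-character state-space size k; defaults to the number
#'   of symbols in each character's declared-by-observation alphabet (at
#'   least 2).
#' @return a \linkS4class{CharacterMatrix}.
#' @export
characterMatrix <- function(codes, taxa = rownames(codes), nStates = NULL) {
  if (is.null(taxa)) stop("taxa labels required")
  ord <- order(taxa)
  taxa <- taxa[ord]
  codes <- codes[ord, , drop = FALSE]
  rownames(codes) <- taxa
  if (is.null(nStates)) {
    nStates <- apply(codes, 2, function(col) {
      syms <- unique(unlist(strsplit(col[!col %in% c("?", "-")], "")))
      max(2L, if (length(syms)) max(as.integer(syms)) + 1L else 2L)
    })
  }
  new("CharacterMatrix", taxa = taxa, codes = codes,
      nStates = as.integer(nStates))
}

#' Subset the characters of a matrix
#'
#' @param cm a \linkS4class{CharacterMatrix}.
#' @param chars integer vector of character (column) indices.
#' @return a \linkS4class{CharacterMatrix}.
#' @export
subsetCharacters <- function(cm, chars) {
  if (any(chars < 1 | chars > ncol(cm@codes))) stop("character index out of bounds")
  new("CharacterMatrix", taxa = cm@taxa,
      codes = cm@codes[, chars, drop = FALSE],
      nStates = cm@nStates[chars])
}

#' Read a NEXUS data block into a CharacterMatrix
#'
#' Minimal parser for the standard-datatype NEXUS dialect: FORMAT line with
#' \code{symbols}/\code{missing}/\code{gap}, MATRIX block with one taxon per
#' line, polymorphisms as \code{(01)} or \code{\{01\}}.
#'
#' @param file path to a NEXUS file.
#' @return a \linkS4class{CharacterMatrix}.
#' @export
readNexusMatrix <- function(file) {
  lines <- readLines(file, warn = FALSE)
  txt <- tolower(paste(lines, collapse = "\n"))
  miss <- "?"; gap <- "-"
  fmt <- regmatches(txt, regexpr("format[^;]*;", txt))
  if (length(fmt)) {
    m <- regmatches(fmt, regexpr("missing\\s*=\\s*\\S", fmt))
    if (length(m)) miss <- substr(m, nchar(m), nchar(m))
    g <- regmatches(fmt, regexpr("gap\\s*=\\s*\\S", fmt))
    if (length(g)) gap <- substr(g, nchar(g), nchar(g))
  }
  i1 <- grep("^\\s*matrix\\s*$", tolower(lines))
  if (!length(i1)) stop("no MATRIX block found")
  i2 <- grep(";", lines)
  i2 <- min(i2[i2 > i1[1]])
  body <- trimws(lines[(i1[1] + 1):(i2 - 1)])
  body <- body[nzchar(body)]
  taxa <- character(0); rows <- list()
  for (ln in body) {
    ln <- sub(";\\s*$", "", ln)
    sp <- regmatches(ln, regexpr("^\\S+", ln))
    rest <- gsub("\\s", "", sub("^\\S+", "", ln))
    toks <- character(0)
    i <- 1
    while (i <= nchar(rest)) {
      ch <- substr(rest, i, i)
      if (ch %in% c("(", "{")) {
        close <- if (ch == "(") ")" else "}"
        j <- i
        while (substr(rest, j, j) != close) j <- j + 1
        toks <- c(toks, substr(rest, i + 1, j - 1))
        i <- j + 1
      } else {
        tok <- if (ch == miss) "?" else if (ch == gap) "-" else ch
        toks <- c(toks, tok)
        i <- i + 1
      }
    }
    taxa <- c(taxa, sp)
    rows[[sp]] <- toks
  }
  nc <- unique(vapply(rows, length, 0L))
  if (length(nc) != 1) stop("ragged MATRIX rows")
  codes <- do.call(rbind, rows)
  rownames(codes) <- taxa
  characterMatrix(codes)
}

#' Write a CharacterMatrix as a NEXUS file
#'
#' @param cm a \linkS4class{CharacterMatrix}.
#' @param file output path.
#' @export
writeNexusMatrix <- function(cm, file) {
  syms <- paste(0:(max(cm@nStates) - 1), collapse = "")
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("#NEXUS", "begin data;",
               sprintf("   dimensions ntax=%d nchar=%d;",
                       length(cm@taxa), ncol(cm@codes)),
               sprintf('   format datatype=standard symbols="%s" missing=? gap=-;',
                       syms),
               "   matrix"), con)
  wid <- max(nchar(cm@taxa)) + 2
  for (i in seq_along(cm@taxa)) {
    toks <- cm@codes[i, ]
    toks <- ifelse(nchar(toks) > 1, paste0("(", toks, ")"), toks)
    writeLines(sprintf("      %-*s%s", wid, cm@taxa[i],
                       paste(toks, collapse = "")), con)
  }
  writeLines(c("   ;", "end;"), con)
  invisible(file)
}

## ---- Mk likelihood ----

#' Discrete-gamma rate category means
#'
#' Mean of each of \code{ncat} equal-probability quantile bins of a
#' Gamma(shape, shape) distribution (mean 1), the standard mean-per-category
#' discretisation.
#'
#' @param alpha gamma shape (> 0).
#' @param ncat number of categories.
#' @return numeric vector of ncat rate multipliers averaging 1.
#' @export
discreteGammaMeans <- function(alpha, ncat) {
  if (alpha <= 0) stop("alpha must be positive")
  if (ncat == 1) return(1)
  qb <- stats::qgamma(seq(0, 1, length.out = ncat + 1), shape = alpha,
                      rate = alpha)
  p <- stats::pgamma(qb, shape = alpha + 1, rate = alpha)
  ncat * diff(p)
}

## Mk transition probability matrix for k states, rates scaled to one
## expected change per unit branch length: P(same) = 1/k + (k-1)/k e^(-k b t)
## with b = 1/(k-1).
mkPmatrix <- function(k, t) {
  e <- exp(-k * t / (k - 1))
  same <- 1 / k + (k - 1) / k * e
  diff <- 1 / k - 1 / k * e
  m <- matrix(diff, k, k)
  diag(m) <- same
  m
}

tipLikelihoods <- function(tokens, k) {
  ## k x length(tokens) matrix of state indicators
  out <- matrix(0, k, length(tokens))
  for (i in seq_along(tokens)) {
    tok <- tokens[i]
    if (tok %in% c("?", "-")) {
      out[, i] <- 1
    } else {
      states <- as.integer(strsplit(tok, "")[[1]]) + 1L
      if (any(states > k)) stop("state code exceeds declared alphabet")
      out[states, i] <- 1
    }
  }
  out
}

## pruning over one k-group given precomputed tip matrices (k x nChar,
## constant patterns appended when correcting); returns per-character
## likelihoods averaged over gamma categories
mkPruneGroup <- function(tipL, k, po, rates) {
  nTip <- length(po$tip.label)
  nNode <- max(po$edge)
  nChar <- ncol(tipL[[1]])
  lik <- numeric(nChar)
  for (r in seq_along(rates)) {
    L <- vector("list", nNode)
    for (i in seq_len(nTip)) L[[i]] <- tipL[[i]]
    for (e in seq_len(nrow(po$edge))) {
      parent <- po$edge[e, 1]; child <- po$edge[e, 2]
      P <- mkPmatrix(k, rates[r] * po$edge.length[e])
      contrib <- P %*% L[[child]]
      L[[parent]] <- if (is.null(L[[parent]])) contrib else L[[parent]] * contrib
    }
    root <- po$edge[nrow(po$edge), 1]
    lik <- lik + colSums(L[[root]]) / k
  }
  lik / length(rates)
}

#' Reusable Mk likelihood evaluator
#'
#' Precomputes the per-taxon tip conditional matrices once so repeated
#' evaluations (as in MCMC) only pay for the pruning pass. The returned
#' function takes \code{(tree, alpha)} and returns the log-likelihood under
#' the same contract as \code{\link{mkLogLikelihood}}.
#'
#' @inheritParams mkLogLikelihood
#' @return function(tree, alpha) -> log-likelihood.
#' @export
mkLikelihoodEvaluator <- function(cm, model = mkModel()) {
  if (ncol(cm@codes) == 0) return(function(tree, alpha = 1) 0)
  taxa <- cm@taxa
  ks <- sort(unique(cm@nStates))
  correct <- model@coding == "variable"
  groups <- lapply(ks, function(k) {
    sel <- which(cm@nStates == k)
    codes <- cm@codes[, sel, drop = FALSE]
    if (correct) {
      constCodes <- matrix(rep(as.character(0:(k - 1)), each = length(taxa)),
                           nrow = length(taxa))
      codes <- cbind(codes, constCodes)
    }
    tipL <- lapply(seq_along(taxa), function(i) tipLikelihoods(codes[i, ], k))
    names(tipL) <- taxa
    list(k = k, nChar = length(sel), tipL = tipL)
  })
  function(tree, alpha = 1) {
    if (is.null(tree$edge.length) || any(tree$edge.length < 0))
      stop("tree must have non-negative branch lengths")
    rates <- discreteGammaMeans(alpha, model@nRateCategories)
    po <- stats::reorder(tree, "postorder")
    tipIdx <- match(po$tip.label, taxa)
    if (anyNA(tipIdx)) stop("tree/matrix taxa mismatch")
    ll <- 0
    for (g in groups) {
      tipL <- g$tipL[po$tip.label]
      lik <- mkPruneGroup(tipL, g$k, po, rates)
      if (correct) {
        denom <- 1 - sum(lik[(g$nChar + 1):(g$nChar + g$k)])
        if (denom <= 0) stop("degenerate Mkv correction (tree length ~ 0)")
        lik <- lik[seq_len(g$nChar)] / denom
      }
      if (any(lik <= 0)) return(-Inf)
      ll <- ll + sum(log(lik))
    }
    ll
  }
}

#' Mk(v)+Gamma log-likelihood by Felsenstein pruning
#'
#' Likelihood of a discrete character matrix on a tree with branch lengths
#' under the symmetric k-state Markov model, with discrete-gamma rate
#' variation. Root placement is irrelevant (the model is reversible);
#' missing cells integrate over all states and polymorphic cells are
#' treated as partial ambiguity. With \code{coding = "variable"} each
#' character's likelihood is conditioned on being variable (Mkv
#' ascertainment correction).
#'
#' @param cm a \linkS4class{CharacterMatrix}.
#' @param tree an \code{ape::phylo} with positive \code{edge.length}, tips
#'   labelled by the matrix taxa.
#' @param alpha discrete-gamma shape.
#' @param model an \linkS4class{MkModel}.
#' @return total log-likelihood (0 for a matrix with no characters).
#' @export
mkLogLikelihood <- function(cm, tree, alpha = 1, model = mkModel()) {
  mkLikelihoodEvaluator(cm, model)(tree, alpha)
}

## ---- simulation ----

#' Simulate discrete characters under Mk+Gamma
#'
#' Characters evolve independently on the given tree under the symmetric
#' k-state model; per-character rates are drawn uniformly from the
#' discrete-gamma category means (matching the inference discretisation).
#'
#' @param tree an \code{ape::phylo} with branch lengths.
#' @param nChars number of characters.
#' @param nStates state-space size k (scalar or per-character vector).
#' @param alpha gamma shape; \code{Inf} for equal rates.
#' @param model an \linkS4class{MkModel} (rate categories; and
#'   \code{coding = "variable"} filters to variable characters when
#'   \code{variableOnly = NULL}).
#' @param variableOnly keep only variable characters (resimulating until
#'   \code{nChars} are collected); defaults to \code{model@coding ==
#'   "variable"}.
#' @return a \linkS4class{CharacterMatrix}.
#' @export
simulateCharacters <- function(tree, nChars, nStates = 2, alpha = Inf,
                               model = mkModel(), variableOnly = NULL) {
  if (is.null(variableOnly)) variableOnly <- model@coding == "variable"
  nStates <- rep_len(nStates, nChars)
  rates <- if (is.infinite(alpha)) 1
           else discreteGammaMeans(alpha, model@nRateCategories)
  po <- stats::reorder(tree, "postorder")
  nTip <- length(po$tip.label)
  ## preorder traversal: reverse postorder edge list
  edges <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE]
  lens <- rev(po$edge.length)
  root <- edges[1, 1]
  simOne <- function(k) {
    repeat {
      r <- rates[sample.int(length(rates), 1)]
      states <- integer(max(po$edge))
      states[root] <- sample.int(k, 1)
      for (e in seq_len(nrow(edges))) {
        t <- r * lens[e]
        pSame <- 1 / k + (k - 1) / k * exp(-k * t / (k - 1))
        par <- states[edges[e, 1]]
        if (stats::runif(1) < pSame) {
          states[edges[e, 2]] <- par
        } else {
          others <- setdiff(seq_len(k), par)
          states[edges[e, 2]] <- others[sample.int(k - 1, 1)]
        }
      }
      tipStates <- states[seq_len(nTip)]
      if (!variableOnly || length(unique(tipStates)) > 1)
        return(as.character(tipStates - 1L))
    }
  }
  codes <- vapply(seq_len(nChars), function(j) simOne(nStates[j]),
                  character(nTip))
  codes <- matrix(codes, nrow = nTip)
  rownames(codes) <- po$tip.label
  characterMatrix(codes, nStates = nStates)
}

## ---- MCMC ----

constraintSplits <- function(constraints, taxa) {
  vapply(constraints, function(cl) {
    canonicalSplit(logicalFromMask(maskFromLabels(cl, taxa)))
  }, "")
}

satisfiesConstraints <- function(splits, needed) {
  all(needed %in% splits)
}

randomStartTree <- function(taxa, blRate, needed, maxTries = 20000) {
  n <- length(taxa)
  for (i in seq_len(maxTries)) {
    phy <- ape::unroot(ape::rtree(n, tip.label = sample(taxa)))
    phy$edge.length <- stats::rexp(nrow(phy$edge), rate = blRate)
    spl <- topologyFromPhylo(phy)@splits
    if (satisfiesConstraints(spl, needed)) return(phy)
  }
  stop("could not find a starting topology satisfying the constraints")
}

## mean pairwise mismatch over comparable (single-state) cells
hammingDistances <- function(cm) {
  n <- length(cm@taxa)
  d <- matrix(0, n, n, dimnames = list(cm@taxa, cm@taxa))
  usable <- nchar(cm@codes) == 1 & cm@codes != "?" & cm@codes != "-"
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- usable[i, ] & usable[j, ]
    d[i, j] <- d[j, i] <- if (any(ok))
      mean(cm@codes[i, ok] != cm@codes[j, ok]) else 0
  }
  d
}

## neighbour-joining starting tree (random fallback for no-data chains or
## when the NJ topology violates the constraints)
startTree <- function(cm, blRate, needed) {
  if (ncol(cm@codes) > 0) {
    phy <- tryCatch({
      t0 <- ape::unroot(ape::multi2di(ape::nj(hammingDistances(cm))))
      t0$edge.length <- pmax(abs(t0$edge.length), 1e-4)
      t0
    }, error = function(e) NULL)
    if (!is.null(phy) &&
        satisfiesConstraints(topologyFromPhylo(phy)@splits, needed))
      return(phy)
  }
  randomStartTree(cm@taxa, blRate, needed)
}

#' Metropolis-Hastings MCMC under Mk(v)+Gamma
#'
#' Single-chain Metropolis-Hastings per run over (topology, branch lengths,
#' gamma shape), with a uniform topology prior, i.i.d. exponential branch
#' length priors and an exponential prior on the gamma shape. Move mix:
#' nearest-neighbour interchange on a random internal edge, branch-length
#' multiplier, and gamma-shape multiplier. Proposals violating monophyly
#' constraints are auto-rejected. With a zero-character matrix the chain
#' samples the prior (uniform over topologies).
#'
#' @param cm a \linkS4class{CharacterMatrix} (>= 4 taxa).
#' @param model an \linkS4class{MkModel}.
#' @param config an \linkS4class{McmcConfig}.
#' @param subsetId provenance label for the returned samples.
#' @return list of \linkS4class{TreeSample} objects, one per run, each with
#'   \code{burninFraction} set from the config (use \code{\link{dropBurnin}}
#'   or the downstream statistics, which drop it automatically) and an
#'   \code{acceptance} attribute with per-move acceptance rates.
#' @export
runMkMcmc <- function(cm, model = mkModel(), config = mcmcConfig(),
                      subsetId = "all") {
  taxa <- cm@taxa
  if (length(taxa) < 4) stop("need at least 4 taxa")
  needed <- constraintSplits(config@constraints, taxa)
  nSamples <- floor(config@nGenerations / config@sampleEvery)
  if (nSamples < 1) stop("nGenerations/sampleEvery must be >= 1")
  sampleAlpha <- model@nRateCategories > 1 && ncol(cm@codes) > 0
  loglik <- mkLikelihoodEvaluator(cm, model)
  runs <- vector("list", config@nRuns)
  for (run in seq_len(config@nRuns)) {
    set.seed(config@seed + 1000L * (run - 1L))
    phy <- startTree(cm, model@blRate, needed)
    alpha <- 1
    ll <- loglik(phy, alpha)
    lp <- sum(stats::dexp(phy$edge.length, model@blRate, log = TRUE)) +
      stats::dexp(alpha, model@shapeRate, log = TRUE)
    acc <- c(nni = 0, bl = 0, alpha = 0)
    tot <- c(nni = 0, bl = 0, alpha = 0)
    tops <- vector("list", nSamples)
    ids <- character(nSamples)
    kept <- 0
    curSplits <- topologyFromPhylo(phy)@splits
    for (gen in seq_len(config@nGenerations)) {
      u <- stats::runif(1)
      move <- if (u < 0.4) "nni" else if (u < 0.8 || !sampleAlpha) "bl" else "alpha"
      tot[move] <- tot[move] + 1
      if (move == "nni") {
        prop <- phangorn::rNNI(phy, moves = 1)
        propSplits <- topologyFromPhylo(prop)@splits
        if (!satisfiesConstraints(propSplits, needed)) {
          ## auto-reject: constraint violated
        } else {
          llP <- loglik(prop, alpha)
          if (log(stats::runif(1)) < llP - ll) {
            phy <- prop; ll <- llP; curSplits <- propSplits
            acc[move] <- acc[move] + 1
          }
        }
      } else if (move == "bl") {
        e <- sample.int(nrow(phy$edge), 1)
        fac <- exp(1.1 * (stats::runif(1) - 0.5))
        prop <- phy
        prop$edge.length[e] <- prop$edge.length[e] * fac
        llP <- loglik(prop, alpha)
        lpP <- lp +
          stats::dexp(prop$edge.length[e], model@blRate, log = TRUE) -
          stats::dexp(phy$edge.length[e], model@blRate, log = TRUE)
        if (log(stats::runif(1)) < (llP + lpP) - (ll + lp) + log(fac)) {
          phy <- prop; ll <- llP; lp <- lpP
          acc[move] <- acc[move] + 1
        }
      } else {
        fac <- exp(1.4 * (stats::runif(1) - 0.5))
        alphaP <- alpha * fac
        llP <- loglik(phy, alphaP)
        lpP <- lp + stats::dexp(alphaP, model@shapeRate, log = TRUE) -
          stats::dexp(alpha, model@shapeRate, log = TRUE)
        if (log(stats::runif(1)) < (llP + lpP) - (ll + lp) + log(fac)) {
          alpha <- alphaP; ll <- llP; lp <- lpP
          acc[move] <- acc[move] + 1
        }
      }
      if (gen %% config@sampleEvery == 0) {
        kept <- kept + 1
        tops[[kept]] <- curSplits
        ids[kept] <- topologyIdFromSplits(curSplits)
      }
    }
    ts <- new("TreeSample", taxa = taxa, splits = tops[seq_len(kept)],
              ids = ids[seq_len(kept)], runId = paste0("run", run),
              subsetId = subsetId, burninFraction = config@burninFraction)
    attr(ts, "acceptance") <- ifelse(tot > 0, acc / tot, NA)
    runs[[run]] <- ts
  }
  runs
}
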