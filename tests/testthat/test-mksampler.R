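test_that("two-taxon likelihood matches the k-state closed form", {
  tr <- ape::read.tree(text = "(A:0.15,B:0.15);")
  m1 <- mkModel(nRateCategories = 1L, coding = "all")
  cmSame <- characterMatrix(matrix(c("0", "0"), 2, 1,
                                   dimnames = list(c("A", "B"), NULL)))
  t <- 0.3
  expect_equal(mkLogLikelihood(cmSame, tr, model = m1),
               log(0.5 * (0.5 + 0.5 * exp(-2 * t))))
  cmDiff <- characterMatrix(matrix(c("0", "1"), 2, 1,
                                   dimnames = list(c("A", "B"), NULL)))
  expect_equal(mkLogLikelihood(cmDiff, tr, model = m1),
               log(0.5 * (0.5 - 0.5 * exp(-2 * t))))
})

test_that("saturation drives likelihoods to independent uniform draws", {
  tr <- ape::read.tree(text = "((A:50,B:50):50,(C:50,D:50):50);")
  m1 <- mkModel(nRateCategories = 1L, coding = "all")
  cm <- characterMatrix(matrix(c("0", "1", "0", "1"), 4, 1,
                               dimnames = list(c("A", "B", "C", "D"), NULL)))
  expect_equal(mkLogLikelihood(cm, tr, model = m1), 4 * log(0.5),
               tolerance = 1e-6)
})

test_that("pruning equals brute-force summation on all 15 topologies", {
  set.seed(91)
  m1 <- mkModel(nRateCategories = 1L, coding = "all")
  codes <- matrix(as.character(sample(0:2, 15, replace = TRUE)), 5, 3,
                  dimnames = list(taxa5, NULL))
  cm <- characterMatrix(codes, nStates = rep(3L, 3))
  for (top in TOPS5) {
    tr <- phyloFromTopology(top)
    tr$edge.length <- stats::rexp(nrow(tr$edge), 5)
    expect_equal(mkLogLikelihood(cm, tr, model = m1), bruteMkLogLik(cm, tr),
                 tolerance = 1e-10)
  }
})

test_that("likelihood agrees with an independent implementation under +Gamma", {
  skip_if_not_installed("phangorn")
  set.seed(93)
  tr <- ape::unroot(ape::rtree(6, tip.label = letters[1:6]))
  tr$edge.length <- stats::rexp(nrow(tr$edge), 5)
  codes <- matrix(as.character(sample(0:1, 6 * 20, replace = TRUE)), 6, 20,
                  dimnames = list(letters[1:6], NULL))
  cm <- characterMatrix(codes, nStates = rep(2L, 20))
  pd <- phangorn::phyDat(codes, type = "USER", levels = c("0", "1"))
  fit <- phangorn::pml(tr, pd, k = 4, shape = 0.6)
  expect_equal(mkLogLikelihood(cm, tr, alpha = 0.6,
                               model = mkModel(nRateCategories = 4L,
                                               coding = "all")),
               fit$logLik, tolerance = 1e-8)
  expect_equal(discreteGammaMeans(0.6, 4),
               as.numeric(phangorn::discrete.gamma(0.6, 4)),
               tolerance = 1e-12)
})

test_that("missing and polymorphic cells integrate over allowed states", {
  tr <- ape::read.tree(text = "((A:0.1,B:0.1):0.1,(C:0.1,D:0.1):0.1);")
  m1 <- mkModel(nRateCategories = 1L, coding = "all")
  base <- characterMatrix(matrix(c("0", "1", "0", "1"), 4, 1,
                                 dimnames = list(LETTERS[1:4], NULL)))
  ## "?" sums the likelihoods of the two resolutions
  qm <- characterMatrix(matrix(c("?", "1", "0", "1"), 4, 1,
                               dimnames = list(LETTERS[1:4], NULL)))
  l0 <- characterMatrix(matrix(c("0", "1", "0", "1"), 4, 1,
                               dimnames = list(LETTERS[1:4], NULL)))
  l1 <- characterMatrix(matrix(c("1", "1", "0", "1"), 4, 1,
                               dimnames = list(LETTERS[1:4], NULL)))
  expect_equal(exp(mkLogLikelihood(qm, tr, model = m1)),
               exp(mkLogLikelihood(l0, tr, model = m1)) +
                 exp(mkLogLikelihood(l1, tr, model = m1)))
  ## polymorphic "(01)" behaves as the same partial ambiguity
  pm <- characterMatrix(matrix(c("01", "1", "0", "1"), 4, 1,
                               dimnames = list(LETTERS[1:4], NULL)))
  expect_equal(mkLogLikelihood(pm, tr, model = m1),
               mkLogLikelihood(qm, tr, model = m1))
})

test_that("Mkv correction renormalises variable patterns to sum to one", {
  tr <- ape::read.tree(text = "((A:0.2,B:0.3):0.1,(C:0.15,D:0.25):0.1);")
  mv <- mkModel(nRateCategories = 1L, coding = "variable")
  pats <- expand.grid(rep(list(c("0", "1")), 4), stringsAsFactors = FALSE)
  variable <- apply(pats, 1, function(r) length(unique(r)) > 1)
  tot <- 0
  for (i in which(variable)) {
    cm <- characterMatrix(matrix(as.character(pats[i, ]), 4, 1,
                                 dimnames = list(LETTERS[1:4], NULL)))
    tot <- tot + exp(mkLogLikelihood(cm, tr, model = mv))
  }
  expect_equal(tot, 1, tolerance = 1e-12)
})

test_that("simulation respects degenerate regimes", {
  tr <- ape::read.tree(text = "((A:0,B:0):0,(C:0,D:0):0);")
  set.seed(101)
  cm <- simulateCharacters(tr, 20, nStates = 2, variableOnly = FALSE,
                           model = mkModel(coding = "all"))
  expect_true(all(apply(cm@codes, 2, function(x) length(unique(x)) == 1)))

  ## saturation: states approach independent uniform draws
  trLong <- ape::read.tree(text = "((A:60,B:60):60,(C:60,D:60):60);")
  cmL <- simulateCharacters(trLong, 3000, nStates = 2, variableOnly = FALSE,
                            model = mkModel(coding = "all"))
  freq0 <- mean(cmL@codes == "0")
  expect_lt(abs(freq0 - 0.5), 0.03)

  ## variable-only filtering leaves no constant characters
  trN <- ape::rtree(6); trN$edge.length <- rep(0.05, nrow(trN$edge))
  cmV <- simulateCharacters(trN, 50, nStates = 2,
                            model = mkModel(coding = "variable"))
  expect_true(all(apply(cmV@codes, 2, function(x) length(unique(x)) > 1)))
})

test_that("likelihood grid prefers the generating gamma shape", {
  set.seed(103)
  tr <- ape::unroot(ape::rtree(8, tip.label = paste0("t", 1:8)))
  tr$edge.length <- stats::rexp(nrow(tr$edge), 5)
  cm <- simulateCharacters(tr, 400, nStates = 2, alpha = 0.4,
                           model = mkModel(coding = "all"),
                           variableOnly = FALSE)
  eval <- mkLikelihoodEvaluator(cm, mkModel(coding = "all"))
  grid <- c(0.05, 0.4, 3, 25)
  lls <- vapply(grid, function(a) eval(tr, a), 0)
  expect_equal(grid[which.max(lls)], 0.4)
})

test_that("prior sampling is uniform over topologies (no data)", {
  cm0 <- characterMatrix(matrix(character(0), 5, 0,
                                dimnames = list(taxa5, NULL)),
                         nStates = integer(0))
  runs <- runMkMcmc(cm0, mkModel(coding = "all"),
                    mcmcConfig(nGenerations = 15000, sampleEvery = 25,
                               burninFraction = 0.2, nRuns = 1L, seed = 11))
  ts <- dropBurnin(runs[[1]])
  counts <- table(factor(topologyIDs(ts),
                         levels = vapply(TOPS5, topologyID, "")))
  expect_equal(sum(counts), nTrees(ts))
  gof <- stats::chisq.test(as.numeric(counts))
  expect_gt(gof$p.value, 0.01)
})

test_that("MCMC recovers a strongly supported generating topology", {
  set.seed(107)
  taxa <- sort(paste0("t", 1:8))
  tr <- ape::unroot(ape::rtree(8, tip.label = sample(taxa)))
  ## identifiable regime: every edge long enough to expect several changes
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.3)
  cm <- simulateCharacters(tr, 150, nStates = 2, alpha = 1,
                           model = mkModel(coding = "variable"))
  runs <- runMkMcmc(cm, mkModel(coding = "variable"),
                    mcmcConfig(nGenerations = 2500, sampleEvery = 10,
                               nRuns = 1L, seed = 13))
  ts <- dropBurnin(runs[[1]])
  modal <- names(sort(table(topologyIDs(ts)), decreasing = TRUE))[1]
  expect_identical(modal, topologyID(topologyFromPhylo(tr)))
  expect_gt(infoSummary(ts)@informationPct, 50)
})

test_that("clade constraints hold in every sampled topology", {
  set.seed(109)
  taxa <- paste0("t", 1:6)
  cm0 <- characterMatrix(matrix(character(0), 6, 0,
                                dimnames = list(taxa, NULL)),
                         nStates = integer(0))
  constraint <- c("t1", "t2", "t3")
  runs <- runMkMcmc(cm0, mkModel(coding = "all"),
                    mcmcConfig(nGenerations = 2000, sampleEvery = 20,
                               nRuns = 1L, seed = 15,
                               constraints = list(constraint)))
  ts <- runs[[1]]
  for (i in seq_len(nTrees(ts)))
    expect_equal(cladePosterior(ts, constraint), 1)
})

test_that("run order does not affect downstream statistics", {
  probs <- skewedProbs5()
  r1 <- makeSyntheticPosterior(TOPS5, probs, 300, seed = 121, runId = "run1")
  r2 <- makeSyntheticPosterior(TOPS5, probs, 300, seed = 122, runId = "run2")
  tabA <- infoTable(list(s = list(r1, r2)))
  tabB <- infoTable(list(s = list(r2, r1)))
  mA <- tabA[tabA$run == "mean", c("coverage_pct", "information_pct",
                                   "dissonance_pct")]
  mB <- tabB[tabB$run == "mean", c("coverage_pct", "information_pct",
                                   "dissonance_pct")]
  expect_equal(mA, mB)
})

test_that("NEXUS matrices round-trip including polymorphism and missing", {
  codes <- matrix(c("0", "1", "?", "01",
                    "2", "-", "1", "0"), 4, 2,
                  dimnames = list(c("sp a", "spB", "spC", "spD"), NULL))
  rownames(codes) <- c("spA", "spB", "spC", "spD")
  cm <- characterMatrix(codes, nStates = c(2L, 3L))
  f <- withr::local_tempfile(fileext = ".nex")
  writeNexusMatrix(cm, f)
  cm2 <- readNexusMatrix(f)
  expect_identical(cm2@codes, cm@codes)
  expect_identical(taxonLabels(cm2), taxonLabels(cm))
})
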