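test_that("OBO parsing reads terms, typed edges and obsolete flags", {
  f <- withr::local_tempfile(lines = miniOboText(), fileext = ".obo")
  g <- readOBO(f)
  expect_equal(nrow(g@terms), 4)
  expect_equal(sum(g@terms$obsolete), 1)
  expect_true(all(c("is_a", "part_of") %in% g@edges$relation))
  expect_equal(g@edges$parent[g@edges$relation == "part_of"], "X:1")

  ## dangling targets warn and drop (or error per config)
  f2 <- withr::local_tempfile(
    lines = c(miniOboText(), "", "[Term]", "id: X:5", "name: dangler",
              "is_a: X:99"), fileext = ".obo")
  expect_warning(g2 <- readOBO(f2), "dangling")
  expect_false("X:99" %in% g2@edges$parent)
  expect_error(readOBO(f2, dangling = "error"), "dangling")
})

test_that("toy ontologies round-trip through OBO", {
  g <- makeToyOntology(depth = 2, branching = 3)
  f <- withr::local_tempfile(fileext = ".obo")
  writeOBO(g, f)
  g2 <- readOBO(f)
  expect_identical(g@terms$id, g2@terms$id)
  expect_identical(g@terms$name, g2@terms$name)
  expect_identical(g@edges[order(g@edges$child), ],
                   g2@edges[order(g2@edges$child), ])
})

test_that("ancestor closures respect relation filters", {
  f <- withr::local_tempfile(lines = miniOboText(), fileext = ".obo")
  g <- readOBO(f)
  ## chain X:3 is_a X:2 is_a X:1, plus X:3 part_of X:1
  expect_setequal(termAncestors(g, "X:3"), c("X:3", "X:2", "X:1"))
  expect_setequal(termAncestors(g, "X:3", relations = "part_of"),
                  c("X:3", "X:1"))
  expect_setequal(termAncestors(g, "X:3", relations = "is_a"),
                  c("X:3", "X:2", "X:1"))
  expect_error(termAncestors(g, "nope"), "unknown term")

  ## diamond: A -> B, A -> C, B -> D, C -> D
  gd <- new("TermGraph",
            terms = data.frame(id = c("A", "B", "C", "D"),
                               name = c("a", "b", "c", "d"),
                               obsolete = FALSE, stringsAsFactors = FALSE),
            edges = data.frame(child = c("A", "A", "B", "C"),
                               parent = c("B", "C", "D", "D"),
                               relation = "is_a", stringsAsFactors = FALSE))
  expect_setequal(termAncestors(gd, "A"), c("A", "B", "C", "D"))
})

test_that("termsUnder returns the query and its descendants", {
  f <- withr::local_tempfile(lines = miniOboText(), fileext = ".obo")
  g <- readOBO(f)
  expect_setequal(termsUnder(g, "X:3"), "X:3")
  expect_setequal(termsUnder(g, "X:2"), c("X:2", "X:3"))
  expect_true(all(c("X:1", "X:3") %in% termsUnder(g, "X:1",
                                                  relations = "part_of")))
})

test_that("Jaccard similarity counts closure overlap", {
  ## chain A is_a B is_a C
  g <- new("TermGraph",
           terms = data.frame(id = c("A", "B", "C"), name = c("a", "b", "c"),
                              obsolete = FALSE, stringsAsFactors = FALSE),
           edges = data.frame(child = c("A", "B"), parent = c("B", "C"),
                              relation = "is_a", stringsAsFactors = FALSE))
  expect_equal(jaccardSimilarity(g, "A", "A"), 1)
  expect_equal(jaccardSimilarity(g, "A", "B"), 2 / 3)  # {B,C} / {A,B,C}

  ## two chains of length 2 sharing only the root: |{R}| / |{R,a1,a2,b1,b2}|
  g2 <- new("TermGraph",
            terms = data.frame(id = c("R", "a1", "a2", "b1", "b2"),
                               name = letters[1:5], obsolete = FALSE,
                               stringsAsFactors = FALSE),
            edges = data.frame(child = c("a2", "a1", "b2", "b1"),
                               parent = c("a1", "R", "b1", "R"),
                               relation = "is_a", stringsAsFactors = FALSE))
  expect_equal(jaccardSimilarity(g2, "a2", "b2"), 1 / 5)

  ## symmetry; equality of closures gives 1
  expect_equal(jaccardSimilarity(g2, "a2", "b2"),
               jaccardSimilarity(g2, "b2", "a2"))
})

test_that("Resnik similarity is the IC of the MICA over the corpus", {
  ## root covers all 8 characters; left/mid nodes split them
  g <- new("TermGraph",
           terms = data.frame(id = c("root", "L", "R", "LL"),
                              name = c("r", "l", "rr", "ll"),
                              obsolete = FALSE, stringsAsFactors = FALSE),
           edges = data.frame(child = c("L", "R", "LL"),
                              parent = c("root", "root", "L"),
                              relation = "is_a", stringsAsFactors = FALSE))
  ann <- data.frame(character = 1:8,
                    term = c("LL", rep("L", 3), rep("R", 4)),
                    stringsAsFactors = FALSE)
  ## disjoint branches: MICA = root, IC = -ln(8/8) = 0
  expect_equal(resnikSimilarity(g, ann, "L", "R"), 0)
  ## same term covering 1 of 8 characters: IC = ln 8
  expect_equal(resnikSimilarity(g, ann, "LL", "LL"), log(8))
  ## MICA covering 4 of 8: IC = ln 2
  expect_equal(resnikSimilarity(g, ann, "LL", "L"), log(2))
  ## deeper MICA never decreases similarity (monotonicity)
  expect_gte(resnikSimilarity(g, ann, "LL", "L"),
             resnikSimilarity(g, ann, "LL", "R"))
  ## no common ancestor: 0 with warning
  g2 <- new("TermGraph",
            terms = data.frame(id = c("P", "Q"), name = c("p", "q"),
                               obsolete = FALSE, stringsAsFactors = FALSE),
            edges = data.frame(child = character(0), parent = character(0),
                               relation = character(0),
                               stringsAsFactors = FALSE))
  expect_warning(v <- resnikSimilarity(g2, ann, "P", "Q"), "no common")
  expect_equal(v, 0)
})

test_that("similarity and distance matrices are symmetric and normalised", {
  g <- makeToyOntology(depth = 2, branching = 2)
  terms <- g@terms$id[-1]
  s <- similarityMatrix(g, terms, metric = "jaccard")
  expect_true(isSymmetric(s))
  expect_true(all(diag(s) == 1))
  d <- semanticDistanceMatrix(g, terms)
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, 1 - s)
})

test_that("UPGMA clustering reconstructs ultrametric distances exactly", {
  ## simple 3-label case: (A,B) then C
  d3 <- matrix(c(0, 0.1, 0.9, 0.1, 0, 0.9, 0.9, 0.9, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  h3 <- clusterDendrogram(d3)
  expect_equal(sort(h3$labels[-h3$merge[1, ]]), c("A", "B"))

  ## ultrametric input: cophenetic distances reproduce the input
  labs <- c("A", "B", "C", "D")
  du <- matrix(1, 4, 4, dimnames = list(labs, labs))
  du["A", "B"] <- du["B", "A"] <- 0.2
  du["A", "C"] <- du["C", "A"] <- 0.6
  du["B", "C"] <- du["C", "B"] <- 0.6
  diag(du) <- 0
  hu <- clusterDendrogram(du)
  expect_equal(as.matrix(stats::cophenetic(hu))[labs, labs], du)

  ## permutation invariance (deterministic tie handling via sorted labels)
  perm <- c("D", "B", "A", "C")
  hp <- clusterDendrogram(du[perm, perm])
  expect_equal(as.matrix(stats::cophenetic(hp))[labs, labs], du)

  expect_error(clusterDendrogram(matrix(c(0, NA, NA, 0), 2, 2,
                                        dimnames = list(c("a", "b"),
                                                        c("a", "b")))),
               "NA")
})

test_that("dissonance dendrograms cluster congruent posteriors", {
  probsA <- skewedProbs5()
  sA1 <- makeSyntheticPosterior(TOPS5, probsA, 500, seed = 81)
  sA2 <- makeSyntheticPosterior(TOPS5, probsA, 500, seed = 82)
  ## C concentrates on a disjoint part of tree space
  probsC <- rev(probsA)
  sC <- makeSyntheticPosterior(TOPS5, probsC, 500, seed = 83)
  dd <- dissonanceDendrogram(list(A = sA1, B = sA2, C = sC),
                             estimator = "plugin")
  ## first merge joins the two same-distribution subsets
  first <- sort(dd$dendrogram$labels[-dd$dendrogram$merge[1, ]])
  expect_equal(first, c("A", "B"))
  ## the distance matrix equals per-pair dissonance
  dAB <- dissonance(list(sA1, sA2), estimator = "plugin")@dissonancePct
  expect_equal(dd$distances["A", "B"], dAB)
  expect_equal(dd$distances, t(dd$distances))
})

test_that("dendrogram leaves map one-to-one onto inputs with monotone heights", {
  g <- makeToyOntology(depth = 2, branching = 3)
  d <- semanticDistanceMatrix(g, g@terms$id[-1])
  h <- clusterDendrogram(d)
  expect_setequal(h$labels, g@terms$id[-1])
  expect_true(all(diff(h$height) >= -1e-12))
  nwk <- dendrogramToNewick(h)
  expect_match(nwk, ";$")
})

test_that("annotation tables validate against ontology and matrix", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("character_index\tterm_id\tterm_label",
               "0\tX:2\tmid", "1\tX:3\tleaf", "2\tX:3\tleaf"), f)
  fobo <- withr::local_tempfile(lines = miniOboText(), fileext = ".obo")
  g <- readOBO(fobo)
  ann <- readAnnotations(f, g, nChars = 3)
  expect_equal(ann$character, 1:3)  # 0-based input, 1-based in R
  expect_error(readAnnotations(f, g, nChars = 2), "out of matrix bounds")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("character_index\tterm_id", "0\tX:77"), f2)
  expect_error(readAnnotations(f2, g), "missing from ontology")
})
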