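toy <- toyInstance()
anchorMap <- buildAnchorMap(toy$graph, toy$scheme)

test_that("category schemes load from TSV with validation", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "A\tG22", "B\tG23"), path)
  scheme <- loadCategoryScheme(path, graph = toy$graph)
  expect_equal(categories(scheme), list(A = "G22", B = "G23"))

  # two lines, same category: one category with two seeds
  writeLines(c("A\tG22", "A\tG21"), path)
  scheme2 <- loadCategoryScheme(path, graph = toy$graph)
  expect_length(categories(scheme2), 1L)
  expect_setequal(categories(scheme2)$A, c("G22", "G21"))

  # a seed under two categories violates the scheme invariant
  writeLines(c("A\tG22", "B\tG22"), path)
  expect_error(loadCategoryScheme(path, graph = toy$graph),
               "more than one category")

  # unresolvable seeds are listed
  writeLines(c("A\tG22", "B\tNOPE"), path)
  expect_error(loadCategoryScheme(path, graph = toy$graph), "NOPE")

  writeLines("# nothing", path)
  expect_error(loadCategoryScheme(path), "empty")
})

test_that("label propagation resolves single-category terms as described", {
  single <- anchorMap@singleCategory
  expect_equal(unname(single[c("G31", "G33", "G42")]), c("A", "B", "B"))
  # multi-parent terms stay unresolved
  expect_false(any(c("G32", "G41", "G43") %in% names(single)))
  # a term with no category-assigned ancestor has an empty anchor set
  expect_equal(nrow(anchorMap@anchors[["G21"]]), 0L)
  # the anchors of G43 span both categories through seeds and
  # propagated single-category terms
  a43 <- anchorMap@anchors[["G43"]]
  expect_setequal(paste(a43$category, a43$anchor),
                  c("A G22", "A G31", "B G23", "B G33"))
})

test_that("term categorization reproduces the worked assignments", {
  expect_equal(categorizeTerm(toy$graph, toy$ic, anchorMap, "G31"),
               data.frame(category = "A", score = 1, anchor = "G31"))
  expect_equal(categorizeTerm(toy$graph, toy$ic, anchorMap, "G42")$category,
               "B")
  # seeds belong to their own category with score 1
  expect_equal(categorizeTerm(toy$graph, toy$ic, anchorMap, "G22"),
               data.frame(category = "A", score = 1, anchor = "G22"))

  best32 <- categorizeTerm(toy$graph, toy$ic, anchorMap, "G32",
                           mode = "best")
  expect_equal(best32$category, "A")
  expect_equal(best32$score, 0.815, tolerance = 1e-3)

  expect_equal(categorizeTerm(toy$graph, toy$ic, anchorMap, "G41",
                              mode = "best")$category, "A")

  multi43 <- categorizeTerm(toy$graph, toy$ic, anchorMap, "G43",
                            mode = "multi", threshold = 0.3)
  expect_equal(multi43$category, "A")   # B-side maximum is below 0.3
  expect_gte(multi43$score, 0.3)

  # terms without labelled ancestors yield an empty result
  expect_equal(nrow(categorizeTerm(toy$graph, toy$ic, anchorMap, "G21")),
               0L)

  # the argmax category is reported even when it misses the threshold
  high <- categorizeTerm(toy$graph, toy$ic, anchorMap, "G43",
                         mode = "multi", threshold = 0.99)
  expect_equal(nrow(high), 1L)
})

test_that("term categorization matches the definitional reference", {
  for (seed in 1:10) {
    g <- randomOntology(sample(10:60, 1), maxParents = 3, seed = seed)
    ic <- computeIC(g, propagateCounts(
      g, syntheticCorpus(g, 60, annPerGene = 2, skew = 1, seed = seed)))
    ids <- termInfo(g)$id
    seeds <- sample(setdiff(ids, unname(rootTerms(g))),
                    min(4, length(ids) - 1))
    scheme <- CategoryScheme(
      setNames(as.list(seeds), paste0("C", seq_along(seeds))), graph = g)
    am <- buildAnchorMap(g, scheme)
    for (t in sample(ids, min(15, length(ids)))) {
      got <- suppressWarnings(
        categorizeTerm(g, ic, am, t, mode = "multi", threshold = 0))
      want <- suppressWarnings(naiveCategorizeTerm(g, ic, scheme, t))
      expect_equal(got$category, want$category,
                   label = sprintf("seed %d term %s", seed, t))
      expect_equal(got$score, want$score, tolerance = 1e-12)
    }
  }
})

test_that("gene categorization aggregates terms by maximum score", {
  ann <- AnnotationSet(c("g1", "g1", "g2", "g3"),
                       c("G32", "G21", "G31", "G21"))
  # single annotated categorizable term passes straight through
  g1 <- categorizeGene(toy$graph, toy$ic, anchorMap, ann, "g1")
  expect_equal(g1$category, "A")
  expect_equal(g1$score, 0.815, tolerance = 1e-3)
  expect_equal(g1$term, "G32")
  # no category-covered annotation: unclassified
  g3 <- categorizeGene(toy$graph, toy$ic, anchorMap, ann, "g3")
  expect_equal(nrow(g3), 0L)
  expect_error(categorizeGene(toy$graph, toy$ic, anchorMap, ann, "nope"),
               "not in annotation set")

  # a gene annotated with two single-category terms gets both at 1.0
  ann2 <- AnnotationSet(c("gx", "gx"), c("G31", "G33"))
  gx <- categorizeGene(toy$graph, toy$ic, anchorMap, ann2, "gx")
  expect_setequal(gx$category, c("A", "B"))
  expect_equal(gx$score, c(1, 1))
})

test_that("gene-set categorization reports stable category statistics", {
  ann <- AnnotationSet(c("g1", "g2", "g3"), c("G31", "G33", "G21"))
  res <- categorizeGenes(toy$graph, toy$ic, anchorMap, ann,
                         c("g1", "g2", "g3"))
  counts <- categoryCounts(res)
  expect_equal(counts, structure(c(A = 1L, B = 1L), unclassified = 1L))

  # invariant to input order
  res2 <- categorizeGenes(toy$graph, toy$ic, anchorMap, ann,
                          c("g3", "g1", "g2"))
  expect_identical(assignmentTable(res)[order(assignmentTable(res)$gene), ],
                   assignmentTable(res2)[order(assignmentTable(res2)$gene), ])

  # all genes unclassified: zero counts everywhere
  ann3 <- AnnotationSet("g9", "G21")
  res3 <- categorizeGenes(toy$graph, toy$ic, anchorMap, ann3, "g9")
  expect_length(categoryCounts(res3), 0L)
  expect_equal(attr(categoryCounts(res3), "unclassified"), 1L)
})

test_that("categories with irrelevant seeds change no assignment", {
  ann <- AnnotationSet(c("g1", "g2"), c("G32", "G31"))
  base <- categorizeGenes(toy$graph, toy$ic, anchorMap, ann,
                          c("g1", "g2"))
  # G21 has no descendants among annotated terms' lineages
  scheme2 <- CategoryScheme(list(A = "G22", B = "G23", Z = "G21"),
                            graph = toy$graph)
  am2 <- buildAnchorMap(toy$graph, scheme2)
  res2 <- categorizeGenes(toy$graph, toy$ic, am2, ann, c("g1", "g2"))
  expect_equal(assignmentTable(base), assignmentTable(res2))
})

test_that("assignments serialize to TSV with unclassified markers", {
  ann <- AnnotationSet(c("g1", "g2"), c("G31", "G21"))
  res <- categorizeGenes(toy$graph, toy$ic, anchorMap, ann,
                         c("g1", "g2"))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeAssignments(res, path)
  lines <- readLines(path)
  expect_true(any(grepl("^g1\tA\t1", lines)))
  expect_true(any(grepl("^g2\tunclassified", lines)))
})
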