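# A categorized background is just a GeneAssignments object; build them
# directly so the null model is tested in isolation from the categorizer.
makeBackground <- function(genes, categoryList) {
  tab <- do.call(rbind, lapply(seq_along(genes), function(i) {
    cats <- categoryList[[i]]
    if (!length(cats)) return(NULL)
    data.frame(gene = genes[i], category = cats, score = 1,
               term = NA_character_)
  }))
  tab <- tab %||% data.frame(gene = character(), category = character(),
                             score = numeric(), term = character())
  new("GeneAssignments", table = tab, genes = genes, mode = "multi",
      threshold = 0.3)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

subsetAssignments <- function(background, genes) {
  tab <- assignmentTable(background)
  new("GeneAssignments",
      table = tab[tab$gene %in% genes, , drop = FALSE],
      genes = genes, mode = background@mode,
      threshold = background@threshold)
}

test_that("category probabilities normalize over assignments", {
  bg <- makeBackground(paste0("g", 1:4),
                       list("A", "A", "A", "B"))
  p <- categoryProbabilities(bg)
  expect_equal(p, c(A = 0.75, B = 0.25))
  expect_equal(sum(p), 1)

  single <- makeBackground(c("g1", "g2"), list("A", "A"))
  expect_equal(categoryProbabilities(single), c(A = 1))

  # invariant under duplicating the whole gene set
  bg2 <- makeBackground(paste0("g", 1:8),
                        rep(list("A", "A", "A", "B"), 2))
  expect_equal(categoryProbabilities(bg2), p)

  empty <- makeBackground(c("g1", "g2"), list(NULL, NULL))
  expect_error(categoryProbabilities(empty), "no gene")
})

test_that("a one-category degree-1 background forces mu = L, sigma = 0", {
  bg <- makeBackground(paste0("g", 1:10), rep(list("A"), 10))
  null <- randomizedNull(bg, L = 6, reps = 50, seed = 7)
  expect_equal(null$mu, 6)
  expect_equal(null$sigma, 0)
})

test_that("every randomized replicate conserves per-gene degree", {
  genes <- paste0("g", 1:40)
  degs <- rep(1:3, length.out = 40)
  catList <- lapply(degs, function(k) LETTERS[seq_len(k)])
  bg <- makeBackground(genes, catList)
  null <- randomizedNull(bg, L = 40, reps = 200, seed = 3)
  counts <- attr(null, "counts")
  # with L = N every replicate's total assignment count is the fixed
  # sum of degrees, which can only hold if each gene kept its degree
  expect_true(all(rowSums(counts) == sum(degs)))
  # a gene cannot carry more categories than exist
  tooMany <- makeBackground("g1", list(LETTERS[1:3]))
  bad <- new("GeneAssignments",
             table = data.frame(gene = "g1",
                                category = c("A", "B"), score = 1,
                                term = NA_character_),
             genes = "g1", mode = "multi", threshold = 0.3)
  expect_error(randomizedNull(subsetAssignments(bad, "g1"), L = 1,
                              reps = 5, seed = 1),
               NA)  # degree 2 of 2 categories is fine
  expect_error(randomizedNull(bg, L = 100, reps = 5, seed = 1), "L must")
})

test_that("two equiprobable categories split the null mean evenly", {
  genes <- paste0("g", 1:60)
  catList <- rep(list("A", "B"), 30)
  bg <- makeBackground(genes, catList)
  reps <- 1000
  null <- randomizedNull(bg, L = 60, reps = reps, seed = 11)
  # each gene keeps degree 1 and draws A w.p. 1/2: mu ~ Binomial mean
  # L/2 with SE sqrt(L/4)/sqrt(reps)
  se <- sqrt(60 / 4) / sqrt(reps)
  expect_lt(abs(null$mu[null$category == "A"] - 30), 3 * se)
})

test_that("identical seeds reproduce identical enrichment results", {
  set.seed(99)
  g <- randomOntology(40, maxParents = 3, seed = 5)
  ic <- computeIC(g, propagateCounts(
    g, syntheticCorpus(g, 120, annPerGene = 2, skew = 1, seed = 5)))
  ann <- syntheticCorpus(g, 120, annPerGene = 2, skew = 1, seed = 5)
  seeds <- sample(setdiff(termInfo(g)$id, unname(rootTerms(g))), 4)
  scheme <- CategoryScheme(setNames(as.list(seeds), paste0("C", 1:4)),
                           graph = g)
  am <- buildAnchorMap(g, scheme)
  bg <- categorizeGenes(g, ic, am, ann, annGenes(ann))
  test <- subsetAssignments(bg, sample(bg@genes, 30))
  r1 <- enrichmentTest(test, bg, reps = 100, seed = 42)
  r2 <- enrichmentTest(test, bg, reps = 100, seed = 42)
  expect_identical(r1, r2)
  expect_true(all(r1$p_enrich >= 0 & r1$p_enrich <= 1))
  expect_true(all(r1$p_deplete >= 0 & r1$p_deplete <= 1))
})

test_that("test genes outside the background are intersected with warning", {
  bg <- makeBackground(paste0("g", 1:10),
                       rep(list("A", "B"), 5))
  test <- makeBackground(c("g1", "g2", "zz"),
                         list("A", "B", "A"))
  expect_warning(res <- enrichmentTest(test, bg, reps = 50, seed = 1),
                 "absent from the background")
  expect_equal(attr(res, "L"), 2L)
  empty <- makeBackground(character(), list())
  expect_error(enrichmentTest(empty, bg, reps = 50, seed = 1), "empty")
})

test_that("a degenerate test set equal to the background gives z near 0", {
  genes <- paste0("g", 1:50)
  catList <- rep(list("A", "B"), 25)
  bg <- makeBackground(genes, catList)
  res <- enrichmentTest(bg, bg, reps = 400, seed = 13)
  # with L = N the null draw is the whole set; only the category
  # reassignment varies, and observed equals its expectation
  expect_true(all(abs(res$z) < 0.5))
})

test_that("a full spike-in of a 10%-prevalence category is enriched", {
  set.seed(1)
  genes <- sprintf("g%03d", 1:400)
  catList <- lapply(seq_along(genes), function(i) {
    if (i <= 40) "X" else sample(c("A", "B", "C"), 1)
  })
  bg <- makeBackground(genes, catList)
  testGenes <- spikeInGeneSet(bg, "X", fraction = 1, size = 40, seed = 2)
  expect_setequal(testGenes, genes[1:40])
  res <- enrichmentTest(subsetAssignments(bg, testGenes), bg,
                        reps = 1000, seed = 3)
  expect_lt(res$p_enrich[res$category == "X"], 1e-2)
})

test_that("null test sets reject at close to the nominal 5% level", {
  set.seed(20)
  genes <- sprintf("g%04d", 1:1000)
  catList <- lapply(seq_along(genes), function(i)
    sample(LETTERS[1:8], sample(2:3, 1)))
  bg <- makeBackground(genes, catList)
  L <- 50
  null <- randomizedNull(bg, L, reps = 1000, seed = 77)
  crit <- stats::qnorm(0.95)
  nDraws <- 250
  tab <- assignmentTable(bg)
  memberOfA <- unique(tab$gene[tab$category == "A"])
  rejections <- logical(nDraws)
  for (d in seq_len(nDraws)) {
    draw <- sample(genes, L)
    obs <- sum(draw %in% memberOfA)
    z <- (obs - null$mu[null$category == "A"]) /
      null$sigma[null$category == "A"]
    rejections[d] <- z > crit
  }
  rate <- mean(rejections)
  band <- stats::qbinom(c(0.025, 0.975), nDraws, 0.05) / nDraws
  expect_gte(rate, band[1])
  expect_lte(rate, band[2])
})

test_that("zero-variance categories are flagged with bounded p-values", {
  # one category, all genes degree 1: sigma is exactly 0
  bg <- makeBackground(paste0("g", 1:10), rep(list("A"), 10))
  # a test subset in which one gene is unclassified
  tab <- assignmentTable(bg)
  test <- new("GeneAssignments",
              table = tab[tab$gene %in% paste0("g", 1:3), , drop = FALSE],
              genes = paste0("g", 1:4), mode = "multi", threshold = 0.3)
  res <- enrichmentTest(test, bg, reps = 100, seed = 5)
  # null forces mu = 4 but only 3 test genes carry the category
  expect_true(res$sigma_zero)
  expect_equal(res$p_deplete, 1 / 100)
})
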