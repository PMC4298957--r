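## Degree-preserving randomization test for category enrichment.
##
## The null model re-assigns categories to the background genes according
## to the background category probabilities p(c), keeping each gene's
## number of categories (its degree) fixed, then draws test-set-sized gene
## samples; z-scores compare the observed per-category gene counts against
## the randomization mean and SD.

#' Category probabilities in a background set
#'
#' `p(c)` is the number of (gene, category) assignments to `c` divided by
#' the total number of assignments; the probabilities sum to 1.
#'
#' @param background a [GeneAssignments-class] for the reference gene set.
#' @return Named numeric vector over categories.
#' @export
categoryProbabilities <- function(background) {
  tab <- assignmentTable(background)
  if (!nrow(tab))
    stop("no gene in the background is assigned to any category")
  f <- table(tab$category)
  p <- as.numeric(f) / sum(f)
  stats::setNames(p, names(f))
}

## per-gene degree (number of assigned categories), unclassified genes 0
assignmentDegrees <- function(x) {
  tab <- assignmentTable(x)
  deg <- stats::setNames(integer(length(x@genes)), x@genes)
  if (nrow(tab)) {
    d <- table(tab$gene)
    deg[names(d)] <- as.integer(d)
  }
  deg
}

#' Randomization null for category counts
#'
#' In each replicate every background gene with degree `k` receives `k`
#' distinct categories drawn sequentially without replacement with
#' probability proportional to `p(c)`; then `L` genes are drawn uniformly
#' without replacement and the number of drawn genes per category is
#' recorded. Degree conservation is asserted in every replicate. Returns
#' the per-category mean and standard deviation over replicates.
#'
#' @param background a [GeneAssignments-class] for the reference gene set.
#' @param L test-set size, `0 < L <=` background size.
#' @param reps number of replicates (>= 2; 1000 by default).
#' @param seed integer seed; results are fully reproducible given the seed.
#' @return data.frame with columns `category`, `mu`, `sigma`; the replicate
#'   count matrix is attached as attribute `counts` (reps x categories).
#' @export
randomizedNull <- function(background, L, reps = 1000, seed = 1) {
  genes <- background@genes
  N <- length(genes)
  if (L <= 0 || L > N) stop("L must be in 1..", N)
  if (reps < 2) stop("reps must be >= 2")
  p <- categoryProbabilities(background)
  cats <- names(p)
  M <- length(cats)
  deg <- assignmentDegrees(background)
  if (any(deg > M))
    stop("gene degree exceeds the number of categories")

  set.seed(seed)
  counts <- matrix(0L, nrow = reps, ncol = M,
                   dimnames = list(NULL, cats))
  active <- which(deg > 0)
  for (r in seq_len(reps)) {
    assigned <- vector("list", N)
    for (i in active)
      assigned[[i]] <- sample.int(M, deg[i], replace = FALSE, prob = p)
    ## degree conservation is structural; assert it anyway
    stopifnot(identical(lengths(assigned)[active], unname(deg[active])))
    chosen <- sample.int(N, L, replace = FALSE)
    hit <- unlist(assigned[chosen])
    if (length(hit))
      counts[r, ] <- tabulate(hit, nbins = M)
  }
  data.frame(category = cats, mu = colMeans(counts),
             sigma = apply(counts, 2, stats::sd), row.names = NULL) |>
    structure(counts = counts)
}

#' Category enrichment of a test gene set
#'
#' Compares observed per-category gene counts in the test set with the
#' degree-preserving randomization null built on the background:
#' `z(c) = (observed(c) - mu(c)) / sigma(c)`, with one-sided normal tail
#' p-values in both directions (`p_enrich = 1 - Phi(z)` for enrichment,
#' `p_deplete = Phi(z)` for depletion). When `sigma = 0`, `z` is 0 if the
#' observation equals the mean, and otherwise the p-value is reported as
#' below `1/reps` with `sigma_zero` flagged.
#'
#' @param test a [GeneAssignments-class] for the test genes; test genes
#'   should be a subset of the background genes (a warning is issued and
#'   the intersection used otherwise).
#' @param background a [GeneAssignments-class] for the reference gene set.
#' @param reps randomization replicates (default 1000).
#' @param seed integer seed.
#' @param fdr if `TRUE`, append Benjamini-Hochberg adjusted enrichment
#'   p-values (off by default; the primary output is unadjusted).
#' @return data.frame with columns `category`, `observed`, `mu`, `sigma`,
#'   `z`, `p_enrich`, `p_deplete`, `sigma_zero`; attributes `reps`, `seed`
#'   and `L` record the run.
#' @export
enrichmentTest <- function(test, background, reps = 1000, seed = 1,
                           fdr = FALSE) {
  testGenes <- test@genes
  if (!length(testGenes)) stop("test gene set is empty")
  extra <- setdiff(testGenes, background@genes)
  if (length(extra)) {
    warning(length(extra), " test gene(s) absent from the background; ",
            "using the intersection")
    testGenes <- intersect(testGenes, background@genes)
    if (!length(testGenes)) stop("no test gene is in the background")
  }
  L <- length(testGenes)
  null <- randomizedNull(background, L, reps = reps, seed = seed)

  testTab <- assignmentTable(test)
  testTab <- testTab[testTab$gene %in% testGenes, , drop = FALSE]
  obs <- vapply(null$category, function(cc)
    length(unique(testTab$gene[testTab$category == cc])), integer(1))

  z <- ifelse(null$sigma > 0, (obs - null$mu) / null$sigma,
              ifelse(obs == null$mu, 0, sign(obs - null$mu) * Inf))
  sigmaZero <- null$sigma == 0 & obs != null$mu
  pEnrich <- stats::pnorm(z, lower.tail = FALSE)
  pDeplete <- stats::pnorm(z, lower.tail = TRUE)
  ## a zero-variance null cannot resolve p below the replicate resolution
  pEnrich[sigmaZero & z > 0] <- 1 / reps
  pDeplete[sigmaZero & z < 0] <- 1 / reps
  res <- data.frame(category = null$category, observed = as.integer(obs),
                    mu = null$mu, sigma = null$sigma, z = z,
                    p_enrich = pEnrich, p_deplete = pDeplete,
                    sigma_zero = sigmaZero)
  if (fdr)
    res$p_enrich_fdr <- stats::p.adjust(res$p_enrich, method = "BH")
  attr(res, "reps") <- reps
  attr(res, "seed") <- seed
  attr(res, "L") <- L
  res
}

#' Write enrichment results to TSV
#'
#' @param res result of [enrichmentTest()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEnrichment <- function(res, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# reps=%d seed=%d L=%d", attr(res, "reps"),
                     attr(res, "seed"), attr(res, "L")), con)
  cols <- c("category", "observed", "mu", "sigma", "z",
            "p_enrich", "p_deplete", "sigma_zero")
  writeLines(paste(cols, collapse = "\t"), con)
  writeLines(apply(res[cols], 1, function(r)
    paste(trimws(r), collapse = "\t")), con)
  invisible(path)
}
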