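## Category-label propagation and gene assignment.
##
## A term that is a descendant of exactly one category's labelled terms is
## assigned to that category with score 1 and itself becomes a label
## ("anchor") for its own descendants. A term reachable from labels of two
## or more categories is scored against every labelled ancestor with the
## semantic similarity S and assigned to the best-scoring category (or to
## every category above a threshold in multi mode).

#' Load a category scheme from TSV
#'
#' Lines of `category<TAB>term id`; `#` comments allowed. Seeds accumulate
#' across lines; a seed appearing under two categories is an error.
#'
#' @param path path to the TSV file.
#' @param graph optional [OntologyGraph-class]; when given, unresolvable
#'   seeds raise an error listing the offenders.
#' @param name scheme name (defaults to the file name).
#' @return A [CategoryScheme-class].
#' @export
loadCategoryScheme <- function(path, graph = NULL, name = NULL) {
  if (!file.exists(path)) stop("cannot read category file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) stop("empty category scheme: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L))
    stop("malformed category line ", which(lengths(fields) < 2L)[1],
         ": expected 'category<TAB>term id'")
  cat <- vapply(fields, `[[`, character(1), 1L)
  seed <- trimws(vapply(fields, `[[`, character(1), 2L))
  categories <- split(seed, cat)
  ## split() sorts by factor level; preserve first-appearance order
  categories <- categories[unique(cat)]
  CategoryScheme(categories, name = name %||% basename(path), graph = graph)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Propagate category labels through the ontology
#'
#' Walks the graph top-down (parents before children). Each term inherits
#' the (category, anchor) pairs of its parents; a user seed adds itself as
#' an anchor of its category, and any term whose inherited anchors span
#' exactly one category is resolved to that category and added as an
#' anchor for its own descendants. A user seed is always resolved to its
#' own category, regardless of inherited labels.
#'
#' @param graph an [OntologyGraph-class].
#' @param scheme a [CategoryScheme-class]; every seed must be in the graph.
#' @return An [AnchorMap-class].
#' @examples
#' toy <- toyInstance()
#' am <- buildAnchorMap(toy$graph, toy$scheme)
#' am@singleCategory[c("G31", "G33", "G42")]  # A, B, B
#' @export
buildAnchorMap <- function(graph, scheme) {
  known <- termInfo(graph)$id
  seeds <- categories(scheme)
  bad <- setdiff(unlist(seeds), known)
  if (length(bad))
    stop("seed term(s) not present in the graph: ",
         paste(bad, collapse = ", "))
  seedCat <- stats::setNames(
    rep(names(seeds), lengths(seeds)), unlist(seeds))

  ord <- topologicalOrder(graph)
  parentsOf <- split(edgeTable(graph)$parent, edgeTable(graph)$child)
  anchors <- stats::setNames(vector("list", length(ord)), ord)
  singleCategory <- character()

  for (t in ord) {
    inh <- list()
    for (pp in parentsOf[[t]] %||% character()) {
      pa <- anchors[[pp]]
      ## the parent itself acts as an anchor if it carries a label
      lab <- if (pp %in% names(seedCat)) seedCat[[pp]]
             else if (pp %in% names(singleCategory)) singleCategory[[pp]]
             else NA_character_
      if (!is.na(lab))
        pa <- rbind(pa, data.frame(category = lab, anchor = pp))
      inh[[length(inh) + 1L]] <- pa
    }
    a <- if (length(inh)) unique(do.call(rbind, inh))
         else data.frame(category = character(), anchor = character())
    rownames(a) <- NULL
    anchors[[t]] <- a
    if (t %in% names(seedCat)) {
      singleCategory[[t]] <- seedCat[[t]]
    } else if (nrow(a) && length(unique(a$category)) == 1L) {
      singleCategory[[t]] <- a$category[1]
    }
  }
  new("AnchorMap", anchors = anchors, singleCategory = singleCategory,
      scheme = scheme)
}

#' Categorize a single term
#'
#' A term resolved to a single category (a seed, or a term all of whose
#' labelled ancestors belong to one category) is assigned there with score
#' 1. A term with anchors in two or more categories is scored per category
#' as the maximum similarity S over that category's anchors; `mode =
#' "best"` returns the top category, `mode = "multi"` every category with
#' score at or above `threshold` (the top category is always included). A
#' term with no labelled ancestor returns an empty result.
#'
#' @param graph an [OntologyGraph-class].
#' @param table an [ICTable-class].
#' @param anchorMap an [AnchorMap-class] from [buildAnchorMap()].
#' @param term a term id.
#' @param mode `"best"` or `"multi"`.
#' @param threshold multi-mode score cutoff in `[0, 1]` (default 0.3, the
#'   package default derived from the score distribution of random
#'   ancestor-descendant pairs).
#' @return data.frame with columns `category`, `score`, `anchor` (the
#'   anchor term that produced the score), ordered by decreasing score.
#' @examples
#' toy <- toyInstance()
#' am <- buildAnchorMap(toy$graph, toy$scheme)
#' categorizeTerm(toy$graph, toy$ic, am, "G32")
#' @export
categorizeTerm <- function(graph, table, anchorMap, term,
                           mode = c("multi", "best"), threshold = 0.3) {
  mode <- match.arg(mode)
  stopifnot(threshold >= 0, threshold <= 1)
  term <- checkTermKnown(graph, term)
  empty <- data.frame(category = character(), score = numeric(),
                      anchor = character())

  single <- anchorMap@singleCategory
  if (term %in% names(single))
    return(data.frame(category = single[[term]], score = 1,
                      anchor = term, row.names = NULL))
  a <- anchorMap@anchors[[term]]
  if (is.null(a) || !nrow(a)) return(empty)
  cats <- unique(a$category)

  perCat <- lapply(cats, function(cc) {
    anch <- a$anchor[a$category == cc]
    s <- vapply(anch, function(aa)
      termSimilarity(graph, table, term, aa)$s, numeric(1))
    data.frame(category = cc, score = max(s),
               anchor = sort(anch[s == max(s)])[1])
  })
  res <- do.call(rbind, perCat)
  res <- res[order(-res$score, res$category), , drop = FALSE]
  rownames(res) <- NULL

  if (mode == "best") {
    res[res$score == res$score[1], , drop = FALSE][
      1, , drop = FALSE]
  } else {
    keep <- res$score >= threshold
    keep[1] <- TRUE  # the argmax category is always reported
    res[keep, , drop = FALSE]
  }
}

#' Categorize one gene
#'
#' A gene's category score is the maximum over its annotated terms of the
#' term-level category score; the annotated term attaining the maximum is
#' recorded as the supporting term. A gene none of whose annotations is
#' covered by any category is unclassified.
#'
#' @inheritParams categorizeTerm
#' @param ann an [AnnotationSet-class].
#' @param gene a gene id present in `ann`.
#' @return data.frame with columns `gene`, `category`, `score`, `term`
#'   (zero rows when unclassified).
#' @export
categorizeGene <- function(graph, table, anchorMap, ann, gene,
                           mode = c("multi", "best"), threshold = 0.3) {
  mode <- match.arg(mode)
  rec <- annRecords(ann)
  if (!gene %in% rec$gene) stop("gene not in annotation set: ", gene)
  terms <- unique(rec$term[rec$gene == gene])
  per <- lapply(terms, function(tm) {
    r <- categorizeTerm(graph, table, anchorMap, tm, mode, threshold)
    if (nrow(r)) cbind(term = tm, r) else NULL
  })
  per <- do.call(rbind, per)
  if (is.null(per) || !nrow(per))
    return(data.frame(gene = character(), category = character(),
                      score = numeric(), term = character()))
  best <- do.call(rbind, lapply(split(per, per$category), function(d) {
    d <- d[order(-d$score, d$term), , drop = FALSE]
    d[1, , drop = FALSE]
  }))
  out <- data.frame(gene = gene, category = best$category,
                    score = best$score, term = best$term)
  out <- out[order(-out$score, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Categorize a set of genes
#'
#' Runs [categorizeGene()] over a gene list and collects the results and
#' per-category statistics. Genes absent from the annotation set are kept
#' as unclassified and counted in the `unknownGenes` attribute.
#'
#' @inheritParams categorizeGene
#' @param genes character vector of gene ids (nonempty).
#' @return A [GeneAssignments-class]; [categoryCounts()] gives per-category
#'   gene counts and the unclassified count.
#' @examples
#' toy <- toyInstance()
#' am <- buildAnchorMap(toy$graph, toy$scheme)
#' ann <- AnnotationSet(c("g1", "g2"), c("G31", "G33"))
#' categoryCounts(categorizeGenes(toy$graph, toy$ic, am, ann,
#'                                c("g1", "g2")))
#' @export
categorizeGenes <- function(graph, table, anchorMap, ann, genes,
                            mode = c("multi", "best"), threshold = 0.3) {
  mode <- match.arg(mode)
  if (!length(genes)) stop("gene list is empty")
  genes <- unique(as.character(genes))
  known <- genes[genes %in% annRecords(ann)$gene]
  rows <- lapply(sort(known), function(g)
    categorizeGene(graph, table, anchorMap, ann, g, mode, threshold))
  tab <- do.call(rbind, rows) %||%
    data.frame(gene = character(), category = character(),
               score = numeric(), term = character())
  rownames(tab) <- NULL
  out <- new("GeneAssignments", table = tab, genes = genes,
             mode = mode, threshold = threshold)
  attr(out@table, "unknownGenes") <- setdiff(genes, known)
  out
}

#' Write per-gene assignments to TSV
#'
#' Columns: gene, category, score, supporting term. Unclassified genes are
#' written with an `unclassified` marker in the category column.
#'
#' @param x a [GeneAssignments-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAssignments <- function(x, path) {
  tab <- assignmentTable(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mode=%s threshold=%g", x@mode, x@threshold), con)
  writeLines("gene\tcategory\tscore\tterm", con)
  if (nrow(tab))
    writeLines(sprintf("%s\t%s\t%.6f\t%s", tab$gene, tab$category,
                       tab$score, tab$term), con)
  for (g in sort(setdiff(x@genes, tab$gene)))
    writeLines(sprintf("%s\tunclassified\tNA\tNA", g), con)
  invisible(path)
}
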