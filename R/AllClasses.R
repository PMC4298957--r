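#' @import methods
NULL

#' Ontology graph
#'
#' A validated directed acyclic graph of ontology terms. Edges point from
#' child to parent and only connect terms of the same namespace; each
#' namespace has exactly one root (a term without parents). Obsolete terms
#' are retained in the term table but carry no edges and take part in no
#' traversal.
#'
#' Construct with [parseOBO()], [readEdgeTSV()] or [randomOntology()].
#'
#' @slot termTable data.frame with columns `id`, `name`, `namespace`,
#'   `obsolete`.
#' @slot edgeTable data.frame with columns `child`, `parent`, `relation`.
#' @slot roots named character vector, namespace -> root id.
#' @slot altIds named character vector mapping alternative ids to primary
#'   ids (may be empty).
#' @slot graph internal igraph representation (child -> parent arcs) over
#'   non-obsolete terms.
#' @seealso [ancestors()], [descendants()], [termInfo()], [edgeTable()],
#'   [rootTerms()]
#' @export
setClass("OntologyGraph",
  slots = c(
    termTable = "data.frame",
    edgeTable = "data.frame",
    roots     = "character",
    altIds    = "character",
    graph     = "ANY"
  )
)

setValidity("OntologyGraph", function(object) {
  tt <- object@termTable
  et <- object@edgeTable
  msgs <- character()
  if (!all(c("id", "name", "namespace", "obsolete") %in% names(tt)))
    msgs <- c(msgs, "termTable must have columns id, name, namespace, obsolete")
  if (anyDuplicated(tt$id))
    msgs <- c(msgs, "term ids must be unique")
  if (nrow(et)) {
    if (!all(c("child", "parent", "relation") %in% names(et)))
      msgs <- c(msgs, "edgeTable must have columns child, parent, relation")
    live <- tt$id[!tt$obsolete]
    if (!all(et$child %in% live) || !all(et$parent %in% live))
      msgs <- c(msgs, "edges may only connect non-obsolete terms of the graph")
    ns <- stats::setNames(tt$namespace, tt$id)
    if (any(ns[et$child] != ns[et$parent]))
      msgs <- c(msgs, "edges must connect terms of the same namespace")
  }
  if (!is.null(object@graph) && !igraph::is_dag(object@graph))
    msgs <- c(msgs, "ontology graph must be acyclic")
  if (length(msgs)) msgs else TRUE
})

#' Gene-to-term annotation set
#'
#' Deduplicated (gene, term) annotation records, with a count of input
#' records that could not be resolved against the companion graph.
#'
#' Construct with [loadAnnotations()] or [syntheticCorpus()].
#'
#' @slot records data.frame with columns `gene`, `term` (primary ids).
#' @slot unresolved data.frame of the input records whose term id was not
#'   resolvable in the graph (same columns); reported, never silently
#'   dropped.
#' @seealso [annRecords()], [annGenes()]
#' @export
setClass("AnnotationSet",
  slots = c(records = "data.frame", unresolved = "data.frame")
)

setValidity("AnnotationSet", function(object) {
  if (!all(c("gene", "term") %in% names(object@records)))
    return("records must have columns gene, term")
  if (anyDuplicated(object@records[c("gene", "term")]))
    return("(gene, term) records must be deduplicated")
  TRUE
})

#' Information-content table
#'
#' Per-term occurrence probability p(x) and information content
#' I(x) = -log p(x), computed on a reference annotation corpus with
#' true-path count propagation. The root of each namespace has p = 1 and
#' I = 0; along every child-parent edge I(child) >= I(parent).
#'
#' Construct with [computeIC()], load/save with [readICTable()] /
#' [writeICTable()].
#'
#' @slot p named numeric, term id -> occurrence probability in (0, 1].
#' @slot ic named numeric, term id -> information content >= 0.
#' @slot namespace named character, term id -> namespace.
#' @slot meta list with at least `nRecords` (total record count),
#'   `nsTotals` (named per-namespace record totals) and `logBase`.
#' @seealso [icValues()], [termProb()]
#' @export
setClass("ICTable",
  slots = c(
    p = "numeric",
    ic = "numeric",
    namespace = "character",
    meta = "list"
  )
)

setValidity("ICTable", function(object) {
  msgs <- character()
  if (!identical(names(object@p), names(object@ic)))
    msgs <- c(msgs, "p and ic must be indexed by the same term ids")
  if (any(object@p <= 0) || any(object@p > 1 + 1e-12))
    msgs <- c(msgs, "probabilities must lie in (0, 1]")
  if (any(object@ic < -1e-9))
    msgs <- c(msgs, "information content must be nonnegative")
  if (length(msgs)) msgs else TRUE
})

#' Category scheme
#'
#' User-defined biological categories, each seeded by one or more ontology
#' term ids. A seed id may belong to only one category.
#'
#' Construct with [CategoryScheme()] or [loadCategoryScheme()].
#'
#' @slot name scheme name.
#' @slot categories named list, category name -> character vector of seed
#'   term ids.
#' @seealso [categories()], [buildAnchorMap()]
#' @export
setClass("CategoryScheme",
  slots = c(name = "character", categories = "list")
)

setValidity("CategoryScheme", function(object) {
  cats <- object@categories
  if (!length(cats)) return("a scheme needs at least one category")
  if (is.null(names(cats)) || any(!nzchar(names(cats))))
    return("categories must be named")
  if (anyDuplicated(names(cats))) return("category names must be unique")
  seeds <- unlist(cats, use.names = FALSE)
  if (anyDuplicated(seeds)) {
    dup <- unique(seeds[duplicated(seeds)])
    return(sprintf("seed term(s) assigned to more than one category: %s",
                   paste(dup, collapse = ", ")))
  }
  TRUE
})

#' Category anchor map
#'
#' For every term, the set of (category, anchor) pairs available for
#' similarity scoring: an anchor is an ancestor-or-self of the term that is
#' either a user seed of the category or a term previously resolved to that
#' single category during top-down propagation. Terms whose anchors span
#' exactly one category are recorded in `singleCategory` and themselves act
#' as anchors for their descendants.
#'
#' Construct with [buildAnchorMap()].
#'
#' @slot anchors named list, term id -> data.frame(category, anchor).
#' @slot singleCategory named character, term id -> category, defined iff
#'   the term's anchor categories span exactly one category.
#' @slot scheme the [CategoryScheme-class] the map was built from.
#' @export
setClass("AnchorMap",
  slots = c(anchors = "list", singleCategory = "character", scheme = "CategoryScheme")
)

#' Per-gene category assignments
#'
#' The result of categorizing a set of genes: one row per (gene, category)
#' with the semantic-similarity score and the annotated term that supports
#' it. Genes with no category-covered annotation are unclassified: they
#' appear in `genes` but have no rows in `table`.
#'
#' Construct with [categorizeGenes()] or [randomBaseline()].
#'
#' @slot table data.frame with columns `gene`, `category`, `score`, `term`.
#' @slot genes character vector of all genes that were submitted.
#' @slot mode `"best"` or `"multi"`.
#' @slot threshold multi-assignment score cutoff in `[0, 1]`.
#' @seealso [assignmentTable()], [categoryCounts()], [enrichmentTest()]
#' @export
setClass("GeneAssignments",
  slots = c(
    table = "data.frame",
    genes = "character",
    mode = "character",
    threshold = "numeric"
  )
)

setValidity("GeneAssignments", function(object) {
  tab <- object@table
  msgs <- character()
  if (!all(c("gene", "category", "score", "term") %in% names(tab)))
    msgs <- c(msgs, "table must have columns gene, category, score, term")
  if (nrow(tab)) {
    if (anyDuplicated(tab[c("gene", "category")]))
      msgs <- c(msgs, "at most one entry per category per gene")
    if (any(tab$score < 0 | tab$score > 1, na.rm = TRUE))
      msgs <- c(msgs, "scores must lie in [0, 1]")
    if (!all(tab$gene %in% object@genes))
      msgs <- c(msgs, "every assigned gene must appear in the gene list")
  }
  if (length(msgs)) msgs else TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "OntologyGraph", function(object) {
  tt <- object@termTable
  cat(sprintf("OntologyGraph with %d terms (%d obsolete), %d edges\n",
              nrow(tt), sum(tt$obsolete), nrow(object@edgeTable)))
  for (ns in names(object@roots))
    cat(sprintf("  namespace %-20s root %s (%d terms)\n",
                ns, object@roots[[ns]], sum(tt$namespace == ns & !tt$obsolete)))
  if (length(object@altIds))
    cat(sprintf("  %d alternative ids mapped\n", length(object@altIds)))
})

setMethod("show", "AnnotationSet", function(object) {
  cat(sprintf("AnnotationSet: %d records, %d genes, %d unique terms\n",
              nrow(object@records), length(unique(object@records$gene)),
              length(unique(object@records$term))))
  if (nrow(object@unresolved))
    cat(sprintf("  %d unresolved input records retained for inspection\n",
                nrow(object@unresolved)))
})

setMethod("show", "ICTable", function(object) {
  cat(sprintf("ICTable over %d terms (%d annotation records, log base %s)\n",
              length(object@ic), object@meta$nRecords,
              format(object@meta$logBase)))
  for (ns in names(object@meta$nsTotals))
    cat(sprintf("  namespace %-20s %d records\n", ns,
                object@meta$nsTotals[[ns]]))
})

setMethod("show", "CategoryScheme", function(object) {
  cat(sprintf("CategoryScheme '%s': %d categories, %d seed terms\n",
              object@name, length(object@categories),
              length(unlist(object@categories))))
})

setMethod("show", "AnchorMap", function(object) {
  nAnch <- sum(vapply(object@anchors, nrow, integer(1)))
  cat(sprintf(
    "AnchorMap: %d terms with anchors (%d pairs), %d single-category terms\n",
    sum(vapply(object@anchors, nrow, integer(1)) > 0), nAnch,
    length(object@singleCategory)))
})

setMethod("show", "GeneAssignments", function(object) {
  counts <- categoryCounts(object)
  cat(sprintf(
    "GeneAssignments: %d genes, mode '%s', threshold %.2f\n",
    length(object@genes), object@mode, object@threshold))
  cat(sprintf("  %d assignments over %d categories; %d unclassified\n",
              nrow(object@table), length(counts),
              attr(counts, "unclassified")))
})

## ---- accessors ----------------------------------------------------------

#' @rdname termInfo
#' @export
setMethod("termInfo", "OntologyGraph", function(x) x@termTable)

#' @rdname edgeTable
#' @export
setMethod("edgeTable", "OntologyGraph", function(x) x@edgeTable)

#' @rdname rootTerms
#' @export
setMethod("rootTerms", "OntologyGraph", function(x) x@roots)

#' @rdname annRecords
#' @export
setMethod("annRecords", "AnnotationSet", function(x) x@records)

#' @rdname annGenes
#' @export
setMethod("annGenes", "AnnotationSet", function(x) unique(x@records$gene))

#' @rdname icValues
#' @export
setMethod("icValues", "ICTable", function(x) x@ic)

#' @rdname termProb
#' @export
setMethod("termProb", "ICTable", function(x) x@p)

#' @rdname categories
#' @export
setMethod("categories", "CategoryScheme", function(x) x@categories)

#' @rdname assignmentTable
#' @export
setMethod("assignmentTable", "GeneAssignments", function(x) x@table)

#' @rdname categoryCounts
#' @export
setMethod("categoryCounts", "GeneAssignments", function(x) {
  tab <- x@table
  cats <- sort(unique(tab$category))
  counts <- vapply(cats, function(cc)
    length(unique(tab$gene[tab$category == cc])), integer(1))
  counts <- stats::setNames(as.integer(counts), cats)
  attr(counts, "unclassified") <-
    length(setdiff(x@genes, unique(tab$gene)))
  counts
})

#' Construct a category scheme
#'
#' @param categories named list mapping category names to character vectors
#'   of seed term ids.
#' @param name scheme name.
#' @param graph optional [OntologyGraph-class]; when given, every seed id is
#'   resolved (alternative ids mapped to primary) and unresolvable seeds
#'   raise an error.
#' @return A [CategoryScheme-class].
#' @examples
#' toy <- toyInstance()
#' CategoryScheme(list(A = "G22", B = "G23"), graph = toy$graph)
#' @export
CategoryScheme <- function(categories, name = "scheme", graph = NULL) {
  categories <- lapply(categories, function(x) unique(as.character(x)))
  if (!is.null(graph)) {
    categories <- lapply(categories, function(ids) resolveTermIds(graph, ids))
    known <- termInfo(graph)$id
    bad <- setdiff(unlist(categories), known)
    if (length(bad))
      stop("seed term(s) not present in the graph: ",
           paste(bad, collapse = ", "))
  }
  new("CategoryScheme", name = name, categories = categories)
}
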