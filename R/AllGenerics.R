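#' Ancestors of a term
#'
#' Transitive closure of the parent relation: every term reachable from
#' `term` by following child-to-parent edges. The term itself is excluded.
#'
#' @param x an [OntologyGraph-class].
#' @param term a single term identifier.
#' @return Character vector of proper ancestor ids (possibly empty).
#' @seealso [descendants()]
#' @export
setGeneric("ancestors", function(x, term) standardGeneric("ancestors"))

#' Descendants of a term
#'
#' Transitive closure of the child relation; the term itself is excluded.
#'
#' @param x an [OntologyGraph-class].
#' @param term a single term identifier.
#' @return Character vector of proper descendant ids (possibly empty).
#' @seealso [ancestors()]
#' @export
setGeneric("descendants", function(x, term) standardGeneric("descendants"))

#' Term metadata table
#'
#' @param x an [OntologyGraph-class].
#' @return A data.frame with columns `id`, `name`, `namespace`, `obsolete`.
#' @export
setGeneric("termInfo", function(x) standardGeneric("termInfo"))

#' Edge table of an ontology
#'
#' @param x an [OntologyGraph-class].
#' @return A data.frame with columns `child`, `parent`, `relation`.
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' Namespace roots
#'
#' @param x an [OntologyGraph-class].
#' @return Named character vector mapping namespace to its root term id.
#' @export
setGeneric("rootTerms", function(x) standardGeneric("rootTerms"))

#' Annotation records
#'
#' @param x an [AnnotationSet-class].
#' @return A data.frame with columns `gene`, `term`.
#' @export
setGeneric("annRecords", function(x) standardGeneric("annRecords"))

#' Annotated genes
#'
#' @param x an [AnnotationSet-class].
#' @return Character vector of distinct gene ids.
#' @export
setGeneric("annGenes", function(x) standardGeneric("annGenes"))

#' Information content values
#'
#' @param x an [ICTable-class].
#' @return Named numeric vector of per-term information content.
#' @export
setGeneric("icValues", function(x) standardGeneric("icValues"))

#' Term occurrence probabilities
#'
#' @param x an [ICTable-class].
#' @return Named numeric vector of per-term occurrence probabilities.
#' @export
setGeneric("termProb", function(x) standardGeneric("termProb"))

#' Category definitions of a scheme
#'
#' @param x a [CategoryScheme-class].
#' @return Named list mapping category name to its seed term ids.
#' @export
setGeneric("categories", function(x) standardGeneric("categories"))

#' Per-gene assignment table
#'
#' @param x a [GeneAssignments-class].
#' @return A data.frame with columns `gene`, `category`, `score`, `term`.
#' @export
setGeneric("assignmentTable", function(x) standardGeneric("assignmentTable"))

#' Per-category gene counts
#'
#' Number of distinct genes assigned to each category (a gene assigned to
#' several categories counts once in each), plus the number of genes with no
#' assignment at all under the attribute `unclassified`.
#'
#' @param x a [GeneAssignments-class].
#' @return Named integer vector of category counts with an `unclassified`
#'   attribute.
#' @export
setGeneric("categoryCounts", function(x) standardGeneric("categoryCounts"))
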