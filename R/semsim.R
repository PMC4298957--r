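## Specialized semantic similarity between a term and a category-assigned
## ancestor ("anchor"), built from three information-content distances:
##
##   alpha — depth of the anchor: IC distance from the namespace root,
##   beta  — mean IC distance of term and anchor to their most informative
##           descendants (a leaf is its own most informative descendant),
##   gamma — IC distance between anchor and term.
##
##   S = alpha / (alpha + beta) * 1 / (1 + gamma),  0 <= S <= 1.
##
## A deep anchor (large alpha) whose subtree adds little extra information
## (small beta) and that sits close to the query term (small gamma) scores
## high: the term fits snugly into a specific category.

isAncestorOrSelf <- function(graph, a, x) {
  a == x || a %in% ancestors(graph, x)
}

lookupIC <- function(table, id) {
  if (!id %in% names(table@ic)) stop("term not in IC table: ", id)
  table@ic[[id]]
}

#' IC distance between two terms on one lineage
#'
#' The absolute difference in information content; defined only for terms
#' in an ancestor-descendant (or identity) relation.
#'
#' @param graph an [OntologyGraph-class].
#' @param table an [ICTable-class].
#' @param x1,x2 term ids, one an ancestor-or-self of the other.
#' @return Nonnegative numeric.
#' @examples
#' toy <- toyInstance()
#' icDistance(toy$graph, toy$ic, "G22", "G43")  # 13.90 - 12.20
#' @export
icDistance <- function(graph, table, x1, x2) {
  if (!isAncestorOrSelf(graph, x1, x2) && !isAncestorOrSelf(graph, x2, x1))
    stop("terms are not in an ancestor-descendant relation: ",
         x1, ", ", x2)
  abs(lookupIC(table, x1) - lookupIC(table, x2))
}

#' Most informative descendant of a term
#'
#' The proper descendant with maximal information content; a leaf is its
#' own most informative descendant. Ties are broken by lexicographic term
#' id for determinism.
#'
#' @param graph an [OntologyGraph-class].
#' @param table an [ICTable-class].
#' @param x a term id.
#' @return A term id.
#' @examples
#' toy <- toyInstance()
#' mostInformativeDescendant(toy$graph, toy$ic, "G22")  # "G43"
#' @export
mostInformativeDescendant <- function(graph, table, x) {
  desc <- descendants(graph, x)
  if (!length(desc)) return(x)
  icd <- vapply(desc, function(d) lookupIC(table, d), numeric(1))
  best <- desc[icd == max(icd)]
  sort(best)[1]
}

#' Anchor depth (alpha)
#'
#' IC distance of the anchor term from its namespace root; since the root
#' has information content 0 this equals the anchor's own IC.
#'
#' @param table an [ICTable-class].
#' @param p the anchor term id.
#' @return Nonnegative numeric.
#' @export
simAlpha <- function(table, p) {
  lookupIC(table, p)
}

#' Subtree-information distance (beta)
#'
#' Mean IC distance of the query term and its anchor to their respective
#' most informative descendants.
#'
#' @param graph an [OntologyGraph-class].
#' @param table an [ICTable-class].
#' @param x the query term id.
#' @param p the anchor term id; must be an ancestor of `x` (or `x` itself).
#' @return Nonnegative numeric.
#' @examples
#' toy <- toyInstance()
#' simBeta(toy$graph, toy$ic, "G32", "G22")  # 1.28
#' @export
simBeta <- function(graph, table, x, p) {
  if (!isAncestorOrSelf(graph, p, x))
    stop("anchor ", p, " is not an ancestor of ", x)
  dp <- icDistance(graph, table, p, mostInformativeDescendant(graph, table, p))
  dx <- icDistance(graph, table, x, mostInformativeDescendant(graph, table, x))
  (dp + dx) / 2
}

#' Anchor-to-term distance (gamma)
#'
#' IC difference between the query term and its anchor.
#'
#' @inheritParams simBeta
#' @return Nonnegative numeric.
#' @examples
#' toy <- toyInstance()
#' simGamma(toy$graph, toy$ic, "G32", "G22")  # 0.11
#' @export
simGamma <- function(graph, table, x, p) {
  if (!isAncestorOrSelf(graph, p, x))
    stop("anchor ", p, " is not an ancestor of ", x)
  max(lookupIC(table, x) - lookupIC(table, p), 0)
}

#' Semantic similarity of a term to a category anchor
#'
#' Combines the three IC distances into
#' `S = alpha/(alpha + beta) * 1/(1 + gamma)`, clamped to `[0, 1]`. In the
#' degenerate case `alpha + beta = 0` (a root-level anchor with no
#' informative descendants) `S = 1/(1 + gamma)` with a warning.
#'
#' @inheritParams simBeta
#' @return A list with components `alpha`, `beta`, `gamma`, `s`.
#' @examples
#' toy <- toyInstance()
#' termSimilarity(toy$graph, toy$ic, "G32", "G22")$s  # 0.815
#' @export
termSimilarity <- function(graph, table, x, p) {
  if (!isAncestorOrSelf(graph, p, x))
    stop("anchor ", p, " is not an ancestor of ", x)
  alpha <- simAlpha(table, p)
  beta <- simBeta(graph, table, x, p)
  gamma <- simGamma(graph, table, x, p)
  if (alpha + beta == 0) {
    warning("anchor ", p, " has zero depth and zero subtree information; ",
            "similarity reduces to 1/(1 + gamma)")
    s <- 1 / (1 + gamma)
  } else {
    s <- alpha / (alpha + beta) * 1 / (1 + gamma)
  }
  list(alpha = alpha, beta = beta, gamma = gamma,
       s = min(max(s, 0), 1))
}
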