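# Independent brute-force references used to cross-check the package's
# traversal, propagation and categorization code paths. These work only
# from the edge table, one step at a time, never through the package's
# own closure machinery.

# direct parents / children from the edge table
edgeParents <- function(graph, term) {
  et <- edgeTable(graph)
  unique(et$parent[et$child == term])
}
edgeChildren <- function(graph, term) {
  et <- edgeTable(graph)
  unique(et$child[et$parent == term])
}

# ancestor closure via repeated single-step parent expansion
naiveAncestors <- function(graph, term) {
  seen <- character()
  frontier <- edgeParents(graph, term)
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(
      unique(unlist(lapply(frontier, edgeParents, graph = graph))), seen)
  }
  seen
}

# per-record accumulation over the naive ancestor closure
naivePropagate <- function(graph, ann) {
  live <- termInfo(graph)$id[!termInfo(graph)$obsolete]
  counts <- setNames(integer(length(live)), live)
  rec <- annRecords(ann)
  for (i in seq_len(nrow(rec))) {
    up <- unique(c(rec$term[i], naiveAncestors(graph, rec$term[i])))
    counts[up] <- counts[up] + 1L
  }
  counts
}

# definitional term categorization: enumerate every (labelled ancestor,
# category) pair and recompute S from the alpha/beta/gamma formulas
naiveCategorizeTerm <- function(graph, table, scheme, term) {
  seeds <- categories(scheme)
  seedCat <- setNames(rep(names(seeds), lengths(seeds)), unlist(seeds))

  # resolve single-category terms top-down, exactly as defined: inherited
  # labelled-ancestor pairs only
  labels <- seedCat
  # a child always has strictly more ancestors than each of its parents,
  # so ascending ancestor count is a valid topological order
  ord <- names(sort(sapply(
    termInfo(graph)$id[!termInfo(graph)$obsolete],
    function(t) length(naiveAncestors(graph, t)), USE.NAMES = TRUE)))
  for (t in ord) {
    if (t %in% names(seedCat)) { labels[t] <- seedCat[[t]]; next }
    anc <- naiveAncestors(graph, t)
    cats <- unique(unname(labels[intersect(anc, names(labels))]))
    if (length(cats) == 1L) labels[t] <- cats
  }

  if (term %in% names(labels))
    return(data.frame(category = unname(labels[term]), score = 1))
  anc <- intersect(naiveAncestors(graph, term), names(labels))
  if (!length(anc))
    return(data.frame(category = character(), score = numeric()))
  ics <- icValues(table)
  sOf <- function(anchor) {
    micOf <- function(x) {
      desc <- character()
      frontier <- edgeChildren(graph, x)
      while (length(frontier)) {
        desc <- union(desc, frontier)
        frontier <- setdiff(
          unique(unlist(lapply(frontier, edgeChildren, graph = graph))),
          desc)
      }
      if (!length(desc)) return(x)
      sort(desc[ics[desc] == max(ics[desc])])[1]
    }
    alpha <- ics[[anchor]]
    beta <- ((ics[[micOf(anchor)]] - ics[[anchor]]) +
             (ics[[micOf(term)]] - ics[[term]])) / 2
    gamma <- ics[[term]] - ics[[anchor]]
    if (alpha + beta == 0) 1 / (1 + gamma)
    else alpha / (alpha + beta) / (1 + gamma)
  }
  perCat <- tapply(vapply(anc, sOf, numeric(1)),
                   unname(labels[anc]), max)
  out <- data.frame(category = names(perCat),
                    score = pmin(pmax(as.numeric(perCat), 0), 1))
  out[order(-out$score, out$category), , drop = FALSE]
}

toyTwoRecordAnnotation <- function() {
  AnnotationSet(c("p1", "p2"), c("G21", "G22"))
}
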