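## Ontology parsing and DAG queries.
##
## Edges are stored child -> parent; traversal follows the true-path
## relations is_a and part_of by default.

SUPPORTED_RELATIONS <- c("is_a", "part_of")

## Assemble and validate an OntologyGraph from term and edge tables.
makeOntologyGraph <- function(termTable, edgeTable, altIds = character()) {
  termTable$id <- as.character(termTable$id)
  rownames(termTable) <- NULL
  live <- termTable[!termTable$obsolete, , drop = FALSE]

  ## drop edges touching obsolete/unknown terms or crossing namespaces
  if (nrow(edgeTable)) {
    edgeTable <- unique(edgeTable)
    keep <- edgeTable$child %in% live$id & edgeTable$parent %in% live$id
    if (any(!keep)) {
      warning(sum(!keep), " edge(s) dropped: endpoint obsolete or unknown")
      edgeTable <- edgeTable[keep, , drop = FALSE]
    }
    ns <- stats::setNames(live$namespace, live$id)
    same <- ns[edgeTable$child] == ns[edgeTable$parent]
    if (any(!same)) {
      warning(sum(!same), " cross-namespace edge(s) dropped")
      edgeTable <- edgeTable[same, , drop = FALSE]
    }
    rownames(edgeTable) <- NULL
  }

  g <- igraph::graph_from_data_frame(
    edgeTable[c("child", "parent")],
    directed = TRUE,
    vertices = data.frame(name = live$id)
  )
  if (!igraph::is_dag(g)) {
    member <- igraph::feedback_arc_set(g)
    inCycle <- if (length(member))
      igraph::ends(g, member)[1, 1] else live$id[1]
    stop("cycle detected in ontology (involves term ", inCycle, ")")
  }

  ## roots: the parentless non-obsolete term of each namespace
  outdeg <- igraph::degree(g, mode = "out")
  parentless <- live$id[outdeg[live$id] == 0]
  roots <- character()
  for (nsName in unique(live$namespace)) {
    r <- parentless[live$namespace[match(parentless, live$id)] == nsName]
    if (length(r) != 1L)
      stop("namespace '", nsName, "' must have exactly one root, found ",
           length(r), if (length(r)) paste0(": ", paste(r, collapse = ", "))
           else "")
    roots[[nsName]] <- r
  }

  new("OntologyGraph", termTable = termTable, edgeTable = edgeTable,
      roots = roots, altIds = altIds, graph = g)
}

#' Parse an OBO ontology file
#'
#' Reads an OBO 1.2/1.4 flat file into an [OntologyGraph-class]. Obsolete
#' terms are retained in the term table but excluded from all edges;
#' `alt_id` entries become aliases of the primary id; cross-namespace edges
#' are dropped with a warning; acyclicity is verified.
#'
#' @param path path to the OBO file.
#' @param relations relations to keep as child-parent edges; subset of
#'   `is_a` and `part_of` (the two relations obeying the true-path rule).
#' @return An [OntologyGraph-class].
#' @examples
#' obo <- file.path(tempdir(), "toy.obo")
#' writeOBO(toyInstance()$graph, obo)
#' parseOBO(obo)
#' @export
parseOBO <- function(path, relations = SUPPORTED_RELATIONS) {
  if (!all(relations %in% SUPPORTED_RELATIONS))
    stop("unsupported relation(s) requested: ",
         paste(setdiff(relations, SUPPORTED_RELATIONS), collapse = ", "),
         " (supported: ", paste(SUPPORTED_RELATIONS, collapse = ", "), ")")
  if (!file.exists(path)) stop("cannot read OBO file: ", path)
  lines <- readLines(path, warn = FALSE)

  ## split into [Term] stanzas
  stanzaStarts <- grep("^\\[", lines)
  termStarts <- grep("^\\[Term\\]$", lines)
  ids <- names <- namespaces <- character()
  obsolete <- logical()
  edges <- list()
  altIds <- character()

  for (s in termStarts) {
    nxt <- stanzaStarts[stanzaStarts > s]
    end <- if (length(nxt)) min(nxt) - 1L else length(lines)
    block <- lines[(s + 1L):end]
    block <- block[nzchar(block) & !startsWith(block, "!")]
    kv <- regmatches(block, regexpr("^[a-z_]+:", block))
    key <- sub(":$", "", kv)
    val <- trimws(sub("^[a-z_]+:", "", block))
    val <- sub("\\s*!.*$", "", val)  # trailing comments

    id <- val[key == "id"][1]
    if (is.na(id)) stop("OBO [Term] stanza without id near line ", s)
    obs <- any(key == "is_obsolete" & val == "true")
    ids <- c(ids, id)
    nm <- val[key == "name"]
    names <- c(names, if (length(nm)) nm[1] else id)
    nsv <- val[key == "namespace"]
    namespaces <- c(namespaces, if (length(nsv)) nsv[1] else "default")
    obsolete <- c(obsolete, obs)

    alt <- val[key == "alt_id"]
    if (length(alt)) altIds[alt] <- id

    if (!obs) {
      if ("is_a" %in% relations) {
        for (p in val[key == "is_a"])
          edges[[length(edges) + 1L]] <- c(id, p, "is_a")
      }
      for (rel in val[key == "relationship"]) {
        parts <- strsplit(trimws(rel), "\\s+")[[1]]
        if (length(parts) >= 2 && parts[1] %in% relations)
          edges[[length(edges) + 1L]] <- c(id, parts[2], parts[1])
      }
    }
  }
  if (!length(ids)) stop("no [Term] stanzas found in ", path)

  edgeTable <- if (length(edges)) {
    m <- do.call(rbind, edges)
    data.frame(child = m[, 1], parent = m[, 2], relation = m[, 3])
  } else {
    data.frame(child = character(), parent = character(),
               relation = character())
  }
  termTable <- data.frame(id = ids, name = names, namespace = namespaces,
                          obsolete = obsolete)
  ## keep only the first stanza per id (duplicate ids are malformed input)
  termTable <- termTable[!duplicated(termTable$id), , drop = FALSE]
  altIds <- altIds[!names(altIds) %in% termTable$id]
  makeOntologyGraph(termTable, edgeTable, altIds)
}

#' Read a toy ontology from an edge list TSV
#'
#' Three tab-separated columns: child, parent, relation (lines starting
#' with `#` ignored). All terms share one namespace.
#'
#' @param path path to the TSV file.
#' @param namespace namespace assigned to every term.
#' @return An [OntologyGraph-class].
#' @export
readEdgeTSV <- function(path, namespace = "toy") {
  if (!file.exists(path)) stop("cannot read edge TSV: ", path)
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          col.names = c("child", "parent", "relation"),
                          colClasses = "character")
  if (!nrow(df)) stop("empty edge list: ", path)
  ids <- unique(c(df$child, df$parent))
  termTable <- data.frame(id = ids, name = ids, namespace = namespace,
                          obsolete = FALSE)
  makeOntologyGraph(termTable, df)
}

#' Serialize an ontology to OBO
#'
#' Writes a minimal OBO 1.2 file (id, name, namespace, is_a /
#' relationship lines) that [parseOBO()] reads back to the same term and
#' edge set.
#'
#' @param graph an [OntologyGraph-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeOBO <- function(graph, path) {
  tt <- termInfo(graph)
  et <- edgeTable(graph)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(tt))) {
    writeLines("[Term]", con)
    writeLines(paste0("id: ", tt$id[i]), con)
    writeLines(paste0("name: ", tt$name[i]), con)
    writeLines(paste0("namespace: ", tt$namespace[i]), con)
    if (tt$obsolete[i]) writeLines("is_obsolete: true", con)
    sel <- et[et$child == tt$id[i], , drop = FALSE]
    for (j in seq_len(nrow(sel))) {
      if (sel$relation[j] == "is_a")
        writeLines(paste0("is_a: ", sel$parent[j]), con)
      else
        writeLines(paste0("relationship: ", sel$relation[j], " ",
                          sel$parent[j]), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

## Map alternative ids to primary ids; unknown ids pass through unchanged.
resolveTermIds <- function(graph, ids) {
  hit <- ids %in% names(graph@altIds)
  ids[hit] <- graph@altIds[ids[hit]]
  ids
}

checkTermKnown <- function(x, term) {
  if (length(term) != 1L) stop("exactly one term id expected")
  term <- resolveTermIds(x, term)
  tt <- x@termTable
  if (!term %in% tt$id) stop("unknown term id: ", term)
  if (tt$obsolete[match(term, tt$id)])
    stop("term is obsolete and carries no edges: ", term)
  term
}

#' @rdname ancestors
#' @examples
#' toy <- toyInstance()
#' ancestors(toy$graph, "G41")
#' @export
setMethod("ancestors", "OntologyGraph", function(x, term) {
  term <- checkTermKnown(x, term)
  reach <- igraph::subcomponent(x@graph, term, mode = "out")$name
  setdiff(reach, term)
})

#' @rdname descendants
#' @examples
#' toy <- toyInstance()
#' descendants(toy$graph, "G22")
#' @export
setMethod("descendants", "OntologyGraph", function(x, term) {
  term <- checkTermKnown(x, term)
  reach <- igraph::subcomponent(x@graph, term, mode = "in")$name
  setdiff(reach, term)
})

## Non-obsolete term ids in topological order, parents before children.
topologicalOrder <- function(graph) {
  ord <- igraph::topo_sort(graph@graph, mode = "in")$name
  ord
}

## namespace lookup for non-obsolete terms
namespaceOf <- function(graph, ids) {
  tt <- graph@termTable
  stats::setNames(tt$namespace[match(ids, tt$id)], ids)
}
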