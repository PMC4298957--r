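## True-path count propagation and information content.
##
## An annotation to a term is also an annotation to every ancestor of that
## term, so occurrence counts are accumulated over the ancestor closure and
## converted to probabilities per namespace: the namespace root always has
## p = 1 and information content 0.

#' Propagate annotation counts up the ontology
#'
#' `count(x)` is the number of annotation records whose term is `x` or a
#' descendant of `x`; each record contributes at most once per term. The
#' count at a namespace root equals the number of records in that
#' namespace.
#'
#' @param graph an [OntologyGraph-class].
#' @param ann an [AnnotationSet-class]; all record terms must be in the
#'   graph.
#' @return Named integer vector over all non-obsolete terms (zeros for
#'   terms under which nothing is annotated).
#' @examples
#' toy <- toyInstance()
#' ann <- AnnotationSet(c("p1", "p2"), c("G21", "G22"))
#' propagateCounts(toy$graph, ann)[c("G0", "G11", "G21", "G22")]
#' @export
propagateCounts <- function(graph, ann) {
  live <- termInfo(graph)$id[!termInfo(graph)$obsolete]
  rec <- annRecords(ann)
  bad <- setdiff(unique(rec$term), live)
  if (length(bad))
    stop("annotation term(s) not in graph: ", paste(bad, collapse = ", "))
  counts <- stats::setNames(integer(length(live)), live)
  if (!nrow(rec)) return(counts)
  direct <- table(rec$term)
  for (tm in names(direct)) {
    up <- c(tm, ancestors(graph, tm))
    counts[up] <- counts[up] + as.integer(direct[[tm]])
  }
  counts
}

#' Compute occurrence probabilities and information content
#'
#' `p(x) = count(x) / T`, with `T` the number of annotation records in
#' `x`'s namespace, and `I(x) = -log p(x)`. Terms never used in the corpus
#' (orphans) receive the smallest nonzero probability of their namespace,
#' i.e. the maximal observed information content.
#'
#' @param graph an [OntologyGraph-class].
#' @param counts propagated counts from [propagateCounts()].
#' @param logBase base of the logarithm (default natural log).
#' @return An [ICTable-class].
#' @examples
#' toy <- toyInstance()
#' ann <- AnnotationSet(c("p1", "p2"), c("G21", "G22"))
#' ic <- computeIC(toy$graph, propagateCounts(toy$graph, ann))
#' icValues(ic)["G0"]  # root: 0
#' @export
computeIC <- function(graph, counts, logBase = exp(1)) {
  ns <- namespaceOf(graph, names(counts))
  roots <- rootTerms(graph)
  nsTotals <- vapply(names(roots), function(n) as.integer(counts[[roots[[n]]]]),
                     integer(1))
  empty <- names(nsTotals)[nsTotals == 0L]
  if (length(empty))
    stop("no annotation records in namespace(s): ",
         paste(empty, collapse = ", "))

  p <- counts / nsTotals[ns]
  for (n in names(nsTotals)) {
    inNs <- ns == n
    nz <- p[inNs & p > 0]
    if (any(inNs & p == 0))
      p[inNs & p == 0] <- min(nz)
  }
  ic <- -log(p) / log(logBase)
  ic[ic < 0] <- 0  # guard against -0
  new("ICTable", p = p, ic = ic, namespace = ns,
      meta = list(nRecords = sum(nsTotals), nsTotals = nsTotals,
                  logBase = logBase))
}

#' Write an information-content table to TSV
#'
#' Plain TSV with `#meta:` header lines carrying the corpus record counts
#' and log base, then columns `term`, `namespace`, `p`, `ic`. Values are
#' written with 15 significant digits so a save/load round trip preserves
#' them to at least 12 significant digits.
#'
#' @param table an [ICTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [readICTable()]
#' @export
writeICTable <- function(table, path) {
  meta <- table@meta
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#meta: nRecords=%d", meta$nRecords), con)
  writeLines(sprintf("#meta: nsTotals=%s",
                     paste(sprintf("%s=%d", names(meta$nsTotals),
                                   meta$nsTotals), collapse = ",")), con)
  writeLines(sprintf("#meta: logBase=%.15g", meta$logBase), con)
  writeLines("term\tnamespace\tp\tic", con)
  writeLines(sprintf("%s\t%s\t%.15g\t%.15g", names(table@p),
                     table@namespace, table@p, table@ic), con)
  invisible(path)
}

#' Read an information-content table from TSV
#'
#' @param path path written by [writeICTable()].
#' @param graph optional [OntologyGraph-class]; when given, terms in the
#'   file but not in the graph trigger a warning (they are retained), and a
#'   mismatch between the file's per-namespace totals and the graph's
#'   namespaces triggers a warning.
#' @return An [ICTable-class].
#' @export
readICTable <- function(path, graph = NULL) {
  if (!file.exists(path)) stop("cannot read IC table: ", path)
  lines <- readLines(path, warn = FALSE)
  metaLines <- lines[startsWith(lines, "#meta:")]
  meta <- list(nRecords = NA_integer_, nsTotals = integer(), logBase = exp(1))
  asInt <- function(x) {  # "NA" marks an injected table without a corpus
    x[x == "NA"] <- NA_character_
    as.integer(x)
  }
  for (ml in metaLines) {
    kv <- trimws(sub("^#meta:", "", ml))
    key <- sub("=.*$", "", kv)
    val <- sub("^[^=]*=", "", kv)
    if (key == "nRecords") meta$nRecords <- asInt(val)
    if (key == "logBase") meta$logBase <- as.numeric(val)
    if (key == "nsTotals") {
      parts <- strsplit(val, ",", fixed = TRUE)[[1]]
      meta$nsTotals <- stats::setNames(
        asInt(sub("^[^=]*=", "", parts)), sub("=.*$", "", parts))
    }
  }
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) stop("IC table has no data rows: ", path)
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  required <- c("term", "namespace", "p", "ic")
  missing <- setdiff(required, header)
  if (length(missing))
    stop("IC table is missing required column(s): ",
         paste(missing, collapse = ", "))
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          colClasses = "character")
  p <- stats::setNames(as.numeric(df$p), df$term)
  ic <- stats::setNames(as.numeric(df$ic), df$term)
  ns <- stats::setNames(df$namespace, df$term)
  if (!is.null(graph)) {
    known <- termInfo(graph)$id
    extra <- setdiff(df$term, known)
    if (length(extra))
      warning(length(extra), " IC table term(s) not in the graph; retained")
    if (!setequal(names(meta$nsTotals), names(rootTerms(graph))))
      warning("IC table namespaces do not match the graph's namespaces")
  }
  new("ICTable", p = p, ic = ic, namespace = ns, meta = meta)
}
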