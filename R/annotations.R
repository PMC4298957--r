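## Gene-to-GO annotation input: GAF 2.x and plain 2-column TSV.

#' Load gene-to-term annotations
#'
#' Reads a GAF 2.x file (17 columns, `!` comment lines; records qualified
#' with `NOT` are excluded) or a 2-column TSV (gene, term id). Term ids are
#' resolved against the graph (alternative ids mapped to primary ids);
#' records whose term is unknown are retained in the `unresolved` slot and
#' reported, never silently dropped. Duplicate (gene, term) pairs are
#' deduplicated.
#'
#' @param path path to the annotation file.
#' @param graph an [OntologyGraph-class] used to resolve term ids.
#' @param format `"auto"` (GAF detected by a `!gaf-version` header),
#'   `"gaf"`, or `"tsv"`.
#' @param excludeEvidence optional character vector of GAF evidence codes
#'   to drop (e.g. `"IEA"`).
#' @return An [AnnotationSet-class].
#' @examples
#' toy <- toyInstance()
#' tsv <- file.path(tempdir(), "ann.tsv")
#' writeLines(c("p1\tG21", "p2\tG22"), tsv)
#' loadAnnotations(tsv, toy$graph)
#' @export
loadAnnotations <- function(path, graph, format = c("auto", "gaf", "tsv"),
                            excludeEvidence = character()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read annotation file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    format <- if (any(startsWith(lines, "!gaf-version"))) "gaf" else "tsv"
  }

  if (format == "gaf") {
    body <- lines[!startsWith(lines, "!") & nzchar(lines)]
    if (!length(body)) stop("annotation file contains no records: ", path)
    fields <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(fields)
    bad <- which(nf < 15L)
    if (length(bad))
      stop("malformed GAF line ", which(!startsWith(lines, "!") &
           nzchar(lines))[bad[1]], ": expected >= 15 columns, got ",
           nf[bad[1]])
    gene <- vapply(fields, `[[`, character(1), 3L)   # DB object symbol
    qualifier <- vapply(fields, `[[`, character(1), 4L)
    term <- vapply(fields, `[[`, character(1), 5L)
    evidence <- vapply(fields, `[[`, character(1), 7L)
    keep <- !grepl("(^|\\|)NOT($|\\|)", qualifier)
    if (length(excludeEvidence))
      keep <- keep & !(evidence %in% excludeEvidence)
    df <- data.frame(gene = gene[keep], term = term[keep])
  } else {
    body <- lines[!startsWith(lines, "#") & nzchar(lines)]
    if (!length(body)) stop("annotation file contains no records: ", path)
    fields <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 2L))
      stop("malformed TSV line ", which(nf < 2L)[1],
           ": expected 2 tab-separated columns")
    df <- data.frame(gene = vapply(fields, `[[`, character(1), 1L),
                     term = vapply(fields, `[[`, character(1), 2L))
  }

  df$term <- resolveTermIds(graph, df$term)
  known <- termInfo(graph)$id[!termInfo(graph)$obsolete]
  ok <- df$term %in% known
  unresolved <- unique(df[!ok, , drop = FALSE])
  if (nrow(unresolved))
    warning(nrow(unresolved), " annotation record(s) reference terms not ",
            "in the graph; kept in the unresolved slot")
  records <- unique(df[ok, , drop = FALSE])
  rownames(records) <- rownames(unresolved) <- NULL
  new("AnnotationSet", records = records, unresolved = unresolved)
}

#' Construct an annotation set from records
#'
#' @param gene,term character vectors of equal length.
#' @return An [AnnotationSet-class] (records deduplicated).
#' @export
AnnotationSet <- function(gene, term) {
  df <- unique(data.frame(gene = as.character(gene),
                          term = as.character(term)))
  rownames(df) <- NULL
  new("AnnotationSet", records = df,
      unresolved = data.frame(gene = character(), term = character()))
}
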