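## Synthetic instances: the worked toy ontology, random DAGs and
## annotation corpora, and spike-in test sets for enrichment controls.

#' The worked toy ontology instance
#'
#' An eleven-term single-namespace DAG with injected (not computed)
#' information content, two categories (A seeded at G22, B seeded at G23)
#' and a registry of the quantities the instance is constructed to
#' reproduce. The authoritative reference IC values are I(G0) = 0, I(G22) = 12.20,
#' I(G32) = 12.31, I(G41) = 13.17 and I(G43) = 13.90; the remaining terms
#' (G11, G21, G23, G31, G33, G42) carry synthetic placeholder ICs chosen
#' to respect edge monotonicity and are not authoritative.
#'
#' Topology: G0 is the root; G11 is the parent of G21, G22 and G23; G31
#' descends from G22 only; G32 from both G22 and G23; G41 from G32; G33
#' and G42 (via G33) from G23 only; G43 from G31 and G33.
#'
#' @return list with components `graph` ([OntologyGraph-class]), `ic`
#'   ([ICTable-class], injected), `scheme` ([CategoryScheme-class]) and
#'   `reference` (named list of reference quantities: the five authoritative
#'   IC values, the alpha/beta/gamma breakdown for the pair (G32, G22),
#'   the similarity scores of G32, G41 and G43 to anchor G22, the
#'   two-record propagation example, and the default threshold 0.3).
#' @examples
#' toy <- toyInstance()
#' termSimilarity(toy$graph, toy$ic, "G32", "G22")
#' @export
toyInstance <- function() {
  edges <- data.frame(
    child  = c("G11", "G21", "G22", "G23", "G31", "G32", "G32", "G33",
               "G41", "G42", "G43", "G43"),
    parent = c("G0",  "G11", "G11", "G11", "G22", "G22", "G23", "G23",
               "G32", "G33", "G31", "G33"),
    relation = "is_a")
  ids <- c("G0", "G11", "G21", "G22", "G23", "G31", "G32", "G33",
           "G41", "G42", "G43")
  termTable <- data.frame(id = ids, name = ids, namespace = "toy",
                          obsolete = FALSE)
  graph <- makeOntologyGraph(termTable, edges)

  ## reference ICs plus monotone synthetic placeholders for the rest
  ic <- c(G0 = 0, G11 = 2.50, G21 = 8.40, G22 = 12.20, G23 = 6.00,
          G31 = 12.23, G32 = 12.31, G33 = 11.75, G41 = 13.17,
          G42 = 12.80, G43 = 13.90)
  icTable <- new("ICTable", p = exp(-ic), ic = ic,
                 namespace = stats::setNames(rep("toy", length(ic)),
                                             names(ic)),
                 meta = list(nRecords = NA_integer_,
                             nsTotals = c(toy = NA_integer_),
                             logBase = exp(1), injected = TRUE))

  scheme <- CategoryScheme(list(A = "G22", B = "G23"), name = "toy-AB",
                           graph = graph)

  reference <- list(
    ic = c(G0 = 0, G22 = 12.20, G32 = 12.31, G41 = 13.17, G43 = 13.90),
    alpha_G22 = 12.20,
    beta_G32_G22 = 1.28,
    gamma_G32_G22 = 0.11,
    S_G22_G32 = 0.815,
    S_G22_G41 = 0.475,
    S_G22_G43 = 0.346,
    counts_two_records = c(G0 = 2L, G11 = 2L, G21 = 1L, G22 = 1L),
    default_threshold = 0.3
  )
  list(graph = graph, ic = icTable, scheme = scheme, reference = reference)
}

#' Generate a random ontology DAG
#'
#' A connected single-root DAG: term `i` (in generation order) picks 1 to
#' `maxParents` parents uniformly among the earlier terms, so a
#' topological order exists by construction. Deterministic per seed.
#'
#' @param nTerms number of terms (>= 2).
#' @param maxParents maximum parents per non-root term.
#' @param seed integer seed.
#' @param namespace namespace for all terms.
#' @return An [OntologyGraph-class].
#' @export
randomOntology <- function(nTerms, maxParents = 3, seed = 1,
                           namespace = "toy") {
  if (nTerms < 2) stop("nTerms must be >= 2")
  if (maxParents < 1) stop("maxParents must be >= 1")
  set.seed(seed)
  ids <- sprintf("T%04d", seq_len(nTerms))
  edges <- lapply(2:nTerms, function(i) {
    k <- sample.int(min(maxParents, i - 1L), 1)
    data.frame(child = ids[i],
               parent = ids[sample.int(i - 1L, k)],
               relation = "is_a")
  })
  edges <- do.call(rbind, edges)
  termTable <- data.frame(id = ids, name = ids, namespace = namespace,
                          obsolete = FALSE)
  makeOntologyGraph(termTable, edges)
}

#' Generate a synthetic annotation corpus
#'
#' Annotates `nGenes` genes with `annPerGene` distinct terms each, drawn
#' with probability proportional to `exp(skew * depth)` where depth is the
#' number of ancestors of the term: `skew = 0` uses terms uniformly,
#' positive skew biases toward deep (specific) terms, emulating the
#' leaf-heavy annotations of curated corpora. Deterministic per seed.
#'
#' @param graph an [OntologyGraph-class].
#' @param nGenes number of genes.
#' @param annPerGene annotations per gene.
#' @param skew depth bias (default 0.5).
#' @param seed integer seed.
#' @return An [AnnotationSet-class].
#' @export
syntheticCorpus <- function(graph, nGenes, annPerGene = 1, skew = 0.5,
                            seed = 1) {
  live <- termInfo(graph)$id[!termInfo(graph)$obsolete]
  set.seed(seed)
  depth <- vapply(live, function(t) length(ancestors(graph, t)),
                  numeric(1))
  w <- exp(skew * depth)
  k <- min(annPerGene, length(live))
  genes <- sprintf("g%04d", seq_len(nGenes))
  rec <- lapply(genes, function(g)
    data.frame(gene = g,
               term = live[sample.int(length(live), k, prob = w)]))
  rec <- do.call(rbind, rec)
  new("AnnotationSet", records = rec,
      unresolved = data.frame(gene = character(), term = character()))
}

#' Build a spiked test gene list
#'
#' Draws `round(fraction * size)` genes from the members of one category
#' of a categorized background and fills the rest uniformly from the
#' non-member background genes — a positive control for enrichment.
#'
#' @param background a [GeneAssignments-class].
#' @param category the category to spike.
#' @param fraction fraction of the test list drawn from the category's
#'   genes, in `[0, 1]`.
#' @param size test-list size.
#' @param seed integer seed.
#' @return Character vector of gene ids.
#' @export
spikeInGeneSet <- function(background, category, fraction, size, seed = 1) {
  stopifnot(fraction >= 0, fraction <= 1, size >= 1)
  tab <- assignmentTable(background)
  members <- unique(tab$gene[tab$category == category])
  if (!length(members))
    stop("category has no member genes in the background: ", category)
  nSpike <- round(fraction * size)
  if (nSpike > length(members))
    stop("category ", category, " has only ", length(members),
         " member gene(s), need ", nSpike)
  others <- setdiff(background@genes, members)
  if (size - nSpike > length(others))
    stop("not enough non-member genes to fill the test list")
  set.seed(seed)
  spike <- sample(members, nSpike)
  rest <- sample(others, size - nSpike)
  sample(c(spike, rest))
}

#' Shipped category schemes
#'
#' Category-definition TSVs installed with the package:
#' `hd_modifiers` (9 broad process categories used for neurodegeneration
#' modifier screens, with the canonical seed GO ids), and three general-purpose
#' sets whose GO-id seed lists are maintainer-curated:
#' `biological_process` (27 categories), `cellular_localization` (8) and
#' `enzyme_function` (6).
#'
#' @param name scheme name; `NULL` lists the available names.
#' @param graph optional [OntologyGraph-class] for seed validation.
#' @return A [CategoryScheme-class], or a character vector of names when
#'   `name` is `NULL`.
#' @examples
#' shippedScheme()
#' length(categories(shippedScheme("biological_process")))  # 27
#' @export
shippedScheme <- function(name = NULL, graph = NULL) {
  dir <- system.file("extdata", "schemes", package = "GOcategorize")
  avail <- sub("\\.tsv$", "", list.files(dir, pattern = "\\.tsv$"))
  if (is.null(name)) return(avail)
  if (!name %in% avail)
    stop("unknown scheme '", name, "'; available: ",
         paste(avail, collapse = ", "))
  loadCategoryScheme(file.path(dir, paste0(name, ".tsv")), graph = graph,
                     name = name)
}
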