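## Multi-label evaluation against a gold standard: cell-wise accuracy over
## the gene x category matrices and the micro-averaged (flattened-cell)
## Matthews correlation coefficient, plus a random-assignment baseline.

#' Align gold-standard and predicted labels into binary matrices
#'
#' @param gold data.frame with columns `gene`, `category` (repeated lines
#'   allowed), or a named list mapping gene to category vector.
#' @param predicted a [GeneAssignments-class] or a data.frame with columns
#'   `gene`, `category`.
#' @param categories character vector fixing the category order (columns).
#' @return list with components `genes`, `categories`, `G` and `P` (binary
#'   matrices of identical shape, genes x categories). Gold genes missing
#'   from the predictions get an all-zero prediction row.
#' @export
buildLabelMatrices <- function(gold, predicted, categories) {
  if (is.list(gold) && !is.data.frame(gold))
    gold <- data.frame(
      gene = rep(names(gold), lengths(gold)),
      category = unlist(gold, use.names = FALSE))
  if (is(predicted, "GeneAssignments"))
    predicted <- assignmentTable(predicted)
  stopifnot(all(c("gene", "category") %in% names(gold)),
            all(c("gene", "category") %in% names(predicted)))
  badCat <- setdiff(gold$category, categories)
  if (length(badCat))
    stop("gold-standard category not in the scheme: ",
         paste(badCat, collapse = ", "))
  genes <- sort(unique(gold$gene))

  fill <- function(df) {
    m <- matrix(0L, nrow = length(genes), ncol = length(categories),
                dimnames = list(genes, categories))
    df <- df[df$gene %in% genes & df$category %in% categories, ,
             drop = FALSE]
    if (nrow(df)) m[cbind(df$gene, df$category)] <- 1L
    m
  }
  list(genes = genes, categories = categories,
       G = fill(gold), P = fill(predicted))
}

#' Multi-label accuracy
#'
#' Fraction of agreeing cells between the gold and prediction matrices:
#' correct assignments to true categories and correct non-assignments to
#' false categories both count.
#'
#' @param m matrices from [buildLabelMatrices()].
#' @return Numeric in `[0, 1]`.
#' @export
multilabelAccuracy <- function(m) {
  stopifnot(identical(dim(m$G), dim(m$P)))
  mean(m$G == m$P)
}

#' Multi-label Matthews correlation coefficient
#'
#' Cells of the gold and prediction matrices are flattened into one binary
#' vector pair (micro-averaging) and the classical MCC is computed;
#' `macro = TRUE` instead averages per-category MCCs. Any zero factor in
#' the denominator yields 0.
#'
#' @param m matrices from [buildLabelMatrices()].
#' @param macro average per-category MCCs instead of flattening.
#' @return Numeric in `[-1, 1]`.
#' @export
multilabelMCC <- function(m, macro = FALSE) {
  mcc1 <- function(g, p) {
    tp <- sum(g == 1 & p == 1); tn <- sum(g == 0 & p == 0)
    fp <- sum(g == 0 & p == 1); fn <- sum(g == 1 & p == 0)
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    if (den == 0) return(0)
    (tp * tn - fp * fn) / den
  }
  if (macro)
    mean(vapply(seq_along(m$categories), function(j)
      mcc1(m$G[, j], m$P[, j]), numeric(1)))
  else
    mcc1(as.vector(m$G), as.vector(m$P))
}

#' Per-category confusion counts
#'
#' @param m matrices from [buildLabelMatrices()].
#' @return data.frame with columns `category`, `tp`, `fp`, `fn`, `tn`.
#' @export
perCategoryConfusion <- function(m) {
  do.call(rbind, lapply(seq_along(m$categories), function(j) {
    g <- m$G[, j]; p <- m$P[, j]
    data.frame(category = m$categories[j],
               tp = sum(g == 1 & p == 1), fp = sum(g == 0 & p == 1),
               fn = sum(g == 1 & p == 0), tn = sum(g == 0 & p == 0))
  }))
}

#' Load a gold standard from TSV
#'
#' Lines of `gene<TAB>category`; repeated lines allowed, `#` comments
#' ignored.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `gene`, `category`.
#' @export
loadGoldStandard <- function(path) {
  if (!file.exists(path)) stop("cannot read gold standard: ", path)
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          col.names = c("gene", "category"),
                          colClasses = "character")
  unique(df)
}

#' Random multi-label baseline
#'
#' Assigns each gene `k` distinct categories uniformly at random, the
#' control predictor used to gauge chance-level accuracy and MCC.
#'
#' @param genes character vector of gene ids.
#' @param categories character vector of category names.
#' @param k categories per gene (default 3).
#' @param seed integer seed.
#' @return A [GeneAssignments-class] with `NA` scores and supporting terms.
#' @export
randomBaseline <- function(genes, categories, k = 3, seed = 1) {
  if (k > length(categories))
    stop("k exceeds the number of categories")
  set.seed(seed)
  genes <- unique(as.character(genes))
  tab <- do.call(rbind, lapply(genes, function(g)
    data.frame(gene = g, category = sample(categories, k),
               score = NA_real_, term = NA_character_)))
  new("GeneAssignments", table = tab, genes = genes,
      mode = "multi", threshold = 0)
}
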