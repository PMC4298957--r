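---
title: "Categorizing genes by information-content semantic similarity"
author: "GOcategorize authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Categorizing genes by information-content semantic similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GOcategorize)
```

## Overview

`GOcategorize` assigns genes to a small set of user-defined biological
categories over the Gene Ontology DAG and tests whether a gene list is
enriched for any category relative to a background. This vignette
explains the model, its assumptions, the tunable parameters, and the
design decisions behind the implementation, including what the
synthetic-data generators do and do not emulate.

## The ontology model

GO is a directed acyclic graph, not a tree: a term may have several
parents, within one of three namespaces (biological process, molecular
function, cellular component). The package keeps namespaces disjoint —
cross-namespace edges are dropped with a warning — and requires exactly
one parentless term (the root) per namespace. Traversal follows the two
relations that obey the true-path rule, `is_a` and `part_of`; which of
the two to use is configurable in `parseOBO()`, with both kept by
default. `part_of` shares the key property that annotation to the child
implies relevance of the parent, which is exactly what count propagation
and ancestor-based categorization rely on; relations without that
property (e.g. `regulates`) are deliberately unsupported. Obsolete terms
are retained for bookkeeping but carry no edges; `alt_id`s are aliases
of their primary id. Acyclicity is verified at parse time (via igraph),
so every downstream algorithm may assume a topological order exists.

## Information content

Given a reference annotation corpus, each record (a deduplicated
gene-term pair) is counted for its term and, by the true-path rule, for
every ancestor of that term. With `T` records in a namespace,

$$p(x) = \frac{\mathrm{count}(x)}{T}, \qquad I(x) = -\log p(x).$$

Three consequences the implementation is built around:

- the namespace root accumulates every record, so `p = 1` and `I = 0` —
  annotating a gene with the root carries no information;
- along every child-parent edge `I(child) >= I(parent)` (a child's
  records are a subset of its parent's), asserted as a property test on
  randomized corpora;
- terms unused in the corpus ("orphans") get the smallest nonzero `p` of
  their namespace, i.e. the maximal observed IC — absence of use is
  treated as maximal specificity rather than as missing data.

The counting unit is the annotation record, not the unique gene, and the
denominator is the per-namespace record total; a global denominator
would give roots `p < 1` and nonzero root IC, breaking the first
property whenever more than one namespace is annotated. The logarithm
base (natural by default) only rescales IC; every score downstream is a
ratio or difference of ICs from one table, so the choice is free as long
as one table is used consistently. IC computation over a large corpus is
the expensive step, so tables are serializable (`writeICTable()` /
`readICTable()`, 15 significant digits, so a round trip is exact to
at least 12).

## Semantic similarity to a category anchor

Categorization is not symmetric similarity: the question is how well a
term belongs *under* a category, so a scored pair always consists of a
query term `x` and an ancestor-or-self anchor `p`. Three IC distances
enter:

- **alpha** `= I(p)`: the anchor's distance from the root. Deep anchors
  are specific, and membership under them is informative.
- **beta** `= (d(p, mic(p)) + d(x, mic(x)))/2`, where `mic` is the most
  informative descendant (the term itself for a leaf) and
  `d` the IC difference along a lineage: how much information the
  subtrees below anchor and term still add. "Descendant" here means the
  full transitive closure, not direct children only; ties for `mic` are
  broken lexicographically for determinism.
- **gamma** `= I(x) - I(p)`: how far the term sits below the anchor.

$$S(p, x) = \frac{\alpha}{\alpha + \beta}\cdot\frac{1}{1 + \gamma} \in [0, 1].$$

The score rewards deep anchors whose subtree is nearly exhausted by the
term (`alpha` large, `beta` small) and penalizes loose membership
(`gamma` large). In the degenerate case `alpha + beta = 0` — a
root-level anchor with an uninformative subtree — the first factor is
taken as 1 with a warning, preserving the `[0, 1]` bound; real corpora
never produce it because seeds are chosen below the root. The
implementation clamps `S` into `[0, 1]` against floating-point drift.
The worked toy instance (`toyInstance()`) pins the formula: three
independent reference score values (0.815, 0.475, 0.346) are reproduced
to three decimals from the reference IC inputs, which guards the closed
form against regressions from any single coincidental match.

## Categorization

Users label categories with seed terms; a seed belongs to exactly one
category. Labels propagate top-down:

1. every term inherits the (category, anchor) pairs of its parents;
2. a labelled parent adds itself as an anchor;
3. a term whose anchors span exactly one category is resolved to it with
   score 1 and becomes an anchor for its own descendants (a user seed is
   always resolved to its own category).

Terms with anchors in several categories are scored per category as the
maximum `S` over that category's anchors; genes take the maximum over
their annotated terms, with the supporting term recorded. Aggregating
by maximum (rather than mean) in both places matches selection by the
highest similarity score; the resolved single-category terms serve as
additional anchors because the toy instance's multi-category term is
explicitly compared against such terms, not only against user seeds.
`mode = "best"` returns the top category (lexicographic tie-break,
deterministic); `mode = "multi"` returns every category with score at
or above the threshold, always including the top category so no gene
with covered annotations is silently dropped.

The default threshold is **0.3**. It is calibrated against the score
scale of unrelated ancestor-descendant pairs, whose mean sits around
0.10 with SD about 0.12, so 0.3 is roughly two SDs above chance-level
similarity; scores of well-fitting terms (e.g. 0.815 above) clear it
comfortably. The threshold is exposed everywhere and on the CLI.

## Enrichment

Classical enrichment tests treat categories as independent, which fails
when genes commonly belong to several correlated categories. The
randomization null preserves exactly that structure: with `p(c)` the
fraction of background (gene, category) assignments in category `c`,
each replicate re-assigns every background gene as many distinct
categories as it really has — sequential draws without replacement with
renormalization, which is what `sample(prob = )` implements — then draws
`L` background genes uniformly without replacement (`L` the test-set
size) and counts genes per category. Over `reps = 1000` replicates this
yields `mu(c)` and `sigma(c)`, and

$$z(c) = \frac{\mathrm{observed}(c) - \mu(c)}{\sigma(c)}$$

with one-sided normal p-values in both directions; enrichment (upper
tail) is the primary readout and depletion is reported alongside.
Unclassified genes keep degree 0 and only dilute `L`. If `sigma = 0`
(forced outcomes, e.g. a single category with all degrees 1) the
p-value cannot be resolved below the replicate resolution and is
reported as `1/reps` with a `sigma_zero` flag. No multiple-testing
correction is applied by default — the intended use is a handful of
user-chosen categories — but Benjamini-Hochberg adjustment is available
behind the `fdr` flag. Degree conservation is asserted inside every
replicate.

The null is mildly conservative for fixed-membership test draws: the
category reassignment adds variance that a draw from the *actual*
categorized background does not have, so the empirical type-I rate at
nominal 0.05 sits slightly below 0.05 (measured around 0.044 under the
test-suite conditions) while remaining within the Monte-Carlo band.
This is a property of the null model, not of the implementation.

## Evaluation

Against a gold standard, predictions are compared as binary
gene-by-category matrices `G` and `P`. Accuracy is the fraction of
agreeing cells — counting correct non-assignments, because with many
categories most cells are 0 and a do-nothing predictor already scores
high. The Matthews correlation coefficient on the flattened cell
vectors (micro-averaging; a macro option exists) corrects for exactly
that imbalance; a random predictor that assigns each gene `k = 3`
categories (the observed average per gene in practice is about 2.5)
centers on MCC 0 however high its accuracy. The random baseline's MCC
has a large per-draw spread when the gold standard is fixed, so the
test suite checks the mean of many draws against a three-standard-error
band around zero rather than a fixed small number.

## Synthetic data: what it does and does not emulate

Property tests run on generated instances (all deterministic per seed):

- `randomOntology(n, maxParents)` grows a connected single-root DAG by
  attaching each new term to 1-3 earlier terms, reproducing the
  multi-parent lineages that make DAG traversal nontrivial;
- `syntheticCorpus()` annotates genes with terms drawn with probability
  proportional to `exp(skew * depth)`; the default `skew` of 0.5 biases
  toward specific terms as curated corpora do;
- `spikeInGeneSet()` builds positive controls with a known enriched
  fraction;
- acceptance-level study conditions use a 1000-gene background with 2-3
  categories per gene over 8 categories plus one 10%-prevalence planted
  category, and 50-gene test sets — sizes chosen so normal approximation
  of the count null is reasonable (means well above 10) while the whole
  suite runs in minutes on one CPU.

What the generators do not emulate: the heavy-tailed term-usage
distribution of real corpora (a few terms carry most annotations),
evidence-code heterogeneity, annotation errors, and the correlation of
annotations across related genes. Passing tests therefore demonstrate
the correctness of the algorithms and the calibration of the null under
the stated conditions, not the field accuracy of category assignments
on any particular organism's annotations — that depends on the corpus
and the user's category definitions.

## Numerical and degenerate-input choices

- Ancestor queries use igraph reachability; unit tests cross-check them
  against naive stepwise parent expansion, and categorization against a
  brute-force reference that re-derives every anchor score from the
  definitional formulas.
- Ties: `mic` ties and best-category ties break lexicographically;
  multi-mode reports all tied categories.
- Empty inputs are errors where silence would mislead (empty annotation
  file, empty scheme, empty test set, namespace with zero records) and
  tolerated where work can proceed (unknown genes in a gene list are
  counted in the run manifest; unresolvable annotation records are kept
  in a reporting slot).
- All randomness (null replicates, generators, baselines) flows from
  explicit integer seeds; the CLI writes every parameter and seed to a
  run manifest, and identical configurations produce byte-identical
  outputs.

## Shipped category schemes

Four schemes install under `inst/extdata/schemes/`: the nine broad
process categories used in neurodegeneration modifier screens (seed GO
ids fixed by convention) and three general-purpose sets — 27 biological
processes, 8 cellular localizations, 6 enzyme functions — whose named
categories follow common usage but whose seed GO ids are
maintainer-curated choices, documented as such in the files. Users are
expected to edit or replace them: the method is designed around
user-defined categories.

## Known limitations

- Only `is_a` and `part_of` are traversed; regulatory relations are out
  of scope.
- The enrichment p-values come from a normal approximation to the
  randomization distribution; for very small backgrounds or categories
  with single-digit expected counts the discreteness of counts makes
  them approximate (the `sigma_zero` flag marks the extreme case).
- The gene-level score aggregates term scores by maximum; genes with
  many weak annotations to a category are not rewarded for redundancy.
- IC tables are corpus- and GO-release-specific; mixing a table with a
  different ontology release triggers warnings, not errors, because ids
  are checked but topology is not.
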