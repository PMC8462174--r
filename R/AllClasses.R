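#' @import methods
#' @importFrom stats dhyper phyper dist rnbinom rnorm runif sd var
#' @importFrom utils read.csv write.csv combn
NULL

#' Run configuration for the multifunctionality pipeline
#'
#' Consolidates every tunable knob of the pipeline: the significance level
#' and expected-cooccurrence filter of the trait-cooccurrence scan, the
#' binarization threshold for fuzzy scores, the modularity resolution and
#' number of seeded Louvain restarts, the permutation count for DistLM
#' p-values, the transform family and admissibility constraint of the
#' forward selection, the minimum retained cluster size, and the rule that
#' decides which stage-1 clusters count as significant.
#'
#' @slot alpha significance level for one-sided cooccurrence tests and for
#'   sequential permutation p-values (default 0.05).
#' @slot minExpected minimum expected shared-modality count for a species
#'   pair to be tested (default 1; set 0 to disable).
#' @slot binarizeThreshold fuzzy-affinity cutoff: a modality counts as
#'   possessed when its score is strictly greater than this (default 0).
#' @slot resolution Louvain modularity resolution (default 1).
#' @slot louvainRestarts number of seeded Louvain restarts; the best-Q
#'   partition is kept (default 20).
#' @slot seed integer seed controlling all randomness.
#' @slot nPermutations permutations for sequential pseudo-F tests
#'   (default 9999).
#' @slot transformFamily `"square"` or `"sqrt"`: the second polynomial-type
#'   transform offered alongside raw and log10(x+1) columns.
#' @slot transformConstraint `"strict"` (log admissible only while neither
#'   raw nor square/sqrt of the same base is selected, and vice versa) or
#'   `"lenient"` (no admissibility coupling).
#' @slot minClusterSize clusters smaller than this are excluded before
#'   abundance aggregation (default 2).
#' @slot significanceRule `"selected_and_p"` (stage-1 clusters must be
#'   selected by adjusted R-squared and have sequential permutation
#'   p <= alpha) or `"selected"` (selection alone suffices).
#' @slot bhCorrect apply Benjamini-Hochberg correction across pairwise
#'   cooccurrence tests (default FALSE; the conventional scan reports raw
#'   one-sided p-values).
#' @exportClass RunConfig
setClass("RunConfig", representation(
  alpha = "numeric",
  minExpected = "numeric",
  binarizeThreshold = "numeric",
  resolution = "numeric",
  louvainRestarts = "integer",
  seed = "integer",
  nPermutations = "integer",
  transformFamily = "character",
  transformConstraint = "character",
  minClusterSize = "integer",
  significanceRule = "character",
  bhCorrect = "logical"
))

setValidity("RunConfig", function(object) {
  msg <- character(0)
  if (!(object@alpha > 0 && object@alpha < 1))
    msg <- c(msg, "alpha must lie strictly between 0 and 1")
  if (object@minExpected < 0) msg <- c(msg, "minExpected must be >= 0")
  if (object@binarizeThreshold < 0)
    msg <- c(msg, "binarizeThreshold must be >= 0")
  if (object@louvainRestarts < 1L) msg <- c(msg, "louvainRestarts must be >= 1")
  if (object@nPermutations < 1L) msg <- c(msg, "nPermutations must be >= 1")
  if (!object@transformFamily %in% c("square", "sqrt"))
    msg <- c(msg, "transformFamily must be 'square' or 'sqrt'")
  if (!object@transformConstraint %in% c("strict", "lenient"))
    msg <- c(msg, "transformConstraint must be 'strict' or 'lenient'")
  if (object@minClusterSize < 1L) msg <- c(msg, "minClusterSize must be >= 1")
  if (!object@significanceRule %in% c("selected_and_p", "selected"))
    msg <- c(msg, "significanceRule must be 'selected_and_p' or 'selected'")
  if (length(msg)) msg else TRUE
})

#' Fuzzy-coded functional trait table
#'
#' Species (or species size-class) rows by trait-modality columns, holding
#' proportional affinity scores. Every modality belongs to exactly one
#' trait category; scores are normalized so each (species, category) block
#' sums to one (blocks summing to zero stay zero and are recorded in
#' `zeroBlocks`).
#'
#' @slot scores numeric matrix, species x modality, with dimnames.
#' @slot categories named character vector mapping each modality column to
#'   its trait-category label.
#' @slot zeroBlocks character vector of "species/category" labels whose
#'   affinity block summed to zero at normalization time.
#' @exportClass FuzzyTraitTable
setClass("FuzzyTraitTable", representation(
  scores = "matrix",
  categories = "character",
  zeroBlocks = "character"
))

setValidity("FuzzyTraitTable", function(object) {
  s <- object@scores
  msg <- character(0)
  if (is.null(rownames(s)) || is.null(colnames(s)))
    msg <- c(msg, "scores must carry species and modality dimnames")
  if (anyDuplicated(rownames(s)))
    msg <- c(msg, "duplicate species ids")
  if (any(s < 0)) msg <- c(msg, "negative affinity scores")
  if (!setequal(names(object@categories), colnames(s)))
    msg <- c(msg, "categories must name every modality column exactly once")
  if (length(msg)) msg else TRUE
})

#' Sample-by-variable matrix
#'
#' Validated container for the three per-sample tables the pipeline
#' consumes: species abundances, environmental characteristics, and
#' ecosystem-function indicators. Rows are samples, columns variables;
#' missing cells are rejected at construction time and abundance values
#' must be non-negative.
#'
#' @slot values numeric matrix, sample x variable, with dimnames.
#' @slot kind one of `"abundance"`, `"environment"`, `"function"`.
#' @exportClass SampleMatrix
setClass("SampleMatrix", representation(
  values = "matrix",
  kind = "character"
))

setValidity("SampleMatrix", function(object) {
  v <- object@values
  msg <- character(0)
  if (!object@kind %in% c("abundance", "environment", "function"))
    msg <- c(msg, "kind must be abundance, environment or function")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must carry sample and variable dimnames")
  if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicate sample ids")
  if (anyDuplicated(colnames(v))) msg <- c(msg, "duplicate variable ids")
  if (anyNA(v)) msg <- c(msg, "missing cells are not allowed")
  if (identical(object@kind, "abundance") && !anyNA(v) && any(v < 0))
    msg <- c(msg, "abundance values must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Binary species-by-modality matrix
#'
#' Presence/absence of trait modalities per species, obtained by
#' thresholding a [FuzzyTraitTable]. `N` (total modality count) is
#' `ncol(cells)` and the per-species possessed-modality counts are the row
#' sums. Species possessing no modality at the chosen threshold are kept
#' but flagged; downstream scans exclude them.
#'
#' @slot cells integer 0/1 matrix, species x modality, with dimnames.
#' @slot flagged character vector of species ids with zero possessed
#'   modalities.
#' @exportClass BinaryTraitMatrix
setClass("BinaryTraitMatrix", representation(
  cells = "matrix",
  flagged = "character"
))

setValidity("BinaryTraitMatrix", function(object) {
  msg <- character(0)
  if (!all(object@cells %in% c(0L, 1L))) msg <- c(msg, "cells must be 0/1")
  if (is.null(rownames(object@cells)) || is.null(colnames(object@cells)))
    msg <- c(msg, "cells must carry dimnames")
  if (!all(object@flagged %in% rownames(object@cells)))
    msg <- c(msg, "flagged species must be rows of the matrix")
  if (length(msg)) msg else TRUE
})

#' Jaccard-weighted species trait network
#'
#' Undirected graph whose nodes are species (isolates retained) and whose
#' edges are the significant positive trait cooccurrences, weighted by
#' Jaccard's coefficient of the two species' modality sets.
#'
#' @slot graph an [igraph::igraph] object; undirected, simple, positive
#'   edge attribute `weight` ([buildTraitNetwork()] produces Jaccard
#'   weights in (0, 1]).
#' @exportClass TraitNetwork
setClass("TraitNetwork", representation(graph = "ANY"))

setValidity("TraitNetwork", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph slot must hold an igraph object")
  msg <- character(0)
  if (igraph::is_directed(g)) msg <- c(msg, "trait network must be undirected")
  if (any(igraph::which_loop(g))) msg <- c(msg, "self-loops are not allowed")
  if (any(igraph::which_multiple(g))) msg <- c(msg, "duplicate edges")
  if (igraph::ecount(g) > 0) {
    w <- igraph::E(g)$weight
    if (is.null(w) || any(w <= 0))
      msg <- c(msg, "edge weights must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Modularity partition of a trait network
#'
#' Cluster assignment for every node of a [TraitNetwork], together with
#' the weighted Newman-Girvan modularity Q of the partition and the set of
#' nodes excluded downstream (singleton isolates and clusters below the
#' minimum size).
#'
#' @slot membership named integer vector, node -> cluster id.
#' @slot Q modularity of the partition.
#' @slot excluded character vector of node ids dropped by the exclusion
#'   rule (filled in by [aggregateClusterAbundance()]).
#' @exportClass Partition
setClass("Partition", representation(
  membership = "integer",
  Q = "numeric",
  excluded = "character"
))

setValidity("Partition", function(object) {
  msg <- character(0)
  if (is.null(names(object@membership)))
    msg <- c(msg, "membership must be named by node id")
  if (anyNA(object@membership)) msg <- c(msg, "every node needs a cluster")
  if (length(object@Q) != 1 || object@Q < -0.5 - 1e-12 || object@Q > 1 + 1e-12)
    msg <- c(msg, "Q must lie in [-0.5, 1]")
  if (length(msg)) msg else TRUE
})

#' Per-sample trait-cluster abundance table
#'
#' A [SampleMatrix] of kind `"abundance"` whose variables are retained
#' trait-cluster ids; each cluster column is the row-wise sum of its member
#' species' abundance columns. `provenance` records the member species of
#' every retained cluster and `excluded` the species dropped by the
#' exclusion rule.
#'
#' @slot provenance named list, cluster id -> character vector of member
#'   species.
#' @slot excluded character vector of excluded species ids.
#' @exportClass ClusterAbundanceTable
setClass("ClusterAbundanceTable", contains = "SampleMatrix", representation(
  provenance = "list",
  excluded = "character"
))

#' Two-stage DistLM selection report
#'
#' For each ecosystem function, the ordered forward-selection path of the
#' two-stage distance-based linear model: stage 1 over trait-cluster
#' abundance columns, stage 2 over environmental columns conditional on the
#' retained stage-1 clusters. Stage totals follow the A/B/C convention:
#' A = variance explained by retained trait clusters, B = variance added by
#' selected environmental characteristics, C = A + B.
#'
#' @slot results named list, one element per function, each a list with
#'   `steps` (data.frame: base, transform, delta_r2, adj_r2_after,
#'   pseudo_F, p_perm, stage, retained), `A`, `B`, `C`.
#' @slot n number of samples the models were fitted on.
#' @slot config the [RunConfig] used.
#' @exportClass DistLMReport
setClass("DistLMReport", representation(
  results = "list",
  n = "integer",
  config = "RunConfig"
))

#' Directed multifunctionality network
#'
#' Source nodes (trait clusters and environmental characteristics) point
#' at function nodes; each edge carries the summed sequential variance
#' explained (delta R-squared, proportion scale) of that predictor for
#' that function, and node size is the out-degree of a source or the
#' in-degree of a function. Edges never connect two sources or two
#' functions.
#'
#' @slot nodes data.frame with columns `name`, `role` (cluster,
#'   environment, function), `size`.
#' @slot edges data.frame with columns `source`, `target`, `weight`.
#' @exportClass MultifunctionalNetwork
setClass("MultifunctionalNetwork", representation(
  nodes = "data.frame",
  edges = "data.frame"
))

setValidity("MultifunctionalNetwork", function(object) {
  msg <- character(0)
  nd <- object@nodes; ed <- object@edges
  if (!all(c("name", "role", "size") %in% names(nd)))
    msg <- c(msg, "nodes needs columns name, role, size")
  if (!all(c("source", "target", "weight") %in% names(ed)))
    msg <- c(msg, "edges needs columns source, target, weight")
  if (nrow(nd) && !all(nd$role %in% c("cluster", "environment", "function")))
    msg <- c(msg, "node roles must be cluster, environment or function")
  if (nrow(ed)) {
    role <- stats::setNames(nd$role, nd$name)
    if (!all(ed$source %in% nd$name) || !all(ed$target %in% nd$name))
      msg <- c(msg, "edge endpoints must be nodes")
    else {
      if (any(role[ed$source] == "function"))
        msg <- c(msg, "functions cannot be edge sources")
      if (any(role[ed$target] != "function"))
        msg <- c(msg, "edge targets must be function nodes")
    }
    if (any(ed$weight <= 0)) msg <- c(msg, "edge weights must be > 0")
  }
  if (length(msg)) msg else TRUE
})
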