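#' @rdname accessors
#' @param x an object of one of the package's classes
#' @export
setGeneric("speciesIds", function(x) standardGeneric("speciesIds"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("variableIds", function(x) standardGeneric("variableIds"))

#' @rdname accessors
#' @export
setGeneric("tableValues", function(x) standardGeneric("tableValues"))

#' @rdname accessors
#' @export
setGeneric("traitScores", function(x) standardGeneric("traitScores"))

#' @rdname accessors
#' @export
setGeneric("modalityCategories", function(x) standardGeneric("modalityCategories"))

#' @rdname accessors
#' @export
setGeneric("clusterAssignments", function(x) standardGeneric("clusterAssignments"))

#' @rdname accessors
#' @export
setGeneric("partitionQ", function(x) standardGeneric("partitionQ"))

#' @rdname accessors
#' @export
setGeneric("excludedNodes", function(x) standardGeneric("excludedNodes"))

#' @rdname accessors
#' @export
setGeneric("clusterMembers", function(x) standardGeneric("clusterMembers"))

#' @rdname accessors
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))

#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' Accessor functions
#'
#' Read-only accessors for the package's S4 classes. `speciesIds()` returns
#' species (row) labels, `sampleIds()`/`variableIds()` the dimnames of a
#' [SampleMatrix], `tableValues()` its numeric matrix, `traitScores()` the
#' fuzzy score matrix, `modalityCategories()` the modality-to-category map,
#' `clusterAssignments()`/`partitionQ()`/`excludedNodes()` the slots of a
#' [Partition], `clusterMembers()` the provenance of a
#' [ClusterAbundanceTable], and `networkGraph()`/`networkNodes()`/
#' `networkEdges()` graph views of the network classes.
#'
#' @name accessors
NULL

#' @rdname accessors
setMethod("speciesIds", "FuzzyTraitTable", function(x) rownames(x@scores))
#' @rdname accessors
setMethod("speciesIds", "BinaryTraitMatrix", function(x) rownames(x@cells))
#' @rdname accessors
setMethod("sampleIds", "SampleMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("variableIds", "SampleMatrix", function(x) colnames(x@values))
#' @rdname accessors
setMethod("tableValues", "SampleMatrix", function(x) x@values)
#' @rdname accessors
setMethod("traitScores", "FuzzyTraitTable", function(x) x@scores)
#' @rdname accessors
setMethod("modalityCategories", "FuzzyTraitTable", function(x) x@categories)
#' @rdname accessors
setMethod("clusterAssignments", "Partition", function(x) x@membership)
#' @rdname accessors
setMethod("partitionQ", "Partition", function(x) x@Q)
#' @rdname accessors
setMethod("excludedNodes", "Partition", function(x) x@excluded)
#' @rdname accessors
setMethod("excludedNodes", "ClusterAbundanceTable", function(x) x@excluded)
#' @rdname accessors
setMethod("clusterMembers", "ClusterAbundanceTable", function(x) x@provenance)
#' @rdname accessors
setMethod("networkGraph", "TraitNetwork", function(x) x@graph)
#' @rdname accessors
setMethod("networkNodes", "TraitNetwork", function(x) {
  data.frame(name = igraph::V(x@graph)$name, stringsAsFactors = FALSE)
})
#' @rdname accessors
setMethod("networkEdges", "TraitNetwork", function(x) {
  g <- x@graph
  if (igraph::ecount(g) == 0)
    return(data.frame(source = character(0), target = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE))
  el <- igraph::as_edgelist(g)
  data.frame(source = el[, 1], target = el[, 2],
             weight = igraph::E(g)$weight, stringsAsFactors = FALSE)
})
#' @rdname accessors
setMethod("networkNodes", "MultifunctionalNetwork", function(x) x@nodes)
#' @rdname accessors
setMethod("networkEdges", "MultifunctionalNetwork", function(x) x@edges)

setMethod("show", "FuzzyTraitTable", function(object) {
  cat(sprintf("FuzzyTraitTable: %d species x %d modalities in %d categories\n",
              nrow(object@scores), ncol(object@scores),
              length(unique(object@categories))))
  if (length(object@zeroBlocks))
    cat(sprintf("  %d zero (species, category) blocks\n",
                length(object@zeroBlocks)))
})

setMethod("show", "SampleMatrix", function(object) {
  cat(sprintf("SampleMatrix [%s]: %d samples x %d variables\n",
              object@kind, nrow(object@values), ncol(object@values)))
})

setMethod("show", "BinaryTraitMatrix", function(object) {
  cat(sprintf("BinaryTraitMatrix: %d species x %d modalities (N = %d)\n",
              nrow(object@cells), ncol(object@cells), ncol(object@cells)))
  if (length(object@flagged))
    cat("  flagged trait-empty species:",
        paste(object@flagged, collapse = ", "), "\n")
})

setMethod("show", "TraitNetwork", function(object) {
  cat(sprintf("TraitNetwork: %d nodes, %d Jaccard-weighted edges\n",
              igraph::vcount(object@graph), igraph::ecount(object@graph)))
})

setMethod("show", "Partition", function(object) {
  k <- length(unique(object@membership))
  cat(sprintf("Partition: %d nodes in %d clusters, Q = %.4f\n",
              length(object@membership), k, object@Q))
})

setMethod("show", "ClusterAbundanceTable", function(object) {
  cat(sprintf(
    "ClusterAbundanceTable: %d samples x %d retained clusters (%d species excluded)\n",
    nrow(object@values), ncol(object@values), length(object@excluded)))
})

setMethod("show", "DistLMReport", function(object) {
  cat(sprintf("DistLMReport: %d functions, n = %d samples\n",
              length(object@results), object@n))
  for (fn in names(object@results)) {
    r <- object@results[[fn]]
    cat(sprintf("  %-30s A = %.3f  B = %.3f  C = %.3f\n",
                fn, r$A, r$B, r$C))
  }
})

setMethod("show", "MultifunctionalNetwork", function(object) {
  cat(sprintf("MultifunctionalNetwork: %d nodes (%d sources, %d functions), %d edges\n",
              nrow(object@nodes), sum(object@nodes$role != "function"),
              sum(object@nodes$role == "function"), nrow(object@edges)))
})

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig:\n")
  for (f in slotNames(object))
    cat(sprintf("  %s: %s\n", f, paste(slot(object, f), collapse = ", ")))
})
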