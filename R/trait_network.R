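#' Assemble the Jaccard-weighted species trait network
#'
#' Nodes are all species supplied (isolates are retained so that
#' disconnected species surface as singleton clusters); edges are the
#' significant positive associations from [cooccurrenceScan()], weighted
#' by Jaccard's coefficient.
#'
#' @param assocs scan result data.frame from [cooccurrenceScan()].
#' @param allSpecies character vector of node ids.
#' @return a [TraitNetwork-class].
#' @export
buildTraitNetwork <- function(assocs, allSpecies) {
  if (anyDuplicated(allSpecies)) stop("duplicate species in node list")
  sig <- assocs[assocs$significant & assocs$jaccard > 0, , drop = FALSE]
  unknown <- setdiff(c(sig$species_a, sig$species_b), allSpecies)
  if (length(unknown))
    stop("associations reference unknown species: ",
         paste(unique(unknown), collapse = ", "))
  key <- paste(pmin(sig$species_a, sig$species_b),
               pmax(sig$species_a, sig$species_b))
  if (anyDuplicated(key))
    stop("duplicate species pair(s) in associations: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(allSpecies), name = allSpecies)
  if (nrow(sig)) {
    g <- igraph::add_edges(g, rbind(sig$species_a, sig$species_b))
    igraph::E(g)$weight <- sig$jaccard
  }
  new("TraitNetwork", graph = g)
}

#' Weighted Newman-Girvan modularity of a partition
#'
#' `Q = sum_c [ w_c / W - (s_c / (2 W))^2 ]` with `w_c` the total
#' intra-cluster edge weight, `s_c` the summed node strength of cluster
#' `c` and `W` the total edge weight of the graph. Invariant under
#' uniform rescaling of all weights; 0 for the one-cluster partition.
#'
#' @param net a [TraitNetwork-class].
#' @param membership named integer/character vector assigning every node
#'   to a cluster, or a [Partition-class].
#' @return modularity Q in `[-0.5, 1]`.
#' @export
modularityScore <- function(net, membership) {
  g <- net@graph
  if (is(membership, "Partition")) membership <- membership@membership
  nodes <- igraph::V(g)$name
  missing <- setdiff(nodes, names(membership))
  if (length(missing))
    stop("nodes missing from partition: ", paste(missing, collapse = ", "))
  if (igraph::ecount(g) == 0) return(0)
  el <- igraph::as_edgelist(g)
  w <- igraph::E(g)$weight
  W <- sum(w)
  memb <- membership[nodes]
  intra <- tapply(w[memb[el[, 1]] == memb[el[, 2]]],
                  memb[el[, 1]][memb[el[, 1]] == memb[el[, 2]]], sum)
  strength <- igraph::strength(g, weights = w)
  s_c <- tapply(strength[nodes], memb, sum)
  wc <- rep(0, length(s_c)); names(wc) <- names(s_c)
  if (length(intra)) wc[names(intra)] <- intra
  sum(wc / W - (s_c / (2 * W))^2)
}

#' Detect trait clusters by seeded Louvain modularity optimization
#'
#' Runs the Louvain algorithm `restarts` times with seeds derived from
#' `seed`, scores each candidate partition with [modularityScore()], and
#' returns the best. Ties are broken by fewest clusters, then by the
#' lexicographically smallest canonical assignment, making the result a
#' pure function of `(net, resolution, seed, restarts)`. Isolated nodes
#' come out as singleton clusters.
#'
#' @param net a non-empty [TraitNetwork-class].
#' @param resolution modularity resolution (default 1).
#' @param seed integer seed.
#' @param restarts number of restarts (default 20).
#' @return a [Partition-class]; cluster ids are `c1, c2, ...` in order of
#'   first appearance along the node list.
#' @export
detectClusters <- function(net, resolution = 1, seed = 1L, restarts = 20L) {
  g <- net@graph
  if (igraph::vcount(g) == 0) stop("empty network")
  if (restarts < 1) stop("restarts must be >= 1")
  nodes <- igraph::V(g)$name
  w <- if (igraph::ecount(g) > 0) igraph::E(g)$weight else NULL
  best <- NULL; bestQ <- -Inf; bestK <- Inf
  for (r in seq_len(restarts)) {
    set.seed(seed + r - 1L)
    cl <- igraph::cluster_louvain(g, weights = w, resolution = resolution)
    memb <- canonicalMembership(igraph::membership(cl), nodes)
    Q <- modularityScore(net, memb)
    better <- Q > bestQ + 1e-12 ||
      (abs(Q - bestQ) <= 1e-12 && length(unique(memb)) < bestK) ||
      (abs(Q - bestQ) <= 1e-12 && length(unique(memb)) == bestK &&
         !is.null(best) && lexLess(memb, best))
    if (is.null(best) || better) {
      best <- memb; bestQ <- Q; bestK <- length(unique(memb))
    }
  }
  lab <- paste0("c", best)
  names(lab) <- nodes
  ids <- stats::setNames(as.integer(best), nodes)
  new("Partition", membership = ids, Q = bestQ, excluded = character(0))
}

# renumber clusters 1, 2, ... in order of first appearance along nodes
canonicalMembership <- function(memb, nodes) {
  memb <- memb[nodes]
  stats::setNames(as.integer(factor(memb, levels = unique(memb))), nodes)
}

lexLess <- function(a, b) {
  d <- which(a != b)
  length(d) > 0 && a[d[1]] < b[d[1]]
}

#' Cluster labels of a partition
#' @param part a [Partition-class].
#' @return named character vector node -> "c<k>" label.
#' @export
clusterLabels <- function(part) {
  stats::setNames(paste0("c", part@membership), names(part@membership))
}

#' Aggregate per-sample abundance over trait clusters
#'
#' Sums the abundance columns of each retained cluster's member species
#' into one column per cluster. Clusters smaller than `minClusterSize`
#' (singleton isolates included) are excluded — mirroring the removal of
#' disconnected single-species clusters before the multifunctionality
#' analysis — and their species recorded in the result. When trait rows
#' are finer than abundance columns (size-class nodes), an explicit
#' `nodeMap` from node id to abundance column is required; name-based
#' guessing is refused.
#'
#' @param part a [Partition-class].
#' @param abundance a [SampleMatrix-class] of kind `"abundance"`.
#' @param minClusterSize minimum member count for a cluster to be
#'   retained (default 2).
#' @param nodeMap optional named character vector, node id -> abundance
#'   column; defaults to the identity.
#' @param stat aggregation statistic, `"sum"` (default) or `"mean"`.
#' @param aliases optional named character vector, cluster id (`"c1"`) ->
#'   display label.
#' @return a [ClusterAbundanceTable-class].
#' @export
aggregateClusterAbundance <- function(part, abundance, minClusterSize = 2L,
                                      nodeMap = NULL, stat = c("sum", "mean"),
                                      aliases = NULL) {
  stopifnot(is(part, "Partition"), is(abundance, "SampleMatrix"))
  stat <- match.arg(stat)
  if (abundance@kind != "abundance")
    stop("abundance table must have kind 'abundance'")
  nodes <- names(part@membership)
  if (is.null(nodeMap)) nodeMap <- stats::setNames(nodes, nodes)
  unmapped <- setdiff(nodes, names(nodeMap))
  if (length(unmapped))
    stop("nodes without an abundance mapping: ",
         paste(unmapped, collapse = ", "))
  absent <- setdiff(unname(nodeMap[nodes]), variableIds(abundance))
  if (length(absent))
    stop("species absent from abundance table: ",
         paste(unique(absent), collapse = ", "))
  lab <- clusterLabels(part)
  sizes <- table(lab)
  keep <- names(sizes)[sizes >= minClusterSize]
  dropped <- nodes[!lab %in% keep]
  keep <- keep[order(as.integer(sub("^c", "", keep)))]
  if (length(keep) == 0) stop("no cluster satisfies the minimum size")
  vals <- tableValues(abundance)
  cols <- lapply(keep, function(k) {
    members <- nodes[lab == k]
    block <- vals[, nodeMap[members], drop = FALSE]
    if (stat == "sum") rowSums(block) else rowMeans(block)
  })
  m <- do.call(cbind, cols)
  labels <- if (!is.null(aliases)) {
    ifelse(keep %in% names(aliases), aliases[keep], keep)
  } else keep
  unknownAlias <- setdiff(names(aliases), paste0("c", unique(part@membership)))
  if (length(unknownAlias))
    stop("aliases reference unknown clusters: ",
         paste(unknownAlias, collapse = ", "))
  colnames(m) <- labels
  rownames(m) <- sampleIds(abundance)
  prov <- lapply(keep, function(k) nodes[lab == k])
  names(prov) <- labels
  new("ClusterAbundanceTable", values = m, kind = "abundance",
      provenance = prov, excluded = dropped)
}

#' @rdname detectClusters
#' @param part a [Partition-class].
#' @param path output CSV path (columns node, cluster, excluded_flag).
#' @export
writePartition <- function(part, path) {
  df <- data.frame(node = names(part@membership),
                   cluster = clusterLabels(part),
                   excluded_flag = names(part@membership) %in% part@excluded,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
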