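#' Assemble the directed multifunctionality network
#'
#' Builds the directed source-to-function graph from a two-stage DistLM
#' report: one edge per (predictor base variable, function) whose
#' retained selection steps sum to a positive sequential variance
#' explained, weighted by that sum (proportion scale). Trait-cluster and
#' environmental predictors are sources, functions are targets; edges
#' never connect two sources or two functions. Node size is the
#' out-degree of a source and the in-degree of a function. Every
#' function in the report appears as a node even when nothing explains
#' it.
#'
#' @param report a [DistLMReport-class].
#' @param aliases optional named character vector renaming nodes for
#'   display (e.g. `c(c1 = "small mobile top 2 cm dwellers")`); an alias
#'   naming an unknown node is an error.
#' @return a [MultifunctionalNetwork-class].
#' @export
assembleMultifunc <- function(report, aliases = NULL) {
  stopifnot(is(report, "DistLMReport"))
  fns <- names(report@results)
  edges <- do.call(rbind, lapply(fns, function(fn) {
    st <- report@results[[fn]]$steps
    st <- st[st$retained, , drop = FALSE]
    if (!nrow(st)) return(NULL)
    agg <- stats::aggregate(delta_r2 ~ base + stage, data = st, FUN = sum)
    agg <- agg[agg$delta_r2 > 0, , drop = FALSE]
    if (!nrow(agg)) return(NULL)
    data.frame(source = agg$base, target = fn, weight = agg$delta_r2,
               role = ifelse(agg$stage == "traits", "cluster", "environment"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(source = character(0), target = character(0),
                        weight = numeric(0), role = character(0),
                        stringsAsFactors = FALSE)
  srcRole <- unique(edges[, c("source", "role")])
  if (anyDuplicated(srcRole$source))
    stop("predictor appears as both cluster and environment: ",
         paste(srcRole$source[duplicated(srcRole$source)], collapse = ", "))
  nodes <- rbind(
    data.frame(name = srcRole$source, role = srcRole$role,
               stringsAsFactors = FALSE),
    data.frame(name = fns, role = "function", stringsAsFactors = FALSE))
  if (!is.null(aliases)) {
    unknown <- setdiff(names(aliases), nodes$name)
    if (length(unknown))
      stop("aliases reference unknown nodes: ",
           paste(unknown, collapse = ", "))
    ren <- function(x) ifelse(x %in% names(aliases), aliases[x], x)
    nodes$name <- ren(nodes$name)
    if (nrow(edges)) {
      edges$source <- ren(edges$source)
      edges$target <- ren(edges$target)
    }
  }
  nodes$size <- vapply(seq_len(nrow(nodes)), function(i) {
    if (nodes$role[i] == "function") sum(edges$target == nodes$name[i])
    else sum(edges$source == nodes$name[i])
  }, numeric(1))
  nodes <- nodes[order(nodes$role, nodes$name), , drop = FALSE]
  rownames(nodes) <- NULL
  edges <- edges[order(edges$source, edges$target),
                 c("source", "target", "weight"), drop = FALSE]
  rownames(edges) <- NULL
  new("MultifunctionalNetwork", nodes = nodes, edges = edges)
}

#' Connectivity summary of a multifunctionality network
#'
#' Per node: role, degree (out-degree for sources, in-degree for
#' functions) and summed incident edge weight, sorted by decreasing
#' degree with alphabetical tie-break. A function's summed in-weight
#' equals its total explained variance (row C of the report).
#'
#' @param net a [MultifunctionalNetwork-class].
#' @return data.frame with columns `node`, `role`, `degree`,
#'   `weight_sum`.
#' @export
connectivitySummary <- function(net) {
  nd <- net@nodes; ed <- net@edges
  if (!nrow(nd))
    return(data.frame(node = character(0), role = character(0),
                      degree = numeric(0), weight_sum = numeric(0),
                      stringsAsFactors = FALSE))
  deg <- vapply(seq_len(nrow(nd)), function(i) {
    if (nd$role[i] == "function") sum(ed$target == nd$name[i])
    else sum(ed$source == nd$name[i])
  }, numeric(1))
  wsum <- vapply(seq_len(nrow(nd)), function(i) {
    if (nd$role[i] == "function") sum(ed$weight[ed$target == nd$name[i]])
    else sum(ed$weight[ed$source == nd$name[i]])
  }, numeric(1))
  out <- data.frame(node = nd$name, role = nd$role, degree = deg,
                    weight_sum = wsum, stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rebuild a multifunctionality network from an edge CSV
#'
#' Inverse of [writeNetwork()] with `format = "edge_csv"` for directed
#' networks: node roles are recovered from the edge structure (targets
#' are functions; sources keep the `cluster` role unless named in
#' `envVars`).
#'
#' @param path edge CSV path written by [writeNetwork()].
#' @param envVars character vector of source names carrying the
#'   `environment` role.
#' @return a [MultifunctionalNetwork-class].
#' @export
readMultifuncNetwork <- function(path, envVars = character(0)) {
  df <- readNetworkEdges(path)
  if (nrow(df) && !all(df$directed))
    stop("edge CSV does not describe a directed network")
  fnIso <- attr(df, "isolates")
  fns <- sort(unique(c(df$target, fnIso)))
  srcs <- sort(unique(df$source))
  nodes <- rbind(
    data.frame(name = srcs,
               role = ifelse(srcs %in% envVars, "environment", "cluster"),
               stringsAsFactors = FALSE),
    data.frame(name = fns, role = "function", stringsAsFactors = FALSE))
  nodes$size <- vapply(seq_len(nrow(nodes)), function(i) {
    if (nodes$role[i] == "function") sum(df$target == nodes$name[i])
    else sum(df$source == nodes$name[i])
  }, numeric(1))
  nodes <- nodes[order(nodes$role, nodes$name), , drop = FALSE]
  rownames(nodes) <- NULL
  edges <- df[order(df$source, df$target),
              c("source", "target", "weight"), drop = FALSE]
  rownames(edges) <- NULL
  new("MultifunctionalNetwork", nodes = nodes, edges = edges)
}
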