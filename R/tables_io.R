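#' Read a fuzzy-coded trait table
#'
#' Reads a comma-separated table whose first column holds species (or
#' species size-class) ids and whose remaining columns hold non-negative
#' fuzzy affinity scores, one column per trait modality. Scores are
#' normalized at read time so that each (species, trait-category) block is
#' proportional (sums to one); blocks summing to zero are left at zero and
#' recorded.
#'
#' @param path path to a CSV file (UTF-8, header row, "." decimal).
#' @param categoryMap named character vector mapping every modality column
#'   to its trait-category label.
#' @return a validated, normalized [FuzzyTraitTable-class].
#' @export
readFuzzyTraits <- function(path, categoryMap) {
  df <- readDelimited(path)
  if (nrow(df) == 0) stop("no species rows in ", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate species id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  checkNumericCells(m, path)
  rownames(m) <- ids
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative score at species '%s', modality '%s'",
                 rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  missing <- setdiff(colnames(m), names(categoryMap))
  if (length(missing))
    stop("modalities missing from category map: ",
         paste(missing, collapse = ", "))
  fuzzyTraitTable(m, categoryMap[colnames(m)])
}

#' Construct a fuzzy trait table from a matrix
#'
#' @param scores species x modality numeric matrix with dimnames.
#' @param categories named character vector, modality -> category.
#' @param normalize apply per-(species, category) normalization (default
#'   TRUE).
#' @return a [FuzzyTraitTable-class].
#' @export
fuzzyTraitTable <- function(scores, categories, normalize = TRUE) {
  obj <- new("FuzzyTraitTable", scores = scores,
             categories = categories[colnames(scores)],
             zeroBlocks = character(0))
  if (normalize) normalizeFuzzyTraits(obj) else obj
}

#' Normalize a fuzzy trait table per (species, category) block
#'
#' Divides each block of scores by its sum so species affinities are
#' proportional within every trait category; all-zero blocks stay zero.
#' The operation is idempotent.
#'
#' @param x a [FuzzyTraitTable-class].
#' @return the normalized [FuzzyTraitTable-class] with `zeroBlocks` filled.
#' @export
normalizeFuzzyTraits <- function(x) {
  s <- x@scores
  cats <- x@categories[colnames(s)]
  zero <- character(0)
  for (cat in unique(cats)) {
    cols <- which(cats == cat)
    blockSums <- rowSums(s[, cols, drop = FALSE])
    z <- blockSums == 0
    if (any(z)) zero <- c(zero, paste0(rownames(s)[z], "/", cat))
    nz <- which(!z)
    if (length(nz))
      s[nz, cols] <- s[nz, cols, drop = FALSE] / blockSums[nz]
  }
  new("FuzzyTraitTable", scores = s, categories = x@categories,
      zeroBlocks = zero)
}

#' Read a sample-by-variable table
#'
#' Reads a comma-separated table whose first column holds sample ids and
#' whose remaining columns are numeric variables. Empty or non-numeric
#' cells are hard errors naming the offending cell; abundance tables must
#' be non-negative.
#'
#' @param path path to a CSV file.
#' @param kind `"abundance"`, `"environment"` or `"function"`.
#' @return a validated [SampleMatrix-class].
#' @export
readSampleMatrix <- function(path, kind = c("abundance", "environment",
                                            "function")) {
  kind <- match.arg(kind)
  df <- readDelimited(path)
  if (nrow(df) == 0) stop("no samples in ", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate sample id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  checkNumericCells(m, path)
  rownames(m) <- ids
  if (kind == "abundance" && any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative abundance at sample '%s', variable '%s'",
                 rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  sampleMatrix(m, kind)
}

#' Construct a sample matrix from a numeric matrix
#'
#' @param values sample x variable numeric matrix with dimnames.
#' @param kind `"abundance"`, `"environment"` or `"function"`.
#' @return a [SampleMatrix-class].
#' @export
sampleMatrix <- function(values, kind) {
  storage.mode(values) <- "double"
  new("SampleMatrix", values = values, kind = kind)
}

#' @rdname readSampleMatrix
#' @param x a [SampleMatrix-class] to write.
#' @export
writeSampleMatrix <- function(x, path) {
  df <- data.frame(sample_id = rownames(x@values), x@values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

readDelimited <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
           colClasses = NA, na.strings = c("NA", ""))
}

checkNumericCells <- function(m, path) {
  if (!is.numeric(m)) {
    suppressWarnings(mm <- apply(m, 2, as.numeric))
    bad <- which(is.na(mm) & !is.na(m), arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("non-numeric cell in %s at row %d, column '%s'",
                   path, bad[1, 1], colnames(m)[bad[1, 2]]))
    m <- mm
  }
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    stop(sprintf("missing cell in %s at row %d, column '%s'",
                 path, bad[1, 1], colnames(m)[bad[1, 2]]))
  }
  invisible(TRUE)
}

# ---- network export / import -------------------------------------------

asIgraph <- function(net) {
  if (is(net, "TraitNetwork")) return(net@graph)
  if (is(net, "MultifunctionalNetwork")) {
    g <- igraph::graph_from_data_frame(
      net@edges[, c("source", "target", "weight"), drop = FALSE],
      directed = TRUE,
      vertices = data.frame(name = net@nodes$name, role = net@nodes$role,
                            size = as.double(net@nodes$size),
                            stringsAsFactors = FALSE))
    return(g)
  }
  stop("unsupported network object of class ", class(net))
}

#' Write a network to a Gephi-compatible file
#'
#' Supports GraphML, GEXF and a plain edge-list CSV with columns
#' `source,target,weight,directed`. Node attributes `role` and `size` are
#' carried for multifunctionality networks; edge weights are written as
#' doubles. An edge CSV written and read back reproduces the node set,
#' directedness and weights to full double precision.
#'
#' @param net a [TraitNetwork-class] or [MultifunctionalNetwork-class].
#' @param path output file path.
#' @param format `"graphml"`, `"gexf"` or `"edge_csv"`.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(net, path, format = c("graphml", "gexf",
                                               "edge_csv")) {
  format <- tryCatch(match.arg(format), error = function(e)
    stop("unknown format '", format[1],
         "'; supported: graphml, gexf, edge_csv"))
  g <- asIgraph(net)
  directed <- igraph::is_directed(g)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "gexf") {
    writeGexf(g, path)
  } else {
    nodes <- igraph::V(g)$name
    if (igraph::ecount(g) > 0) {
      el <- igraph::as_edgelist(g)
      df <- data.frame(source = el[, 1], target = el[, 2],
                       weight = sprintf("%.12g", igraph::E(g)$weight),
                       directed = directed, stringsAsFactors = FALSE)
    } else {
      df <- data.frame(source = character(0), target = character(0),
                       weight = character(0), directed = logical(0))
    }
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    # isolates would be lost from a pure edge list; keep them in a sidecar
    iso <- nodes[igraph::degree(g) == 0]
    if (length(iso))
      writeLines(iso, paste0(path, ".nodes"))
  }
  invisible(path)
}

#' @rdname writeNetwork
#' @return `readNetworkEdges()` returns a data.frame with columns
#'   `source`, `target`, `weight`, `directed` (plus any isolate nodes from
#'   the sidecar file as attribute `"isolates"`).
#' @export
readNetworkEdges <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 colClasses = c(source = "character", target = "character",
                                weight = "numeric", directed = "logical"))
  sidecar <- paste0(path, ".nodes")
  attr(df, "isolates") <- if (file.exists(sidecar)) readLines(sidecar)
                          else character(0)
  df
}

# GEXF 1.2 writer (draft spec, Gephi-compatible). igraph has no GEXF
# support, so the XML is assembled directly; attvalues carry role/size.
writeGexf <- function(g, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  directed <- if (igraph::is_directed(g)) "directed" else "undirected"
  vnames <- igraph::V(g)$name
  role <- igraph::vertex_attr(g, "role")
  size <- igraph::vertex_attr(g, "size")
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">',
    sprintf('  <graph mode="static" defaultedgetype="%s">', directed),
    '    <attributes class="node">',
    '      <attribute id="0" title="role" type="string"/>',
    '      <attribute id="1" title="size" type="double"/>',
    '    </attributes>',
    '    <nodes>')
  for (i in seq_along(vnames)) {
    r <- if (is.null(role)) "species" else role[i]
    s <- if (is.null(size)) 0 else size[i]
    lines <- c(lines,
      sprintf('      <node id="%s" label="%s">', esc(vnames[i]), esc(vnames[i])),
      '        <attvalues>',
      sprintf('          <attvalue for="0" value="%s"/>', esc(r)),
      sprintf('          <attvalue for="1" value="%.12g"/>', s),
      '        </attvalues>',
      '      </node>')
  }
  lines <- c(lines, '    </nodes>', '    <edges>')
  if (igraph::ecount(g) > 0) {
    el <- igraph::as_edgelist(g)
    w <- igraph::E(g)$weight
    for (i in seq_len(nrow(el)))
      lines <- c(lines,
        sprintf('      <edge id="%d" source="%s" target="%s" weight="%.12g"/>',
                i - 1L, esc(el[i, 1]), esc(el[i, 2]), w[i]))
  }
  lines <- c(lines, '    </edges>', '  </graph>', '</gexf>')
  writeLines(lines, path)
  invisible(path)
}
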