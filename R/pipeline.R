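#' Read a modality-to-category map CSV
#'
#' Two columns, `modality` and `category`.
#'
#' @param path CSV path.
#' @return named character vector modality -> category.
#' @export
readCategoryMap <- function(path) {
  df <- readDelimited(path)
  if (!all(c("modality", "category") %in% names(df)))
    stop("category map needs columns 'modality' and 'category'")
  if (anyDuplicated(df$modality))
    stop("modalities mapped to more than one category: ",
         paste(unique(df$modality[duplicated(df$modality)]), collapse = ", "))
  stats::setNames(as.character(df$category), as.character(df$modality))
}

#' Run the full multifunctionality pipeline from a configuration file
#'
#' Executes the whole analysis in order: read and normalize the trait
#' table; binarize; cooccurrence scan; trait-network assembly; Louvain
#' cluster detection; cluster-abundance aggregation with exclusion;
#' two-stage DistLM over every function; multifunctionality-network
#' assembly. Every artifact (scan CSV, partition CSV, report JSON,
#' Table-style CSV, network files, run log) is written under the
#' configured output directory; the log records the configuration, its
#' hash, the seed and per-stage summaries. Any stage failure aborts with
#' the stage name.
#'
#' The configuration file holds the [RunConfig-class] keys plus an
#' `inputs` block (`traits`, `categories`, `abundance`, `environment`,
#' `functions`, optional `node_map`, `aliases`) and an `output_dir`.
#'
#' @param configPath YAML or JSON configuration path.
#' @return (invisibly) a list with all intermediate objects: `config`,
#'   `traits`, `binary`, `scan`, `network`, `partition`, `clusters`,
#'   `report`, `multifunc`, and the `outputDir`.
#' @export
runPipeline <- function(configPath) {
  raw <- if (grepl("\\.json$", configPath, ignore.case = TRUE))
    jsonlite::fromJSON(configPath, simplifyVector = TRUE)
  else yaml::read_yaml(configPath)
  cfg <- readRunConfig(configPath)
  inputs <- raw$inputs
  for (field in c("traits", "categories", "abundance", "environment",
                  "functions")) {
    if (is.null(inputs[[field]]))
      stop("configuration is missing inputs$", field)
    if (!file.exists(inputs[[field]]))
      stop("inputs$", field, " does not exist: ", inputs[[field]])
  }
  outDir <- if (is.null(raw$output_dir)) "." else raw$output_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(outDir, "run.log")
  unlink(log)
  logLine(log, "INFO", paste("config hash", configHash(cfg),
                             "seed", cfg@seed))
  for (s in slotNames(cfg))
    logLine(log, "INFO", sprintf("config %s = %s", s,
                                 paste(slot(cfg, s), collapse = ",")))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      logLine(log, "ERROR", paste(name, "failed:", conditionMessage(e)))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  traits <- stage("read_traits", {
    cmap <- readCategoryMap(inputs$categories)
    readFuzzyTraits(inputs$traits, cmap)
  })
  if (length(traits@zeroBlocks))
    logLine(log, "WARN", paste("zero fuzzy blocks:",
                               paste(traits@zeroBlocks, collapse = "; ")))
  abundance <- stage("read_abundance",
                     readSampleMatrix(inputs$abundance, "abundance"))
  env <- stage("read_environment",
               readSampleMatrix(inputs$environment, "environment"))
  functions <- stage("read_functions",
                     readSampleMatrix(inputs$functions, "function"))
  binary <- stage("binarize", withCallingHandlers(
    binarizeTraits(traits, cfg@binarizeThreshold),
    warning = function(w) {
      logLine(log, "WARN", conditionMessage(w))
      invokeRestart("muffleWarning")
    }))
  scan <- stage("cooccurrence_scan",
                cooccurrenceScan(binary, alpha = cfg@alpha,
                                 minExpected = cfg@minExpected,
                                 bhCorrect = cfg@bhCorrect))
  writeScan(scan, file.path(outDir, "cooccurrence_scan.csv"))
  logLine(log, "INFO", sprintf("scan: %d pairs tested, %d significant",
                               nrow(scan), sum(scan$significant)))
  net <- stage("build_network",
               buildTraitNetwork(scan, speciesIds(traits)))
  writeNetwork(net, file.path(outDir, "trait_network.graphml"), "graphml")
  part <- stage("detect_clusters",
                detectClusters(net, resolution = cfg@resolution,
                               seed = cfg@seed,
                               restarts = cfg@louvainRestarts))
  logLine(log, "INFO", sprintf("clusters: %d detected, Q = %.4f",
                               length(unique(clusterAssignments(part))),
                               partitionQ(part)))
  nodeMap <- if (!is.null(inputs$node_map)) {
    nm <- readDelimited(inputs$node_map)
    stats::setNames(as.character(nm[[2]]), as.character(nm[[1]]))
  } else NULL
  clusters <- stage("aggregate", aggregateClusterAbundance(
    part, abundance, minClusterSize = cfg@minClusterSize,
    nodeMap = nodeMap))
  part@excluded <- clusters@excluded
  writePartition(part, file.path(outDir, "partition.csv"))
  if (length(clusters@excluded))
    logLine(log, "WARN", paste("excluded species:",
                               paste(clusters@excluded, collapse = ", ")))
  report <- stage("distlm", runTwoStage(functions, clusters, env, cfg,
                                        log = log))
  writeReport(report, file.path(outDir, "distlm_report.json"))
  reportTable(report, file.path(outDir, "distlm_table.csv"))
  aliases <- if (!is.null(inputs$aliases)) {
    al <- readDelimited(inputs$aliases)
    stats::setNames(as.character(al[[2]]), as.character(al[[1]]))
  } else NULL
  mf <- stage("assemble", assembleMultifunc(report, aliases = aliases))
  writeNetwork(mf, file.path(outDir, "multifunc_network.gexf"), "gexf")
  writeNetwork(mf, file.path(outDir, "multifunc_network_edges.csv"),
               "edge_csv")
  write.csv(connectivitySummary(mf),
            file.path(outDir, "connectivity_summary.csv"),
            row.names = FALSE, quote = FALSE)
  logLine(log, "INFO", "pipeline complete")
  invisible(list(config = cfg, traits = traits, binary = binary,
                 scan = scan, network = net, partition = part,
                 clusters = clusters, report = report, multifunc = mf,
                 outputDir = outDir))
}
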