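#' Create a pipeline run configuration
#'
#' All arguments have the pipeline's documented defaults; see
#' [RunConfig-class] for the meaning of each knob.
#'
#' @param alpha one-sided significance level (default 0.05).
#' @param minExpected expected-cooccurrence filter (default 1).
#' @param binarizeThreshold fuzzy-score cutoff, possession means score
#'   strictly greater (default 0).
#' @param resolution Louvain resolution (default 1).
#' @param louvainRestarts seeded Louvain restarts (default 20).
#' @param seed integer seed (default 1).
#' @param nPermutations permutations per sequential test (default 9999).
#' @param transformFamily `"square"` or `"sqrt"` (default `"square"`).
#' @param transformConstraint `"strict"` or `"lenient"` (default
#'   `"strict"`).
#' @param minClusterSize minimum retained cluster size (default 2).
#' @param significanceRule `"selected_and_p"` or `"selected"` (default
#'   `"selected_and_p"`).
#' @param bhCorrect Benjamini-Hochberg correction over the cooccurrence
#'   scan (default FALSE).
#' @return a validated [RunConfig-class] object.
#' @export
runConfig <- function(alpha = 0.05, minExpected = 1, binarizeThreshold = 0,
                      resolution = 1, louvainRestarts = 20L, seed = 1L,
                      nPermutations = 9999L, transformFamily = "square",
                      transformConstraint = "strict", minClusterSize = 2L,
                      significanceRule = "selected_and_p",
                      bhCorrect = FALSE) {
  new("RunConfig",
      alpha = as.numeric(alpha), minExpected = as.numeric(minExpected),
      binarizeThreshold = as.numeric(binarizeThreshold),
      resolution = as.numeric(resolution),
      louvainRestarts = as.integer(louvainRestarts), seed = as.integer(seed),
      nPermutations = as.integer(nPermutations),
      transformFamily = transformFamily,
      transformConstraint = transformConstraint,
      minClusterSize = as.integer(minClusterSize),
      significanceRule = significanceRule,
      bhCorrect = isTRUE(bhCorrect))
}

configAsList <- function(cfg) {
  out <- lapply(slotNames(cfg), function(s) slot(cfg, s))
  names(out) <- slotNames(cfg)
  out
}

#' Read or write a run configuration file
#'
#' Configurations are stored as YAML (or JSON) with keys matching the
#' [RunConfig-class] slots; unknown keys are an error so that typos fail
#' loud. Missing keys fall back to the defaults of [runConfig()].
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `readRunConfig()` returns a [RunConfig-class];
#'   `writeRunConfig()` returns `path` invisibly.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(runConfig))
  extra <- setdiff(names(vals), c(known, "inputs", "output_dir"))
  if (length(extra))
    stop("unknown configuration keys: ", paste(extra, collapse = ", "))
  do.call(runConfig, vals[intersect(names(vals), known)])
}

#' @rdname readRunConfig
#' @param cfg a [RunConfig-class] object.
#' @export
writeRunConfig <- function(cfg, path) {
  stopifnot(is(cfg, "RunConfig"))
  vals <- configAsList(cfg)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path)
  }
  invisible(path)
}

#' Hash of a configuration, recorded in every output for provenance
#' @param cfg a [RunConfig-class].
#' @return character scalar.
#' @export
configHash <- function(cfg) {
  txt <- paste(vapply(slotNames(cfg),
                      function(s) paste0(s, "=", paste(slot(cfg, s), collapse = ",")),
                      character(1)),
               collapse = ";")
  # small polynomial rolling hash, enough to fingerprint a config in logs
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

# Minimal structured run log: one writer shared by all pipeline stages.
logLine <- function(log, level, msg) {
  if (is.null(log)) return(invisible(NULL))
  line <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  level, msg)
  cat(line, "\n", file = log, append = TRUE, sep = "")
  invisible(NULL)
}
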