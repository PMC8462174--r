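#' Two-stage distance-based linear model over all ecosystem functions
#'
#' For each function column, fits the study's two-stage selection
#' protocol on the Euclidean distance of the raw function values.
#' Stage 1 forward-selects among the expanded trait-cluster abundance
#' columns; the clusters that prove significant (per the configured
#' rule) are then forced into a second model to which environmental
#' columns are forward-added. Stage totals per function:
#' A = variance explained by the retained trait clusters, B = variance
#' added by the retained environmental columns (the significance rule
#' applies to both stages), C = A + B; the
#' sequential per-step increases along the final path sum exactly to C.
#'
#' @param functions [SampleMatrix-class] of kind `"function"`.
#' @param clusters a [ClusterAbundanceTable-class] (or abundance-kind
#'   [SampleMatrix-class]) of trait-cluster abundances.
#' @param env [SampleMatrix-class] of kind `"environment"`.
#' @param cfg a [RunConfig-class]; governs the transform family and
#'   constraint, permutation count, alpha and significance rule.
#' @param log optional path of a run log to append stage summaries to.
#' @return a [DistLMReport-class].
#' @export
runTwoStage <- function(functions, clusters, env, cfg = runConfig(),
                        log = NULL) {
  stopifnot(is(functions, "SampleMatrix"), is(clusters, "SampleMatrix"),
            is(env, "SampleMatrix"), is(cfg, "RunConfig"))
  ids <- sampleIds(functions)
  for (tbl in list(clusters = clusters, env = env)) {
    if (!identical(sampleIds(tbl), ids)) {
      d1 <- setdiff(ids, sampleIds(tbl)); d2 <- setdiff(sampleIds(tbl), ids)
      stop("sample-id mismatch between tables",
           if (length(d1)) paste0("; missing: ", paste(d1, collapse = ", ")),
           if (length(d2)) paste0("; extra: ", paste(d2, collapse = ", ")),
           if (!length(c(d1, d2))) "; same ids but different order")
    }
  }
  n <- length(ids)
  candC <- expandTransforms(clusters, cfg@transformFamily)
  candE <- expandTransforms(env, cfg@transformFamily)
  for (d in c(candC$degenerate, candE$degenerate))
    logLine(log, "WARN", paste("degenerate predictor column excluded:", d))
  fnames <- variableIds(functions)
  results <- vector("list", length(fnames))
  names(results) <- fnames
  for (fi in seq_along(fnames)) {
    fn <- fnames[fi]
    y <- tableValues(functions)[, fn]
    gram <- gowerCenter(as.matrix(dist(y)))
    seedF <- cfg@seed + 101L * fi
    steps1 <- forwardSelect(gram, candC, forced = NULL,
                            constraint = cfg@transformConstraint,
                            nPerm = cfg@nPermutations, seed = seedF)
    retain <- if (cfg@significanceRule == "selected_and_p" && nrow(steps1))
      steps1$p_perm <= cfg@alpha else rep(TRUE, nrow(steps1))
    kept <- steps1[retain, , drop = FALSE]
    # re-walk the retained path so the sequential increments are the ones
    # actually reported (dropping a middle step changes those after it)
    keptIdx <- match(paste(kept$base, kept$transform),
                     paste(candC$meta$base, candC$meta$transform))
    path1 <- sequentialPath(gram, candC$X[, keptIdx, drop = FALSE],
                            candC$meta[keptIdx, , drop = FALSE],
                            forced = NULL, nPerm = cfg@nPermutations,
                            seed = seedF + 1L)
    forcedX <- candC$X[, keptIdx, drop = FALSE]
    steps2 <- forwardSelect(gram, candE,
                            forced = if (length(keptIdx)) forcedX else NULL,
                            constraint = cfg@transformConstraint,
                            nPerm = cfg@nPermutations, seed = seedF + 2L)
    retain2 <- if (cfg@significanceRule == "selected_and_p" && nrow(steps2))
      steps2$p_perm <= cfg@alpha else rep(TRUE, nrow(steps2))
    kept2 <- steps2[retain2, , drop = FALSE]
    kept2Idx <- match(paste(kept2$base, kept2$transform),
                      paste(candE$meta$base, candE$meta$transform))
    path2 <- sequentialPath(gram, candE$X[, kept2Idx, drop = FALSE],
                            candE$meta[kept2Idx, , drop = FALSE],
                            forced = if (length(keptIdx)) forcedX else NULL,
                            nPerm = cfg@nPermutations, seed = seedF + 3L)
    A <- sum(path1$delta_r2)
    B <- sum(path2$delta_r2)
    allSteps <- rbind(
      cbind(path1, stage = rep("traits", nrow(path1)),
            retained = rep(TRUE, nrow(path1))),
      cbind(path2, stage = rep("environment", nrow(path2)),
            retained = rep(TRUE, nrow(path2))))
    dropped <- rbind(cbind(steps1[!retain, , drop = FALSE],
                           stage = rep("traits", sum(!retain))),
                     cbind(steps2[!retain2, , drop = FALSE],
                           stage = rep("environment", sum(!retain2))))
    if (nrow(dropped)) {
      allSteps <- rbind(allSteps,
        cbind(dropped, retained = rep(FALSE, nrow(dropped))))
      logLine(log, "INFO", sprintf(
        "%s: selections dropped by significance rule: %s",
        fn, paste(dropped$base, collapse = ", ")))
    }
    rownames(allSteps) <- NULL
    results[[fn]] <- list(steps = allSteps, A = A, B = B, C = A + B)
    logLine(log, "INFO", sprintf("%s: A=%.4f B=%.4f C=%.4f", fn, A, B, A + B))
  }
  new("DistLMReport", results = results, n = as.integer(n), config = cfg)
}

# sequential R^2 decomposition along a fixed, ordered set of columns
sequentialPath <- function(gram, X, meta, forced = NULL, nPerm = 999L,
                           seed = 1L) {
  n <- nrow(gram$G)
  out <- data.frame(base = character(0), transform = character(0),
                    delta_r2 = numeric(0), adj_r2_after = numeric(0),
                    pseudo_F = numeric(0), p_perm = numeric(0),
                    stringsAsFactors = FALSE)
  curX <- if (is.null(forced)) matrix(0, n, 0) else forced
  curR2 <- fitR2(gram, curX)$r2
  for (j in seq_len(ncol(X))) {
    newX <- cbind(curX, X[, j, drop = FALSE])
    fit <- fitR2(gram, newX)
    mf <- ncol(newX)
    Fobs <- (fit$r2 - curR2) / ((1 - fit$r2) / (n - mf - 1))
    p <- permutationPvalue(gram, X[, j, drop = FALSE],
                           if (ncol(curX) > 0) curX else NULL,
                           nPerm = nPerm, seed = seed + j)$p
    out <- rbind(out, data.frame(
      base = meta$base[j], transform = meta$transform[j],
      delta_r2 = fit$r2 - curR2,
      adj_r2_after = adjustedR2(fit$r2, n, mf),
      pseudo_F = Fobs, p_perm = p, stringsAsFactors = FALSE))
    curX <- newX
    curR2 <- fit$r2
  }
  out
}

#' Stage totals of a DistLM report
#'
#' @param report a [DistLMReport-class].
#' @return data.frame with one row per function and columns `A` (trait
#'   clusters), `B` (environmental characteristics), `C` (total).
#' @export
stageTotals <- function(report) {
  do.call(rbind, lapply(names(report@results), function(fn) {
    r <- report@results[[fn]]
    data.frame(fn = fn, A = r$A, B = r$B, C = r$C,
               stringsAsFactors = FALSE)
  }))
}

#' Serialize a DistLM report to JSON
#'
#' @param report a [DistLMReport-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path) {
  out <- list(
    n = report@n,
    config = configAsList(report@config),
    config_hash = configHash(report@config),
    functions = lapply(report@results, function(r)
      list(steps = r$steps, A = r$A, B = r$B, C = r$C)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

transformFootnote <- function(transforms) {
  has <- function(x) any(transforms %in% x)
  poly <- has(c("square", "sqrt"))
  if (has("log10p1") && (has("raw") || poly)) return("c")
  if (has("log10p1") || poly || (has("raw") && poly)) return("b")
  if (identical(sort(unique(transforms)), "raw")) return("a")
  "b"  # raw + square falls through has(poly) above; defensive default
}

#' Export a predictors-by-functions selection table
#'
#' One row per predictor base variable, one column per function; cells
#' hold the summed sequential variance explained of that predictor's
#' retained columns with a transform-set footnote letter (a: raw only;
#' b: log only, square only, or raw plus square; c: log together with
#' raw or square). Three trailing rows carry the A/B/C stage totals.
#'
#' @param report a [DistLMReport-class].
#' @param path optional CSV output path.
#' @return the table as a data.frame (invisibly when `path` is given).
#' @export
reportTable <- function(report, path = NULL) {
  fns <- names(report@results)
  bases <- unique(unlist(lapply(report@results, function(r)
    r$steps$base[r$steps$retained])))
  tab <- matrix("-", nrow = length(bases) + 3, ncol = length(fns),
                dimnames = list(c(bases, "(A) trait clusters R2",
                                  "(B) environment R2", "(C) total R2"),
                                fns))
  for (fn in fns) {
    r <- report@results[[fn]]
    st <- r$steps[r$steps$retained, , drop = FALSE]
    for (b in unique(st$base)) {
      rows <- st[st$base == b, , drop = FALSE]
      tab[b, fn] <- sprintf("%.4g^%s", sum(rows$delta_r2),
                            transformFootnote(rows$transform))
    }
    tab["(A) trait clusters R2", fn] <- sprintf("%.4g", r$A)
    tab["(B) environment R2", fn] <- sprintf("%.4g", r$B)
    tab["(C) total R2", fn] <- sprintf("%.4g", r$C)
  }
  df <- data.frame(predictor = rownames(tab), tab, check.names = FALSE,
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  if (!is.null(path)) {
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    return(invisible(df))
  }
  df
}
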