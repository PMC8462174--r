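#' Parameters for the synthetic study generator
#'
#' The generator plants a known trait-cluster structure and known linear
#' predictor-to-function effects so every pipeline stage can be checked
#' against ground truth. Defaults emulate the statistical shape of a
#' soft-sediment macrofauna study: six trait clusters of six species
#' (size-class) rows, a modality pool large enough for exact
#' cooccurrence tests to resolve the planted overlap structure, 49
#' samples, overdispersed (negative-binomial) counts, four
#' sediment-style environmental variables, and function responses that
#' are linear in standardized cluster abundances and environmental
#' values plus Gaussian noise.
#'
#' @param nClusters planted trait clusters (default 6).
#' @param speciesPerCluster species rows per cluster (default 6).
#' @param nModalities size of the modality pool (default 180; each
#'   cluster owns a disjoint 30-modality core).
#' @param withinOverlap probability a member carries each modality of its
#'   own cluster core (default 0.8).
#' @param betweenNoise probability a member carries any given off-cluster
#'   modality (default 0.2).
#' @param nCategories trait categories the modalities are split into
#'   (default 30, i.e. 6 modalities per category).
#' @param nSamples samples (default 49: seven plots at seven sites).
#' @param abundanceDispersion negative-binomial size parameter (default
#'   2; `Inf` gives Poisson counts).
#' @param meanAbundance per-cluster mean count (recycled; default 20).
#' @param envSpec named list of environmental variable distributions,
#'   each `list(dist = "uniform", min, max)` or
#'   `list(dist = "normal", mean, sd)`.
#' @param effectSpec data.frame with columns `target`, `source`,
#'   `coefficient`: linear effects of standardized sources (planted
#'   cluster ids `c1...` or environmental variables) on functions.
#' @param noiseSd Gaussian noise s.d. per function (recycled; default 1).
#' @param functionNames names of the function columns (defaults to the
#'   targets of `effectSpec`).
#' @param seed integer seed; every generator is a pure function of
#'   `(params, seed)`.
#' @return a validated parameter list of class `SimulationParams`.
#' @export
simulationParams <- function(nClusters = 6L, speciesPerCluster = 6L,
                             nModalities = 180L, withinOverlap = 0.8,
                             betweenNoise = 0.2, nCategories = 30L,
                             nSamples = 49L, abundanceDispersion = 2,
                             meanAbundance = 20,
                             envSpec = defaultEnvSpec(),
                             effectSpec = defaultEffectSpec(),
                             noiseSd = 1, functionNames = NULL,
                             seed = 1L) {
  p <- list(nClusters = as.integer(nClusters),
            speciesPerCluster = as.integer(speciesPerCluster),
            nModalities = as.integer(nModalities),
            withinOverlap = withinOverlap, betweenNoise = betweenNoise,
            nCategories = as.integer(nCategories),
            nSamples = as.integer(nSamples),
            abundanceDispersion = abundanceDispersion,
            meanAbundance = meanAbundance, envSpec = envSpec,
            effectSpec = effectSpec, noiseSd = noiseSd,
            functionNames = functionNames, seed = as.integer(seed))
  if (p$withinOverlap < 0 || p$withinOverlap > 1 ||
      p$betweenNoise < 0 || p$betweenNoise > 1)
    stop("withinOverlap and betweenNoise must be probabilities")
  if (p$nSamples < 4) stop("need at least 4 samples")
  if (p$nClusters * p$speciesPerCluster < 2)
    stop("need at least two species")
  if (!is.null(p$effectSpec) && any(!is.finite(p$effectSpec$coefficient)))
    stop("effect coefficients must be finite")
  class(p) <- "SimulationParams"
  p
}

#' @rdname simulationParams
#' @export
defaultEnvSpec <- function() {
  list(mud = list(dist = "uniform", min = 0, max = 60),
       som = list(dist = "uniform", min = 0.5, max = 6),
       shell_hash = list(dist = "uniform", min = 0, max = 40),
       water_content = list(dist = "uniform", min = 20, max = 60))
}

#' @rdname simulationParams
#' @export
defaultEffectSpec <- function() {
  # one or two cluster effects plus at most one environmental effect per
  # function, with coefficients on standardized sources (noise s.d. 1)
  data.frame(
    target = c("ammonium", "ammonium", "nox", "nox", "phosphate",
               "denitrification", "oxygen_consumption",
               "oxygen_consumption", "oxygen_production",
               "om_degradation", "primary_producers", "primary_producers"),
    source = c("c1", "mud", "c2", "shell_hash", "som",
               "c1", "c1", "mud", "c5", "c1", "c4", "c2"),
    coefficient = c(0.7, 0.5, 0.6, 0.7, 0.8,
                    0.8, 0.9, 0.6, 1.0, 0.5, 1.0, 0.6),
    stringsAsFactors = FALSE)
}

#' Coefficient achieving a target partial R-squared
#'
#' For effects on standardized, roughly orthogonal sources with noise
#' s.d. `noiseSd`, a coefficient `noiseSd * sqrt(r / (1 - sum(rAll)))`
#' yields expected partial R-squared `r` when the effects in `rAll`
#' share the function.
#'
#' @param r target partial R-squared of this effect.
#' @param rAll partial R-squared of all effects on the same function
#'   (including `r`).
#' @param noiseSd noise standard deviation.
#' @return coefficient value.
#' @export
effectCoefficient <- function(r, rAll = r, noiseSd = 1) {
  if (sum(rAll) >= 1) stop("total planted R^2 must be < 1")
  noiseSd * sqrt(r / (1 - sum(rAll)))
}

#' Simulate a fuzzy-coded trait table with planted clusters
#'
#' Each planted cluster owns a disjoint core of
#' `floor(nModalities / nClusters)` modalities; a member species carries
#' each core modality with probability `withinOverlap` and each
#' off-cluster modality with probability `betweenNoise`. Carried
#' modalities receive affinity 1 and the table is normalized per
#' (species, category) block, so binarizing at threshold 0 recovers the
#' planted presence pattern exactly.
#'
#' @param p a [simulationParams()] object.
#' @return list with `traits` ([FuzzyTraitTable-class]) and `planted`
#'   (named integer vector of true cluster labels).
#' @export
simulateTraits <- function(p) {
  stopifnot(inherits(p, "SimulationParams"))
  K <- p$nClusters; S <- p$speciesPerCluster; M <- p$nModalities
  coreSize <- M %/% K
  if (coreSize < 1) stop("cluster core sets exceed the modality pool")
  set.seed(p$seed)
  modalities <- sprintf("m%03d", seq_len(M))
  core <- split(seq_len(K * coreSize), rep(seq_len(K), each = coreSize))
  planted <- rep(seq_len(K), each = S)
  species <- sprintf("sp%02d_c%d", seq_len(K * S), planted)
  scores <- matrix(0, K * S, M, dimnames = list(species, modalities))
  for (i in seq_len(K * S)) {
    own <- core[[planted[i]]]
    scores[i, own] <- rbinom(length(own), 1, p$withinOverlap)
    oth <- setdiff(seq_len(M), own)
    scores[i, oth] <- rbinom(length(oth), 1, p$betweenNoise)
  }
  catSize <- ceiling(M / p$nCategories)
  categories <- stats::setNames(
    sprintf("cat%02d", rep(seq_len(p$nCategories), each = catSize)[seq_len(M)]),
    modalities)
  list(traits = fuzzyTraitTable(scores, categories),
       planted = stats::setNames(as.integer(planted), species))
}

#' Simulate abundance and environment tables
#'
#' Species counts are negative-binomial with cluster-specific means
#' (size parameter `abundanceDispersion`; `Inf` gives the Poisson
#' limit); environmental variables are drawn per `envSpec`.
#'
#' @param p a [simulationParams()] object.
#' @param planted named integer vector of species cluster labels, as
#'   returned by [simulateTraits()].
#' @return list with `abundance` and `environment`
#'   ([SampleMatrix-class]).
#' @export
simulateCommunity <- function(p, planted) {
  stopifnot(inherits(p, "SimulationParams"))
  if (!is.infinite(p$abundanceDispersion) && p$abundanceDispersion <= 0)
    stop("abundanceDispersion must be positive")
  set.seed(p$seed + 1L)
  n <- p$nSamples
  mu <- rep(p$meanAbundance, length.out = p$nClusters)
  counts <- sapply(names(planted), function(sp) {
    m <- mu[planted[sp]]
    if (is.infinite(p$abundanceDispersion)) stats::rpois(n, m)
    else rnbinom(n, size = p$abundanceDispersion, mu = m)
  })
  rownames(counts) <- sprintf("s%02d", seq_len(n))
  envCols <- sapply(p$envSpec, function(sp) {
    switch(sp$dist,
           uniform = runif(n, sp$min, sp$max),
           normal = rnorm(n, sp$mean, sp$sd),
           stop("unknown distribution: ", sp$dist))
  })
  rownames(envCols) <- rownames(counts)
  list(abundance = sampleMatrix(counts, "abundance"),
       environment = sampleMatrix(envCols, "environment"))
}

#' Simulate function tables from planted linear effects
#'
#' Each function is a linear combination of standardized source columns
#' (planted-cluster abundance sums or environmental variables) plus
#' Gaussian noise. Also returns the realized sequential variance
#' explained of every planted effect, computed by ordinary least squares
#' on the realized design.
#'
#' @param p a [simulationParams()] object.
#' @param clusters cluster abundance table (e.g. the planted-cluster
#'   sums from [simulateStudy()], or an [aggregateClusterAbundance()]
#'   result).
#' @param env environment [SampleMatrix-class].
#' @return list with `functions` ([SampleMatrix-class]) and `realized`
#'   (data.frame: `target`, `source`, `coefficient`, `realized_r2`).
#' @export
simulateFunctions <- function(p, clusters, env) {
  stopifnot(inherits(p, "SimulationParams"))
  set.seed(p$seed + 2L)
  sources <- cbind(tableValues(clusters), tableValues(env))
  spec <- p$effectSpec
  unknown <- setdiff(spec$source, colnames(sources))
  if (length(unknown))
    stop("unknown effect source(s): ", paste(unknown, collapse = ", "))
  fns <- p$functionNames
  if (is.null(fns)) fns <- unique(spec$target)
  n <- nrow(sources)
  sd_ <- rep(p$noiseSd, length.out = length(fns))
  vals <- matrix(0, n, length(fns),
                 dimnames = list(rownames(sources), fns))
  realized <- NULL
  for (j in seq_along(fns)) {
    fn <- fns[j]
    eff <- spec[spec$target == fn, , drop = FALSE]
    y <- rnorm(n, 0, sd_[j])
    if (nrow(eff)) {
      Z <- scale(sources[, eff$source, drop = FALSE])
      y <- y + drop(Z %*% eff$coefficient)
      # realized sequential variance explained, by projection on the
      # true design (robust to the zero-noise perfect-fit case)
      yc <- y - mean(y)
      r2prev <- 0
      for (k in seq_len(nrow(eff))) {
        Zk <- scale(Z[, seq_len(k), drop = FALSE], scale = FALSE)
        r2 <- sum(qr.fitted(qr(Zk), yc)^2) / sum(yc^2)
        realized <- rbind(realized, data.frame(
          target = fn, source = eff$source[k],
          coefficient = eff$coefficient[k],
          realized_r2 = r2 - r2prev, stringsAsFactors = FALSE))
        r2prev <- r2
      }
    }
    vals[, j] <- y
  }
  list(functions = sampleMatrix(vals, "function"),
       realized = if (is.null(realized)) data.frame(
         target = character(0), source = character(0),
         coefficient = numeric(0), realized_r2 = numeric(0)) else realized)
}

#' Simulate a complete synthetic study
#'
#' Generates all four input tables with ground truth: the fuzzy trait
#' table with planted clusters, the abundance and environment tables,
#' and function responses driven by the planted-cluster abundance sums
#' and environmental variables.
#'
#' @param p a [simulationParams()] object.
#' @return list with `traits`, `abundance`, `environment`, `functions`,
#'   `planted` (true labels), `plantedClusters`
#'   (planted-cluster abundance sums as a [SampleMatrix-class]) and
#'   `realized` (realized effect table).
#' @export
simulateStudy <- function(p = simulationParams()) {
  tr <- simulateTraits(p)
  comm <- simulateCommunity(p, tr$planted)
  sums <- sapply(sort(unique(tr$planted)), function(k)
    rowSums(tableValues(comm$abundance)[, names(tr$planted)[tr$planted == k],
                                        drop = FALSE]))
  colnames(sums) <- paste0("c", sort(unique(tr$planted)))
  plantedClusters <- sampleMatrix(sums, "abundance")
  fun <- simulateFunctions(p, plantedClusters, comm$environment)
  list(traits = tr$traits, planted = tr$planted,
       abundance = comm$abundance, environment = comm$environment,
       plantedClusters = plantedClusters, functions = fun$functions,
       realized = fun$realized)
}

#' Write a simulated study to disk
#'
#' Writes the four input CSVs (traits, trait-category map, abundance,
#' environment, functions) plus a ground-truth JSON (planted partition,
#' effect specification, realized sequential R-squared).
#'
#' @param study result of [simulateStudy()].
#' @param dir output directory (created if needed).
#' @param p the [simulationParams()] used (echoed into the JSON).
#' @return `dir`, invisibly.
#' @export
writeStudy <- function(study, dir, p = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- study$traits
  df <- data.frame(species_id = speciesIds(tr), traitScores(tr),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, file.path(dir, "traits.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(data.frame(modality = names(modalityCategories(tr)),
                       category = unname(modalityCategories(tr))),
            file.path(dir, "trait_categories.csv"), row.names = FALSE,
            quote = FALSE)
  writeSampleMatrix(study$abundance, file.path(dir, "abundance.csv"))
  writeSampleMatrix(study$environment, file.path(dir, "environment.csv"))
  writeSampleMatrix(study$functions, file.path(dir, "functions.csv"))
  truth <- list(planted = as.list(study$planted),
                realized = study$realized)
  if (!is.null(p)) truth$params <- unclass(p)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
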