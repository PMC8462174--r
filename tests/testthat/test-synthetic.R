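test_that("trait simulation is a pure function of its parameters", {
  p <- simulationParams(seed = 12L)
  a <- simulateTraits(p)
  b <- simulateTraits(p)
  expect_identical(traitScores(a$traits), traitScores(b$traits))
  expect_identical(a$planted, b$planted)
  c_ <- simulateTraits(simulationParams(seed = 13L))
  expect_false(identical(traitScores(a$traits), traitScores(c_$traits)))
})

test_that("extreme overlap settings produce the expected structure", {
  p <- simulationParams(nClusters = 2L, speciesPerCluster = 3L,
                        nModalities = 10L, withinOverlap = 1,
                        betweenNoise = 0, nCategories = 2L, seed = 3L)
  tr <- simulateTraits(p)
  bin <- binarizeTraits(tr$traits)
  within <- jaccardSimilarity(bin, "sp01_c1", "sp02_c1")
  expect_equal(within, 1)
  between <- jaccardSimilarity(bin, "sp01_c1", "sp04_c2")
  expect_equal(between, 0)
  # full noise erases all block structure: every species identical
  pAll <- simulationParams(nClusters = 2L, speciesPerCluster = 3L,
                           nModalities = 10L, withinOverlap = 1,
                           betweenNoise = 1, nCategories = 2L, seed = 3L)
  trAll <- simulateTraits(pAll)
  cells <- binarizeTraits(trAll$traits)@cells
  expect_true(all(cells == 1))
})

test_that("core sets larger than the modality pool are rejected", {
  expect_error(simulateTraits(simulationParams(nClusters = 20L,
                                               nModalities = 10L)),
               "core sets exceed")
})

test_that("community counts follow the requested dispersion regime", {
  planted <- stats::setNames(rep(1L, 4), paste0("sp", 1:4))
  p <- simulationParams(nClusters = 1L, speciesPerCluster = 4L,
                        nSamples = 2500L, abundanceDispersion = Inf,
                        meanAbundance = 20, seed = 5L)
  comm <- simulateCommunity(p, planted)
  counts <- tableValues(comm$abundance)
  ratio <- apply(counts, 2, var) / colMeans(counts)
  expect_true(all(abs(ratio - 1) < 0.15))  # Poisson limit
  pOver <- simulationParams(nClusters = 1L, speciesPerCluster = 4L,
                            nSamples = 2500L, abundanceDispersion = 2,
                            meanAbundance = 20, seed = 5L)
  over <- tableValues(simulateCommunity(pOver, planted)$abundance)
  ratioOver <- apply(over, 2, var) / colMeans(over)
  expect_true(all(ratioOver > 5))  # mu + mu^2/size = 20 + 200
  expect_error(simulateCommunity(
    simulationParams(abundanceDispersion = 0), planted),
    "must be positive")
})

test_that("zero mean abundance silences a cluster's species", {
  planted <- stats::setNames(rep(1:2, each = 2), paste0("sp", 1:4))
  p <- simulationParams(nClusters = 2L, speciesPerCluster = 2L,
                        meanAbundance = c(0, 20), nSamples = 10L, seed = 6L)
  comm <- simulateCommunity(p, planted)
  counts <- tableValues(comm$abundance)
  expect_true(all(counts[, c("sp1", "sp2")] == 0))
  expect_gt(sum(counts[, c("sp3", "sp4")]), 0)
})

test_that("different seeds give different communities", {
  planted <- stats::setNames(rep(1L, 3), paste0("sp", 1:3))
  p1 <- simulationParams(nClusters = 1L, speciesPerCluster = 3L, seed = 1L)
  p2 <- simulationParams(nClusters = 1L, speciesPerCluster = 3L, seed = 2L)
  expect_false(identical(
    tableValues(simulateCommunity(p1, planted)$abundance),
    tableValues(simulateCommunity(p2, planted)$abundance)))
})

test_that("noiseless single-source functions are perfectly explained", {
  p <- simulationParams(
    effectSpec = data.frame(target = "f1", source = "c1",
                            coefficient = 1, stringsAsFactors = FALSE),
    noiseSd = 0, seed = 7L)
  st <- simulateStudy(p)
  g <- gowerCenter(as.matrix(dist(tableValues(st$functions)[, "f1"])))
  x <- scale(tableValues(st$plantedClusters)[, "c1"], scale = FALSE)
  expect_equal(fitR2(g, x)$r2, 1, tolerance = 1e-9)
})

test_that("all-zero coefficients leave functions as pure noise", {
  p <- simulationParams(
    effectSpec = data.frame(target = "f1", source = "c1",
                            coefficient = 0, stringsAsFactors = FALSE),
    seed = 8L)
  st <- simulateStudy(p)
  expect_equal(st$realized$realized_r2[1], 0, tolerance = 0.2)
  expect_error(simulateFunctions(
    simulationParams(effectSpec = data.frame(
      target = "f1", source = "ghost", coefficient = 1)),
    st$plantedClusters, st$environment), "unknown effect source")
})

test_that("realized planted R2 concentrates on its target as n grows", {
  target <- c(0.3, 0.2)
  spec <- data.frame(
    target = "f1", source = c("c1", "mud"),
    coefficient = c(effectCoefficient(0.3, target),
                    effectCoefficient(0.2, target)),
    stringsAsFactors = FALSE)
  for (n in c(49L, 500L)) {
    reals <- sapply(1:20, function(s) {
      st <- simulateStudy(simulationParams(nSamples = n, effectSpec = spec,
                                           seed = 100L + s))
      st$realized$realized_r2
    })
    tol <- if (n == 49L) 0.12 else 0.05
    expect_lt(abs(mean(reals[1, ]) - 0.3), tol)
    expect_lt(abs(mean(reals[2, ]) - 0.2), tol)
  }
})

test_that("study export writes all tables plus machine-readable truth", {
  p <- simulationParams(nSamples = 10L, seed = 9L)
  st <- simulateStudy(p)
  d <- tempfile()
  writeStudy(st, d, p)
  expect_true(all(file.exists(file.path(d,
    c("traits.csv", "trait_categories.csv", "abundance.csv",
      "environment.csv", "functions.csv", "ground_truth.json")))))
  tr <- readFuzzyTraits(file.path(d, "traits.csv"),
                        readCategoryMap(file.path(d, "trait_categories.csv")))
  expect_equal(traitScores(tr), traitScores(st$traits), tolerance = 1e-9)
  truth <- jsonlite::fromJSON(file.path(d, "ground_truth.json"))
  expect_equal(unlist(truth$planted), st$planted)
})
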