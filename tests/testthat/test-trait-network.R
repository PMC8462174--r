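twoTriangles <- function() {
  networkFixture(letters[1:6],
                 data.frame(source = c("a", "a", "b", "d", "d", "e"),
                            target = c("b", "c", "c", "e", "f", "f"),
                            weight = rep(1, 6)))
}

test_that("network assembly keeps isolates and rejects bad input", {
  scan <- data.frame(species_a = "a", species_b = "b", q = 3L,
                     expected = 1, p_lt = 1, p_gt = 0.01, jaccard = 0.6,
                     significant = TRUE, stringsAsFactors = FALSE)
  net <- buildTraitNetwork(scan, c("a", "b", "c"))
  expect_equal(igraph::vcount(networkGraph(net)), 3)
  expect_equal(igraph::ecount(networkGraph(net)), 1)
  expect_equal(networkEdges(net)$weight, 0.6)

  none <- scan; none$significant <- FALSE
  iso <- buildTraitNetwork(none, c("a", "b", "c"))
  expect_equal(igraph::ecount(networkGraph(iso)), 0)

  expect_error(buildTraitNetwork(scan, c("a", "x")), "unknown species")
  dup <- rbind(scan, data.frame(species_a = "b", species_b = "a", q = 3L,
                                expected = 1, p_lt = 1, p_gt = 0.01,
                                jaccard = 0.5, significant = TRUE))
  expect_error(buildTraitNetwork(dup, c("a", "b")), "duplicate species pair")
})

test_that("modularity matches the weighted Newman-Girvan definition", {
  net <- twoTriangles()
  comp <- c(a = 1L, b = 1L, c = 1L, d = 2L, e = 2L, f = 2L)
  expect_equal(modularityScore(net, comp), 0.5, tolerance = 1e-12)
  one <- stats::setNames(rep(1L, 6), letters[1:6])
  expect_equal(modularityScore(net, one), 0, tolerance = 1e-12)
  # invariance under uniform weight rescaling
  g10 <- networkGraph(net)
  igraph::E(g10)$weight <- igraph::E(g10)$weight * 10
  net10 <- new("TraitNetwork", graph = g10)
  expect_equal(modularityScore(net10, comp), 0.5, tolerance = 1e-12)
  expect_error(modularityScore(net, comp[-1]), "missing from partition")
})

test_that("modularity agrees with igraph on random weighted graphs", {
  set.seed(21)
  for (rep in 1:10) {
    g <- igraph::sample_gnp(12, 0.35)
    if (igraph::ecount(g) == 0) next
    igraph::E(g)$weight <- runif(igraph::ecount(g), 0.1, 1)
    igraph::V(g)$name <- sprintf("n%02d", 1:12)
    net <- new("TraitNetwork", graph = g)
    memb <- stats::setNames(sample(1:3, 12, replace = TRUE),
                            igraph::V(g)$name)
    expect_equal(modularityScore(net, memb),
                 igraph::modularity(g, memb, weights = igraph::E(g)$weight),
                 tolerance = 1e-12)
  }
})

test_that("cluster detection recovers disconnected cliques exactly", {
  edges <- do.call(rbind, lapply(list(letters[1:5], letters[6:10]),
                                 function(v) {
    p <- t(combn(v, 2))
    data.frame(source = p[, 1], target = p[, 2], weight = 1,
               stringsAsFactors = FALSE)
  }))
  net <- networkFixture(letters[1:10], edges)
  part <- detectClusters(net, seed = 4L, restarts = 5L)
  memb <- clusterAssignments(part)
  expect_equal(length(unique(memb)), 2)
  expect_equal(length(unique(memb[letters[1:5]])), 1)
  expect_equal(length(unique(memb[letters[6:10]])), 1)
  skip_if_not_installed("mclust")
  truth <- rep(1:2, each = 5)
  expect_equal(mclust::adjustedRandIndex(memb, truth), 1)
})

test_that("isolated species become singleton clusters", {
  p <- t(combn(letters[1:4], 2))
  net <- networkFixture(c(letters[1:4], "anemone"),
                        data.frame(source = p[, 1], target = p[, 2],
                                   weight = 1))
  part <- detectClusters(net, seed = 2L, restarts = 3L)
  memb <- clusterAssignments(part)
  expect_false(memb["anemone"] %in% memb[letters[1:4]])
  expect_equal(sum(memb == memb["anemone"]), 1)
})

test_that("cluster detection is deterministic and never beaten by one cluster", {
  net <- twoTriangles()
  p1 <- detectClusters(net, seed = 9L, restarts = 4L)
  p2 <- detectClusters(net, seed = 9L, restarts = 4L)
  expect_identical(clusterAssignments(p1), clusterAssignments(p2))
  expect_identical(partitionQ(p1), partitionQ(p2))
  expect_gte(partitionQ(p1), 0)
  expect_error(detectClusters(new("TraitNetwork",
                                  graph = igraph::make_empty_graph(0, FALSE))),
               "empty network")
})

abund4 <- function() {
  m <- rbind(s1 = c(3, 4, 5, 2), s2 = c(0, 1, 2, 7))
  colnames(m) <- c("sp1", "sp2", "sp3", "sp4")
  sampleMatrix(m, "abundance")
}

partFixture <- function(memb) {
  new("Partition", membership = memb, Q = 0.3, excluded = character(0))
}

test_that("cluster abundance aggregation sums member columns", {
  part <- partFixture(c(sp1 = 1L, sp2 = 1L, sp3 = 2L, sp4 = 2L))
  tab <- aggregateClusterAbundance(part, abund4())
  expect_equal(unname(tableValues(tab)[, "c1"]), c(7, 1))
  expect_equal(unname(tableValues(tab)[, "c2"]), c(7, 9))
  expect_equal(clusterMembers(tab)$c1, c("sp1", "sp2"))
  # conservation: totals across retained clusters equal species totals
  expect_equal(rowSums(tableValues(tab)), rowSums(tableValues(abund4())))
})

test_that("small clusters and singleton isolates are excluded and recorded", {
  part <- partFixture(c(sp1 = 1L, sp2 = 1L, sp3 = 2L, sp4 = 3L))
  tab <- aggregateClusterAbundance(part, abund4(), minClusterSize = 2L)
  expect_equal(colnames(tableValues(tab)), "c1")
  expect_setequal(excludedNodes(tab), c("sp3", "sp4"))
})

test_that("all-singletons with minimum size one reproduces the input", {
  part <- partFixture(c(sp1 = 1L, sp2 = 2L, sp3 = 3L, sp4 = 4L))
  tab <- aggregateClusterAbundance(part, abund4(), minClusterSize = 1L)
  expect_equal(unname(tableValues(tab)), unname(tableValues(abund4())))
})

test_that("aggregation validates species mapping and aliases", {
  part <- partFixture(c(sp1 = 1L, sp2 = 1L, spX = 2L, spY = 2L))
  expect_error(aggregateClusterAbundance(part, abund4()),
               "absent from abundance table: spX, spY")
  # explicit node -> column map handles size-class rows
  nm <- c(sp1 = "sp1", sp2 = "sp2", spX = "sp3", spY = "sp4")
  tab <- aggregateClusterAbundance(part, abund4(), nodeMap = nm)
  expect_equal(unname(tableValues(tab)[, "c2"]), c(7, 9))
  part2 <- partFixture(c(sp1 = 1L, sp2 = 1L, sp3 = 2L, sp4 = 2L))
  lab <- aggregateClusterAbundance(part2, abund4(),
                                   aliases = c(c1 = "small mobile"))
  expect_true("small mobile" %in% colnames(tableValues(lab)))
  expect_error(aggregateClusterAbundance(part2, abund4(),
                                         aliases = c(c9 = "ghost")),
               "unknown clusters")
})

test_that("mean aggregation divides by member count", {
  part <- partFixture(c(sp1 = 1L, sp2 = 1L, sp3 = 1L, sp4 = 1L))
  tab <- aggregateClusterAbundance(part, abund4(), stat = "mean")
  expect_equal(unname(tableValues(tab)[, "c1"]),
               unname(rowMeans(tableValues(abund4()))))
})
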