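centred <- function(x) x - mean(x)

candidateSet <- function(X, base, transform) {
  list(X = X, meta = data.frame(base = base, transform = transform,
                                stringsAsFactors = FALSE),
       degenerate = character(0))
}

test_that("gower centring reproduces the hand-computed two-point case", {
  g <- gowerCenter(as.matrix(dist(c(0, 1))))
  expect_equal(g$G, matrix(c(0.25, -0.25, -0.25, 0.25), 2),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(g$totalSS, 0.5, tolerance = 1e-12)
  z <- gowerCenter(matrix(0, 3, 3))
  expect_equal(z$totalSS, 0)
  expect_error(gowerCenter(matrix(c(0, 1, 2, 0), 2)), "symmetric")
  expect_error(gowerCenter(matrix(c(0, -1, -1, 0), 2)), "non-negative")
})

test_that("trace of the centred Gram equals the total sum of squares", {
  set.seed(31)
  y <- rnorm(50, 3, 2)
  g <- gowerCenter(as.matrix(dist(y)))
  expect_equal(g$totalSS, 49 * var(y), tolerance = 1e-9)
  expect_lt(max(abs(rowSums(g$G))), 1e-9 * 50)
})

test_that("distance-based R2 equals least-squares R2 for Euclidean data", {
  expect_equal(fitR2(gowerCenter(as.matrix(dist(2 * (1:10)))),
                     cbind(centred(1:10)))$r2, 1, tolerance = 1e-10)
  set.seed(32)
  for (rep in 1:50) {
    n <- 50; m <- sample(1:4, 1)
    y <- rnorm(n); X <- matrix(rnorm(n * m), n)
    g <- gowerCenter(as.matrix(dist(y)))
    Xc <- scale(X, scale = FALSE)
    expect_equal(fitR2(g, Xc)$r2, olsR2(y, X), tolerance = 1e-8)
  }
})

test_that("distance-based R2 agrees with an independent dbRDA implementation", {
  skip_if_not_installed("vegan")
  set.seed(33)
  y <- rnorm(30); X <- data.frame(a = rnorm(30), b = rnorm(30))
  ours <- fitR2(gowerCenter(as.matrix(dist(y))),
                as.matrix(scale(X, scale = FALSE)))$r2
  ref <- vegan::RsquareAdj(vegan::dbrda(dist(y) ~ a + b, data = X))$r.squared
  expect_equal(ours, ref, tolerance = 1e-8)
})

test_that("rank deficiency and constant responses are hard errors", {
  y <- rnorm(20)
  g <- gowerCenter(as.matrix(dist(y)))
  X <- cbind(x1 = centred(1:20), x2 = centred(1:20) * 2)
  expect_error(fitR2(g, X), "collinear")
  expect_error(fitR2(gowerCenter(matrix(0, 5, 5)), cbind(rnorm(5))),
               "constant response")
})

test_that("adjusted R2 follows its closed form", {
  expect_equal(adjustedR2(1, 49, 3), 1)
  expect_equal(adjustedR2(0, 49, 1), 1 - 48 / 47, tolerance = 1e-12)
  expect_equal(adjustedR2(0.5, 49, 1), 1 - 0.5 * 48 / 47, tolerance = 1e-12)
  expect_lte(adjustedR2(0.7, 30, 4), 0.7)
  expect_error(adjustedR2(0.5, 5, 4), "n > v")
})

test_that("permutation p-values are deterministic and exact for perfect fits", {
  set.seed(34)
  y <- rnorm(25)
  g <- gowerCenter(as.matrix(dist(y)))
  self <- cbind(centred(y))
  p1 <- permutationPvalue(g, self, nPerm = 199, seed = 5)
  expect_equal(p1$p, 1 / 200, tolerance = 1e-12)
  p2 <- permutationPvalue(g, self, nPerm = 199, seed = 5)
  expect_identical(p1, p2)
})

test_that("the observed partial pseudo-F matches its closed form", {
  set.seed(35)
  n <- 30
  y <- rnorm(n); x0 <- centred(rnorm(n)); x1 <- centred(rnorm(n))
  g <- gowerCenter(as.matrix(dist(y)))
  out <- permutationPvalue(g, cbind(x1), cbind(x0), nPerm = 9, seed = 1)
  r2full <- fitR2(g, cbind(x0, x1))$r2
  r2red <- fitR2(g, cbind(x0))$r2
  expect_equal(out$Fobs, (r2full - r2red) / ((1 - r2full) / (n - 3)),
               tolerance = 1e-10)
})

test_that("transform expansion yields three centred columns per variable", {
  m <- cbind(mud = c(0, 3, 9, 1), som = c(1, 2, 3, 4),
             shell = c(5, 5, 5, 5), water = c(2, 0, 1, 4))
  rownames(m) <- paste0("s", 1:4)
  env <- sampleMatrix(m, "environment")
  sq <- expandTransforms(env, "square")
  expect_equal(nrow(sq$meta), 9)  # 'shell' is constant: all three dropped
  expect_setequal(sq$degenerate, c("shell.raw", "shell.square",
                                   "shell.log10p1"))
  expect_lt(max(abs(colSums(sq$X))), 1e-10)
  logCol <- sq$X[, "mud.log10p1"]
  raw <- log10(c(0, 3, 9, 1) + 1)
  expect_equal(logCol, centred(raw), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(raw[1:3], c(0, 0.60206, 1), tolerance = 1e-5)
  sr <- expandTransforms(env, "sqrt")
  expect_equal(sr$X[, "som.sqrt"], centred(sqrt(1:4)), tolerance = 1e-10,
               ignore_attr = TRUE)
  neg <- sampleMatrix(matrix(c(-1, 2, 3, 4), 4, 1,
                             dimnames = list(paste0("s", 1:4), "x")),
                      "environment")
  expect_error(expandTransforms(neg, "sqrt"), "'x'")
})

test_that("forward selection takes orthogonal signals in marginal-R2 order", {
  n <- 100
  Qm <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n))))[, 2:4]
  y <- sqrt(0.5) * Qm[, 1] + sqrt(0.3) * Qm[, 2] + sqrt(0.2) * Qm[, 3]
  g <- gowerCenter(as.matrix(dist(y)))
  cand <- candidateSet(cbind(e1 = Qm[, 1], e2 = Qm[, 2]),
                       base = c("e1", "e2"),
                       transform = c("raw", "raw"))
  steps <- forwardSelect(g, cand, computeP = FALSE)
  expect_equal(steps$base, c("e1", "e2"))
  expect_equal(steps$delta_r2, c(0.5, 0.3), tolerance = 1e-10)
  # sequential additivity against a full refit
  full <- fitR2(g, cand$X)$r2
  expect_equal(sum(steps$delta_r2), full, tolerance = 1e-12)
})

test_that("selection can stop empty on pure noise", {
  set.seed(37)
  stopped <- 0
  for (rep in 1:10) {
    n <- 30
    y <- rnorm(n)
    g <- gowerCenter(as.matrix(dist(y)))
    cand <- candidateSet(cbind(a = centred(rnorm(n))), "a", "raw")
    steps <- forwardSelect(g, cand, computeP = FALSE)
    if (nrow(steps) == 0) stopped <- stopped + 1
    # whenever something is selected its adjusted R2 improved on zero
    if (nrow(steps)) expect_gt(steps$adj_r2_after[1], 0)
  }
  expect_gt(stopped, 0)
})

test_that("strict admissibility never mixes log with raw or square", {
  set.seed(38)
  for (rep in 1:20) {
    n <- 40
    x <- runif(n, 0, 10)
    y <- log10(x + 1) + x * runif(1, -0.2, 0.2) + rnorm(n, 0, 0.2)
    g <- gowerCenter(as.matrix(dist(y)))
    env <- sampleMatrix(matrix(c(x, runif(n)), n, 2,
                               dimnames = list(paste0("s", 1:n),
                                               c("x", "z"))),
                        "environment")
    cand <- expandTransforms(env, "square")
    strict <- forwardSelect(g, cand, constraint = "strict", computeP = FALSE)
    selX <- strict$transform[strict$base == "x"]
    expect_false("log10p1" %in% selX &&
                   any(c("raw", "square") %in% selX))
  }
})

test_that("lenient mode may combine log with raw for the same base", {
  # response needs both the log and the raw shape of x
  set.seed(39)
  n <- 60
  x <- runif(n, 0, 20)
  y <- 3 * log10(x + 1) - 0.2 * x
  g <- gowerCenter(as.matrix(dist(y)))
  env <- sampleMatrix(matrix(x, n, 1,
                             dimnames = list(paste0("s", 1:n), "x")),
                      "environment")
  cand <- expandTransforms(env, "square")
  lenient <- forwardSelect(g, cand, constraint = "lenient", computeP = FALSE)
  selX <- lenient$transform[lenient$base == "x"]
  expect_true("log10p1" %in% selX && any(c("raw", "square") %in% selX))
  strict <- forwardSelect(g, cand, constraint = "strict", computeP = FALSE)
  selS <- strict$transform[strict$base == "x"]
  expect_false("log10p1" %in% selS && any(c("raw", "square") %in% selS))
})

twoStageFixture <- function(n = 30, seed = 41) {
  set.seed(seed)
  # wide overdispersed counts: the raw-linear signal is then cleanly
  # separated from its square and log competitors in the candidate set
  cl <- matrix(rnbinom(n * 2, size = 1, mu = 40), n, 2,
               dimnames = list(sprintf("s%02d", 1:n), c("cA", "cB")))
  env <- matrix(runif(n * 2, 0, 10), n, 2,
                dimnames = list(rownames(cl), c("mud", "som")))
  y <- 2 * cl[, "cA"] + cl[, "cB"]
  fns <- matrix(y, n, 1, dimnames = list(rownames(cl), "flux"))
  list(functions = sampleMatrix(fns, "function"),
       clusters = sampleMatrix(cl, "abundance"),
       env = sampleMatrix(env, "environment"))
}

test_that("a noiseless linear response is recovered exactly in stage one", {
  fx <- twoStageFixture()
  cfg <- runConfig(seed = 8L, nPermutations = 99L)
  rep_ <- runTwoStage(fx$functions, fx$clusters, fx$env, cfg)
  r <- rep_@results$flux
  expect_equal(r$A, 1, tolerance = 1e-9)
  expect_lt(r$B, 1e-9)
  sel <- unique(r$steps$base[r$steps$retained & r$steps$stage == "traits"])
  expect_setequal(sel, c("cA", "cB"))
})

test_that("stage totals obey the A plus B equals C identity", {
  fx <- twoStageFixture(seed = 42)
  set.seed(43)
  noisy <- tableValues(fx$functions) + rnorm(30, 0, 30)
  fns <- sampleMatrix(noisy, "function")
  cfg <- runConfig(seed = 9L, nPermutations = 99L)
  rep_ <- runTwoStage(fns, fx$clusters, fx$env, cfg)
  for (r in rep_@results) {
    expect_equal(r$A + r$B, r$C, tolerance = 1e-12)
    kept <- r$steps[r$steps$retained, , drop = FALSE]
    expect_equal(sum(kept$delta_r2), r$C, tolerance = 1e-12)
    expect_true(all(kept$delta_r2 >= -1e-12))
  }
})

test_that("sample-id mismatches between tables abort with a diff", {
  fx <- twoStageFixture()
  envBad <- tableValues(fx$env)
  rownames(envBad)[1] <- "sXX"
  expect_error(
    runTwoStage(fx$functions, fx$clusters, sampleMatrix(envBad, "environment"),
                runConfig(nPermutations = 9L)),
    "mismatch.*missing: s01")
})

test_that("report serialization and table export carry the footnotes", {
  fx <- twoStageFixture()
  cfg <- runConfig(seed = 8L, nPermutations = 99L)
  rep_ <- runTwoStage(fx$functions, fx$clusters, fx$env, cfg)
  f <- tempfile(fileext = ".json")
  writeReport(rep_, f)
  back <- jsonlite::fromJSON(f)
  expect_equal(back$functions$flux$C, rep_@results$flux$C,
               tolerance = 1e-12)
  expect_equal(back$n, 30)
  tab <- reportTable(rep_)
  expect_true("flux" %in% names(tab))
  expect_true(any(grepl("\\^[abc]$", tab$flux)))
  totals <- stageTotals(rep_)
  expect_equal(totals$C, totals$A + totals$B, tolerance = 1e-12)
})
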