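# Independent oracles and small fixture builders shared across tests.

# Exhaustive shared-modality distribution: enumerate every pair of
# subsets of sizes (na, nb) from N modalities via bitmasks and tally the
# intersection sizes. Returns P(q = j) for j = 0..min(na, nb).
bruteSharedDist <- function(N, na, nb) {
  masks <- 0:(2^N - 1)
  pc <- vapply(masks, function(m) sum(bitwAnd(m, 2^(0:(N - 1))) > 0),
               numeric(1))
  A <- masks[pc == na]
  B <- masks[pc == nb]
  counts <- integer(min(na, nb) + 1)
  for (a in A) {
    q <- vapply(B, function(b) sum(bitwAnd(bitwAnd(a, b),
                                           2^(0:(N - 1))) > 0), numeric(1))
    tab <- tabulate(q + 1, nbins = length(counts))
    counts <- counts + tab
  }
  counts / (length(A) * length(B))
}

# All set partitions of 1..n (restricted growth strings).
allPartitions <- function(n) {
  out <- list()
  rec <- function(assign, maxLab) {
    k <- length(assign) + 1
    if (k > n) {
      out[[length(out) + 1]] <<- assign
      return(invisible(NULL))
    }
    for (lab in seq_len(maxLab + 1))
      rec(c(assign, lab), max(maxLab, lab))
  }
  rec(integer(0), 0L)
  out
}

olsR2 <- function(y, X) summary(stats::lm(y ~ X))$r.squared

# BinaryTraitMatrix straight from a 0/1 matrix.
binaryFixture <- function(m) {
  storage.mode(m) <- "integer"
  if (is.null(rownames(m))) rownames(m) <- sprintf("sp%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("m%02d", seq_len(ncol(m)))
  new("BinaryTraitMatrix", cells = m,
      flagged = rownames(m)[rowSums(m) == 0])
}

# TraitNetwork from an edge data.frame (source, target, weight).
networkFixture <- function(nodes, edges) {
  k <- nrow(edges)
  scan <- data.frame(species_a = as.character(edges$source),
                     species_b = as.character(edges$target),
                     q = rep(1L, k), expected = rep(1, k),
                     p_lt = rep(1, k), p_gt = rep(0, k),
                     jaccard = edges$weight, significant = rep(TRUE, k),
                     stringsAsFactors = FALSE)
  buildTraitNetwork(scan, nodes)
}

# Hand-built DistLMReport, for tests of downstream consumers.
reportFixture <- function(perFunction, n = 49L, cfg = runConfig()) {
  results <- lapply(perFunction, function(steps) {
    if (is.null(steps$retained)) steps$retained <- TRUE
    A <- sum(steps$delta_r2[steps$stage == "traits" & steps$retained])
    B <- sum(steps$delta_r2[steps$stage == "environment" & steps$retained])
    list(steps = steps, A = A, B = B, C = A + B)
  })
  new("DistLMReport", results = results, n = n, config = cfg)
}

stepRow <- function(base, stage, delta, transform = "raw", p = 0.01,
                    retained = TRUE) {
  data.frame(base = base, transform = transform, delta_r2 = delta,
             adj_r2_after = NA_real_, pseudo_F = NA_real_, p_perm = p,
             stage = stage, retained = retained, stringsAsFactors = FALSE)
}

writeTempCsv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
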