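#' Binarize a fuzzy trait table
#'
#' A species possesses a modality when its fuzzy affinity score is
#' strictly greater than `threshold` (default 0: any nonzero affinity,
#' since fuzzy coding is proportional). Species left with no modality at
#' the chosen threshold are flagged with a warning and excluded from
#' downstream scans, never silently dropped.
#'
#' @param traits a [FuzzyTraitTable-class].
#' @param threshold non-negative affinity cutoff.
#' @return a [BinaryTraitMatrix-class].
#' @export
binarizeTraits <- function(traits, threshold = 0) {
  stopifnot(is(traits, "FuzzyTraitTable"))
  if (threshold < 0) stop("threshold must be >= 0")
  cells <- (traits@scores > threshold) * 1L
  storage.mode(cells) <- "integer"
  flagged <- rownames(cells)[rowSums(cells) == 0]
  if (length(flagged))
    warning("species with no modality at threshold ", threshold, ": ",
            paste(flagged, collapse = ", "))
  new("BinaryTraitMatrix", cells = cells, flagged = flagged)
}

#' Exact probabilities for the number of shared trait modalities
#'
#' Under the probabilistic cooccurrence model, the number of modalities
#' shared by two species that possess `nA` and `nB` of the `N` modalities
#' is hypergeometric: random subsets of sizes `nA` and `nB` intersect in
#' exactly `j` modalities with probability
#' `choose(nA, j) * choose(N - nA, nB - j) / choose(N, nB)`. Tail
#' probabilities are computed exactly (log-gamma arithmetic, no Monte
#' Carlo): `pLt` is the probability of sharing at most `q` modalities by
#' chance, `pGt` of sharing at least `q`.
#'
#' @param N total number of trait modalities.
#' @param nA,nB modalities possessed by each species.
#' @param q observed number of shared modalities; must satisfy
#'   `max(0, nA + nB - N) <= q <= min(nA, nB)`.
#' @return list with `pExact`, `pLt`, `pGt`.
#' @export
pairProbabilities <- function(N, nA, nB, q) {
  if (nA < 0 || nB < 0 || nA > N || nB > N)
    stop("need 0 <= nA, nB <= N")
  lo <- max(0, nA + nB - N); hi <- min(nA, nB)
  if (q < lo || q > hi)
    stop(sprintf("infeasible q = %d: support is [%d, %d]", q, lo, hi))
  list(pExact = dhyper(q, nA, N - nA, nB),
       pLt = phyper(q, nA, N - nA, nB),
       pGt = phyper(q - 1, nA, N - nA, nB, lower.tail = FALSE))
}

#' Jaccard similarity of two species' modality sets
#'
#' `q / (nA + nB - q)` where `q` is the shared-modality count: 1 for
#' identical modality sets, 0 for disjoint ones.
#'
#' @param bin a [BinaryTraitMatrix-class].
#' @param a,b species ids (rows of `bin`).
#' @return numeric in `[0, 1]`.
#' @export
jaccardSimilarity <- function(bin, a, b) {
  stopifnot(is(bin, "BinaryTraitMatrix"))
  va <- bin@cells[a, ]; vb <- bin@cells[b, ]
  union <- sum(va | vb)
  if (union == 0) stop("both species are trait-empty: ", a, ", ", b)
  sum(va & vb) / union
}

#' Scan all species pairs for significant trait cooccurrence
#'
#' Tests every unordered pair of usable species (those possessing at
#' least one modality) for sharing more modalities than expected under
#' the hypergeometric model. A pair is a significant positive association
#' when `pGt < alpha`; only those pairs later become network edges.
#' Pairs whose expected shared count `nA * nB / N` falls below
#' `minExpected` are filtered out before testing. Results are sorted by
#' `(species_a, species_b)` and fully deterministic.
#'
#' @param bin a [BinaryTraitMatrix-class] with at least two usable
#'   species.
#' @param alpha one-sided significance level (default 0.05).
#' @param minExpected expected-count filter (default 1; 0 disables).
#' @param bhCorrect apply Benjamini-Hochberg correction to the `p_gt`
#'   column before flagging significance (default FALSE: raw one-sided
#'   p-values, no multiplicity correction).
#' @return data.frame with columns `species_a`, `species_b`, `q`,
#'   `expected`, `p_lt`, `p_gt`, `jaccard`, `significant`.
#' @export
cooccurrenceScan <- function(bin, alpha = 0.05, minExpected = 1,
                             bhCorrect = FALSE) {
  stopifnot(is(bin, "BinaryTraitMatrix"))
  cells <- bin@cells
  usable <- rownames(cells)[rowSums(cells) > 0]
  if (length(usable) < 2)
    stop("need at least two species possessing modalities")
  usable <- sort(usable)
  m <- cells[usable, , drop = FALSE]
  N <- ncol(m)
  n <- rowSums(m)
  Q <- m %*% t(m)  # shared-modality counts for all pairs at once
  pairs <- t(combn(length(usable), 2))
  nA <- n[pairs[, 1]]; nB <- n[pairs[, 2]]
  q <- Q[pairs]
  expected <- nA * nB / N
  keep <- expected >= minExpected
  pairs <- pairs[keep, , drop = FALSE]
  nA <- nA[keep]; nB <- nB[keep]; q <- q[keep]; expected <- expected[keep]
  pLt <- phyper(q, nA, N - nA, nB)
  pGt <- phyper(q - 1, nA, N - nA, nB, lower.tail = FALSE)
  jac <- q / (nA + nB - q)
  pFlag <- if (bhCorrect) stats::p.adjust(pGt, "BH") else pGt
  out <- data.frame(
    species_a = usable[pairs[, 1]],
    species_b = usable[pairs[, 2]],
    q = as.integer(q),
    expected = expected,
    p_lt = pLt,
    p_gt = pGt,
    jaccard = jac,
    significant = pFlag < alpha,
    stringsAsFactors = FALSE)
  out[order(out$species_a, out$species_b), , drop = FALSE]
}

#' @rdname cooccurrenceScan
#' @param scan a scan result data.frame.
#' @param path output CSV path.
#' @export
writeScan <- function(scan, path) {
  write.csv(scan, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
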