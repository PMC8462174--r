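#' Gower-centred Gram matrix of a distance matrix
#'
#' The distance-based linear model operates on `G = C A C` where
#' `A = -D^2 / 2`, `C = I - 11'/n` is the centring operator and `D` the
#' sample-by-sample distance matrix (McArdle-Anderson construction). For
#' a Euclidean distance built from data `Y`, `tr(G)` equals the total sum
#' of squared deviations of `Y`.
#'
#' @param D symmetric non-negative distance matrix with zero diagonal
#'   (a `dist` object is accepted).
#' @return list with `G` (n x n symmetric, row sums zero) and `totalSS`
#'   (`tr(G)`).
#' @export
gowerCenter <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-10)) stop("distance matrix must be symmetric")
  if (any(D < 0)) stop("distance matrix must be non-negative")
  n <- nrow(D)
  A <- -0.5 * D * D
  rm <- rowMeans(A)
  G <- A - outer(rm, rep(1, n)) - outer(rep(1, n), rm) + mean(A)
  G <- (G + t(G)) / 2
  list(G = G, totalSS = sum(diag(G)))
}

#' Variance explained by predictors in a distance-based linear model
#'
#' `R^2 = tr(H G H) / tr(G)` with `H` the hat matrix of the centred
#' predictor columns, together with the pseudo-F ratio
#' `[tr(HGH)/m] / [tr((I-H)G(I-H))/(n-m-1)]`. For a univariate response
#' under Euclidean distance this reproduces ordinary least-squares R^2.
#'
#' @param gram result of [gowerCenter()].
#' @param X matrix of centred predictor columns (may have zero columns:
#'   `R^2 = 0`).
#' @return list with `r2`, `pseudoF`, `m` (number of predictor columns).
#' @export
fitR2 <- function(gram, X) {
  G <- gram$G
  trG <- gram$totalSS
  if (trG <= 1e-300) stop("constant response: total sum of squares is zero")
  n <- nrow(G)
  if (is.null(X) || ncol(X) == 0)
    return(list(r2 = 0, pseudoF = NA_real_, m = 0L))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    stop("rank-deficient predictors; collinear column(s): ",
         paste(dep, collapse = ", "))
  }
  Qm <- qr.Q(qrX)
  trHG <- sum(Qm * (G %*% Qm))  # tr(HG), H = QQ'
  m <- ncol(X)
  r2 <- trHG / trG
  pseudoF <- if (n > m + 1)
    (trHG / m) / ((trG - trHG) / (n - m - 1)) else NA_real_
  list(r2 = r2, pseudoF = pseudoF, m = m)
}

#' Adjusted R-squared
#'
#' `1 - (1 - R^2) (n - 1) / (n - v - 1)`, the stopping criterion of the
#' forward-selection procedure; `v` counts fitted predictor columns
#' (transform columns, not base variables).
#'
#' @param r2 unadjusted R-squared.
#' @param n sample count.
#' @param v number of predictor columns.
#' @return adjusted R-squared (can be negative).
#' @export
adjustedR2 <- function(r2, n, v) {
  if (n <= v + 1) stop("need n > v + 1 for adjusted R^2")
  1 - (1 - r2) * (n - 1) / (n - v - 1)
}

#' Sequential permutation test for added predictors
#'
#' Tests the variance added by `Xtest` over the forced columns `Xforced`
#' by permutation of residuals under the reduced model (Freedman-Lane):
#' the residual Gram `(I - H0) G (I - H0)` is row/column permuted
#' simultaneously and the partial pseudo-F recomputed each time.
#' `p = (1 + #[F* >= F_obs]) / (1 + nPerm)`; seeded and reproducible.
#'
#' @param gram result of [gowerCenter()].
#' @param Xtest centred columns under test.
#' @param Xforced centred columns of the reduced model (may be NULL).
#' @param nPerm number of permutations.
#' @param seed integer seed.
#' @return list with `p`, `Fobs`.
#' @export
permutationPvalue <- function(gram, Xtest, Xforced = NULL, nPerm = 999L,
                              seed = 1L) {
  G <- gram$G
  n <- nrow(G)
  X0 <- if (is.null(Xforced)) matrix(0, n, 0) else Xforced
  Xf <- cbind(X0, Xtest)
  m0 <- ncol(X0); mf <- ncol(Xf); mt <- mf - m0
  H0 <- if (m0 > 0) tcrossprod(qr.Q(qr(X0))) else matrix(0, n, n)
  Hf <- tcrossprod(qr.Q(qr(Xf)))
  I0 <- diag(n) - H0
  Gr <- I0 %*% G %*% I0
  Gr <- (Gr + t(Gr)) / 2
  pfStat <- function(Gp) {
    num <- sum(Hf * Gp) - sum(H0 * Gp)
    den <- sum(diag(Gp)) - sum(Hf * Gp)
    if (den <= 0) return(if (num > 0) Inf else NaN)  # saturated model
    (num / mt) / (den / (n - mf - 1))
  }
  Fobs <- pfStat(Gr)
  set.seed(seed)
  exceed <- 0L
  for (i in seq_len(nPerm)) {
    p <- sample.int(n)
    if (pfStat(Gr[p, p]) >= Fobs - 1e-12) exceed <- exceed + 1L
  }
  list(p = (1 + exceed) / (1 + nPerm), Fobs = Fobs)
}

#' Expand a table into raw, polynomial-type and log candidate columns
#'
#' Each base variable yields three centred candidate columns: the raw
#' values, either the square (`family = "square"`, approximating a
#' second-degree polynomial response together with the raw column) or the
#' square root (`family = "sqrt"`), and `log10(x + 1)`. Square root and
#' log transforms require non-negative values. Constant columns are
#' degenerate: they are excluded from the candidate set and reported.
#'
#' @param table a [SampleMatrix-class] (environment or cluster-abundance
#'   table).
#' @param family `"square"` or `"sqrt"`.
#' @return list with `X` (n x k matrix of centred columns), `meta`
#'   (data.frame: `base`, `transform`), `degenerate` (character vector of
#'   excluded column labels).
#' @export
expandTransforms <- function(table, family = c("square", "sqrt")) {
  family <- match.arg(family)
  vals <- tableValues(table)
  n <- nrow(vals)
  cols <- list(); meta <- list(); degen <- character(0)
  for (v in colnames(vals)) {
    x <- vals[, v]
    if (family == "sqrt" && any(x < 0))
      stop("negative values in '", v, "' forbid the square-root transform")
    if (any(x < 0))
      stop("negative values in '", v, "' forbid the log10(x+1) transform")
    second <- if (family == "square") x^2 else sqrt(x)
    trio <- list(raw = x, log10p1 = log10(x + 1))
    trio[[family]] <- second
    for (tr in names(trio)) {
      z <- trio[[tr]]
      if (sd(z) < 1e-12) {
        degen <- c(degen, paste0(v, ".", tr))
        next
      }
      cols[[paste0(v, ".", tr)]] <- z - mean(z)
      meta[[paste0(v, ".", tr)]] <- data.frame(base = v, transform = tr,
                                               stringsAsFactors = FALSE)
    }
  }
  X <- if (length(cols)) do.call(cbind, cols) else matrix(0, n, 0)
  meta <- if (length(meta)) do.call(rbind, meta) else
    data.frame(base = character(0), transform = character(0))
  rownames(meta) <- NULL
  list(X = X, meta = meta, degenerate = degen)
}

# admissibility of candidate i given transforms already selected per base
admissible <- function(meta, i, selected, constraint) {
  if (constraint == "lenient") return(TRUE)
  base <- meta$base[i]; tr <- meta$transform[i]
  selTr <- meta$transform[selected][meta$base[selected] == base]
  if (tr == "log10p1") !any(selTr %in% c("raw", "square", "sqrt"))
  else !any(selTr == "log10p1")
}

#' Forward selection by adjusted R-squared with transform admissibility
#'
#' Starting from the forced columns, repeatedly adds the admissible
#' candidate column that maximizes the adjusted R-squared of the model
#' and stops when no admissible candidate increases it. Under the strict
#' constraint, a log column is admissible only while neither the raw nor
#' the square(-root) column of the same base variable is selected, and
#' vice versa. Ties are broken lexicographically by (base, transform).
#' Each accepted step records the sequential R-squared increase, the
#' partial pseudo-F and a sequential permutation p-value conditional on
#' everything selected before it.
#'
#' @param gram result of [gowerCenter()].
#' @param candidates candidate set from [expandTransforms()].
#' @param forced matrix of columns forced into the model (or NULL).
#' @param constraint `"strict"` or `"lenient"`.
#' @param nPerm permutations per accepted step.
#' @param seed integer seed.
#' @param computeP compute permutation p-values (default TRUE).
#' @return data.frame of selection steps: `base`, `transform`,
#'   `delta_r2`, `adj_r2_after`, `pseudo_F`, `p_perm`.
#' @export
forwardSelect <- function(gram, candidates, forced = NULL,
                          constraint = c("strict", "lenient"),
                          nPerm = 999L, seed = 1L, computeP = TRUE) {
  constraint <- match.arg(constraint)
  X <- candidates$X; meta <- candidates$meta
  n <- nrow(gram$G)
  F0 <- if (is.null(forced)) matrix(0, n, 0) else forced
  if (ncol(F0) > 0 && qr(F0)$rank < ncol(F0))
    stop("forced columns are rank-deficient")
  emptyStep <- data.frame(base = character(0), transform = character(0),
                          delta_r2 = numeric(0), adj_r2_after = numeric(0),
                          pseudo_F = numeric(0), p_perm = numeric(0),
                          stringsAsFactors = FALSE)
  if (ncol(X) == 0) return(emptyStep)
  selected <- integer(0)
  curX <- F0
  curR2 <- fitR2(gram, curX)$r2
  curAdj <- adjustedR2(curR2, n, ncol(curX))
  steps <- emptyStep
  repeat {
    cand <- setdiff(seq_len(ncol(X)), selected)
    cand <- cand[vapply(cand, function(i)
      admissible(meta, i, selected, constraint), logical(1))]
    if (!length(cand)) break
    best <- NULL
    for (i in cand) {
      xi <- X[, i]
      # skip candidates collinear with the current model
      resid <- xi - if (ncol(curX) > 0) qr.fitted(qr(curX), xi) else 0
      if (sqrt(sum(resid^2)) < 1e-8 * sqrt(sum(xi^2))) next
      if (n <= ncol(curX) + 2) next
      fit <- fitR2(gram, cbind(curX, xi))
      adj <- adjustedR2(fit$r2, n, ncol(curX) + 1)
      key <- paste(meta$base[i], meta$transform[i])
      if (is.null(best) || adj > best$adj + 1e-12 ||
          (abs(adj - best$adj) <= 1e-12 && key < best$key))
        best <- list(i = i, adj = adj, r2 = fit$r2, key = key)
    }
    if (is.null(best) || best$adj <= curAdj + 1e-12) break
    i <- best$i
    mf <- ncol(curX) + 1
    Fobs <- (best$r2 - curR2) / ((1 - best$r2) / (n - mf - 1))
    p <- if (computeP)
      permutationPvalue(gram, X[, i, drop = FALSE],
                        if (ncol(curX) > 0) curX else NULL,
                        nPerm = nPerm, seed = seed + length(selected))$p
    else NA_real_
    steps <- rbind(steps, data.frame(
      base = meta$base[i], transform = meta$transform[i],
      delta_r2 = best$r2 - curR2, adj_r2_after = best$adj,
      pseudo_F = Fobs, p_perm = p, stringsAsFactors = FALSE))
    selected <- c(selected, i)
    curX <- cbind(curX, X[, i, drop = FALSE])
    curR2 <- best$r2
    curAdj <- best$adj
  }
  steps
}
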