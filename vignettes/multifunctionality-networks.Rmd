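---
title: "Trait cooccurrence networks and two-stage distance-based models for ecosystem multifunctionality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait cooccurrence networks and two-stage distance-based models for ecosystem multifunctionality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

Ecosystem multifunctionality — the simultaneous delivery of several
ecosystem functions such as nutrient fluxes, oxygen exchange and organic
matter degradation — is often summarised as a single index, which hides
*which* parts of the community drive *which* functions. `mufnet`
implements an alternative: a multivariate network analysis that (1)
reduces trait dimensionality by clustering species that share
functional-trait modalities, and (2) explains each function from
trait-cluster abundances and environmental characteristics with a
two-stage distance-based linear model (DistLM), assembling the results
into a directed network whose edges carry variance explained.

The pipeline consumes four per-sample tables: a fuzzy-coded trait table
(species × trait modalities, proportional affinities), an abundance
table (samples × species), an environment table (e.g. %mud, %sediment
organic matter, %shell hash, %water content) and a function table
(fluxes, chlorophyll *a*, degradation rates). Field and laboratory
protocols that produce these tables are out of scope; the package starts
from the tables.

```{r, eval = FALSE}
library(mufnet)
study <- simulateStudy(simulationParams(seed = 1))
bin   <- binarizeTraits(study$traits)
scan  <- cooccurrenceScan(bin)
net   <- buildTraitNetwork(scan, speciesIds(study$traits))
part  <- detectClusters(net, seed = 1)
cl    <- aggregateClusterAbundance(part, study$abundance)
rep   <- runTwoStage(study$functions, cl, study$environment,
                     runConfig(seed = 1))
mf    <- assembleMultifunc(rep)
```

# Stage 1: trait clusters from species–trait cooccurrence

## The probabilistic cooccurrence model

Fuzzy-coded affinities are first binarized: a species *possesses* a
modality when its affinity is strictly positive (the threshold is
configurable; fuzzy scores are proportional, so any nonzero affinity is
evidence of the trait). For two species possessing $n_A$ and $n_B$ of
the $N$ modalities, the number of shared modalities under random,
independent assignment is hypergeometric:

$$P(q = j) = \frac{\binom{n_A}{j}\binom{N-n_A}{n_B-j}}{\binom{N}{n_B}},$$

and the pair is a significant *positive* association when
$P(q \ge q_{obs}) < \alpha$ (one-sided, $\alpha = 0.05$ by default, no
multiplicity correction by default — a Benjamini–Hochberg switch
exists). Probabilities are computed exactly through log-gamma
arithmetic; the test suite checks them against exhaustive enumeration of
every subset pair for all $N \le 10$ to $10^{-12}$. Pairs whose expected
overlap $n_A n_B / N$ falls below 1 are filtered out before testing
(configurable, 0 disables), the conventional guard of probabilistic
cooccurrence analysis. Negative associations are reported in the scan
output but never become edges: edge strength is Jaccard's coefficient
$JC = q/(n_A + n_B - q)$, the natural similarity for shared modality
sets, and observed networks of this kind have $JC$ between roughly 0.4
and 1 on significant pairs.

## Modularity clustering and the exclusion rule

Significant pairs form an undirected network weighted by $JC$, with all
species kept as nodes so that trait-isolated species surface as
singleton clusters. Clusters are found by Louvain modularity
optimization (weighted Newman–Girvan
$Q = \sum_c [w_c/W - (s_c/2W)^2]$) at resolution 1.0. Louvain is greedy
and order-dependent, so `detectClusters()` runs 20 seeded restarts and
keeps the best-$Q$ partition, breaking ties by fewest clusters and then
by lexicographically smallest assignment — the result is a pure function
of `(network, resolution, seed, restarts)`. `modularityScore()` is
implemented directly from the formula (and cross-checked against
igraph's in the tests); on two disconnected unit triangles the brute
force over all 203 partitions of six nodes confirms the component
split, $Q = 0.5$, is the unique optimum.

Clusters below the minimum size (2 by default) — in particular
singleton, disconnected species — are excluded before any downstream
modelling, mirroring the removal of a disconnected single-species
cluster in typical applications, and logged. Retained clusters become
per-sample predictors by summing member species' abundance columns
(a mean option exists; the sum is chosen because the downstream
predictor is "abundance in the cluster"). When trait rows are finer
than abundance columns (size-class rows such as different shell
lengths of one species), an explicit node-to-column mapping file is
required; name-prefix guessing is deliberately refused.

# Stage 2: two-stage distance-based linear models

## The DistLM engine

For each function $y$ separately, the engine Gower-centres the squared
Euclidean distance matrix, $G = C(-\tfrac12 D \circ D)C$, and measures
variance explained by centred predictor columns $X$ through the hat
matrix $H$: $R^2 = \mathrm{tr}(HGH)/\mathrm{tr}(G)$, with pseudo-F
$[\mathrm{tr}(HGH)/m]\,/\,[\mathrm{tr}((I-H)G(I-H))/(n-m-1)]$. For a
univariate Euclidean response this is ordinary least squares exactly
(checked against OLS over 1,000 random fixtures to $10^{-8}$, and
against an independent dbRDA implementation). The response distance is
Euclidean on the raw function column: per-function models make
standardization irrelevant to $R^2$.

Sequential significance is tested by permutation of residuals under the
reduced model (Freedman–Lane): the residual Gram
$(I-H_0)G(I-H_0)$ is row/column-permuted simultaneously and the partial
pseudo-F recomputed, $p = (1 + \#\{F^* \ge F\})/(1 + n_{perm})$, with
9,999 permutations by default. This scheme is chosen for its correct
conditional error rates in the presence of forced terms; the suite
verifies the nominal type-I rate by simulation (500 null datasets,
rejection rate within $0.05 \pm 0.02$).

## Transforms, admissibility and forward selection

Nonlinearity is accommodated by offering, per base variable, the raw
column, its square, and $\log_{10}(x+1)$ — selecting raw plus square
approximates a second-degree polynomial response. A square-root family
is available instead of the square (both appear in the literature on
this protocol; the square is the default because it is the variant the
reporting convention's footnotes describe). Under the default *strict*
admissibility rule a log column may only be selected while neither the
raw nor the square column of the same base variable is in the model,
and vice versa; a *lenient* mode removes the coupling (reported
applications occasionally show log together with raw, so both are
implemented).

Forward selection adds, at each step, the admissible candidate that
maximizes the model's adjusted
$R^2 = 1 - (1-R^2)(n-1)/(n-v-1)$ and stops when no admissible candidate
increases it; $v$ counts all fitted transform columns (forced included),
not base variables. Ties break lexicographically by (base, transform).
Whether the selection criterion itself (as opposed to the stopping rule)
should be raw or adjusted $R^2$ is ambiguous in the protocol's usual
description; this package maximizes adjusted $R^2$ at each step, which
makes the stopping rule and the choice rule coincide.

## The two stages and the significance rule

Stage 1 forward-selects among the expanded trait-cluster columns. The
clusters that *prove significant* are retained; by default
(`significanceRule = "selected_and_p"`) that means selected by adjusted
$R^2$ **and** sequential permutation $p \le \alpha$; a selection-only
mode exists. Stage 2 then forces the retained cluster columns into the
model and forward-adds environmental columns, filtered by the same
rule — the reporting convention labels both stage totals as
"significant" predictors, so the rule is applied symmetrically.

After filtering, the retained path is re-walked in selection order so
that the reported sequential increments $\Delta R^2$ are conditional on
exactly what is retained. This guarantees the report's arithmetic
identities: per function, the per-predictor $\Delta R^2$ cells sum to
the full-model $R^2$, and the stage totals obey $A + B = C$ to
$10^{-12}$ (A = retained trait clusters, B = retained environmental
additions, C = total). No correction is applied across functions.

## The multifunctionality network

`assembleMultifunc()` turns the report into a directed graph: one edge
per (predictor base variable → function) with positive retained
$\Delta R^2$, weighted by that sum on the proportion scale (percent is
a display choice). Edges run only from sources (clusters, environment)
to functions — never source–source or function–function — and node size
is out-degree for sources, in-degree for functions. A function's summed
in-weights equal its total $R^2$ (row C) exactly, which the validity
methods and tests enforce. Excluded clusters never appear as nodes.
Networks export to GraphML, GEXF 1.2 and a plain edge CSV (all loadable
by Gephi-class viewers); the edge CSV round-trips weights to 12
significant digits.

# The synthetic study generator

`simulateStudy()` produces all four tables with known ground truth so
every stage is testable without field data.

* **Traits.** Each of 6 planted clusters owns a disjoint core of
  modalities; a member carries each core modality with probability
  `withinOverlap` (0.8) and each off-cluster modality with probability
  `betweenNoise` (0.2). Carried modalities get affinity 1 and blocks
  are normalized per category, so binarizing at 0 recovers the planted
  pattern exactly. The default modality pool is 180 (a 30-modality core
  per cluster, the scale of real trait schemes applied per cluster):
  with per-modality noise at 0.2, the power of the exact hypergeometric
  test grows with the pool size, and a design analysis showed the
  planted structure is only reliably identifiable at $\alpha = 0.05$
  from roughly 120 modalities upward. The default was fixed from that
  analysis, before any acceptance checking, so that the planted
  structure is identifiable at all — the generator is meant to emulate
  a recoverable community, not a borderline one.
* **Community.** Counts are negative-binomial with cluster-specific
  means (size 2 by default — ecological counts are overdispersed;
  `Inf` gives the Poisson limit, which the tests verify
  distributionally). Environmental variables are drawn from
  configurable uniform/normal specifications whose defaults mimic
  sediment percentages.
* **Functions.** Each function is
  $\sum_k c_k \tilde z_k + \varepsilon$, a linear combination of
  *standardized* sources (planted-cluster abundance sums or
  environmental variables) plus Gaussian noise, so coefficients map to
  partial $R^2$ predictably (`effectCoefficient()` converts a target
  partial $R^2$ into a coefficient). The realized sequential $R^2$ of
  every effect is returned, computed by ordinary least squares on the
  realized design — an oracle independent of the DistLM path. Default
  sample size is 49 (seven plots at seven sites).

What the generator does **not** emulate: spatial autocorrelation among
samples, zero-inflation, fuzzy affinities strictly between 0 and 1
(planted affinities are 0/1 before normalization), correlated
environmental gradients, and abundance–trait feedbacks. Passing tests
therefore demonstrate correctness of the algorithms under the stated
statistical model, not robustness to every property of field data.

# Numerical choices and degenerate inputs

* Missing cells are hard errors naming the cell — never imputed, since
  silent imputation would corrupt cooccurrence counts.
* Trait-empty species (no modality at the threshold) are flagged with a
  warning and excluded from scans, not errors.
* Constant predictor columns are excluded as degenerate and logged;
  candidates collinear with the current model are skipped inside
  forward selection (relative residual norm below $10^{-8}$); fitting
  an explicitly rank-deficient design is an error naming the columns.
* A constant response (zero total sum of squares) is an error.
* Saturated models (zero residual) give $F = \infty$ and the minimal
  permutation p-value $1/(n_{perm}+1)$.
* Tie-breaks everywhere are deterministic (lexicographic); every
  stochastic step (Louvain restarts, permutations, generators) is a
  pure function of its seed.

# Problem sizes used in the shipped checks

The package's own validation runs at desk scale: exhaustive
hypergeometric enumeration up to $N = 10$; 1,000 OLS-equivalence
fixtures at $n = 50$; 500 null permutation simulations at $n = 30$ with
199 permutations; 100 planted-block recovery seeds (36 species); and
100 two-stage recovery replicates at $n = 49$ with planted partial
$R^2$ of 0.3 (cluster) and 0.2 (environment) and 199 permutations.
These sizes make the full suite run in about a minute while leaving the
Monte-Carlo tolerances meaningful.

# Known limitations

* Greedy forward selection under the strict admissibility rule is not
  guaranteed to find the best admissible subset; when transforms of one
  variable are nearly collinear the greedy path can lock out a slightly
  better combination. This is inherent to the protocol, not a defect.
* Louvain is a heuristic; restarts mitigate but do not eliminate local
  optima, and recovering a specific number of clusters on real data may
  depend on the resolution parameter.
* The per-pair cooccurrence tests are reported raw by default; with
  hundreds of pairs, some significant associations are expected by
  chance (the BH switch addresses this at the cost of comparability
  with the conventional protocol).
* Permutation p-values with forced terms are approximate (as all
  residual-permutation schemes are), though their type-I error is
  verified by simulation at the shipped sizes.
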