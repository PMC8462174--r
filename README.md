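# mufnet

Multivariate network analysis of ecosystem multifunctionality for
trait-based community ecology.

Ecosystem multifunctionality — the simultaneous performance of several
ecosystem functions (nutrient fluxes, oxygen exchange, organic-matter
degradation, primary-producer standing stock) — is usually condensed
into a single index, which obscures which parts of a community drive
which functions. `mufnet` implements a network alternative for benthic
(and other) community data, in two stages:

1. **Reducing trait dimensionality.** Species described by fuzzy-coded
   functional traits are tested pairwise for sharing more trait
   modalities than chance allows. With $n_A$, $n_B$ modalities possessed
   out of $N$, the shared count $q$ is hypergeometric,
   $P(q=j) = \binom{n_A}{j}\binom{N-n_A}{n_B-j}\big/\binom{N}{n_B}$,
   and a pair is a significant positive association when
   $P(q \ge q_{obs}) < \alpha$. Significant pairs form an undirected
   network weighted by Jaccard's coefficient
   $JC = q/(n_A+n_B-q)$; Louvain modularity clustering (weighted
   Newman–Girvan $Q$, seeded restarts, deterministic tie-breaks) yields
   trait clusters of functionally similar species. Disconnected or
   undersized clusters are excluded, and retained clusters become
   per-sample predictors by summing member abundances.
2. **Multivariate network analysis.** Each function is modelled by a
   two-stage distance-based linear model (DistLM,
   $R^2 = \mathrm{tr}(HGH)/\mathrm{tr}(G)$ on the Gower-centred
   Euclidean distance): forward selection by adjusted
   $R^2 = 1-(1-R^2)(n-1)/(n-v-1)$ over raw/square/log10(x+1) candidate
   columns with transform-admissibility rules, first over trait-cluster
   abundances, then — with significant clusters forced — over
   environmental characteristics, with sequential Freedman–Lane
   permutation p-values. The per-predictor sequential $\Delta R^2$
   values populate a directed source→function network whose edge
   weights are variance explained and whose node sizes are degrees.

A synthetic-study generator with planted trait clusters and planted
linear cluster/environment→function effects makes every stage testable
end to end against ground truth.

## Worked example

```r
library(mufnet)

study <- simulateStudy(simulationParams(seed = 1))   # four tables + truth
bin   <- binarizeTraits(study$traits)
scan  <- cooccurrenceScan(bin)                       # 84 of 630 pairs significant
net   <- buildTraitNetwork(scan, speciesIds(study$traits))
part  <- detectClusters(net, seed = 1)
part
#> Partition: 36 nodes in 6 clusters, Q = 0.7492

cl  <- aggregateClusterAbundance(part, study$abundance)
rep <- runTwoStage(study$functions, cl, study$environment,
                   runConfig(seed = 1, nPermutations = 999))
rep
#> DistLMReport: 8 functions, n = 49 samples
#>   ammonium                       A = 0.343  B = 0.155  C = 0.498
#>   nox                            A = 0.353  B = 0.220  C = 0.573
#>   phosphate                      A = 0.000  B = 0.566  C = 0.566
#>   denitrification                A = 0.180  B = 0.089  C = 0.269
#>   oxygen_consumption             A = 0.595  B = 0.094  C = 0.689
#>   oxygen_production              A = 0.544  B = 0.042  C = 0.586
#>   om_degradation                 A = 0.354  B = 0.000  C = 0.354
#>   primary_producers              A = 0.537  B = 0.000  C = 0.537

mf <- assembleMultifunc(rep)
head(connectivitySummary(mf), 3)
#>   node        role degree weight_sum
#> 1   c1     cluster      4  1.2957559
#> 2  mud environment      3  0.3384114
#> 3  nox    function      3  0.5731576
```

The six detected clusters recover the six planted trait blocks exactly
(adjusted Rand index 1 against the generator's labels). Per function,
row A is the variance explained by the significant trait clusters, row
B what significant environmental characteristics add on top, and
C = A + B (exact to 1e-12); the connectivity summary shows cluster `c1`
explaining four functions — its out-degree and the summed variance it
accounts for. Networks export with `writeNetwork()` to GraphML, GEXF or
edge CSV for Gephi-class viewers, and `runPipeline("config.yaml")`
drives the whole analysis from a configuration file
(`inst/scripts/mufnet-cli.R` wraps it for the shell).

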