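# wocna

Community analysis for snow algae bloom microbiomes — and, more
generally, for amplicon surveys structured as *regions × blooms × zones*
— with a weighted OTU correlation network analysis (WOCNA) at its core.

Red snow algae blooms host bacteria and fungi whose co-occurrence
structure and environmental associations are the scientific target:
which sub-communities (modules) of OTUs co-vary, how stable those
modules are, which field measurements (ORP, dissolved oxygen,
conductivity, nitrate, ammonium, potassium, pH, algae and pollen
densities, elevation) track them, and how abundant focal taxa connect to
the rest of the community. `wocna` is aimed at microbial ecologists who
have OTU count tables (mothur `.shared` or generic wide TSV), consensus
taxonomy, and per-sample environmental measurements.

## What it computes

* **Iterative-rarefaction diversity** — subsampling without replacement
  (multivariate hypergeometric) to a common depth, averaged over
  iterations: observed richness S_obs, Simpson evenness
  E_D = (1/D)/S_obs, Gini-Simpson diversity 1 − D with
  D = Σ p_i², and mean Bray–Curtis dissimilarity
  BC = 1 − 2·Σ min(x_i, y_i)/(Σx + Σy).
* **Zone and region tests** — Wilcoxon rank-sum (regions) and
  within-bloom paired signed-rank (zone pairs M–P, M–A, P–A), exact
  where feasible, with the half-sum-of-signed-ranks statistic
  S = (W⁺ − W⁻)/2 and median-difference (MD) effect sizes; taxonomic
  roll-ups with low-abundance grouping.
* **PerMANOVA** — single-covariate permutational MANOVA on the mean
  Bray–Curtis matrix: pseudo-F from the Gower-centered inner-product
  matrix and the covariate's hat matrix, R², permutation p with the
  add-one rule.
* **WOCNA** — Hellinger transform h = √(n/N); soft-thresholded
  correlation adjacency a = |cor|^β (signed variant available);
  topological overlap TOM; average-linkage clustering with a gap-based
  dynamic tree cut; eigen-OTUs (first principal components); bootstrap
  clusterwise Jaccard stability; Kendall tau-b module–trait and
  module–OTU correlation heatmaps.
* **Co-association networks** — Kendall tau-b edges among abundant OTUs
  (AA > 100) with boundary-inclusive thresholds |τ| ≥ 0.40 and
  p ≤ 0.10, first-order (ego) neighbourhoods, connectivity summaries,
  GraphML/TSV export.
* **Synthetic communities** — a generator planting modules, environment
  drivers and zonal gradients with full ground truth, so every stage is
  testable against a known answer.

## Worked example

```r
library(wocna)

sim <- generateCommunity(n_otus = 120, n_modules = 3, module_size = 8,
                         w = 1.5, seed = 1)
sim$otu
#> OtuTable: 120 OTUs x 30 samples
#>   lineage prefixes: A=3, B=58, F=59
#>   zones: A=10, M=10, P=10
#>   regions: Cascades, Rockies

h   <- hellingerTransform(sim$otu)
ms  <- eigenOtus(h, detectModules(tomSimilarity(softAdjacency(h))))
ms
#> ModuleSet: 3 modules over 120 OTUs (96 unassigned)
#>   sizes: M1=8, M2=8, M3=8, grey=96
#>   eigen-OTUs over 30 samples; var explained M1=0.77, M2=0.74, M3=0.83
```

The three planted modules are recovered exactly (96 noise OTUs stay in
the reserved `grey` pool). Their eigen-OTUs track the environmental
features the generator coupled to them — the planted drivers ORP, DO and
conductivity sit on the diagonal of the Kendall-tau heatmap with p below
0.001:

```r
mc <- moduleCorrelations(ms, env = sim$env)
round(mc$env@tau[, 1:3], 2)
#>     ORP    DO conductivity
#> M1 0.48 -0.24        -0.02
#> M2 0.17  0.49         0.11
#> M3 0.03  0.22         0.46

bootstrapStability(h, B = 50, seed = 2)
#> StabilityReport: 3 modules, B = 50 bootstrap replicates
#>  module size mean_jaccard dissolved_fraction
#>      M1    8    0.8631667               0.00
#>      M2    8    0.8218333               0.06
#>      M3    8    0.8557727               0.04
```

Mean best-match Jaccard above 0.8 means each module is recognisably
re-derived in the large majority of sample resamples — these are stable
sub-communities, not clustering artifacts. A paired zone contrast in
which all nine blooms move the same way yields the maximal signed-rank
statistic and its exact tail:

```r
signedRankTest(c(0.7, 1.3, 2.9, 3.1, 4.8, 5.2, 6.4, 7.7, 9.5))
#> exact signed-rank: S = 22.5, p = 0.00390625, MD = 4.8, n = 9
```

`runPipeline()` chains the stages (prefilter → diversity → zone tests →
PerMANOVA → per-region WOCNA → stability → networks) under one YAML-able
configuration with a mandatory seed, writes CSV/TSV artifacts plus a
JSON manifest with checksums, and reruns byte-identically.

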