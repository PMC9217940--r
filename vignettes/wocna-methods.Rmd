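---
title: "Weighted OTU correlation network analysis for snow bloom communities: models and methods"
author: "wocna package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted OTU correlation network analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wocna)
```

## The scientific setting

Red snow algae blooms -- dense late-season accumulations of *Sanguina*-type
algae on alpine snow -- host diverse bacterial and fungal communities whose
assembly is poorly understood. A standard field design samples each bloom
in three zones along the visual algal-density gradient: medial (M, dense
red), peripheral (P, pink) and adjacent (A, visually uncolonized), across
multiple blooms in two or more mountain regions, together with field
physiochemistry (ORP, dissolved oxygen, conductivity, TDS, salinity,
nitrate, ammonium, potassium, pH) and hemocytometric algae and pollen
densities.

`wocna` implements the statistical stages such a survey needs once
sequence processing has produced OTU count tables:

1. iterative-rarefaction alpha diversity and mean Bray-Curtis
   dissimilarity;
2. nonparametric region and zone contrasts with median-difference effect
   sizes;
3. single-covariate PerMANOVA on the mean distance matrix;
4. a weighted OTU correlation network analysis (WOCNA): Hellinger
   transformation, soft-thresholded correlation adjacency, topological
   overlap, module detection, eigen-OTUs, bootstrap clusterwise Jaccard
   stability, and Kendall-tau module-trait correlation; and
5. thresholded first-order OTU co-association networks.

A synthetic community generator with full ground truth exercises every
stage, so each procedure is tested against data whose correct answer is
known.

## Rarefaction and diversity

Library sizes differ by orders of magnitude, so all diversity and
dissimilarity quantities are computed on repeated random subsamples drawn
*without replacement* (multivariate hypergeometric, matching mothur's
subsampling semantics) to a common depth, and averaged over iterations
(default 1000). The depth is configurable; the conventional field choice
is the smallest library in the lineage table, which in published bloom
surveys is of order 10^4 for algae to 10^5 for a whole community. Per
sample, with proportions $p_i = n_i/N$:

* Simpson concentration $D = \sum_i p_i^2$, Gini-Simpson diversity $1-D$;
* observed richness $S_{obs}$; Simpson evenness $E_D = (1/D)/S_{obs}$.

The plug-in $p_i^2$ form is the default: after rarefaction to a shared
depth its finite-sample bias is common to all samples, and comparisons
are unaffected. The unbiased $\sum n_i(n_i-1)/(N(N-1))$ form is available
via `correction = "unbiased"`. Whether evenness should be computed on
rarefied or raw counts is not standardised in the field; `wocna` computes
all three metrics on each rarefied draw and averages, which keeps the
metrics mutually consistent at a common depth.

Bray-Curtis dissimilarity $BC(x, y) = 1 - 2\sum_i \min(x_i, y_i) /
(\sum_i x_i + \sum_i y_i)$ is evaluated on each rarefied pair (via
`vegan::vegdist`) and averaged element-wise. Per-iteration seeds derive
from the master seed by a counter scheme, so results do not depend on the
order in which iterations run. Note one boundary subtlety: two identical
samples rarefied independently to less than their full depth have a small
positive expected dissimilarity; the exact zero holds at full depth.

## Zonal and regional tests

Region contrasts use the Wilcoxon rank-sum test; zone contrasts are
paired within blooms (each bloom contributes one sample per zone) and use
the Wilcoxon signed-rank test. Conventions:

* Exact zeros among paired differences are dropped before ranking
  (Wilcoxon's original procedure). With a 10-bloom design and one
  zero/missing pair this yields $n = 9$ usable pairs; when all nine move
  the same way the statistic attains its maximum.
* The signed-rank statistic is reported in the half-sum-of-signed-ranks
  convention $S = (W^+ - W^-)/2 = W^+ - n(n+1)/4$, the convention used by
  JMP, so $|S| \le n(n+1)/4$ (22.5 at $n = 9$). For the rank-sum test the
  analogous signed centered statistic $S = W_1 - n_1(N+1)/2$ is reported;
  its sign follows the group order.
* Exact two-sided p-values (doubled tail, capped at 1) are used when the
  data are untied and small ($n \le 25$ paired; $n_1+n_2 \le 20$
  unpaired); otherwise normal approximations with tie correction (and
  continuity correction in the rank-sum case). The exact machinery uses
  the exact distributions in base R; the test suite checks it against
  full $2^n$ and $\binom{N}{n_1}$ enumeration.
* The effect size is the median difference (MD) of relative abundances
  computed within the lineage's own table (e.g. algal RA among algal
  OTUs), so dominant-taxon MDs are of order 0.1.
* Raw p-values are reported by default -- these screens are exploratory
  -- with a Benjamini-Hochberg flag for reuse.

Taxonomic roll-ups aggregate counts at a chosen rank and group taxa whose
total relative abundance falls below a threshold into a single remainder,
so each row still sums to 1.

## PerMANOVA

Each covariate is tested in its own one-term model (DF = 1), not in a
joint sequential fit: a per-feature screen is order-independent and
matches how distance-based environmental screens are tabulated. With
$G = -\tfrac12 J D^{(2)} J$ the Gower-centered matrix and $H$ the hat
matrix of the centered covariate,

$$F = \frac{\mathrm{tr}(HGH)/1}{\mathrm{tr}((I-H)G(I-H))/(N-2)},
\qquad R^2 = \frac{\mathrm{tr}(HGH)}{\mathrm{tr}(G)}.$$

Significance comes from permuting the covariate's sample labels, with the
add-one rule $p = (1 + \#\{F^\pi \ge F\})/(1 + n_\pi)$ (never exactly
zero; default 9999 permutations), or from complete enumeration of all
$n!$ labellings for tiny designs, in which case the identity permutation
is part of the reference set and $p = \#\{F^\pi \ge F\}/n!$. Continuous
covariates are z-scored first (a floating-point stabilisation only);
negative eigenvalue mass of the non-Euclidean Bray-Curtis matrix is
retained in the traces, as in common `adonis` practice. Unrestricted
permutations are the default; bloom-level exchangeability is arguable and
restricted (strata) permutation is out of scope. The implementation is
verified against Anderson's group-sum formulation and `vegan::adonis2`
to 1e-10, and against a fully enumerated four-sample configuration.

## WOCNA

**Hellinger input.** Raw counts are transformed per sample to
$h_{ij} = \sqrt{n_{ij}/N_i}$ -- the square root of relative abundance,
whose row-wise Euclidean geometry is the Hellinger distance. This is the
only reading of a "Hellinger" preprocessing step that can feed a
correlation network, and it gives higher weight to abundant OTUs. The
transform removes library-size effects exactly (scaling a sample's
counts changes nothing).

**Adjacency.** Pearson correlation of the transformed OTU profiles
(Kendall tau-b available via `cor_method`), soft-thresholded:
unsigned $a_{ij} = |r_{ij}|^\beta$ (default) or signed
$a_{ij} = ((1+r_{ij})/2)^\beta$. Unsigned is the default because module
analyses of OTU data routinely report negative module-OTU correlations,
which an unsigned construction permits within modules. The default
$\beta = 4$ is a mid-range choice for tables of 10^2 OTUs; `pickSoftPower`
offers the scale-free-fit criterion (smallest power whose signed
$R^2 \ge 0.8$ on the log-log connectivity regression) when a data-driven
choice is wanted, and flags the result "unverified" when no power
reaches the target.

**Topological overlap.**
$TOM_{ij} = (\sum_{u \ne i,j} a_{iu}a_{uj} + a_{ij}) /
(\min(k_i, k_j) + 1 - a_{ij})$ rewards pairs that share neighbourhoods;
modules are found by average-linkage hierarchical clustering of
$1 - TOM$.

**Tree cut.** Two cuts are provided. The static cut slices at a fixed
height. The default dynamic cut is a basic gap-splitting variant: a
branch with at least `min_module_size` members (default 5) qualifies as
a module when it is separated from the rest of the tree by a merge-height
gap of at least `min_gap` (default 0.2) times the dendrogram's height
range. Two refinements make the rule robust without approaching the
PAM-assisted hybrid variant (out of scope):

* *straggler tolerance* -- single leaves or side-branches totalling fewer
  than `min_module_size` members that join a branch on its way up do not
  close its gap; the gap ends where a competing group of at least
  `min_module_size` members joins;
* *separable unions split* -- a qualifying branch that unites two or more
  disjoint qualifying branches yields to them (a separable union is a
  set of modules, not one), while a branch containing a single nested
  qualifying sub-branch absorbs it (the inclusive branch wins).

OTUs in no accepted branch receive the reserved `grey` label. In
structureless data no branch exhibits a qualifying gap and essentially
everything stays grey -- the procedure does not manufacture modules from
noise. The cut is deterministic; the entire WOCNA path contains no RNG.
Module labels are size-ordered (`M1`, `M2`, ...) with a colour alias
table for presentation; colours are not semantically portable across
runs or regions.

**Eigen-OTUs and module-trait correlation.** Each module is summarised
by the first principal component of its column-standardised member
profiles, scaled to unit variance and sign-oriented so the mean
correlation with members is non-negative (ties broken toward a positive
loading sum; modules with near-zero mean member correlation -- e.g. two
anti-correlated halves -- are flagged rather than silently oriented).
Module-environment and module-OTU associations use Kendall tau-b with
tie-corrected p-values; missing environmental values are removed
pairwise, never imputed, because field meters fail and silent imputation
would bias the rank correlation. Cells with fewer than 3 complete pairs
are reported missing. Analyses are run per region when regions differ
compositionally, since modules fitted across a strong regional contrast
would largely encode region.

**Stability.** Module robustness is assessed by resampling *samples*
with replacement (B bootstrap replicates, default 100), rerunning
adjacency, TOM and the cut with identical parameters, and recording each
reference module's best-match Jaccard similarity
$\max_C |R \cap C| / |R \cup C|$ against the re-derived clusters. The
sampling unit is the sample, not the OTU, because the question is
robustness to which snows were collected. The unassigned pool is not a
match candidate (configurable). A replicate Jaccard below 0.5 counts as
a dissolution, the conventional cluster-stability reading. Both the
dominant module's membership share (`moduleShare`) and its stability
are reported, as the two statistics answer different questions.

## Co-association networks

For one region at a time, OTUs whose within-region absolute abundance
exceeds `aa_min` (default 100 reads) are candidate nodes; every candidate
pair's Kendall tau-b and p-value are computed on per-sample relative
abundance profiles, and edges with $|\tau| \ge 0.40$ **and** $p \le 0.10$
are retained -- both comparisons boundary-inclusive, so a pair at exactly
(0.40, 0.10) is an edge. The published threshold is phrased as a vertex
criterion, but a correlation threshold is only well-defined on pairs;
`wocna` therefore reads it as an edge criterion and keeps isolated
candidates as nodes, so "limited connectivity" of a focal taxon (degree
near 0) is representable. First-order (ego) neighbourhoods extract a
focal OTU, its direct neighbours and (optionally) neighbour-neighbour
edges. No multiplicity correction is applied, matching exploratory use.

Relative abundance is the default profile because raw counts would let
library size dominate the ranks; note that closure makes RA profiles of
*truly independent* taxa weakly dependent whenever a dominant
subcommunity swings the denominator -- the usual compositional caveat
for correlation networks. `profile = "counts"` is available.

## The synthetic generator

`generateCommunity` emulates the study design the analyses assume, with
complete ground truth:

* **Design**: 2 regions with 6 and 4 blooms, 3 zones per bloom
  (M/P/A), hence 30 samples -- the canonical field layout.
* **Counts**: log-linear negative-binomial model. For OTU $j$ in sample
  $i$, $\log\mu_{ij} = \mu_j + w_j z_{m(j),i} + \text{offsets}$ with one
  latent factor $z_m \sim N(0,1)$ per module per sample; members of a
  module share its factor with loading $w$ (default 1.2, a calibration
  choice), noise OTUs have $w_j = 0$. Counts are drawn with variance
  $\mu + \phi\mu^2$, $\phi = 0.1$ by default (moderate overdispersion,
  appropriate for the abundant taxa that dominate network analyses), and
  thinned by 5% excess zeros.
* **Zonal gradient**: designated algal OTUs are multiplied by
  (A, P, M) = (1, 2, 4) in expectation. Cell-count gradients across bloom
  zones span two orders of magnitude, but *sequence-space* differences
  are far more modest -- published zone contrasts of dominant algal OTUs
  show relative-abundance median differences of order 0.1 -- so the
  generator plants a modest read-count gradient and leaves stronger ones
  to `generateZoneGradient`, which layers binomial
  thinning/amplification onto any table.
* **Environment**: feature $k$ driven by module $m$ is
  $\alpha z_m + N(0,1)$ (default $\alpha = 1$), mapped affinely onto the
  instrument's scale (rank statistics are unaffected); algae and pollen
  densities follow the observed A < P < M concentration ordering with
  log-normal noise. Environmental features are driven by module factors,
  not by single OTUs, because module-environment inference is the
  analysis target.
* **Region**: noise fungal OTUs get a random-signed log-offset between
  regions (default 0.5), emulating regional structuring of fungi.

Everything is deterministic under the mandatory seed. What the generator
does **not** emulate: taxonomic assignment realism, phylogenetic signal,
sequencing error and chimeras, PCR/primer bias, and the full severity of
compositional coupling in tables dominated by one taxon (the planted
algal OTUs are kept modest). Passing recovery tests therefore show the
pipeline is correct and well-calibrated *for the factor-model class of
community structure*; they do not certify performance on tables whose
counts are noisier (higher $\phi$), sparser, or dominated by a single
taxon, where any correlation-network method degrades.

## Numerical choices and test design

* Per-iteration and per-replicate seeds derive from the master seed by a
  counter scheme; reruns are byte-identical, and all integer draws stay
  within 32-bit range.
* Exact tests switch to tie-corrected normal approximations at the
  conventional size limits quoted above; two-sided p-values are doubled
  tails capped at 1.
* Oracle tolerances: TOM against a triple-loop oracle at 1e-12; PerMANOVA
  against the group-sum formulation at 1e-10; exact Wilcoxon p against
  full enumeration at 1e-12.
* Null-calibration experiments use designs whose exact-test sizes are
  close to nominal (10 paired differences; two groups of 8), 1000
  replicates each; permutation PerMANOVA uses 8 samples and 99
  permutations per replicate so the p-value grid contains 0.05.
* Recovery experiments run at desk scale -- 120 OTUs, 3 planted modules
  of 8, 30 samples, 20 seeds; bootstrap stability at B = 50 over 10
  seeds -- sizes chosen so the whole suite runs in about a minute while
  leaving the conclusions unchanged at larger tables.
* Degenerate inputs fail loudly and early: all-zero samples name the
  sample, infeasible designs and depth overruns are errors, constant
  covariates and constant correlation inputs are refused or flagged
  rather than returning NaN.

## Known limitations

* The dynamic cut is the basic tree variant; the PAM-assisted hybrid
  (which rescues borderline members into modules) is deliberately not
  implemented, so recovered modules can run a few members short of the
  planted truth when stragglers attach late.
* Compositional dependence: correlation on relative abundances (and,
  damped, on Hellinger data) reflects closure as well as ecology;
  SparCC-style compositionally aware estimators are out of scope.
* Single-covariate PerMANOVA does not adjust covariates for one another,
  and unrestricted permutation ignores bloom-level grouping.
* Blockwise approximations are absent: tables beyond ~10^4 OTUs would
  need a different implementation of the adjacency/TOM step.
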