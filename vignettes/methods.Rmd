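---
title: "Methods: comparative landscape population genetics with popcompare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative landscape population genetics with popcompare}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popcompare)
```

# Scope

`popcompare` implements a comparative population-genetic analysis for
multilocus codominant microsatellite data sampled from georeferenced sites:
diversity statistics, Hardy–Weinberg exact testing, pairwise F~ST~,
hierarchical AMOVA over geographic groups (e.g. watersheds), landscape
predictor construction, and weighted multiple regression on distance
matrices with AICc permutation significance ("MRMPA"). A forward-time
stepping-stone simulator generates data with known structure so that every
stage can be exercised and validated without any external download.

This vignette documents the statistical models, the defaults and why they
were chosen, the numerical conventions, and what the validation suite does
and does not establish.

# Data model

A `genotype_dataset` holds individuals typed at a shared panel of loci
(typically 10, the usual microsatellite panel size), each assigned to a
population site with planar UTM coordinates, an optional group label, and
optional site-level climate scalars. Three conventions apply throughout:

* **Allele identity is the integer code as read** (fragment length or
  repeat count); no binning or recoding is attempted.
* **Missingness is per locus per individual.** A genotype is missing only
  as a whole pair; half-missing calls are a parse error. Individuals are
  never dropped globally — each per-locus statistic excludes exactly the
  individuals untyped at that locus.
* **Population order follows the site-metadata file order** and every
  matrix carries explicit labels, so alignment between genetic and
  landscape matrices is always checkable.

Readers are provided for the Genepop dialect (2- and 3-digit encodings,
`00`/`000` missing) and the STRUCTURE-format matrix (one- and two-row
layouts, `-9` missing), with matching writers; the same cohort encoded both
ways parses to the same dataset. Coordinates are treated as planar meters
in a single UTM zone — adequate for a study area spanning one zone, and
deliberately free of geodesic corrections.

# Diversity statistics

For allele gene counts $N_i$ ($N = \sum_i N_i = 2n$ genes from $n$ typed
individuals):

* **Allelic richness** $A$ is the number of distinct alleles. In the
  per-population table, the population's $A$ is the mean of its per-locus
  values, and cohort-level rows report the mean ± SE across populations.
* **Rarefied allelic richness** at $g$ genes is
  $A_R(g) = \sum_i \left[1 - \binom{N-N_i}{g} / \binom{N}{g}\right]$,
  the expected distinct-allele count in a random $g$-gene subsample. The
  default $g = 4$ standardises to the information content of a
  two-individual site, the smallest sample a field collection typically
  yields. The binomial ratio is evaluated as a running product of exact
  ratios, which is why the enumeration test can demand agreement to 1e-12.
  When $g$ exceeds the typed gene count the statistic is undefined: the
  population/locus is skipped with a warning, never zero-filled, and `NA`
  markers propagate into reports.
* **Observed heterozygosity** $H_O$ is the fraction of typed individuals
  whose two alleles differ.
* **Unbiased expected heterozygosity** is Nei's small-sample-corrected
  gene diversity $uH_E = \frac{2n}{2n-1}(1 - \sum_i p_i^2)$; the correction
  always inflates the plug-in value, which matters at the 2–6 individual
  sites the pipeline is designed to tolerate.

# Hardy–Weinberg exact test

The test statistic is the conditional probability of the genotype array
given the allele counts,
$P(\text{array}) = n!\, 2^H \prod_k a_k! \,/\, \big((2n)! \prod_{i\le j} g_{ij}!\big)$,
and the p-value is the total conditional probability of arrays no more
probable than the observed one (ties included).

The Monte Carlo estimate uses a chain on *gene-slot assignments*: the $2n$
genes occupy $2n$ labelled slots, two per individual. A uniformly random
assignment of the gene multiset to slots induces exactly the conditional
array distribution above (an array corresponds to $n!/\prod g_{ij}! \times
2^H$ slot states), so a chain that swaps the contents of two uniformly
chosen slots and always accepts has the exact stationary law — the
classical genotype-switching construction reduced to its symmetric core.
The p-value is the long-run fraction of visited arrays at or below the
observed probability, with a Monte Carlo standard error from batch means.

Defaults follow the standard contract for this test: dememorisation
10,000, 1,000 batches of 10,000 iterations. The validation suite uses
shorter chains and compares against full enumeration of the array space
(all two-allele tables asserted to $n = 50$, three-allele tables to
$n = 12$), requiring agreement within three Monte Carlo standard errors.
Monomorphic loci and samples of fewer than three individuals are reported
"not testable" and count as conforming. The default testing scope is the
pooled island-wide sample per cohort, where a Wahlund-style heterozygote
deficit from pooling differentiated populations is detectable; per-population
scope is available.

Multiple testing uses sequential Bonferroni (Holm): sort the $m$ p-values,
reject while $p_{(i)} \le \alpha/(m-i+1)$, stop at the first failure, with
flags returned in input order ($\alpha = 0.05$ by default).

# Differentiation: F~ST~ and hierarchical AMOVA

Both statistics work at the gene level with the 0/1 allele-mismatch
distance, under which sums of squared deviations reduce to counting
mismatching gene pairs: a pool with allele counts $c_k$ (total $n$) has
$SSD = [\binom{n}{2} - \sum_k \binom{c_k}{2}]/n$. Variance components come
from the standard moment equations with unequal-sample-size coefficients;
multi-locus statistics sum components over loci before forming ratios
(each locus weighted by its own typed sample). Negative estimates are
reported as computed — truncation would bias the downstream regression.

* **Pairwise F~ST~** is the two-level variance-component estimator
  (θ in the AMOVA framework, the computation population-genetics packages
  perform under the "Wright's F-statistic" label). Significance comes from
  shuffling individuals between the two populations,
  $p = (\#\{F_{perm} \ge F_{obs}\} + 1)/(B+1)$, default $B = 100$.
* **Hierarchical AMOVA** partitions variance among groups, among
  populations within groups, and within populations;
  $F_{CT} = \sigma_a^2/\sigma_T^2$,
  $F_{SC} = \sigma_b^2/(\sigma_b^2+\sigma_c^2)$,
  $F_{ST} = (\sigma_a^2+\sigma_b^2)/\sigma_T^2$, with the 0/0 case defined
  as 0 (no variance at either level). Degrees of freedom follow the
  gene-level convention ($G-1$, $P-G$, $2N-P$; total $2N-1$). Permutation
  schemes: F~CT~ permutes whole populations among groups; F~SC~ permutes
  individuals among populations within groups; F~ST~ permutes individuals
  across the whole sample; default 10,000 permutations, all one-sided with
  the $(b+1)/(B+1)$ estimator so p is never exactly zero. Groups containing
  a single population are retained but contribute no permutable structure
  to F~SC~.

The validation suite checks the count-based engine against a completely
independent evaluation of the same quadratic forms from raw pairwise
mismatch matrices on all small fixtures, and checks that with every
population its own group the three-level engine collapses to the global
two-level θ.

# Landscape predictors

* **Euclidean distance** between site coordinates (planar meters).
* **Cost rasters** encode dispersal habitat as the union of buffers around
  feature layers (coastline, major rivers — supplied as densely sampled
  point sets): cell centers within the buffer cost 1, everything else a
  penalty multiplier. The penalty default is 100× and finite, so all site
  pairs stay connected (matrix regression needs complete predictors);
  `Inf` turns unsuitable habitat into an absolute barrier, and unreachable
  pairs become `NA` with a warning. Buffers are species-specific study
  inputs (e.g. 10 km around the coast for a strict coastal specialist,
  75 km around rivers and coast for a generalist).
* **Least-cost dispersal distance** is the minimum accumulated cost over
  8-connected lattice paths with step cost $res \cdot (c_i + c_j)/2$,
  scaled by $\sqrt 2$ on diagonals — the standard cost-distance convention;
  on a unit-cost raster it is path length in meters (bounded between the
  Euclidean distance and ≈1.0824× it, the 8-connectivity chamfer error).
  Shortest paths are computed by Dijkstra's algorithm via `igraph`; the
  test oracle is an independent Bellman–Ford-style relaxation. Sites snap
  to the nearest cell center with deterministic tie-breaking toward the
  lower index. Bit-exact parity with any particular GIS implementation is
  not claimed; the contract (convention above) is what is tested.
* **Bray–Curtis dissimilarity** of site-level climate scalars reduces to
  $|x-y|/(x+y)$ per pair, in $[0,1]$, with $0/0 := 0$ and negative inputs
  rejected. Climate variables (annual precipitation in mm, isothermality)
  enter as site metadata; extracting them from interpolated climate
  surfaces is outside the package's scope and is emulated by the simulator.

# MRMPA: weighted matrix regression with AICc permutation

The response (pairwise F~ST~) and all predictors are unrolled over the
lower triangle in one fixed, documented pair order. Pair $(i,j)$ carries
weight $n_i + n_j$ — the total number of samples behind the comparison —
down-weighting F~ST~ values estimated from small sites (`min(n_i, n_j)` is
available as an alternative reading). Weights are normalised to mean 1
before fitting, making AICc differences invariant to weight rescaling.
Fits are weighted least squares with an intercept always included;
rank-deficient designs are an error naming the collinear columns.

$AICc = n \ln(RSS_w/n) + 2k + 2k(k+1)/(n-k-1)$ with $k$ counting
intercept, slopes and error variance. Saturated fits ($RSS = 0$) are
flagged and excluded from averaging.

**Permutation test.** One designated predictor matrix has its rows and
columns permuted by the same population-label permutation (the matrix's
internal structure is preserved; only its pairing with the other matrices
changes), the model is refitted, and
$p = (\#\{AICc_{perm} < AICc_{obs}\} + 1)/(B+1)$, default $B$ = 10,000.
The raw proportion without the +1 correction is available by flag.
Exhaustive mode enumerates all $k!$ label permutations (identity included,
ties counted), and the Monte Carlo estimate is required to agree with it
within three binomial standard errors on small problems.

**Model set and averaging.** All $2^p - 1$ non-empty predictor subsets
plus the intercept-only model are fitted — a per-predictor "total AICc
weight" only makes sense against a multi-model set. Akaike weights are
$w_m = e^{-\Delta_m/2}/\sum_j e^{-\Delta_j/2}$. Averaged coefficients are
*conditional* (averaged over models containing the predictor); the
zero-filled alternative is exposed as a flag. The adjusted standard error
follows the Burnham–Anderson unconditional-variance form
$\widehat{SE} = \sum_m w_m \sqrt{se_m^2 + (\beta_m - \bar\beta)^2} / \sum_m w_m$,
with $z = |\bar\beta|/\widehat{SE}$ and a two-sided normal p-value. The
per-predictor permutation p reported alongside comes from permuting that
predictor under the full model. Models whose AICc is undefined at the
problem size (n ≤ k+1, possible with very few populations and the full
predictor set) are dropped from the set with a logged warning rather than
failing the whole comparison. Residuals of the AICc-best model get a
Shapiro–Wilk normality check on the weighted residuals.

The Euclidean-only isolation-by-distance analysis is the same machinery
with a single-predictor model set, run before the landscape models as the
more parsimonious baseline.

# The simulator: what it emulates and what it does not

`simulate_genotypes()` runs forward-time Wright–Fisher reproduction per
deme: each offspring gene is drawn uniformly from the previous
generation's gene pool of its source deme; migration is gametic (each
inherited gene independently migrant, probability $m$ per chain neighbour,
or total $m$ split evenly in the island layout); mutation is strict
stepwise ±1 repeat with probability $\mu$, reflecting at repeat count 1 so
allele codes stay positive. Burn-in defaults to $10N$ generations. After
burn-in, individuals are sampled without replacement per deme and genotype
dropout is applied independently. Forward simulation was chosen over
coalescent machinery for transparency: the stepwise-mutation and gametic-
migration semantics are exactly as stated, so the $m \leftrightarrow
F_{ST}$ mapping is well defined.

`simulate_landscape()` lays demes on a linear coastal transect (default
spacing 25 km, UTM-like offsets), generates climate scalars as a linear
spatial gradient plus Gaussian site noise — so climate dissimilarity
rank-correlates with distance, the situation the landscape models assume —
and emits a toy coastline with a consistent cost raster. All outputs are
written in exactly the formats the pipeline reads (Genepop, delimited site
table, ESRI ASCII grid).

Three presets pin the study conditions:

* `panmixia` — one deme of $N = 200$, 2,000 generations, 10 loci at
  $\mu = 5\times10^{-4}$, sampled into 8 pseudo-populations of 10 along
  the transect: the null for every test.
* `strong_IBD` — 8 demes in a chain, $N = 50$, nearest-neighbour
  $m = 0.01$, $\mu = 5\times10^{-4}$, 10 loci, 20 sampled per deme,
  $10N = 500$ generations of burn-in.
* `hierarchical_watersheds` — two groups of four demes; within-group edges
  at $m = 0.05$, the single between-group edge at $m = 0.005$ (10× lower),
  otherwise as `strong_IBD`: vicariant watershed-style structure
  detectable as $F_{CT} > 0$.

Sample sizes, locus counts and allele-number ranges mirror what small
shorebird microsatellite collections look like (2–40 individuals per site,
2–12 alleles per locus); the simulator makes no attempt to match any real
species' absolute parameter values, and it omits selection, linkage, null
alleles and genotyping error. Passing tests therefore demonstrate that the
*statistical machinery* is correct and well calibrated on data satisfying
its assumptions — not that any particular biological conclusion holds for
real data.

# Validation design and problem sizes

The deep validation suite asserts, at sizes chosen to keep the full run in
minutes on one core:

1. rarefaction equals subsample enumeration (to 1e-12) for every allele
   count vector with ≤ 8 genes and every $g$;
2. HWE chain p-values sit within 3 Monte Carlo SEs of full enumeration on
   two-allele tables to $n = 50$ and three-allele tables to $n = 12$;
3. AMOVA sums of squares and variance components match direct
   quadratic-form evaluation on all fixtures with ≤ 12 individuals, with
   percent variation summing to 100 and df to $2N-1$;
4. under panmictic simulation (the single-deme generator sampled into 8
   pseudo-populations — enough populations that the group-permutation null
   of F~CT~ has a fine support), the F~ST~-permutation, AMOVA F~CT~ and
   MRMPA p-values are uniform by Kolmogorov–Smirnov at 200 replicates ×
   199 permutations;
5. Monte Carlo MRMPA p agrees with exhaustive enumeration (≤ 6
   populations, $B$ = 10,000) within 3 binomial SEs;
6. parameter recovery: the `strong_IBD` preset yields a positive weighted
   slope of F~ST~ on distance with permutation p < 0.05 in ≥ 80% of 50
   seeds; `panmixia` rejects in ≤ 12%; `hierarchical_watersheds` gives
   F~CT~ p < 0.05 in ≥ 80% (199 permutations inside these loops; the
   analysis default remains 10,000);
7. least-cost distances equal exhaustive relaxation on ≤ 6×6 grids and the
   analytic chamfer value on uniform rasters;
8. identical seeds reproduce end-to-end reports byte for byte (all
   randomness flows from one master seed through per-stage derived
   streams).

# Numerical conventions and edge cases

* Undefined statistics are `NA` everywhere, never 0; reports carry them
  through, and skipped units are logged as data in the run summary.
* Permutation p-values use $(b+1)/(B+1)$; ties with the observed statistic
  count as exceedances (tolerance $10^{-12}$ absolute, $10^{-9}$ relative
  for log-probability ties in the HWE chain).
* AMOVA ratios with zero denominators: 0/0 is 0 (no variance at either
  level), otherwise `NA`.
* Site-to-cell snapping is deterministic (nearest center, ties toward the
  lower index); cost cells must be ≥ 1 so costs are multipliers of
  distance.
* Negative variance components and negative F~ST~ are reported as
  computed.
* The Genepop writer chooses 3-digit encoding only when an allele exceeds
  99, and refuses alleles above 999.

# Known limitations

* The HWE chain's default iteration counts are conservative; for large
  allele numbers the batch SE should be checked before trusting borderline
  p-values.
* The AMOVA df convention reports complete-data degrees of freedom while
  components use per-locus typed samples; with heavy missingness the SS/df
  columns of the report are descriptive rather than exact mean squares.
* Least-cost distances inherit the 8-connectivity chamfer bias (up to
  ≈ 8.2% over the true geodesic on uniform cost); comparisons across
  rasters of similar resolution are unaffected, absolute values should not
  be over-interpreted.
* The matrix-permutation test treats populations as exchangeable under the
  null; strong heteroscedasticity across sites is only partially absorbed
  by the $n_i + n_j$ weights.
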