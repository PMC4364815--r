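# popcompare

Comparative landscape population genetics for codominant microsatellite
data.

`popcompare` is for population geneticists comparing sympatric species (or
any set of cohorts) sampled at shared georeferenced sites with small and
unequal sample sizes. It answers three questions per cohort from a
multilocus genotype table plus site metadata:

1. **How much diversity is there, and is it in Hardy–Weinberg
   proportions?** Per-population allelic richness *A*, rarefied allelic
   richness *A*<sub>R</sub> (standardised to 4 genes by default), observed
   heterozygosity *H*<sub>O</sub> and Nei's unbiased expected
   heterozygosity u*H*<sub>E</sub>; exact HWE tests estimated by Markov
   chain Monte Carlo on the island-wide sample, with sequential Bonferroni
   (Holm) correction.
2. **How is variation structured in space?** Pairwise F<sub>ST</sub>
   (variance-component θ) with permutation significance, and a three-level
   hierarchical AMOVA (among groups such as watersheds / among populations
   within groups / within populations) with the standard permutation
   schemes for F<sub>CT</sub>, F<sub>SC</sub> and F<sub>ST</sub>.
3. **What explains the structure?** Isolation by distance tested by
   weighted multiple regression of the F<sub>ST</sub> matrix on predictor
   matrices — Euclidean distance, least-cost dispersal distance across a
   habitat cost raster, Bray–Curtis climate dissimilarities — with pair
   weights *n<sub>i</sub>* + *n<sub>j</sub>*, significance from AICc
   permutation (rows and columns of one predictor permuted together,
   p = (#{AICc<sub>perm</sub> < AICc<sub>obs</sub>}+1)/(B+1)), all-subsets
   model comparison, and Akaike-weight model averaging with
   Burnham–Anderson adjusted standard errors.

The core model-averaged quantity per predictor *x* is

```
w_m = exp(-Δ_m/2) / Σ_j exp(-Δ_j/2)           (Akaike weights)
β̄_x = Σ_{m∋x} w_m β_m / Σ_{m∋x} w_m          (conditional average)
SE_x = Σ_{m∋x} w_m sqrt(se_m² + (β_m − β̄_x)²) / Σ_{m∋x} w_m
```

with z = |β̄|/SE and a two-sided normal p-value.

Because studies of this kind rarely deposit raw genotypes, the package
ships a forward-time Wright–Fisher stepping-stone simulator (stepwise ±1
mutation, gametic migration, chain or island layouts) plus a landscape
emulator, so the entire pipeline runs and is validated end-to-end on
synthetic data with known structure. See `vignettes/methods.Rmd` for the
full statistical account.

## Worked example

Simulate the strong isolation-by-distance scenario (8 demes in a chain,
N = 50, m = 0.01 per neighbour, 10 microsatellite loci, 20 sampled per
deme), write it in the pipeline's input formats, and run the analysis:

```r
library(popcompare)
cfg   <- scenario_preset("strong_IBD", seed = 42)
paths <- write_scenario(cfg, "scenario")
rep <- run_pipeline(run_config(
  genotypes = paths$genotypes, sites = paths$sites, raster = paths$raster,
  stages = c("diversity", "fst", "amova", "ibd_euclidean"),
  fst_permutations = 99, amova_permutations = 999,
  mrmpa_permutations = 999, seed = 1))
```

`rep$diversity` (excerpt): per-site sample size and diversity, then the
across-population mean ± SE —

```
 group population   n   A   A_R   H_O  uH_E  A_se A_R_se
 north     site01  20 1.5 1.215 0.110 0.116    NA     NA
 ...
 2 groups    mean 160 2.1 1.497 0.255 0.250 0.112  0.058
```

`rep$amova` — the two halves of the chain diverge (F_CT = 0.22) and
populations within halves differ too (F_SC = 0.26), both supported by
permutation:

```
                       component  df      SS variance percent p_value
                    Among groups   1  96.416  0.48559   22.34   0.029
 Among populations within groups   6 112.325  0.43674   20.09   0.001
              Within populations 312 390.425  1.25136   57.57   0.001
F_CT = 0.2234, F_SC = 0.2587, F_ST = 0.4243 (999 permutations)
```

`rep$ibd_euclidean` — the weighted Euclidean-distance model beats the
intercept-only model by 21 AICc units; the permuted-predictor p-value and
the model-averaged slope agree that differentiation increases with
distance (β ≈ 2.3e-6 per meter of separation):

```
            model k    AICc delta weight perm_p
 (intercept only) 2 -108.09 21.25      0     NA
        euclidean 3 -129.34  0.00      1  0.001
 predictor total_weight         beta  adjusted_se      z p_value perm_p_full
 euclidean            1 2.340288e-06 3.968529e-07 5.8971       0       0.002
best-model residual normality: W = 0.951, p = 0.215
```

Every number above is reproducible: all randomness flows from the
`seed` arguments through per-stage derived streams, and re-running the
same configuration rewrites byte-identical reports.

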