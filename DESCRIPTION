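Package: popcompare
Title: Comparative Landscape Population Genetics for Codominant Microsatellite Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for comparative population-genetic analysis of
    multilocus codominant microsatellite genotypes sampled from georeferenced
    sites: per-population diversity statistics (allelic richness, rarefied
    allelic richness, observed and unbiased expected heterozygosity),
    Hardy-Weinberg exact tests by Markov chain Monte Carlo, sequential
    Bonferroni correction, pairwise F_ST with permutation significance,
    three-level hierarchical analysis of molecular variance (AMOVA) over
    geographic groups such as watersheds, landscape predictor construction
    (Euclidean distance, habitat cost rasters with least-cost dispersal
    distances, Bray-Curtis climate dissimilarity), and weighted multiple
    regression on distance matrices with AICc permutation significance and
    Akaike-weight model averaging. Includes a forward-time stepping-stone
    simulator of microsatellite evolution under stepwise mutation so the
    whole pipeline can be exercised and validated on synthetic data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
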