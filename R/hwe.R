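#' Hardy-Weinberg exact test by Markov chain Monte Carlo
#'
#' Estimates the exact-test p-value for one locus: the probability, under
#' the conditional distribution of genotype arrays given the observed allele
#' counts, of arrays no more probable than the observed one
#' (\eqn{P(\mathrm{array}) \propto 2^H / \prod_{i \le j} g_{ij}!}, with H the
#' heterozygote count). A Guo-Thompson switch chain walks the array space;
#' the p-value is the fraction of post-dememorization states at or below the
#' observed array's conditional probability, with a Monte Carlo standard
#' error from batch means.
#'
#' @param geno_counts square numeric matrix of genotype counts; entry
#'   `[i, j]` (either triangle) counts genotypes carrying alleles i and j.
#'   Row/column names are the allele labels.
#' @param dememorization burn-in steps (default 10000).
#' @param batches number of batches (default 1000).
#' @param iterations steps per batch (default 10000).
#' @param seed integer seed; the chain is reproducible given the seed.
#' @return list of class `hwe_result`: `p_value`, `mc_se`, `testable`,
#'   `n_alleles`, `n_individuals`, `chain_settings`.
#' @export
hwe_exact_test <- function(geno_counts, dememorization = 10000,
                           batches = 1000, iterations = 10000, seed = 1) {
  geno_counts <- as.matrix(geno_counts)
  k <- nrow(geno_counts)
  low <- geno_counts
  low[upper.tri(low)] <- low[upper.tri(low)] + t(geno_counts)[upper.tri(low)]
  low[upper.tri(low)] <- 0
  n <- sum(low)
  settings <- list(dememorization = dememorization, batches = batches,
                   iterations = iterations)
  # alleles actually present
  present <- rowSums(low) + colSums(low) > 0
  if (sum(present) < 2L || n < 3) {
    return(structure(list(p_value = NA_real_, mc_se = NA_real_,
                          testable = FALSE, n_alleles = sum(present),
                          n_individuals = n, chain_settings = settings),
                     class = "hwe_result"))
  }
  res <- with_seed(seed, hwe_chain_cpp(low_int(low), as.integer(dememorization),
                                       as.integer(batches), as.integer(iterations)))
  structure(list(p_value = res$p_value, mc_se = res$mc_se, testable = TRUE,
                 n_alleles = sum(present), n_individuals = n,
                 chain_settings = settings),
            class = "hwe_result")
}

low_int <- function(m) { storage.mode(m) <- "integer"; m }

#' @export
print.hwe_result <- function(x, ...) {
  if (!x$testable) cat("HWE exact test: not testable (monomorphic or n < 3)\n")
  else cat(sprintf("HWE exact test: p = %.4f (MC s.e. %.2g), %d alleles, n = %d\n",
                   x$p_value, x$mc_se, x$n_alleles, x$n_individuals))
  invisible(x)
}

#' Genotype count matrix for a locus
#'
#' Tabulates diploid genotype counts at one locus, in one population or the
#' pooled (island-wide) sample, over typed individuals only.
#'
#' @param ds a [genotype_dataset()].
#' @param locus locus name.
#' @param population site id or `NULL` for pooled.
#' @return square numeric matrix with allele labels; counts stored in the
#'   lower triangle (`[i, j]`, i >= j in allele sort order).
#' @export
genotype_count_matrix <- function(ds, locus, population = NULL) {
  gt <- locus_genotypes(ds, locus, population)
  alleles <- sort(unique(c(gt)))
  k <- length(alleles)
  m <- matrix(0L, k, k, dimnames = list(alleles, alleles))
  if (!nrow(gt)) return(m)
  i <- match(pmax(gt[, 1L], gt[, 2L]), alleles)
  j <- match(pmin(gt[, 1L], gt[, 2L]), alleles)
  for (r in seq_along(i)) m[i[r], j[r]] <- m[i[r], j[r]] + 1L
  m
}

#' Per-locus HWE testing across a dataset
#'
#' Runs the exact test at every locus, either on the pooled island-wide
#' sample (default, the scope at which a Wahlund-style heterozygote deficit
#' from pooling differentiated populations is detectable) or within each
#' population. Populations with fewer than 3 typed individuals at a locus
#' are excluded from testing (degenerate chain) but are never dropped from
#' other statistics. Monomorphic loci are reported as not testable and count
#' as conforming.
#'
#' @param ds a [genotype_dataset()].
#' @param scope `"island"` (pooled) or `"population"`.
#' @param dememorization,batches,iterations chain settings (defaults are the
#'   pipeline's standard 10000 / 1000 / 10000).
#' @param alpha level for the Holm-corrected flags (default 0.05).
#' @param seed integer seed; per-locus chains use derived sub-seeds.
#' @return data frame of class `hwe_table`: `locus`, `scope_unit`,
#'   `n`, `p_value`, `mc_se`, `testable`, `significant_raw`,
#'   `significant_holm` (Holm across all testable rows).
#' @export
hwe_test_all <- function(ds, scope = c("island", "population"),
                         dememorization = 10000, batches = 1000,
                         iterations = 10000, alpha = 0.05, seed = 1) {
  scope <- match.arg(scope)
  units <- if (scope == "island") list(NULL) else as.list(populations(ds))
  rows <- list()
  for (u in units) {
    for (loc in ds$loci) {
      m <- genotype_count_matrix(ds, loc, u)
      n <- sum(m)
      res <- if (n < 3) {
        list(p_value = NA_real_, mc_se = NA_real_, testable = FALSE)
      } else {
        hwe_exact_test(m, dememorization, batches, iterations,
                       seed = derive_seed(seed, paste0("hwe:", loc, ":", u %||% "island")))
      }
      rows[[length(rows) + 1L]] <-
        data.frame(locus = loc, scope_unit = u %||% "island", n = n,
                   p_value = res$p_value, mc_se = res$mc_se,
                   testable = res$testable, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$significant_raw <- !is.na(out$p_value) & out$p_value <= alpha
  out$significant_holm <- FALSE
  testable <- which(out$testable & !is.na(out$p_value))
  if (length(testable)) {
    out$significant_holm[testable] <-
      sequential_bonferroni(out$p_value[testable], alpha)
  }
  class(out) <- c("hwe_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
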