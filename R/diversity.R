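#' Allelic richness
#'
#' Number of distinct alleles observed at a locus (gene counts > 0).
#'
#' @param counts named integer vector of gene counts per allele, as from
#'   [allele_counts()].
#' @return integer count, or `NA` when no genes were typed.
#' @export
allelic_richness <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) return(NA_integer_)
  length(counts)
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a random subsample of `g` genes
#' drawn without replacement from the observed sample:
#' \deqn{A_R(g) = \sum_i \left[1 - \binom{N - N_i}{g} / \binom{N}{g}\right]}
#' with \eqn{N_i} the gene count of allele i and \eqn{N = \sum_i N_i}.
#' This removes the sample-size bias of the raw allele count; the pipeline
#' standardises to `g = 4` genes, the smallest sample size a two-individual
#' site provides.
#'
#' @param counts named integer vector of gene counts per allele.
#' @param g number of genes to rarefy to (default 4).
#' @return expected allele count; `NA` with a warning when `g` exceeds the
#'   typed gene count (the population is skipped, never zero-filled).
#' @export
rarefied_allelic_richness <- function(counts, g = 4) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (!length(counts) || N < 2) return(NA_real_)
  if (g < 2) stop("rarefaction size g must be >= 2")
  if (g > N) {
    warning(sprintf("rarefaction to %d genes impossible with %d typed genes; skipped", g, N))
    return(NA_real_)
  }
  # P(allele i absent from the subsample) = prod_{j=0}^{g-1} (N - N_i - j)/(N - j),
  # computed as a running product (exact in doubles at these sizes).
  p_absent <- vapply(counts, function(ni) {
    if (N - ni < g) return(0)
    j <- 0:(g - 1)
    prod((N - ni - j) / (N - j))
  }, numeric(1))
  sum(1 - p_absent)
}

#' Observed heterozygosity
#'
#' Fraction of typed individuals whose two alleles differ, at one locus in
#' one population (or the pooled sample).
#'
#' @param ds a [genotype_dataset()].
#' @param locus locus name.
#' @param population site id or `NULL` for the pooled sample.
#' @return proportion in `[0, 1]`, or `NA` if no individual is typed.
#' @export
observed_heterozygosity <- function(ds, locus, population = NULL) {
  gt <- locus_genotypes(ds, locus, population)
  if (!nrow(gt)) return(NA_real_)
  mean(gt[, 1L] != gt[, 2L])
}

#' Unbiased expected heterozygosity (Nei's gene diversity)
#'
#' \deqn{uH_E = \frac{2n}{2n - 1}\left(1 - \sum_i p_i^2\right)}
#' with allele frequencies \eqn{p_i = N_i / 2n} over \eqn{2n} typed genes.
#' The small-sample correction factor compensates for the downward bias of
#' the plug-in gene diversity at the small and unequal sample sizes typical
#' of field collections.
#'
#' @param counts named integer vector of gene counts per allele.
#' @return proportion, or `NA` if fewer than 2 genes are typed.
#' @export
unbiased_expected_heterozygosity <- function(counts) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (N < 2) return(NA_real_)
  p <- counts / N
  (N / (N - 1)) * (1 - sum(p^2))
}

#' Sequential Bonferroni (Holm) significance flags
#'
#' Holm's step-down procedure: sort the m p-values ascending and reject
#' while \eqn{p_{(i)} \le \alpha / (m - i + 1)}, stopping at the first
#' failure. Flags are returned in the input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param alpha family-wise error level (default 0.05).
#' @return logical vector of rejection flags, input order.
#' @export
sequential_bonferroni <- function(p_values, alpha = 0.05) {
  if (!length(p_values)) return(logical(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "holm") <= alpha
}

#' Per-population diversity table
#'
#' For each population: number of individuals, mean across loci of the
#' distinct-allele count (A), of rarefied allelic richness at `g` genes
#' (A_R), of observed heterozygosity (H_O), and of unbiased expected
#' heterozygosity (uH_E). Loci where a statistic is undefined for a
#' population (e.g. fewer than `g` typed genes) are excluded from that
#' population's mean. A final aggregate row gives the across-population
#' mean +/- standard error of each statistic.
#'
#' @param ds a [genotype_dataset()].
#' @param g rarefaction size in genes (default 4).
#' @param label optional cohort label (e.g. species code) stored in the
#'   `label` column.
#' @return data frame of class `diversity_table` with columns `group`,
#'   `population`, `label`, `n`, `A`, `A_R`, `H_O`, `uH_E`; the aggregate
#'   row has population `"mean"` and columns `*_se` filled.
#' @export
diversity_table <- function(ds, g = 4, label = NA_character_) {
  pops <- populations(ds)
  grp <- site_groups(ds, required = FALSE)
  per_pop <- lapply(pops, function(p) {
    stats_by_locus <- vapply(ds$loci, function(loc) {
      cnt <- allele_counts(ds, loc, p)
      c(A = as.numeric(allelic_richness(cnt)),
        A_R = suppressWarnings(rarefied_allelic_richness(cnt, g)),
        H_O = observed_heterozygosity(ds, loc, p),
        uH_E = unbiased_expected_heterozygosity(cnt))
    }, numeric(4))
    data.frame(group = if (is.null(grp)) NA_character_ else grp[[p]],
               population = p, label = label,
               n = sum(ds$pop == p),
               A = mean(stats_by_locus["A", ], na.rm = TRUE),
               A_R = mean(stats_by_locus["A_R", ], na.rm = TRUE),
               H_O = mean(stats_by_locus["H_O", ], na.rm = TRUE),
               uH_E = mean(stats_by_locus["uH_E", ], na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, per_pop)
  se <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2) return(NA_real_)
    stats::sd(x) / sqrt(length(x))
  }
  agg <- data.frame(group = sprintf("%d groups", length(unique(stats::na.omit(tab$group)))),
                    population = "mean", label = label, n = sum(tab$n),
                    A = mean(tab$A, na.rm = TRUE), A_R = mean(tab$A_R, na.rm = TRUE),
                    H_O = mean(tab$H_O, na.rm = TRUE), uH_E = mean(tab$uH_E, na.rm = TRUE),
                    stringsAsFactors = FALSE)
  agg$A_se <- se(tab$A); agg$A_R_se <- se(tab$A_R)
  agg$H_O_se <- se(tab$H_O); agg$uH_E_se <- se(tab$uH_E)
  tab$A_se <- NA_real_; tab$A_R_se <- NA_real_
  tab$H_O_se <- NA_real_; tab$uH_E_se <- NA_real_
  out <- rbind(tab, agg)
  rownames(out) <- NULL
  class(out) <- c("diversity_table", "data.frame")
  out
}

#' @export
print.diversity_table <- function(x, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits = 3)
  print(y, row.names = FALSE, ...)
  invisible(x)
}

# group (watershed) label per site; list keyed by site id
site_groups <- function(ds, required = TRUE) {
  grp <- ds$sites$group
  if (is.null(grp)) {
    if (required) stop("hierarchical analysis requested but site metadata has no `group` column")
    return(NULL)
  }
  if (required && anyNA(grp)) {
    stop("hierarchical analysis requested but sites lack a group label: ",
         paste(ds$sites$id[is.na(grp)], collapse = ", "))
  }
  as.list(stats::setNames(grp, ds$sites$id))
}
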