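#' Construct a multilocus diploid genotype dataset
#'
#' The universal container for the pipeline: individuals typed at a shared
#' panel of codominant loci (microsatellites), each belonging to a population
#' site with planar (UTM) coordinates, an optional hierarchical group label
#' (e.g. watershed), and optional site-level climate scalars.
#'
#' Allele identity is the integer code as read from file (fragment length or
#' repeat count); alleles are never binned or recoded. A genotype is missing
#' only as a whole pair; half-missing calls are rejected. Missingness is
#' per locus per individual: individuals are never dropped globally, each
#' per-locus statistic excludes only the individuals untyped at that locus.
#'
#' @param loci character vector of locus names (ordered).
#' @param ind_id character vector of individual identifiers.
#' @param pop character vector, same length as `ind_id`: population (site) id
#'   of each individual.
#' @param alleles integer array `length(ind_id) x 2 x length(loci)`; `NA` for
#'   missing calls. Within an individual/locus the pair is unordered.
#' @param sites data frame of site metadata with at least a column `id`;
#'   typically also `easting`, `northing` (meters, one UTM zone), `group`
#'   (e.g. watershed) and climate columns. Site order here fixes population
#'   order in every downstream matrix. If `NULL`, sites are synthesised from
#'   the distinct values of `pop` in order of first appearance.
#'
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(loci, ind_id, pop, alleles, sites = NULL) {
  loci <- as.character(loci)
  ind_id <- as.character(ind_id)
  pop <- as.character(pop)
  n <- length(ind_id)
  if (length(pop) != n) stop("`pop` must match `ind_id` in length")
  if (length(dim(alleles)) != 3L ||
      dim(alleles)[1] != n || dim(alleles)[2] != 2L ||
      dim(alleles)[3] != length(loci)) {
    stop("`alleles` must be an n x 2 x n_loci array")
  }
  storage.mode(alleles) <- "integer"
  if (any(alleles <= 0L, na.rm = TRUE)) {
    stop("allele values must be positive integers (missing encoded as NA)")
  }
  half <- xor(is.na(alleles[, 1L, , drop = FALSE]), is.na(alleles[, 2L, , drop = FALSE]))
  if (any(half)) {
    bad <- which(half, arr.ind = TRUE)[1L, ]
    stop(sprintf("half-missing genotype: individual '%s', locus '%s'",
                 ind_id[bad[1L]], loci[bad[3L]]))
  }
  if (is.null(sites)) {
    sites <- data.frame(id = unique(pop), stringsAsFactors = FALSE)
  }
  if (!is.data.frame(sites) || is.null(sites$id)) {
    stop("`sites` must be a data frame with an `id` column")
  }
  sites$id <- as.character(sites$id)
  if (anyDuplicated(sites$id)) stop("duplicate site id in metadata")
  unknown <- setdiff(pop, sites$id)
  if (length(unknown)) {
    stop("individuals assigned to sites absent from metadata: ",
         paste(unknown, collapse = ", "))
  }
  keep <- sites$id %in% pop
  if (any(!keep)) sites <- sites[keep, , drop = FALSE]
  rownames(sites) <- NULL
  dimnames(alleles) <- list(ind_id, NULL, loci)
  structure(
    list(loci = loci, ind_id = ind_id,
         pop = factor(pop, levels = sites$id),
         alleles = alleles, sites = sites),
    class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d individuals, %d loci, %d populations\n",
              length(x$ind_id), length(x$loci), nlevels(x$pop)))
  n_by_pop <- table(x$pop)
  cat("  individuals per population:",
      paste(sprintf("%s=%d", names(n_by_pop), n_by_pop), collapse = ", "), "\n")
  miss <- mean(is.na(x$alleles[, 1L, ]))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Population names of a dataset
#' @param ds a `genotype_dataset`.
#' @return character vector of site ids in metadata (matrix) order.
#' @export
populations <- function(ds) levels(ds$pop)

#' Number of typed individuals per population at a locus
#' @param ds a `genotype_dataset`.
#' @param locus locus name.
#' @return named integer vector over populations.
#' @export
typed_counts <- function(ds, locus) {
  li <- match_locus(ds, locus)
  typed <- !is.na(ds$alleles[, 1L, li])
  tab <- table(ds$pop[typed])
  out <- integer(nlevels(ds$pop))
  names(out) <- levels(ds$pop)
  out[names(tab)] <- as.integer(tab)
  out
}

match_locus <- function(ds, locus) {
  li <- match(locus, ds$loci)
  if (is.na(li)) stop("unknown locus: ", locus)
  li
}

#' Allele counts (genes) at a locus
#'
#' Counts each allele's genes over non-missing calls only, so the total is
#' twice the number of typed individuals. This is the shared kernel behind
#' all frequency-based statistics.
#'
#' @param ds a `genotype_dataset`.
#' @param locus locus name.
#' @param population a site id, or `NULL` for the pooled (island-wide) sample.
#' @return named integer vector, names = allele values, values = gene counts.
#' @export
allele_counts <- function(ds, locus, population = NULL) {
  li <- match_locus(ds, locus)
  a <- ds$alleles[, , li, drop = FALSE]
  dim(a) <- dim(a)[1:2]
  if (!is.null(population)) {
    if (!population %in% levels(ds$pop)) stop("unknown population: ", population)
    a <- a[ds$pop == population, , drop = FALSE]
  }
  v <- c(a)
  v <- v[!is.na(v)]
  if (!length(v)) return(structure(integer(0), names = character(0)))
  tab <- table(v)
  structure(as.integer(tab), names = names(tab))
}

#' Extract one population's genotypes at one locus
#' @keywords internal
locus_genotypes <- function(ds, locus, population = NULL) {
  li <- match_locus(ds, locus)
  a <- ds$alleles[, , li, drop = FALSE]
  dim(a) <- dim(a)[1:2]
  if (!is.null(population)) a <- a[ds$pop == population, , drop = FALSE]
  a[!is.na(a[, 1L]), , drop = FALSE]
}

#' Restrict a dataset to a subset of populations
#' @param ds a `genotype_dataset`.
#' @param pops character vector of site ids to keep.
#' @return a `genotype_dataset` over the subset (site order preserved).
#' @export
subset_populations <- function(ds, pops) {
  if (!all(pops %in% levels(ds$pop))) {
    stop("unknown population(s): ",
         paste(setdiff(pops, levels(ds$pop)), collapse = ", "))
  }
  keep <- ds$pop %in% pops
  genotype_dataset(ds$loci, ds$ind_id[keep], as.character(ds$pop[keep]),
                   ds$alleles[keep, , , drop = FALSE],
                   ds$sites[ds$sites$id %in% pops, , drop = FALSE])
}
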