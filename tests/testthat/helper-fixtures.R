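# small dataset builders used across tests

# build a dataset from a list of populations, each a list of individuals,
# each individual a list of length-2 allele vectors (NA pair = missing)
make_ds <- function(pops, loci = NULL, sites = NULL) {
  L <- length(pops[[1]][[1]])
  if (is.null(loci)) loci <- paste0("L", seq_len(L))
  ind_id <- character(0); pop <- character(0)
  rows <- list()
  for (pn in names(pops)) {
    for (i in seq_along(pops[[pn]])) {
      ind_id <- c(ind_id, sprintf("%s_%d", pn, i))
      pop <- c(pop, pn)
      rows[[length(rows) + 1L]] <- pops[[pn]][[i]]
    }
  }
  alleles <- array(NA_integer_, dim = c(length(rows), 2L, L))
  for (r in seq_along(rows)) {
    for (l in seq_len(L)) alleles[r, , l] <- as.integer(rows[[r]][[l]])
  }
  genotype_dataset(loci, ind_id, pop, alleles, sites)
}

# sites on a line with groups and climate, for landscape/pipeline tests
line_sites <- function(ids, spacing = 10000, groups = NULL,
                       precipitation = NULL) {
  k <- length(ids)
  data.frame(id = ids,
             easting = 300000 + (seq_len(k) - 1) * spacing,
             northing = rep(7500000, k),
             group = groups %||% rep(c("g1", "g2"), length.out = k),
             precipitation = precipitation %||% seq(400, 400 + 50 * (k - 1), length.out = k),
             isothermality = seq(50, 40, length.out = k),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
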