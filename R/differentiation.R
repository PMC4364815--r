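# Variance-component differentiation statistics on allele identity.
#
# Both pairwise F_ST and the hierarchical AMOVA work at the gene level with
# the 0/1 allele-mismatch distance: sums of squared deviations reduce to
# counting mismatching gene pairs, so for a pool with allele gene counts c_k
# (total n) the within-pool sum of squares is
#   SSD = [ C(n,2) - sum_k C(c_k,2) ] / n.
# Variance components follow the standard moment equations with
# unequal-sample-size coefficients; multi-locus statistics sum the
# components over loci before forming ratios. Individuals untyped at a
# locus contribute nothing to that locus (listwise within locus).

# ratio with the 0/0 -> 0 convention (no variance at either level)
safe_ratio <- function(num, den) {
  if (abs(den) < 1e-300) { if (abs(num) < 1e-300) 0 else NA_real_ } else num / den
}

ssd_pool <- function(counts) {
  n <- sum(counts)
  if (n < 2) return(0)
  (n * (n - 1) / 2 - sum(counts * (counts - 1) / 2)) / n
}

# per-locus gene-count matrix (pops x alleles) from an individual-level
# allele-index matrix; pop_of_ind is an integer vector in 1..P
pop_allele_counts <- function(pair_idx, pop_of_ind, P, k) {
  gene_pop <- rep(pop_of_ind, 2L)
  gene_allele <- c(pair_idx[, 1L], pair_idx[, 2L])
  keep <- !is.na(gene_allele)
  m <- tabulate((gene_allele[keep] - 1L) * P + gene_pop[keep], nbins = P * k)
  matrix(m, nrow = P, ncol = k)
}

# locus-wise allele-index encoding used by the permutation machinery
locus_index_list <- function(ds) {
  lapply(seq_along(ds$loci), function(li) {
    a <- ds$alleles[, , li, drop = FALSE]
    dim(a) <- dim(a)[1:2]
    alleles <- sort(unique(c(a[!is.na(a)])))
    list(idx = matrix(match(a, alleles), ncol = 2L), k = max(1L, length(alleles)))
  })
}

# two-level variance components (among / within populations) for one locus
fst_components_locus <- function(M) {
  n_p <- rowSums(M)
  keep <- n_p > 0
  M <- M[keep, , drop = FALSE]
  n_p <- n_p[keep]
  P <- nrow(M)
  n <- sum(n_p)
  if (P < 2 || n - P < 1) return(c(sig_a = 0, sig_w = 0))
  ssd_wp <- sum(apply(M, 1L, ssd_pool))
  ssd_t <- ssd_pool(colSums(M))
  sig_w <- ssd_wp / (n - P)
  nc <- (n - sum(n_p^2) / n) / (P - 1)
  ms_a <- (ssd_t - ssd_wp) / (P - 1)
  c(sig_a = (ms_a - sig_w) / nc, sig_w = sig_w)
}

#' Pairwise F_ST between two populations
#'
#' Variance-component estimator in the AMOVA framework on allele identity:
#' per locus, the among- and within-population components are obtained from
#' the gene-level sums of squares with the unequal-sample-size coefficient,
#' components are summed over loci, and F_ST is the ratio of summed
#' among-population to summed total components. Slightly negative values
#' are reported as computed. Loci untyped in either population are excluded.
#'
#' @param ds a [genotype_dataset()].
#' @param pop_a,pop_b site ids.
#' @return F_ST estimate (may be negative); `NA` if no locus is typed in
#'   both populations.
#' @export
pairwise_fst <- function(ds, pop_a, pop_b) {
  sub <- subset_populations(ds, c(pop_a, pop_b))
  lidx <- locus_index_list(sub)
  pop_of_ind <- as.integer(sub$pop)
  fst_from_indices(lidx, pop_of_ind, 2L)
}

fst_from_indices <- function(lidx, pop_of_ind, P) {
  comp <- vapply(lidx, function(l) {
    M <- pop_allele_counts(l$idx, pop_of_ind, P, l$k)
    if (sum(rowSums(M) > 0) < 2) return(c(NA_real_, NA_real_))
    fst_components_locus(M)
  }, numeric(2))
  ok <- !is.na(comp[1L, ])
  if (!any(ok)) return(NA_real_)
  sig_a <- sum(comp[1L, ok]); sig_w <- sum(comp[2L, ok])
  tot <- sig_a + sig_w
  if (tot <= 0) return(0)
  sig_a / tot
}

#' Pairwise F_ST matrix with permutation p-values
#'
#' All unordered population pairs; significance per pair from shuffling
#' individuals between the two populations: p = (#\{F_perm >= F_obs\} + 1) /
#' (B + 1), one-sided.
#'
#' @param ds a [genotype_dataset()].
#' @param permutations number of permutations B per pair (default 100).
#' @param seed integer seed.
#' @return list with `fst` and `p_value`, both [pairwise_matrix()] objects
#'   (`p_value` diagonal is 0 by construction and not meaningful).
#' @export
fst_matrix <- function(ds, permutations = 100, seed = 1) {
  pops <- populations(ds)
  k <- length(pops)
  if (k < 2) stop("need at least 2 populations")
  fst <- matrix(0, k, k, dimnames = list(pops, pops))
  pmat <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      sub <- subset_populations(ds, c(pops[i], pops[j]))
      lidx <- locus_index_list(sub)
      pop_of_ind <- as.integer(sub$pop)
      obs <- fst_from_indices(lidx, pop_of_ind, 2L)
      fst[i, j] <- fst[j, i] <- obs
      if (is.na(obs)) { pmat[i, j] <- pmat[j, i] <- NA_real_; next }
      n_ind <- length(pop_of_ind)
      hits <- with_seed(derive_seed(seed, paste0("fst:", pops[i], ":", pops[j])), {
        sum(vapply(seq_len(permutations), function(b) {
          perm <- pop_of_ind[sample.int(n_ind)]
          f <- fst_from_indices(lidx, perm, 2L)
          !is.na(f) && f >= obs - 1e-12
        }, logical(1)))
      })
      pmat[i, j] <- pmat[j, i] <- (hits + 1) / (permutations + 1)
    }
  }
  list(fst = pairwise_matrix(fst), p_value = pairwise_matrix(pmat))
}

# three-level component engine: per-locus count matrices -> components
amova_components <- function(Mlist, group_of_pop) {
  g_levels <- unique(group_of_pop)
  acc <- c(ssd_a = 0, ssd_b = 0, ssd_c = 0, sig_a = 0, sig_b = 0, sig_c = 0)
  for (M in Mlist) {
    n_p <- rowSums(M)
    keep <- n_p > 0
    Mk <- M[keep, , drop = FALSE]
    grp <- group_of_pop[keep]
    n_p <- n_p[keep]
    P <- nrow(Mk); G <- length(unique(grp)); n <- sum(n_p)
    if (P < 2 || G < 2) next
    ssd_wp <- sum(apply(Mk, 1L, ssd_pool))
    ssd_wg <- sum(vapply(unique(grp), function(g)
      ssd_pool(colSums(Mk[grp == g, , drop = FALSE])), numeric(1)))
    ssd_t <- ssd_pool(colSums(Mk))
    ssd_ag <- ssd_t - ssd_wg
    ssd_ap <- ssd_wg - ssd_wp
    df_a <- G - 1; df_b <- P - G; df_c <- n - P
    if (df_c < 1) next
    N_g <- vapply(unique(grp), function(g) sum(n_p[grp == g]), numeric(1))
    Sg <- sum(vapply(unique(grp), function(g) {
      np <- n_p[grp == g]; sum(np^2) / sum(np)
    }, numeric(1)))
    sig_c <- ssd_wp / df_c
    if (df_b > 0) {
      n1 <- (n - Sg) / df_b
      sig_b <- (ssd_ap / df_b - sig_c) / n1
    } else sig_b <- 0
    n2 <- (Sg - sum(n_p^2) / n) / df_a
    n3 <- (n - sum(N_g^2) / n) / df_a
    sig_a <- (ssd_ag / df_a - sig_c - n2 * sig_b) / n3
    acc <- acc + c(ssd_ag, ssd_ap, ssd_wp, sig_a, sig_b, sig_c)
  }
  acc
}

#' Three-level hierarchical AMOVA
#'
#' Partitions allelic variance among groups (e.g. watersheds), among
#' populations within groups, and within populations, from the pairwise
#' allele-mismatch decomposition at the gene level. Fixation indices:
#' F_CT = sigma_a^2 / sigma_T^2, F_SC = sigma_b^2 / (sigma_b^2 + sigma_c^2),
#' F_ST = (sigma_a^2 + sigma_b^2) / sigma_T^2. Components are estimated per
#' locus with that locus's sample sizes and summed over loci; negative
#' components are reported as computed.
#'
#' Permutation schemes (one-sided, p = (b+1)/(B+1)): F_CT permutes whole
#' populations among groups; F_SC permutes individuals among populations
#' within groups; F_ST permutes individuals among populations across the
#' whole sample.
#'
#' @param ds a [genotype_dataset()].
#' @param grouping optional named character vector/list site id -> group;
#'   defaults to the `group` column of the site metadata.
#' @param permutations permutations per index (default 10000).
#' @param seed integer seed.
#' @return object of class `amova_result`: `table` (df, SS, variance
#'   component, percent variation per level), `indices` (F_CT, F_SC, F_ST),
#'   `p_values`.
#' @export
amova_three_level <- function(ds, grouping = NULL, permutations = 10000,
                              seed = 1) {
  pops <- populations(ds)
  if (is.null(grouping)) grouping <- site_groups(ds, required = TRUE)
  grouping <- unlist(grouping)
  if (!all(pops %in% names(grouping))) {
    stop("grouping lacks entries for: ",
         paste(setdiff(pops, names(grouping)), collapse = ", "))
  }
  group_of_pop <- as.character(grouping[pops])
  if (length(unique(group_of_pop)) < 2L) {
    stop("F_CT undefined: all populations fall in one group")
  }
  lidx <- locus_index_list(ds)
  pop_of_ind <- as.integer(ds$pop)
  P <- length(pops)
  Mlist <- lapply(lidx, function(l) pop_allele_counts(l$idx, pop_of_ind, P, l$k))
  obs <- amova_components(Mlist, group_of_pop)

  N <- length(ds$ind_id)
  G <- length(unique(group_of_pop))
  df <- c(G - 1L, P - G, 2L * N - P)
  sig <- obs[c("sig_a", "sig_b", "sig_c")]
  ss <- obs[c("ssd_a", "ssd_b", "ssd_c")]
  tot <- sum(sig)
  if (abs(tot) < 1e-300 || all(ss == 0)) {
    pct <- rep(NA_real_, 3)
    indices <- c(F_CT = NA_real_, F_SC = NA_real_, F_ST = NA_real_)
  } else {
    pct <- 100 * sig / tot
    indices <- c(F_CT = sig[[1L]] / tot,
                 F_SC = safe_ratio(sig[[2L]], sig[[2L]] + sig[[3L]]),
                 F_ST = (sig[[1L]] + sig[[2L]]) / tot)
  }

  p_values <- c(F_CT = NA_real_, F_SC = NA_real_, F_ST = NA_real_)
  if (permutations > 0 && !anyNA(indices)) {
    stat <- function(comp) {
      t2 <- sum(comp[4:6])
      c(ct = safe_ratio(comp[[4L]], t2),
        sc = safe_ratio(comp[[5L]], comp[[5L]] + comp[[6L]]),
        st = safe_ratio(comp[[4L]] + comp[[5L]], t2))
    }
    # F_CT: permute populations among groups
    hits_ct <- with_seed(derive_seed(seed, "amova:ct"), {
      sum(vapply(seq_len(permutations), function(b) {
        s <- stat(amova_components(Mlist, group_of_pop[sample.int(P)]))
        s[["ct"]] >= indices[[1L]] - 1e-12
      }, logical(1)))
    })
    # F_SC: permute individuals among populations within groups
    group_of_ind <- group_of_pop[pop_of_ind]
    hits_sc <- with_seed(derive_seed(seed, "amova:sc"), {
      sum(vapply(seq_len(permutations), function(b) {
        perm <- pop_of_ind
        for (g in unique(group_of_ind)) {
          w <- which(group_of_ind == g)
          perm[w] <- pop_of_ind[w][sample.int(length(w))]
        }
        Mp <- lapply(lidx, function(l) pop_allele_counts(l$idx, perm, P, l$k))
        s <- stat(amova_components(Mp, group_of_pop))
        s[["sc"]] >= indices[[2L]] - 1e-12
      }, logical(1)))
    })
    # F_ST: permute individuals across the whole sample
    hits_st <- with_seed(derive_seed(seed, "amova:st"), {
      sum(vapply(seq_len(permutations), function(b) {
        perm <- pop_of_ind[sample.int(N)]
        Mp <- lapply(lidx, function(l) pop_allele_counts(l$idx, perm, P, l$k))
        s <- stat(amova_components(Mp, group_of_pop))
        s[["st"]] >= indices[[3L]] - 1e-12
      }, logical(1)))
    })
    p_values <- c(F_CT = (hits_ct + 1) / (permutations + 1),
                  F_SC = (hits_sc + 1) / (permutations + 1),
                  F_ST = (hits_st + 1) / (permutations + 1))
  }

  tab <- data.frame(
    component = c("Among groups", "Among populations within groups",
                  "Within populations", "Total"),
    df = c(df, sum(df)),
    SS = c(unname(ss), sum(ss)),
    variance = c(unname(sig), tot),
    percent = c(unname(pct), if (anyNA(pct)) NA_real_ else 100),
    stringsAsFactors = FALSE)
  structure(list(table = tab, indices = indices, p_values = p_values,
                 permutations = permutations),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("Hierarchical AMOVA (allele identity)\n")
  tab <- x$table
  tab$SS <- round(tab$SS, 3); tab$variance <- round(tab$variance, 5)
  tab$percent <- round(tab$percent, 2)
  tab$p_value <- c(round(x$p_values, 4), NA)
  print(tab, row.names = FALSE)
  cat(sprintf("F_CT = %.4f, F_SC = %.4f, F_ST = %.4f (%d permutations)\n",
              x$indices[["F_CT"]], x$indices[["F_SC"]], x$indices[["F_ST"]],
              x$permutations))
  invisible(x)
}

#' Write an AMOVA report table
#' @param res an `amova_result`.
#' @param path output path (tab-separated, Table-style rows: component, df,
#'   SS, variance component, percent variation, p-value).
#' @return `path`, invisibly.
#' @export
write_amova_report <- function(res, path) {
  tab <- res$table
  tab$p_value <- c(res$p_values, NA)
  utils::write.table(format(tab, digits = 10, trim = TRUE), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
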