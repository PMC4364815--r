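# independent oracles: brute-force / enumeration implementations kept
# deliberately separate from the package's computational paths

# expected distinct alleles in a g-gene subsample, by full enumeration of
# all C(N, g) subsets
oracle_rarefaction <- function(counts, g) {
  genes <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(genes), g)
  mean(apply(subs, 2L, function(ix) length(unique(genes[ix]))))
}

# exact HWE p-value by enumeration of every genotype array with the
# observed allele counts; geno is a square count matrix (lower triangle)
oracle_hwe_enum <- function(geno) {
  k <- nrow(geno)
  low <- geno
  low[upper.tri(low)] <- low[upper.tri(low)] + t(geno)[upper.tri(geno)]
  low[upper.tri(low)] <- 0
  # allele gene counts: 2*g_ii + sum over heterozygote cells touching i
  a <- sapply(seq_len(k), function(i) {
    het <- 0
    for (j in seq_len(k)) if (j != i) het <- het + low[max(i, j), min(i, j)]
    2 * low[i, i] + het
  })
  n <- sum(low)
  cells <- which(lower.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  logp_array <- function(m) {
    h <- sum(m[cells[cells[, 1] != cells[, 2], , drop = FALSE]])
    lfactorial(n) + h * log(2) - sum(lfactorial(m[cells])) +
      sum(lfactorial(a)) - lfactorial(2 * n)
  }
  obs_logp <- logp_array(low)
  total <- 0
  hit <- 0
  rec <- function(ci, m, rem) {
    if (ci > nrow(cells)) {
      if (all(rem == 0)) {
        lp <- logp_array(m)
        total <<- total + exp(lp)
        if (lp <= obs_logp + 1e-9) hit <<- hit + exp(lp)
      }
      return(invisible())
    }
    i <- cells[ci, 1]; j <- cells[ci, 2]
    gmax <- if (i == j) rem[i] %/% 2 else min(rem[i], rem[j])
    for (g in 0:gmax) {
      m[i, j] <- g
      r2 <- rem
      if (i == j) r2[i] <- r2[i] - 2 * g
      else { r2[i] <- r2[i] - g; r2[j] <- r2[j] - g }
      rec(ci + 1L, m, r2)
    }
  }
  rec(1L, matrix(0, k, k), a)
  hit / total
}

# sum of squared deviations of a gene cluster from pairwise 0/1 mismatches
oracle_ssd <- function(gene_values) {
  n <- length(gene_values)
  if (n < 2) return(0)
  d <- outer(gene_values, gene_values, "!=") * 1
  sum(d[lower.tri(d)]) / n
}

# full AMOVA decomposition evaluated directly from gene vectors
oracle_amova <- function(ds, group_of_pop) {
  pops <- popcompare::populations(ds)
  acc <- c(ssd_a = 0, ssd_b = 0, ssd_c = 0, sig_a = 0, sig_b = 0, sig_c = 0)
  for (loc in ds$loci) {
    gv <- list()
    for (p in pops) {
      gt <- ds$alleles[ds$pop == p, , match(loc, ds$loci), drop = FALSE]
      v <- c(gt)
      gv[[p]] <- v[!is.na(v)]
    }
    n_p <- lengths(gv)
    keep <- n_p > 0
    gv <- gv[keep]; n_p <- n_p[keep]
    grp <- group_of_pop[pops][keep]
    P <- length(gv); G <- length(unique(grp)); n <- sum(n_p)
    if (P < 2 || G < 2 || n - P < 1) next
    ssd_wp <- sum(vapply(gv, oracle_ssd, numeric(1)))
    ssd_wg <- sum(vapply(unique(grp), function(g)
      oracle_ssd(unlist(gv[grp == g])), numeric(1)))
    ssd_t <- oracle_ssd(unlist(gv))
    df_a <- G - 1; df_b <- P - G; df_c <- n - P
    N_g <- vapply(unique(grp), function(g) sum(n_p[grp == g]), numeric(1))
    Sg <- sum(vapply(unique(grp), function(g) sum(n_p[grp == g]^2) / sum(n_p[grp == g]),
                     numeric(1)))
    sig_c <- ssd_wp / df_c
    sig_b <- if (df_b > 0) ((ssd_wg - ssd_wp) / df_b - sig_c) / ((n - Sg) / df_b) else 0
    n2c <- (Sg - sum(n_p^2) / n) / df_a
    n3c <- (n - sum(N_g^2) / n) / df_a
    sig_a <- ((ssd_t - ssd_wg) / df_a - sig_c - n2c * sig_b) / n3c
    acc <- acc + c(ssd_t - ssd_wg, ssd_wg - ssd_wp, ssd_wp, sig_a, sig_b, sig_c)
  }
  acc
}

# two-population theta from the same quadratic forms (independent of the
# package's count-based route)
oracle_fst_pair <- function(ds, pop_a, pop_b) {
  sig_a_sum <- 0; sig_w_sum <- 0
  for (loc in ds$loci) {
    ga <- c(ds$alleles[ds$pop == pop_a, , match(loc, ds$loci)])
    gb <- c(ds$alleles[ds$pop == pop_b, , match(loc, ds$loci)])
    ga <- ga[!is.na(ga)]; gb <- gb[!is.na(gb)]
    na <- length(ga); nb <- length(gb); n <- na + nb
    if (na == 0 || nb == 0) next
    ssd_wp <- oracle_ssd(ga) + oracle_ssd(gb)
    ssd_t <- oracle_ssd(c(ga, gb))
    sig_w <- ssd_wp / (n - 2)
    nc <- (n - (na^2 + nb^2) / n)
    sig_a <- ((ssd_t - ssd_wp) / 1 - sig_w) / nc
    sig_a_sum <- sig_a_sum + sig_a
    sig_w_sum <- sig_w_sum + sig_w
  }
  sig_a_sum / (sig_a_sum + sig_w_sum)
}

# least-cost distances by Bellman-Ford-style fixed-point relaxation over
# the 8-connected lattice (no priority queue; iterate to convergence)
oracle_least_cost <- function(raster, from_rc, to_rc) {
  g <- raster$grid
  nr <- nrow(g); nc <- ncol(g); res <- raster$resolution
  dist <- matrix(Inf, nr, nc)
  dist[from_rc[1], from_rc[2]] <- 0
  moves <- expand.grid(dr = -1:1, dc = -1:1)
  moves <- moves[!(moves$dr == 0 & moves$dc == 0), ]
  repeat {
    changed <- FALSE
    for (r in seq_len(nr)) for (cc in seq_len(nc)) {
      if (!is.finite(dist[r, cc])) next
      for (m in seq_len(nrow(moves))) {
        r2 <- r + moves$dr[m]; c2 <- cc + moves$dc[m]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (is.na(g[r2, c2]) || is.na(g[r, cc])) next
        step <- res * (g[r, cc] + g[r2, c2]) / 2 *
          (if (moves$dr[m] != 0 && moves$dc[m] != 0) sqrt(2) else 1)
        if (dist[r, cc] + step < dist[r2, c2] - 1e-12) {
          dist[r2, c2] <- dist[r, cc] + step
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  dist[to_rc[1], to_rc[2]]
}

# enumerate compositions of total gene count N over n_alleles alleles
# (each allele count >= 1), for rarefaction property sweeps
all_count_vectors <- function(N, n_alleles) {
  if (n_alleles == 1) return(list(N))
  out <- list()
  for (first in seq_len(N - n_alleles + 1)) {
    for (rest in all_count_vectors(N - first, n_alleles - 1)) {
      out[[length(out) + 1L]] <- c(first, rest)
    }
  }
  out
}
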