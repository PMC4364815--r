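test_that("complete fixation gives F_ST = 1 and cloned populations give ~0", {
  fixed <- make_ds(list(
    a = lapply(1:5, function(i) list(c(1, 1), c(3, 3))),
    b = lapply(1:5, function(i) list(c(2, 2), c(4, 4)))))
  expect_equal(pairwise_fst(fixed, "a", "b"), 1)
  # one population cloned into two labels: estimator noise around zero
  set.seed(21)
  g <- lapply(1:60, function(i) list(sample(1:4, 2, replace = TRUE),
                                     sample(1:3, 2, replace = TRUE)))
  clone <- make_ds(list(a = g[1:30], b = g[31:60]))
  f <- pairwise_fst(clone, "a", "b")
  expect_lt(abs(f), 0.05)
})

test_that("two-population theta matches the quadratic-form oracle", {
  # 2 pops x 4 individuals x 1 locus with gene counts {A:6,B:2} vs {A:2,B:6}
  ds <- make_ds(list(
    a = list(list(c(1, 1)), list(c(1, 1)), list(c(1, 1)), list(c(2, 2))),
    b = list(list(c(1, 1)), list(c(2, 2)), list(c(2, 2)), list(c(2, 2)))))
  expect_equal(pairwise_fst(ds, "a", "b"), oracle_fst_pair(ds, "a", "b"),
               tolerance = 1e-12)
  # multi-locus instance with missing data
  ds2 <- make_ds(list(
    a = list(list(c(1, 2), c(5, 5)), list(c(1, 1), c(NA, NA)),
             list(c(2, 2), c(5, 6))),
    b = list(list(c(2, 3), c(6, 6)), list(c(3, 3), c(6, 6)),
             list(c(NA, NA), c(5, 6)))))
  expect_equal(pairwise_fst(ds2, "a", "b"), oracle_fst_pair(ds2, "a", "b"),
               tolerance = 1e-12)
})

test_that("fst_matrix is symmetric, labelled, and its p-values behave", {
  fixed <- make_ds(list(
    a = lapply(1:3, function(i) list(c(1, 1), c(3, 3))),
    b = lapply(1:3, function(i) list(c(2, 2), c(4, 4)))))
  res <- fst_matrix(fixed, permutations = 100, seed = 1)
  expect_s3_class(res$fst, "pairwise_matrix")
  expect_equal(res$fst["a", "b"], res$fst["b", "a"])
  expect_equal(res$fst["a", "b"], 1)
  # fixed difference: only label-swap ties can reach the observed value;
  # permutations that mix the two fixed pools strictly lower F_ST, but the
  # all-or-nothing reassignments tie, so p stays near its minimum
  expect_lte(res$p_value["a", "b"], 0.15)
  # one panmictic pool split into two labels: p spread over its support
  set.seed(5)
  ps <- vapply(1:30, function(r) {
    g <- lapply(1:40, function(i) list(sample(1:3, 2, TRUE)))
    ds <- make_ds(list(a = g[1:20], b = g[21:40]))
    fst_matrix(ds, permutations = 49, seed = r)$p_value["a", "b"]
  }, numeric(1))
  expect_gt(median(ps), 0.2)
  expect_lt(median(ps), 0.8)
})

test_that("perfect group structure yields F_CT = 1 with zero within-group variance", {
  sites <- line_sites(c("a", "b", "c", "d"), groups = c("G1", "G1", "G2", "G2"))
  ds <- make_ds(list(
    a = lapply(1:4, function(i) list(c(1, 1))),
    b = lapply(1:4, function(i) list(c(1, 1))),
    c = lapply(1:4, function(i) list(c(2, 2))),
    d = lapply(1:4, function(i) list(c(2, 2)))), sites = sites)
  res <- amova_three_level(ds, permutations = 0)
  expect_equal(unname(res$indices["F_CT"]), 1)
  expect_equal(unname(res$indices["F_SC"]), 0)
  expect_equal(res$table$variance[3], 0)  # within populations
})

test_that("an invariant dataset yields zero SS and undefined indices", {
  sites <- line_sites(c("a", "b"), groups = c("G1", "G2"))
  ds <- make_ds(list(
    a = lapply(1:3, function(i) list(c(1, 1))),
    b = lapply(1:3, function(i) list(c(1, 1)))), sites = sites)
  res <- amova_three_level(ds, permutations = 0)
  expect_equal(sum(res$table$SS[1:3]), 0)
  expect_true(all(is.na(res$indices)))
})

test_that("AMOVA matches the direct quadratic-form oracle on small fixtures", {
  set.seed(77)
  # 3 groups x 2 pops x 4 diploid individuals x 2 loci, fixed genotypes
  pops <- list()
  for (p in 1:6) {
    pops[[paste0("p", p)]] <- lapply(1:4, function(i)
      list(sample(1:3, 2, TRUE), sample(4:6, 2, TRUE)))
  }
  grp <- setNames(rep(c("g1", "g2", "g3"), each = 2), names(pops))
  sites <- line_sites(names(pops), groups = grp[names(pops)])
  ds <- make_ds(pops, sites = sites)
  res <- amova_three_level(ds, permutations = 0)
  orc <- oracle_amova(ds, grp)
  expect_equal(res$table$SS[1:3], unname(orc[c("ssd_a", "ssd_b", "ssd_c")]),
               tolerance = 1e-10)
  expect_equal(res$table$variance[1:3],
               unname(orc[c("sig_a", "sig_b", "sig_c")]), tolerance = 1e-10)
  # conservation: percent sums to 100, df to 2N - 1
  expect_equal(sum(res$table$percent[1:3]), 100, tolerance = 1e-9)
  expect_equal(sum(res$table$df[1:3]), 2L * length(ds$ind_id) - 1L)
  # unbalanced variant with missing genotypes
  pops$p1 <- pops$p1[1:2]
  pops$p3[[1]][[2]] <- c(NA, NA)
  ds2 <- make_ds(pops, sites = sites)
  res2 <- amova_three_level(ds2, permutations = 0)
  orc2 <- oracle_amova(ds2, grp)
  expect_equal(res2$table$variance[1:3],
               unname(orc2[c("sig_a", "sig_b", "sig_c")]), tolerance = 1e-10)
})

test_that("with singleton groups AMOVA F_ST equals the global theta", {
  set.seed(8)
  pops <- list()
  for (p in 1:4) {
    pops[[paste0("p", p)]] <- lapply(1:5, function(i)
      list(sample(p:(p + 2), 2, TRUE)))
  }
  grp <- setNames(paste0("G", 1:4), names(pops))  # every pop its own group
  sites <- line_sites(names(pops), groups = grp[names(pops)])
  ds <- make_ds(pops, sites = sites)
  res <- amova_three_level(ds, permutations = 0)
  # global two-level theta from the same engine with a single grouping level
  lidx <- popcompare:::locus_index_list(ds)
  global <- popcompare:::fst_from_indices(lidx, as.integer(ds$pop), 4L)
  expect_equal(unname(res$indices["F_ST"]), global, tolerance = 1e-10)
  expect_equal(res$table$variance[2], 0)  # F_SC collapses
})

test_that("grouping with a single group is rejected", {
  sites <- line_sites(c("a", "b"), groups = c("G1", "G1"))
  ds <- make_ds(list(a = list(list(c(1, 2))), b = list(list(c(2, 2)))),
                sites = sites)
  expect_error(amova_three_level(ds, permutations = 0), "one group")
})
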