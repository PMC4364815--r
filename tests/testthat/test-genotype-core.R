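test_that("minimal Genepop files parse with correct alleles and pop sizes", {
  f <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("two pops, one locus", "L1", "POP",
               "a1 , 0101", "a2 , 0102", "POP",
               "b1 , 0202", "b2 , 0202"), f)
  ds <- read_genepop(f)
  expect_equal(ds$loci, "L1")
  expect_equal(as.integer(table(ds$pop)), c(2L, 2L))
  expect_equal(sort(unique(c(ds$alleles))), c(1L, 2L))
  expect_equal(unname(allele_counts(ds, "L1", "pop1")), c(3L, 1L))
})

test_that("Genepop parse errors name the offending token", {
  f <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("t", "L1", "POP", "a1 , 010"), f)
  expect_error(read_genepop(f), "010")
  writeLines(c("t", "L1", "POP", "a1 , 0100"), f)
  expect_error(read_genepop(f), "half-missing")
  writeLines(c("t", "L1", "L2", "POP", "a1 , 0101"), f)
  expect_error(read_genepop(f), "expected 2")
})

test_that("000000 tokens become missing genotypes excluded from counts", {
  f <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("t", "L1", "POP",
               "a1 , 000000", "a2 , 101102"), f)
  ds <- read_genepop(f)
  expect_true(is.na(ds$alleles[1, 1, 1]))
  cnt <- allele_counts(ds, "L1", "pop1")
  expect_equal(sum(cnt), 2L)  # only the typed individual contributes
})

test_that("Genepop write/read round-trips datasets exactly", {
  set.seed(11)
  for (maxa in c(9L, 150L)) {  # exercise 2- and 3-digit encodings
    pops <- list(
      pop1 = list(list(c(1, 2), c(maxa, 1)), list(c(NA, NA), c(2, 2))),
      pop2 = list(list(c(3, 3), c(1, maxa))))
    ds <- make_ds(pops)
    f <- withr::local_tempfile(fileext = ".gen")
    write_genepop(ds, f)
    ds2 <- read_genepop(f)
    expect_equal(ds2$alleles, ds$alleles, ignore_attr = TRUE)
    expect_equal(as.character(ds2$pop), sub("pop", "pop", as.character(ds$pop)))
    expect_equal(ds2$loci, ds$loci)
    # second round trip is the identity
    f2 <- withr::local_tempfile(fileext = ".gen")
    write_genepop(ds2, f2)
    ds3 <- read_genepop(f2)
    expect_identical(ds3$alleles, ds2$alleles)
  }
})

test_that("STRUCTURE layouts parse and agree with Genepop on the same cohort", {
  # one-row layout, with missing pair
  f <- withr::local_tempfile()
  writeLines(c("i1 p1 1 2 5 5", "i2 p1 -9 -9 5 6", "i3 p2 2 2 6 6"), f)
  ds <- read_structure_table(f, one_row_per_individual = TRUE)
  expect_equal(length(ds$loci), 2L)
  expect_true(is.na(ds$alleles[2, 1, 1]))
  # two-row layout, one individual, two loci
  f2 <- withr::local_tempfile()
  writeLines(c("i1 p1 1 5", "i1 p1 2 5"), f2)
  ds2 <- read_structure_table(f2, one_row_per_individual = FALSE)
  expect_equal(dim(ds2$alleles), c(1L, 2L, 2L))
  expect_equal(sort(ds2$alleles[1, , 1]), c(1L, 2L))
  # same cohort via both formats parses to equal genotypes
  g <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("t", "L1", "L2", "POP",
               "i1 , 0102 0505", "i2 , 0000 0506", "POP", "i3 , 0202 0606"), g)
  dg <- read_genepop(g)
  expect_equal(dg$alleles, ds$alleles, ignore_attr = TRUE)
  expect_equal(as.integer(dg$pop), as.integer(ds$pop))
})

test_that("STRUCTURE parse contract: ragged rows and absent pop column", {
  f <- withr::local_tempfile()
  writeLines(c("i1 p1 1 2", "i2 p1 1"), f)
  expect_error(read_structure_table(f), "ragged")
  f2 <- withr::local_tempfile()
  writeLines(c("i1 1 2", "i2 2 2"), f2)
  expect_error(read_structure_table(f2, pop_col = NULL), "site_map")
  ds <- read_structure_table(f2, pop_col = NULL,
                             site_map = c(i1 = "p1", i2 = "p2"))
  expect_equal(populations(ds), c("p1", "p2"))
})

test_that("site metadata reads printed coordinates and rejects bad rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,easting,northing,group,precipitation",
               "Namakia,585313,8242761,Melaky,900",
               "Andavadoaka,320670,7555488,Mikea,500"), f)
  sites <- read_site_metadata(f)
  expect_equal(sites$easting[sites$id == "Namakia"], 585313)
  expect_equal(sites$group[sites$id == "Andavadoaka"], "Mikea")
  writeLines(c("id,easting,northing", "A,1,2", "A,3,4"), f)
  expect_error(read_site_metadata(f), "duplicate")
  writeLines(c("id,easting,northing", "A,abc,2"), f)
  expect_error(read_site_metadata(f), "non-numeric")
})

test_that("empty group labels block hierarchical analysis", {
  sites <- line_sites(c("A", "B", "C", "D"))
  sites$group[2] <- NA
  ds <- make_ds(list(A = list(list(c(1, 2))), B = list(list(c(1, 1))),
                     C = list(list(c(2, 2))), D = list(list(c(1, 2)))),
                sites = sites)
  expect_error(amova_three_level(ds, permutations = 0), "group")
})

test_that("allele_counts totals are even and pooled counts are additive", {
  ds <- make_ds(list(
    p1 = list(list(c(1, 1), c(2, 3)), list(c(1, 2), c(NA, NA))),
    p2 = list(list(c(2, 2), c(3, 3)))))
  for (loc in ds$loci) {
    per_pop <- lapply(populations(ds), function(p) allele_counts(ds, loc, p))
    tot <- allele_counts(ds, loc)
    expect_true(all(sum(tot) %% 2 == 0))
    pooled <- Reduce(function(a, b) {
      keys <- union(names(a), names(b))
      out <- setNames(integer(length(keys)), keys)
      out[names(a)] <- a; out[names(b)] <- out[names(b)] + b
      out
    }, per_pop)
    expect_equal(tot[sort(names(tot))], pooled[sort(names(pooled))])
    n_typed <- sum(typed_counts(ds, loc))
    expect_equal(sum(tot), 2L * n_typed)
  }
  expect_error(allele_counts(ds, "nope"), "unknown locus")
  expect_error(allele_counts(ds, "L1", "nope"), "unknown population")
})

test_that("half-missing genotypes are rejected at construction", {
  alleles <- array(c(1L, NA, 2L, 2L), dim = c(1, 2, 2))
  expect_error(genotype_dataset("L1", "i1", "p1",
                                array(c(1L, NA), dim = c(1, 2, 1))),
               "half-missing")
})
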