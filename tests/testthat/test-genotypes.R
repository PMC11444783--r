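test_that("CSV round-trip preserves genotypes, groups and missingness", {
  gm <- gm_from_rows(list(c(1, 2, NA, NA), c(3, 3, 1, 4)),
                     ids = c("a", "b"), groups = c("G1", "G2"))
  path <- tempfile(fileext = ".csv")
  write_genotypes(gm, path)
  back <- read_genotypes(path, "csv")
  expect_identical(back$a1, gm$a1)
  expect_identical(back$a2, gm$a2)
  expect_identical(unname(back$groups), unname(gm$groups))
})

test_that("GenePop reader handles 2-digit codes, missing, Pop blocks", {
  path <- tempfile(fileext = ".gen")
  writeLines(c("toy file", "locA", "locB", "Pop",
               "ind1 , 0101 0000", "ind2 , 0102 0304",
               "Pop", "ind3 , 0202 0103"), path)
  gm <- read_genotypes(path, "genepop")
  expect_equal(dim(gm), c(3L, 2L))
  expect_equal(unname(gm$a1["ind1", ]), c(1L, NA))
  expect_equal(unname(gm$a2["ind1", ]), c(1L, NA))
  expect_equal(unname(c(gm$a1["ind2", 2], gm$a2["ind2", 2])), c(3L, 4L))
  expect_equal(unname(gm$groups), c("pop1", "pop1", "pop2"))
  # 3-digit dialect round-trips through the writer
  out <- tempfile(fileext = ".gen")
  write_genepop(gm, out)
  gm2 <- read_genotypes(out, "genepop")
  expect_identical(gm2$a1, gm$a1)
  expect_identical(gm2$a2, gm$a2)
})

test_that("parser errors carry location information", {
  path <- tempfile(fileext = ".gen")
  writeLines(c("t", "locA", "locB", "Pop", "ind1 , 0101"), path)
  expect_error(read_genotypes(path, "genepop"), "line 5")
  df <- data.frame(individual_id = c("a", "a"), locus = c("L1", "L1"),
                   allele1 = c(1, 2), allele2 = c(1, 2))
  p2 <- tempfile(fileext = ".csv")
  write.csv(df, p2, row.names = FALSE)
  expect_error(read_genotypes(p2, "csv"), "duplicate")
})

test_that("simulated export parses back to the right shape", {
  pop <- founder_world(seed = 3)
  d <- tempfile()
  write_simulation(pop, simulate_replicates(pop), d)
  gm <- read_genotypes(file.path(d, "truth_genotypes.csv"), "csv")
  expect_equal(dim(gm), dim(pop$true_genotypes))
  expect_identical(gm$a1, pop$true_genotypes$a1)
  reps <- read_replicates(file.path(d, "replicates.csv"))
  expect_equal(length(reps$individuals), length(pop$true_genotypes$individuals))
})

test_that("consensus implements the dropout / conflict rules", {
  rules <- consensus_rules()
  # dropout-resolved heterozygote
  r1 <- call_consensus(reps_one(list(c(1, 2), c(1, 1), c(2, 2))), rules)
  expect_equal(unname(c(r1$genotypes$a1[1, 1], r1$genotypes$a2[1, 1])),
               c(1L, 2L))
  expect_equal(unname(r1$flags[1, 1]), "dropout_resolved")
  # disjoint heterozygotes conflict
  r2 <- call_consensus(reps_one(list(c(1, 2), c(3, 4))), rules)
  expect_true(is.na(r2$genotypes$a1[1, 1]))
  expect_equal(unname(r2$flags[1, 1]), "conflict")
  # homozygote needs two observations
  r3 <- call_consensus(reps_one(list(c(1, 1), c(NA, NA))), rules)
  expect_true(is.na(r3$genotypes$a1[1, 1]))
  expect_equal(unname(r3$flags[1, 1]), "missing")
  r4 <- call_consensus(reps_one(list(c(1, 1), c(1, 1))), rules)
  expect_equal(unname(c(r4$genotypes$a1[1, 1], r4$genotypes$a2[1, 1])),
               c(1L, 1L))
  expect_equal(unname(r4$flags[1, 1]), "confirmed")
  # three alleles across replicates conflict even with a consistent pair
  r5 <- call_consensus(reps_one(list(c(1, 2), c(1, 2), c(1, 3))), rules)
  expect_equal(unname(r5$flags[1, 1]), "conflict")
  expect_error(call_consensus(replicate_set(list(), character(0),
                                            character(0))),
               "empty")
})

test_that("consensus is replicate-order invariant and idempotent under
           duplication", {
  rep_rows <- list(c(1, 2, 1, 1), c(1, 1, 1, 3), c(2, 2, NA, NA))
  base <- call_consensus(reps_one(rep_rows))
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    r <- call_consensus(reps_one(rep_rows[perm]))
    expect_identical(r$genotypes$a1, base$genotypes$a1)
    expect_identical(r$flags, base$flags)
  }
  dup <- call_consensus(reps_one(c(rep_rows, rep_rows[2])))
  expect_identical(dup$genotypes$a1, base$genotypes$a1)
  expect_identical(dup$genotypes$a2, base$genotypes$a2)
})

test_that("error-free replicates reproduce truth exactly through consensus", {
  cfg <- sim_config(seed = 9, dropout_rate = 0, false_allele_rate = 0,
                    locus_failure_rate = 0, n_seasons = 2)
  pop <- simulate_population(cfg)
  cons <- call_consensus(simulate_replicates(pop, cfg))
  expect_identical(cons$genotypes$a1, pop$true_genotypes$a1)
  expect_identical(cons$genotypes$a2, pop$true_genotypes$a2)
  expect_true(all(cons$flags == "confirmed"))
})

test_that("re-genotyping flags follow the two rules", {
  cfg <- sim_config(seed = 10, n_seasons = 2)
  pop <- simulate_population(cfg)
  cons <- call_consensus(simulate_replicates(pop, cfg))
  fl <- flag_regenotyping(cons, min_loci = 10)
  expect_identical(fl$flagged, fl$reason_i | fl$reason_ii)
  expect_identical(unname(fl$reason_i), unname(cons$loci_typed < 10))
  expect_identical(unname(fl$reason_ii),
                   unname(apply(cons$flags == "conflict", 1, any)))
  # hand-built cases: 13/13 clean not flagged; 9 loci flagged (i);
  # conflict flagged (ii)
  clean <- call_consensus(reps_one(list(rep(c(1, 2), 13), rep(c(1, 2), 13)),
                                   loci = paste0("L", 1:13)))
  expect_false(flag_regenotyping(clean, 10)$flagged)
  nine <- call_consensus(reps_one(
    list(c(rep(c(1, 2), 9), rep(NA, 8)), c(rep(c(1, 2), 9), rep(NA, 8))),
    loci = paste0("L", 1:13)))
  f9 <- flag_regenotyping(nine, 10)
  expect_true(f9$flagged); expect_true(f9$reason_i); expect_false(f9$reason_ii)
  confl <- call_consensus(reps_one(
    list(rep(c(1, 2), 13), c(c(3, 4), rep(c(1, 2), 12))),
    loci = paste0("L", 1:13)))
  fc <- flag_regenotyping(confl, 10)
  expect_true(fc$flagged); expect_true(fc$reason_ii); expect_false(fc$reason_i)
})

test_that("filter_min_loci drops only under-typed individuals, keeps order", {
  rows <- list(rep(c(1, 2), 7),                    # 7 typed
               c(rep(c(1, 2), 6), NA, NA),          # 6 typed
               rep(c(2, 2), 7))                     # 7 typed
  gm <- gm_from_rows(rows, ids = c("keep1", "drop6", "keep2"))
  out <- filter_min_loci(gm, 7)
  expect_identical(out$individuals, c("keep1", "keep2"))
  expect_identical(filter_min_loci(gm, 0)$individuals, gm$individuals)
  expect_error(filter_min_loci(gm, 14), "all individuals")
})
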