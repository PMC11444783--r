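# naive per-pair, per-locus loop oracle for the estimator
qg_oracle <- function(gm, i, j, freqs) {
  num_ij <- den_ij <- num_ji <- den_ji <- 0
  for (l in seq_along(gm$loci)) {
    x <- c(gm$a1[i, l], gm$a2[i, l]); y <- c(gm$a1[j, l], gm$a2[j, l])
    if (anyNA(x) || anyNA(y)) next
    p <- function(a) {
      f <- freqs$freqs[[l]][as.character(a)]
      ifelse(is.na(f), 0, f)
    }
    sh <- 0.5 * ((x[1] == y[1]) + (x[1] == y[2]) +
                   (x[2] == y[1]) + (x[2] == y[2]))
    num_ij <- num_ij + sh - p(x[1]) - p(x[2])
    den_ij <- den_ij + 1 + (x[1] == x[2]) - p(x[1]) - p(x[2])
    num_ji <- num_ji + sh - p(y[1]) - p(y[2])
    den_ji <- den_ji + 1 + (y[1] == y[2]) - p(y[1]) - p(y[2])
  }
  (num_ij / den_ij + num_ji / den_ji) / 2
}

test_that("clone limit and oracle agreement on small instances", {
  # identical homozygotes at every locus with p = 0.5 -> r = 1
  gm <- gm_from_rows(list(c(1, 1, 1, 1), c(1, 1, 1, 1),
                          c(2, 2, 2, 2), c(2, 2, 2, 2)))
  rel <- qg_relatedness(gm)
  expect_equal(rel$r["i1", "i2"], 1)
  # matrix vs naive loop oracle, 10 individuals with missingness
  set.seed(55)
  gm2 <- make_hwe(10, panel_freqs(seed = 56, n_loci = 8), seed = 57)
  gm2$a1[1, 1:2] <- NA; gm2$a2[1, 1:2] <- NA
  fr <- allele_frequencies(gm2)
  rel2 <- qg_relatedness(gm2, fr)
  for (i in 1:9) for (j in (i + 1):10)
    expect_equal(rel2$r[i, j], unname(qg_oracle(gm2, i, j, fr)),
                 tolerance = 1e-9)
  # symmetry and excluded diagonal
  expect_identical(rel2$r, t(rel2$r))
  expect_true(all(is.na(diag(rel2$r))))
})

test_that("pedigree oracle: parent-offspring ~ 0.5, unrelated ~ 0, sample
           mean ~ 0", {
  f <- panel_freqs(seed = 61)
  set.seed(62)
  n_pairs <- 2000
  parents <- make_hwe(n_pairs, f, seed = 63)
  others <- make_hwe(n_pairs, f, seed = 64)
  # offspring: one allele from parent, one from the gene pool
  off1 <- off2 <- matrix(NA_integer_, n_pairs, 13)
  for (l in 1:13) {
    fromp <- ifelse(runif(n_pairs) < 0.5, parents$a1[, l], parents$a2[, l])
    pool <- sample(length(f[[l]]), n_pairs, TRUE, f[[l]])
    off1[, l] <- pmin(fromp, pool); off2[, l] <- pmax(fromp, pool)
  }
  ids <- c(paste0("par", 1:n_pairs), paste0("off", 1:n_pairs),
           paste0("unr", 1:n_pairs))
  gm <- genotype_matrix(rbind(parents$a1, off1, others$a1),
                        rbind(parents$a2, off2, others$a2), ids,
                        paste0("L", 1:13))
  fr <- allele_frequencies(gm)
  po <- qg_pairwise(gm, cbind(1:n_pairs, n_pairs + 1:n_pairs), fr)
  un <- qg_pairwise(gm, cbind(1:n_pairs, 2 * n_pairs + 1:n_pairs), fr)
  expect_lt(abs(mean(po) - 0.5), 0.02)
  expect_lt(abs(mean(un)), 0.02)
  # estimator is frequency-centred: mean over all pairs in a 94-strong
  # reference sample is ~ 0
  gm94 <- make_hwe(94, f, seed = 65)
  rel94 <- qg_relatedness(gm94)
  expect_lt(abs(mean(rel94$r[upper.tri(rel94$r)])), 0.02)
})

test_that("class means aggregate within-group role pairs correctly", {
  # two subordinate females with a known r: class mean is exactly that r
  gm <- gm_from_rows(list(c(1, 2, 3, 4), c(1, 2, 3, 4), c(1, 1, 2, 2),
                          c(3, 3, 1, 2), c(2, 3, 1, 3)))
  roles <- data.frame(id = paste0("i", 1:5),
                      sex = c("F", "F", "M", "F", "M"),
                      group = "G1",
                      role = c("subordinate", "subordinate", "dominant",
                               "dominant", "pup"))
  rel <- qg_relatedness(gm)
  ct <- class_relatedness(rel, roles)
  expect_equal(ct$mean_r[ct$class == "subF_subF"], rel$r["i1", "i2"])
  expect_equal(ct$mean_r[ct$class == "dominant_pair"], rel$r["i3", "i4"])
  expect_equal(ct$n_pairs[ct$class == "pup_pup"], 0)
  # full-skew world: within-litter pups are full sibs (mean ~ 0.5) and
  # subordinate cohorts sit above unrelated immigrants
  cfg <- sim_config(seed = 66, dominant_maternity_share = 1,
                    dominant_paternity_share = 1, n_seasons = 4,
                    male_dispersal_prob = 0, female_dispersal_prob = 0,
                    pup_survival = 0.6)
  pop <- simulate_population(cfg)
  rel2 <- qg_relatedness(pop$true_genotypes)
  ct2 <- class_relatedness(rel2, pop$individuals)
  expect_lt(abs(ct2$mean_r[ct2$class == "within_litter"] - 0.5), 0.06)
  expect_gt(ct2$mean_r[ct2$class == "subF_subF"],
            ct2$mean_r[ct2$class == "dominant_pair"])
})

test_that("breeder permutation test: degenerate and extreme cases", {
  # group G1 genetically identical (a second, variable group keeps the
  # reference frequencies non-degenerate) -> null always equals observed
  clone <- rep(c(1, 2), 6)
  set.seed(71)
  varied <- lapply(1:6, function(i) sample(4, 12, TRUE))
  gm <- gm_from_rows(c(rep(list(clone), 6), varied))
  roles <- data.frame(id = paste0("i", 1:6),
                      sex = rep(c("M", "F"), 3), group = "G1",
                      role = c("dominant", "dominant", rep("subordinate", 4)))
  rel <- qg_relatedness(gm)
  bt <- breeder_permutation_test(rel, roles, n = 100, seed = 1)
  expect_equal(bt$p, 1)
  expect_equal(length(bt$null), 100)
  expect_true(all(bt$null == bt$observed))
  # observed below every null value -> p = 1/(n+1); synthetic surface where
  # the dominant pair is far less related than any alternative partner
  ids <- paste0("i", 1:10)
  rsyn <- matrix(0.4, 10, 10, dimnames = list(ids, ids))
  diag(rsyn) <- NA
  rsyn["i1", "i2"] <- rsyn["i2", "i1"] <- -0.5
  rel3 <- structure(list(r = rsyn, excluded = matrix(FALSE, 10, 10),
                         freqs = NULL), class = "relatedness_matrix")
  roles3 <- data.frame(id = ids, sex = rep(c("M", "F"), 5), group = "G1",
                       role = c("dominant", "dominant",
                                rep("subordinate", 8)))
  bt2 <- breeder_permutation_test(rel3, roles3, n = 1000, seed = 5,
                                  include_partner = FALSE)
  expect_true(bt2$observed < min(bt2$null))
  expect_equal(bt2$p, 1 / 1001)
  # with the partner drawable the p-value can only be larger
  bt2b <- breeder_permutation_test(rel3, roles3, n = 1000, seed = 5)
  expect_gte(bt2b$p, bt2$p)
  # determinism
  bt3 <- breeder_permutation_test(rel3, roles3, n = 1000, seed = 5,
                                  include_partner = FALSE)
  expect_identical(bt2$null, bt3$null)
})

test_that("between-group means equal a brute-force dyad average", {
  gm <- make_hwe(18, panel_freqs(seed = 81, n_loci = 6), seed = 82)
  groups <- setNames(rep(c("A", "B", "C"), each = 6), gm$individuals)
  rel <- qg_relatedness(gm)
  bg <- between_group_relatedness(rel, groups)
  expect_identical(bg, t(bg))
  manual <- mean(rel$r[groups == "A", groups == "B"])
  expect_equal(bg["A", "B"], manual)
  # a constant relatedness surface averages to a constant matrix
  rconst <- matrix(0.3, 9, 9, dimnames = list(paste0("i", 1:9),
                                              paste0("i", 1:9)))
  diag(rconst) <- NA
  relc <- structure(list(r = rconst,
                         excluded = matrix(FALSE, 9, 9), freqs = NULL),
                    class = "relatedness_matrix")
  bgc <- between_group_relatedness(relc, setNames(rep(c("A", "B", "C"),
                                                      each = 3),
                                                  paste0("i", 1:9)))
  expect_true(all(abs(bgc - 0.3) < 1e-12))
})

test_that("mantel test: perfect correlation, degeneracy, calibration", {
  set.seed(9)
  m1 <- matrix(0, 7, 7)
  m1[upper.tri(m1)] <- runif(21)
  m1 <- m1 + t(m1)
  mt <- mantel_test(m1, m1, n_perm = 199, seed = 1)
  expect_equal(mt$r, 1)
  expect_equal(mt$p, 1 / 200)
  expect_error(mantel_test(m1, matrix(1, 7, 7), n_perm = 99),
               "zero variance")
  expect_error(mantel_test(m1, matrix(0, 6, 6)), "square")
  # agreement with vegan on the statistic and a similar p
  if (requireNamespace("vegan", quietly = TRUE)) {
    m2 <- matrix(0, 7, 7); m2[upper.tri(m2)] <- runif(21); m2 <- m2 + t(m2)
    mt2 <- mantel_test(m1, m2, n_perm = 499, seed = 2,
                       alternative = "greater")
    vg <- vegan::mantel(as.dist(m1), as.dist(m2), permutations = 499)
    expect_equal(mt2$r, unname(vg$statistic), tolerance = 1e-12)
  }
  # calibration: independent random matrices give uniform-ish p
  ps <- vapply(1:200, function(b) {
    set.seed(1000 + b)
    a <- matrix(0, 7, 7); a[upper.tri(a)] <- runif(21); a <- a + t(a)
    b2 <- matrix(0, 7, 7); b2[upper.tri(b2)] <- runif(21); b2 <- b2 + t(b2)
    mantel_test(a, b2, n_perm = 99, seed = b)$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})
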