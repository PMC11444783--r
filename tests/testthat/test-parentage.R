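test_that("candidate rules: pregnancy window, father age, population mode", {
  meta <- data.frame(
    id = c("pup1", "f_in", "f_out", "f_othergrp", "m_ok", "m_young",
           "m_othergrp"),
    sex = c("M", "F", "F", "F", "M", "M", "M"),
    group = c("G1", "G1", "G1", "G2", "G1", "G1", "G2"),
    birth_date = c("2018-01-10", "2014-01-01", "2014-01-01", "2014-01-01",
                   "2015-06-01", "2016-06-01", "2013-01-01"),
    stringsAsFactors = FALSE)
  preg <- data.frame(
    female_id = c("f_in", "f_out", "f_othergrp"),
    date = c("2018-01-20", "2017-10-05", "2018-01-10"),  # +10d, -97d, same day
    stringsAsFactors = FALSE)
  cs <- build_candidates("pup1", meta, preg)
  expect_identical(cs$pup1$mothers, "f_in")       # 3-months-early excluded
  # conception 2017-11-21: m_ok is 2.47y (in), m_young 1.47y (out)
  expect_identical(cs$pup1$fathers, "m_ok")
  cs2 <- build_candidates("pup1", meta, preg, father_mode = "population")
  expect_true(all(cs$pup1$fathers %in% cs2$pup1$fathers))
  expect_true("m_othergrp" %in% cs2$pup1$fathers)
  meta$group[1] <- NA
  expect_error(build_candidates("pup1", meta, preg), "without group")
})

test_that("single-locus LOD hand cases and Mendelian exclusion", {
  # pup (1,2), candidate (1,1), p1 = p2 = 0.5 -> transition 0.5 equals the
  # background 2pq = 0.5, LOD = 0
  gm <- gm_from_rows(list(c(1, 2), c(1, 1), c(2, 2), c(1, 2)),
                     ids = c("pup", "candA", "candB", "candC"))
  af <- allele_frequencies(gm)   # p1 = p2 = 0.5 by construction
  sc <- lod_scores(gm, "pup", "candA", character(0), af, error_rate = 0)
  expect_equal(unname(sc$mother_lod["candA"]), 0)
  # pup (1,1) vs candidate (2,2): exclusion at error 0
  gm2 <- gm_from_rows(list(c(1, 1), c(2, 2), c(1, 2)),
                      ids = c("pup", "bad", "filler"))
  af2 <- allele_frequencies(gm2)
  sc2 <- lod_scores(gm2, "pup", "bad", character(0), af2, error_rate = 0)
  expect_identical(unname(sc2$mother_lod["bad"]), -Inf)
  expect_equal(unname(sc2$mother_mismatch["bad"]), 1L)
  # positive error rate keeps the score finite
  sc3 <- lod_scores(gm2, "pup", "bad", character(0), af2, error_rate = 0.05)
  expect_true(is.finite(sc3$mother_lod["bad"]))
  expect_error(lod_scores(gm2, "pup", "bad", character(0), af2,
                          error_rate = 1), "error_rate")
})

test_that("true parents win the pair LOD on error-free trios", {
  pop <- founder_world(seed = 31)
  gm <- pop$true_genotypes
  fr <- allele_frequencies(gm)
  meta <- pop$individuals; ped <- pop$pedigree
  pups <- head(meta$id[meta$role == "pup"], 25)
  for (p in pups) {
    grp <- meta$group[meta$id == p]
    ig <- meta[meta$group == grp & meta$id != p & meta$role != "pup", ]
    row <- ped[ped$id == p, ]
    if (!all(c(row$dam, row$sire) %in% ig$id)) next
    sc <- lod_scores(gm, p, ig$id[ig$sex == "F"], ig$id[ig$sex == "M"], fr,
                     error_rate = 0)
    best <- which(sc$pair_lod == max(sc$pair_lod, na.rm = TRUE), arr.ind = TRUE)
    expect_true(any(rownames(sc$pair_lod)[best[, 1]] == row$dam &
                      colnames(sc$pair_lod)[best[, 2]] == row$sire))
  }
})

test_that("confidence simulation: self-consistency, determinism, invariants", {
  f <- panel_freqs(seed = 91)
  af <- structure(list(freqs = lapply(f, function(v)
    setNames(v, seq_along(v))), n_typed = rep(100, 13),
    loci = paste0("L", 1:13)), class = "allele_frequencies")
  # easy regime: no error, everyone sampled, unrelated candidates
  easy <- conf_sim_params(prop_mothers_sampled = 1, prop_fathers_sampled = 1,
                          prop_loci_typed = 1, error_rate = 0,
                          prop_related_mothers = 0, prop_related_fathers = 0,
                          n_cycles = 300)
  thr <- simulate_confidence(af, easy, seed = 7)
  expect_lt(thr$strict, 5)
  expect_gte(mean(thr$correct[!is.na(thr$deltas)]), 0.95)
  expect_gte(thr$strict, thr$relaxed)
  expect_gte(thr$relaxed, 0)
  thr2 <- simulate_confidence(af, easy, seed = 7)
  expect_identical(thr[c("strict", "relaxed", "deltas")],
                   thr2[c("strict", "relaxed", "deltas")])
  expect_error(conf_sim_params(prop_mothers_sampled = 1.2), "in \\[0, 1\\]")
})

test_that("related-candidate generator hits its target relatedness", {
  f <- panel_freqs(seed = 95)
  af <- structure(list(freqs = lapply(f, function(v)
    setNames(v, seq_along(v))), n_typed = rep(100, 13),
    loci = paste0("L", 1:13)), class = "allele_frequencies")
  set.seed(96)
  n <- 1500
  par <- kinskew:::draw_hwe(n, af)
  a1 <- a2 <- matrix(NA_integer_, n, 13)
  for (i in 1:n) {
    cand <- kinskew:::related_candidate(par$a1[i, ], par$a2[i, ], 0.31, af)
    a1[i, ] <- cand$a1; a2[i, ] <- cand$a2
  }
  gm <- genotype_matrix(rbind(par$a1, a1), rbind(par$a2, a2),
                        c(paste0("p", 1:n), paste0("c", 1:n)),
                        af$loci)
  r <- qg_pairwise(gm, cbind(1:n, n + 1:n), allele_frequencies(gm))
  expect_lt(abs(mean(r) - 0.31), 0.03)
})

test_that("assignment conventions: sole candidate, exclusions, tiers", {
  thr <- list(strict = 6, relaxed = 2)
  pl <- matrix(4.2, 1, 1, dimnames = list("m1", "f1"))
  lods <- list(pair_lod = pl,
               mother_mismatch = c(m1 = 0L), father_mismatch = c(f1 = 0L))
  a <- assign_parentage(lods, thr, pup = "p")
  expect_equal(a$delta, 4.2)          # sole pair: delta = its (positive) LOD
  expect_equal(a$confidence, "80%")
  pl2 <- matrix(c(-Inf, -Inf), 1, 2, dimnames = list("m1", c("f1", "f2")))
  lods2 <- list(pair_lod = pl2, mother_mismatch = c(m1 = 2L),
                father_mismatch = c(f1 = 3L, f2 = 1L))
  a2 <- assign_parentage(lods2, thr, pup = "p")
  expect_equal(a2$confidence, "none")
  expect_true(is.na(a2$mother))
  pl3 <- matrix(c(10, 1), 1, 2, dimnames = list("m1", c("f1", "f2")))
  lods3 <- list(pair_lod = pl3, mother_mismatch = c(m1 = 0L),
                father_mismatch = c(f1 = 0L, f2 = 0L))
  a3 <- assign_parentage(lods3, thr, pup = "p")
  expect_equal(a3$delta, 9)
  expect_equal(a3$confidence, "95%")
  expect_equal(a3$father, "f1")
})

test_that("skew summary reproduces the printed-count arithmetic", {
  roles <- data.frame(id = c(paste0("dF", 1:7), paste0("sF", 1:7),
                             "dM1", "sM1"),
                      role = c(rep("dominant", 7), rep("subordinate", 7),
                               "dominant", "subordinate"))
  mk <- function(n_dom_m, n_sub_m, n_dom_f, n_sub_f) {
    data.frame(
      pup = paste0("p", seq_len(n_dom_m + n_sub_m)),
      mother = c(rep("dF1", n_dom_m), rep("sF1", n_sub_m)),
      father = c(rep("dM1", n_dom_f), rep("sM1", n_sub_f),
                 rep(NA, n_dom_m + n_sub_m - n_dom_f - n_sub_f)),
      confidence = "95%", stringsAsFactors = FALSE)
  }
  # 31 dominant / 4 subordinate mothers; 28 dominant / 4 subordinate fathers
  sk <- skew_summary(mk(31, 4, 28, 4), roles)
  expect_equal(round(sk$maternity$dominant_pct, 1), 88.6)
  expect_equal(sk$paternity$subordinate_pct, 12.5)
  # full skew: 100% dominant on both sides
  sk2 <- skew_summary(mk(10, 0, 10, 0), roles)
  expect_equal(sk2$maternity$dominant_pct, 100)
  expect_equal(sk2$paternity$dominant_pct, 100)
})

test_that("population-wide father mode preserves the assigned father when
           the within-group winner is the true father", {
  pop <- founder_world(seed = 33)
  gm <- pop$true_genotypes
  fr <- allele_frequencies(gm)
  meta <- pop$individuals; ped <- pop$pedigree
  thr <- list(strict = 3, relaxed = 1)
  pups <- head(meta$id[meta$role == "pup"], 15)
  all_m <- meta$id[meta$sex == "M" & meta$role != "pup"]
  for (p in pups) {
    grp <- meta$group[meta$id == p]
    ig <- meta[meta$group == grp & meta$id != p & meta$role != "pup", ]
    row <- ped[ped$id == p, ]
    if (!all(c(row$dam, row$sire) %in% ig$id)) next
    sc_in <- lod_scores(gm, p, ig$id[ig$sex == "F"], ig$id[ig$sex == "M"],
                        fr, error_rate = 0.01)
    a_in <- assign_parentage(sc_in, thr, pup = p)
    if (!identical(a_in$father, row$sire)) next
    sc_all <- lod_scores(gm, p, ig$id[ig$sex == "F"],
                         setdiff(all_m, p), fr, error_rate = 0.01)
    a_all <- assign_parentage(sc_all, thr, pup = p)
    expect_identical(a_all$father, a_in$father)
  }
})
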