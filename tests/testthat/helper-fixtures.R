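# Shared fixture builders. Everything is generated in code; no data files.

# tiny genotype matrix from a list of rows; each row a vector
# c(a1_l1, a2_l1, a1_l2, a2_l2, ...), NA for missing
gm_from_rows <- function(rows, ids = NULL, loci = NULL, groups = NULL) {
  m <- do.call(rbind, rows)
  L <- ncol(m) / 2
  a1 <- m[, seq(1, by = 2, length.out = L), drop = FALSE]
  a2 <- m[, seq(2, by = 2, length.out = L), drop = FALSE]
  if (is.null(ids)) ids <- paste0("i", seq_along(rows))
  if (is.null(loci)) loci <- paste0("L", seq_len(L))
  genotype_matrix(a1, a2, ids, loci, groups = groups)
}

# replicate set for a single individual from a list of replicate rows
reps_one <- function(rep_rows, id = "x", loci = NULL) {
  m <- do.call(rbind, rep_rows)
  L <- ncol(m) / 2
  a1 <- m[, seq(1, by = 2, length.out = L), drop = FALSE]
  a2 <- m[, seq(2, by = 2, length.out = L), drop = FALSE]
  if (is.null(loci)) loci <- paste0("L", seq_len(L))
  colnames(a1) <- colnames(a2) <- loci
  sids <- paste0(id, "_S", seq_along(rep_rows))
  rownames(a1) <- rownames(a2) <- sids
  replicate_set(list(list(a1 = a1, a2 = a2, sample_ids = sids)), id, loci)
}

# a drifted multi-deme fixture with strong differentiation (for clustering)
make_demes <- function(n_demes = 6, per = 12, L = 10, n_alleles = 6,
                       sharpen = 3, seed = 99) {
  set.seed(seed)
  a1 <- a2 <- matrix(NA_integer_, n_demes * per, L)
  g <- rep(paste0("D", seq_len(n_demes)), each = per)
  for (d in seq_len(n_demes)) for (l in seq_len(L)) {
    f <- as.vector(stats::rmultinom(1, 40, rep(1 / n_alleles, n_alleles))) + 0.05
    f <- (f / sum(f))^sharpen; f <- f / sum(f)
    rows <- which(g == paste0("D", d))
    a1[rows, l] <- sample(n_alleles, per, TRUE, f)
    a2[rows, l] <- sample(n_alleles, per, TRUE, f)
  }
  genotype_matrix(pmin(a1, a2), pmax(a1, a2), groups = g)
}

# Hardy-Weinberg draws from given per-locus frequency vectors
make_hwe <- function(n, freq_list, seed = 1) {
  set.seed(seed)
  L <- length(freq_list)
  a1 <- a2 <- matrix(NA_integer_, n, L)
  for (l in seq_len(L)) {
    k <- length(freq_list[[l]])
    a1[, l] <- sample(k, n, TRUE, freq_list[[l]])
    a2[, l] <- sample(k, n, TRUE, freq_list[[l]])
  }
  genotype_matrix(pmin(a1, a2), pmax(a1, a2))
}

# panel of 13 loci with He ~ 0.61 (Dirichlet 0.29, 8 alleles)
panel_freqs <- function(seed = 4, n_loci = 13, n_alleles = 8, conc = 0.29) {
  set.seed(seed)
  lapply(seq_len(n_loci), function(l) {
    g <- stats::rgamma(n_alleles, conc, 1)
    g / sum(g)
  })
}

# a small world used across tests (two breeding seasons: all candidate
# parents are unrelated founders)
founder_world <- function(seed = 1, ...) {
  simulate_population(sim_config(seed = seed, n_seasons = 2, ...))
}
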