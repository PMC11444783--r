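#' Pipeline configuration
#'
#' One seeded configuration covering the full simulate -> consensus ->
#' filter -> diagnostics -> F-stats -> relatedness -> parentage ->
#' clustering chain. Any stage can be toggled off; dependent fields are
#' simply omitted from the report.
#'
#' @param sim a [sim_config()].
#' @param stages character subset of
#'   `c("diagnostics", "fstats", "relatedness", "parentage", "clustering")`
#'   (consensus and filtering always run).
#' @param min_loci_consensus re-genotyping flag threshold (rule i).
#' @param min_loci_relatedness inclusion threshold for relatedness.
#' @param n_perm permutations for F-statistics and Mantel tests.
#' @param n_breeder_perm permutations for the breeder-pair test.
#' @param conf_params a [conf_sim_params()] for parentage confidence.
#' @param cluster_k K values to fit (needs >= 3 consecutive for selection).
#' @param cluster_runs replicate runs per K.
#' @param cluster_burnin,cluster_iters MCMC settings.
#' @param seed master seed for all stages.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            stages = c("diagnostics", "fstats", "relatedness",
                                       "parentage", "clustering"),
                            min_loci_consensus = 10L,
                            min_loci_relatedness = 7L,
                            n_perm = 999L, n_breeder_perm = 1000L,
                            conf_params = conf_sim_params(n_cycles = 1000L),
                            cluster_k = 5:9, cluster_runs = 2L,
                            cluster_burnin = 500L, cluster_iters = 1000L,
                            seed = 1L) {
  structure(list(sim = sim, stages = stages,
                 min_loci_consensus = as.integer(min_loci_consensus),
                 min_loci_relatedness = as.integer(min_loci_relatedness),
                 n_perm = as.integer(n_perm),
                 n_breeder_perm = as.integer(n_breeder_perm),
                 conf_params = conf_params,
                 cluster_k = as.integer(cluster_k),
                 cluster_runs = as.integer(cluster_runs),
                 cluster_burnin = as.integer(cluster_burnin),
                 cluster_iters = as.integer(cluster_iters),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on a simulated population
#'
#' Executes the stages in dependency order, writes every artifact as
#' CSV/JSON under `out_dir`, and returns (and writes) a machine-readable
#' report aggregating the headline statistics. Deterministic under the
#' master seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return the report, invisibly (also written to `report.json`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) message(sprintf("[kinskew] %s", sprintf(...)))
  report <- list(seed = config$seed, stages = config$stages)

  sim_cfg <- config$sim
  sim_cfg$seed <- config$seed
  sim_cfg <- do.call(sim_config, unclass(sim_cfg))

  log_stage("simulate")
  pop <- simulate_population(sim_cfg)
  reps <- simulate_replicates(pop, sim_cfg)
  write_simulation(pop, reps, file.path(out_dir, "simdata"))
  report$n_individuals <- nrow(pop$individuals)

  log_stage("consensus")
  cons <- call_consensus(reps)
  flags <- flag_regenotyping(cons, config$min_loci_consensus)
  utils::write.csv(flags, file.path(out_dir, "regenotyping_flags.csv"),
                   row.names = FALSE)
  gm <- cons$genotypes
  gm$groups <- stats::setNames(pop$individuals$group, pop$individuals$id)
  write_genotypes(gm, file.path(out_dir, "consensus_genotypes.csv"))
  report$n_flagged_regenotyping <- sum(flags$flagged)
  report$consensus_concordance <- consensus_concordance(cons, pop)

  gm_f <- filter_min_loci(gm, config$min_loci_relatedness)
  report$n_after_min_loci_filter <- length(gm_f$individuals)

  if ("diagnostics" %in% config$stages) {
    log_stage("diagnostics")
    ls_tab <- locus_summary(gm_f)
    utils::write.csv(ls_tab, file.path(out_dir, "locus_summary.csv"),
                     row.names = FALSE)
    pi <- probability_of_identity(allele_frequencies(gm_f))
    report$mean_He <- mean(ls_tab$He)
    report$mean_PIC <- mean(ls_tab$PIC)
    report$panel_PI <- pi$panel
  }

  if ("fstats" %in% config$stages) {
    log_stage("fstats")
    fs <- suppressWarnings(
      fstat_permutation(gm_f, n_perm = config$n_perm,
                        seed = derive_seed(config$seed, "fstat_perm")))
    report$F_ST <- unname(fs$observed["F_ST"])
    report$F_IS <- unname(fs$observed["F_IS"])
    report$F_IT <- unname(fs$observed["F_IT"])
    report$p_F_ST <- fs$p_fst
    report$p_F_IS <- fs$p_fis
  }

  roles <- pop$individuals[pop$individuals$id %in% gm_f$individuals, ]
  if ("relatedness" %in% config$stages) {
    log_stage("relatedness")
    rel <- qg_relatedness(gm_f)
    utils::write.csv(rel$r, file.path(out_dir, "relatedness_matrix.csv"))
    ct <- class_relatedness(rel, roles)
    utils::write.csv(ct, file.path(out_dir, "class_relatedness.csv"),
                     row.names = FALSE)
    bt <- breeder_permutation_test(rel, roles, n = config$n_breeder_perm,
                                   seed = derive_seed(config$seed, "breeder"))
    report$class_relatedness <- stats::setNames(
      as.list(ct$mean_r), ct$class)
    report$breeder_test <- list(observed = bt$observed, p = bt$p,
                                n = bt$n_permutations)
  }

  if ("parentage" %in% config$stages) {
    log_stage("parentage")
    pa <- sim_parentage(pop, gm_f, config,
                        seed = derive_seed(config$seed, "parentage"))
    utils::write.csv(pa$assignments,
                     file.path(out_dir, "parentage_assignments.csv"),
                     row.names = FALSE)
    report$parentage <- pa$summary
    report$conf_thresholds <- list(strict = pa$thresholds$strict,
                                   relaxed = pa$thresholds$relaxed)
  }

  if ("clustering" %in% config$stages) {
    log_stage("clustering")
    runs <- list()
    for (k in config$cluster_k)
      for (rrun in seq_len(config$cluster_runs))
        runs[[length(runs) + 1L]] <- fit_admixture(
          gm_f, k, config$cluster_burnin, config$cluster_iters,
          seed = derive_seed(config$seed, sprintf("clust_%d_%d", k, rrun)))
    sel <- select_k(runs)
    utils::write.csv(sel$table, file.path(out_dir, "evanno_table.csv"),
                     row.names = FALSE)
    k_best <- if (is.na(sel$K_by_deltaK)) sel$K_by_lnpd else sel$K_by_deltaK
    cand <- Filter(function(r) r$K == k_best, runs)
    best <- cand[[which.max(vapply(cand, `[[`, numeric(1), "LnPD"))]]
    utils::write.csv(best$Q, file.path(out_dir, "Q_matrix.csv"))
    report$K_by_lnpd <- sel$K_by_lnpd
    report$K_by_deltaK <- sel$K_by_deltaK
  }

  report$version <- as.character(utils::packageVersion("kinskew"))
  # cheap deterministic provenance digest of the full configuration
  cfg_txt <- paste(deparse(unclass(config)), collapse = "")
  report$config_digest <- sprintf("%08x",
    sum(utf8ToInt(cfg_txt) * seq_along(utf8ToInt(cfg_txt))) %% 4294967291)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

# fraction of consensus calls (non-missing in consensus) equal to truth
consensus_concordance <- function(cons, pop) {
  gm <- cons$genotypes; truth <- pop$true_genotypes
  idx <- match(gm$individuals, truth$individuals)
  called <- !is.na(gm$a1)
  same <- gm$a1 == truth$a1[idx, , drop = FALSE] &
    gm$a2 == truth$a2[idx, , drop = FALSE]
  sum(same[called]) / sum(called)
}

# parentage stage on a simulated population: candidates from group/roles at
# the pup's birth season, thresholds from a confidence simulation, skew from
# the assignments
sim_parentage <- function(pop, gm, config, seed) {
  freqs <- allele_frequencies(gm)
  thr <- simulate_confidence(freqs, config$conf_params, seed = seed)
  meta <- pop$individuals
  pups <- meta$id[meta$role == "pup" & meta$id %in% gm$individuals]
  rows <- list()
  for (p in pups) {
    grp <- meta$group[meta$id == p]
    born <- meta$birth_season[meta$id == p]
    adult_enough <- is.na(meta$birth_season) | meta$birth_season == 0L |
      born - meta$birth_season >= 2L    # the over-2-years candidate rule
    in_grp <- meta[meta$group == grp & meta$id != p &
                     meta$role != "pup" & adult_enough, , drop = FALSE]
    mothers <- intersect(in_grp$id[in_grp$sex == "F"], gm$individuals)
    fathers <- intersect(in_grp$id[in_grp$sex == "M"], gm$individuals)
    if (length(mothers) == 0 || length(fathers) == 0) next
    sc <- lod_scores(gm, p, mothers, fathers, freqs,
                     error_rate = config$conf_params$error_rate)
    rows[[p]] <- assign_parentage(sc, thr, pup = p)
  }
  assignments <- do.call(rbind, rows)
  roles <- meta[, c("id", "role")]
  sk <- skew_summary(assignments, roles)
  ped <- pop$pedigree
  truth_ok <- mapply(function(p, m, f) {
    row <- ped[ped$id == p, ]
    identical(row$dam, m) && identical(row$sire, f)
  }, assignments$pup, assignments$mother, assignments$father)
  list(assignments = assignments, thresholds = thr,
       summary = list(
         n_pups_tested = nrow(assignments),
         n_correct_vs_truth = sum(truth_ok, na.rm = TRUE),
         maternity = sk$maternity, paternity = sk$paternity))
}
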