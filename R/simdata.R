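#' Simulation configuration
#'
#' Describes a cooperatively breeding population of territorial groups, each
#' headed by a single dominant breeding pair with subordinate helpers, and
#' the faecal-DNA genotyping noise laid over it. Defaults emulate a
#' habituated seven-group study population of roughly a hundred sampled
#' individuals: thirteen microsatellites with mean expected heterozygosity
#' near 0.61, strong dominant reproductive skew (88.6% maternity, 87.5%
#' paternity) and 3:1 male-biased dispersal.
#'
#' @param n_groups number of social groups.
#' @param group_size_mean mean number of founding adults per group.
#' @param n_loci number of microsatellite loci.
#' @param alleles_per_locus number of allele labels per locus.
#' @param founder_freq_concentration symmetric Dirichlet concentration for
#'   founder allele frequencies. The default 0.29 with 8 alleles gives
#'   E\[He\] = 1 - (a+1)/(ka+1) ~ 0.61.
#' @param dominant_maternity_share probability a litter's dam is the group's
#'   dominant female.
#' @param dominant_paternity_share probability a litter's sire is the
#'   dominant male.
#' @param male_dispersal_prob,female_dispersal_prob per-season probability
#'   that a subordinate adult switches groups; defaults keep the 3:1 male
#'   bias.
#' @param outside_immigrant_frac fraction of dispersal events that arrive
#'   from outside the study population as novel founders (unhabituated
#'   groups) rather than transfers between simulated groups.
#' @param n_seasons number of breeding seasons simulated.
#' @param litters_per_season_mean Poisson mean emerged litters per
#'   group-season (truncated at 1); pregnancies that produce no emerged
#'   pups are not modelled, so this is the emerged-litter rate, not the
#'   pregnancy rate.
#' @param litter_size_mean Poisson mean pups per litter (truncated at 1).
#' @param pup_survival probability a pup survives to recruit as a
#'   subordinate adult in the next season.
#' @param dropout_rate per-allele dropout probability in heterozygous calls,
#'   per replicate.
#' @param false_allele_rate per-locus probability that one allele of a
#'   replicate call is replaced by a random other allele of that locus.
#' @param locus_failure_rate per-locus probability a replicate fails wholly.
#' @param n_replicates faecal replicates per individual.
#' @param seed master seed; fixes the full output bit-for-bit.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_groups = 7L, group_size_mean = 6L, n_loci = 13L,
                       alleles_per_locus = 8L,
                       founder_freq_concentration = 0.29,
                       dominant_maternity_share = 0.886,
                       dominant_paternity_share = 0.875,
                       male_dispersal_prob = 0.10,
                       female_dispersal_prob = 0.033,
                       outside_immigrant_frac = 0.25,
                       n_seasons = 3L, litters_per_season_mean = 1.45,
                       litter_size_mean = 3.5, pup_survival = 0.39,
                       dropout_rate = 0.2, false_allele_rate = 0.01,
                       locus_failure_rate = 0.05, n_replicates = 3L,
                       seed = 1L) {
  cfg <- list(n_groups = as.integer(n_groups),
              group_size_mean = as.integer(group_size_mean),
              n_loci = as.integer(n_loci),
              alleles_per_locus = as.integer(alleles_per_locus),
              founder_freq_concentration = founder_freq_concentration,
              dominant_maternity_share = dominant_maternity_share,
              dominant_paternity_share = dominant_paternity_share,
              male_dispersal_prob = male_dispersal_prob,
              female_dispersal_prob = female_dispersal_prob,
              outside_immigrant_frac = outside_immigrant_frac,
              n_seasons = as.integer(n_seasons),
              litters_per_season_mean = litters_per_season_mean,
              litter_size_mean = litter_size_mean,
              pup_survival = pup_survival,
              dropout_rate = dropout_rate,
              false_allele_rate = false_allele_rate,
              locus_failure_rate = locus_failure_rate,
              n_replicates = as.integer(n_replicates),
              seed = as.integer(seed))
  counts <- c("n_groups", "group_size_mean", "n_loci", "alleles_per_locus",
              "n_seasons", "n_replicates")
  for (f in counts)
    if (cfg[[f]] < 1) stop(f, " must be >= 1")
  props <- c("dominant_maternity_share", "dominant_paternity_share",
             "male_dispersal_prob", "female_dispersal_prob",
             "outside_immigrant_frac", "pup_survival", "dropout_rate",
             "false_allele_rate", "locus_failure_rate")
  for (f in props)
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0, 1]")
  if (cfg$founder_freq_concentration <= 0)
    stop("founder_freq_concentration must be positive")
  if (cfg$litters_per_season_mean <= 0 || cfg$litter_size_mean <= 0)
    stop("litter means must be positive")
  structure(cfg, class = "sim_config")
}

# Independent per-operation RNG streams: the stream for operation `key` is
# seeded with (master * 7919 + sum of key's character codes) mod 2^31 - 1,
# so each operation is reproducible in isolation.
derive_seed <- function(seed, key) {
  as.integer((as.double(seed) * 7919 + sum(utf8ToInt(key))) %% 2147483647)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[sample.int(length(g), 1)] <- 1
  g / sum(g)
}

# draw unordered genotype pair(s) from allele frequencies
draw_genotype <- function(n, freqs) {
  k <- length(freqs)
  a1 <- sample.int(k, n, replace = TRUE, prob = freqs)
  a2 <- sample.int(k, n, replace = TRUE, prob = freqs)
  cbind(pmin(a1, a2), pmax(a1, a2))
}

#' Simulate a pedigree-structured population
#'
#' Founds `n_groups` groups with adults drawn in Hardy-Weinberg proportions
#' from Dirichlet founder allele frequencies, then steps season by season:
#' subordinate adults disperse with sex-specific probabilities (joint moves
#' into the same destination in one season are coalition events), each group
#' produces Poisson litters whose dam is the dominant female with probability
#' `dominant_maternity_share` (else a uniformly chosen subordinate adult
#' female; sire analogous with `dominant_paternity_share`), offspring alleles
#' follow Mendelian segregation, and surviving pups recruit as subordinates
#' the next season. Dominants hold their position throughout; roles are
#' reported as of the final season, with individuals born in the final
#' season as pups.
#'
#' @param config a [sim_config()].
#' @return a list of class `simulated_population` with elements
#'   `individuals` (data.frame: id, sex, group, role, birth_season, origin,
#'   litter_id), `pedigree` (data.frame: id, dam, sire; `NA` unknown),
#'   `switch_events` (data.frame: event_id, id, sex, season, from_group,
#'   to_group, coalition), `true_genotypes` (a complete
#'   [genotype_matrix()]), `founder_freqs` (list per locus) and `config`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "population"))
  k <- config$alleles_per_locus
  freqs <- lapply(seq_len(config$n_loci), function(l)
    rdirichlet1(rep(config$founder_freq_concentration, k)))

  groups <- paste0("G", seq_len(config$n_groups))
  new_id <- local({
    counter <- 0L
    function(n = 1L) {
      counter <<- counter + n
      sprintf("M%04d", seq.int(counter - n + 1L, counter))
    }
  })

  draw_founder <- function() {
    g <- vapply(freqs, function(f) draw_genotype(1, f), numeric(2))
    list(a1 = g[1, ], a2 = g[2, ])
  }

  # individual registry (grown as lists for speed, bound at the end)
  ind <- list()
  geno1 <- list(); geno2 <- list()
  ped <- list()
  add_ind <- function(id, sex, group, role, birth_season, origin, litter_id,
                      a1, a2, dam = NA_character_, sire = NA_character_) {
    ind[[id]] <<- list(id = id, sex = sex, group = group, role = role,
                       birth_season = birth_season, origin = origin,
                       litter_id = litter_id)
    geno1[[id]] <<- a1; geno2[[id]] <<- a2
    ped[[id]] <<- c(dam = dam, sire = sire)
  }

  # founding: per group, one dominant pair plus subordinates of alternating sex
  for (g in groups) {
    n_adults <- max(2L, stats::rpois(1, config$group_size_mean))
    sexes <- c("F", "M", rep_len(c("M", "F"), n_adults - 2L))
    roles <- c("dominant", "dominant", rep("subordinate", n_adults - 2L))
    for (i in seq_len(n_adults)) {
      fg <- draw_founder()
      add_ind(new_id(), sexes[i], g, roles[i], 0L, "natal", NA_character_,
              fg$a1, fg$a2)
    }
  }

  switch_rows <- list()
  event_counter <- 0L
  litter_counter <- 0L

  current <- function(field) vapply(ind, `[[`, character(1), field)

  for (season in seq_len(config$n_seasons)) {
    roles <- current("role"); sexes <- current("sex"); grp <- current("group")
    ids <- names(ind)

    ## dispersal of subordinate adults
    subs <- ids[roles == "subordinate"]
    if (length(subs) > 0 && config$n_groups >= 1) {
      p <- ifelse(sexes[subs] == "M", config$male_dispersal_prob,
                  config$female_dispersal_prob)
      movers <- subs[stats::runif(length(subs)) < p]
      dests <- character(0)
      for (m in movers) {
        from <- grp[m]
        others <- setdiff(groups, from)
        if (length(others) == 0) next
        to <- if (length(others) == 1) others else sample(others, 1)
        ind[[m]]$group <- to
        ind[[m]]$origin <- "immigrant"
        grp[m] <- to
        dests <- c(dests, to)
        switch_rows[[length(switch_rows) + 1L]] <- data.frame(
          id = m, sex = sexes[m], season = season, from_group = from,
          to_group = to, stringsAsFactors = FALSE)
      }
      ## outside immigrants: novel founders joining as subordinates
      n_out <- stats::rbinom(1, length(movers),
                             config$outside_immigrant_frac)
      if (n_out > 0) {
        for (j in seq_len(n_out)) {
          to <- if (length(groups) == 1) groups else sample(groups, 1)
          sex <- sample(c("M", "F"), 1, prob = c(0.75, 0.25))
          fg <- draw_founder()
          add_ind(new_id(), sex, to, "subordinate", NA_integer_, "immigrant",
                  NA_character_, fg$a1, fg$a2)
        }
      }
    }

    ## breeding; only individuals at least 2 seasons old are eligible
    ## (founders and outside immigrants count as old), matching the
    ## over-2-years field rule for candidate parents
    roles <- current("role"); sexes <- current("sex"); grp <- current("group")
    birth <- vapply(ind, function(x)
      if (is.na(x$birth_season) || x$birth_season == 0L) -10L
      else x$birth_season, integer(1))
    ids <- names(ind)
    for (g in groups) {
      members <- ids[grp == g]
      adults <- members[roles[members] %in% c("dominant", "subordinate") &
                          season - birth[members] >= 2L]
      af <- adults[sexes[adults] == "F"]
      am <- adults[sexes[adults] == "M"]
      if (length(af) == 0)
        stop(sprintf("no adult females in group %s at season %d", g, season))
      if (length(am) == 0)
        stop(sprintf("no adult males in group %s at season %d", g, season))
      dom_f <- adults[roles[adults] == "dominant" & sexes[adults] == "F"]
      dom_m <- adults[roles[adults] == "dominant" & sexes[adults] == "M"]
      sub_f <- setdiff(af, dom_f); sub_m <- setdiff(am, dom_m)
      n_litters <- max(1L, stats::rpois(1, config$litters_per_season_mean))
      for (lt in seq_len(n_litters)) {
        dam <- if (length(sub_f) > 0 &&
                   stats::runif(1) >= config$dominant_maternity_share) {
          if (length(sub_f) == 1) sub_f else sample(sub_f, 1)
        } else dom_f[1]
        sire <- if (length(sub_m) > 0 &&
                    stats::runif(1) >= config$dominant_paternity_share) {
          if (length(sub_m) == 1) sub_m else sample(sub_m, 1)
        } else dom_m[1]
        if (is.na(dam) || is.na(sire)) next  # group lost a dominant: skip
        litter_counter <- litter_counter + 1L
        litter_id <- sprintf("LIT%04d", litter_counter)
        n_pups <- max(1L, stats::rpois(1, config$litter_size_mean))
        for (p in seq_len(n_pups)) {
          pick <- stats::runif(config$n_loci) < 0.5
          a_dam <- ifelse(pick, geno1[[dam]], geno2[[dam]])
          pick <- stats::runif(config$n_loci) < 0.5
          a_sire <- ifelse(pick, geno1[[sire]], geno2[[sire]])
          add_ind(new_id(), sample(c("M", "F"), 1), g, "pup", season,
                  "natal", litter_id,
                  pmin(a_dam, a_sire), pmax(a_dam, a_sire),
                  dam = dam, sire = sire)
        }
      }
    }

    ## recruitment / pup survival (pups of earlier seasons mature)
    if (season < config$n_seasons) {
      roles <- current("role"); ids <- names(ind)
      pups <- ids[roles == "pup"]
      for (p in pups) {
        if (stats::runif(1) < config$pup_survival) {
          ind[[p]]$role <- "subordinate"
        } else {
          geno1[[p]] <- geno1[[p]]  # genotype kept; individual dies
          ind[[p]]$role <- "dead"
        }
      }
    }
  }

  ## assemble outputs, dropping dead individuals from the sampled population
  keep <- vapply(ind, function(x) x$role != "dead", logical(1))
  ind <- ind[keep]
  individuals <- do.call(rbind, lapply(ind, function(x)
    data.frame(id = x$id, sex = x$sex, group = x$group, role = x$role,
               birth_season = x$birth_season, origin = x$origin,
               litter_id = x$litter_id, stringsAsFactors = FALSE)))
  rownames(individuals) <- NULL
  ids <- individuals$id
  a1 <- do.call(rbind, geno1[ids]); a2 <- do.call(rbind, geno2[ids])
  loci <- sprintf("L%02d", seq_len(config$n_loci))
  gm <- genotype_matrix(a1, a2, ids, loci,
                        groups = individuals$group)
  # pedigree is the truth container: it records every individual ever born,
  # including pups that died before the sampled population was assembled
  pedigree <- data.frame(
    id = names(ped),
    dam = vapply(ped, `[[`, character(1), "dam"),
    sire = vapply(ped, `[[`, character(1), "sire"),
    stringsAsFactors = FALSE, row.names = NULL)

  switches <- if (length(switch_rows) > 0) do.call(rbind, switch_rows)
    else data.frame(id = character(), sex = character(), season = integer(),
                    from_group = character(), to_group = character(),
                    stringsAsFactors = FALSE)
  if (nrow(switches) > 0) {
    key <- paste(switches$season, switches$from_group, switches$to_group)
    switches$event_id <- match(key, unique(key))
    sizes <- table(switches$event_id)
    switches$coalition <- as.vector(sizes[as.character(switches$event_id)]) > 1
  } else {
    switches$event_id <- integer(0); switches$coalition <- logical(0)
  }

  structure(list(individuals = individuals, pedigree = pedigree,
                 switch_events = switches, true_genotypes = gm,
                 founder_freqs = freqs, config = config),
            class = "simulated_population")
}

#' @export
print.simulated_population <- function(x, ...) {
  cat(sprintf(
    "simulated_population: %d individuals, %d groups, %d loci, %d switches\n",
    nrow(x$individuals), length(unique(x$individuals$group)),
    length(x$true_genotypes$loci), nrow(x$switch_events)))
  invisible(x)
}

#' Simulate noisy faecal-DNA replicate genotypes
#'
#' Lays the genotyping error process over the true genotypes: per replicate
#' and locus the call fails wholly with `locus_failure_rate`; in surviving
#' heterozygous calls each allele independently drops out with
#' `dropout_rate` (leaving an apparent homozygote); with `false_allele_rate`
#' one allele is replaced by a uniformly chosen other allele of that locus.
#'
#' @param pop a [simulate_population()] result.
#' @param config a [sim_config()] (error rates and `n_replicates` used).
#' @return a [replicate_set()].
#' @export
simulate_replicates <- function(pop, config = pop$config) {
  stopifnot(inherits(pop, "simulated_population"),
            inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "replicates"))
  gm <- pop$true_genotypes
  n <- length(gm$individuals); L <- length(gm$loci)
  k <- config$alleles_per_locus
  calls <- vector("list", n)
  for (i in seq_len(n)) {
    R <- config$n_replicates
    a1 <- matrix(rep(gm$a1[i, ], each = R), R, L)
    a2 <- matrix(rep(gm$a2[i, ], each = R), R, L)
    fail <- matrix(stats::runif(R * L) < config$locus_failure_rate, R, L)
    het <- a1 != a2 & !fail
    d1 <- het & matrix(stats::runif(R * L) < config$dropout_rate, R, L)
    d2 <- het & matrix(stats::runif(R * L) < config$dropout_rate, R, L)
    both <- d1 & d2   # both dropping kills the call entirely
    a1[d2 & !both] <- a2[d2 & !both]   # allele 2 drops -> homozygote allele1
    a2[d1 & !both] <- a1[d1 & !both]
    fail <- fail | both
    fa <- matrix(stats::runif(R * L) < config$false_allele_rate, R, L) & !fail
    idx <- which(fa)
    if (length(idx) > 0 && k > 1) {
      for (j in idx) {
        which_allele <- stats::runif(1) < 0.5
        cur <- if (which_allele) a1[j] else a2[j]
        repl <- sample.int(k - 1L, 1L)
        repl <- if (repl >= cur) repl + 1L else repl
        if (which_allele) a1[j] <- repl else a2[j] <- repl
      }
    }
    a1[fail] <- NA_integer_; a2[fail] <- NA_integer_
    swap <- !is.na(a1) & a1 > a2
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
    sample_ids <- sprintf("%s_S%d", gm$individuals[i], seq_len(R))
    dimnames(a1) <- dimnames(a2) <- list(sample_ids, gm$loci)
    calls[[i]] <- list(a1 = a1, a2 = a2, sample_ids = sample_ids)
  }
  replicate_set(calls, gm$individuals, gm$loci)
}

#' Write simulator outputs as plain-text artifacts
#'
#' Emits `truth_genotypes.csv`, `replicates.csv`, `metadata.csv`,
#' `pedigree.csv`, `switch_events.csv` and `truth.gen` (GenePop) into a
#' directory.
#'
#' @param pop a [simulate_population()] result.
#' @param reps optional [replicate_set()] from [simulate_replicates()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(pop, reps = NULL, dir) {
  stopifnot(inherits(pop, "simulated_population"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(pop$true_genotypes, file.path(dir, "truth_genotypes.csv"))
  write_genepop(pop$true_genotypes, file.path(dir, "truth.gen"),
                title = "simulated truth genotypes")
  utils::write.csv(pop$individuals, file.path(dir, "metadata.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(pop$pedigree, file.path(dir, "pedigree.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(pop$switch_events, file.path(dir, "switch_events.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(reps)) write_replicates(reps, file.path(dir, "replicates.csv"))
  invisible(dir)
}
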