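#' Build candidate parent sets for pups
#'
#' Candidate mothers are same-group females recorded as pregnant within
#' `pregnancy_window_days` of the pup's birth. Candidate fathers are males
#' over `father_min_age_years` at conception (taken as birth date minus
#' `gestation_days`), drawn from the pup's group, or from the whole
#' population in `father_mode = "population"` (the extra-group paternity
#' robustness check).
#'
#' @param pups character vector of pup ids (must appear in `metadata`).
#' @param metadata data.frame with columns `id`, `sex`, `group`,
#'   `birth_date` (ISO date).
#' @param pregnancies data.frame with columns `female_id`, `date`.
#' @param pregnancy_window_days window around the pup's birth within which a
#'   pregnancy record qualifies a female (default 60, i.e. two months).
#' @param father_min_age_years minimum male age at conception (default 2).
#' @param gestation_days used to place conception before birth (default 50).
#' @param father_mode `"within_group"` (default) or `"population"`.
#' @return named list per pup: `mothers`, `fathers` (character vectors) and
#'   `rules` (provenance strings).
#' @export
build_candidates <- function(pups, metadata, pregnancies,
                             pregnancy_window_days = 60L,
                             father_min_age_years = 2,
                             gestation_days = 50L,
                             father_mode = c("within_group", "population")) {
  father_mode <- match.arg(father_mode)
  metadata$birth_date <- as.Date(metadata$birth_date)
  pregnancies$date <- as.Date(pregnancies$date)
  out <- list()
  for (p in pups) {
    row <- metadata[metadata$id == p, , drop = FALSE]
    if (nrow(row) != 1) stop("pup not in metadata: ", p)
    if (is.na(row$group) || !nzchar(row$group))
      stop("pup without group: ", p)
    born <- row$birth_date
    conception <- born - gestation_days
    females <- metadata[metadata$sex == "F" & metadata$id != p &
                          metadata$group == row$group, , drop = FALSE]
    preg_ok <- vapply(females$id, function(f) {
      d <- pregnancies$date[pregnancies$female_id == f]
      length(d) > 0 && any(abs(as.numeric(d - born)) <= pregnancy_window_days)
    }, logical(1))
    mothers <- females$id[preg_ok]
    male_pool <- metadata[metadata$sex == "M" & metadata$id != p, ,
                          drop = FALSE]
    if (father_mode == "within_group")
      male_pool <- male_pool[male_pool$group == row$group, , drop = FALSE]
    age_y <- as.numeric(conception - male_pool$birth_date) / 365.25
    fathers <- male_pool$id[!is.na(age_y) & age_y > father_min_age_years]
    out[[p]] <- list(
      mothers = mothers, fathers = fathers,
      rules = c(
        mothers = sprintf("same-group females pregnant within %d days of birth",
                          pregnancy_window_days),
        fathers = sprintf("%s males aged > %g years at conception",
                          if (father_mode == "within_group") "same-group"
                          else "population-wide", father_min_age_years)))
  }
  out
}

# P(parent genotype transmits allele v)
transmit_prob <- function(c1, c2, v) ((c1 == v) + (c2 == v)) / 2

# background HWE probability of the pup genotype at locus l
pup_background <- function(freqs, l, a, b) {
  pa <- freq_of(freqs, l, a); pb <- freq_of(freqs, l, b)
  if (a == b) pa^2 else 2 * pa * pb
}

#' LOD scores for candidate parents of one pup
#'
#' Per locus the likelihood that the candidate is a parent (Mendelian
#' transmission times a population draw for the other allele) is compared
#' with the likelihood that it is unrelated (the pup's Hardy-Weinberg
#' genotype probability). Mistyping at rate `error_rate` mixes the
#' transmission probability with the background: `T' = (1-e) T + e P(pup)`.
#' The LOD is the sum of log ratios over co-typed loci; parent-pair LODs use
#' the joint trio transmission probability, falling back to the
#' single-parent term at loci where only one candidate is typed. With
#' `error_rate = 0` an opposite-homozygote mismatch gives `-Inf` (a
#' Mendelian exclusion).
#'
#' @param x a [genotype_matrix()] containing the pup and all candidates.
#' @param pup pup id.
#' @param mothers,fathers candidate id vectors (either may be empty).
#' @param freqs an [allele_frequencies()] object.
#' @param error_rate per-locus mistyping rate in `[0, 1)` (default 0.05).
#' @return list with `mother_lod`, `father_lod` (named numeric),
#'   `pair_lod` (mothers x fathers matrix), `mother_mismatch`,
#'   `father_mismatch` (opposite-homozygote counts).
#' @export
lod_scores <- function(x, pup, mothers, fathers, freqs,
                       error_rate = 0.05) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  ip <- match(pup, x$individuals)
  if (is.na(ip)) stop("pup not genotyped: ", pup)
  single <- function(cand) {
    ic <- match(cand, x$individuals)
    lod <- 0; mism <- 0L; used <- 0L
    for (l in seq_along(x$loci)) {
      a <- x$a1[ip, l]; b <- x$a2[ip, l]
      c1 <- x$a1[ic, l]; c2 <- x$a2[ic, l]
      if (is.na(a) || is.na(c1)) next
      used <- used + 1L
      pa <- freq_of(freqs, l, a); pb <- freq_of(freqs, l, b)
      tr <- if (a == b) transmit_prob(c1, c2, a) * pa
            else transmit_prob(c1, c2, a) * pb + transmit_prob(c1, c2, b) * pa
      bg <- pup_background(freqs, l, a, b)
      if (tr == 0) mism <- mism + 1L
      tr <- (1 - error_rate) * tr + error_rate * bg
      lod <- lod + log(tr) - log(bg)
    }
    if (used == 0) lod <- NA_real_
    list(lod = lod, mismatch = mism)
  }
  m_res <- lapply(mothers, single); f_res <- lapply(fathers, single)
  mother_lod <- stats::setNames(vapply(m_res, `[[`, numeric(1), "lod"), mothers)
  father_lod <- stats::setNames(vapply(f_res, `[[`, numeric(1), "lod"), fathers)
  pair_lod <- matrix(NA_real_, length(mothers), length(fathers),
                     dimnames = list(mothers, fathers))
  for (m in seq_along(mothers)) for (f in seq_along(fathers)) {
    im <- match(mothers[m], x$individuals); iff <- match(fathers[f], x$individuals)
    lod <- 0; used <- 0L
    for (l in seq_along(x$loci)) {
      a <- x$a1[ip, l]; b <- x$a2[ip, l]
      if (is.na(a)) next
      m1 <- x$a1[im, l]; m2 <- x$a2[im, l]
      f1 <- x$a1[iff, l]; f2 <- x$a2[iff, l]
      bg <- pup_background(freqs, l, a, b)
      if (!is.na(m1) && !is.na(f1)) {
        tr <- if (a == b) transmit_prob(m1, m2, a) * transmit_prob(f1, f2, a)
              else transmit_prob(m1, m2, a) * transmit_prob(f1, f2, b) +
                   transmit_prob(m1, m2, b) * transmit_prob(f1, f2, a)
      } else if (!is.na(m1)) {
        pa <- freq_of(freqs, l, a); pb <- freq_of(freqs, l, b)
        tr <- if (a == b) transmit_prob(m1, m2, a) * pa
              else transmit_prob(m1, m2, a) * pb + transmit_prob(m1, m2, b) * pa
      } else if (!is.na(f1)) {
        pa <- freq_of(freqs, l, a); pb <- freq_of(freqs, l, b)
        tr <- if (a == b) transmit_prob(f1, f2, a) * pa
              else transmit_prob(f1, f2, a) * pb + transmit_prob(f1, f2, b) * pa
      } else next
      used <- used + 1L
      tr <- (1 - error_rate) * tr + error_rate * bg
      lod <- lod + log(tr) - log(bg)
    }
    pair_lod[m, f] <- if (used > 0) lod else NA_real_
  }
  list(mother_lod = mother_lod, father_lod = father_lod,
       pair_lod = pair_lod,
       mother_mismatch = stats::setNames(
         vapply(m_res, `[[`, integer(1), "mismatch"), mothers),
       father_mismatch = stats::setNames(
         vapply(f_res, `[[`, integer(1), "mismatch"), fathers))
}

#' Simulation parameters for parentage confidence
#'
#' Defaults mirror a faecal-DNA microsatellite study design: two candidate
#' parents of each sex, roughly half of true parents sampled, 91% of loci
#' typed, 5% of loci mistyped, a minimum of 7 typed loci, and 80% of
#' candidates related to the true parent at r = 0.31 (mothers) / 0.27
#' (fathers).
#'
#' @param n_candidate_mothers,n_candidate_fathers candidates per offspring.
#' @param prop_mothers_sampled,prop_fathers_sampled probability the true
#'   parent is among the candidates.
#' @param prop_loci_typed per-locus typing probability per individual.
#' @param error_rate per-locus mistyping probability (also used as the
#'   likelihood error model rate).
#' @param min_typed_loci individuals below this are dropped from a cycle.
#' @param prop_related_mothers,prop_related_fathers fraction of non-true
#'   candidates related to the true parent.
#' @param r_related_mothers,r_related_fathers target relatedness of related
#'   candidates, achieved by giving the candidate one allele from the true
#'   parent per locus with probability `2r` (a partial parent-offspring
#'   ancestry draw with expected relatedness r).
#' @param n_cycles Monte-Carlo cycles (default 10000).
#' @return list of class `conf_sim_params`.
#' @export
conf_sim_params <- function(n_candidate_mothers = 2L, n_candidate_fathers = 2L,
                            prop_mothers_sampled = 0.48,
                            prop_fathers_sampled = 0.47,
                            prop_loci_typed = 0.91, error_rate = 0.05,
                            min_typed_loci = 7L,
                            prop_related_mothers = 0.8,
                            prop_related_fathers = 0.8,
                            r_related_mothers = 0.31,
                            r_related_fathers = 0.27,
                            n_cycles = 10000L) {
  pars <- list(n_candidate_mothers = as.integer(n_candidate_mothers),
               n_candidate_fathers = as.integer(n_candidate_fathers),
               prop_mothers_sampled = prop_mothers_sampled,
               prop_fathers_sampled = prop_fathers_sampled,
               prop_loci_typed = prop_loci_typed, error_rate = error_rate,
               min_typed_loci = as.integer(min_typed_loci),
               prop_related_mothers = prop_related_mothers,
               prop_related_fathers = prop_related_fathers,
               r_related_mothers = r_related_mothers,
               r_related_fathers = r_related_fathers,
               n_cycles = as.integer(n_cycles))
  for (f in c("prop_mothers_sampled", "prop_fathers_sampled",
              "prop_loci_typed", "prop_related_mothers",
              "prop_related_fathers"))
    if (pars[[f]] < 0 || pars[[f]] > 1) stop(f, " must be in [0, 1]")
  if (pars$error_rate < 0 || pars$error_rate >= 1)
    stop("error_rate must be in [0, 1)")
  if (pars$r_related_mothers < 0 || pars$r_related_mothers > 0.5 ||
      pars$r_related_fathers < 0 || pars$r_related_fathers > 0.5)
    stop("related-candidate r must be in [0, 0.5]")
  structure(pars, class = "conf_sim_params")
}

# draw n HWE genotypes at all loci from an allele_frequencies object;
# returns list(a1, a2) integer matrices n x L
draw_hwe <- function(n, freqs) {
  L <- length(freqs$freqs)
  a1 <- a2 <- matrix(NA_integer_, n, L)
  for (l in seq_len(L)) {
    f <- freqs$freqs[[l]]
    lab <- as.integer(names(f))
    a1[, l] <- sample(lab, n, replace = TRUE, prob = f)
    a2[, l] <- sample(lab, n, replace = TRUE, prob = f)
  }
  list(a1 = pmin(a1, a2), a2 = pmax(a1, a2))
}

# offspring of (d1,d2) x (s1,s2) row vectors over L loci
mendel_child <- function(d1, d2, s1, s2) {
  L <- length(d1)
  fromd <- ifelse(stats::runif(L) < 0.5, d1, d2)
  froms <- ifelse(stats::runif(L) < 0.5, s1, s2)
  list(a1 = pmin(fromd, froms), a2 = pmax(fromd, froms))
}

# candidate related to parent (p1,p2) at target r: per locus, with
# probability 2r the candidate carries one allele drawn from the parent
# (expected r of a parent-offspring dyad is 0.5, so mixing at 2r gives r)
related_candidate <- function(p1, p2, r, freqs) {
  L <- length(p1)
  base <- draw_hwe(1, freqs)
  share <- stats::runif(L) < 2 * r
  fromp <- ifelse(stats::runif(L) < 0.5, p1, p2)
  a1 <- ifelse(share, fromp, base$a1[1, ])
  a2 <- base$a2[1, ]
  list(a1 = pmin(a1, a2), a2 = pmax(a1, a2))
}

#' Calibrate delta confidence thresholds by simulation
#'
#' Monte-Carlo cycles generate a true family from the allele frequencies,
#' build candidate sets per the sampling/relatedness parameters, degrade the
#' genotypes (typing rate, mistyping), score all candidate parent pairs with
#' [lod_scores()], and record the delta (top minus second pair LOD) together
#' with whether the top pair is the true parent pair. The strict (95%) and
#' relaxed (80%) thresholds are the smallest deltas at which the assignments
#' above them reach that reliability; `Inf` when unattainable under the
#' stated sampling fractions.
#'
#' @param freqs an [allele_frequencies()] object (the study panel).
#' @param params a [conf_sim_params()] object.
#' @param seed RNG seed.
#' @return list of class `conf_thresholds`: `strict`, `relaxed`,
#'   `assignment_rate_strict`, `assignment_rate_relaxed`, `params`,
#'   `n_cycles`, `seed`, `deltas`, `correct`.
#' @export
simulate_confidence <- function(freqs, params = conf_sim_params(), seed = 1L) {
  stopifnot(inherits(freqs, "allele_frequencies"),
            inherits(params, "conf_sim_params"))
  set.seed(seed)
  L <- length(freqs$freqs)
  n_cyc <- params$n_cycles
  deltas <- rep(NA_real_, n_cyc); correct <- rep(FALSE, n_cyc)
  degrade <- function(a1, a2) {
    typed <- stats::runif(L) < params$prop_loci_typed
    mistype <- stats::runif(L) < params$error_rate
    if (any(mistype)) {
      g <- draw_hwe(1, freqs)
      a1[mistype] <- g$a1[1, mistype]; a2[mistype] <- g$a2[1, mistype]
    }
    a1[!typed] <- NA_integer_; a2[!typed] <- NA_integer_
    list(a1 = a1, a2 = a2, n_typed = sum(typed))
  }
  for (cyc in seq_len(n_cyc)) {
    dam <- draw_hwe(1, freqs); sire <- draw_hwe(1, freqs)
    pup <- mendel_child(dam$a1[1, ], dam$a2[1, ], sire$a1[1, ], sire$a2[1, ])
    make_cands <- function(truth, n_cand, p_sampled, p_rel, r_rel) {
      cands <- list(); truth_in <- stats::runif(1) < p_sampled
      if (truth_in) cands[[1]] <- list(a1 = truth$a1[1, ], a2 = truth$a2[1, ])
      while (length(cands) < n_cand) {
        cands[[length(cands) + 1L]] <-
          if (stats::runif(1) < p_rel)
            related_candidate(truth$a1[1, ], truth$a2[1, ], r_rel, freqs)
          else { g <- draw_hwe(1, freqs); list(a1 = g$a1[1, ], a2 = g$a2[1, ]) }
      }
      list(cands = cands, truth_idx = if (truth_in) 1L else NA_integer_)
    }
    cm <- make_cands(dam, params$n_candidate_mothers,
                     params$prop_mothers_sampled,
                     params$prop_related_mothers, params$r_related_mothers)
    cf <- make_cands(sire, params$n_candidate_fathers,
                     params$prop_fathers_sampled,
                     params$prop_related_fathers, params$r_related_fathers)
    pup_d <- degrade(pup$a1, pup$a2)
    if (pup_d$n_typed < params$min_typed_loci) next
    keep_m <- keep_f <- c()
    dm <- lapply(cm$cands, function(g) degrade(g$a1, g$a2))
    df <- lapply(cf$cands, function(g) degrade(g$a1, g$a2))
    keep_m <- which(vapply(dm, `[[`, integer(1), "n_typed") >=
                      params$min_typed_loci)
    keep_f <- which(vapply(df, `[[`, integer(1), "n_typed") >=
                      params$min_typed_loci)
    if (length(keep_m) == 0 || length(keep_f) == 0) next
    ids <- c("pup",
             paste0("M", keep_m), paste0("F", keep_f))
    a1 <- rbind(pup_d$a1,
                do.call(rbind, lapply(dm[keep_m], `[[`, "a1")),
                do.call(rbind, lapply(df[keep_f], `[[`, "a1")))
    a2 <- rbind(pup_d$a2,
                do.call(rbind, lapply(dm[keep_m], `[[`, "a2")),
                do.call(rbind, lapply(df[keep_f], `[[`, "a2")))
    gm <- genotype_matrix(a1, a2, ids, freqs$loci)
    sc <- lod_scores(gm, "pup", paste0("M", keep_m), paste0("F", keep_f),
                     freqs, error_rate = params$error_rate)
    pl <- sc$pair_lod
    ord <- order(pl, decreasing = TRUE, na.last = NA)
    if (length(ord) == 0) next
    top <- ord[1]
    d <- if (length(ord) >= 2) pl[top] - pl[ord[2]]
         else max(pl[top], 0)
    deltas[cyc] <- d
    tm <- arrayInd(top, dim(pl))
    correct[cyc] <- !is.na(cm$truth_idx) && !is.na(cf$truth_idx) &&
      keep_m[tm[1]] == cm$truth_idx && keep_f[tm[2]] == cf$truth_idx
  }
  ok <- !is.na(deltas)
  d_ok <- deltas[ok]; c_ok <- correct[ok]
  cutoff_for <- function(level) {
    cand_d <- sort(unique(c(0, d_ok)))
    for (d in cand_d) {
      sel <- d_ok >= d
      if (sum(sel) > 0 && mean(c_ok[sel]) >= level)
        return(list(cut = d, rate = sum(sel & c_ok) / length(d_ok)))
    }
    list(cut = Inf, rate = 0)
  }
  relaxed <- cutoff_for(0.80); strict <- cutoff_for(0.95)
  structure(list(strict = strict$cut, relaxed = relaxed$cut,
                 assignment_rate_strict = strict$rate,
                 assignment_rate_relaxed = relaxed$rate,
                 params = params, n_cycles = n_cyc, seed = seed,
                 deltas = deltas, correct = correct),
            class = "conf_thresholds")
}

#' @export
print.conf_thresholds <- function(x, ...) {
  cat(sprintf(
    "confidence thresholds (%d cycles): strict (95%%) = %.3f, relaxed (80%%) = %.3f\n",
    x$n_cycles, x$strict, x$relaxed))
  invisible(x)
}

#' Assign parentage from LOD scores and calibrated thresholds
#'
#' Picks the top parent pair by joint LOD; delta is the gap to the second
#' pair (a sole pair's delta is its LOD when positive, else 0). The
#' confidence tier is `"95%"` when delta meets the strict cutoff, `"80%"`
#' at the relaxed cutoff, else `"none"`. Ties are broken by fewer total
#' mismatches, then lexically by (mother, father) id. Pairs with `-Inf`
#' LOD (Mendelian exclusion under a zero error rate) are never assigned.
#'
#' @param lods a [lod_scores()] result for one pup.
#' @param thresholds a `conf_thresholds` object (or a list with `strict`,
#'   `relaxed`).
#' @param pup pup id carried through to the output.
#' @return one-row data.frame: pup, mother, father, pair_lod, delta,
#'   confidence, mother_mismatch, father_mismatch, note.
#' @export
assign_parentage <- function(lods, thresholds, pup = NA_character_) {
  pl <- lods$pair_lod
  empty <- function(note) data.frame(
    pup = pup, mother = NA_character_, father = NA_character_,
    pair_lod = NA_real_, delta = NA_real_, confidence = "none",
    mother_mismatch = NA_integer_, father_mismatch = NA_integer_,
    note = note, stringsAsFactors = FALSE)
  if (length(pl) == 0 || all(is.na(pl) | pl == -Inf))
    return(empty("no scorable candidate pair"))
  mism <- outer(lods$mother_mismatch, lods$father_mismatch, `+`)
  ord <- order(pl, -mism, decreasing = TRUE, na.last = NA)
  ## refine ties deterministically: lod desc, mismatches asc, ids lexical
  key <- order(-pl[ord], mism[ord],
               rownames(pl)[arrayInd(ord, dim(pl))[, 1]],
               colnames(pl)[arrayInd(ord, dim(pl))[, 2]])
  ord <- ord[key]
  ord <- ord[pl[ord] > -Inf]
  if (length(ord) == 0) return(empty("all candidate pairs excluded"))
  top <- ord[1]
  delta <- if (length(ord) >= 2) pl[top] - pl[ord[2]] else max(pl[top], 0)
  tm <- arrayInd(top, dim(pl))
  conf <- if (delta >= thresholds$strict) "95%"
          else if (delta >= thresholds$relaxed) "80%" else "none"
  data.frame(pup = pup, mother = rownames(pl)[tm[1]],
             father = colnames(pl)[tm[2]],
             pair_lod = pl[top], delta = delta, confidence = conf,
             mother_mismatch = unname(lods$mother_mismatch[tm[1]]),
             father_mismatch = unname(lods$father_mismatch[tm[2]]),
             note = "", stringsAsFactors = FALSE)
}

#' Reproductive-skew summary from parentage assignments
#'
#' Tallies assigned pups by parent role and reports dominant shares, plus
#' the composition of co-parent pairs (both dominant / mixed / both
#' subordinate).
#'
#' @param assignments data.frame as returned by rbind-ing
#'   [assign_parentage()] rows.
#' @param roles data.frame with `id`, `role` (`dominant`/`subordinate`),
#'   roles at the pup's conception.
#' @param min_confidence lowest tier counted (`"80%"` by default; use
#'   `"none"` to count all top assignments).
#' @return list with `maternity`, `paternity` (counts + percentage tables)
#'   and `pair_composition`.
#' @export
skew_summary <- function(assignments, roles, min_confidence = "80%") {
  lvl <- c(none = 0, `80%` = 1, `95%` = 2)
  keep <- lvl[assignments$confidence] >= lvl[[min_confidence]]
  a <- assignments[keep & !is.na(assignments$mother), , drop = FALSE]
  role_of <- stats::setNames(roles$role, roles$id)
  tab <- function(ids) {
    r <- role_of[ids]
    n_dom <- sum(r == "dominant", na.rm = TRUE)
    n_sub <- sum(r == "subordinate", na.rm = TRUE)
    n <- n_dom + n_sub
    list(n = n, dominant = n_dom, subordinate = n_sub,
         dominant_pct = if (n > 0) 100 * n_dom / n else NA_real_,
         subordinate_pct = if (n > 0) 100 * n_sub / n else NA_real_)
  }
  mat <- tab(a$mother)
  pat <- tab(a$father[!is.na(a$father)])
  comp <- table(factor(paste0(
    ifelse(role_of[a$mother] == "dominant", "domF", "subF"), "_",
    ifelse(role_of[a$father] == "dominant", "domM", "subM")),
    levels = c("domF_domM", "domF_subM", "subF_domM", "subF_subM")))
  list(maternity = mat, paternity = pat, pair_composition = comp)
}
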