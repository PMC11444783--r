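#' Queller-Goodnight pairwise relatedness
#'
#' For an ordered pair (x -> y) and locus with reference allele frequencies
#' `p`, the locus contribution is
#' `num = 0.5 * (I(x1=y1) + I(x1=y2) + I(x2=y1) + I(x2=y2)) - p(x1) - p(x2)`
#' and `den = 1 + I(x1=x2) - p(x1) - p(x2)`; the directed estimate is the
#' ratio of sums over loci typed in both individuals, and the reported r is
#' the mean of the two directions. Reference frequencies default to the full
#' filtered sample including the focal pair; set `exclude_pair = TRUE` to
#' recompute frequencies leaving each pair out.
#'
#' @param x a [genotype_matrix()], normally pre-filtered with
#'   [filter_min_loci()].
#' @param freqs an [allele_frequencies()] object; computed from `x` when
#'   `NULL`.
#' @param exclude_pair recompute reference frequencies excluding the focal
#'   pair (slower; default `FALSE`, the GenAlEx-style behaviour).
#' @return a list of class `relatedness_matrix`: `r` (symmetric numeric
#'   matrix, `NA` diagonal and excluded pairs), `excluded` (logical matrix),
#'   `freqs`.
#' @export
qg_relatedness <- function(x, freqs = NULL, exclude_pair = FALSE) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (is.null(freqs)) freqs <- allele_frequencies(x)
  n <- length(x$individuals); L <- length(x$loci)
  r <- matrix(NA_real_, n, n, dimnames = list(x$individuals, x$individuals))
  excluded <- matrix(FALSE, n, n, dimnames = dimnames(r))
  # per-locus frequency of each individual's own alleles
  pa1 <- pa2 <- matrix(NA_real_, n, L)
  for (l in seq_len(L)) {
    pa1[, l] <- freq_of(freqs, l, x$a1[, l])
    pa2[, l] <- freq_of(freqs, l, x$a2[, l])
  }
  pa1[is.na(x$a1)] <- NA; pa2[is.na(x$a1)] <- NA
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      ok <- !is.na(x$a1[i, ]) & !is.na(x$a1[j, ])
      if (!any(ok)) { excluded[i, j] <- excluded[j, i] <- TRUE; next }
      fq <- freqs
      if (exclude_pair) {
        fq <- allele_frequencies(x[-c(i, j), ])
      }
      s <- qg_pair(x, i, j, ok, fq)
      if (is.na(s)) { excluded[i, j] <- excluded[j, i] <- TRUE; next }
      r[i, j] <- r[j, i] <- s
    }
  }
  structure(list(r = r, excluded = excluded, freqs = freqs),
            class = "relatedness_matrix")
}

# one symmetrized QG estimate; ok = loci typed in both
qg_pair <- function(x, i, j, ok, freqs) {
  num_ij <- den_ij <- num_ji <- den_ji <- 0
  for (l in which(ok)) {
    xi <- c(x$a1[i, l], x$a2[i, l]); yj <- c(x$a1[j, l], x$a2[j, l])
    sh <- 0.5 * (sum(xi[1] == yj) + sum(xi[2] == yj))
    pxi <- freq_of(freqs, l, xi)
    pyj <- freq_of(freqs, l, yj)
    num_ij <- num_ij + sh - sum(pxi)
    den_ij <- den_ij + 1 + (xi[1] == xi[2]) - sum(pxi)
    num_ji <- num_ji + sh - sum(pyj)
    den_ji <- den_ji + 1 + (yj[1] == yj[2]) - sum(pyj)
  }
  if (den_ij == 0 || den_ji == 0) {
    warning("zero denominator sum for a pair; excluded")
    return(NA_real_)
  }
  (num_ij / den_ij + num_ji / den_ji) / 2
}

#' @export
print.relatedness_matrix <- function(x, ...) {
  v <- x$r[upper.tri(x$r)]
  cat(sprintf("relatedness_matrix: %d individuals; mean r = %.3f (%d excluded pairs)\n",
              nrow(x$r), mean(v, na.rm = TRUE), sum(is.na(v))))
  invisible(x)
}

#' Queller-Goodnight relatedness for specified pairs only
#'
#' Same estimator as [qg_relatedness()] but evaluated only at the requested
#' index pairs, which is much cheaper when a full matrix is not needed
#' (e.g. scoring thousands of simulated dyads).
#'
#' @param x a [genotype_matrix()].
#' @param pairs two-column matrix of individual indices or ids.
#' @param freqs an [allele_frequencies()] object; computed from `x` when
#'   `NULL`.
#' @return numeric vector of r values (NA where undefined).
#' @export
qg_pairwise <- function(x, pairs, freqs = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (is.null(freqs)) freqs <- allele_frequencies(x)
  if (is.character(pairs))
    pairs <- matrix(match(pairs, x$individuals), ncol = 2)
  pairs <- as.matrix(pairs)
  if (is.character(pairs[1, 1]))
    pairs <- apply(pairs, 2, match, x$individuals)
  vapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    ok <- !is.na(x$a1[i, ]) & !is.na(x$a1[j, ])
    if (!any(ok)) return(NA_real_)
    qg_pair(x, i, j, ok, freqs)
  }, numeric(1))
}

#' Within-group relatedness by role class
#'
#' Averages pairwise r over within-group dyads per role-pair class. Roles
#' must be one of `dominant`, `subordinate`, `pup`. Classes reported:
#' `dominant_pair` (dominant M x dominant F), `subF_subF`, `subM_subM`,
#' `domM_pup`, `domF_pup`, `sub_pup`, `pup_pup`, and `within_litter` when a
#' `litter_id` column is present.
#'
#' @param rel a [qg_relatedness()] result.
#' @param roles data.frame with columns `id`, `sex` (`"M"`/`"F"`), `group`,
#'   `role`, optionally `litter_id`.
#' @return data.frame with class, n_pairs, mean_r.
#' @export
class_relatedness <- function(rel, roles) {
  stopifnot(inherits(rel, "relatedness_matrix"))
  ids <- rownames(rel$r)
  roles <- roles[roles$id %in% ids, , drop = FALSE]
  idx <- stats::setNames(match(roles$id, ids), roles$id)
  pair_mean <- function(ids_a, ids_b, same_set = FALSE) {
    vals <- c()
    for (a in ids_a) for (b in ids_b) {
      if (a == b) next
      if (same_set && a > b) next
      vals <- c(vals, rel$r[idx[a], idx[b]])
    }
    vals <- vals[!is.na(vals)]
    c(n = length(vals), mean = if (length(vals)) mean(vals) else NA_real_)
  }
  out <- list()
  add <- function(class, v)
    out[[length(out) + 1L]] <<- data.frame(class = class, n_pairs = v["n"],
                                           mean_r = v["mean"],
                                           stringsAsFactors = FALSE)
  agg <- function(class, f) {
    tot <- c(n = 0, mean = NA_real_); acc <- c();
    for (g in unique(roles$group)) {
      rg <- roles[roles$group == g, , drop = FALSE]
      v <- f(rg)
      if (!is.null(v) && v["n"] > 0) acc <- c(acc, rep(v["mean"], v["n"]))
    }
    add(class, c(n = length(acc),
                 mean = if (length(acc)) mean(acc) else NA_real_))
  }
  agg("dominant_pair", function(rg) {
    dm <- rg$id[rg$role == "dominant" & rg$sex == "M"]
    df <- rg$id[rg$role == "dominant" & rg$sex == "F"]
    if (length(dm) && length(df)) pair_mean(dm, df) else NULL
  })
  agg("subF_subF", function(rg) {
    s <- rg$id[rg$role == "subordinate" & rg$sex == "F"]
    if (length(s) > 1) pair_mean(s, s, same_set = TRUE) else NULL
  })
  agg("subM_subM", function(rg) {
    s <- rg$id[rg$role == "subordinate" & rg$sex == "M"]
    if (length(s) > 1) pair_mean(s, s, same_set = TRUE) else NULL
  })
  agg("domM_pup", function(rg) {
    d <- rg$id[rg$role == "dominant" & rg$sex == "M"]
    p <- rg$id[rg$role == "pup"]
    if (length(d) && length(p)) pair_mean(d, p) else NULL
  })
  agg("domF_pup", function(rg) {
    d <- rg$id[rg$role == "dominant" & rg$sex == "F"]
    p <- rg$id[rg$role == "pup"]
    if (length(d) && length(p)) pair_mean(d, p) else NULL
  })
  agg("sub_pup", function(rg) {
    s <- rg$id[rg$role == "subordinate"]
    p <- rg$id[rg$role == "pup"]
    if (length(s) && length(p)) pair_mean(s, p) else NULL
  })
  agg("pup_pup", function(rg) {
    p <- rg$id[rg$role == "pup"]
    if (length(p) > 1) pair_mean(p, p, same_set = TRUE) else NULL
  })
  if ("litter_id" %in% names(roles)) {
    acc <- c()
    for (lt in unique(stats::na.omit(roles$litter_id))) {
      p <- roles$id[!is.na(roles$litter_id) & roles$litter_id == lt]
      if (length(p) > 1) {
        v <- pair_mean(p, p, same_set = TRUE)
        if (v["n"] > 0) acc <- c(acc, rep(v["mean"], v["n"]))
      }
    }
    add("within_litter", c(n = length(acc),
                           mean = if (length(acc)) mean(acc) else NA_real_))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Breeder-pair permutation test
#'
#' Tests whether dominant breeding pairs are less related than expected if
#' dominants paired randomly with opposite-sex adult groupmates. Observed
#' statistic: mean r over the actual dominant pairs. Each permutation
#' replaces every dominant's partner with one uniformly drawn opposite-sex
#' adult groupmate with defined r, and records the across-group mean; the
#' one-tailed p-value is `(1 + #{null <= observed}) / (n + 1)`. Pups are
#' never candidate partners.
#'
#' @param rel a [qg_relatedness()] result.
#' @param roles data.frame with `id`, `sex`, `group`, `role`.
#' @param n number of permutations (default 1000).
#' @param seed RNG seed.
#' @param include_partner keep the actual partner in the candidate pool
#'   (default `TRUE`: the observed pairing is one of the drawable pairings,
#'   which keeps the permutation p-value exact under exchangeability). Set
#'   `FALSE` to draw only among alternative partners.
#' @return a list of class `permutation_test`: `observed`, `null`
#'   (length-`n` numeric), `p`, `n_permutations`, `seed`,
#'   `n_groups_used`.
#' @export
breeder_permutation_test <- function(rel, roles, n = 1000L, seed = 1L,
                                     include_partner = TRUE) {
  stopifnot(inherits(rel, "relatedness_matrix"))
  ids <- rownames(rel$r)
  roles <- roles[roles$id %in% ids, , drop = FALSE]
  obs_pairs <- list(); cand <- list()
  for (g in unique(roles$group)) {
    rg <- roles[roles$group == g, , drop = FALSE]
    dm <- rg$id[rg$role == "dominant" & rg$sex == "M"]
    df <- rg$id[rg$role == "dominant" & rg$sex == "F"]
    if (length(dm) != 1 || length(df) != 1) next
    if (is.na(rel$r[dm, df])) next
    adults <- rg[rg$role != "pup", , drop = FALSE]
    # candidate partners per dominant: opposite-sex adult groupmates with
    # defined r to the dominant
    cm <- adults$id[adults$sex == "F" & adults$id != df]
    cm <- cm[!is.na(rel$r[dm, cm])]
    cf <- adults$id[adults$sex == "M" & adults$id != dm]
    cf <- cf[!is.na(rel$r[df, cf])]
    if (include_partner) {
      cm <- unique(c(cm, df)); cf <- unique(c(cf, dm))
    }
    if (length(cm) == 0 && length(cf) == 0) {
      warning("group ", g, ": no eligible opposite-sex groupmates; excluded")
      next
    }
    obs_pairs[[g]] <- c(dm = dm, df = df)
    cand[[g]] <- list(dm = dm, df = df, for_dm = cm, for_df = cf)
  }
  if (length(obs_pairs) == 0)
    stop("no group has a dominant pair with eligible partners")
  observed <- mean(vapply(obs_pairs, function(p) rel$r[p["dm"], p["df"]],
                          numeric(1)))
  set.seed(seed)
  null <- numeric(n)
  for (b in seq_len(n)) {
    vals <- c()
    for (g in names(cand)) {
      cc <- cand[[g]]
      if (length(cc$for_dm) > 0) {
        pick <- if (length(cc$for_dm) == 1) cc$for_dm
                else sample(cc$for_dm, 1)
        vals <- c(vals, rel$r[cc$dm, pick])
      }
      if (length(cc$for_df) > 0) {
        pick <- if (length(cc$for_df) == 1) cc$for_df
                else sample(cc$for_df, 1)
        vals <- c(vals, rel$r[cc$df, pick])
      }
    }
    null[b] <- mean(vals)
  }
  p <- (1 + sum(null <= observed)) / (n + 1)
  structure(list(observed = observed, null = null, p = p,
                 n_permutations = n, seed = seed,
                 n_groups_used = length(obs_pairs)),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("permutation test: observed = %.4f, p = %.4g (%d permutations)\n",
              x$observed, x$p, x$n_permutations))
  invisible(x)
}

#' Mean between-group relatedness matrix
#'
#' @param rel a [qg_relatedness()] result.
#' @param groups named id -> group map.
#' @return symmetric group x group matrix of mean cross-group pairwise r
#'   (diagonal: mean within-group r).
#' @export
between_group_relatedness <- function(rel, groups) {
  stopifnot(inherits(rel, "relatedness_matrix"))
  ids <- rownames(rel$r)
  g <- groups[ids]
  glev <- sort(unique(g))
  if (length(glev) < 2) stop("need >= 2 groups")
  out <- matrix(NA_real_, length(glev), length(glev),
                dimnames = list(glev, glev))
  for (i in seq_along(glev)) for (j in seq_along(glev)) {
    if (j < i) next
    block <- rel$r[g == glev[i], g == glev[j], drop = FALSE]
    if (i == j) {
      v <- block[upper.tri(block)]
    } else v <- as.vector(block)
    v <- v[!is.na(v)]
    out[i, j] <- out[j, i] <- if (length(v)) mean(v) else NA_real_
  }
  out
}

#' Mantel test between two square matrices
#'
#' Pearson correlation of the off-diagonal upper-triangle entries, with a
#' null built by simultaneous row/column permutation of the second matrix.
#'
#' @param m1,m2 symmetric numeric matrices of identical dimension (>= 3).
#' @param n_perm permutations (default 999).
#' @param seed RNG seed.
#' @param alternative `"two.sided"` (default, on `|r|`) or `"greater"`.
#' @return list with `r`, `p`, `n_perm`, `null`.
#' @export
mantel_test <- function(m1, m2, n_perm = 999L, seed = 1L,
                        alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (!all(dim(m1) == dim(m2)) || nrow(m1) != ncol(m1))
    stop("matrices must be square and of identical shape")
  if (nrow(m1) < 3) stop("need >= 3 rows")
  ut <- upper.tri(m1)
  v1 <- m1[ut]; v2 <- m2[ut]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("zero variance in off-diagonal entries; Mantel statistic undefined")
  r_obs <- stats::cor(v1, v2)
  set.seed(seed)
  null <- numeric(n_perm)
  n <- nrow(m1)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    null[b] <- stats::cor(v1, m2[perm, perm][ut])
  }
  hits <- if (alternative == "two.sided") sum(abs(null) >= abs(r_obs))
          else sum(null >= r_obs)
  list(r = r_obs, p = (1 + hits) / (n_perm + 1), n_perm = n_perm, null = null)
}
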