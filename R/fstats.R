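#' Hierarchical F-statistics over social groups
#'
#' Nei's heterozygosity formulation. Per locus, with groups weighted by the
#' number of typed individuals: `H_O` is the weighted mean observed
#' heterozygosity, `H_S` the weighted mean within-group expected
#' heterozygosity, `H_T` the expected heterozygosity of the sample-size
#' weighted pooled allele frequencies. Then `F_IS = (H_S - H_O)/H_S`,
#' `F_ST = (H_T - H_S)/H_T`, `F_IT = (H_T - H_O)/H_T`, so the identity
#' `(1 - F_IT) = (1 - F_IS)(1 - F_ST)` holds exactly per locus. Overall
#' statistics are formed from across-locus mean components.
#'
#' A locus with `H_S = 0` has undefined `F_IS` and is excluded from the
#' overall `F_IS`/`F_IT` components with a warning.
#'
#' @param x a [genotype_matrix()].
#' @param groups named character vector mapping individual id to group; by
#'   default taken from `x$groups`.
#' @param correction apply the `2n/(2n-1)` small-sample correction to
#'   within-group expected heterozygosity (default `TRUE`).
#' @return a list of class `fstats_result`: `per_locus` data.frame (H_O,
#'   H_S, H_T, F_IS, F_ST, F_IT) and `overall` named numeric.
#' @export
f_statistics <- function(x, groups = x$groups, correction = TRUE) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (is.null(groups)) stop("group labels required")
  groups <- groups[x$individuals]
  if (anyNA(groups)) stop("every individual needs a group label")
  glev <- unique(groups)
  per <- lapply(seq_along(x$loci), function(l) {
    a1 <- x$a1[, l]; a2 <- x$a2[, l]
    keep <- !is.na(a1)
    g <- groups[keep]; a1 <- a1[keep]; a2 <- a2[keep]
    use <- names(which(table(g) >= 2))
    sel <- g %in% use
    g <- g[sel]; a1 <- a1[sel]; a2 <- a2[sel]
    if (length(unique(g)) < 2)
      return(data.frame(locus = x$loci[l], H_O = NA_real_, H_S = NA_real_,
                        H_T = NA_real_, F_IS = NA_real_, F_ST = NA_real_,
                        F_IT = NA_real_))
    n_g <- table(g)[unique(g)]
    w <- as.numeric(n_g) / sum(n_g)
    ho_g <- he_g <- numeric(length(n_g))
    alleles <- sort(unique(c(a1, a2)))
    pool <- rep(0, length(alleles)); names(pool) <- alleles
    for (i in seq_along(n_g)) {
      gi <- names(n_g)[i]
      b1 <- a1[g == gi]; b2 <- a2[g == gi]
      n <- length(b1)
      ho_g[i] <- mean(b1 != b2)
      pg <- table(factor(c(b1, b2), levels = alleles)) / (2 * n)
      he <- 1 - sum(pg^2)
      if (correction) he <- (2 * n / (2 * n - 1)) * he
      he_g[i] <- he
      pool <- pool + w[i] * as.numeric(pg)
    }
    H_O <- sum(w * ho_g); H_S <- sum(w * he_g); H_T <- 1 - sum(pool^2)
    F_IS <- if (H_S > 0) (H_S - H_O) / H_S else NA_real_
    F_ST <- if (H_T > 0) (H_T - H_S) / H_T else NA_real_
    F_IT <- if (H_T > 0) (H_T - H_O) / H_T else NA_real_
    data.frame(locus = x$loci[l], H_O = H_O, H_S = H_S, H_T = H_T,
               F_IS = F_IS, F_ST = F_ST, F_IT = F_IT,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  und <- !is.na(per$H_S) & per$H_S == 0
  if (any(und))
    warning("F_IS undefined (H_S = 0) at loci: ",
            paste(per$locus[und], collapse = ", "))
  ok <- stats::complete.cases(per[, c("H_O", "H_S", "H_T")]) &
    per$H_T > 0 & per$H_S > 0
  mo <- colMeans(per[ok, c("H_O", "H_S", "H_T"), drop = FALSE])
  overall <- c(
    H_O = unname(mo["H_O"]), H_S = unname(mo["H_S"]), H_T = unname(mo["H_T"]),
    F_IS = unname((mo["H_S"] - mo["H_O"]) / mo["H_S"]),
    F_ST = unname((mo["H_T"] - mo["H_S"]) / mo["H_T"]),
    F_IT = unname((mo["H_T"] - mo["H_O"]) / mo["H_T"]))
  structure(list(per_locus = per, overall = overall,
                 correction = correction),
            class = "fstats_result")
}

#' @export
print.fstats_result <- function(x, ...) {
  cat("F-statistics (Nei heterozygosity formulation)\n")
  print(round(x$overall, 4))
  invisible(x)
}

#' Permutation significance for F_ST and F_IS
#'
#' `F_ST` null: permute individuals among groups (upper tail). `F_IS` null:
#' permute the alleles of each group's gene pool among its individuals
#' (two-sided, on the absolute deviation). p-values use the add-one rule
#' `(1 + hits)/(n_perm + 1)`.
#'
#' @param x a [genotype_matrix()].
#' @param groups named id -> group map (default `x$groups`).
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed.
#' @param correction passed to [f_statistics()].
#' @return list with `observed`, `p_fst`, `p_fis`, `n_perm`, and the null
#'   vectors `null_fst`, `null_fis`.
#' @export
fstat_permutation <- function(x, groups = x$groups, n_perm = 999L,
                              seed = 1L, correction = TRUE) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  obs <- f_statistics(x, groups, correction = correction)$overall
  groups <- groups[x$individuals]
  set.seed(seed)
  null_fst <- null_fis <- numeric(n_perm)
  n <- length(x$individuals)
  for (b in seq_len(n_perm)) {
    ## F_ST: shuffle group labels over individuals
    gs <- stats::setNames(sample(unname(groups)), x$individuals)
    null_fst[b] <- suppressWarnings(
      f_statistics(x, gs, correction = correction)$overall["F_ST"])
    ## F_IS: shuffle alleles among individuals within each group
    xp <- x
    for (l in seq_along(x$loci)) {
      for (g in unique(groups)) {
        idx <- which(groups == g & !is.na(x$a1[, l]))
        if (length(idx) < 2) next
        pool <- sample(c(x$a1[idx, l], x$a2[idx, l]))
        m <- length(idx)
        v1 <- pool[seq_len(m)]; v2 <- pool[m + seq_len(m)]
        xp$a1[idx, l] <- pmin(v1, v2); xp$a2[idx, l] <- pmax(v1, v2)
      }
    }
    null_fis[b] <- suppressWarnings(
      f_statistics(xp, groups, correction = correction)$overall["F_IS"])
  }
  p_fst <- (1 + sum(null_fst >= obs["F_ST"], na.rm = TRUE)) / (n_perm + 1)
  p_fis <- (1 + sum(abs(null_fis) >= abs(obs["F_IS"]), na.rm = TRUE)) /
    (n_perm + 1)
  list(observed = obs, p_fst = p_fst, p_fis = p_fis, n_perm = n_perm,
       null_fst = null_fst, null_fis = null_fis)
}

#' Pairwise group F_ST matrix
#'
#' [f_statistics()] restricted to each pair of groups; diagonal 0. Pairs
#' where a group has fewer than 2 typed individuals get `NA` with a warning.
#'
#' @inheritParams f_statistics
#' @return symmetric group x group numeric matrix of overall F_ST.
#' @export
pairwise_group_fst <- function(x, groups = x$groups, correction = TRUE) {
  if (is.null(groups)) stop("group labels required")
  groups <- groups[x$individuals]
  glev <- sort(unique(groups))
  if (length(glev) < 2) stop("need >= 2 groups")
  out <- matrix(0, length(glev), length(glev), dimnames = list(glev, glev))
  for (i in seq_along(glev)) for (j in seq_along(glev)) {
    if (j <= i) next
    sel <- groups %in% glev[c(i, j)]
    sizes <- table(groups[sel])
    if (any(sizes < 2)) {
      warning(sprintf("pair (%s, %s): a group has < 2 individuals",
                      glev[i], glev[j]))
      out[i, j] <- out[j, i] <- NA_real_
      next
    }
    sub <- x[sel, ]
    fs <- suppressWarnings(
      f_statistics(sub, stats::setNames(groups[sel], x$individuals[sel]),
                   correction = correction))
    out[i, j] <- out[j, i] <- unname(fs$overall["F_ST"])
  }
  out
}
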