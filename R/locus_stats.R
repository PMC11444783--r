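#' Gene-count allele frequencies per locus
#'
#' @param x a [genotype_matrix()].
#' @return a list of class `allele_frequencies`: `freqs` (list per locus of
#'   named frequency vectors summing to 1) and `n_typed` (individuals typed
#'   per locus).
#' @export
allele_frequencies <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  freqs <- vector("list", length(x$loci)); names(freqs) <- x$loci
  n_typed <- integer(length(x$loci)); names(n_typed) <- x$loci
  for (l in seq_along(x$loci)) {
    v <- c(x$a1[, l], x$a2[, l])
    v <- v[!is.na(v)]
    if (length(v) == 0)
      stop("no typed individuals at locus ", x$loci[l])
    tab <- table(v)
    freqs[[l]] <- as.numeric(tab) / length(v)
    names(freqs[[l]]) <- names(tab)
    n_typed[l] <- length(v) / 2
  }
  structure(list(freqs = freqs, n_typed = n_typed, loci = x$loci),
            class = "allele_frequencies")
}

# frequency lookup for integer allele labels at locus l (0 if unseen)
freq_of <- function(af, l, alleles) {
  f <- af$freqs[[l]]
  out <- f[as.character(alleles)]
  out[is.na(out)] <- 0
  unname(out)
}

#' Per-locus diagnostics table
#'
#' Computes, per locus: sample size, allele count, observed heterozygosity
#' `Ho`, expected heterozygosity `He` (both the unbiased small-sample
#' corrected value `2n/(2n-1) * (1 - sum p^2)` and the uncorrected one),
#' polymorphic information content (Botstein), a chi-square Hardy-Weinberg
#' test with rare-class pooling (expected count < 5), and the summation
#' null-allele frequency estimate `(He - Ho)/(He + Ho)`.
#'
#' Monomorphic loci get `Ho = He = PIC = 0` and HWE p = 1.
#'
#' @param x a [genotype_matrix()].
#' @return data.frame with one row per locus, plus a `mean` attribute row in
#'   the `summary` attribute.
#' @export
locus_summary <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  af <- allele_frequencies(x)
  rows <- lapply(seq_along(x$loci), function(l) {
    a1 <- x$a1[, l]; a2 <- x$a2[, l]
    keep <- !is.na(a1)
    a1 <- a1[keep]; a2 <- a2[keep]
    n <- length(a1)
    p <- af$freqs[[l]]
    k <- length(p)
    ho <- mean(a1 != a2)
    he_raw <- 1 - sum(p^2)
    he <- if (n > 0) (2 * n / (2 * n - 1)) * he_raw else NA_real_
    pic <- if (k > 1) {
      p2 <- outer(p^2, p^2)
      1 - sum(p^2) - 2 * sum(p2[upper.tri(p2)])
    } else 0
    hwe <- hwe_chisq(a1, a2, p)
    null_f <- if (he + ho > 0) (he - ho) / (he + ho) else 0
    data.frame(locus = x$loci[l], n_typed = n, k = k, Ho = ho,
               He = he, He_uncorrected = he_raw, PIC = pic,
               HWE_chisq = hwe$stat, HWE_df = hwe$df, HWE_p = hwe$p,
               null_freq = null_f, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# chi-square HWE test on genotype classes with pooling of classes whose
# expected count falls below 5; df = classes_after_pooling - k (floor 1),
# mirroring the usual k(k+1)/2 - k before pooling
hwe_chisq <- function(a1, a2, p) {
  k <- length(p)
  if (k < 2) return(list(stat = 0, df = 0L, p = 1))
  n <- length(a1)
  alleles <- as.integer(names(p))
  combos <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  exp_ct <- obs_ct <- numeric(nrow(combos))
  for (r in seq_len(nrow(combos))) {
    i <- combos[r, 1]; j <- combos[r, 2]
    ai <- alleles[i]; aj <- alleles[j]
    if (i == j) {
      exp_ct[r] <- n * p[i]^2
      obs_ct[r] <- sum(a1 == ai & a2 == ai)
    } else {
      exp_ct[r] <- n * 2 * p[i] * p[j]
      obs_ct[r] <- sum(pmin(a1, a2) == min(ai, aj) &
                         pmax(a1, a2) == max(ai, aj))
    }
  }
  pool <- exp_ct < 5
  if (any(pool) && sum(!pool) >= 1) {
    exp_keep <- c(exp_ct[!pool], sum(exp_ct[pool]))
    obs_keep <- c(obs_ct[!pool], sum(obs_ct[pool]))
  } else if (all(pool)) {
    return(list(stat = 0, df = 0L, p = 1))
  } else {
    exp_keep <- exp_ct; obs_keep <- obs_ct
  }
  stat <- sum((obs_keep - exp_keep)^2 / exp_keep)
  df <- max(1L, length(exp_keep) - k)
  list(stat = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Probability of identity of the marker panel
#'
#' Per-locus PI is the probability that two random individuals under
#' Hardy-Weinberg share a genotype, `sum p_i^4 + sum_{i<j} (2 p_i p_j)^2`;
#' the panel value is the product across loci.
#'
#' @param af an [allele_frequencies()] object.
#' @return list with `per_locus` (named numeric) and `panel` (scalar).
#' @export
probability_of_identity <- function(af) {
  stopifnot(inherits(af, "allele_frequencies"))
  per <- vapply(af$freqs, function(p) {
    k <- length(p)
    het <- if (k > 1) {
      pp <- outer(p, p)
      sum((2 * pp[upper.tri(pp)])^2)
    } else 0
    sum(p^4) + het
  }, numeric(1))
  list(per_locus = per, panel = prod(per))
}
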