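#' Diploid microsatellite genotype matrix
#'
#' The central container for multilocus diploid genotypes. Alleles are
#' abstract integer labels; a call at a locus is either a complete unordered
#' pair or wholly missing (`NA` in both slots). Storage is a pair of
#' individual-by-locus integer matrices with the smaller allele in `a1`, so
#' that `(2, 1)` and `(1, 2)` compare equal.
#'
#' @param a1,a2 integer matrices (individuals x loci) holding the two allele
#'   labels per call, `NA` for missing. Pairs are sorted internally.
#' @param individuals character vector of unique individual ids (rownames).
#' @param loci character vector of unique locus ids (colnames).
#' @param groups optional character vector of group labels, one per
#'   individual.
#' @return an object of class `genotype_matrix` with elements `a1`, `a2`,
#'   `individuals`, `loci`, `groups`.
#' @export
genotype_matrix <- function(a1, a2, individuals = rownames(a1),
                            loci = colnames(a1), groups = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!identical(dim(a1), dim(a2)))
    stop("a1 and a2 must have identical dimensions")
  if (is.null(individuals)) individuals <- paste0("ind", seq_len(nrow(a1)))
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(a1)))
  individuals <- as.character(individuals); loci <- as.character(loci)
  if (anyDuplicated(individuals)) stop("duplicate individual ids")
  if (anyDuplicated(loci)) stop("duplicate locus ids")
  if (length(individuals) != nrow(a1) || length(loci) != ncol(a1))
    stop("id vectors do not match matrix dimensions")
  half <- xor(is.na(a1), is.na(a2))
  if (any(half))
    stop("half-missing calls: alleles must be both present or both missing")
  # store unordered pairs canonically
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  dimnames(a1) <- dimnames(a2) <- list(individuals, loci)
  if (!is.null(groups)) {
    groups <- as.character(groups)
    if (length(groups) != length(individuals))
      stop("groups must have one label per individual")
    names(groups) <- individuals
  }
  structure(list(a1 = a1, a2 = a2, individuals = individuals, loci = loci,
                 groups = groups),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci (%.1f%% missing)\n",
              length(x$individuals), length(x$loci),
              100 * mean(is.na(x$a1))))
  if (!is.null(x$groups))
    cat("groups:", paste(names(table(x$groups)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(length(x$individuals), length(x$loci))

#' Subset a genotype matrix by individuals and/or loci
#'
#' @param x a [genotype_matrix()].
#' @param i,j individual / locus index (integer, logical or character).
#' @param ... ignored.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$individuals)
  if (missing(j)) j <- seq_along(x$loci)
  genotype_matrix(x$a1[i, j, drop = FALSE], x$a2[i, j, drop = FALSE],
                  groups = if (!is.null(x$groups)) unname(x$groups[i]))
}

#' Number of non-missing loci per individual
#' @param x a [genotype_matrix()].
#' @return named integer vector.
#' @export
loci_typed <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  rowSums(!is.na(x$a1))
}

## ---------------------------------------------------------------------------
## I/O: long CSV (sample_id, individual_id, locus, allele1, allele2; 0=missing)
## and GenePop.

#' Read genotypes from CSV or GenePop files
#'
#' CSV files use the long schema `individual_id, locus, allele1, allele2`
#' with optional `sample_id` and `group` columns; allele code 0 means
#' missing. GenePop files may use 2- or 3-digit allele codes (auto-detected
#' by token length); each "Pop" block becomes a group.
#'
#' @param path file path.
#' @param format `"csv"` or `"genepop"`.
#' @return a [genotype_matrix()]; group labels attached when the format
#'   carries them.
#' @export
read_genotypes <- function(path, format = c("csv", "genepop")) {
  format <- match.arg(format)
  if (format == "csv") read_genotypes_csv(path) else read_genepop(path)
}

read_genotypes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "locus", "allele1", "allele2")
  if (!all(need %in% names(df)))
    stop("CSV must contain columns: ", paste(need, collapse = ", "))
  ids <- unique(df$individual_id)
  loci <- unique(df$locus)
  key <- paste(match(df$individual_id, ids), match(df$locus, loci))
  if (anyDuplicated(key)) {
    bad <- which(duplicated(key))[1]
    stop(sprintf("duplicate genotype row for individual '%s' locus '%s' (row %d)",
                 df$individual_id[bad], df$locus[bad], bad + 1L))
  }
  a1 <- matrix(NA_integer_, length(ids), length(loci),
               dimnames = list(ids, loci))
  a2 <- a1
  i <- match(df$individual_id, ids); j <- match(df$locus, loci)
  v1 <- as.integer(df$allele1); v2 <- as.integer(df$allele2)
  v1[v1 == 0L] <- NA_integer_; v2[v2 == 0L] <- NA_integer_
  half <- xor(is.na(v1), is.na(v2))
  if (any(half))
    stop(sprintf("half-missing call at row %d: use 0 for both alleles",
                 which(half)[1] + 1L))
  a1[cbind(i, j)] <- v1; a2[cbind(i, j)] <- v2
  groups <- NULL
  if ("group" %in% names(df)) {
    g <- df$group[!duplicated(df$individual_id)]
    groups <- g[match(ids, unique(df$individual_id))]
  }
  genotype_matrix(a1, a2, ids, loci, groups = groups)
}

#' Write genotypes to a long CSV
#'
#' @param x a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(x, path) {
  stopifnot(inherits(x, "genotype_matrix"))
  n <- length(x$individuals); L <- length(x$loci)
  df <- data.frame(
    individual_id = rep(x$individuals, times = L),
    locus = rep(x$loci, each = n),
    allele1 = as.vector(x$a1), allele2 = as.vector(x$a2),
    stringsAsFactors = FALSE)
  df$allele1[is.na(df$allele1)] <- 0L
  df$allele2[is.na(df$allele2)] <- 0L
  if (!is.null(x$groups)) df$group <- rep(unname(x$groups), times = L)
  df <- df[order(match(df$individual_id, x$individuals)), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) stop("GenePop file too short")
  body <- lines[-1]                      # first line is a title
  pop_at <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (length(pop_at) == 0) stop("no 'Pop' separator found")
  locus_lines <- body[seq_len(pop_at[1] - 1)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  ids <- character(); g <- character(); rows1 <- list(); rows2 <- list()
  pop_idx <- 0L
  for (k in seq(pop_at[1], length(body))) {
    line <- body[k]
    if (grepl("^\\s*pop\\s*$", line, ignore.case = TRUE)) {
      pop_idx <- pop_idx + 1L
      next
    }
    parts <- strsplit(line, ",")[[1]]
    if (length(parts) < 2)
      stop(sprintf("GenePop parse error at line %d: missing ',' separator",
                   k + 1L))
    id <- trimws(parts[1])
    toks <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
    if (length(toks) != length(loci))
      stop(sprintf("GenePop parse error at line %d: %d genotypes for %d loci",
                   k + 1L, length(toks), length(loci)))
    width <- unique(nchar(toks))
    if (length(width) != 1 || !width %in% c(4L, 6L))
      stop(sprintf("GenePop parse error at line %d: allele codes must be 2 or 3 digits",
                   k + 1L))
    half <- width / 2
    v1 <- as.integer(substr(toks, 1, half))
    v2 <- as.integer(substr(toks, half + 1, width))
    if (anyNA(v1) || anyNA(v2))
      stop(sprintf("GenePop parse error at line %d: non-numeric allele code",
                   k + 1L))
    v1[v1 == 0L] <- NA_integer_; v2[v2 == 0L] <- NA_integer_
    # one-sided zero means the whole call is missing in GenePop practice
    miss <- is.na(v1) | is.na(v2)
    v1[miss] <- NA_integer_; v2[miss] <- NA_integer_
    ids <- c(ids, id); g <- c(g, paste0("pop", pop_idx))
    rows1[[length(rows1) + 1L]] <- v1; rows2[[length(rows2) + 1L]] <- v2
  }
  if (anyDuplicated(ids)) {
    d <- ids[duplicated(ids)][1]
    stop("duplicate individual id in GenePop file: ", d)
  }
  a1 <- do.call(rbind, rows1); a2 <- do.call(rbind, rows2)
  genotype_matrix(a1, a2, ids, loci, groups = g)
}

#' Write genotypes in GenePop format
#'
#' Uses 3-digit allele codes and one "Pop" block per group (a single block
#' when no groups are attached).
#'
#' @param x a [genotype_matrix()].
#' @param path output path.
#' @param title header line for the file.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(x, path, title = "kinskew export") {
  stopifnot(inherits(x, "genotype_matrix"))
  if (any(x$a1 > 999, na.rm = TRUE)) stop("allele labels exceed 3 digits")
  g <- if (is.null(x$groups)) rep("pop1", length(x$individuals))
       else unname(x$groups)
  fmt <- function(v) {
    v[is.na(v)] <- 0L
    sprintf("%03d", v)
  }
  out <- c(title, x$loci)
  for (gr in unique(g)) {
    out <- c(out, "Pop")
    for (i in which(g == gr)) {
      geno <- paste0(fmt(x$a1[i, ]), fmt(x$a2[i, ]))
      out <- c(out, paste0(x$individuals[i], " , ", paste(geno, collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Replicate sets and consensus calling

#' Set of replicate genotypes per individual
#'
#' Holds the raw per-sample genotypes from repeated amplifications of the
#' same individuals (the multi-tubes approach used for faecal DNA). Each
#' individual carries >= 1 replicate over a common locus panel.
#'
#' @param calls list, one element per individual, each a list with elements
#'   `a1`, `a2` (replicate x locus integer matrices, `NA` missing) and
#'   `sample_ids`.
#' @param individuals character ids, parallel to `calls`.
#' @param loci character locus panel.
#' @return an object of class `replicate_set`.
#' @export
replicate_set <- function(calls, individuals, loci) {
  if (length(calls) != length(individuals))
    stop("one calls element per individual required")
  if (length(calls) == 0) stop("empty replicate set")
  for (k in seq_along(calls)) {
    el <- calls[[k]]
    if (nrow(el$a1) < 1) stop("each individual needs >= 1 replicate")
    if (ncol(el$a1) != length(loci))
      stop("replicate loci do not match panel for ", individuals[k])
  }
  structure(list(calls = calls, individuals = as.character(individuals),
                 loci = as.character(loci)),
            class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  nr <- vapply(x$calls, function(el) nrow(el$a1), integer(1))
  cat(sprintf("replicate_set: %d individuals, %d loci, %g-%g replicates\n",
              length(x$individuals), length(x$loci), min(nr), max(nr)))
  invisible(x)
}

#' Read a replicate set from a long CSV
#'
#' Schema: `sample_id, individual_id, locus, allele1, allele2` (0 = missing).
#' Replicates of one individual are its distinct `sample_id`s.
#'
#' @param path CSV path.
#' @return a [replicate_set()].
#' @export
read_replicates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "individual_id", "locus", "allele1", "allele2")
  if (!all(need %in% names(df)))
    stop("CSV must contain columns: ", paste(need, collapse = ", "))
  loci <- unique(df$locus)
  ids <- unique(df$individual_id)
  v1 <- as.integer(df$allele1); v2 <- as.integer(df$allele2)
  v1[v1 == 0L] <- NA_integer_; v2[v2 == 0L] <- NA_integer_
  calls <- lapply(ids, function(id) {
    sub <- df[df$individual_id == id, , drop = FALSE]
    samples <- unique(sub$sample_id)
    a1 <- matrix(NA_integer_, length(samples), length(loci),
                 dimnames = list(samples, loci))
    a2 <- a1
    i <- match(sub$sample_id, samples); j <- match(sub$locus, loci)
    a1[cbind(i, j)] <- v1[df$individual_id == id]
    a2[cbind(i, j)] <- v2[df$individual_id == id]
    list(a1 = a1, a2 = a2, sample_ids = samples)
  })
  replicate_set(calls, ids, loci)
}

#' Write a replicate set to a long CSV
#' @param reps a [replicate_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_replicates <- function(reps, path) {
  stopifnot(inherits(reps, "replicate_set"))
  rows <- list()
  for (k in seq_along(reps$individuals)) {
    el <- reps$calls[[k]]
    for (r in seq_len(nrow(el$a1))) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = el$sample_ids[r],
        individual_id = reps$individuals[k],
        locus = reps$loci,
        allele1 = ifelse(is.na(el$a1[r, ]), 0L, el$a1[r, ]),
        allele2 = ifelse(is.na(el$a2[r, ]), 0L, el$a2[r, ]),
        stringsAsFactors = FALSE)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Consensus-calling rules
#'
#' @param min_homozygote_reps minimum number of replicates in which an allele
#'   must be the sole allele observed before a homozygote is accepted.
#'   Follows the multi-tubes tradition: a single apparent homozygote could be
#'   a dropout artefact.
#' @return a list of class `consensus_rules`.
#' @export
consensus_rules <- function(min_homozygote_reps = 2L) {
  stopifnot(min_homozygote_reps >= 1)
  structure(list(min_homozygote_reps = as.integer(min_homozygote_reps)),
            class = "consensus_rules")
}

# consensus for one locus of one individual; reps is a 2-column matrix of
# allele pairs (rows = replicates), NA rows already removed
consensus_one_locus <- function(pairs, rules) {
  if (nrow(pairs) == 0)
    return(list(a1 = NA_integer_, a2 = NA_integer_, flag = "missing"))
  alleles <- sort(unique(as.vector(pairs)))
  hets <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (length(alleles) >= 3)
    return(list(a1 = NA_integer_, a2 = NA_integer_, flag = "conflict"))
  if (nrow(hets) > 0) {
    # all het replicates must agree (with <= 2 alleles total they do), and
    # every replicate must be {a,b}, {a,a} or {b,b} -- guaranteed here
    a <- min(alleles); b <- max(alleles)
    if (length(alleles) != 2)
      return(list(a1 = NA_integer_, a2 = NA_integer_, flag = "conflict"))
    flag <- if (nrow(hets) == nrow(pairs)) "confirmed" else "dropout_resolved"
    return(list(a1 = a, a2 = b, flag = flag))
  }
  # only homozygous replicates seen
  if (length(alleles) == 2) {
    # two disjoint homozygotes: jointly consistent with the heterozygote
    # {a,b} under dropout in every replicate
    return(list(a1 = alleles[1], a2 = alleles[2], flag = "dropout_resolved"))
  }
  if (nrow(pairs) >= rules$min_homozygote_reps)
    return(list(a1 = alleles[1], a2 = alleles[1], flag = "confirmed"))
  list(a1 = NA_integer_, a2 = NA_integer_, flag = "missing")
}

#' Call consensus genotypes from replicate amplifications
#'
#' Implements dropout-aware multi-tube consensus. Per locus: a heterozygote
#' `{a,b}` is called when both alleles are observed and every replicate is
#' consistent with `{a,b}` under dropout (i.e. equals `{a,b}`, `{a,a}` or
#' `{b,b}`); a homozygote `(a,a)` is called only when `a` is the sole allele
#' observed in at least `min_homozygote_reps` replicates; three or more
#' distinct alleles (which includes any pair of disjoint heterozygotes) is a
#' conflict and the locus is set missing.
#'
#' @param reps a [replicate_set()].
#' @param rules a [consensus_rules()] object.
#' @return a list of class `consensus_result` with elements `genotypes`
#'   (a [genotype_matrix()]), `flags` (individual x locus character matrix
#'   with values `confirmed`, `dropout_resolved`, `missing`, `conflict`) and
#'   `loci_typed` (named integer vector).
#' @export
call_consensus <- function(reps, rules = consensus_rules()) {
  stopifnot(inherits(reps, "replicate_set"))
  n <- length(reps$individuals); L <- length(reps$loci)
  a1 <- matrix(NA_integer_, n, L, dimnames = list(reps$individuals, reps$loci))
  a2 <- a1
  flags <- matrix("missing", n, L, dimnames = list(reps$individuals, reps$loci))
  for (k in seq_len(n)) {
    el <- reps$calls[[k]]
    for (l in seq_len(L)) {
      v1 <- el$a1[, l]; v2 <- el$a2[, l]
      keep <- !is.na(v1) & !is.na(v2)
      res <- consensus_one_locus(cbind(v1[keep], v2[keep]), rules)
      a1[k, l] <- res$a1; a2[k, l] <- res$a2; flags[k, l] <- res$flag
    }
  }
  gm <- genotype_matrix(a1, a2, reps$individuals, reps$loci)
  structure(list(genotypes = gm, flags = flags, loci_typed = loci_typed(gm)),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: %d individuals, %d loci; %d conflict calls\n",
              nrow(x$flags), ncol(x$flags), sum(x$flags == "conflict")))
  invisible(x)
}

#' Flag individuals requiring re-genotyping
#'
#' An individual is flagged when (i) fewer than `min_loci` loci were typed in
#' consensus, or (ii) any locus showed replicate mismatches not explained by
#' occasional allelic dropout (a conflict).
#'
#' @param results a `consensus_result` from [call_consensus()].
#' @param min_loci amplification threshold for rule (i); default 10.
#' @return data.frame with columns `individual_id`, `flagged`, `reason_i`,
#'   `reason_ii`, `reasons`.
#' @export
flag_regenotyping <- function(results, min_loci = 10L) {
  stopifnot(inherits(results, "consensus_result"))
  ri <- results$loci_typed < min_loci
  rii <- apply(results$flags == "conflict", 1, any)
  reasons <- mapply(function(a, b) {
    r <- c(if (a) sprintf("(i) fewer than %d loci amplified", min_loci),
           if (b) "(ii) unexplained genotype mismatch (conflict)")
    paste(r, collapse = "; ")
  }, ri, rii)
  data.frame(individual_id = names(results$loci_typed),
             flagged = ri | rii, reason_i = unname(ri), reason_ii = unname(rii),
             reasons = unname(reasons), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Drop individuals typed at too few loci
#'
#' @param x a [genotype_matrix()].
#' @param min_loci minimum number of non-missing loci to retain an
#'   individual; default 7 (relatedness-analysis inclusion rule).
#' @return filtered [genotype_matrix()] with original ordering preserved.
#' @export
filter_min_loci <- function(x, min_loci = 7L) {
  stopifnot(inherits(x, "genotype_matrix"))
  keep <- loci_typed(x) >= min_loci
  if (!any(keep)) stop("all individuals fall below the min_loci threshold")
  x[keep, ]
}
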