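#' Fill unobserved days in a group-composition series
#'
#' Days between two observations are imputed as the mean of the flanking
#' observed group sizes (applied as a constant across the whole gap, the
#' reading of "mean of the sizes observed immediately before and after";
#' `method = "ramp"` gives a true linear ramp instead). Days outside the
#' observed range are never imputed.
#'
#' @param series data.frame with columns `date` (ISO or Date) and `size`,
#'   dates strictly increasing.
#' @param method `"flank_mean"` (default) or `"ramp"`.
#' @return data.frame `date`, `size`, `interpolated` covering every day from
#'   the first to the last observation.
#' @export
interpolate_sizes <- function(series, method = c("flank_mean", "ramp")) {
  method <- match.arg(method)
  d <- as.Date(series$date)
  if (is.unsorted(d, strictly = TRUE)) stop("dates must be strictly increasing")
  if (length(d) == 1)
    return(data.frame(date = d, size = series$size, interpolated = FALSE))
  days <- seq(d[1], d[length(d)], by = "day")
  size <- rep(NA_real_, length(days))
  obs <- match(d, days)
  size[obs] <- series$size
  for (i in seq_len(length(d) - 1)) {
    if (obs[i + 1] - obs[i] < 2) next
    gap <- seq(obs[i] + 1L, obs[i + 1] - 1L)
    size[gap] <- if (method == "flank_mean")
      (series$size[i] + series$size[i + 1]) / 2
    else series$size[i] + (series$size[i + 1] - series$size[i]) *
      (gap - obs[i]) / (obs[i + 1] - obs[i])
  }
  data.frame(date = days, size = size,
             interpolated = is.na(match(days, d)))
}

#' Mean daily group size over a period
#'
#' @param daily data.frame from [interpolate_sizes()].
#' @param from,to period bounds (inclusive); default the whole series.
#' @return arithmetic mean of the daily sizes in the overlap.
#' @export
weighted_group_size <- function(daily, from = min(daily$date),
                                to = max(daily$date)) {
  from <- as.Date(from); to <- as.Date(to)
  sel <- daily$date >= from & daily$date <= to
  if (!any(sel)) stop("period does not overlap the daily series")
  mean(daily$size[sel])
}

#' Mean-of-means group-season summaries
#'
#' For each metric column: group-season values are first averaged within
#' group across seasons, then across groups, so a group observed over many
#' seasons cannot dominate the estimate. The SE is across group means.
#'
#' @param values data.frame with columns `group`, `season`, and one or more
#'   numeric metric columns.
#' @return data.frame: metric, mean (mean of group means), se, n_groups,
#'   pooled_mean (for comparison).
#' @export
season_summaries <- function(values) {
  metrics <- setdiff(names(values), c("group", "season"))
  if (length(metrics) == 0) stop("no metric columns")
  rows <- lapply(metrics, function(mname) {
    v <- values[!is.na(values[[mname]]), c("group", mname)]
    if (nrow(v) == 0)
      return(data.frame(metric = mname, mean = NA_real_, se = NA_real_,
                        n_groups = 0L, pooled_mean = NA_real_))
    gm <- tapply(v[[mname]], v$group, mean)
    data.frame(metric = mname, mean = mean(gm),
               se = stats::sd(gm) / sqrt(length(gm)),
               n_groups = length(gm), pooled_mean = mean(v[[mname]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Dispersal / group-switch summary
#'
#' @param events data.frame with one row per switching individual:
#'   `event_id`, `id`, `sex`, `from_group`, `to_group`, optionally `date`
#'   or `season`, and optionally `competitors_before`/`competitors_after`
#'   (same-sex subordinate counts where both groups were monitored).
#' @return list: `n_individuals`, `n_events`, `by_sex` counts,
#'   `male_fraction`, `n_single`, `n_coalition`, `coalition_composition`
#'   (all_male / all_female / mixed), and `competitor_change` stats when the
#'   columns are present.
#' @export
switch_summary <- function(events) {
  if (nrow(events) == 0)
    return(list(n_individuals = 0L, n_events = 0L,
                by_sex = c(M = 0L, F = 0L), male_fraction = NA_real_,
                n_single = 0L, n_coalition = 0L,
                coalition_composition = c(all_male = 0L, all_female = 0L,
                                          mixed = 0L)))
  sizes <- table(events$event_id)
  comp <- c(all_male = 0L, all_female = 0L, mixed = 0L)
  for (e in names(sizes[sizes > 1])) {
    sx <- unique(events$sex[events$event_id == e])
    key <- if (length(sx) > 1) "mixed"
           else if (sx == "M") "all_male" else "all_female"
    comp[key] <- comp[key] + 1L
  }
  by_sex <- c(M = sum(events$sex == "M"), F = sum(events$sex == "F"))
  out <- list(
    n_individuals = nrow(events), n_events = length(sizes),
    by_sex = by_sex, male_fraction = unname(by_sex["M"] / nrow(events)),
    n_single = sum(sizes == 1), n_coalition = sum(sizes > 1),
    coalition_composition = comp)
  if (all(c("competitors_before", "competitors_after") %in% names(events))) {
    ch <- events$competitors_after - events$competitors_before
    ch <- ch[!is.na(ch)]
    out$competitor_change <- list(mean = mean(ch), n = length(ch),
                                  decreased = sum(ch < 0),
                                  increased = sum(ch > 0))
  }
  out
}

#' Null expectations for reproductive skew from behavioural observations
#'
#' If every observed pregnancy produced equally many pups, the expected
#' dominant maternity share is `1 / mean_pregnant_females` (the dominant is
#' always among the pregnant females). If every observed mating male had an
#' equal chance of siring, the expected subordinate paternity share is
#' `(mean_mating_males - 1) / mean_mating_males`. Truncated integer
#' percentages are reported alongside the exact values.
#'
#' @param mean_pregnant_females mean pregnant females per group-season
#'   (>= 1).
#' @param mean_mating_males mean mating males per group-season (>= 1).
#' @return list with exact shares (percent) and truncated percentages.
#' @export
expected_skew <- function(mean_pregnant_females, mean_mating_males) {
  if (mean_pregnant_females < 1 || mean_mating_males < 1)
    stop("means must be >= 1 (the dominant is always present)")
  dom_mat <- 100 / mean_pregnant_females
  sub_pat <- 100 * (mean_mating_males - 1) / mean_mating_males
  list(expected_dominant_maternity_pct = dom_mat,
       expected_dominant_maternity_pct_trunc = floor(dom_mat),
       expected_subordinate_paternity_pct = sub_pat,
       expected_subordinate_paternity_pct_trunc = floor(sub_pat))
}

#' Pup survival to one year
#'
#' Proportion of emerged pups surviving to 365 days. Pups flagged as having
#' emigrated before one year are ambiguous (alive but unobserved); the
#' uncensored estimate counts them as deaths, the censored estimate removes
#' them from the denominator, and both are reported.
#'
#' @param pups data.frame with columns `emergence_date`, `last_seen_date`,
#'   optionally logical `emigrated` and `known_dead`.
#' @return list: `n_emerged`, `n_survived`, `survival_pct` (uncensored),
#'   `survival_pct_censored`, or `NA` values with a note when no pups.
#' @export
survival_summary <- function(pups) {
  if (nrow(pups) == 0)
    return(list(n_emerged = 0L, n_survived = NA_integer_,
                survival_pct = NA_real_, survival_pct_censored = NA_real_,
                note = "no emerged pups"))
  days <- as.numeric(as.Date(pups$last_seen_date) -
                       as.Date(pups$emergence_date))
  survived <- days >= 365
  emigrated <- if ("emigrated" %in% names(pups)) pups$emigrated & !survived
               else rep(FALSE, nrow(pups))
  n <- nrow(pups)
  list(n_emerged = n, n_survived = sum(survived),
       survival_pct = 100 * sum(survived) / n,
       survival_pct_censored = 100 * sum(survived) / (n - sum(emigrated)),
       n_emigrated_before_1y = sum(emigrated))
}
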