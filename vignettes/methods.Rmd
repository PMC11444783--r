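---
title: "Models, simulations and design choices in kinskew"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, simulations and design choices in kinskew}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`kinskew` analyses the genetic structure of cooperatively breeding
populations genotyped non-invasively at microsatellite loci: one dominant
breeding pair per social group, subordinate helpers, and faecal-DNA
genotypes whose error process (allelic dropout, false alleles, whole-locus
failure) must be handled before any population-genetic inference. This
vignette documents the models, the synthetic world used to validate them,
the numerical choices, and the places where the design was genuinely open.
It states no empirical result that the test suite does not itself compute.

## 1. The synthetic world

`sim_config()` describes a population of `n_groups` territorial groups.
Founding adults (HWE draws from per-locus Dirichlet allele frequencies) fill
each group; one male and one female become the dominant pair and hold the
position throughout. Each season, subordinate adults disperse with
sex-specific probabilities (default 0.10 male / 0.033 female, preserving a
3:1 male bias; simultaneous moves along the same route form coalition
events), each group produces Poisson-truncated-at-1 litters whose dam is the
dominant female with probability `dominant_maternity_share` (default 0.886)
and sire the dominant male with `dominant_paternity_share` (0.875), pups
inherit alleles by Mendelian segregation, and survivors (default 39%)
recruit as subordinates the next season.

Parameter choices that were open, decided once:

* **Heterozygosity control.** With `k` alleles and symmetric Dirichlet
  concentration `a`, `E[He] = 1 − (a+1)/(ka+1)`. The default `k = 8`,
  `a = 0.29` gives `E[He] = 0.61`, the target panel diversity; the test
  suite verifies a 20-seed mean within ±0.05.
* **Demography.** The field rates are 1.45 *emerged* litters per
  group-season (litters that produce no emerged pups are not modelled) of
  mean size 3.5, with 39% first-year survival. With 6 founding adults per
  group and 3 seasons this yields sampled populations of ~105–125
  individuals across 7 groups with ~35–45 current-season pups — the scale of
  a seven-group, ~94-individual field study. Adults are immortal; population
  size is controlled by these rates, not by mortality.
* **Breeding age.** Only individuals at least two seasons old breed (both
  sexes), mirroring the over-2-years rule used for candidate fathers in the
  field. Without it, newly recruited offspring of the dominant pair enter
  candidate-parent sets as full siblings of later pups and occasionally
  outscore a true parent — the field design's age and pregnancy filters are
  precisely what remove those confounders.
* **Error model.** Per replicate and locus: whole-locus failure (default
  0.05), then per-allele dropout in heterozygotes (0.2; both alleles
  dropping surfaces as a failed locus), then a false allele replacing one
  allele uniformly (0.01). These defaults are plausible faecal-DNA rates and
  are *not* estimates of any particular study's rates, which are unreported.
* **Reproducibility.** Each operation derives its own RNG stream from the
  master seed (`seed * 7919 + utf8(key) mod 2^31−1`), so `simulate_population`
  and `simulate_replicates` are independently reproducible; identical
  configurations serialize byte-identically.

What the generator does **not** emulate: stutter artefacts and allele-size
binning (alleles are abstract labels), pregnancy loss, adult mortality and
dominance turnover, territory geometry, and unobserved-group censusing. A
green parameter-recovery test therefore establishes estimator correctness on
idealized pedigrees with the stated noise, not robustness to every artefact
of real fragment data.

## 2. Consensus genotyping

The multi-tubes rule set in `call_consensus()`: a heterozygote *{a,b}* is
called when both alleles are observed and every replicate at the locus is
*{a,b}*, *{a,a}* or *{b,b}* (all dropout-consistent); a homozygote *(a,a)*
only when *a* is the sole allele observed in at least
`min_homozygote_reps = 2` replicates; three or more distinct alleles (which
covers disjoint heterozygotes) is a conflict, and conflicted loci are set
missing. The homozygote threshold is the consequential choice — it converts
single-replicate homozygotes into missing data rather than risking dropout
artefacts — and is exposed in `consensus_rules()`. Re-genotyping flags
reproduce the two field triggers: fewer than 10 loci amplified, or any
conflict. Additional replicates are merged into the same `replicate_set` and
consensus recomputed; there is no separate second-pass state.

## 3. Estimators

**Diagnostics.** He uses the unbiased small-sample correction (the
uncorrected value is also reported); PIC follows Botstein; the HWE test is a
chi-square over genotype classes with expected-count-below-5 pooling and
`df = classes − k` (floor 1) — an exact Monte-Carlo test is out of scope;
the null-allele estimate is the summation form `(He−Ho)/(He+Ho)`, chosen
over iterative EM for transparency.

**F-statistics.** The Nei heterozygosity formulation matches the verbal
definitions ("reduction in heterozygosity …"): group components weighted by
typed sample size, `H_T` from pooled weighted frequencies. The identity
`(1−F_IT) = (1−F_IS)(1−F_ST)` is algebraic per locus and tested to 1e-9.
Overall values come from across-locus mean components; loci with `H_S = 0`
are excluded (F_IS undefined there). Weir–Cockerham variance components are
a documented extension point, not implemented. Permutation nulls: individuals
among groups for F_ST (upper tail), alleles among individuals within groups
for F_IS (two-sided), `p = (1 + hits)/(n_perm + 1)`, default 999
permutations (the source analysis does not state its count).

**Relatedness.** The Queller–Goodnight estimator is implemented exactly
(per-locus numerator/denominator sums, symmetrized). Reference frequencies
come from the full ≥7-loci filtered sample including the focal pair (the
GenAlEx-style default); `exclude_pair = TRUE` recomputes them per pair. The
breeder-pair permutation test replaces each dominant's partner with a
uniform draw among opposite-sex adult groupmates with defined r; pups are
never candidates. The actual partner remains drawable by default
(`include_partner = TRUE`), which keeps the permutation p-value exact under
exchangeability; the stricter alternatives-only scheme sits behind the flag.
One-tailed `p = (1 + #{null ≤ obs})/(n + 1)`.

**Parentage.** Transition probabilities are the standard single-parent and
parent-pair Mendelian forms under HWE; mistyping mixes in the background at
rate e: `T' = (1−e)T + e·P(pup)`. This is the stated error model, validated
by simulation — it is not claimed bit-identical to any Cervus version. The
parent *pair* is the assignment unit (Δ is defined over pairs); at loci
where only one candidate is typed the pair likelihood falls back to the
single-parent term. Confidence thresholds come from Monte-Carlo cycles
reproducing the published simulation design (two candidates per sex,
0.48/0.47 sampled, 91% loci typed, 5% mistyped, minimum 7 loci, 80% of
candidates related at r = 0.31/0.27). Related candidates are generated by a
partial-ancestry draw — with probability 2r per locus the candidate carries
one allele from the true parent — giving expected relatedness r; the tests
verify the realized mean within 0.03. Thresholds are the smallest Δ at which
assignments above it are ≥95% (strict) / ≥80% (relaxed) correct; because the
95% set is a subset of the 80% set, strict ≥ relaxed always. A sole
candidate pair's Δ is its LOD when positive, else 0; ties break by fewer
mismatches then lexical id. Candidates are never hard-excluded on a single
mismatch when e > 0; mismatch counts are reported.

**Clustering.** A Gibbs sampler over allele-origin indicators with
independent Dirichlet(1) cluster frequencies and Dirichlet(α) admixture, α
updated by a Metropolis step (uniform(0,10) prior, sd 0.25 proposals);
written in C++ against R's RNG so runs are seed-reproducible.
`Ln P(D) = mean(logL) − var(logL)/2` over retained sweeps; Q is the
posterior mean. Model selection reports both max-mean-LnPD and Evanno's
`ΔK = |L″(K)|/SD(L(K))` (interior K, ≥2 runs each) side by side. The
'locprior' and correlated-frequencies variants are not implemented; K
selection is therefore validated on strongly separated fixtures where
locprior is immaterial. Desk-scale MCMC defaults (2000/2000) are far below
production settings (100k/100k), which remain available via arguments.

## 4. Life-history computations

Group-size gaps are filled with the *mean of the flanking observations held
constant across the gap* — the implemented reading of a source description
that calls this "linear interpolation" while defining the flanking mean; a
true ramp is available via `method = "ramp"`. No extrapolation outside the
observed range. Summaries use the mean-of-means rule (group-season →
group mean → across-group mean) so that long-observed groups cannot
dominate. Expected skew nulls: dominant maternity `1/mean pregnant females`,
subordinate paternity `(mean mating males − 1)/mean mating males`, reported
both exactly and as truncated integer percentages (100/1.8 → 55%), since the
published 55% is the floor of the exact value. Survival to one year is
reported uncensored and with pre-one-year emigrants removed from the
denominator, reflecting the ambiguity of emigration before 365 days.

## 5. Acceptance scenarios and their limits

The criterion tests in `tests/testthat/test-acceptance.R` are scenario
checks, each computed from scratch:

1. the in-study arithmetic (88.6%, 12.5%, 55%, 50%, 39%) from printed
   counts;
2. estimator oracles — QG means 0.5/0.0 ± 0.02 on 2000 simulated dyads, the
   F identity to 1e-9, negative F_IS in unrelated-breeder high-skew worlds;
3. permutation calibration (KS uniformity over 200 replicates for the
   breeder and Mantel tests) and power (100 zero-dispersal, natal-kin
   worlds; ≥95 of 100 at p ≤ 0.01 with 1000 permutations);
4. parentage — 100% recovery in a founder-candidate error-free world, and
   deterministic thresholds under the published simulation parameters at
   10,000 cycles;
5. both Ln P(D) and ΔK selecting K = 6 on a six-deme drifted fixture;
6. consensus concordance ≥95% at dropout 0.2 / false-allele 0.01 with three
   replicates on a 94 × 13 fixture, and exact truth recovery at zero error.

Known limitations: no Weir–Cockerham F-statistics, no alternative
relatedness estimators (Lynch–Ritland, Wang), no sibship reconstruction or
MCMC parentage, no linkage-disequilibrium diagnostics, no CLUMPP-style run
alignment, and the clustering model omits locprior — results on *weakly*
differentiated groups should be interpreted accordingly.
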