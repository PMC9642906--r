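---
title: "Clustering longitudinal behaviour trajectories and validating them as STI predictors"
author: "trajclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering longitudinal behaviour trajectories and validating them as STI predictors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajclust)
```

## The problem

Cohorts of people living with HIV are followed at roughly semiannual visits
over many years. At each visit a short questionnaire records sexual behaviour:
whether the participant had sex with non-steady partners (nsP), and if so
whether anal or vaginal intercourse took place and whether condoms were used
all the time. From these three answers a binary flag for condomless anal
intercourse with non-steady partners (nsCAI) is derived per visit. The
scientific question this package addresses is whether participants fall into
a small number of *long-term behaviour patterns* — rather than being
described only by their most recent answer — and whether membership in such a
pattern adds prospective predictive value for future behaviour and for
sexually transmitted infections (STIs), over and above conventional
covariates (age, last reported behaviour, prior syphilis).

Because the cohort data that motivate this design are access-restricted, the
package pairs the analysis pipeline with a synthetic-cohort generator with
*planted* cluster structure. Every stage is validated on cohorts whose truth
is known, and all reported quantities in the test-suite and acceptance script
are computed on such cohorts.

## The procedure

1. **Trajectory construction.** Visits are mapped onto a calendar grid of
   half-year bins (default 2001H2–2017H1, 32 bins). Calendar time, not
   patient time, indexes the bins, so historical shifts in behaviour (e.g.
   treatment-as-prevention messaging) appear as common features of a bin
   rather than being smeared across follow-up ages. Each cell holds 0, 1 or
   missing. If several visits fall in one bin they aggregate by OR (any
   report marks the half-year); a latest-visit-wins mode exists for irregular
   data. Bins are half-open calendar intervals (Jan 1–Jul 1, Jul 1–Jan 1).

2. **Distance.** For two trajectories the dissimilarity is the Jaccard
   distance: the proportion of discordant bins among co-observed bins where
   at least one participant reports the behaviour. Bins missing in either
   trajectory are excluded from numerator and denominator
   (pairwise-complete). Co-observed-but-all-zero pairs get distance 1; a pair
   with *no* co-observed bin is an error rather than a silent guess. Ignoring
   concordant zeros is deliberate: two people who rarely report the behaviour
   should be similar because of *when* they report it, not because of the
   long stretches in which neither does.

3. **Clustering.** Agglomerative hierarchical clustering under the Ward
   criterion, implemented with the Lance–Williams recurrence. The `ward.D2`
   form (recurrence on squared distances, square-root heights) is the
   default; `ward.D` is available behind a flag. Ties in the minimal linkage
   are broken by the lexicographically smallest pair of smallest original
   member indices, which makes merge order deterministic across platforms.
   Participants who *never* report the behaviour are excluded from the tree
   and appended as a reserved baseline cluster 0, so "k clusters" always
   means k hierarchical clusters plus the baseline stratum. Cutting the tree
   at k undoes the last k − 1 merges; labels 1..k are assigned in ascending
   order of mean trajectory positivity.

4. **Validation as predictors.** Records are split at a cut-off date
   (default 2017-05-01, half-open: the cut-off day itself belongs to the
   outcome period). Clusters are inferred from the observation period only;
   outcomes come from the non-overlapping outcome period: behaviour at first
   follow-up, any/count of nurse- or physician-reported STIs, and any/count
   of laboratory-confirmed incident syphilis. An incident episode is a
   treponemal seroconversion, or a VDRL titer above 1:8 that also exceeds
   four times the most recent prior titer (strict inequalities; both
   thresholds configurable; a rise from a non-reactive 0 to above 1:8
   triggers). Nested GLMs (logistic for binary outcomes, Poisson for counts)
   with covariates age, last pre-cut-off flag and prior syphilis are compared
   with the same model plus the cluster factor (baseline 0 as reference) by
   likelihood-ratio test, AIC, BIC and auROC, with a seeded, outcome-
   stratified 5-fold cross-validation and a sweep over the number of
   clusters. Cluster membership is also benchmarked against simpler
   trajectory summaries: last value, last two values, ever, and mean.

## Inclusion criteria

A participant enters the analysis with at least two non-missing feature
records before the cut-off spanning at least two years, and at least one
post-cut-off record with a non-missing value of the feature, so that every
configured outcome is evaluable. Span is measured first-to-last qualifying
record in days / 365.25.

## The synthetic generator

`simulate_cohort()` draws each participant either into a never-event baseline
stratum (default 30%) or into one of K latent profiles; at each retained bin
the event is Bernoulli with the profile's bin probability. Missing visits are
independent Bernoulli per (participant, bin), default 20%; an optional
late-entry setting truncates leading bins to mimic staggered enrolment. Visit
dates are uniform inside their bin. `simulate_study()` additionally draws age
(Normal(40, 10) truncated to [18, 80], matching the age scale of the cohorts
this design targets), cluster-dependent prior-syphilis indicators, and
post-cut-off outcomes from reference-coded logistic/Poisson models; it then
*materialises* those outcomes as the raw tables the ingest layer reads —
post-cut-off questionnaire answers, dated STI report rows, and a serology
table whose titer resets and spikes reproduce the planted episode counts
exactly under the classification rule. Default planted effects are
alternating cluster log-odds of ±1 (±0.5 on the log-rate scale for counts),
0.7 for last behaviour, 0.6 for prior syphilis and −0.03 per year of age,
with intercepts placed so a reference participant of age 40 has outcome
probability ≈ 0.15 (rate 0.25 for STI counts, 0.1 for syphilis counts).

**Default profile shapes.** The templates are flat-low (0.10), flat-high
(0.85), a rising logistic ramp (0.03 → 0.90, midpoint ~55% through the
window), its falling mirror, a flat intermediate (0.45) and a hump. The flat
levels and ramp endpoints are deliberately contrasted: with semiannual
binning and Bernoulli sampling noise, curves that run too close over a large
part of the window (e.g. a 0.75 plateau against a ramp that reaches 0.88)
produce latent groups that overlap in Jaccard geometry and are not reliably
recoverable even in principle. The defaults are chosen so the planted groups
are separated the way empirical behaviour-trend clusters are — clearly apart
for most of the calendar window — and so satisfy the generator's contract of
well-separated curves (mean pairwise L1 distance ≥ 0.15 with margin).

**What the generator does not emulate.** Within-person serial correlation
beyond cluster membership (bins are conditionally independent given the
profile), calendar events affecting all clusters simultaneously, informative
missingness, dropout, and any attempt to match real cohort demographics or
cluster proportions. Consequently, passing recovery tests show the pipeline
recovers structure *of this conditional-independence kind*; on real data,
serial correlation would typically make trajectories smoother and clusters
easier to separate, but this is not demonstrated here.

## Numerical and design choices

* **Ward variant.** `ward.D2` is the default because distances (not squared
  distances) are the natural input here; `ward.D` is kept for comparability
  with legacy analyses. The variant is recorded in output metadata.
* **Determinism.** All simulation takes an explicit integer seed and uses a
  private RNG stream that restores the caller's `.Random.seed`. Tie-breaks in
  agglomeration are lexicographic. Repeated `simulate` + `run` invocations
  are byte-identical.
* **Missing-distance convention.** Pairwise-complete bin exclusion was chosen
  over encoding missing as 0 because an unobserved half-year is not evidence
  of absence; the alternative would pull participants with sparse follow-up
  towards the baseline-like clusters.
* **Cross-validation.** Cluster labels are *fixed inputs* to the CV: the
  clustering is estimated once from observation-period data, and the CV
  assesses the regression step, mirroring a design in which clusters are
  inferred before outcomes exist. Re-clustering per training fold is possible
  in principle but would answer a different question (stability of the
  clustering itself) and is not the default. Folds are seeded and stratified
  by outcome; accuracy uses a 0.5 threshold on fitted probabilities.
* **Comparator arms.** The nested model always contains age, last flag and
  prior syphilis. A comparator column identical to a nested covariate (the
  `last` comparator; the newer half of `last_two`) is dropped from the
  augmented design instead of being fitted as a collinear copy — so `last`
  reduces to the nested model with p = 1 by construction.
* **Prior syphilis coding.** Indicator for binary outcomes, episode count for
  count outcomes. Age enters linearly in years.
* **Degenerate fits.** Constant outcomes and separation are flagged with
  warnings rather than silent divergence; rank deficiency is an error naming
  the collinear columns.
* **Type-I calibration of the cluster LRT.** Under planted null effects the
  LRT for adding clusters is calibrated: across thousands of simulated
  cohorts (n = 1000) the rejection rate at α = 0.05 is statistically
  indistinguishable from 5% and the p-value distribution is close to uniform.
  Single batches of 1000 replicates fluctuate within binomial noise.

## Problem sizes used in the checks

The automated checks run at sizes chosen to make the statistical assertions
sharp while staying lightweight: recovery uses 20 cohorts of n = 600 (32
bins, 20% missing visits, 30% baseline stratum, K = 3); calibration uses 1000
null cohorts of n = 1000; power uses 200 cohorts of n = 2000 at the default
±1 effects; the clustering implementation is checked against a from-scratch
agglomeration oracle on 200 random matrices of up to 12 trajectories and
against `stats::hclust` on larger ones.

## Worked example

```{r example, eval = FALSE}
st <- simulate_study(n_participants = 500, K = 3, seed = 7)
res <- run_behaviour_analysis(st$visits, st$labs, st$sti, st$participants,
                              config = default_config(k = 3))
subset(res$comparison, comparator == "cluster")
res$sweep$out_nsCAI$bic_optimal_k
plot_trend_curves(res$trends)
```

## Known limitations

* The Jaccard distance is undefined for pairs with no co-observed bins; very
  sparse follow-up can make a cohort unclusterable rather than silently
  imputed.
* The agglomeration is quadratic in memory and roughly cubic in time; it is
  comfortable for cohorts of a few thousand, not for hundreds of thousands.
* The count-outcome models are plain Poisson (negative-binomial dispersion is
  not fitted); repeated-measures outcomes with person-level random effects
  are out of scope.
* No multiple-testing correction is applied across outcomes; each
  outcome's LRT p-value is reported raw.
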