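# trajclust

Unsupervised clustering of longitudinal binary sexual-behaviour trajectories,
and validation of the resulting clusters as prospective predictors of
behaviour and sexually transmitted infections (STIs).

## What it does and for whom

Epidemiologists following cohorts with semiannual behaviour questionnaires
(e.g. HIV cohorts recording condomless anal intercourse with non-steady
partners, **nsCAI**, or any non-steady-partner sex, **nsP**) often summarise
a participant's history by their most recent answer. `trajclust` instead
treats the whole follow-up as a binary trajectory on a calendar grid of
half-year bins and asks two questions:

1. Do participants group into a small number of long-term behaviour
   patterns?
2. Does knowing a participant's pattern improve *prospective* prediction of
   behaviour and STIs beyond conventional covariates?

## Method

For participants $i, j$ with trajectories $x_i, x_j \in \{0, 1, \text{NA}\}^T$,
similarity is the **Jaccard distance** over co-observed bins:

$$d(x_i, x_j) = \frac{\#\{t : x_{it} \neq x_{jt}\}}{\#\{t : x_{it} = 1 \text{ or } x_{jt} = 1\}},$$

with bins missing in either trajectory excluded. Participants with at least
one positive bin are clustered by **agglomerative hierarchical clustering
under the Ward criterion** (Lance–Williams recurrence, `ward.D2` form,
deterministic tie-breaking); participants who never report the behaviour form
a reserved **baseline cluster 0**. Cutting the tree at $k$ gives $k + 1$
exposure categories.

Records are split at a cut-off date (default 2017-05-01). Clusters use only
pre-cut-off data; outcomes (first-follow-up behaviour, nurse/physician-
reported STI reports, laboratory-confirmed incident syphilis — defined as
treponemal seroconversion or a VDRL titer > 1:8 with a > 4-fold rise) use
only post-cut-off data. Nested GLMs

$$g(E[Y]) = \beta_0 + \beta_{\text{age}} \cdot \text{age} + \beta_{\text{last}} \cdot \text{last} + \beta_{\text{syph}} \cdot \text{syph} \;\; (+ \; \beta_{c(i)})$$

with logistic link for binary outcomes and log link for counts are compared
with and without the cluster factor by likelihood-ratio test, AIC, BIC and
auROC, with stratified 5-fold cross-validation, a benchmark against simple
trajectory summaries (last, last two, ever, mean) and a sweep over the number
of clusters.

A seeded synthetic-cohort generator with planted cluster structure
(`simulate_study()`) produces all four input tables plus a truth sidecar, so
the entire pipeline is testable without access-restricted cohort data.

## Worked example

```r
library(trajclust)
st <- simulate_study(n_participants = 500, K = 3, seed = 7)
res <- run_behaviour_analysis(st$visits, st$labs, st$sti, st$participants,
                              config = default_config(k = 3))
subset(res$comparison, comparator == "cluster")
```

```
    outcome comparator    p_lrt aic_without aic_with bic_without bic_with auroc_without auroc_with
  out_nsCAI    cluster 1.71e-11         587      540         604      570         0.622      0.731
    sti_any    cluster 9.47e-04         613      603         630      632         0.617      0.659
   syph_any    cluster 1.31e-04         363      348         380      378         0.664      0.726
  sti_count    cluster 3.26e-06         843      821         860      851            NA         NA
 syph_count    cluster 4.06e-05         434      417         451      446            NA         NA
```

Each row compares the conventional model (age + last flag + prior syphilis)
with the same model plus cluster membership for one post-cut-off outcome.
Here the planted clusters are highly informative for future behaviour
(p_LRT = 1.7e-11; BIC drops from 604 to 570; auROC rises from 0.62 to 0.73)
and informative, though less decisively by BIC, for the STI and syphilis
outcomes — the qualitative pattern this framework is designed to expose.

```r
res$assignment
#> Cluster assignment: 500 participants, 3 hierarchical cluster(s) + baseline cluster 0
#>   0   1   2   3
#> 149 120 115 116
res$sweep$out_nsCAI$bic_optimal_k
#> [1] 3
```

The assignment recovers the generator's layout (149 never-reporters in
cluster 0, three planted groups), and the BIC sweep selects the planted
number of clusters.

`write_run_outputs(res, "results/")` emits the comparison table, sweep,
trend curves, assignment, dendrogram (CSV + Newick) and run metadata. A thin
command-line wrapper lives at `inst/cli/trajclust.R`
(`Rscript trajclust.R simulate|run ...`).

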