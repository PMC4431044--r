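# qgenie

Quality assessment of published genetic association studies with the
Q-Genie instrument: scoring, psychometric validation, and
quality-stratified meta-analysis sensitivity.

## What this is for

Meta-analyses of genetic association studies pool odds ratios across
studies of very uneven quality — genotyping error, batch effects,
under-powered samples, unchecked model assumptions — and low-quality
studies inflate between-study heterogeneity and bias the summary
estimate. The Q-Genie instrument scores a study on 11 items (hypothesis,
comparison groups, technical and non-technical classification of the
genetic variant, sources of bias, power, planned analyses, statistical
methods, tested assumptions, interpretation), each on a 7-point Likert
scale anchored by "poor" and "excellent". The total (11–77 with a
control group, 10–70 without, where the comparison-group item is
dropped) classifies the study as **low** (≤ 35, or ≤ 32 without control
group), **moderate** (≤ 45 / ≤ 40), or **high** quality.

The package is aimed at systematic reviewers and methodologists who want
to (a) score studies and classify them, (b) re-validate the instrument
on their own rating data, and (c) run the downstream sensitivity
analysis: re-pool a meta-analysis after excluding low-quality studies
and quantify the change in heterogeneity and precision.

## What it computes

* **Scoring/classification** — totals, cut-point schemes, batch scoring
  with class distributions (`total_score`, `classify`, `batch_score`,
  `score_table`).
* **Item analysis** — corrected item-total correlations (items outside
  [0.2, 0.9] flagged as uninformative), Cronbach's α and α-if-deleted,
  endorsement rates (`item_stats`).
* **Reliability (generalizability theory)** — variance components of
  the crossed study × rater × item design via expected-mean-square
  equations, and absolute-error dependability coefficients

  Φ = σ²_τ / (σ²_τ + σ²_Δ),

  where σ²_Δ includes facet main effects; internal consistency,
  inter-rater, overall, and a nested-design inter-user coefficient
  (`estimate_variance_components`, `phi_coefficient`,
  `reliability_suite`, `inter_user_phi`).
* **Standard setting** — borderline-groups regression: regress totals
  on the global-impression grade (1/2/3) and read cut scores at grades
  1.5 and 2.5 (`derive_cutpoints`).
* **Construct validity** — Spearman ρ of totals against impact factor
  and citation rates, with self-citation exclusion (`validity_table`).
* **Meta-analysis sensitivity** — Woolf 2×2 conversion,
  DerSimonian–Laird random-effects pooling, Cochran's Q, I² with the
  Higgins–Thompson test-based confidence interval, and
  exclude-low-quality re-pooling (`pool`, `heterogeneity_from_q`,
  `sensitivity_by_quality`).
* **Seeded simulators** for every input, with ground truth returned for
  recovery testing (`sim_config`, `simulate_ratings`,
  `simulate_global_impressions`, `simulate_impact`, `simulate_meta`).

## Worked example

```r
library(qgenie)

# simulated validation bundle: 30 studies, 4 raters (2 groups), 11 items
cfg <- sim_config()
sim <- simulate_ratings(cfg, seed = 42)
long <- ratings_to_long(sim$ratings)
meta <- data.frame(study_id = dimnames(sim$ratings)[[1]],
                   has_control_group = TRUE)

scores <- score_table(long, meta)
head(scores, 4)
#>   study_id rater_id      variant score quality
#> 1 study_01  rater_1 with_control    67    high
#> 2 study_01  rater_2 with_control    68    high
#> 3 study_01  rater_3 with_control    64    high
#> 4 study_01  rater_4 with_control    56    high
```

Each row is one rater's total for one study under the with-control
scheme (low ≤ 35 < moderate ≤ 45 < high). Reliability of those ratings,
as absolute-error G-coefficients:

```r
reliability_suite(sim$ratings, sim$rater_groups)
#> G-coefficients of reliability (absolute error), by rater group
#>     group internal_consistency inter_rater overall
#>  non_user                 0.96        0.91    0.90
#>      user                 0.95        0.88    0.86
#> Inter-user (all raters, nested in groups): 0.94
```

`internal_consistency` is the dependability of a study's mean over the
11 items (raters fixed), `inter_rater` over the 2 raters (items fixed),
`overall` over both; `inter_user` asks how far one user-status group's
scores generalize to the other. Heterogeneity numbers can be re-derived
from a published Q statistic alone:

```r
h <- heterogeneity_from_q(21.1, 6)
#> I2 = 72% (95% CI 38%-87%), p = 0.0018
```

and the sensitivity procedure on a simulated meta-analysis in which two
low-quality studies carry an upward bias:

```r
sensitivity_by_quality(simulate_meta(cfg, seed = 43))
#> All studies:
#> DerSimonian-Laird random-effects meta-analysis of 7 studies
#> Pooled OR 1.25 (95% CI 0.99-1.58), tau^2 = 0.0701
#> Heterogeneity: Q = 23.55 (6 d.f., p = 0.00063), I^2 = 75% (95% CI 46%-88%)
#>
#> Excluding 2 low-quality:
#> DerSimonian-Laird random-effects meta-analysis of 5 studies
#> Pooled OR 1.06 (95% CI 0.94-1.19), tau^2 = 0.0000
#> Heterogeneity: Q = 1.89 (4 d.f., p = 0.76), I^2 = 0% (95% CI 0%-79%)
```

Exclusion removes the heterogeneity (I² 75% → 0%), shrinks the pooled
odds ratio back toward the simulation's true value of 1.15, and narrows
the confidence interval — the pattern the instrument is designed to
expose.

The same workflow runs from the shell via the thin wrapper:

```sh
Rscript inst/exec/qgenie.R simulate --seed 42 --out sim/
Rscript inst/exec/qgenie.R run --ratings sim/ratings.csv --meta sim/metadata.csv \
    --group-map sim/group_map.csv --global sim/global.csv \
    --impact sim/impact.csv --effects sim/effects.csv --out reports/
```

See `vignettes/qgenie-methods.Rmd` for the models, conventions and
design decisions, and `?sim_config` for every simulator knob.

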