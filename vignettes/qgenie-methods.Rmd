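---
title: "Methods: scoring, reliability and sensitivity analysis for genetic association study quality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, reliability and sensitivity analysis for genetic association study quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qgenie)
```

## The problem

Meta-analyses of genetic association studies pool odds ratios across
studies of very uneven methodological quality: genotyping error, batch
effects, under-powered samples, unchecked Hardy–Weinberg assumptions and
selective reporting all bias individual estimates, and pooling them
inflates heterogeneity and distorts the summary effect. The Q-Genie
instrument addresses this by scoring each published study on 11 items —
from the adequacy of the hypothesis through genotyping classification,
power, statistical methods, and interpretation — each on a 7-point
Likert scale anchored by "poor" (1) and "excellent" (7). The total score
classifies a study as low, moderate, or high quality, and the class
feeds a sensitivity analysis: re-pool the meta-analysis after dropping
the low-quality studies and compare heterogeneity and precision.

This package implements the instrument, the psychometric machinery used
to validate it, and the downstream meta-analysis sensitivity procedure,
all exercised against seeded simulators with known ground truth.

## Scoring and classification

`total_score()` sums the 11 item responses (range 11–77). Item 3 asks
about the description of comparison groups, so for studies without a
control group (e.g. quantitative-trait studies) it is dropped and the
10-item total (range 10–70) is used; a response supplied anyway is
ignored with a warning rather than silently summed. Missing responses
are never imputed — scoring an incomplete rating is an error naming the
item — because no defensible imputation rule exists for an evaluative
instrument with correlated items.

`classify()` applies a `cutpoint_scheme()`: scores at or below `low_max`
are low, at or below `moderate_max` moderate, above it high. The shipped
defaults are the published schemes, 35/45 for the with-control variant
and 32/40 without; both are plain parameters so schemes re-derived from
new data (below) can be substituted.

When several raters score the same study, classification is per rater by
default; `score_table(..., aggregate = "mean")` instead averages the
per-rater totals before classifying. We default to per-rater
classification because averaging discards the rater disagreement that
the reliability analysis is about, and an instrument user in practice
holds one rater's form.

## Item discrimination and internal consistency

`item_total_correlation()` defaults to the *corrected* (item-rest) form
— the item against the sum of the other ten — since the uncorrected form
contains the item in its own criterion and is inflated for short scales;
the uncorrected variant is available via `corrected = FALSE`. Items with
correlations below 0.2 carry little discriminative signal and items
above 0.9 are redundant with the rest of the scale; `item_stats()` flags
both as candidates for exclusion review. `cronbach_alpha()` is the
classical variance-ratio form, with `alpha_if_deleted()` recomputed on
the reduced matrix (it requires at least three items: alpha on a single
remaining item is undefined and raises rather than returning).

Group-stratified tables (e.g. raters who routinely read genetic
association studies versus raters who do not) are produced by filtering
raters by a group label and averaging each study's ratings over the
group's raters before computing study-level statistics. Whether the
original validation tables were built from averaged or pooled per-rater
rows is not determinable from the published material; averaging is our
choice and is documented rather than presented as canonical.
`endorsement_rate()` — the fraction of ratings of 6 or 7 — is always
computed from the raw per-rater ratings, not the averages.

## Generalizability theory

The rating design is fully crossed: every rater scores every study on
every item. The three-way random-effects decomposition attributes
variance to the study (`p`, the universe score — the only variance we
*want*), rater (`r`), item (`i`), their pairwise interactions, and the
confounded three-way interaction plus error (`pri_e`).
`estimate_variance_components()` converts the three-way ANOVA mean
squares through the standard expected-mean-square equations for balanced
designs, e.g.

$$\hat\sigma^2_{pr} = \frac{MS_{pr} - MS_{pri}}{n_i}, \qquad
\hat\sigma^2_{p} = \frac{MS_p - MS_{pr} - MS_{pi} + MS_{pri}}{n_r n_i}.$$

Moment estimators can go negative in small samples; negative estimates
are truncated to zero and flagged (`$truncated`), the conventional
choice for reporting, while the pre-truncation values (`$raw`) are kept
for unbiasedness checks. Unbalanced or incomplete designs are rejected
outright — there is no REML fallback — because every downstream formula
here assumes balance.

`phi_coefficient()` computes the absolute-error dependability
coefficient $\Phi = \sigma^2_\tau / (\sigma^2_\tau + \sigma^2_\Delta)$.
Absolute error includes facet *main* effects (a harsh rater hurts an
absolute score even if they rank studies perfectly), which is the
appropriate error definition when raters are considered a random sample
of all possible raters and scores are interpreted against fixed
cut-points. Three conventions to be aware of:

* **Fixed facets.** For inter-rater reliability the item facet is held
  fixed at the design's $n_i$; the study-by-item interaction then joins
  the universe score ($\sigma^2_\tau = \sigma^2_p + \sigma^2_{pi}/n_i$),
  the item main effect drops out of the error entirely, and interactions
  involving items are averaged over the $n_i$ fixed conditions. This is
  the standard mixed-design convention; both facets are configurable, so
  a single-facet re-analysis that instead collapses the other facet
  before estimation can be compared against it.
* **Internal consistency** is the mirror image (items random, raters
  fixed), and **overall** dependability generalizes over both facets at
  the design sizes.
* The **relative** (generalizability) coefficient, whose error keeps
  only components crossing the study with a random facet, is exposed via
  `type = "relative"` for diagnostics; it can never fall below the
  absolute coefficient.

Inter-user reliability — how far a rating from one user-status group
generalizes to the other — uses a nested design: each rater's item
ratings are summed to a study total, raters are nested in groups, and
`inter_user_phi()` applies the nested-design expected-mean-square
equations with both group and rater-within-group random:

$$\Phi = \frac{\sigma^2_p}{\sigma^2_p + \sigma^2_g/n_g +
\sigma^2_{pg}/n_g + \sigma^2_{r:g}/(n_g n_r) +
\sigma^2_{pr:g,e}/(n_g n_r)}.$$

When the group components vanish this collapses exactly to a pooled
inter-rater coefficient with $n_g n_r$ raters, which the tests verify
algebraically.

## Standard setting by borderline-groups regression

Raters additionally answer a single global-impression question (1–7);
ratings 1–2 map to grade "low", 3–4 to "moderate", 5–7 to "high". The
asymmetric bands reflect the positive skew typical of evaluative Likert
ratings. `derive_cutpoints()` regresses the instrument total on the
numeric grade (coded 1/2/3, equally spaced) by ordinary least squares
and reads the cut scores at the borderline grades 1.5 and 2.5 — the
borderline-regression convention for standard setting. Predictions are
rounded half-up because published schemes are integer scores; fits with
non-positive slope (quality not increasing with grade) or a single grade
present are rejected. For the without-control variant, totals are
recomputed with item 3 excluded before fitting. Whether to fit per-rater
(score, grade) pairs or rater-averaged ones is open in the source
material; the pipeline fits per-rater pairs, which keeps the regression
n at raters × studies and weights raters equally.

## Construct validity

Higher-quality studies should be cited more and appear in higher-impact
journals. `validity_table()` reports Spearman's $\rho$ between study
totals and impact factor, average citations per year (with and without
self-citations by the first and senior authors), and total citations.
Citations per year divides by the inclusive count of calendar years
since publication with a floor of one, so a study published in the
analysis year is not divided by zero. $\rho$ is the Pearson correlation
of midranks; p-values use the t approximation on $n-2$ degrees of
freedom, adequate at the instrument-validation sample sizes (n = 30). An
exact full-enumeration permutation p-value is available for very small
samples (`exact = TRUE`, capped at n = 8, beyond which enumeration is
pointless and the t approximation is already accurate).

## Meta-analysis and the quality-stratified sensitivity procedure

Effects enter as log odds ratios with standard errors, or as 2×2 counts
converted by the Woolf method (`effect_from_2x2()`), adding 0.5 to every
cell only when some cell is zero. `pool()` defaults to
DerSimonian–Laird random effects — the source meta-analysis pooled
odds ratios in the presence of heterogeneity, for which a fixed-effect
model would be indefensible — with the fixed-effect model behind a flag.
Heterogeneity is summarized by Cochran's Q, its chi-square p-value, and
$I^2 = \max(0, (Q - df)/Q)$, with the Higgins–Thompson *test-based*
confidence interval on the $\ln H$ scale. The test-based interval was
chosen over Q-profile alternatives because it is the closed form
consistent with both published worked intervals for this analysis
(I² 72%, CI 38–87% at Q = 21.1 on 6 d.f.; I² 0%, CI 0–75% at Q = 3.04
on 5 d.f., reproduced in `heterogeneity_from_q()` examples). Display
rounding follows the field's reporting style: whole percents for I²,
two decimals for odds ratios.

`sensitivity_by_quality()` pools all studies, re-pools without the
low-quality ones, and reports the change in Q, I², $\tau^2$ and CI
width plus a forest-plot-ready per-study table. Note that excluding
studies always discards information: when the biased studies drive
heterogeneity the precision gain from a smaller $\hat\tau^2$ normally
dominates, but in marginal cases (small $\hat\tau^2$ to begin with,
excluded studies carrying large inverse-variance weight) the restricted
interval can come out slightly wider. The simulation tests quantify how
often each happens rather than assuming a direction.

## The synthetic-data generators

No raw per-study ratings or per-dataset effect sizes are published for
the original validation sample, so all numeric validation here is
parameter recovery on simulated data. `sim_config()` defaults mirror the
validation design: 30 studies, 4 raters in 2 user-status groups, 11
items, grand mean 4.5 on the 7-point scale. The default variance
components ($\sigma^2_p = 1.0$, $\sigma^2_r = 0.1$, $\sigma^2_i = 0.2$,
$\sigma^2_{pr} = 0.3$, $\sigma^2_{pi} = 0.2$, $\sigma^2_{ri} = 0.05$,
$\sigma^2_{pri,e} = 0.8$) put roughly a third of total variance in true
study differences with a sizeable residual — the regime in which the
instrument's reported coefficient magnitudes (dependability in the
0.4–0.85 band) arise naturally.

`simulate_ratings()` draws all seven effects as independent zero-mean
normals and discretizes by round-and-clip. Clipping at the scale ends
shrinks extreme latent values, which biases component recovery when the
grand mean sits near 1 or 7; a graded-threshold alternative is provided,
and the recovery tests that assert *unbiasedness* use the continuous
pre-discretization output (`discretize = "none"`), where the estimators
are exactly moment-unbiased. What the simulator does **not** emulate:
ordinal response styles (end aversion, halo effects), rater drift over
time, and item-specific response distributions — so passing recovery
tests demonstrate the estimators, not that real rater behaviour follows
the crossed normal model.

The companion generators derive everything else from the same latent
study quality: `simulate_global_impressions()` anchors global ratings at
2/4/6 by latent tercile plus rater noise (0.5 SD by default — enough to
blur adjacent grades occasionally, as real global impressions do);
`simulate_impact()` links log impact factor linearly to standardized
latent quality (weight 0.5, noise 0.3) with Poisson citation counts and
a 10% expected self-citation share; `simulate_meta()` draws a
7-study meta-analysis (matching the worked example's 7 datasets) with
true pooled log OR $\log 1.15$, $\tau^2 = 0$, per-study SEs uniform on
0.08–0.25, and an upward bias of 0.5 on the log-OR scale injected into
the 2 studies labelled low quality — so that excluding them both
removes heterogeneity and moves the pooled estimate, the pattern the
sensitivity procedure is designed to reveal.

Every generator is a pure function of (configuration, seed) and restores
the caller's RNG state.

## Problem sizes used in the test suite

The recovery tests run at sizes chosen to make Monte-Carlo error small
relative to the assertions while keeping the default suite quick: 500
replicates of a 200-study array for component unbiasedness (each
component's mean estimate within 3 Monte-Carlo standard errors of
truth), 1,000 random component sets for the monotonicity of $\Phi$ in
the D-study sizes, 200 replicates at n = 300 for cut-point recovery
(within ±1 of 35/45 in at least 95%), and 200 seeded replicates of the
biased meta-analysis simulation. Definitional-oracle comparisons
(sums-of-squares, covariance-form alpha and item-rest correlations,
midrank Spearman, metafor cross-checks) run at small sizes where the
reference route is exact.

## Known limitations

* Balanced designs only: missing rating cells are an error, never
  imputed or handled by REML.
* The instrument item text ships as published; no rater training
  material or form rendering is included.
* Citation counts are inputs; the package does not retrieve them.
* The exact-permutation Spearman p-value is capped at n = 8.
* Cut-point derivation assumes the three global grades are equally
  spaced on the quality continuum; if that coding is wrong the
  borderline predictions shift accordingly.
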