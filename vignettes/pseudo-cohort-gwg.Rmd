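---
title: "Pseudo-cohort estimation of gestational weight gain: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudo-cohort estimation of gestational weight gain: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwgcohort)
```

## The design and its assumptions

Gestational weight gain (GWG) is defined longitudinally — the weight a
woman gains between conception and delivery — but cross-sectional household
surveys observe each woman only once. The pseudo-cohort design substitutes
population means for individual follow-up: if pregnant women reporting
gestational month $m$ are exchangeable with the women who will reach month
$m+1$, the sequence of month-specific mean weights $W_1, \dots, W_9$ traces
the population trajectory, and the total gain is the difference between the
trajectory's endpoints.

Two features of survey anthropometry shape the estimator:

1. **Pre-pregnancy weight is unobserved.** The baseline is proxied by the
   mean weight of non-pregnant women *at risk of conception*: menstruating,
   sexually active, using no contraceptive method (modern or natural), and
   not having given birth within the previous 12 months. The postpartum
   exclusion avoids contaminating the baseline with retained pregnancy
   weight; restricting to women at conception risk, rather than all
   non-pregnant women, keeps the baseline population comparable to the
   women who actually become pregnant.
2. **Gestational age is month-binned.** A reported month $m$ represents a
   ±2-week window around day $30m$, so $W_9$ represents day 270 and
   understates weight at delivery (40 weeks). The third-trimester monthly
   rate $(W_9 - W_6)/3$ is extrapolated one-third of a month further:
   $W_{del} = \tfrac{10}{9} W_9 - \tfrac{1}{9} W_6$. We fix the month
   length at 30 days because it is the only convention under which "40
   weeks" and "9 months and 10 days" coincide (280 days).

The design's identifying assumptions — no cohort effects across gestational
months, normal gestation length, accurate month self-report — are
assumptions about the survey population, not checkable from a single
cross-section. The synthetic generator (below) exists partly to probe what
happens when they fail.

## Weighting

Surveys of this kind carry design weights reflecting household/individual
selection probabilities, and multi-country pooling requires
post-stratification so that small, heavily sampled countries do not
dominate. The factor for country $c$ is its population share among the
countries represented in the analysis set,
$f_c = P_c / \sum_{c' \in \text{set}} P_{c'}$, from a user-supplied
metadata table (reference-year total populations). The final weight
$w_i \propto s_i f_{c(i)}$ is rescaled so $\sum_i w_i = n$, the unweighted
record count. We read the balancing of weighted and unweighted sample sizes
as exactly this rescaling: it is the standard survey normalisation, and it
is what makes $n$ the natural divisor in the SE formula below.

Two consequences of this contract are worth stating. Final weights are
invariant to rescaling all sampling weights by a constant, and — because
both the mean and the SE estimator are scale-invariant in the weights —
restricting globally normalised weights to a subgroup gives the same
estimates as renormalising within the subgroup. Stratified analyses
therefore need no per-stratum weight handling.

## Uncertainty

For a weighted mean with weights normalised to $\sum w = n$ we use

$$\widehat{se}^2 = \frac{1}{n}\cdot\frac{\sum_i w_i (x_i - \bar x)^2}{n - 1},$$

which reduces to the classical $s/\sqrt n$ under equal weights. This
estimator ignores the design effect of unequal weights and of cluster
sampling; a Taylor-linearised cluster-robust alternative is available via
the `cluster` argument wherever means are computed, and the acceptance
bootstrap (tests) quantifies the understatement at the default weight
dispersion as a few percent. Intervals are $\bar x \pm 1.96\,se$ throughout
— analysis sets are large enough that a $t$ correction would be
cosmetic — and a single-observation group reports its mean with `NA` SE and
no interval.

Derived quantities propagate variance assuming independence of the group
means involved, which holds by construction (distinct women):
$\mathrm{var}(W_{del}) = (10/9)^2 se_9^2 + (1/9)^2 se_6^2$ (delta method on
the linear extrapolation), and each gain's variance is the sum of its two
anchors' variances. On noiseless inputs all SEs collapse to zero and the
intervals are degenerate — a property the tests assert.

Group and period contrasts use the CI-overlap rule: a difference is flagged
only when the two 95% intervals are disjoint, with closed intervals, so
exact endpoint contact counts as overlap (a deterministic tie rule).
The rule is conservative: contrasts whose two-sample $z$-test would reject
at $p \approx 0.04$ typically still show overlapping intervals, and the
test suite pins that behaviour down as documented, expected conservatism
rather than a defect. No multiplicity adjustment is applied across strata.

## Eligibility filtering choices

Exclusions are tallied under the *first* failing criterion in a fixed
precedence — pregnancy status, postpartum, contraception, menstruation,
abstinence, missing weight — so tallies are mutually exclusive, sum to the
number excluded, and are reproducible regardless of row order. Missing
eligibility attributes fail their criterion (we do not impute), with one
deliberate exception: a missing time-since-last-birth means no birth was
recorded and passes the postpartum screen, because the exclusion targets
women *known* to have delivered recently. The postpartum screen applies
only to the at-risk set; currently pregnant women are screened on
completeness of gestational month and weight alone. The postpartum window
is a parameter (`postpartum_exclusion_months = 12`) to support sensitivity
analysis. A reported gestational month of 10 — a small fraction of
self-reports — is recoded to 9 rather than dropped.

First-trimester gain is reported exactly as computed ($W_3 - W_{pre}$),
even when small or negative; we do not force it to zero.

## The synthetic generator

`truth_params()` defines a generating process whose defaults are the
reference scenario the package is validated against:

- **Countries.** Four countries, one per sub-region, with 2020-scale
  populations (206/115/90/59 million) and baseline mean weights 57.8,
  55.2, 56.1 and 59.8 kg, whose population-weighted mean is 57.1 kg.
  Sample shares are equal — survey sample sizes are not proportional to
  population, which is precisely why post-stratification matters.
- **Trajectory.** Piecewise-linear in gestational days with knots at 0,
  90, 180 and 280 days and trimester gains 1.2, 2.2 and 3.2 kg
  (total 6.6 kg). A quadratic third-trimester option reaches the same
  280-day endpoint along an accelerating path and exists solely to probe
  extrapolation bias.
- **Noise.** Between-woman baseline SD 9.9 kg plus measurement/short-term
  SD 8 kg, giving a cross-sectional weight SD of
  $\sqrt{9.9^2 + 8^2} \approx 12.7$ kg, typical of adult-female weight in
  the target surveys.
- **Composition.** Pregnant fraction 0.198; the reported-month
  distribution follows the empirical month counts of the target surveys
  (months 1 and 9 underrepresented); 0.3% of pregnant women report
  month 10. Among non-pregnant women: 85% menstruating, 75% sexually
  active, 25% using contraception, 18% with a birth in the last year —
  so about 39% qualify as at risk, a rate the tests verify against the
  product of the rates.
- **Sampling.** Lognormal cluster-level weights (sdlog 0.3, mean 1) over
  50 clusters per country: moderate, heavy-tailed weight variation of the
  kind survey design weights show.
- **Gestational day.** Uniform within the reported month's ±14-day window
  (`day_sampling = "window"`), matching the month-binning convention; the
  `"center"` option pins each woman to day $30m$ so that zero-noise runs
  are exactly recoverable, which the exactness tests use.

The generator returns closed-form truth alongside the records: true month
means (integrating the piecewise line over each ±14-day window — months 3
and 6 straddle knots, so the window mean is not simply the line's value at
the centre), the true 280-day endpoint, and the large-sample expectations
of the pipeline's own estimators. Under the window convention the
extrapolated-total expectation differs from the true 6.6 kg by under
0.01 kg, which is why recovery tests can target the true value directly.

Stratifier effects (additive baseline and total-gain offsets by education,
wealth or residence level, gain offsets allocated to trimesters
proportionally) create known subgroup contrasts for testing the stratified
and comparison machinery.

**What the generator does not emulate** — and what passing tests therefore
do not establish about real data: cohort effects across gestational months,
gestation-length variation (every pregnancy runs to 280 days),
within-cluster outcome correlation (weights vary by cluster but outcomes
are independent, so the default SE's clustering understatement is not
exercised), systematic month misreporting (available as an option,
`month_misreport_rate`, default 0), and any dependence of eligibility
attributes on weight. Validation shows the estimator recovers the truth of
*this* process; on real data the design assumptions above still carry the
inferential burden.

## Validation problem sizes

The test suite exercises exact recovery on noiseless single-country
cohorts (n = 5,000; with multi-country heterogeneous baselines the
finite-sample country mix perturbs every mean, so exactness is only
defined in the single-country case), stochastic recovery of the 6.6 kg
total within 3 estimated SEs across 100 seeds at n = 20,000, convergence
to closed-form truth at n = 100,000 with zero noise, a 2,000-replicate
bootstrap check of the delta-method delivery SE (agreement within 15%),
and brute-force re-derivations of the filters and weights on randomised
fixtures. The acceptance script simulates at n = 110,000 — the scale of
the pooled surveys the design targets — and two trend periods of 54,600
and 49,100 records on a common country panel.

## Known limitations

- The month-window convention makes month means of a piecewise-linear
  trajectory slightly nonlinear near knots; the induced bias in the
  extrapolated total is negligible (<0.01 kg) but not zero.
- The default SE understates uncertainty under strong weight dispersion or
  cluster correlation; use `cluster` when cluster identifiers exist.
- The CI-overlap rule's conservatism is inherited by design; it is a
  screening flag, not a hypothesis test.
- Linear extrapolation understates delivery weight when third-trimester
  gain accelerates (and overstates it when gain decelerates); the
  quadratic-truth property test quantifies the direction.
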