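---
title: "Risk-factor statistics and screening economics for proliferative diabetic retinopathy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-factor statistics and screening economics for proliferative diabetic retinopathy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdrscreen)
```

## The problem

Proliferative diabetic retinopathy (PDR) is the vision-threatening end stage
of diabetic retinopathy, and young-onset type 1 diabetes (T1D) patients carry
a particularly high lifetime risk.  `pdrscreen` implements two connected
analyses for a cross-sectional case-control cohort of young-onset T1D
patients (diagnosed at or before 30 years of age, diabetes duration over five
years):

1. a **univariate risk-factor battery** comparing PDR cases with
   non-proliferative/no-retinopathy (NPDR) comparators, and
2. a **deterministic budget-impact model** projecting the cost and the
   prevented PDR cases of a national retinopathy screening programme.

The underlying patient-level data are not publicly deposited, so the package
also ships a **synthetic cohort generator** that emulates the published
group-level summaries, making the whole pipeline testable end to end.

## The statistical battery

Every risk factor is dichotomized (`dichotomize()`) and summarised as a 2x2
exposure-by-outcome table with cells `a` (risk, PDR), `b` (risk, NPDR),
`c` (reference, PDR), `d` (reference, NPDR).  The built-in factors are:

* long-term glycaemic control: *poor* means a long-term average
  HbA1c above 7% (53 mmol/mol);
* regularity of ophthalmological examinations per screening guidelines;
* age at diabetes onset, at/before versus after 18 years;
* diabetes duration above versus at/below the cohort median
  (22.5 years in the study cohort).

For each table the package computes:

* the cross-product **odds ratio** $\widehat{OR} = ad/bc$ with the **Woolf
  interval** $\exp\!\big(\ln\widehat{OR} \pm z_{1-\alpha/2}
  \sqrt{1/a+1/b+1/c+1/d}\big)$ and a Wald p-value on $\ln OR$.  This equals
  the exponentiated coefficient of a univariate binary-exposure logistic
  regression (the package's test suite verifies the equivalence against a
  maximum-likelihood `glm()` fit to six significant figures).  A single zero
  cell triggers the Haldane–Anscombe +0.5 adjustment, flagged in the result;
  a zero diagonal is an error.
* the **continuity-corrected chi-square**
  $\sum \big(\max(0, |O-E| - \tfrac12)\big)^2 / E$ with 1 df.  The clamp at
  zero makes proportional tables score exactly 0.  The Yates correction is
  the default because the study's printed statistics (16.2, 24.7, 11.7, 9.9)
  match it, while plain Pearson gives 18.4 for the first table; the
  uncorrected statistic remains available via `correct = FALSE`.  (The
  printed values appear truncated rather than rounded at one decimal — the
  corrected statistic for the duration table is 9.978 — so reproduction
  checks use a one-unit-in-the-last-digit band.)

Continuous variables are compared after **normality routing**
(`normality_route()`): the one-sample Kolmogorov–Smirnov distance against a
normal with estimated mean and SD is compared with the Lilliefors-corrected
critical value (Stephens' modified-statistic approximation; plain KS critical
values are anti-conservative when parameters are estimated).  Non-normal
variables are summarised as median [min–max] and compared with the
**Mann–Whitney U test** (midranks, tie-corrected variance, continuity-
corrected z) together with the **Hodges–Lehmann shift estimate** — the median
of all pairwise between-group differences — and its order-statistic
confidence interval at the normal-approximation rank cutoffs.  Normal
variables use the pooled-variance Student t-test (pooled, not Welch, as the
common default of era statistical packages; switchable only by calling
`pooled_t_test()` directly versus your own alternative).

Numerical notes:

* For large cohorts the Hodges–Lehmann order statistics are selected by
  value-bisection with `findInterval()` counting, $O((n+m)\log)$ per rank,
  rather than materialising all $n \times m$ differences (infeasible at
  $10^5$ per group).  The dense path is kept for $nm \le 2\times10^6$ and
  both paths agree to machine precision.
* The normal approximation to the exact Mann–Whitney p (validated in the
  test suite against full enumeration of label assignments) is accurate to
  about 0.02 absolute at group sizes of 7–8, but only to about 0.17 for
  groups of 2–3, where the exact null distribution is very coarse.  With the
  study's group sizes (27 and 31) the approximation is excellent.
* Records lying exactly on an exclusive dichotomization threshold (e.g. a
  duration equal to the median split) have no natural side; `dichotomize()`
  raises an error listing the patient ids unless an explicit `tie_policy`
  ("lower"/"upper") is chosen.
* No multiplicity adjustment is applied: the factors are reported as
  univariate tests with raw p-values, matching the source analysis.

## The screening economics model

`run_scenario()` is a single-period deterministic model.  With population
$P$, uptake $u$, screening interval $y$ (years), PDR prevalence $\pi$, and
preventive effect $e$:

$$\text{screened} = Pu, \qquad
  \text{cost} = Pu \cdot c_v / y, \qquad
  \text{expected} = Pu\pi, \qquad
  \text{prevented} = Pu\pi e,$$

where $c_v$ is the combined per-visit cost (fundus photography EUR 40.16 +
OCT EUR 36.71 = EUR 76.87).  Avoided treatment spending multiplies the
prevented cases (rounded half-up to whole persons for display) by the annual
treated-patient cost: 4 monitoring visits at $c_v$, one laser session
(EUR 84.32), five intravitreal anti-VEGF injections (procedure EUR 304.91 +
aflibercept EUR 655.91 each) and one vitrectomy (EUR 2011.55), totalling
EUR 7207.45 per patient per year.  All money is carried in integer euro
cents, so every reported amount is exact to the cent.

Design choices worth stating explicitly:

* The programme cost charges **one combined visit per screened person per
  round**; the published cost column (EUR 461,220 for 6,000 screened) forces
  this reading, while the "4 visits/year" multiplier belongs to the treated-
  patient cost only.
* The headline "net economic impact" column of the source table equals
  *prevented cases x EUR 7207.45* with **no** subtraction of the programme
  cost.  The model reports both that publication-compatible quantity
  (`avoided_treatment_eur`) and the economically net one
  (`net_of_screening_eur`).
* Biennial screening halves the annualised programme cost and leaves the
  preventive effect unchanged, exactly as in the published biennial row;
  this is an assumption of the source model, not an epidemiological claim.
* Prevented cases are rounded half-up before the monetary multiplication.
  At medium uptake this gives 1974 cases (6,000 x 0.47 x 0.70 = 1973.4 …
  the printed 1973 is unreachable under any rounding of 1974.0 and is
  treated as a typo); the headline EUR 14.2M annual saving still reproduces
  at one-decimal-million precision.
* `break_even()` runs on the *unrounded* model (case rounding disabled for
  continuity) and bisects to $10^{-6}$ relative tolerance.  For the
  preventive effect the closed form is
  $e^\ast = c_v / (\pi \cdot \text{treated cost}) \approx 0.023$: screening
  pays for itself at an effectiveness of about 2.3%.
* No discounting, Markov transitions, QALYs, or probabilistic sensitivity —
  the source model is single-period deterministic, and the package keeps
  that scope.

## The synthetic cohort generator

`generate_cohort()` targets the published group summaries
(`table1_cohort_spec()`):

* **Skewed variables** (duration, onset age, LDL, triglycerides) are drawn
  from a Beta distribution rescaled to the published [min, max].  The first
  shape parameter is fixed at 2 for identifiability and a unimodal density;
  the second is solved numerically so that the distribution median equals
  the published median.  This respects the printed range exactly and the
  median asymptotically.
* **Symmetric variables** (HbA1c, fasting glucose, blood pressures, total
  cholesterol) are normal draws truncated at zero; all published means sit
  many SDs above zero, so truncation is inert in practice.
* **Age is derived**, not sampled: age = onset + duration, clipped towards
  the published age range but never more than 2 years away from the sum, so
  the internal-consistency invariant holds by construction.  Note the
  published NPDR medians are mutually inconsistent at the one-year level
  (onset 28 + duration 20 = 48 versus printed age median 47), so the age
  median is only recoverable within that slack.
* **Categorical fields** (sex, long-term control, exam regularity) are
  independent Bernoulli draws at the published fractions.  Long-term control
  is sampled independently of the generated current-HbA1c value because the
  study's category derives from historical records, not the measurement at
  examination.

The generator emulates *marginal* distributions only: apart from the
age = onset + duration identity it models no between-variable correlation
(none is published), so a generated cohort will not reproduce the published
odds ratios — those depend on the joint distribution.  That is what
`fixture_cohort()` is for: a deterministic 58-patient cohort whose four
dichotomized factors match the published counts exactly.  Passing parameter-
recovery tests therefore demonstrates correct marginal targeting, not
clinical realism of joint structure.

At $10^5$ patients per group, every sampled target median and mean is
recovered within 2% relative error and every categorical fraction within
0.01 absolute (asserted in the test suite; the recovery run takes a few
seconds).  Default problem sizes elsewhere in the suite (300–20,000 per
group) were chosen to exercise both Hodges–Lehmann code paths while keeping
the whole suite under ten seconds.

## Known limitations

* The study's raw continuous data are unpublished, so the in-text
  Mann–Whitney Z values and the t statistic for blood pressure are not
  reproduction targets; the machinery is instead validated by enumeration,
  closed forms, and coverage simulation (the Woolf interval covers a known
  odds ratio in 93–97% of 1,000 simulated case-control tables).
* The published low-uptake net impact (EUR 7,113,753.24) differs by EUR 0.09
  from 987 x 7207.45 = EUR 7,113,753.15; the model reproduces the arithmetic,
  not the typo.
* The Lilliefors critical values use Stephens' approximation, adequate for
  n >= 4 at the supported alpha levels; it is a design decision, not a claim
  about the original analysts' software.
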