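# pdrscreen

Risk-factor statistics and screening economics for proliferative diabetic
retinopathy (PDR) in young-onset type 1 diabetes (T1D).

PDR is the vision-threatening end stage of diabetic retinopathy, and
young-onset T1D patients (diagnosed at or before age 30, diabetes duration
over five years) carry a particularly high lifetime risk. `pdrscreen` is for
ophthalmic epidemiologists and health economists who want to (a) run the
standard univariate case-control battery on such a cohort and (b) project
the budget impact of a national retinopathy screening programme — plus a
synthetic cohort generator so the whole pipeline is testable without any
patient-level data.

## What it computes

**Risk statistics.** Each risk factor (poor long-term control, HbA1c > 7%;
irregular eye exams; onset ≤ 18 y; duration above the cohort median) is
dichotomized into a 2×2 table *(a, b, c, d)* and scored with

- the cross-product odds ratio *OR = ad/bc* with the Woolf interval
  exp(ln OR ± z·√(1/a + 1/b + 1/c + 1/d)) — identical to the exponentiated
  univariate logistic-regression coefficient — with Haldane–Anscombe +0.5
  adjustment on zero cells, and
- the Yates continuity-corrected chi-square
  Σ (max(0, |O−E| − ½))² / E on 1 df.

Continuous variables route through a Lilliefors-corrected
Kolmogorov–Smirnov normality check to either the Mann–Whitney U test with
the Hodges–Lehmann shift estimate (median of all pairwise differences, with
an order-statistic confidence interval) or the pooled-variance t-test.

**Screening economics.** A single-period deterministic model: screened =
population × uptake; programme cost = screened × €76.87 (fundus + OCT) per
round; expected PDR cases = screened × prevalence (0.47); prevented cases =
expected × preventive effect (0.70); avoided treatment spending = prevented
× €7207.45 per treated patient-year. Money is held in integer cents — every
output is exact. Break-even and one-way sensitivity analyses are included.

**Synthetic cohorts.** `generate_cohort()` draws cohorts whose marginal
distributions match published group summaries (scaled-Beta skewed variables,
truncated-normal symmetric ones, age = onset + duration);
`fixture_cohort()` deterministically rebuilds the 58-patient study cohort's
categorical structure exactly.

## Worked example

```r
library(pdrscreen)
comp <- compare_groups(fixture_cohort(), duration_threshold = 22.5)
print(comp)
```

```
Dichotomized risk factors
  Factor                 PDR a/c    NPDR b/d     chi2        p            OR (95% CI)
  longterm_control          23/4        9/22    16.20 5.706e-05     14.06 (3.77-52.35)
  exam_regularity           22/5        4/27    24.74 6.566e-07    29.70 (7.11-124.14)
  onset_age                16/11        4/27    11.75 0.0006081      9.82 (2.67-36.05)
  duration                  20/7        9/22     9.98  0.001584      6.98 (2.19-22.25)
```

Poor glycaemic control multiplies the odds of PDR by about 14, and irregular
eye examinations by nearly 30; all four factors are significant at the 0.01
level.

```r
writeLines(render_scenario_table(scenario_grid(default_scenarios(),
                                               cost_inputs())))
```

```
Scenario                       Screened   Screening cost   Expected  Prevented  Avoided treatment   Net of screening
Annual - Low Uptake (30%)          3000       230,610.00       1410        987       7,113,753.15       6,883,143.15
Annual - Medium (60%)              6000       461,220.00       2820       1974      14,227,506.30      13,766,286.30
Annual - High (90%)                9000       691,830.00       4230       2961      21,341,259.45      20,649,429.45
Biennial - Medium (60%)            6000       230,610.00       2820       1974      14,227,506.30      13,996,896.30
```

Screening 6,000 of 10,000 patients annually costs €0.46M and avoids about
€14.2M in yearly treatment spending; even at 30% uptake the programme is
strongly cost-saving. "Avoided treatment" is prevented cases × treated-year
cost; "net of screening" additionally subtracts the programme cost.

A command-line wrapper covers the same pipeline:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","pdrscreen.R",package="pdrscreen"))')" \
  report --out results/
```

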