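# rptcs — dynamic conditional survival for resected primary retroperitoneal tumors

`rptcs` implements the dynamic (conditional) survival analysis used for
registry cohorts of surgically resected primary retroperitoneal tumors
(RPTs): Kaplan–Meier estimation of overall survival (OS) and cause-specific
cancer survival (CSS) with Greenwood variance, kernel-smoothed hazard
curves, log-rank comparisons, univariable and multivariable Cox
proportional-hazards models, and — at its core — the conditional survival
statistic

    CS(y | x) = S(x + y) / S(x)

the probability of surviving a further `y` years given survival to year
`x`. The 3-year conditional series `COS3(x) = OS(x+3)/OS(x)` and
`CCSS3(x) = CSS(x+3)/CSS(x)` quantify how prognosis improves with time
already survived; subgroup gaps are summarised by the standardized
difference `d = (P2 − P1)/√[P(1 − P)]` with the pooled cohort rate `P`,
banded at |d| = 0.1 / 0.3 / 0.5.

It is written for biostatisticians and clinical researchers working with
SEER-style case listings. Because registry extracts cannot be
redistributed, the package includes a seeded generator of SEER-like cohorts
(covariate marginals, competing cause-specific proportional-hazards clocks,
accrual and administrative censoring) so the entire pipeline is testable
and reproducible end to end.

## Worked example

```r
library(rptcs)

coh <- generate_cohort(sim_config(n_subjects = 1594, seed = 7))
flt <- apply_inclusion_filters(coh)
os  <- km_curve(flt$cohort, "os")
os
#> OS Kaplan-Meier curve: 1594 subjects, 632 events, follow-up to 155 months

round(100 * survival_at(os, c(12, 36, 60))$estimate, 1)
#> [1] 88.9 71.4 60.7          # actual 1-, 3-, 5-year OS (%)

s <- cs3_series(os, x_max = 5)
round(s$cs3, 1)
#> [1] 71.4 73.3 75.7 79.1 80.0 79.4   # COS3 over years already survived
```

The actual OS falls over time while the 3-year conditional rate rises: a
patient who has already survived 4 years has an 80% chance of 3 more years,
against 71% at surgery. Subgroup gaps shrink as time passes:

```r
strata <- stratified_cs3(flt$cohort, "fnclcc_grade", "os", x_max = 5)
dt <- d_series(strata, s, list(c("I", "III")))
data.frame(x = dt$x, d = round(dt$d, 2), band = dt$band)
#>   x    d        band
#> 1 0 0.50    moderate
#> 2 1 0.64 significant
#> 3 2 0.65 significant
#> 4 3 0.60 significant
#> 5 4 0.46    moderate
#> 6 5 0.22       small
```

The same statistic applied to published subgroup rates:

```r
standardized_difference(0.905, 0.538, 0.718)
#> d = 0.82 (significant): P2 = 0.905, P1 = 0.538, pooled P = 0.718
```

`run_pipeline(pipeline_config(...))` chains the whole analysis — inclusion
filters with an attrition report, KM and smoothed-hazard curves for both
endpoints, univariable screen, multivariable Cox fit, the conditional
survival matrix, stratified CS3 tables with d rows — writing each table to
disk plus a manifest with content hashes; identical seeds give
byte-identical outputs.

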