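# urrbmi

Tools for measuring how China's **Urban-Rural Resident Basic Medical
Insurance (URRBMI)** — the flat-premium scheme covering roughly 70% of the
population — redistributes income. The package is for health-financing and
health-equity researchers who want either a transparent calibrated model of
the scheme's premium/deductible/coinsurance arithmetic, or a survey
pipeline that estimates before/after-reimbursement inequality from
CHFS-style household microdata.

## What it computes

Inequality is measured on grouped data: after sorting incomes and splitting
the population into *n* equal groups, the Lorenz curve joins the cumulative
population share *p*<sub>t</sub> and income share *q*<sub>t</sub>, and

> G = 1 − 2B = Σ<sub>t</sub> (p<sub>t</sub> q<sub>t+1</sub> − p<sub>t+1</sub> q<sub>t</sub>),

with B the trapezoid area beneath the curve. The redistributive effect of
reimbursement is the Musgrave-Thin index **MT = G − G\***, the drop in the
Gini from after out-of-pocket payment (G) to after reimbursement (G\*), and
its relative form **RMT = 100·MT/G** (%).

Three layers build on this:

* **Benefit rules** — `policy_schedule()` / `reimbursement()`: payout
  min(rate·max(0, expense − deductible), ceiling).
* **Calibrated microsimulation** — five income quintiles (0.3–3 W<sub>r</sub>,
  W<sub>r</sub> = RMB 40,000), five expense brackets, an income-tilted
  probability matrix, and the Beijing 2024 secondary-tier schedule;
  `scenario1()` measures redistribution among the insured, `scenario2()`
  compares enrolment against an uninsured counterfactual.
* **Survey pipeline** — `analyze_survey()` constructs per-capita disposable
  income from CHFS-named variables (f2001a, f2024, f2025_*, …), classifies
  URRBMI enrolment, and estimates Gini/MT nationally, by region and by
  expenditure tercile. `simulate_survey()` generates synthetic CHFS-like
  data with an embedded truth sheet, since the real CHFS is
  access-restricted.

## Worked example

```r
library(urrbmi)

gini_grouped(c(0.3, 0.6, 1, 2, 3))   # initial quintile Gini
#> [1] 0.3942029

scenario1(urrbmi_calibration())
#>   bracket gini_after_oop gini_after_reimb     mt rmt_percent
#> 1    0.02         0.3977           0.3977 0.0000    0.000000
#> 2    0.08         0.4006           0.3872 0.0134    3.344983
#> 3    0.14         0.4054           0.3789 0.0265    6.536754
#> 4    0.20         0.4120           0.3727 0.0393    9.538835
#> 5    0.26         0.4206           0.3683 0.0523   12.434617
```

Reading the Scenario 1 table: at the deductible bracket (0.02 W<sub>r</sub>)
no benefit is triggered and MT = 0; for a 0.26 W<sub>r</sub> hospital bill
the reimbursement cuts the quintile Gini from 0.4206 to 0.3683 — an
absolute redistribution of 0.0523, or 12.43% of the pre-benefit Gini. MT
rises monotonically with claim size: bigger bills, stronger redistribution.

The empirical pipeline on synthetic data:

```r
sim <- simulate_survey(generator_config(n_households = 5000, seed = 2024))
res <- analyze_survey(sim$data)
res$national
#>    stratum     n gini_before gini_after          mt
#> 1 national 14690   0.5432899   0.538971 0.004318881
res$by_bracket_inpatient
#>   stratum   n gini_before gini_after          mt
#> 1     low 495   0.5376469  0.5315380 0.006108918
#> 2  medium 495   0.6079314  0.5717742 0.036157201
#> 3    high 495   0.6140691  0.5301832 0.083885849
```

The national MT is small but positive (the scheme narrows inequality
overall), and bracketed MT rises low → medium → high — the same
qualitative pattern the calibrated model predicts. `sim$truth` carries the
generator's own computation of these indices; the pipeline recovers it to
10<sup>−12</sup>.

Command-line wrappers around the same functions:

```sh
Rscript inst/exec/urrbmi.R theory   --out tables/
Rscript inst/exec/urrbmi.R simulate --out survey.csv --truth truth.json --seed 7
Rscript inst/exec/urrbmi.R analyze  --in survey.csv --out results/
```

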