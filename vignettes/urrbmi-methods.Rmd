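---
title: "Measuring the redistributive effect of resident basic medical insurance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the redistributive effect of resident basic medical insurance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urrbmi)
```

## The question

China's Urban-Rural Resident Basic Medical Insurance (URRBMI) collects a
flat annual premium from every enrollee and reimburses part of their
medical bills above a deductible. Does the scheme, on net, narrow or widen
the income distribution — and by how much? This package answers that
question twice: with a small calibrated model whose arithmetic can be
checked by hand, and with an empirical pipeline over household-survey
microdata.

## Inequality indices

All measurement rests on the Gini coefficient computed on grouped data.
After ranking incomes ascending and splitting the population into $n$
equally sized groups, the Lorenz curve joins the points
$(p_t, q_t)$, with $p_t = t/n$ the cumulative population share and $q_t$
the cumulative income share. With $B$ the area beneath the curve
(trapezoid rule over consecutive points),

$$G = 1 - 2B = \sum_{t=0}^{n-1}(p_t q_{t+1} - p_{t+1} q_t), \qquad G \in [0, 1].$$

For equally weighted groups this is algebraically identical to the
pairwise mean-difference form
$G = \sum_i\sum_j |x_i - x_j| / (2n^2\bar x)$; `gini_pairwise()` implements
that form as an independent cross-check and the test suite holds the two
routes to within $10^{-9}$ on random vectors. A micro-data vector (one
person per group) is simply the $n$-group case at $n$ = sample size.

The redistributive effect of a benefit is summarized by the Musgrave-Thin
index $MT = G - G^{*}$, where $G$ is the Gini after out-of-pocket payment
but before reimbursement and $G^{*}$ the Gini after reimbursement, and by
its relative form $RMT = 100\,MT/G$ (%). $MT>0$ means the payout
compresses the distribution. `mt_index()` refuses to form $RMT$ when
$G = 0$ rather than divide by zero.

## The benefit rule

`policy_schedule()` captures the four parameters of the scheme: flat
premium, deductible, coinsurance rate, and the ceiling on a single claim's
payout. The reimbursement for an expense $e$ is

$$r(e) = \min\{c \cdot \max(0,\, e - d),\; \text{ceiling}\},$$

nondecreasing and piecewise linear in $e$. The ceiling is read as a cap on
the *payout per claim*; in the calibrated model the largest claim is
0.26 $W_r$ against a ceiling of 6 $W_r$, so the cap never binds there, and
`stage_incomes()` warns if a user calibration makes it bind, because the
closed-form stage arithmetic below assumes it does not.

## The calibrated theoretical model

The population is five equally sized income quintiles at 0.3, 0.6, 1, 2
and 3 times the reference per-capita disposable income $W_r$ (RMB 40,000).
The benefit rule is the Beijing 2024 secondary-tier schedule: premium
0.01 $W_r$, deductible 0.02 $W_r$, coinsurance 78%. Inpatient bills take
one of five bracket values — 0.02, 0.08, 0.14, 0.20, 0.26 $W_r$ — kept
modest by construction so that no stage income can turn negative; the
lowest bracket equals the deductible and doubles as the zero-spending
case. Each quintile faces bracket probabilities that tilt against the
poor: the poorest quintile's probabilities rise 0.10 to 0.30 across
brackets in 0.05 steps, the richest fall 0.30 to 0.10, the middle is flat
at 0.20. Each quintile's five probabilities sum to one.

Income then evolves through four states (`stage_incomes()`): initial;
after the premium; after out-of-pocket payment, where the bracket expense
enters *weighted by the quintile's probability* of incurring it; and
after reimbursement, where the *full* benefit $c(e-d)$ is added back,
unweighted. That asymmetry — expected spending but full payout — is the
convention of the calibrated model we reproduce; it is what makes the
worked example run $1 \to 0.99 \to 0.95 \to 1.0904\,W_r$ for the middle
quintile at the 0.20 $W_r$ bracket, and every emitted table depends on
it. We document it rather than reinterpret it, since no alternative
weighting reproduces the published income vectors.

Two scenarios are evaluated per bracket. **Scenario 1** (`scenario1()`)
compares the insured population before and after reimbursement: MT is
zero at the deductible bracket and grows strictly with claim size.
**Scenario 2** (`scenario2()`) compares the insured-and-reimbursed
distribution against a counterfactual uninsured population that pays no
premium and bears the full probability-weighted bill: MT is slightly
negative at the deductible bracket (the insured paid a premium for
nothing) and positive above it.

### Rounding convention

The published versions of these tables report Ginis to 4 decimals and
derive MT and RMT *from the rounded Ginis*: at the 0.14 $W_r$ bracket the
full-precision MT is 0.026449 while the table value 0.0265 equals
0.4054 − 0.3789. `scenario1()` and `scenario2()` therefore default to
`digits = 4`, rounding the Ginis before differencing, which reproduces
every published MT/RMT cell; pass `digits = NULL` for full precision
(used by the monotonicity and invariance tests, which must not depend on
rounding artifacts). RMT is reported as a percentage with 2 decimals.

## The empirical pipeline

The survey pipeline mirrors the 2019 China Household Finance Survey
(CHFS) schema; the real microdata are access-restricted, so the package
validates the pipeline on synthetic data instead (below) and makes no
claim of reproducing the published survey estimates.

Per-capita disposable income is constructed per household
(`per_capita_disposable_income()`): the sum of wage, agricultural,
business, property and transfer income, minus income tax (`a3137`),
annual resident pension contributions (`f1008a`), employee pension
contributions (`f1008`, a *monthly* amount annualized by 12 — the only
reading consistent with its being listed among annual deductions), the
medical premium (`f2004`), and a flat RMB 230 per worker for unemployment
insurance; divided by household size (`a2000`). The premium is subtracted
exactly once, here. Negative household results are excluded and counted,
never propagated.

URRBMI enrolment is insurance-type code 2, 3 or 4 (the urban-resident and
rural schemes merged into URRBMI by 2019); reimbursements are the sums of
scheme components 2+3+4 of the inpatient (`f2025_*`, series R2) and
non-inpatient (`f2029_*`, series Q2) breakdowns. Missing reimbursement
components mean no claim and count as zero; missing *expenses* mean no
bracket and exclude the row from bracketed strata only. Expenditure
terciles use the empirical 33.33/66.67 percentile cut points of the
positive amounts, ties to the lower bracket.

Per stratum (national, the four NBS macro-regions via the shipped
province lookup, or the terciles), the before-income is per-capita
disposable income minus the out-of-pocket expense, the after-income adds
the scheme reimbursement, and MT is the Gini difference
(`redistribution_by_stratum()`).

Where the survey design is silent the pipeline exposes switches
(`survey_config()`) rather than hard-coding a guess:

* **Unit of analysis** — `"person"` (default): each individual is one
  observation carrying the household per-capita income. `"household"`
  collapses to one observation per household.
* **Expense attachment** — `"person"` (default): a member's expense and
  reimbursement adjust that member's observation in full; `"percapita"`
  spreads them over the household.
* **Sample** — `"all"` (default): the full national sample, matching the
  published framing of the national estimates; non-enrollees simply carry
  zero scheme reimbursement. `"urrbmi"` restricts to enrollees.

Rows in always equal rows analyzed plus rows excluded, and every
exclusion (negative household income, out-of-pocket payment exceeding
income, non-enrollees under the restricted sample) is counted in a log
the runners write to disk.

## The synthetic generator

`simulate_survey()` emulates the features the pipeline relies on, not the
CHFS marginals: right-skewed incomes (per-capita lognormal by region,
East richest — default spreads give a national Gini near 0.5); household
sizes 1–6; URRBMI enrolment rates around the scheme's roughly 70%
population coverage, higher in the West, with the remainder mostly in the
employee scheme; an inpatient process in which 12% of persons incur an
episode whose bracket probabilities tilt linearly with within-region
income rank at ±0.05 per bracket step (the direction and magnitude of the
calibrated gradient: the poorest face 0.10…0.30 across brackets, the
richest the reverse); and reimbursements generated by the benefit engine
itself, never drawn. Income components are fixed wage-dominant shares of
one household draw, with transfer income taking the exact remainder so
components always reassemble the draw. One master seed drives the whole
draw through R's default Mersenne-Twister stream; identical configs give
byte-identical CSVs.

What the generator does **not** emulate: survey weights, item
nonresponse and skip patterns, within-household income heterogeneity,
province-level variation beyond the four regions, and the real CHFS
marginal distributions. Passing tests therefore demonstrate that the
pipeline *computes the right thing on data with the assumed structure*,
not that the published survey estimates are recovered.

Alongside the data, `simulate_survey()` emits a truth sheet: the
before/after-reimbursement Gini and MT computed directly from the
generated microdata through an independent Gini route (the sorted-index
formula $G = 2\sum_i i\,x_{(i)}/(n\sum x) - (n+1)/n$ rather than the
Lorenz trapezoid). The acceptance suite requires the pipeline to recover
the truth sheet to $10^{-12}$ on a 10,000-household population — an
end-to-end check that income construction, enrolment classification,
reimbursement aggregation and the exclusion rules are exact, not merely
close.

## Numerical choices and scales

* Published-value comparisons use an absolute tolerance of 5e-5, the
  half-width of 4-decimal rounding; internal computation is full
  precision.
* Gini results are clipped to $[0,1]$ to remove floating-point dust on
  constant vectors; the trapezoid and index formulas agree to well below
  the $10^{-12}$ recovery tolerance at the sample sizes used.
* Sorting is stable; the Gini is permutation-invariant, so ties cannot
  affect results.
* Test and acceptance problem sizes — 1,000 random vectors for the
  oracle identity, 10,000 households (about 30,000 persons) for the
  synthetic round trip — run in seconds on one CPU and are large enough
  that the qualitative patterns (positive national MT, bracket-monotone
  MT) are stable across seeds.

## Limitations

The theoretical model is a five-point calibration, not a behavioral
model: no demand response, no moral hazard, no multi-year dynamics, one
hospital tier. The empirical pipeline implements the measurement, but its
published point estimates cannot be reproduced here because the CHFS
microdata are restricted; the synthetic validation shows correctness of
the computation, not of any empirical claim. Survey design weights and
variance estimation for the Gini are out of scope.
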