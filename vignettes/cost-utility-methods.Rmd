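---
title: "Methods: lifetime cost-utility analysis of diagnostic delay in JIA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lifetime cost-utility analysis of diagnostic delay in JIA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the model

Juvenile idiopathic arthritis (JIA) is an inflammatory arthritis with
onset before age 16. Without timely referral to a pediatric rheumatologist,
the window for aggressive disease-modifying treatment closes and long-term
joint damage, disability and higher healthcare use follow. `jiacea`
quantifies, from a cross-sectional survey of children and young people
with JIA, what a delayed diagnosis (6+ months from actively seeking
treatment, versus under 6 months) costs a health funder over a patient's
lifetime — in quality-adjusted life years (QALYs) and in dollars — and
what that implies as a willingness-to-pay threshold for interventions that
shorten time to diagnosis.

The economic model is deliberately simple and transparent. For participant
$i$, measured at age $a_i$ with CHU9D utility $u_i$ and annual government
healthcare cost $c_i$:

$$\mathrm{pvQALY}_i = u_i \, A(r, L_i), \qquad
  \mathrm{pvCost}_i = c_i \, A(r, L_i), \qquad
  \mathrm{NMB}_i = \lambda\,\mathrm{pvQALY}_i - \mathrm{pvCost}_i,$$

where $L_i$ is the remaining life expectancy at $a_i$ from a life table
and $A(r, L) = (1-(1+r)^{-L})/r$ is the end-of-year annuity factor at
discount rate $r$. Incremental results are Welch (unequal-variance) mean
differences between the two delay groups, with t-based 95% intervals. The
central behavioural assumption is **constant differences over the
lifetime horizon**: each participant's observed annual utility and cost
persist unchanged to death. Survey data reaching 20 years post-diagnosis
show no narrowing of the group differences, and longitudinal JIA studies
suggest differences persist or widen, so holding them constant is the
conservative choice; it is still an extrapolation, and the discount rate
sensitivity (3%/7%) is the main guard on it.

Key parameters, all settable in `econ_params()`:

| parameter | default | units | why |
|---|---|---|---|
| `discount_rate` | 0.05 | per annum | reference-case rate for Australian evaluations; 0.03/0.07 in sensitivity |
| `wtp_per_qaly` | 50,000 | AUD/QALY | generally accepted Australian threshold |
| `aud_usd_rate` | 1.51 | AUD per USD | 2023 average, for USD companion results |
| `exclusion_window` | 1 | years | drops participants surveyed within a year of diagnosis to remove short-term treatment effects |
| `use_sex_specific` | FALSE | — | unisex life-table column by default (see below) |

Discounting is end-of-year: the first year's outcome is discounted once,
and a fractional final year contributes its fraction at the following
year's discount factor. The closed form is checked against an explicit
year-by-year summation oracle in the tests (1,000 random rate/horizon
pairs, 1e-9 tolerance).

Projection starts at **age at survey**, because that is when utility and
cost were measured; starting at diagnosis would attribute the measured
annual quantities to years before they were observed. This was a genuinely
open choice — the alternative is exposed simply by supplying a different
age column.

## CHU9D scoring

The Child Health Utility 9D instrument asks nine questions (worry,
sadness, pain, tiredness, annoyance, school work, sleep, daily routine,
activities), each on a five-level scale, and a preference-weight value set
maps each response profile to a utility anchored at 1 (full health) and 0
(dead). Scoring is additive: utility is the sum of nine per-dimension
contributions, so the value set is a 9 x 5 table.

The full Australian adolescent value set is published externally as a
table we do not redistribute. The bundled default
(`default_chu9d_value_set()`) fixes each dimension's level-1 and level-5
contributions to the published per-dimension ranges (e.g. worry 0.22 down
to 0.11, pain 0.11 down to -0.02) and interpolates levels 2–4 linearly.
That reproduces every published range endpoint exactly; the best state
scores 1.02 and the worst 0.00 because the printed range endpoints are
rounded to two decimals and sum to 1.02, not 1.00. We deliberately do
**not** renormalize — the published rounding is the data we have — and
the real value set can be swapped in via `load_value_set()` without any
code change. Monotonicity (worsening a level never raises utility) is
enforced at load time unless explicitly overridden.

Participants with an incomplete CHU9D score `NA` and are excluded from
utility-side analyses (never silently scored zero), mirroring the source
survey's 89% completion.

## Micro-costing

Annual government costs are counts of healthcare use multiplied by unit
costs, in four categories: medical investigations, health professional
visits, hospitalizations, and medications. The unit-cost schedule is
**data, not code**: the bundled default carries one priced item per cost
component with plausible 2023-AUD placeholder fees (schedule-style fees
for investigations and visits, efficient-price-style per-admission costs
for hospitalizations, per-pack subsidy costs for drugs), and any official
schedule CSV can be loaded instead. Calibration targets throughout are the
published component *means*, not individual item fees.

Three survey-driven rules from the source costing are implemented:

* **Medicare Safety Net** — when a participant reports reaching the
  threshold, the government pays an additional `rebate_fraction` (default
  0.8) of schedule-fee spend above the annual threshold (default 2,414
  AUD), allocated proportionally across the schedule-fee components.
* **Chronic disease care plan** — participants using allied health are
  assumed to hold a care plan; one annual care-plan rebate item is added
  to the primary-care component.
* **Medications** — standard dosing assumptions per drug (e.g.
  methotrexate 15 mg weekly oral or subcutaneous, adalimumab 40 mg
  fortnightly, prednisone 25 mg daily), whole-pack dispensing (packs per
  year round **up**), aggregated into the four reported rows: csDMARDs,
  bDMARDs, tsDMARDs, oral corticosteroids. Corticosteroid injections and
  infusions are not costed as medications — they are part of
  hospitalization costs.

Aggregation identities (total = sum of category subtotals = sum of
components), monotonicity in counts, and degree-1 homogeneity in the
schedule (with the safety-net threshold scaled as part of the schedule)
are property-tested. One reconciliation matters when comparing to the
published component table: the published professional-visit subtotals are
smaller than the sum of their own printed component rows (participant-level
missingness in the source), and the published group totals equal
investigations + professional-visit *subtotal* + hospitalizations +
medications. `reference_cost_components()` and
`reference_cost_subtotals()` carry both, and nothing forces agreement.

## Life table

The bundled default life table is **synthetic**: a Gompertz–Makeham
hazard $\mu(x) = A + B e^{Cx}$ with $A = 2\times10^{-4}$, $C = 0.095$ and
$B$ solved so that life expectancy at birth is 84.5 years (unisex), with
optional female/male columns at 86.5/82.5 — contemporary
high-income-country values. Remaining expectancy at fractional ages is
linearly interpolated between whole-year rows. Any official national life
table replaces it via `load_life_table()` (weak monotonicity in age is
validated, with the usual infant-mortality exception allowed below age 2).
Projection defaults to the unisex column; with ~69% of the cohort female,
sex-specific columns would shift the mean annuity by well under 1% and are
opt-in.

At the cohort's mean survey age (~11.7 years) the table gives ~73
remaining years, hence a 5% annuity factor of ~19.43 — the multiplier
connecting annual differences to lifetime present values.

## The synthetic-cohort generator

`generate_cohort()` exists so that every downstream stage is testable
against known truth without access to participant data. Its defaults *are*
the study conditions: 163 participants, 61/163 delayed, utility means
0.59/0.44 (SD 0.29), annual cost means 18,765/29,494 AUD (SD
16,416/37,034), onset ages 4.4/5.7 (SD 3.8/3.6), diagnosis-to-survey gaps
6.3/5.1 years, 69% female, uveitis 33.3%/9.8%, 11.4% incomplete CHU9D
assigned independently of group.

* **CHU9D responses** come from a shared-cutpoint ordinal logistic model:
  participant $i$ has a latent severity $t_i \sim N(\theta_g, \tau_g)$ and
  each dimension's level follows $P(L > l \mid t) =
  \mathrm{logit}^{-1}(t - c_l)$ with fixed cutpoints. $(\theta_g, \tau_g)$
  are solved by nested root-finding against deterministic Gaussian
  quadrature so that the *scored* utility matches the target group mean
  **and** SD under whatever value set is in use.
* **Utilization counts** are zero-inflated Poisson per cost component,
  moment-matched so expected cost equals the (reconciled) published
  component mean; a common dispersion factor on the non-medication
  components makes total cost variance hit the published group SD after
  accounting for the medication classes, which are Bernoulli
  use-prevalence times a drug drawn from a within-class mix at standard
  dosing. The expected care-plan cost is netted out of the primary-care
  target so group cost means stay exactly on target.
* **Ages**: onset is a scaled beta on [0, 16) matched in closed form to
  the target mean/SD. (A truncated normal — the obvious first choice —
  cannot reach the printed early-group SD: on this support, given mean
  4.4, the family's SD supremum is about 3.74 versus the printed 3.8.)
  The diagnosis-to-survey gap is a truncated normal whose parameters are
  solved against the realized per-participant bounds (survey age at most
  25). Reported ages are coarsened as captured in the survey: nearest
  month up to age 1, nearest half-year up to 4, nearest full year above.
* **Delay measures**: the seeking-to-diagnosis delay is drawn over the
  survey's categorical bins and mapped to configurable midpoints; the
  onset-to-diagnosis delay adds a gamma-distributed onset-to-seeking lag
  whose variance is solved analytically so the Pearson correlation
  between the two measures, computed on *reported* (coarsened) ages,
  lands at the 0.80 target (an approximate analytic correction accounts
  for coarsening variance; pre-coarsening delays are stored alongside).

`calibration_report()` compares realized moments to every target and
flags misses beyond three standard errors (fourth-moment standard errors
for SDs, which matters for the heavy-tailed costs); at n = 10,000 the
default calibration produces no flags.

What the generator does **not** emulate: participant-level correlation
between utility and cost (they are conditionally independent given
group), dimension-specific published means (only the overall utility
moments are targeted), state/remoteness/education structure, and any
non-random CHU9D missingness. Consequently, passing tests demonstrate
that the *pipeline* recovers whatever structure the generator encodes at
the published moments — not that the synthetic data reproduce every joint
feature of the real survey.

## Numerical choices

* Quadrature for the utility calibration uses a 321-point grid over ±8
  latent SDs; root-finding tolerances are 1e-8/1e-9 (`uniroot`).
* Truncated-normal sampling and moments are computed on whichever normal
  tail holds less mass, keeping full floating-point precision when the
  solve pushes parameters far from the support (needed for the strongly
  right-skewed gap distributions).
* Welch intervals come from `stats::t.test`; identical groups short-cut
  to difference 0, p = 1; groups with under two observations raise
  errors rather than returning NaN.
* Chi-squared tests default to no continuity correction (correction and
  the Fisher-exact small-cell fallback are both exposed and flagged in
  the output).
* The CEA plane bootstrap resamples participants within group, seeded,
  2,000 replicates by default; its point estimate is the analytic
  incremental mean by construction.
* Problem sizes: tests run one n = 10,000 cohort for calibration checks,
  five n = 10,000 cohorts for the headline-results checks, and fifty
  n = 2,000 cohorts for parameter recovery; `scripts/acceptance.R` uses
  fifty n = 10,000 cohorts. These sizes put Monte-Carlo error well inside
  the assertion tolerances.

## Known limitations

* The constant-difference lifetime extrapolation is the dominant
  assumption; the discount-rate scenarios bound its sensitivity but do
  not test trajectory shapes (age-varying utilities are out of scope).
* The bundled value set interpolates between published range endpoints;
  mid-level utilities will differ slightly from the true published
  weights until a full set is supplied.
* Unit costs are placeholder schedule entries; component-level cost
  *means* are calibrated, but item-level realism (e.g. admissions per
  year implied by a unit cost) is approximate, and the published cost
  SDs are reproduced partly through a common dispersion inflation.
* Mortality is assumed independent of JIA status and delay group.
* The adjusted analysis approximates the source's generalized additive
  model with a natural-spline age term in `lm`; curvature beyond three
  degrees of freedom is not fitted by default.
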