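---
title: "Modelling annual health checks for adults with intellectual disability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling annual health checks for adults with intellectual disability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ahcmodel)
```

## The decision problem

Adults with intellectual disability (ID) die earlier and carry more
undetected illness than the general population. England incentivises
general practices to offer them an annual health check (AHC): a structured
review that improves the identification of conditions such as hypertension,
sensory impairment and osteoporosis, and nudges people into national cancer
screening. The economic question is whether the check's yearly cost —
£258 per person when general-practice doctor and nurse time, support-worker
accompaniment and social-worker input are all costed — buys enough health,
measured in quality-adjusted life years (QALYs), to be worth it from a
health-service perspective.

`ahcmodel` answers this with a set of condition-specific cohort models. A
hypothetical cohort enters at age 40 (50 for osteoporosis and breast
screening, 60 for bowel screening, matching programme starting ages) and is
followed in annual cycles until age 100 under two strategies that differ
*only* in arm-specific effectiveness parameters: the probability that a
condition is identified and managed, that a person is referred to an eye or
hearing exam, investigated for osteoporosis, or participates in screening.
Each condition contributes a present value of incremental lifetime cost and
QALYs; these are summed and the discounted annuity of the intervention cost
is added. All present values are discounted at 3.5% per year to the common
base age of 40, so models with later starting ages carry a discounting
offset — without a single time origin the per-condition results could not
be added.

## Model structure

**State-transition conditions.** Hypertension (managed/unmanaged disease,
first-year and subsequent post-stroke and post-CHD states), glaucoma
(treated/untreated mild–moderate–severe disease and visual impairment),
osteoporosis (treated/untreated disease, hip fracture with first-year,
second-year and post states), bowel screening and breast screening are
annual-cycle Markov cohort models. Transition matrices are rebuilt each
cycle from age-banded incidence and mortality, validated to be
row-stochastic within 1e-9 (residual probability is never silently
renormalised — a misspecified row aborts the run naming the age and state),
and death states are checked to be absorbing. Rewards are per-state annual
costs and utilities; one-off costs (diagnosis work-ups, screening-detected
treatment, the lifetime early-versus-late treatment cost differences) are
charged to new entrants at the cycle of transition.

Two structural simplifications are deliberate. First, "undetected" and
"unmanaged" hypertension are a single state: they carry identical risks and
rewards, and the printed evidence distinguishes only managed versus not.
Second, identification is applied once, at incidence. Re-applying the
identification probability every cycle would drive both arms to near-total
management within two cycles and erase the printed arm difference; applying
it at onset preserves it, at the price of ignoring late catch-up
identification in the standard-care arm.

**Cascade conditions.** Diabetes, cataract and hearing problems have no
published state-level progression for this population; instead the evidence
gives lifetime cost and QALY differences conditional on reaching treatment.
These are modelled as probability cascades over the survival-weighted
incident population: each year's incident cases are multiplied through the
branch probabilities (referral × attendance × need × acceptance, etc.) and
the published lifetime deltas are booked at that cycle, discounted to age
40. Hearing-aid users are tracked as an absorbing fraction of the living
cohort so the annual utility gain and follow-on cost accrue for life. A
one-cycle toy version of each cascade is verified against brute-force
enumeration of the branch tree in the test suite.

**Double counting.** Stroke and CHD appear only inside the hypertension
model, hip fracture only inside osteoporosis. Diabetes incidence carries a
configurable overlap adjustment with hypertension, default 0. Background
mortality is not decremented for the cause-specific deaths modelled inside
conditions; the residual double-count is small (annual cause-specific risks
are of order 1e-3 against background annual mortality of 1e-2 and above)
but it is a known approximation.

## Mortality

Background mortality comes from an annual life table. The packaged
synthetic table is Gompertz, `qx = 1 - exp(-a * exp(b * age))` with
`a = 3.584e-05`, `b = 0.09`, calibrated once so that period life expectancy
at birth is ≈ 81 years — England-like — and capped at 1 at age 100. The
threefold excess mortality of adults with ID is applied as probability
scaling `min(1, 3 * qx)` (a hazard-scale alternative `1 - (1-qx)^3` exists
for sensitivity work; below age 85 the two differ by little). The age cap
of 100 bounds runtime and matters little: with threefold mortality,
survivorship past 95 is negligible.

```{r}
lt <- adjust_id_mortality(default_life_table(), 3)
s <- survival_curve(lt, 40, 100)
s
# discounted survival annuity behind the intervention cost
intervention_cost_pv(1, s, 0.035)
```

## Parameters, ranges and distributions

All inputs live in a registry of named entries, each carrying the published
range (percent entries normalised at load), an optional explicit base-case
point, an optional standard deviation for inputs published as mean (SD),
an age band, an arm tag and a provenance flag. Validation is strict:
range inversions, probabilities outside [0, 1], utilities above 1 and
missing names referenced by any condition model are load-time errors that
list every gap.

**Base case.** The evidence tables publish ranges, not points. The base
case resolves each range to its explicit point when one is published
(adherence 75%, obesity proportion 33.5%, prescription 99.6%, ...) and to
the midpoint otherwise. Because the published probabilistic results were
produced from base-case points that are not themselves in the public
tables, the packaged fixture sets explicit points inside the published
ranges for a minority of entries where the midpoint is a poor central
estimate — most notably the annual probability of an unaddressed hearing
problem, whose published range (2–13.4%) spans prevalence-style and
incidence-style readings; the fixture uses 2.25%, the incidence-like end,
since the cascade re-exposes the surviving cohort every year. Each such
entry says so in its `source_note`. Six entries are tagged
`provenance: assumption` because no value is published at all: standard-care
bowel-screening participation, the female cohort proportion, annual
breast-cancer case fatality, the treatment effect on hip fracture, the
visual-impairment utility, and the diabetes–hypertension overlap (default
0). These are the model's honest soft spots; anyone with access to better
estimates should override them in the YAML config.

**PSA distributions.** Ranges are interpreted as central 95% intervals
(`ci95`), the common reading of published uncertainty ranges: beta for
probabilities, proportions and utilities (method of moments, mean at the
base-case point, SD = range/3.92 or the published SD; infeasible SDs are
shrunk with a warning); gamma for non-negative costs; lognormal for
relative risks; normal (truncated to a valid support where one exists) for
signed lifetime deltas; a point mass for degenerate ranges. A `minmax`
interpretation (scaled beta with the range as support) is available as a
configuration switch and serves as the fallback when beta moment matching
fails. All draws are independent — no correlation structure is published —
and every parameter is drawn exactly once per PSA iteration, so a run is
reproducible from its root seed (per-draw sub-seeds are derived by
counter), and overrides imposed *after* sampling preserve common random
numbers across one-way sensitivity rows.

## Numerical conventions

- **Half-cycle correction**: per-cycle accrual is the reward dotted with
  the trapezoidal average of start- and end-of-cycle occupancy; one-off
  entry costs are charged to the flow of new entrants without averaging.
- **Discounting**: cycle *k* (0-based) of a model starting at age *s* is
  discounted by `(1+r)^-(k + s - 40)`.
- **Intervention cost**: component staff costs are rounded to whole pounds
  before summation (so the £258 build-up is reproduced exactly:
  72 + 43 + 136 + 7), and the yearly cost is paid while alive with the same
  trapezoidal survival weighting as the engine.
- **ICER dominance**: flagged (`ok`, `dominant`, `dominated`, `undefined`),
  never thrown, so a PSA draw with non-positive QALY gain cannot abort a
  run; such draws are excluded from the mean per-draw ICER (count
  reported) but retained for CEAC and net-monetary-benefit statistics.
  Both the mean of per-draw ICERs and the ratio of means are always
  reported — with skewed QALY denominators the former is systematically
  larger (Jensen's inequality), and the headline statistic follows the
  per-draw-mean convention.
- **Percentile intervals**: 95% intervals over draws are the 2.5%/97.5%
  empirical percentiles.

## What the synthetic data do and do not show

The Gompertz life table emulates the *shape* of a national period life
table, not its year-to-year irregularities (infant mortality, accident
humps); since the model only uses ages 40+, this matters little. The
parameter fixture reproduces published ranges, so PSA spread reflects
published uncertainty — but the six assumption-tagged entries carry made-up
ranges, and the base-case points inside published ranges are calibration
choices, not published values. Passing tests therefore demonstrate internal
correctness (engine against micro-simulation, cascades against enumeration,
accounting identities exactly) and consistency with the published headline
results under this configuration; they do not validate the model against
real cohort outcomes, which is beyond any desk exercise.

Problem sizes used throughout: cohort models run 40–60 annual cycles over
3–9 states; the probabilistic analysis uses 1000 draws; micro-simulation
oracles use 200,000 individuals. A full 1000-draw experiment takes on the
order of a minute.

## Known limitations

- No carer costs, care-home admission, or societal perspective — health
  service costs only.
- Screening participation is applied per annual cycle rather than on the
  2-/3-yearly national schedules.
- Conditions excluded from the evidence base (dementia, epilepsy, COPD,
  mental health, ...) are not modelled, so the QALY gain is a lower bound
  with respect to scope, while the additive mortality treatment slightly
  double-counts cause-specific deaths.
- Utilities come from general-population sources; if ID-specific utilities
  are lower across all states, incremental results change little (the
  differences largely cancel), but absolute QALY totals would shift.
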