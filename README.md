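# ahcmodel

Decision-analytic cost-utility modelling of **annual health checks (AHC)
versus standard primary care for adults with intellectual disability (ID)**,
followed from age 40 until death.

Adults with ID carry roughly threefold mortality and a much higher burden of
undetected, treatable conditions than the general population. Annual health
checks in general practice aim to close that gap by identifying conditions
earlier and steering people into screening and treatment. This package
implements the full economic model behind that question for analysts in
health technology assessment: eight condition-specific annual-cycle Markov
cohort models and screening/referral cascades (hypertension, glaucoma,
osteoporosis, bowel and breast cancer screening, diabetes, cataract, hearing
problems), aggregated into lifetime incremental costs (2016 GBP, NHS
perspective) and quality-adjusted life years (QALYs), both discounted at
3.5% per year to a common base age of 40, with half-cycle correction.

The headline statistics are the standard cost-effectiveness toolkit:

- **ICER** = ΔC / ΔE, the incremental cost-effectiveness ratio, with
  dominance flags for draws where ΔE ≤ 0;
- **NMB(λ)** = λ·ΔE − ΔC, net monetary benefit at willingness-to-pay λ;
- **CEAC**: P(NMB(λ) > 0) across probabilistic draws;
- probabilistic sensitivity analysis (PSA): every parameter drawn from a
  distribution matched to its published range (beta for probabilities and
  utilities, gamma for costs, lognormal for relative risks, truncated normal
  for signed lifetime deltas), 1000 Monte Carlo draws;
- one-way sensitivity analysis, in particular over the yearly cost of the
  health check itself (£258/person at base case, built up from GP, practice
  nurse, support-worker and social-worker time).

Every input ships in a validated parameter registry
(`inst/extdata/ahc_parameters.yaml`) of published ranges, and a synthetic
Gompertz life table calibrated to England-like longevity (life expectancy at
birth ≈ 81 y) supplies background mortality, so everything runs offline.

## Worked example

```r
library(ahcmodel)

pset <- ahc_parameter_fixture()     # published parameter registry
bc   <- run_base_case(pset)         # deterministic, at base-case points
bc$strategy
#> <ahc_strategy_result>
#>   incremental cost:      4827.38 GBP (intervention 4719.78)
#>   incremental QALYs:     0.0780

psa <- run_psa(pset, n_draws = 1000, seed = 1)
psa
#> <ahc_psa: 1000 draws, seed 1>
#>   inc cost    4825.90 (SD 107.39, 95% 4645.54-5055.94)
#>   inc QALY     0.0748 (SD 0.0463, 95% 0.0239-0.2019)
#>   mean ICER  87628.56 (95% 24488.07-195681.78, 1 draws excluded)
#>   ratio-of-means ICER 64503.46
#>   P(cost-effective at  20000 GBP/QALY) = 0.007
#>   P(cost-effective at  30000 GBP/QALY) = 0.057
```

Reading: the health-check strategy costs about £4.8k more per person over a
lifetime — almost all of it the £258/year check itself, paid while alive
(discounted survival annuity ≈ 18.3 years) — and gains about 0.075 QALYs,
for a mean per-draw ICER far above the usual £20,000–£30,000 thresholds: at
its current cost the check is not cost-effective. The one-way analysis shows
what would change that:

```r
one_way_sa(pset, parameter_name = "intervention.yearly_cost",
           values = c(50, 75, 100, 150), n_draws = 1000, seed = 1)
#>   value mean_inc_cost mean_inc_qaly mean_icer   icer_lo   icer_hi p_ce_20000 p_ce_30000
#> 1    50      1020.811    0.07481621  18090.82  5649.633  37846.48      0.663      0.923
#> 2    75      1478.154    0.07481621  26448.72  7902.764  56059.70      0.365      0.681
#> 3   100      1935.497    0.07481621  34806.62 10182.786  74932.73      0.218      0.456
#> 4   150      2850.183    0.07481621  51522.42 14723.800 113131.92      0.083      0.226
```

At £50 per check per year the strategy would be cost-effective in about
two-thirds of draws at £20,000/QALY. `ce_plane(psa)` returns the scatter
coordinates for a cost-effectiveness plane; `run_base_case(..., out_dir=)`
and `write_psa()` write JSON/CSV outputs embedding version, seed and
parameter hash. A thin command-line wrapper with `base-case`, `psa`,
`owsa`, `ceplane` and `fixtures export` commands ships in `inst/cli/ahc`.

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "ahcmodel", load_package = "installed")'
```

The suite checks the engine against count-based micro-simulations of 200,000
individuals, the cascades against brute-force branch enumeration, discounting
against closed-form annuities, and the null-effect identity (equalising both
arms leaves exactly the intervention annuity).

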