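# widenedpipe

Tools for analysing tip-to-base widening of xylem conduits under the
**widened pipe model (WPM)**: the prediction that natural selection, trading
off hydraulic resistance against the costs of rapid conduit widening, drives
every terrestrial plant's conduit profile onto a single universal curve.

The package is for plant hydraulics and allometry researchers who have (or
want to simulate) per-plant series of mean conduit diameters measured at
increasing distances from the stem tip, and who want to fit and compare
widening models, account for hydraulic and carbon costs, and place plants on
the resistance–widening Pareto front.

## The model in brief

Let σ(h) be conduit lumen cross-sectional area at distance *h* from the stem
tip, σ_M its basal value at *h* = h_M (plant height), and h_0 the length of a
single conductive unit (400 µm for vessels and hydroids, 4000 µm for
tracheids). Pareto-optimal profiles minimize

  Ω + λW,  Ω = ∫ σ⁻²(h) dh (rescaled Hagen–Poiseuille resistance),
       W = ∫ σ̇²(h) dh (widening cost: embolism risk + construction),

and the stationary profile is the closed form

  σ(h) = σ_M · F(h/h_M),  **F(x) = √( x (2 − x) )**,

independent of λ after rescaling — one curve for all plants. Near the tip,
diameter grows as h^0.25; at the base the area profile sits 29.3% below the
tip-matched power law. Optimal plants obey ln Ω = −ln W + J with J nearly
constant — an inverse relationship between the two costs across species.

The package implements this closed form and its hydraulic accounting
(resistance, conductance, carbon cost, widening cost; `universal_curve()`,
`resistance_wpm()`, `carbon_cost()`, …), an independent variational oracle
(`solve_euler_lagrange()`, `minimize_functional_direct()`), per-plant
least-squares fitting of the WPM against uniform, square-root and linear
competitor profiles (`fit_profiles()`), pooled normalization with
equal-population binning and χ² model comparison (`chi_square_table()`),
cohort cost summaries and the Pareto front (`summarize_costs()`,
`pareto_front()`), a field-protocol synthetic cohort generator
(`generate_cohort()`), and CSV ingestion of trait tables
(`read_profiles()`). Results are tibbles throughout, with `autoplot()`
methods for the main result types and a thin command-line wrapper in
`inst/cli/wpm.R`.

## Worked example

Simulate a 103-plant cohort with the field sampling protocol (dense near the
apex, doubling spacing below; measured diameters are means of 25 conduits),
fit all five profile models, and compare them:

```r
library(widenedpipe)

cohort <- generate_cohort(cohort_spec(seed = 1))
fits   <- fit_profiles(cohort$profiles)
chi_square_table(cohort$profiles, fits)
#> # A tibble: 5 × 5
#>   model              chi2   dof        p n_bins
#>   <chr>             <dbl> <int>    <dbl>  <int>
#> 1 wpm               0.246    15 9.52e-12     15
#> 2 wpm_avg_anchor    0.623    15 8.65e- 9     15
#> 3 sqrt_west        37.1      15 9.99e- 1     15
#> 4 linear_savage   700.       15 1   e+ 0     15
#> 5 uniform        3367.       15 1   e+ 0     15
```

The fitted WPM sits far inside the pooled scatter (χ² = 0.25 over 15 bins;
the lower-tail p ≈ 0 marks a good fit under the package's convention), the
basal-anchored WPM variant is nearly as good, and the pure power-law,
linear and uniform profiles are progressively worse. Cost accounting on the
same cohort:

```r
costs <- summarize_costs(cohort$profiles, fits)
conductance_height_regression(costs)
#>    slope intercept r_squared     n
#> 1 -0.165      1.46    0.0485   103
carbon_matched_conductance_gain(costs)
#>   conductance_slope conductance_slope_gm carbon_slope     n
#> 1              1.44                 1.44         1.03   103
```

Conductance is essentially height-invariant (slope −0.17, R² = 0.05 on the
log–log regression: a 100-fold taller plant conducts about the same), and
the WPM profile delivers ~1.44× the conductance of the fitted power-law
profile at practically identical carbon cost (carbon cross-plot slope 1.03).
Finally, the Pareto front:

```r
pareto_front(costs)
#> <pareto_points: 103 plants, 5 optimal>
#> # A tibble: 103 × 6
#>   plant_id  conduit_type       eps  ln_W ln_Omega zone
#>   <chr>     <chr>            <dbl> <dbl>    <dbl> <chr>
#> 1 synth_001 hydroid      0.000115  -2.47    5.41  optimal
#> 2 synth_002 vessel       0.0000696  2.17    0.884 accessible
#> ...
```

Narrow-conduit plants (tracheids, hydroids) cluster at high resistance and
low widening cost; vessel-bearing plants at the opposite end — the inverse
relationship of the front.

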