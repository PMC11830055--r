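# dkrmr

Steady-state modelling of lipase-catalysed **dynamic kinetic resolution
(DKR)** of racemic ibuprofen ester in a hollow-fibre membrane bioreactor.

In this reactor an enantioselective lipase immobilised in the porous fibre
wall hydrolyses only the (S)-ester while a base catalyst racemises the
unreacted (R)-ester in situ, so the theoretical yield of the valuable
(S)-acid exceeds the 50% ceiling of a plain kinetic resolution. At steady
state the dimensionless concentrations of the two esters across the wall
(`1 <= x <= 2`) obey the coupled nonlinear boundary value problem

```
S1'' + (1 + B0)/x · S1' = Φ² S1 / [(1 + S1/Θ)(1 + φξ2 + ξ1 S2)]
S2'' + (1 + B0)/x · S2' = γ (S1 − S2)/(S1 + S2)
S1'(1) = S2'(1) = 0,   S1(2) = S2(2) = 1
```

with Thiele modulus squared `Φ²`, Bodenstein number `B0`, Michaelis group
`Θ`, racemization group `γ`, and inhibition groups `ξ1`, `ξ2`, `φ`.

The package provides, for this model:

* closed-form homotopy-perturbation **series solutions** for both species,
  including the third-order (R)-ester truncation that the published
  comparison tables actually used;
* an independent **collocation solver** (3-stage Lobatto IIIA, the bvp4c
  scheme family) with mesh-doubling residual control and a
  grid-independence certificate;
* local and **mean integrated effectiveness factors**: closed-form deficit
  variants (`printed` and the default `table_consistent`), adaptive
  quadrature under rate- or concentration-based local definitions, and the
  zero-Thiele limit;
* series **validity-region scanning** with an explicit criterion and
  linear frontier fitting, plus **normalized sensitivity analysis** of the
  effectiveness factor;
* presets and reference values for the eight published tables, a
  one-command reproduction run, and an explicit register of quantities the
  printed formulas provably cannot reproduce.

Everything is tidyverse-native: parameters are a one-row tibble, every
result is a tibble with `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

```r
library(dkrmr)

p <- dkr_params(phi2 = 0.5, b0 = 8.68, theta = 3.27, gamma = 1,
                xi1 = 2, xi2 = 0.03, phi_frac = 1)

hpm_profile(p, x = seq(1, 2, 0.2))
#> # A tibble: 6 × 4
#>       x    s1    s2 method
#>   <dbl> <dbl> <dbl> <chr>
#> 1   1   0.984  1.00 hpm
#> 2   1.2 0.985  1.00 hpm
#> 3   1.4 0.988  1.00 hpm
#> 4   1.6 0.992  1.00 hpm
#> 5   1.8 0.996  1.00 hpm
#> 6   2   1      1    hpm

glance(solve_profiles(p))
#> # A tibble: 1 × 5
#>   method   max_residual mesh_points s1_inner s2_inner
#>   <chr>           <dbl>       <int>    <dbl>    <dbl>
#> 1 numeric 0.00000000980         513    0.984     1.00

glance(compare_hpm_numeric(p, species = "s1"))
#> # A tibble: 1 × 5
#>   species order      n average_pct_error max_pct_error
#>   <chr>   <chr>  <int>             <dbl>         <dbl>
#> 1 s1      second     6          0.000152      0.000305
```

The series and the collocation solution agree to an average of 0.000152%
over the six tabulated radii: at these operating conditions (moderate
diffusion limitation, `Φ² = 0.5`) the wall is nearly saturated with
substrate, the (S)-ester dips only ~1.6% below its bulk value at the inner
radius, and the truncated series is essentially exact.

The mean integrated effectiveness factor collapses as the modulus grows
(here the tabulated modulus `m` enters as `Φ² = m²`, the convention of the
published effectiveness tables):

```r
effectiveness_sweep(dkr_params(phi2 = 1, b0 = 8.68, theta = 5,
                               xi1 = 7.23, xi2 = 0.25, phi_frac = 1),
                    c(0.1, 1, 10), modulus = "phi")
#> # A tibble: 3 × 7
#>   modulus_value   phi2   s1b   s2b theta eta_m variant
#>           <dbl>  <dbl> <dbl> <dbl> <dbl> <dbl> <chr>
#> 1           0.1   0.01     1     1     5 1.000 table_consistent
#> 2           1     1        1     1     5 0.994 table_consistent
#> 3          10   100        1     1     5 0.433 table_consistent
```

At `m = 10` only 43% of the enzyme's intrinsic activity is used — the
reaction outruns diffusion and the wall interior is starved.

A command-line interface wrapping the same functions lives at
`inst/cli/dkr.R`:

```sh
Rscript inst/cli/dkr.R profile --method bvp --phi2 0.5 --b0 8.68 \
    --theta 3.27 --gamma 1 --xi1 2 --xi2 0.03 --phi-frac 1 --out profile.csv
Rscript inst/cli/dkr.R reproduce-tables --out-dir tables
```

The second command regenerates all eight reference tables and exits
non-zero if any regenerated column deviates beyond its documented
tolerance.

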