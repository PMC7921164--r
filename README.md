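# adaptr

Estimation of **time-dependent parameter trajectories** in kinetic metabolic
models from longitudinal metabolite data, refined by longitudinal
gene-expression data — the ADAPT approach (Analysis of Dynamic Adaptations
in Parameter Trajectories), for systems biologists who have a mass-action
ODE model of a metabolic network and mean ± SD time-series measurements
from a treatment or disease-progression study, and who want to know *which
kinetic processes changed, when, and by how much*, including estimates for
pools and fluxes that were never measured directly.

## The method

The metabolic network is a state-space model

```
dx/dt = N f(x, p, u),    y = g(x, f, p),
```

with stoichiometry `N`, mass-action rate laws `f`, parameters `p` and an
output map `g` onto the measured observables. Measurement uncertainty is
propagated by a Monte Carlo ensemble of cubic smoothing splines through
Gaussian resamples of the data. After multistart calibration of the
untreated baseline, the treatment horizon is split into `N_t` segments and
the parameters of each segment are re-estimated by minimizing

```
chi^2 = chi_d^2 + lambda_g1 * chi_g1^2 + lambda_g2 * chi_g2^2
```

where `chi_d^2` is the weighted SSE against the data interpolants,
`chi_g1^2 = sum_i (1/N_ci) sum_j (1 - rho_ij)^2` rewards Pearson correlation
between parameter trajectories and their coupled genes' expression profiles,
and `chi_g2^2 = sum_i (1/N_ci) sum_j (P_i / G_ij)^2` penalizes parameter
changes (`P_i`: baseline-normalized parameter derivative) except where the
coupled genes' expression is itself changing (`G_ij`: normalized gene
derivative, floored at 1e-6). Ensembles over spline samples and random
`(lambda_g1, lambda_g2)` pairs are filtered by a 95%-interval acceptance
criterion, grouped by gene correlation (`G_0.05` = the best-correlated 5%),
and compared by per-time variance reduction; the net rate of any metabolite
pool decomposes into additive/subtractive flux routes with fractional
contributions and peak times.

Because the original mouse study's measurements exist only as published
figures, the package ships a synthetic benchmark (`benchmark_suite()`) with
a reduced 5-state hepatic-lipid toy model and known ground truth, so every
stage is testable offline.

## Worked example

```r
library(adaptr)

suite  <- benchmark_suite()            # scenarios A (recovery), B, C
B      <- suite$B                      # latent cytosol/ER TG split
bundle <- scenario_data(B, seed = 1, n_t = 21)

base <- calibrate_baseline(B$model, bundle$data,
                           n_scatter = 400, keep_fraction = 0.05, seed = 2)
ens  <- build_spline_ensemble(bundle$data, n_samples = 48, seed = 3)
bl   <- lapply(1:48, function(s)
  refine_baseline(B$model, bundle$data, ens$anchors[[s]], base$p[[1]]))

scan <- scan_lambdas(B$model, bl, ens, bundle$data, bundle$coupling,
                     n_runs = 48, seed = 7, n_t = 21, t_end = 21)
scan
#> <solution_ensemble> 48 runs, 46 accepted, 12 unregularized (G0)

vr <- variance_reduction(group_g(scan, 0.05), group_g0(scan), "tg_cyt")
head(vr, 3)
#> # A tibble: 3 x 4
#>    time var_group var_reference    vr
#>   <dbl>     <dbl>         <dbl> <dbl>
#> 1     0     0.174          1.88 0.908
#> 2     1    57.6          178.   0.676
#> 3     2    18.0           83.6  0.785
```

The `vr` column is `1 - Var(G_0.05)/Var(G0)` for the *unmeasured* cytosolic
TG pool: the solutions with the highest gene correlation pin down a quantity
the metabolic data alone leave undetermined (the measured total pool is
described equally well by both groups). The exact numbers vary with the
seeds; these were printed by this code.

Flux-route analysis on an accepted solution:

```r
sol <- scan$solutions[[which(scan$runs$accepted)[1]]]
dec <- decompose_pool(B$model, c("tg_cyt", "tg_er"))
time_to_peak(fractional_contribution(
  route_components(sol, dec, routes = list(uptake = "f_est", dnl = "f_dnl",
                                           clearance = "f_clr"))),
  sol$times)
#> # A tibble: 3 x 3
#>   route     time_to_peak peak_fraction
#>   <chr>            <dbl>         <dbl>
#> 1 uptake               0         0.658
#> 2 dnl                 21         0.396
#> 3 clearance            0         0.207
```

The fractional contribution of the FFA-uptake route is maximal in the
earliest phase of the treatment, long before de novo lipogenesis reaches
its peak — the route-timing signature built into the benchmark truth, which
the acceptance suite verifies across the whole accepted ensemble.

Results objects are tidyverse-friendly: `tidy()` returns long tibbles,
`glance()` one-row summaries, and `autoplot()` draws trajectory and band
plots. A thin command line lives at `inst/cli/adapt.R`
(`synth | calibrate | fit | scan | analyze | report`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the main pipeline from scratch on the synthetic benchmarks at
reduced scale — constant-parameter recovery, a regularization-constant
scan with grouping and variance reduction, and the flux-route timing
analysis — printing a summary of each stage and writing the results JSON
to `--out`.
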