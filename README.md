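# irfa — immunoreactive fraction assay modelling

Radiolabeling a monoclonal antibody (radioiodination, chelator
conjugation, ...) inevitably damages part of the product. The
**immunoreactive fraction** *r* — the share of the labelled antibody that
can still bind its antigen — is a mandatory quality-control figure for new
radioimmunoconjugates. It is defined at dynamic equilibrium under infinite
antigen excess, so it can only be reached by extrapolating a saturation
binding assay: a fixed trace of labelled antibody ([T] ≈ 0.1 nM) against
increasing coated antigen [Ag]₀, read out on a γ-counter.

Two extrapolation estimators compete:

- the **rectangular hyperbola** (Langmuir isotherm), fitted by nonlinear
  least squares:

  B/T = r·[Ag]₀ / ([Ag]₀ + K_D)

- the **Lindmo plot**, the double-inverse linearization fitted by ordinary
  least squares, with 1/r at the y-intercept and slope K_D/r:

  T/B = 1/r + (1/[Ag]₀)·(K_D/r)

Both are approximations: the true isotherm under **antigen depletion**
(bound antibody consuming free antigen) is the smaller root of

x² − x·(K_D/T + [Ag]₀/T + r) + r·[Ag]₀/T = 0,  x = B/T,

and real assays also suffer **unattained equilibrium** (pseudo-first-order
association with rate constant k_on·[Ag]₀ — low-antigen wells equilibrate
slowest), finite plate binding capacity and complex desorption. This
package implements the exact model, the two estimators with stepwise
low-antigen exclusion, a four-component error-propagation model (antigen
amount, antibody amount, nonspecific binding, γ-counter), the kinetic and
plate-saturation scenarios, and a seeded Monte-Carlo engine that compares
the estimators for accuracy, precision and robustness. It also reduces
real plate γ-counts to saturation curves and provides assay-design
helpers. The practical conclusion the simulations support: the hyperbola
is robust (a stable ≈10% overestimate of r under slow kinetics), while
the unexcluded Lindmo fit amplifies low-bound-fraction errors into
nonsense estimates.

## Worked example

Noise-free bound fractions at K_D = 1 nM, distorted by 1200 min of slow
kinetics (k_on = 1.444·10⁻⁴ nM⁻¹min⁻¹), then fitted both ways:

```r
library(irfa)
params <- binding_parameters(r = 0.7, kd = 1, t_total = 0.1)
grid <- scenario_grid(params, kd_axis = 1,
                      settings = kinetic_settings(time = 1200))
pts <- grid_points(grid)
round(pts$bound_fraction, 4)
#> [1] 0.0747 0.1748 0.3374 0.5236 0.6457 0.6822 0.6913

fit_hyperbola(pts)
#> IRFA fit (hyperbola)
#>   r      : 80 %
#>   KD     : 6.64 nM
#>   points : 7 used, 0 dropped (non-positive)

fit_lindmo(pts)
#> IRFA fit (lindmo)
#>   r      : 158 %
#>   KD     : 24 nM
#>   points : 7 used, 0 dropped (non-positive)

fit_hyperbola(apply_exclusion(pts, 5))   # drop ag0 <= 5 nM
#> IRFA fit (hyperbola)
#>   r      : 74 %
#>   KD     : 3.74 nM
#>   points : 4 used, 0 dropped (non-positive)
```

The true value is 70%: the hyperbola overshoots mildly (80%, and 74% after
excluding the slow low-antigen points) while the Lindmo line returns a
meaningless 158%. Adding the stochastic error model and repeating over 25
simulated triplicate experiments:

```r
cfg <- simulation_config(seed = 42)
sm <- run_comparison_study(cfg)
sm[sm$kd_nM == 1 & sm$exclusion_nM %in% c(0, 5), ]
#>  kd_nM    method exclusion_nM mean_r_pct sd_r_pct n_flagged
#>      1 hyperbola            0         80        1         0
#>      1 hyperbola            5         74        2         0
#>      1    lindmo             0        201      579         3
#>      1    lindmo             5         75        2         0
```

`mean_r_pct ± sd_r_pct` summarise the estimates over replicates;
`n_flagged` counts non-converged or negative fits. The hyperbola is
precise (SD ≈ 1 point); the unexcluded Lindmo fit is chaotic.

A thin command-line front end over the same functions is available at
`exec/irfa` (`fit`, `plate`, `kinetics`, `design`, `error-grid`,
`simulate` subcommands).

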