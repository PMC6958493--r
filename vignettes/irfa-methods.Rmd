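---
title: "Models and methods behind irfa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind irfa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irfa)
```

## The assay and its models

An immunoreactive fraction assay (IRFA) incubates a fixed trace of
radiolabeled antibody, total concentration $[T]$, against wells coated
with increasing total antigen $[Ag]_0$, and measures the bound fraction
$B/T$ from supernatant $\gamma$-counts. The immunoreactive fraction $r$
is the bound fraction that would be reached at equilibrium under infinite
antigen excess; it must be extrapolated.

Three nested models appear in the package:

**Exact depletion isotherm.** Monovalent binding at equilibrium with mass
balance ($[Ag] = [Ag]_0 - B$) makes $x = B/T$ the smaller root of

$$x^2 - x\left(\frac{K_D}{T} + \frac{[Ag]_0}{T} + r\right)
  + r\,\frac{[Ag]_0}{T} = 0 .$$

The smaller root is the physical one: it vanishes at $[Ag]_0 = 0$ and
tends to $r$ as $[Ag]_0 \to \infty$. `bound_fraction_exact()` computes the
larger root first and recovers the smaller from the product of roots
$r\,[Ag]_0/T$. This matters numerically: with the default grid the ratio
$[Ag]_0/T$ reaches $800$, where the subtractive form of the quadratic
formula loses most of its significant digits to cancellation. When the
discriminant falls below $10^{-12}\max(1, s^2)$ (near-coincident roots) a
warning is emitted; the regime is not reachable from the standard study
conditions but can be provoked with extreme parameter choices.

**Rectangular hyperbola.** The depletion-free Langmuir form
$B/T = r\,[Ag]_0 / ([Ag]_0 + K_D)$, used both as a generating
approximation and as the nonlinear estimator's model.

**Lindmo line.** The double inverse $T/B = 1/r + (1/[Ag]_0)(K_D/r)$, an
algebraically exact linearization of the hyperbola that redistributes
error catastrophically: inverting small bound fractions turns small
absolute errors into enormous ones.

Units are fixed internally to nM and minutes; $r$ is stored as a fraction
and rendered as a percentage only in printed output.

## Estimators

`fit_hyperbola()` performs unweighted, *unconstrained*
Levenberg–Marquardt least squares (via `minpack.lm::nlsLM`). No bounds
are imposed on $\hat r$ or $\hat K_D$ deliberately: estimates above 100%
or below zero are diagnostically meaningful and standard curve-fitting
software reports them. Starting values are $r_0 = \max(B/T)$ and
$K_{D,0}$ = the first antigen level at which the curve passes $r_0/2$
(median level as fallback); tolerances are tightened to $10^{-15}$ on the
objective and parameters with up to 1000 iterations, far past the
reporting precision (integer percent for $r$, 3 significant figures for
$K_D$), so reported values are insensitive to optimiser settings.
Exact last-digit agreement with any particular commercial fitter is not
guaranteed at full precision, only at reporting precision.

`fit_lindmo()` is ordinary least squares of $T/B$ on $1/[Ag]_0$,
*unweighted* — the historical protocol's assumption of constant CV is
exactly what the error model shows to be false, and weighting would
change the method under study. $\hat r = 1/\text{intercept}$,
$\hat K_D = \text{slope}/\text{intercept}$. Non-positive bound fractions
(possible after noise injection) have no reciprocal: they are excluded
from the transform and counted, never silently, while the hyperbola fit
keeps them. Estimates that are non-finite, negative, or from
non-converged fits are *flagged*, not removed: the summary statistics of
a naive analysis would include them, and the comparison is about exactly
that fragility.

`apply_exclusion()` implements stepwise deletion of low-antigen points
(thresholds none/1.25/2.5/5 nM in the study), the standard remedy for
the Lindmo fit's fragility.

## Kinetics and plate scenarios

With antigen in large excess, association is pseudo-first order with rate
constant $k_{on}' = k_{on}[Ag]_0$, so the bound fraction at time $t$ is
the equilibrium value times $1 - e^{-k_{on}[Ag]_0 t}$
(`integrated_rate_factor()`). The $k_{off}$ contribution to the
integrated rate is omitted (irreversible approximation): the model is
intended for slow, high-affinity complexes, and the distorted data are
qualitative by construction. Consequences: low-antigen wells are
systematically depressed (they equilibrate with half-time
$\ln 2 / (k_{on}[Ag]_0)$), which mimics a higher-$K_D$ isotherm and is
precisely the mechanism that breaks the Lindmo extrapolation.

The default $k_{on} = 1.444\cdot10^{-4}$ nM$^{-1}$min$^{-1}$ is the value
recovered from a laboratory kinetic assay by half-time inversion at
$[Ag]_0 = 20$ nM ($t_{1/2} = 240$ min); `kon_from_half_time()` and
`estimate_kon_from_kinetic_series()` implement that estimation (half-max
crossing located by linear interpolation between bracketing time points —
the method of locating it is otherwise unspecified, and linear
interpolation is the least-assumption choice at the sampling densities of
a plate assay).

Plate scenarios: polystyrene has finite protein-binding capacity
(`max_coated_antigen()`), so applied levels above a cap (default 30 nM, a
conservative figure for large antigens) all coat the same amount. The
antigen series keeps the *nominal* applied labels \{40, 80\} nM for
fitting and reporting — the experimenter knows what was applied, not what
coated — while all computation uses the *coated* values \{30, 30\}. In
the desorbing scenario, complex at the capped wells is additionally
multiplied by 0.9. That desorption multiplier is deliberately
time-independent, a model simplification: real desorption grows with
time, but a constant 10% loss is sufficient to study its effect on the
estimators, and the simulation makes no claim to model desorption
kinetics.

## Error model

Four sources, each expressed as an SD of $B/T$ per grid cell:

| source | default | propagation |
|---|---|---|
| coated antigen amount | 10% relative | triplet of full-model evaluations at $\{0.9, 1, 1.1\}[Ag]_0$ |
| applied antibody amount | 1% relative | apparent-fraction transform $B'/T = B/T - \frac{\Delta T}{T}(1 - B/T)$ |
| nonspecific binding | blank SD 1.5% | constant $\sqrt{2}\cdot 0.015 \approx 0.021$ |
| $\gamma$-counter | 0.01 absolute | constant |

The triplet SDs use the **sample** ($n-1 = 2$) denominator: the symmetric
triplet $\{x-\delta, x, x+\delta\}$ then has SD exactly $\delta$, which
makes the antibody component exactly
$0.01\,(1 - B/T)$ — range 0.003–0.010 over the default grid — and the
antigen component peak at 0.018 where $K_D \approx [Ag]_0$. The
population convention would shrink both by $\sqrt{2/3}$ and contradict
those ranges. The overall SD is the cellwise quadratic sum; over the
default equilibrium grid it spans about 0.024–0.030 and is dominated by
the antigen and nonspecific terms.

When kinetics are active, the antigen and antibody SDs are recomputed
from the kinetics-distorted bound fractions; the antigen perturbation
enters the integrated rate factor as well as the isotherm (the coated
amount governs both the equilibrium level and the association rate).
This double entry is a modelling choice — the alternative, perturbing the
isotherm only, is available via `perturb_rate_factor = FALSE` and
differs appreciably only at slow (low-antigen) cells.

The CV grid divides the overall SD by the mean bound fractions; cells
with non-positive means are returned as `NA` and counted rather than
raising, because noisy replicate grids legitimately contain them. For
smoother CV contours a denser KD axis can simply be supplied; no
interpolation is special-cased.

## Monte-Carlo engine

The study conditions are the package defaults: $r = 70\%$,
$[T] = 0.1$ nM, nine $K_D$ values $\{0.01, \ldots, 100\}$ nM (half-decade
steps), the seven-level antigen series, kinetics at $t = 1200$ min,
$n = 25$ replicate pseudo-experiments. Each replicate draws every cell
from a normal distribution centred on the distorted mean with SD equal to
the overall SD divided by $\sqrt{3}$ — the SD of a triplicate *mean*.
One draw per cell is distributionally identical to averaging three
explicit draws at the full SD; `explicit_triplicates = TRUE` switches to
the literal version for verification. Negative draws are retained.

Randomness uses R's Mersenne–Twister with a dedicated substream per
(replicate, $K_D$ row), derived arithmetically from the user seed, so
excluding or reordering rows never shifts another row's draws and the
whole summary is bit-reproducible from `(config, seed)`. Exclusion
variants refit the *same* draws, matching the stepwise-deletion design.
With 25 replicates the standard error of a mean $\hat r$ is about
$SD/5$, so replicated summary means are stable to roughly a percentage
point wherever the estimator itself is stable; exact reproduction of any
particular published run would require its (unknown) seed, and agreement
is therefore assessed within the reported dispersion.

## Plate arithmetic

Real plates are reduced with the blank-based convention: blanks (blocked,
uncoated wells) lose only nonspecific binding, which is invariant across
wells because the blocked polystyrene area is invariant, so the working
total is $T \equiv \overline{U}_{blank}$ and each well's bound fraction
is $(\overline{U}_{blank} - U)/\overline{U}_{blank}$. The separate
total-activity tubes are used only as the internal control
$B_{NS} = \overline{T}_{tubes} - \overline{U}_{blank}$. Negative bound
fractions are warned about and reported unclipped so that downstream
estimator behaviour on real noisy data matches the simulation's.
Kinetic-assay rows pipetted without replicates are accepted with
per-level $n = 1$ (no SD); the blank triplet still anchors the scale.

For assay design, the wetted polystyrene area of a well is the base disc
plus the lateral band of the coating volume (94.7 mm² for a 6.4 mm well
and 100 µL), and the maximum coatable antigen is capacity × area /
volume, expressed in nM for a given molecular weight. The 500 ng/cm²
capacity figure carries one significant digit, so the per-well bindable
mass is kept at that precision by default (500 ng, hence 50 nM at
100 kDa); `mass_sig_digits = Inf` gives the unrounded arithmetic
(47.4 nM).

## What the simulator does and does not emulate

The generator reproduces: Gaussian per-cell noise with the error budget's
cell-dependent SD, the systematic kinetic depression, plate saturation
(duplicated coated tail under distinct nominal labels), and constant
desorption. It does not emulate: reversible kinetics ($k_{off}$ during
association), Poisson counting statistics (the counter SD is fixed,
appropriate when counting times are chosen to hit a target precision),
avidity/multivalent binding, partial antigen adsorption or inaccessible
epitopes, or time-dependent desorption. Passing tests therefore
demonstrate estimator behaviour *under this error structure*, not under
every laboratory pathology; in particular real $K_D$ estimates from an
IRFA are further biased by incomplete antigen adsorption, one reason the
package's documentation discourages reading $\hat K_D$ quantitatively
off an IRFA at all.

## Numerical and design choices, in brief

- Root extraction via product-of-roots (cancellation-safe to
  $[Ag]_0/T \sim 10^3$ and beyond); discriminant warning threshold
  $10^{-12}$.
- Unconstrained fits; flagging instead of constraining or discarding.
- Sample-SD convention for error triplets (see above).
- One draw per cell at SD$/\sqrt{3}$; substreams per (replicate, row).
- Exclusion threshold semantics: drop $[Ag]_0 \le$ threshold, nominal
  labels.
- Problem sizes: the shipped tests and the acceptance script run the full
  9 × 7 grid with $n = 25$ replicates (the study conditions themselves),
  plus a 4000-draw check of the noise scale on a single cell; the whole
  suite completes in well under a minute on one core.

## Known limitations

- The irreversible kinetic factor overstates distortion for fast-off
  complexes; no reversible mode is provided.
- $\hat K_D$ from kinetics-distorted data is systematically high for both
  estimators; the package reports it but the assay should not be used to
  measure affinity.
- The desorption model is a constant multiplier, not a kinetic process.
- Counter error is homoscedastic; very low-activity assays (< 1000 cpm)
  would need a Poisson term the model intentionally omits.
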