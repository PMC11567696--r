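---
title: "Discrete diffusive association rate models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discrete diffusive association rate models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffrate)
```

## The model family and its assumptions

All models in this package answer the same question: the pseudo-first-order
rate (encounters per second) at which diffusing probe molecules at number
density $C$ (1/m³) with relative diffusion coefficient $D$ (m²/s) reach one
target molecule. They differ only in what they assume about the concentration
gradient around the target and about the collision geometry.

**Continuous-gradient models.** The Smoluchowski rate
$r = 4\pi r_0 C D$ assumes a steady-state Fick gradient around an absorbing
sphere of radius $r_0$; the Langmuir–Schaefer rate
$r = 2 A C \sqrt{D/(\pi t)}$ assumes a one-dimensional gradient that keeps
evolving, so its rate decays as $1/\sqrt{t}$. Both are appropriate when a
*real* depletion gradient can form — aggregation, multilayer adsorption —
and both are first order in $C$.

**Discrete reshuffle models.** For one-on-one association, the gradient
around a single target is virtual: whenever the probe population rearranges
over its mean separation $L = C^{-1/3}$, the target cannot distinguish the
new nearest neighbor from the old one and the imagined gradient restarts.
That happens every critical time
$$t_c = \frac{1}{2 D C^{2/3}}, \qquad \sqrt{2 D t_c} = L ,$$
an identity the test suite asserts exactly. Counting one encounter attempt
per $t_c$, a success fraction $a$, and an empirical factor of 2 for the
self-similar sub-steps of diffusion that the coarse time grid misses, gives
the 0D rate $r = 2a/t_c = 4 a D C^{2/3}$. Expressing $a$ through a binding
area ($a = 4A/4\pi L^2$) or a collision volume ($a = C V_0$) gives the 2D
and 3D forms with orders 4/3 and 5/3 in concentration. The fractional order
is the experimentally testable signature; the shipped single-molecule
DNA–dye dataset shows order $0.67 \pm 0.05$.

```{r order}
fit_power_law(yoyo_lambda_dataset())
```

## Parameters, units, defaults

Everything internal is SI (m, s, kg, K, 1/m³); bench units (nM, nm, nm²,
nm³, µm) are converted only at I/O boundaries (`nM_to_number_density()`,
the CLI flags, the inversion-table columns). Constants are CODATA:
$N_A = 6.02214076\times 10^{23}$/mol, $k_B = 1.380649\times10^{-23}$ J/K,
$R = 8.31446$ J/(mol·K).

The parameters that matter:

* `D` — relative diffusion coefficient, m²/s. For the fixture we use the
  published probe value $2.9\times10^{-10}$ m²/s throughout. The published
  probe radius (~0.9 nm) and this $D$ are stored verbatim side by side even
  though they are only mutually Stokes–Einstein-consistent at a slightly
  non-standard viscosity; neither is derived from the other.
* `ell` — cylinder length for the effective-radius reporting conventions
  $r_0 = A/\ell$ and $r_0 = \sqrt{V_0/\ell}$, default 1 µm (the stretched
  DNA target). These conventions are *inferred*: they reproduce every
  published effective-radius cell from the corresponding area/volume cell,
  but they are reporting conventions, not physical derivations.
* `fractal_correction` in `critical_time()` — halves $t_c$, default off.
  The rate equations that use the factor of 2 carry it in their printed
  coefficients, so the flag exists for transparency and double counting is
  structurally impossible.

## Coefficient decisions

Two coefficients in the 2D family deserve explicit justification because
typography in the field's literature is unreliable:

* The **2D coefficient is $4/\pi$**, not $4\pi$: substituting
  $a = 4A/(4\pi L^2)$ into $r = 4 a D C^{2/3}$ at $L = C^{-1/3}$ *forces*
  $r = (4/\pi) A D C^{4/3}$, and only this value reproduces the published
  area column (≈3400 nm² at 1 nM; $4\pi$ would give ≈340 nm²). The identity
  is asserted to $10^{-12}$ in the tests.
* The **reshuffle form of the 2D rate is $2\sqrt{2/\pi}\,A D C^{4/3}$**,
  the unique result of substituting $t = t_c$ into the Langmuir–Schaefer
  rate. Its ratio to the $4/\pi$ form is $\sqrt{\pi/2} \approx 1.25$ — a
  constant the tests pin down symbolically. (A factor of exactly $\sqrt 2$
  is sometimes quoted for this comparison; the implemented algebra gives
  $\sqrt{\pi/2}$, and we document rather than reconcile the difference.)
* The **3D area-like rewrite** is implemented as the unambiguous algebraic
  identity $(16\pi/3)(r_0^3/L)\,D C^{4/3}$, equal to the volume form with
  $V_0 = \tfrac43\pi r_0^3$ at $L = C^{-1/3}$ (tested), because the printed
  compact form of this rewrite is typographically ambiguous.

One column of the published table is knowingly inconsistent: its $t_c$
values are ≈10× smaller than $1/(2DC^{2/3})$ evaluated with the published
$D$. `reproduce_table2()` therefore recomputes $t_c$ from the equation,
annotates the discrepancy, and excludes that column from its pass/fail
audit; everything else reproduces within the 10% tolerance implied by the
2-significant-figure printed cells.

## Fitting

Order fitting is OLS of $\log r$ on $\log C$ with equal weights: measured
rates span ~25× in the fixture and the models are exact power laws, so log
residuals are the natural scale. Order uncertainty is the OLS standard
error (six-point datasets do not support fancier machinery; `simulate()` on
a geometry fit provides parametric replicates when needed). A degenerate
dataset (all rates equal) returns order 0 with infinite standard error and
a flag, not an error.

Constant-geometry fits exploit that every time-independent model is linear
in its single geometry parameter: the log-space least-squares solution is
the geometric mean of the per-point inversions, which is exact, closed
form, and zero-residual if and only if the data lie on the model curve.
`compare_models()` ranks models by RMS log-residual with ties broken by
canonical id order; since all models are pure power laws, the ranking is
driven by the gap between each model's concentration exponent and the
data's apparent order.

## The Monte Carlo engine

`simulate_absorbing_sphere()` propagates independent walkers with Gaussian
increments (variance $2D\,\delta t$ per axis) in a periodic cube with
minimum-image distance to one absorbing sphere; absorbed walkers are
re-injected uniformly so concentration stays fixed. The box side is
$(n/C)^{1/3}$, fixing concentration exactly. Design choices:

* **Endpoint-crossing absorption, no bridge correction.** A walker is
  absorbed when a step *ends* inside the sphere; paths that cross and exit
  within one step are missed. The resulting bias shrinks with step length;
  configurations with $\sqrt{2D\delta t} > r_0/3$ are refused outright, and
  the test suite bounds the residual bias empirically by step halving. The
  1D monitors (`simulate_first_passage_1d()`,
  `estimate_coarse_graining_factor()`) additionally apply the standard
  continuity correction (barrier pulled in by $0.5826\sigma$), which is
  exact to first order for flat barriers.
* **Seeding.** Each run seeds R's Mersenne–Twister once from its config;
  all operations are single-threaded and vectorized, so identical seeds
  give bitwise-identical trajectories and changing only the seed changes
  the draws. The determinism contract is tested literally with
  `identical()`.
* **Problem sizes.** The suite validates the Smoluchowski flux with ~10⁴
  walkers in a box of side 40 $r_0$ over ~200 expected encounters (3-SE
  band ≈15%), against which the known systematics — finite-box periodic
  images (~+5% at side 40 $r_0$), endpoint-miss bias (~−5% at the chosen
  step), residual transient after the 20% burn-in — are small. These sizes
  are the package's chosen compromise between statistical power and a
  test suite that runs comfortably on one CPU; scale `walker_count` and
  `total_time` up for tighter bands.
* **Transient enhancement.** The early-time rate onto an initially
  uniform distribution exceeds the steady plateau by a factor
  $1 + r_0/\sqrt{\pi D t}$. For one target at realistic dilution the excess
  counts sit below Poisson noise in any single run, so the test aggregates
  early-vs-late windows across 16 seeded replicate boxes rather than
  pretending one run can resolve it.
* **The factor-of-2 question.** `estimate_coarse_graining_factor()` treats
  the claimed factor ≈2 between continuous diffusion and discrete per-$t_c$
  counting as an *output*, not an assertion. Under its explicit first-exit
  renewal convention the transition rate analytically equals $1/t_c$
  (ratio 1, confirmed by the mean-exit-time identity $L^2/2D$); other
  counting conventions (e.g. raw cell-index flips, whose rate diverges as
  the sampling step shrinks) give larger factors. The function documents
  its protocol precisely so the discrepancy is visible rather than hidden.
* **Mirror mode.** `boundary_mode = "mirror_plane"` places the target
  hemisphere on a specularly reflecting plane, emulating a
  surface-immobilized target; it is exploratory and no factor-of-2 surface
  enhancement is asserted.

## What the synthetic generator does and does not emulate

`generate_synthetic()` draws $r_i = \text{model}(g, D, C_i)\,e^{\epsilon_i}$
with $\epsilon_i \sim N(0, \sigma_{\log})$ — an exact power law with
multiplicative measurement noise. That reflects the dominant error
structure of single-molecule rate estimates (relative, roughly lognormal),
and it makes recovery tests sharp: noiseless data must return the
generating exponent to $10^{-9}$, and at $\sigma_{\log} = 0.1$ with 20
points the fitted order lands within ±0.1 of truth in ≥95% of replicates.
It does **not** emulate concentration-dependent chemistry — in the real
dye–DNA system the inverted binding area falls with concentration
(binding/intercalation competition), a trend the package reports via
`invert_dataset()` but deliberately does not model. Passing recovery tests
therefore demonstrates correctness of the fitting pipeline, not that real
data follow a single-parameter model.

## Numerical conventions and degenerate inputs

Fractional powers are computed on positive reals only; validators reject
non-finite or non-positive physical quantities before any power is taken.
Zero concentration yields infinite separation and infinite critical time
(graceful blank-row handling) instead of an error; zero rate inverts to
zero geometry; effective fractions above 1 (geometry larger than the
neighbor sphere) are domain errors rather than silent saturations.
Quadrature-based tests integrate on ranges scaled to the diffusion length
$\sqrt{4Dt}$ so the adaptive rule resolves the Gaussian peak at any scale.

## Known limitations

* No hydrodynamic or electrostatic interactions, no convection, and no
  multi-step sequential binding — the engine simulates ideal independent
  Brownian walkers only.
* The Langmuir–Schaefer and naive continuous models require an explicit
  time and are excluded from time-independent inversion and ranking
  (`invert_langmuir_schaefer()` exists separately so misuse is loud).
* The cylinder effective-radius conventions are reporting conventions
  inferred from the published table, and the $t_c$ column inconsistency
  noted above is documented, not repaired.
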