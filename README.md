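# diffrate

Forward prediction, inverse geometry estimation, and stochastic validation
for the family of diffusive association/adsorption rate equations used in
single-molecule binding kinetics.

## The problem

How often does a diffusing probe molecule find a single target in dilute
solution? The classical answers — hard-sphere collision theory, the
Smoluchowski steady-state flux, and the Langmuir–Schaefer transient flux —
assume a continuously evolving Fick concentration gradient and predict rates
that are first order in probe concentration. A discrete alternative argues
that around a single target the imagined gradient must be *reshuffled* every
time the probe population rearranges over its mean separation
L = C^(−1/3), i.e. every critical time

    t_c = 1 / (2 D C^(2/3)),

which yields a family of fractional-order rate laws, one per collision
geometry (the per-attempt success fraction `a`, a binding area `A`, or a
collision volume `V0`):

| model | rate equation | order in C |
|---|---|---|
| discrete 0D | r = 2a/t_c = 4 a D C^(2/3) | 2/3 |
| Smoluchowski (1D) | r = 4π r0 C D | 1 |
| discrete 2D | r = (4/π) A D C^(4/3) | 4/3 |
| 2D, reshuffle form | r = 2√(2/π) A D C^(4/3) | 4/3 |
| Langmuir–Schaefer | r = 2 A C √(D/(π t)) | 1 |
| discrete 3D | r = 2 C V0/t_c = 4 V0 D C^(5/3) | 5/3 |

`diffrate` implements the whole family with a dimensional-analysis registry,
closed-form inversion from measured rates, log–log reaction-order fitting,
transport utilities (Stokes–Einstein, Gaussian propagator, first-passage
closed forms), and a seeded Brownian-dynamics Monte Carlo engine that checks
the stochastic assumptions (absorbing-sphere flux, capture fractions, mean
exit times) against their analytic oracles. It ships the published
single-molecule dataset of YOYO-1 dye binding to stretched λ-DNA as an
embedded fixture.

## Worked example

```r
library(diffrate)

ds <- yoyo_lambda_dataset()          # 6 measured (C, r) pairs, 1-100 nM
fit_power_law(ds)
#> <power_law_fit> rate = k * C^order
#>   order:  0.6719 +/- 0.0454
#>   ln(k):  -27.7933   R^2: 0.9821   n: 6
```

The measured binding rate rises as roughly C^(2/3) — far from first order —
which is exactly the exponent of the discrete 0D model. Inverting each model
for the geometry it would need at each concentration:

```r
invert_dataset(ds, D = 2.9e-10)      # published probe D, m^2/s
#>  conc_nM  L_um tc_us rate_per_s a_1e3 r0_1d_nm A_nm2 r0_2d_nm V_1e4_nm3 r0_3d_nm
#>        1 1.184  2418       0.63 0.762   0.2871  3355    3.355    126.46    35.56
#>        3 0.821  1162       1.49 0.866   0.2263  1834    1.834     47.93    21.89
#>        5 0.693   827       2.85 1.178   0.2597  1775    1.775     39.13    19.78
#>       10 0.550   521       4.00 1.042   0.1823   989    0.989     17.30    13.15
#>       50 0.321   178      10.00 0.891   0.0911   289    0.289      2.96     5.44
#>      100 0.255   112      15.00 0.842   0.0683   172    0.172      1.40     3.74
```

The 0D fraction `a` stays nearly constant (~0.9 × 10⁻³) across a 100-fold
concentration range, while the Smoluchowski radius and the 3D volume must
shrink with concentration to fit the same data — the 0D/2D picture describes
this system, the 1D/3D ones do not:

```r
compare_models(ds, D = 2.9e-10)
#> <model_comparison> ranked by RMS log-residual
#>            model geometry_symbol best_parameter residual_norm
#>      discrete_0d               a      9.201e-04        0.1443
#>  smoluchowski_1d              r0      1.636e-10        0.5402
#>      discrete_2d               A      9.017e-16        1.0595
#>   discrete_2d_tc               A      7.194e-16        1.0595
#>      discrete_3d              V0      1.603e-22        1.5851
```

The Monte Carlo engine validates the continuum benchmarks, e.g. the
steady-state encounter rate of an absorbing sphere against 4π r0 D C:

```r
cfg <- sim_config(1, 0.1, target_radius = 1, box_side = 24,
                  time_step = 0.005, total_time = 100, seed = 17)
simulate_absorbing_sphere(cfg)
#> <encounter_stats> 141 encounters; rate 1.337 +/- 0.1 /s (Smoluchowski 1.256 /s), seed 17
```

A command-line wrapper is installed at `inst/cli/diffrate`:

```sh
Rscript inst/cli/diffrate predict --model smoluchowski --r0-nm 0.29 --conc-nM 1 --D 2.9e-10
# rate: 0.636439 /s
Rscript inst/cli/diffrate table2     # full fixture reproduction, PASS/FAIL
```

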