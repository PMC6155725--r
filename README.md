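# saxsdecomp

Decomposition of 1-D small-angle X-ray scattering (SAXS) profiles into
generalized Guinier–Porod components, for systems where several
nanostructures scatter at once — the motivating case is cellulose
dissolved at high concentration in an ionic liquid, where a large
entangled-chain aggregate, a microfibril-sized aggregate and a power-law
shoulder from unresolvably large fibril bundles superimpose. The package
is aimed at scattering practitioners who have reduced 1-D curves
(q, I(q)[, σ]) in hand and want sizes, exponents and uncertainties out.

## What it computes

Each compact scatterer follows the generalized Guinier–Porod model

    I(q) = I0 · q^(−s) · exp(−q² Rg² / (3−s))   for q ≤ q1
    I(q) = D · q^(−d)                            for q ≥ q1

with crossover `q1 = (1/Rg)·√((d−s)(3−s)/2)` and prefactor `D` fixed by
value-and-slope continuity at `q1`. A measured profile is fitted with a
sum of such components plus an optional pure Porod shoulder `Ds·q^(−ds)`
by weighted nonlinear least squares, initialized automatically from the
peaks of the Kratky representation `q²I(q)` (a globular component peaks
at `q* = √3/Rg`). Near-spherical aggregates are sized through
`R² = (5/3)Rg²`, i.e. diameter `2√(5/3)·Rg`. Gel-like profiles without a
Kratky peak are fitted instead with the Debye–Bueche model
`A/(1+ξ²q²)²`, optionally plus an Ornstein–Zernike term `A/(1+ξ²q²)`,
with a parsimony comparison between the two.

A seeded synthetic-data generator reproduces the reference
concentration series (30–80 mol % cellulose, instrument window
q = 0.142–2.844 nm⁻¹) so the whole pipeline is testable without any
measured data.

## Worked example

Simulate one noisy 60 mol % profile (two aggregates plus shoulder, 2%
multiplicative noise) and decompose it:

```r
library(saxsdecomp)

prof <- simulate_profile(reference_model(60),
                         noise = noise_model(level = 0.02, seed = 1),
                         concentration = 60)
fit <- fit_composite(prof, initialize_from_kratky(prof, 2))
fit
#> <saxs_fit> composite model, 256 points in q = 0.142-2.84 nm^-1
#>   reduced chi^2 = 0.9319, 10 free parameter(s), converged: TRUE
#>   ggp1.i0    1.0346 +/- 2.89
#>   ggp1.rg    5.8677 +/- 4.73
#>   ggp1.d     3.7414 +/- 1.63
#>   ggp1.s     0 +/- 2.24
#>   ggp2.i0    0.50745 +/- 0.0087
#>   ggp2.rg    1.6288 +/- 0.0904
#>   ggp2.d     3.9983 +/- 0.0424
#>   ggp2.s     0.057289 +/- 0.161
#>   porod.D    0.00033663 +/- 0.0079
#>   porod.d    3.5463 +/- 9.9

round(sphere_diameter(fit$model$ggp[[2]]$rg), 2)
#> [1] 4.21
round(sphere_diameter(fit$model$ggp[[1]]$rg), 2)
#> [1] 15.15
```

Component 1 (the larger Rg) is the entangled-chain aggregate, here
recovered at Rg ≈ 5.9 nm (generated truth 5.9) with a deliberately
honest, large standard error: its Guinier region overlaps the Porod
shoulder, so a single 2%-noise curve constrains it weakly. Component 2
is the microfibril-like aggregate, Rg ≈ 1.63 nm, whose equivalent-sphere
diameter of ~4.1–4.2 nm matches the known cellulose microfibril size.
A reduced χ² near 1 says the weighted fit is consistent with the noise
model. `analyze_series()` runs the same workflow across a whole
concentration series and `export_report()` writes the parameter table
(CSV/JSON) with `n/a` markers where a component is absent.

## Acceptance script

`scripts/acceptance.R` recomputes the package's headline quantities from
scratch at run time: the equivalent-sphere diameters implied by the
fitted radii of gyration of the reference series, the mean recovered
radii from composite fits of 20 freshly simulated noisy 60 mol %
replicates, and the mean recovered Debye–Bueche correlation length from
20 simulated gel-regime curves. Run it from the repository root against
the installed package:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The `--seed` argument controls every source of randomness; the output
is a small JSON object of named numeric results.

## Layout

- `R/` — profile I/O and preprocessing, model functions, fitting,
  series pipeline, synthetic-data generator
- `inst/cli/saxsdecomp.R` — thin command-line wrapper
  (`simulate` / `fit` / `kratky` subcommands)
- `vignettes/saxs-decomposition.Rmd` — methods notes: model forms,
  numerical choices, what the generator does and does not emulate
- `tests/testthat/` — unit, property and acceptance tests
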