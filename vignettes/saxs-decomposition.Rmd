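---
title: "Decomposing SAXS profiles into Guinier-Porod components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing SAXS profiles into Guinier-Porod components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saxsdecomp)
```

## The problem

Small-angle X-ray scattering (SAXS) probes structure on the 1-100 nm
scale through the azimuthally averaged intensity $I(q)$ at low momentum
transfer $q$. For concentrated polymer solutions — the motivating case
is cellulose dissolved in an imidazolium ionic liquid — the measured
curve superimposes scattering from several coexisting nanostructures:
compact aggregates of different sizes plus a power-law tail from
objects larger than the instrument window. `saxsdecomp` decomposes such
profiles into additive components, extracts sizes with uncertainties,
and handles the gel-like regime where a correlation-length model is the
appropriate description instead.

## The models

**Generalized Guinier-Porod.** Each compact scatterer is described by
the empirical piecewise model

$$I(q) = I_0\, q^{-s} \exp\!\left(\frac{-q^2 R_g^2}{3-s}\right), \qquad q \le q_1,$$
$$I(q) = D\, q^{-d}, \qquad q \ge q_1,$$

with forward intensity $I_0$, radius of gyration $R_g$, Porod exponent
$d$ and dimensionality parameter $s$ ($s=0$ globular, $1$ rod, $2$
lamella). Requiring the branches to match in value *and* logarithmic
slope at the crossover fixes

$$q_1 = \frac{1}{R_g}\sqrt{\frac{(d-s)(3-s)}{2}}, \qquad
  D = I_0\, q_1^{\,d-s} \exp\!\left(\frac{-q_1^2 R_g^2}{3-s}\right).$$

Published renderings of these equations sometimes typeset the
exponents ambiguously; the package adopts the standard
negative-exponent form above, which is the only reading that (a)
reduces to the Guinier law at $s=0$, (b) makes $q_1$ the value-and-slope
matching point, and (c) reproduces the published Kratky peak positions.
`ggp_porod_prefactor()` always derives $D$ from the continuity
condition rather than any closed-form re-expression.

**Porod shoulder.** Scatterers beyond the instrument's resolvable size
(here, microfibril bundles $> 50$ nm) contribute only their power-law
tail, modelled as a pure $D_s q^{-d_s}$ term with $d_s \in (3, 4]$ by
default.

**Correlation-length models.** Gel-like profiles without a Kratky peak
are fitted with the Debye-Bueche form $I = A/(1+\xi^2 q^2)^2$
(long-range inhomogeneities) optionally plus an Ornstein-Zernike term
$I = A/(1+\xi^2 q^2)$ (chain concentration fluctuations);
`compare_models()` formalizes the judgement of whether the extra term
is warranted.

**Sizing.** For a near-spherical scatterer ($s \approx 0$) the
equivalent-sphere diameter follows from $R^2 = \tfrac{5}{3} R_g^2$, so
`sphere_diameter()` returns $2\sqrt{5/3}\,R_g$.

## Kratky-based initialization

In the Kratky representation $q^2 I(q)$ a globular component peaks at
$q^* = \sqrt{3}/R_g$ (more generally $\sqrt{(2-s)(3-s)/2}/R_g$), so
peak positions seed radii and peak heights seed amplitudes
($I_0 = K(q^*) R_g^2 e/3$). Because a weak large-aggregate peak can sit
on the rising flank of a stronger small-aggregate curve and produce no
local maximum of its own, `initialize_from_kratky()` extracts peaks
*greedily*: find the strongest maximum of the smoothed curve, seed a
component, subtract its Kratky contribution, and search the residual
again. A smoothed curve that still rises toward the lowest measured $q$
seeds the Porod shoulder.

## Fitting: objective, uncertainties, numerical choices

Fits minimize $\sum_i w_i (I_{\mathrm{obs},i} - I_{\mathrm{model},i})^2$
in intensity space with $w_i = 1/\sigma_i^2$ when uncertainties are
present, else unweighted. Intensity space (rather than the Kratky
transform) is the conventional regression space in which reported
standard deviations are interpretable.

* Optimizer: bounded quasi-Newton (`nlminb`) on a log scale for
  amplitude- and length-type parameters; a seeded multistart (default
  5 starts, 10% jitter) runs at coarse tolerance, the best candidate is
  polished at `rel.tol = 1e-12`, and finally a few Gauss-Newton steps
  using the finite-difference residual Jacobian take noise-free
  problems to machine precision (nlminb alone stalls at its
  finite-difference gradient noise floor, around 6 significant digits).
* Bounds: $R_g \in [0.1, 50]$ nm (the instrument window),
  $d \le 4.5$, $s \in [0, 2.99]$ (the factor $3-s$ is kept positive by
  the bound, not by epsilon-fudging), shoulder $d_s \in (3, 4]$,
  amplitudes positive. The coupled constraint $d > s$ is enforced by
  penalty; all default truths sit far from that cliff.
* Uncertainties: standard deviations from the covariance of the
  linearized problem at the optimum,
  $\widehat{\mathrm{cov}} = \chi^2_\nu (J^\top J)^{-1}$ — the
  conventional meaning of "nonlinear regression" error bars. Singular
  information matrices yield `NA` standard errors rather than an error.
* Convergence: non-convergence sets a flag instead of throwing.
  `nlminb`'s "false convergence (8)" after a confirming restart at the
  optimum is classified as converged: it indicates tolerances tighter
  than the objective's numerical resolution, which the restart has
  verified.
* Components are reported ordered by descending $R_g$, so "component 1"
  is always the large aggregate regardless of initialization order
  (label-swap symmetry is tested).

## The synthetic-data generator

No raw data accompany the reference study, so the generator *is* the
test bed. It emulates the stated world directly:

* Instrument grid: $q = 0.142$-$2.844$ nm$^{-1}$, 256 points, linear
  spacing (Cu K$\alpha$, $\lambda = 0.154$ nm).
* Composite models per concentration from the published parameter
  table (`reference_series_params()`): one component at 30-40 mol %,
  two components plus shoulder at 50-80 mol %.
* Forward intensities are not published; the defaults are
  $I_{0,\mathrm{large}} = 1$, $I_{0,\mathrm{small}} = 0.5$, and a
  shoulder prefactor chosen so the shoulder contributes 20% of the
  total intensity at $q_{\min}$. Derived checks are constructed to be
  amplitude-invariant (peak positions, recovered radii, ratios against
  the generator).
* Noise: multiplicative Gaussian with 2% relative standard deviation —
  a typical laboratory-source figure — or Poisson counting noise;
  `sigma` carries the true per-point standard deviation; identical
  seeds give bit-identical profiles.
* Replicates: three per concentration above 40 mol % (sample
  inhomogeneity), one otherwise.

What the generator does **not** emulate: instrumental smearing,
detector geometry, dark current, polydispersity, or the true (unknown)
noise statistics of the experiment. A green recovery test therefore
establishes that the estimator inverts its own stated world, not that
it would reproduce the instrument's systematics.

One caveat the tests surface deliberately: with the default amplitudes
at 2% noise, the shoulder term and the large component's Guinier region
overlap enough that single-fit $R_{g1}$ estimates scatter widely (and
the $s_1 \ge 0$, $d_s \le 4$ bounds, both active at the truth, skew
them slightly low). The 20-replicate mean lands within the published
$\pm 0.5$ nm, which is the level at which the reference analysis
reports that parameter.

## Design choices on genuinely open points

* **Background subtraction before replicate averaging** is the pipeline
  default; the reference procedure does not state the order. Both
  operations are linear in intensity, so the mean is unaffected — only
  the bookkeeping of uncertainties differs.
* **A flat background term** is supported but off by default; the
  reference fits do not mention one.
* **Ratio normalization**: the published "normalized $I_2(0)/I_1(0)$"
  does not define its constant; the package divides by the series
  maximum (bounding the series by 1) and records the convention in the
  report. These values are a documented convention, not a reproduction.
* **Shoulder exponent**: whether $d_s$ was fixed at 4.0 or converged
  there is indeterminate from the published table; it is free by
  default within $(3, 4]$ and can be fixed via the `fixed` mask.
* **Component counts** default to the published pattern (one below
  50 mol %, two plus shoulder at and above); `analyze_series()` accepts
  any plan function.

## Limitations

* No instrumental smearing or polydispersity; exponents close to $q$-window
  edges are weakly constrained.
* The piecewise model's derivative is continuous only to first order at
  $q_1$; fits that pin $q_1$ exactly on a data point can show tiny
  residual kinks.
* Correlation-length fits assume the window excludes Bragg-like
  features; no automatic model switching is attempted (the gel-regime
  model is invoked explicitly, mirroring practice).
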