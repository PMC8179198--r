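---
title: "The widened pipe model: methods and design notes"
author: "widenedpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The widened pipe model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(widenedpipe)
library(dplyr)
```

## The model

Water moving from roots to leaves travels almost its whole path inside xylem
conduits — vessels in most flowering plants, tracheids in most gymnosperms,
hydroids in mosses. Conduits widen from the stem tip toward the base, and the
*form* of that widening is the object this package models.

Write $\sigma(h)$ for the conduit lumen cross-sectional area at distance $h$
from the stem tip, $h_M$ for plant height, and $h_0$ for the length of a
single conductive unit (the lower cutoff below which a continuum profile is
meaningless). Two selection pressures pull the profile in opposite
directions:

* **Hydraulic resistance.** Under laminar (Hagen–Poiseuille) flow the
  resistance of the whole path is, up to the viscosity and the circular
  cross-section factor, the purely geometric *rescaled resistance*
  $$\Omega = \int_{h_0}^{h_M} \frac{dh}{\sigma^2(h)}.$$
  Rapid widening lowers $\Omega$.
* **Widening cost.** Fast tip-to-base widening means wide conduits, which
  embolize more easily and cost more carbon to build and maintain. The
  penalty is taken as the first non-trivial term of an expansion in the
  widening rate,
  $$W = \int_{h_0}^{h_M} \dot\sigma^2(h)\, dh,$$
  with the quadratic coefficient absorbed into the trade-off weight.

Pareto-optimal profiles minimize $\Omega + \lambda W$, i.e. the functional
with Lagrangian $L = \sigma^{-2} + (\alpha/2)\dot\sigma^2$, where
$\alpha > 0$ encodes the relative weighting. The Euler–Lagrange equation is
$\alpha\ddot\sigma = -2/\sigma^3$, and its stationary profile with basal area
$\sigma_M$ is the closed form implemented in `universal_curve()`:
$$\sigma(h) = \sigma_M\, F(h/h_M), \qquad F(x) = \sqrt{x\,(2 - x)}.$$

Three consequences give the model its empirical teeth:

1. Near the tip $F(x) \approx \sqrt{2x}$, so conduit *diameter* grows as
   $h^{0.25}$ — pure power-law widening, but only near the tip.
2. At the base the area profile falls $1 - 1/\sqrt{2} \approx 29.3\%$ below
   the tip-matched power law: measurable curvature in normalized data.
3. After rescaling by $(\sigma_M, h_M)$ the curve has *no free parameters*
   and in particular does not depend on $\lambda$: every plant should
   collapse onto the same line.

```{r universal}
universal_curve(c(0.1, 0.5, 1))
```

## Verifying the closed form variationally

The closed form is verified rather than trusted: `solve_euler_lagrange()`
solves the boundary-value problem by damped Newton iteration on a
finite-difference mesh, and `minimize_functional_direct()` minimizes the
trapezoid-discretized functional over all interior node values with a
quasi-Newton optimizer followed by a Newton polish of the stationarity
system. The two routes share nothing but the mesh, and both must land on
$\sigma_M F(h/h_M)$; `check_local_minimum()` additionally certifies that
random 1% perturbations never lower the discretized objective.

```{r variational}
wp <- wpm_problem(sigma_M = 1, h_M = 1, h_0 = 1e-3)
sol <- solve_euler_lagrange(wp)
max(abs(sol$sigma / universal_curve(sol$h) - 1))
```

Two numerical choices matter here:

* **Mesh.** The solution behaves as $\sqrt{h}$ near the tip, with unbounded
  curvature, so the default mesh is uniform in $\sqrt{h}$ (1001 nodes).
  This reaches ~1e-5 relative accuracy where an equally spaced mesh of the
  same size reaches only ~5e-3; an equally spaced mesh remains available via
  `mesh = "uniform"`.
* **Lower boundary.** The profile closes ($\sigma \to 0$) at $h = 0$, where
  the $1/\sigma^2$ term is singular. The problem is therefore anchored at
  the physical cutoff $h_0$, with boundary value taken from the profile
  itself; this treatment of the tip is a reconstruction, chosen because
  $h_0$ is the model's own lower cutoff.
* **Convergence.** The Euler–Lagrange residual must fall below $10^{-8}$ in
  scaled units; for extreme trade-off weights the stencil's double-precision
  round-off floor is detected and reported rather than iterated against.
  Non-convergence always sets a flag and raises a warning — never silent.

## Fitting field data

A measured profile is a short series (typically 14–20 heights) of mean
conduit diameters, sampled densely near the apex — every centimetre for the
first 10 cm, then 20, 30, 60, 120, 240, 480, 960 cm and doubling — plus the
base. Diameters are converted to areas ($\sigma = \pi D^2/4$) at ingestion
(`read_profiles()`), and all fitting happens in area space because the
universal prediction is for cross-sectional area.

Each candidate widening model has exactly one free amplitude $z$:

| model | normalized shape |
|---|---|
| `uniform` | $1$ |
| `sqrt_west` | $\sqrt{x}$ |
| `linear_savage` | $x$ |
| `wpm` | $F(x)$ |
| `wpm_avg_anchor` | $F(x)$, amplitude fixed to the mean of the two basal-most points |

`fit_plant()` minimizes the unweighted sum of squared area residuals. The
models are linear in $z$, but the fit is run as a general one-parameter
optimization anyway — a gradient-based optimizer from five starting values
spanning 0.25–4 times the basal-most measured area, cross-checked by a
derivative-free golden-section search — so the machinery carries over
unchanged to any non-linear profile variant; a fit is accepted only when the
two optimizers agree to $10^{-4}$ relative. Plants with fewer than three
points, or no agreeing optimum, are flagged failed and excluded downstream
with a warning.

Pooling and comparison follow the per-model normalization convention: each
model normalizes each plant by *its own* fitted amplitude, the pooled cloud
is reduced to 15 equally populated bins (`bin_equal_population()`;
remainder points go to the highest-$x$ bins, a fixed arbitrary tie rule),
and the agreement statistic is
$$\chi^2 = \sum_{b=1}^{15}\left(\frac{\bar y_b - g(\bar x_b)}{s_b}\right)^2,$$
with $s_b$ the per-bin SD of the pooled points (`chi_square_model()`).

Two conventions here were genuinely open and are worth stating:

* **Weights.** SD, not SEM, of the pooled points per bin. With on the order
  of a hundred points per bin, SD-weighting puts $\chi^2$ for a correct
  model in the 0.1–0.5 range while badly wrong models land in the tens to
  thousands; SEM-weighting would rescale everything by the bin population.
  The SD choice is the one consistent with the magnitudes this statistic is
  expected to take for a correct model, and is isolated in one function
  should a different convention be needed.
* **p-value tail.** `p` is the lower-tail CDF $P(X \le \chi^2)$ with
  `dof = 15` (the bin count; amplitudes are fitted per plant before pooling,
  so no parameter-count correction is applied). Under this convention a
  small $p$ accompanies a *good* fit — the bin means sit far inside the
  scatter — and $p \approx 1$ flags a model outside it. An upper-tail
  convention cannot reproduce that pattern.
* **Binning axis.** Bins are equally populated in $x$; since membership is
  invariant under monotone transforms, only the bin-centre definition
  depends on this, and the untransformed mean $x$ is used. The $\sqrt{x}$
  stretch (`axis_transform()`) is display-only.

## Cost accounting and the Pareto front

With per-plant fitted $\sigma_M$ (widened-pipe) and $A$ (pure power law
$\sigma = A\sqrt{h/h_M}$), `summarize_costs()` evaluates closed forms for
the rescaled resistances
$$\Omega_{PL} = \frac{h_M}{A^2}\ln\frac{h_M}{h_0}, \qquad
  \Omega_{WPM} = \frac{h_M}{2\sigma_M^2}\ln\frac{2h_M - h_0}{h_0},$$
their reciprocal conductances, the widening cost, and the carbon cost
$C = 2\sqrt{\pi}\int \sqrt{\sigma}\,dh$ — the wall surface area per unit
wall thickness (a constant wall thickness contributes only a
proportionality factor and is set to one). The power-law carbon cost has
the closed form $\tfrac{8}{5} h_M \sqrt{\pi A}\,(1 - (h_0/h_M)^{5/4})$; the
widened-pipe branch has no elementary antiderivative and is evaluated by
adaptive quadrature. Every closed form in the package is tested against
adaptive quadrature of its defining integrand across a parameter sweep
before being relied on.

Cohort-level results follow directly:

* `conductance_height_regression()` — OLS of $\ln \mathrm{Cond}_{WPM}$ on
  $\ln h_M$; near-zero slope is the height-invariance of water supply.
* `carbon_matched_conductance_gain()` — through-origin cross-plot slopes.
  The "slope" of a conductance cross-plot is not uniquely defined by a
  scatter of paired points, so both the through-origin OLS slope
  ($\sum xy/\sum x^2$, the primary statistic) and the geometric-mean slope
  ($\sqrt{\sum y^2/\sum x^2}$) are reported. The analytic benchmark
  `analytic_conductance_gain()` fixes $A$ by exact carbon matching and
  gives $\approx 1.3$–$1.4$ for realistic cutoff ratios, approaching
  $2\,(4/(5 I_0))^4 \approx 1.40$ ($I_0 = \int_0^1 (t(2-t))^{1/4} dt$) as
  $h_0/h_M \to 0$.
* `pareto_front()` — per-plant $(\ln W, \ln\Omega)$ points. For optimal
  profiles the product $\Omega\, W$ depends only on $\varepsilon = h_0/h_M$
  (verified numerically across decades of $\sigma_M$ and $h_M$ before being
  used), so fronts are the lines $\ln\Omega = -\ln W + J(\varepsilon)$ with
  the slowly varying intercept `pareto_J()`. A plant is classified
  `"optimal"` when no other plant beats it on both axes simultaneously;
  whether the published front's additive constant matches `pareto_J()`
  exactly cannot be checked from the main-text material, so $J$ is asserted
  only through its near-constancy (about 1.5–3.7 over the empirical
  cutoff range).

## The synthetic cohort generator

`generate_cohort()` exists so the entire pipeline is testable without the
original trait dataset. It emulates the *statistical structure* the analysis
assumes, with defaults fixed once to the study conditions:

* 103 plants, heights log-uniform between 1 m and 110 m (the span from the
  smallest shrubs to the tallest redwoods), sampled at the field protocol
  heights above;
* conduit types in proportions 0.85 vessel / 0.14 tracheid / 0.01 hydroid,
  with cutoffs $h_0$ = 400 µm (vessels, hydroids) and 4000 µm (tracheids);
* basal amplitude law $\sigma_M = c\, h_M^{1/2}$ with $c$ = 1.5, 0.5 and
  0.15 µm^(3/2) for vessels, tracheids and hydroids. The square-root
  exponent makes tip diameters shared across plants (the same $h^{0.25}$
  law near every apex) and renders conductance height-invariant up to a
  logarithm — the pattern the real cohort shows; it also places tracheid
  plants at high resistance / low widening cost and vessel plants at the
  opposite corner of the front. The narrower coefficients for tracheids and
  hydroids reflect their systematically narrower lumina.
* measurement noise: each sampled height reports the mean of 25 per-conduit
  diameters drawn lognormally around the true curve with a 20% coefficient
  of variation — the averaging-of-25 protocol with a typical anatomical
  spread. The noise model (lognormal, multiplicative, independent across
  conduits) is the package's own choice; the field protocol specifies only
  the averaging.
* leaf-measured plants (10% by default) are generated identically to stems
  and differ only in metadata, mirroring how large-leaved plants substitute
  leaves for sheddable twigs.

What the generator deliberately does **not** emulate: phylogenetic
covariance among species, organ-specific widening differences, within-plant
serial correlation of measurement error, and real anatomical departures
from the generating curve. Green pipeline tests on synthetic cohorts
therefore demonstrate statistical correctness of the machinery — parameter
recovery, model identifiability, the direction of every comparative result
— not empirical validity of the model, which only field data can supply.

## Problem sizes used in the test suite

Simulation-backed tests use cohorts of 30–103 plants; the amplitude-recovery
check uses 200 single plants at the default noise; model-selection stability
uses 50 replicate cohorts of 40 plants. Variational checks run on 201–401
node meshes spanning trade-off weights over more than four decades. These
sizes put every Monte-Carlo assertion comfortably away from its threshold
while keeping the default suite around a minute.

## Known limitations

* Interconduit pit membranes, conduit branching/network geometry and
  temperature-dependent sap viscosity are outside the model, as is any
  term beyond the quadratic in the widening-cost expansion.
* The $h_0$-anchored treatment of the singular tip boundary is a
  reconstruction; alternatives (e.g. regularized $\sigma(0) > 0$) would
  perturb the near-tip solution at the cutoff scale.
* $\chi^2$ weighting and the front intercept $J$ involve conventions
  documented above; both are isolated behind single functions and flagged
  as revisitable.
* The uniform pipe has zero widening cost, so it sits at $\ln W = -\infty$;
  Pareto analysis is restricted to widening profiles.
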