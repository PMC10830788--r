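---
title: "Methods: Turing patterns on a sphere with a bud-scar hole"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Turing patterns on a sphere with a bud-scar hole}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turingcap)
```

## The model

During cell division in budding yeast, activated Cdc42 accumulates at a
single spot ("pole") on the cell membrane, and the bud grows there. Each
division leaves a bud scar, a circular membrane region that Cdc42 cannot
enter. `turingcap` studies whether diffusion-driven (Turing) pattern
formation — the leading mechanistic explanation of polarisation — is robust
to such scars, by modelling the membrane as the unit sphere with a geodesic
disc of radius $\varepsilon$ removed (the cap $\Omega_\varepsilon$, hole
centred at the South Pole) and solving the dimensionless Schnakenberg system

$$
u_t = \Delta u + \gamma\,(a - u + u^2 v), \qquad
v_t = d\,\Delta v + \gamma\,(b - u^2 v),
$$

with homogeneous Neumann (no-flux) conditions on the hole rim: no protein
crosses into the scar. Here $u$ is the activator (activated Cdc42), $v$ the
inhibitor, $\Delta$ the Laplace–Beltrami operator, $d$ the inhibitor/
activator diffusion ratio and $\gamma$ a reaction strength that scales with
the squared cell radius. Throughout, $(a, b) = (0.20, 1.00)$, giving the
homogeneous steady state $u_0 = a + b = 1.2$, $v_0 = b/(a+b)^2 \approx 0.69$.

## Linear stability and mode selection

Diffusion-driven instability requires the four classical inequalities
(checked by `turing_conditions()`): stability without diffusion
($f_u + g_v < 0$, $\det A > 0$) plus destabilisation by diffusion
($d f_u + g_v > 0$ and a positive dispersion discriminant). A
Laplace–Beltrami eigenvalue $\lambda$ feeds the pattern iff

$$
\gamma L < \lambda < \gamma M, \qquad
L, M = \frac{d f_u + g_v \mp \sqrt{(d f_u + g_v)^2 - 4 d \det A}}{2d}.
$$

On the sphere $\lambda_n = n(n+1)$ with multiplicity $2n+1$. The critical
diffusion `critical_diffusion()` makes the interval degenerate; at
$(a,b) = (0.20, 1.00)$, $d_c \approx 17.01$. The reaction strength that
parks $n(n+1)$ exactly at that degenerate point is

$$
\gamma_c(n) = \frac{2 d_c\, n(n+1)}{d_c f_u + g_v},
$$

giving 6.87, 20.62, 41.24, 68.73 for $n = 1,\dots,4$. Some sources print
this formula with $n^2(n+1)^2$ in the numerator, which does **not**
reproduce those tabulated values; `critical_gamma()` therefore defaults to
the $n(n+1)$ form and exposes the other variant behind `as_printed = TRUE`.

### Perturbed eigenvalues of the punctured sphere

For a small hole the Neumann eigenvalues move continuously:
$\lambda_n^m(\varepsilon) \to n(n+1)$ as $\varepsilon \to 0$. We use the
leading-order expansions

$$
\lambda_n^0(\varepsilon) = n(n+1) + (2n+1)\tfrac{n(n+1)}{4}\,\varepsilon^2,
\qquad
\lambda_n^m(\varepsilon) = n(n+1) - (2n+1)\, c_n^m\, \varepsilon^{2m},
\quad
c_n^m = \frac{(m+n)!}{4^m\, m!\, (m-1)!\, (n-m)!}.
$$

The zonal ($m = 0$) coefficient is printed in parts of the literature as
$4/(n(n+1))$. We validated both variants against the package's own discrete
Laplace–Beltrami eigensolver on cap meshes (resolution 0.075,
$\varepsilon \in \{0.1, 0.2\}$, degrees 1–3): the discrete shifts match
$n(n+1)/4$ within 10–30% (the residual consistent with the dropped
higher-order terms), while the reciprocal form is off by factors of 4–7 and
does not even scale correctly across degrees. The $m \ge 1$ formula verifies
as printed. The package therefore defaults to the $n(n+1)/4$ zonal
coefficient; `as_printed = TRUE` gives the reciprocal variant. The sign
structure — zonal branch up, all others down — and hence every qualitative
robustness conclusion is identical under either choice.

These expansions are truncated at leading order and are quantitative only
for small $\varepsilon$; for $\varepsilon \gtrsim 0.3$ they are indicative
only, which is why the discrete eigensolver (`lb_eigenpairs()`) is kept as
the reference.

## Discretisation

**Meshes.** `cap_mesh(epsilon, resolution)` builds a deterministic
latitude-band triangulation: vertices on colatitude rings spaced
`resolution` apart, per-ring counts proportional to the circumference,
adjacent rings stitched by an angular merge, and the rim ring placed exactly
on $z = -\cos\varepsilon$ (at least 8 rim vertices even for the smallest
holes). The flat-triangle area converges to the exact cap area
$2\pi(1 + \cos\varepsilon)$ at $O(h^2)$. The full sphere at the default
resolution 0.05 has roughly 5,000 vertices. Determinism means an
(epsilon, resolution) pair always yields bitwise-identical meshes.

**Space.** Continuous piecewise-linear (cG(1)) finite elements on the flat
triangles; consistent mass matrix $M$ and stiffness $K$ with in-plane
surface gradients. Neumann conditions are natural: no boundary rows are
touched, and $K\mathbf{1} = 0$ holds to round-off.

**Time.** The first-order semi-implicit backward-Euler scheme: backward
Euler with the reaction nonlinearities frozen at the previous step,
$f \to a - u_i + u_i u_{i-1} v_{i-1}$ and $g \to b - u_{i-1}^2 v_i$. Each
step then solves two *decoupled* sparse SPD systems,

$$
\bigl[(1 + k\gamma) M + k K - k\gamma M_{w}\bigr] u_i
  = M u_{i-1} + k\gamma a\, M\mathbf{1},
\qquad
\bigl[M + k d K + k\gamma M_{w_2}\bigr] v_i
  = M v_{i-1} + k\gamma b\, M\mathbf{1},
$$

where $M_w$ is the consistent mass weighted by the cG(1) interpolant of
$w = u_{i-1} v_{i-1}$ (and $w_2 = u_{i-1}^2$), assembled from the exact
$\int \phi_i \phi_j \phi_k$ triple products. A row-sum mass-lumped variant
is available (`lumped = TRUE`) for speed; all reported results use the
consistent default. The homogeneous steady state is an exact fixed point of
the step. Matrices are refactorised every step with a reused symbolic
Cholesky analysis. Step sizes follow the reference study: $k = 0.01$ for
modes 1–2, $k = 0.005$ for modes 3–4; larger steps (e.g. $k = 0.02$ at
$\gamma = 20.62$) visibly delay pattern onset through the scheme's numerical
damping, so they are not used.

**Initial conditions.** Independent uniform perturbations on
$[-10^{-4}, 10^{-4})$ around $(u_0, v_0)$ at every node, activator drawn
before inhibitor in node-index order under one seed per run, so replicates
are portable. Whether the two species' perturbations were independent in the
reference study is not stated; independence is assumed here.

**Eigensolver.** `lb_eigenpairs()` solves $K x = \lambda M x$ by
shift-invert ARPACK (through igraph) with a Rayleigh–Ritz cleanup, or
densely below ~900 nodes; the two paths agree to $10^{-9}$ on shared
problems. Discrete sphere eigenvalues converge to $n(n+1)$ from above at
$O(h^2)$ (about 0.2% error for $\lambda = 2$ at resolution 0.075).

## Pattern characterisation

**Harmonic projection.** `project_harmonics()` computes
$U_n^m = \int_{\Omega_\varepsilon} u\, Y_n^m\, dx$ with the mesh quadrature
(cG(1) interpolation of $uY$, then the consistent mass), using orthonormal
real harmonics without the Condon–Shortley phase, and a $1/\sqrt{2}$ factor
for $m > 0$ (the real-part-of-complex-harmonics convention, under which
$Y_n^{-m} = Y_n^m$). A constant field $u_0 = 1.2$ on the full sphere gives
$U_0^0 = 1.2 \cdot 2\sqrt{\pi} \approx 4.25$. On the punctured sphere the
basis is not orthonormal over the domain; coefficients at large
$\varepsilon$ should be read with that caveat.

**Poles.** Nodes with $u \ge 0.95\, u_{\max}$ (threshold configurable; 0.95
is a calibration against visual counting, not a derived constant) are
clustered by DBSCAN on their 3D coordinates. No DBSCAN implementation ships
with the available R stack, so the package carries a small standard one
(min_samples counts the point itself). Defaults — neighbourhood radius 2.5×
the maximum edge length, minimum cluster size 3 — were calibrated on
synthetic Gaussian bump fields, where the returned count equals the number
of constructed bumps. If DBSCAN labels everything noise (possible only for
very few qualifying nodes) the $\epsilon$-connectivity components are used,
so a detected maximum always yields at least one pole. The pole-area
fraction attributes one third of each incident triangle's area to a
qualifying node — the standard vertex-area rule; the reference study does
not specify its apportionment. Pole-to-hole distance is the great-circle
distance from the hole *centre* $(0,0,-1)$ to the nearest clustered node,
and is undefined (`NA`) on the closed sphere.

## Ensembles and statistics

`run_ensemble()` executes the factorial design (parameter sets × radii ×
repetitions) with per-run seeds derived by a stated integer hash of the base
seed and cell indices, so any sub-design reproduces independently. Failures
are logged and excluded, never imputed. The full reference design is 4 modes
× 15 radii (0 to 0.70 in steps of 0.05 — an assumption, the radii are not
listed in the source) × 20 repetitions = 1200 runs. Percentiles use linear
interpolation between order statistics (`quantile` type 7); the convention
is a documented choice. The trend test (`slope_test()`) averages repetitions
per radius first and then regresses the cell means on the radius, with a
two-sided t test on the slope at level 0.05 — regressing on pooled rows
would pretend to more degrees of freedom than the design has. The
hole-distance metric is undefined at $\varepsilon = 0$; that cell is dropped
from its regression.

## Problem sizes used by the tests and the acceptance script

The shipped checks run a scaled-down version of the study, chosen by
convergence experiments rather than by the full 1200-run design:

* mode-2 sphere runs use resolution 0.075 (~2,240 vertices). A convergence
  study of the final maximum ($u_{\max}$ 1.757 at $h = 0.15$, 1.753 at
  $h = 0.1$, 1.749 at $h = 0.075$, seed fixed) shows the extremes are
  mesh-converged to well under 1% there;
* mode-1 robustness runs use resolution 0.15 over radii
  $\{0, 0.2, 0.4, 0.6\}$ with 5 seeds each (pole counts and area fractions
  are stable from $h = 0.15$ to $h = 0.075$);
* eigenvalue checks use resolutions 0.15 and 0.075;
* 5 seeds per condition, medians reported.

Consequently the stochastic envelopes (5th/95th percentiles over 20
repetitions) of the full design are *not* reproduced by the tests; medians
and invariants are.

## What the synthetic data do and do not emulate

The mesh generator and the seeded uniform initial perturbations are the
package's synthetic data; they emulate the reference setup (unit sphere,
single South-Pole hole, $10^{-4}$ uniform noise). They do not emulate real
membranes: no geometry irregularity, no multiple scars, no spatially varying
kinetics, no stochastic reaction noise during the dynamics. Passing tests
therefore validate the numerical method and the robustness conclusion for
the idealised model, not Cdc42 biology.

## Known limitations

* Flat (non-isoparametric) boundary elements: the rim is a polygon through
  the exact circle, so boundary quadrature carries an $O(h^2)$ geometric
  error absorbed in the reported tolerances.
* The perturbation expansions are leading-order only; no claim is made for
  large holes.
* Projection onto full-sphere harmonics on a punctured domain is a
  deliberate, documented approximation.
* No adaptive time stepping; step sizes are fixed per mode.
* The hole is fixed at the South Pole; arbitrary hole positions (equivalent
  by symmetry) and multiple holes are out of scope.

## A worked check

```{r theory}
critical_diffusion(0.2, 1)
critical_gamma(1:4, 0.2, 1)
excited_modes(schnak_params(0.2, 1, 20.62, 18), epsilon = 0.1, n_max = 4)
```

```{r sim, eval = FALSE}
# a full desk-scale replicate (about half a minute)
mesh <- cap_mesh(epsilon = 0.2, resolution = 0.15)
sim <- simulate_schnakenberg(mesh, schnak_params(0.2, 1, 20.62, 18),
                             T_final = 50, k = 0.01, seed = 1)
pattern_metrics(sim$state, mesh)
```
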