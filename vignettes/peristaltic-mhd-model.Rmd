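---
title: "Peristaltic MHD Jeffrey-fluid transport: model, numerics and design choices"
author: "peristMHD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peristaltic MHD Jeffrey-fluid transport: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peristMHD)
```

## The physical problem

Peristalsis — transport of a fluid by a progressive wave of contraction along
a flexible channel wall — drives flow in the esophagus, intestine, ureter and
many biomedical pumping devices. `peristMHD` implements a closed-form model
of this process for a Jeffrey-type viscoelastic fluid in a two-dimensional
symmetric channel that is inclined at angle $\alpha$ to the horizontal,
permeated by a magnetic field of strength expressed through the Hartmann
number $M$ and inclined at angle $\beta$, and subject to a volumetric heat
source or sink together with thermal buoyancy.

In the frame moving with the wave the wall is stationary,
$$h(x) = 1 + \varepsilon\sin(2\pi x),$$
with $\varepsilon \in [0, 1)$ the amplitude ratio (occlusion).  All lengths
are scaled by the mean half-width, velocities by the wave speed, so the model
is fully described by the nine dimensionless numbers held in a
`flowParams()` object.

## The reduced system and its exact solution

Under the lubrication approximation (long wavelength $\delta = a/\lambda \to
0$, low Reynolds number) the momentum and energy balances collapse to a pair
of one-way-coupled ODEs in the cross-stream coordinate $y$ at each axial
station $x$:

$$\theta'' + \eta\,Br^2\,\theta = 0, \qquad \theta(0) = 0,\ \theta(h) = 1,$$
$$u'' - a_1 u = a_1 - c_I - a_2\theta, \qquad u(0) = 0,\ u(h) = -1,$$

with
$a_1 = M^2(1+\lambda_1)\cos^2\beta$ (effective magnetic group; note the
$\cos^2\beta$ modulation by the field inclination),
$a_2 = c_2(1+\lambda_1)$ (effective buoyancy group), and the forcing
constant $c_I = (1+\lambda_1)\bigl(c_1\sin\alpha - dp/dx\bigr)$, which
collects gravity and the pressure gradient.  The energy equation decouples
from $u$: it is solved first and feeds the momentum equation as a source.
The wave-frame boundary values ($u = -1$ at the wall, $u = 0$ and $\theta = 0$
on the centreline) are the ones the model prescribes and are reproduced
exactly by construction.

The temperature solution is
$\theta = \sin(Br\,y\sqrt{\eta}) / \sin(Br\,h\sqrt{\eta})$ and the velocity
adds a hyperbolic homogeneous pair and a buoyancy particular term
$a_2\theta/(a_1 + Br^2\eta)$.  The homogeneous coefficients are obtained by
solving the $2\times 2$ boundary system directly rather than transcribing
printed constants; a test verifies that the two agree in the regime where the
printed exponential form is representable.

Shear stress is the analytic derivative,
$S_{xy} = u'(y)/(1+\lambda_1)$ — the Jeffrey ratio $\lambda_1$ acts both
through this prefactor and inside $a_1$, $a_2$, $c_I$.

## Pumping characteristics

The wave-frame flow rate $F = \int_0^h u\,dy$ is affine in $dp/dx$, so
prescribing $F$ determines the pressure gradient by a two-point linear solve
(`solveDpdx()`), exact to rounding.  The per-wavelength pressure rise and
friction force are
$$\Delta p_\lambda = \int_0^{2\pi} \frac{dp}{dx}\,dx, \qquad
  F_\lambda = \int_0^{2\pi} -h^2 \frac{dp}{dx}\,dx,$$
computed by composite Gauss–Legendre quadrature (16 nodes per panel, panel
count doubled until successive estimates differ by less than $10^{-9}$).
The $[0, 2\pi]$ window is the model's printed convention even though $h$ has
period 1; a one-wavelength window (`window = "one"`) is provided, and for a
straight channel the two differ exactly by the factor $2\pi$.

The model's printed closed-form expression for $dp/dx$ is *implicit* (its
right side contains constants that themselves depend on $dp/dx$) and, when
evaluated by fixed-point iteration, does not coincide with the
flux-condition gradient; `pumpingDiscrepancy()` documents the difference
rather than silently preferring one route.  The flux condition is the
product path throughout: it is the only route whose meaning is unambiguous.

## Stream function and trapping

$\Psi(x,y) = \int_0^y u\,dy'$ in closed form, with $\Psi = 0$ on the
centreline and $\Psi = F$ on the wall (both walls are streamlines in the
wave frame — an invariant the tests enforce to $10^{-8}$).  Trapped boluses
are closed streamline families; `detectBoluses()` makes that operational:

* contours of $\Psi$ at 41 evenly spaced levels between the grid minimum and
  maximum (marching squares on a boundary-fitted $(x, y/h)$ grid — a
  homeomorphism of the channel, so closedness is unchanged);
* closed contours touching neither wall, grouped into nested families;
* one bolus per outermost contour, area by the shoelace formula in physical
  coordinates.

The grid spans two periods and outermost contours with centroid in
$[0.5, 1.5)$ are kept (centroid reported mod 1), which handles contours
crossing the periodic seam without split-contour bookkeeping.  The default
resolution is $129 \times 129$ nodes per period; halving the node spacing
changes reported areas by less than 1 %.

## The finite-difference oracle

`fdSolve()` re-solves the reduced system with second-order central
differences on a uniform grid — temperature first (tridiagonal), then
momentum with the discrete temperature as source — sharing *no* algebra with
the closed forms (no exponentials, no cosecants, no printed constants).
`verifyClosedForm()` reports max-abs discrepancies for $u$, $\theta$,
$S_{xy}$ and the flux at $n = 4001$ nodes; the observed convergence order is
$2.0 \pm 0.2$, and the scheme is exact for the quadratic lubrication limit
($M = 0$, $\eta = 0$, $c_2 = 0$), which the tests exploit as a closed-book
cross-check.  Near-singular temperature systems are detected through a
1-norm condition estimate.

## Parameters, defaults and admissibility

| parameter | meaning | default | admissible |
|---|---|---|---|
| `eps` | wall occlusion | 0.5 | $[0, 1)$ |
| `M` | Hartmann number | 2 | $\ge 0$ |
| `beta` | field inclination (rad) | $\pi/6$ | $(-\pi/2, \pi/2)$ |
| `alpha` | channel inclination (rad) | $\pi/4$ | $[0, \pi/2]$ |
| `lambda1` | Jeffrey time ratio | 0.5 | $\ge 0$ |
| `Br` | Brinkman number | 2 | $> 0$ |
| `eta` | heat source/sink | 0.5 | $\ge 0$ |
| `c1` | gravity group | 1 | $\ge 0$ |
| `c2` | buoyancy group | 1 | any sign |

These defaults are this package's choice of a representative configuration:
each sits inside the ranges the standard parameter studies sweep.  Angles
are radians everywhere in the API; the CLI and config reader accept degrees
behind an explicit flag, to avoid unit ambiguity.

**Resonance guard.**  The temperature form is singular where
$Br\,h\sqrt{\eta} = k\pi$; validation rejects configurations with
$Br\,(1+\varepsilon)\sqrt{\eta} \ge \pi$ with a diagnostic naming the
condition.  One visible consequence: a Brinkman sweep up to $Br = 7$ is
admissible only for small $\eta$, so the standard Brinkman bolus study
(`bolusStudy("Br")`) runs at $\eta = 0.05$, which keeps $Br = 7$ inside the
guard.

**Degenerate limits.**  Two limit paths replace numerically unstable
branches: for $(Br\,h\sqrt\eta)^2 < 10^{-10}$ the temperature uses
$\theta = y/h$ (the cosecant form loses all precision there), and for
$a_1 < 10^{-8}$ (e.g. $M = 0$) the velocity's $c_I/a_1$ form is replaced by
the analytic $a_1 \to 0$ buoyant-lubrication solution — an error by default,
enabled with `degenerate = "limit"` so that degeneracy is never silent.
For large $M(1+\varepsilon)$ the homogeneous pair is evaluated in a
wall-anchored decaying-exponential (hyperbolic) basis, so nothing overflows
at Hartmann numbers far beyond the studied range.

## Documented study conditions

Two conditions of the parameter studies were genuinely open and are fixed
here once, with reasons:

* **Velocity-profile studies run at fixed $dp/dx = -1$** (a favourable
  gradient, $dp/dx < c_1\sin\alpha$, i.e. net forward forcing).  The
  characteristic profile shapes and trends of the reported studies — in
  particular the increase of $u$ with $\lambda_1$ — belong to this regime:
  $\lambda_1$ multiplies the forcing constant $c_I$, so its effect follows
  the sign of the net forcing, and an adverse gradient reverses it.
* **Bolus studies run at fixed $F = 0$** (laboratory-frame mean flow equal
  to the wave speed, the classic trapping condition).  Closed streamlines
  exist only for $F \gtrsim -0.2$ at the default geometry; at the pumping
  default $F = -0.4$ the stream function is monotone across the channel and
  no trapping occurs at all.

The pumping studies use the package default $F = -0.4$.

## Known limitations

* The model resolves the *reduced* system only; $\delta$- and Re-scaled
  terms (including viscous dissipation in the energy balance and the full
  viscoelastic stress) are outside its validity envelope, so nothing here
  should be read as a finite-wavelength or inertial prediction.
* The centreline conditions $u = 0$, $\theta = 0$ are the model's printed
  boundary conditions and are implemented as such; they differ from the
  symmetry conditions ($u' = 0$, $\theta' = 0$) a half-channel argument
  would suggest, so field shapes near $y = 0$ reflect that choice.
* At fixed flow rate the flux condition pins $c_I$ independently of
  $\alpha$ and $c_1$, which forces
  $\partial \Delta p_\lambda/\partial \alpha = 2\pi c_1 \cos\alpha \ge 0$
  and $\partial \Delta p_\lambda/\partial c_1 = 2\pi\sin\alpha \ge 0$
  identically: within this model the pressure rise cannot decrease
  algebraically with channel inclination or the gravity group at fixed $F$.
  Reported decreases of that kind can only be magnitude statements in
  co-pumping regimes ($\Delta p_\lambda < 0$).
* Bolus areas are contour-ladder quantities: they depend (weakly, < 1 % at
  the default resolution) on grid and level choices, which is why the level
  ladder and resolution are fixed and recorded in every sweep.

## A worked verification

```{r verify}
p <- defaultParams()
verifyClosedForm(p, dpdx = 1, x = 0, n = 2001)
```

```{r pumping}
pumpingCurve(c(-0.6, -0.4, -0.2), p)
```

```{r bolus}
bolusStudy("M", p, nx = 65, ny = 65)
```
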