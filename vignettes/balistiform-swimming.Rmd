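---
title: "Balistiform swimming and the caudal-fin opening angle: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Balistiform swimming and the caudal-fin opening angle: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finprop)
```

## The question

The filefish *Rudarius ercodes* swims balistiform: thrust comes from
traveling waves passed along the dorsal and anal fins while the body stays
rigid. Tank observations show the fish folding its caudal fin shut when it
accelerates in a straight line and spreading it open while hovering or
cruising. `finprop` packages the machinery needed to study that trade-off:
a parametric swimmer geometry with a configurable caudal opening angle
$\varphi$, the fin-wave kinematics, a self-propelled flow simulation, the
hydrodynamic performance statistics used in fish energetics, and a
velocimetry module for markerless-tracking exports. Everything is testable
against synthetic data with closed-form ground truth.

The reference animal is a 57 mm fish (model box 57 x 7 x 40 mm, mass
2.6 g) in artificial seawater at 24 °C ($\rho$ = 1023.6881 kg/m³,
$\nu$ = 9.5818e-7 m²/s). Observed caudal presets are 5° ("closed") and
100° ("full-open"); 30° and 60° are interpolating model cases. Slow and
fast gaits correspond to fin frequencies of about 10 and 29 Hz around an
observed average of 14 Hz.

## Fin kinematics

A fin ray at station $x$ rotates about the fin base line by

$$\theta(x,t) = \beta(t)\,\theta_{\max}\sin\!\big(2\pi(x/\lambda + f t)\big),$$

with $\beta$ a startup ramp active during the first cycle. A point at
height $z$ above the base line maps to

$$y' = z\sin\theta + y,\qquad
\Delta z = 2z\cos\!\Big(\frac{\pi-\theta}{2}\Big)\sin\frac{\theta}{2},\qquad
z' = z - \Delta z,$$

which is algebraically $z' = z\cos\theta$, so the fin-ray length is
preserved exactly: $(y'-y)^2 + z'^2 = z^2$. This identity is enforced to
1e-12 relative in the tests.

Two details deserve comment.

**The startup ramp.** The published quartic
$\beta = ((t-T)^4 + T^4)/T^4$ equals 2 at $t=0$ and falls to 1 at $t=T$:
it *doubles* the first-cycle excursion, the opposite of its stated purpose
of protecting the startup. Both behaviours are shipped:
`ramp_mode = "as_printed"` reproduces the formula verbatim (and the tests
document $\beta(0)=2$), while the default `"monotone"`,
$\beta = 1-((T-t)/T)^4$, rises smoothly from rest and is used by all
swimming runs.

**Wave direction.** With the phase $2\pi(x/\lambda + ft)$ and the head at
$x=0$, crests travel toward the head; the described physics (median-fin
wake convecting over the caudal fin, waves traveling tailward) requires
the opposite sense. `fin_angle()` keeps the printed phase and exposes a
`direction` argument; simulations use `direction = -1`, i.e.
$2\pi(x/\lambda - ft)$, so the wave runs head-to-tail and the swimmer
moves head-first.

Amplitude and wavelength are not published. Defaults are
$\theta_{\max} = 30°$ and $\lambda$ equal to the fin-base length (one
wavelength on the fin), both configurable; the observation that amplitude
and wavelength stay fixed across speeds (only $f$ changes) motivates
treating them as constants.

## Geometry and the planar reduction

`build_swimmer_geometry()` composes closed triangulated shells: an
ellipsoidal body, thin dorsal/anal fin slabs reaching the full 40 mm
height, and a caudal fin modeled as two rounded lobes folded symmetrically
about the peduncle axis by $\pm\varphi/2$. Folding leaves the overall
width untouched (the lobes stay inside the 7 mm body width), reproducing
the front-view invariance of the original models. Watertightness (every
edge shared by exactly two triangles), bounding-box fidelity within 1%,
and area convergence under refinement are tested for all four presets.

The flow solver is two-dimensional: it works in the horizontal plane cut
through the fins, where the interaction that matters — the reverse Kármán
street shed by the dorsal fin meeting the caudal fin — lives. In that cut:

* the undulating fin appears as a filament whose lateral displacement is
  $H\sin\theta(x,t)$ with $H$ the fin height at the cut;
* the caudal fin appears as one slender chord when closed, and as **two
  laterally offset shorter chords** when open: a lobe folded by
  $\varphi/2$ meets the cut plane a distance $s = z_{\rm cut}/\cos(\varphi/2)$
  from the axis, at lateral offset $z_{\rm cut}\tan(\varphi/2)$, and the
  rounded lobe outline makes the in-plane chord non-increasing in
  $\varphi$ (`caudal_cut()`, `planar_analogue()`).

Opening the fin therefore turns a streamlined trailing plate into a bluff
pair — the planar signature of the extra vortex shedding that the study
identifies behind the open caudal fin.

For the literal mm-scale mesh these cuts are made wherever requested; for
the solver boundary the lobe span (0.25 L) and cut height (0.1 L) are
desk-scale analogue parameters chosen once so that the four presets remain
distinguishable on the default grid (h = L/32).

## Flow solver

`flow_step()` advances the incompressible Navier-Stokes equations on a
staggered (MAC) grid:

* SSP-RK3 time integration of advection and diffusion; advective fluxes
  either central second-order (default; energy-conserving, used for the
  analytic validations) or QUICK upwind-biased (used for the
  boundary-dominated swimming runs at cell Péclet numbers around 15);
* explicit diffusion — at the target Reynolds numbers the advective CFL
  limit binds two orders of magnitude before the diffusive one, so an
  implicit diffusion solve would buy nothing;
* a direct-forcing immersed boundary: marker velocities are imposed by
  interpolating the predicted field with a 3-point regularized delta
  (Roma kernel), forcing, and spreading back; the reaction gives the
  fluid force on the body. Markers are spaced at 0.5 h;
* an incremental pressure-correction projection: the predictor carries
  the lagged pressure gradient and the Poisson equation is solved for the
  pressure increment — without this the splitting error is first order in
  $\Delta t$ and dominates everything (a fact the Taylor-Green convergence
  test would catch immediately);
* the pressure Poisson equation is solved by geometric multigrid
  (red-black Gauss-Seidel V-cycles) to a relative residual of 1e-10,
  with a conjugate-gradient fallback for grids that do not coarsen.

Channel boundaries: Dirichlet inflow on the upstream face, convective
outflow downstream, free-slip lateral walls (the tank's "free flow-out"
condition is under-specified; these are the conventional choices). A
global mass-balance correction on the outflow face keeps the Neumann
Poisson problem solvable. The domain is 8 L x 4 L (the tank-to-body ratio
is not published; this is comfortably larger than the wake region of
interest).

Validation: Taylor-Green kinetic energy decays as $e^{-4\nu k^2 t}$
within 0.005% at 64² (the acceptance band is 2%), with close to
second-order convergence across 32²/64²/128²; post-projection divergence
stays at the solver tolerance (~1e-12) every step; vorticity and
Q-criterion reproduce closed forms on rigid rotation and planar strain; a
towed cylinder at Re 40 lands in the classical steady-wake drag range
(measured C_d ≈ 1.8 at 16 cells per diameter against the fine-grid value
of ≈1.5 — the regularized delta inflates the effective diameter by about
a cell on each side, and the checked band is 1.2-1.9). Residual slip at
thin-plate markers is a few percent of the free
stream after one forcing iteration and tightens monotonically with more
iterations (the default swimming runs use two); edge markers dominate the
residual.

## Self-propulsion coupling

The body has one degree of freedom (x), mirroring the observation of
minimal lateral motion. Newton's law $m\,du_a/dt = F$ is discretized with
the second-order backward difference

$$\frac{3u_a^{n+1} - 4u_a^n + u_a^{n-1}}{2\Delta t} = \frac{F^{n+1}}{m},$$

exact for linear-in-time velocities and second order otherwise (verified
by Richardson halving on sinusoidal forcing); the undefined history at the
first step is handled with one backward-Euler step. $F^{n+1}$ is implicit:
each step extrapolates $\tilde u = 2u^n - u^{n-1}$, sets the body-frame
far-field inflow to $-\tilde u$, advances the flow, integrates the surface
force, updates $u_a$, and optionally repeats (Picard, default two passes,
relative tolerance 1e-6). The simulation runs in the body frame — wake
positions differ from the tank frame by a Galilean shift; for the thin
swimmer the neglected frame-acceleration force is negligible.

Energy expenditure follows the surface-power integral
$P_e = \int \sum_s (f_x \dot x + f_y \dot y)\,dt$ with tank-frame surface
velocities (fin deformation plus body translation), integrated by
trapezoid over the averaging window. Thrust and drag are split per
element by the sign of the x-force, which makes the net-force identity
$F = T_f - D$ exact by construction — the published relation between the
three quantities — at the cost of mixing pressure and friction
contributions (a pressure/viscous split is logged diagnostically from the
pressure jump across the boundary). The drag coefficient supports both
the standard $D/(\tfrac12\rho U_a^2 s)$ and the published first-power
convention $D/(\tfrac12\rho U_a s)$; they differ by exactly $U_a$ and the
convention used is recorded in every summary.

## The reduced-scale study conditions

`gen_paper_case()` emits the experiment matrix: four caudal presets, two
frequencies, at either physical scale or the reduced desk scale used for
paired comparisons — body length 1, one cycle per time unit, a
frequency-based Reynolds number $fL^2/\nu = 500$, a 256 x 128 grid over
8 L x 4 L, 200 steps per cycle ($\Delta t = T/200$), 10 cycles.

The analogue inertia per unit span is $m^* = 0.3\,\rho L^2$. The bare
in-plane body ellipse would give $m^* \approx 0.09\,\rho L^2$; with that
value the two-dimensional force-to-mass ratio is so large that the body
reaches quasi-steady speed inside the one-cycle startup ramp and then
relaxes downward — nothing like the 11-15 undulation cycles the fish
needs to reach its measured speed. $m^*$ was therefore set once so the
acceleration phase spans the simulated window. Even so, a mild (~6%)
overshoot of the cycle-2 mean persists: suppressing the startup-impulse
overshoot entirely would need $m^* \gtrsim 0.4\,\rho L^2$ while a
within-window plateau would need $m^* \lesssim 0.04$, and both cannot
hold at once in two dimensions where the drag slope is weak.

At these conditions the paired closed vs full-open comparison reproduces,
as sign-level statements, the mechanism found in three dimensions:
cycle-averaged drag is lower with the caudal fin closed, cycle-averaged
net thrust is higher, a fixed intermediate speed is reached sooner, and
the caudal-fin thrust taken alone is *higher* when open (the wake of the
median fin feeding the open caudal pair).

## What the planar analogue does not reproduce

Two findings are inherently three-dimensional and are **not** reproduced:

* the ordering of Froude efficiency and cost of transport (open more
  efficient, cheaper per distance). In three dimensions the closed, folded
  fin has the *larger* wetted area and pays more friction power; in a
  planar cut two stacked lobes collapse onto one plate, so the closed
  configuration can never carry more wetted boundary than the open pair.
  The corresponding acceptance assertions are retained and fail, by
  design, as a documented limitation rather than being weakened;
* the published 3-D percentage magnitudes (4.1% drag, 6.6%/7.3% net
  thrust, 30%/18% speed differences). Only signs are meaningful at this
  scale.

Other limitations: no fin elasticity (also excluded at full scale), no
pitch/yaw/heave freedom, no turning, laminar flow only, and synthetic
tracks model pose-estimation error as isotropic Gaussian pixel jitter —
real exports show heteroscedastic, occasionally catastrophic outliers
that the confidence threshold is meant to catch.

## Velocimetry

`estimate_speed()` drops samples below a confidence threshold (default
0.9), interpolates gaps, smooths positions with a local least-squares
quadratic (Savitzky-Golay, half-width 5 frames at 60 fps), differentiates
centrally, and reports speeds in BL/s; the plateau speed $u_e$ is the
top-decile mean (the operationalization chosen for "the measured swimming
velocity" — a mean or instantaneous variant is a parameter away).
`fin_frequency()` counts zero crossings (quantum $1/(2T_{\rm window})$;
a periodogram peak is the cross-check), and `correlate_f_u()` fits the
linear frequency-speed relation. On synthetic tracks with 1 px noise the
speed is recovered within 5%, and 14 and 29 Hz sinusoids (the latter just
under the 30 Hz Nyquist limit of 60 fps video) are recovered within one
crossing quantum.

The worked acceleration values follow the definition
$\alpha = u_e / t_0$: with $u_e$ = 0.73 BL/s, reaching it in 11.4 cycles
at 10 Hz gives 0.64 BL/s², in 14.9 cycles 0.49 BL/s², and the 3.5-cycle
gap is 0.35 s.

```{r alpha}
average_acceleration(0.73, 11.4 / 10)
average_acceleration(0.73, 14.9 / 10)
```

## Problem sizes and determinism

The test suite runs the analytic validations at 32²-128², the cylinder
at 192 x 96, short propulsion checks at 64 x 32 to 96 x 48, and one full
paired comparison at the study conditions (256 x 128, 10 cycles). The
acceptance script repeats the paired comparison and the validations from
scratch. Every stochastic generator takes an explicit seed and restores
the global RNG state; identical configurations produce bitwise-identical
series.
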