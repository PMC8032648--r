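---
title: "Generalized hydrodynamic friction for active surfaces: models, numerics, and the cilia-pair study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalized hydrodynamic friction for active surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stokeslets)
```

## The model

The package simulates shape-changing surfaces immersed in a viscous fluid
in the zero-Reynolds-number limit, where the flow obeys the Stokes
equation `0 = -grad p + mu laplacian u` with the no-slip condition
`u(x) = v(x)` on the moving surface. Inertia is absent: the dynamics is a
balance of forces at every instant, and the flow responds linearly and
instantaneously to the boundary motion.

Two assumptions make the problem small. First, admissible shapes are
constrained to a low-dimensional family `S(q)` parameterized by
generalized coordinates `q = (q1, ..., qn)` — a beat phase, arm lengths,
rigid-body degrees of freedom. Second, the internal machinery that drives
shape change is coarse-grained into scalar driving forces `Q_i(q_i)`, one
per coordinate, each depending only on its own coordinate (appropriate
when `i` labels distinct units such as different cilia) and independent of
load. The interface reserves a hook for load-dependent driving
`Q_i(q_i, P_i)`, which would turn the force balance into an implicit
equation; it is not implemented.

By linearity, the surface velocity and the traction (surface force
density) both expand in the coordinate rates,

```
v(x) = sum_i w_i(x; q) qdot_i,     w_i = dx/dq_i
f(x) = sum_j g_j(x; q) qdot_j,
```

and projecting tractions onto the velocity basis gives the generalized
friction matrix `Gamma_ij(q) = integral w_i . g_j dA`. It is symmetric (a
consequence of the Lorentz reciprocal theorem, verified numerically rather
than assumed) and positive definite wherever the `w_i` are independent;
`qdot . Gamma . qdot` is the dissipation rate and plays the role of a
Rayleigh dissipation function. The equations of motion are the force
balance `Q_i = P_i = sum_j Gamma_ij qdot_j`, i.e. `qdot = Gamma^-1 Q`.

Because `Gamma` depends on the shape but not on the rates, it is
precomputed on a grid over `q` (`n * m^n` resistance solves for `m` nodes
per coordinate — the build reports this count), serialized to JSON, and
interpolated during dynamics.

## The flow solver

Surfaces are discretized as clouds of collocation points ("blob"
elements) with areas `A_k` and per-element blob radii. The velocity due to
a point force is the regularized Stokeslet of the standard smooth blob
`phi_eps(r) = 15 eps^4 / (8 pi (r^2 + eps^2)^(7/2))`, giving the kernel
`[delta_ij (r^2 + 2 eps^2) + r_i r_j] / (8 pi mu (r^2 + eps^2)^(3/2))`.
The resistance problem (velocities to tractions) is a dense collocation
solve by LU factorization with an optional condition-number diagnostic;
iterative and fast-multipole solvers are out of scope at the problem sizes
the package targets (hundreds of elements).

For the half space above a rigid no-slip wall (fixed at `z = 0`) the Blake
image system is added: an opposite-sign Stokeslet, a potential doublet and
a Stokeslet doublet at the mirror point. Only the primary Stokeslet is
regularized. The images sit a distance `2h` below the wall (with `h` the
source height) and are never approached by admissible field points, so
regularizing them would only perturb the no-slip property: with singular
images the wall condition holds exactly in the `eps -> 0` kernel and to
`O(eps^2/h^2)` with regularization. The transcription of the image system
is deliberately not trusted: the test suite checks `u = 0` on the wall at
random configurations to machine precision, kernel reciprocity in both
domains, and the constant-height `1/d^3` decay of the wall-parallel far
field.

Discretization choices:

* **Spheres** are Fibonacci lattices with equal areas `A = 4 pi a^2 / N`
  and blob radius `0.35 sqrt(A)`. The coefficient was fixed by a
  convergence study against the analytic Stokes drag `6 pi mu a`
  (errors 0.44%/0.34%/0.26% at N = 250/500/1000, decreasing
  monotonically; rotational resistance `8 pi mu a^3` to about 1%).
* **Cilia** are chains of blobs along the centerline with spacing
  `L/n_segments`, blob radius equal to the filament radius (default
  0.1 um), and lateral area `2 pi a ds` per segment. Spacing below the
  element diameter is rejected.

## Velocity bases, symmetrization, interpolation

The velocity basis is computed by central differences with default step
`1e-6` in coordinate units (forward differences are available for
generators only defined one-sided); rigid-translation coordinates return
their exact unit vectors. Central differencing is exact on quadratic
families and `O(h^2)` otherwise — both properties are tested. The
generator contract (identical element enumeration and areas under small
coordinate perturbations) is checked and violations are errors.

The assembled `Gamma` is checked for relative asymmetry below `1e-4`
(discretization breaks the exact reciprocal-theorem symmetry slightly); a
violation is reported as a warning, never silently fixed, and the
symmetric part is used. Positive definiteness is asserted with tolerance
`-1e-8 * ||Gamma||` on the smallest eigenvalue.

Friction tables store `Gamma` at every node of a tensor grid. Periodic
coordinates use uniform grids on `[0, 2 pi)` without the duplicate
endpoint and are interpolated by truncated Fourier series with all `m`
modes (the Nyquist mode of an even grid is treated as a pure cosine so the
interpolant is real); nodes are reproduced exactly, band-limited functions
with at most `m/2` harmonics are recovered to machine precision, and
periodicity is built in. Cubic-spline (periodic or free-end) and Lagrange
polynomial interpolation are provided for one-coordinate tables.
Interpolated matrices are symmetrized entrywise; extrapolation beyond a
non-periodic grid is a domain error. Table files carry the kernel
configuration and a payload hash checked on load; rebuilding a table from
the same configuration yields a byte-identical file (serialization uses 17
significant digits, which round-trips doubles exactly, and no
timestamps — determinism is preferred over build metadata).

## Dynamics

`integrate_dynamics()` evolves free coordinates by the reduced force
balance with `deSolve`'s adaptive solver (defaults `rtol 1e-8`,
`atol 1e-10`); prescribed coordinates move their friction contribution to
the right-hand side, and constrained coordinates are the zero-rate special
case. For non-free coordinates the conjugate friction force — the
external force required to impose the motion, e.g. the clamping force of a
swimmer dragged through a uniform flow in its co-moving frame — is
reported along the trajectory together with the dissipation rate. Energy
bookkeeping (`sum Q_i qdot_i = R`) and the linear scaling of dissipated
energy per traversal with traversal speed are tested.

Rigid-body motion uses the six coordinates (three material-frame
translations, three rotations); the 6x6 grand friction matrix reduces to
the classical resistance matrix, and the free-swimmer solve enforces zero
total force and torque on the returned traction. Frames are advanced by
the exact rotation exponential (Rodrigues) followed by a polar
re-orthonormalization guard, avoiding chart singularities; orthonormality
drift stays below `1e-9` over thousands of random steps. The three-sphere
swimmer is integrated quasi-statically along its arm-length path: at zero
Reynolds number displacement per cycle is a geometric phase, so the path
parameter replaces time, which makes rate independence exact by
construction and is tested against a smoothly reparameterized traversal.

## The synthetic beat pattern

The experimental centerline data the cilia-pair study would ideally use is
not shipped; a synthetic generator replaces it. The centerline is built
from a traveling wave of the tangent angle: with arclength fraction
`u = s/L`,

```
theta(u, phi) = theta_mean + (amp_base + amp_tip * u) * cos(phi - k u)
chi(u, phi)   = asym * u * sin(phi - k u - asym_lag)
```

where `theta` is the polar angle from the wall normal (tilted toward `+y`,
the effective-stroke direction) and `chi` the out-of-plane azimuth. The
unit tangent is integrated from the wall-anchored base. Defaults
(`L = 10 um`, `theta_mean = 0.45`, `amp_base = 0.35`, `amp_tip = 1.25`,
`k = 1.8`, `asym = 0.35`, `asym_lag = 1.2`, 20 segments, beat frequency
32 Hz, water viscosity `1e-3 Pa s`) were chosen once, on geometric
grounds, to emulate a Paramecium-like beat: an extended fast effective
stroke sweeping the `+y` half-space (tip height 0.97 L at mid-stroke), a
curled recovery closer to the wall (tip height 0.23 L), a lateral
excursion during recovery that breaks the beat-plane mirror symmetry, no
wall penetration and no self-intersection (both validated at
construction). Setting `asym = 0` gives a planar beat.

What the generator does **not** emulate: a measured waveform (so absolute
friction values, the detailed shape of `Gamma_11(phi)`, and the specific
directions at which the in-phase state loses stability are
pattern-specific), waveform compliance or amplitude degrees of freedom,
and beat noise. Passing tests therefore demonstrate the machinery —
symmetries, scalings, calibration, stability analysis — on a realistic
synthetic beat, not agreement with any particular organism's waveform.

## The cilia-pair study

Two identical cilia, bases separated by `d` along a direction at angle
`psi` from `+x` (the effective stroke of both along `+y`; defaults
`d = 18 um`, `psi = 5 pi / 6`). The phase-space tables are built on an
`m x m` grid (`m = 16` in the study scans, 24 by default); the
cross-friction symmetry `Gamma_12 = Gamma_21` is asserted on the grid, and
the self-friction is approximated by the isolated-cilium table — the
approximation error is measured (about `1.5e-4` at `d = 18 um`) and
stored, which is what justifies calibrating the driving force on the
isolated cilium: requiring constant phase speed `omega_0` fixes
`Q(phi) = omega_0 Gamma_11(phi)` uniquely. Because dynamics uses the same
interpolant as calibration, the isolated unit beats at `omega_0` to
integrator accuracy (relative period error below `1e-6` over ten cycles).

Stability of in-phase beating is quantified by the one-cycle Lyapunov
exponent: phases start at `-delta0/2` and `+delta0/2` (default
`delta0 = 1e-3` rad, small enough that halving it changes the exponent by
well under 1%), the pair is integrated until the mean phase completes one
cycle (event detection on `phibar = 2 pi`), and
`lambda = log|delta(T)/delta0|`. Steady states are found from a fan of
eight initial phase differences spanning `(-pi, pi]`, sampling `delta`
exactly at mean-phase multiples of `2 pi` (it oscillates weakly within a
cycle); convergence is declared when the per-cycle change drops below
`1e-4` rad within a 200-cycle horizon, converged values are clustered with
circular tolerance 0.05 rad, and a zero-drift case (vanishing coupling) is
flagged neutral rather than converged. At `d = 18 um` the strongest
contraction is about `lambda = -0.026` per cycle, so the formal
convergence criterion fires only near the end of (or just beyond) the
default horizon; the reported value is the last sampled `delta` either
way.

### Finite-distance corrections to the 1/d^3 law

The far-field coupling between wall-anchored cilia is governed by the
wall-parallel Blake response at constant height, which decays as `1/d^3`.
The package's distance scans (five separations, 15-60 um, i.e. 1.5-6
cilium lengths) fit the decay of the torus L2 norm of `Gamma_12` and of
`|lambda|`. At these moderate separations the fitted exponents carry
`O(L/d)` corrections whose sign depends on the separation direction: for
the shipped pattern the fit gives about 2.5 (coupling norm) and 2.6
(`|lambda|`) at `psi = 5 pi/6`. The
asymptotic law is recovered far out: between 120 and 480 um the fitted
exponent is 2.98 (tested), and the kernel-level control — a wall-parallel
point force evaluated at constant height over 10-100 source heights —
gives 2.978. The scan API excludes distances below 1.5 L from fits (with
1.5 L itself counted as far field) and warns.

Symmetries are verified rather than assumed: `lambda(psi) =
lambda(psi + pi)` (point reflection swaps the two identical cilia), the
in-phase manifold `delta = 0` is invariant to `1e-8` over 50 cycles, and
relabeling the cilia maps trajectories onto the point-reflected
configuration exactly.

## Problem sizes and tolerances used in the shipped checks

The test suite and the reproduction script run at desk scale by design:
20 blob segments per cilium, 16x16 phase grids, five distances between 15
and 60 um, twelve separation directions at 18 um, spheres with 250-500
elements, three-sphere swimmers with 60-80 elements per sphere. These
sizes keep every resistance solve dense and small (at most a few thousand
unknowns) while leaving the measured quantities (drag errors under 5%,
symmetry residuals under `1e-6`, interpolation errors at the grid's
Nyquist limit) comfortably inside their tolerances.

## Known limitations

* Absolute friction values depend on the blob discretization and are not
  directly comparable to boundary-element results on triangulated meshes;
  structure, symmetries and scalings are.
* The blob method degrades when surfaces approach within a few blob radii;
  the pair analysis rejects intersecting configurations but does not add
  lubrication corrections.
* Load-dependent driving forces, stochastic (biological) noise, elastic
  amplitude degrees of freedom, and groups of more than two cilia are out
  of scope; the configuration schema reserves a `noise` block and the
  driving-force interface a load hook.
* Finite Reynolds numbers and viscoelastic fluids break the superposition
  principle the whole construction rests on.
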