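---
title: "Methods: an oxygen-coupled angiogenesis model and its verified MOL/RK4 solver"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an oxygen-coupled angiogenesis model and its verified MOL/RK4 solver}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angiomol)
```

## The model

`angiomol` simulates a one-dimensional continuum model of tumor-induced
angiogenesis on the dimensionless domain $\Omega = [0, L_f]$, with the parent
vessel at $x = 0$ and the tumor edge at $x = L_f$. Five fields interact:
endothelial cell density $C$, protease $P$, inhibitor $I$, extracellular
matrix (ECM) density $F$, and oxygen $O$:

$$
\begin{aligned}
\partial_t C &= \partial_x\!\left[ d_C \partial_x C
  - C\left(\alpha_1 \partial_x F - \alpha_2 \partial_x I
  + \alpha_3 \partial_x \phi\right)\right] + k_1 C (1 - C) H(O),\\
\partial_t P &= d_P \partial_{xx} P - k_3 P I + k_4 T C + k_5 T - k_6 P,\\
\partial_t I &= d_I \partial_{xx} I - k_3 P I,\\
\partial_t F &= -k_2 P F,\\
\partial_t O &= d_O \partial_{xx} O - \frac{\gamma_1 C O}{K_O + O}
  + \gamma_2 (O_{\max} - O)\, \beta C,
\end{aligned}
$$

with homogeneous Neumann (no-flux) conditions at both endpoints for every
field. $H(O) = O / (K_O + O)$ is the Michaelis–Menten factor that saturates
oxygen-dependent proliferation and consumption. The tumor angiogenic factor
(TAF) is a fixed spatial profile $T(x) = \exp(-\epsilon^{-1}(L_f - x)^2)$
peaking at the tumor edge, used through its logarithmic regularization
$\phi(x) = \alpha_4^{-1} \log(1 + \alpha_4 T(x))$, which caps the effective
taxis drive where $T$ saturates.

Modeling assumptions worth keeping in mind:

* The ECM equation is a pure local decay ($F$ is degraded by protease and
  never rebuilt); it has no diffusion, so its numerics differ qualitatively
  from the other fields.
* The chemotaxis sensitivity $\alpha_2$ is *negative* and enters the flux as
  $-\alpha_2 \partial_x I$; with the reference value $\alpha_2 = -0.1$ the
  effective inhibitor-gradient coefficient is $+0.1$, i.e. motion *up*
  inhibitor gradients. This is counterintuitive biologically, but the model
  equations are implemented exactly as stated; the package does not
  reinterpret the sign.
* Oxygen supply is proportional to endothelial density (nascent vasculature
  perfuses), with ceiling $O_{\max}$.

## Parameters

`model_parameters()` carries the full coefficient set. Fourteen values
(diffusivities, taxis sensitivities, kinetic rates $k_1$–$k_3$, $k_6$,
oxygen constants) follow the published physiological reference table. Six are
**package defaults**, because no reference value exists: $k_4 = 0.1$,
$k_5 = 0.05$ (TAF-driven protease production at mid-range magnitudes
consistent with the other kinetic rates), $\beta = 1$ (vessel functionality
as a pure scale factor), $O_{\max} = 1$ (oxygen normalized to its ceiling),
$\epsilon = 0.01$ (TAF transition width $\sqrt{\epsilon} = 0.1$, a thin but
grid-resolvable tumor rim at $M \ge 32$), and $\alpha_4 = 1$ (mild
regularization). `parameter_table()` prints every value with its provenance,
and the same provenance flags are written into every run's `metadata.yaml`.
These choices were fixed once, before any verification below, and are not
tuned.

```{r}
parameter_table(model_parameters())
```

Validation enforces the sign conditions under which well-posedness holds
(`strict = TRUE`): positive diffusivities and rates, $\alpha_1, \alpha_3 > 0$,
$\alpha_2 < 0$. Verification workflows may relax this (`strict = FALSE`) to
zero out couplings — e.g. the pure-diffusion reduction used as a
heat-equation oracle — but negative rates are never admitted.

## Discretization

Space is discretized on $M + 1$ equidistant nodes $x_j = j \Delta x$. The
gradient matrix uses central differences inside and second-order one-sided
stencils $(-3, 4, -1)/(2\Delta x)$ and $(1, -4, 3)/(2\Delta x)$ at the
endpoints; the Laplacian is the standard three-point stencil whose boundary
rows $(-2, 2)/\Delta x^2$ and $(2, -2)/\Delta x^2$ encode the ghost
reflection $u_{-1} = u_1$ implied by zero flux. Two structural identities are
worth stating because the tests rely on them:

* both operators annihilate constants (every row sums to zero), and
* under trapezoidal weights $(\tfrac12, 1, \dots, 1, \tfrac12)\Delta x$ the
  Laplacian conserves mass exactly (the flux sum telescopes), so any
  consistent one-step integrator conserves the weighted total of a purely
  diffusing field to round-off.

The Laplacian's eigenvalues are known in closed form,
$\lambda_m = -(4/\Delta x^2) \sin^2(m \pi \Delta x / (2 L_f))$ with cosine
eigenvectors, and `laplacian_spectrum()` exposes them; they drive the
stability analysis below. $M \ge 4$ is required so the one-sided boundary
stencils never collide; interior rows are central stencils everywhere, and
the one-sided forms appear only in rows $0$ and $M$.

The semi-discrete system $dU/dt = L(U) + N(U)$ splits into linear diffusion
$L$ and nonlinear advection/reaction $N$; the taxis flux is assembled exactly
as $D_x\big(C \odot (\alpha_1 D_x F - \alpha_2 D_x I + \alpha_3\,
d\phi/dx)\big)$ with $d\phi/dx$ precomputed *with the discrete gradient*, not
the analytic derivative, so the scheme is the literal matrix form of the
model. Time integration is classical four-stage RK4 applied to $L + N$
together (no splitting). Stage times are $t$, $t + \Delta t/2$,
$t + \Delta t/2$, $t + \Delta t$; the physical model is autonomous and
ignores them, but manufactured-solution sources are time-dependent and need
the classical non-autonomous stage times to retain fourth order. The stage
vectors are named `stage_1..stage_4` throughout to avoid any collision with
the kinetic rates $k_1..k_6$.

Two interchangeable engines implement the same scheme: a compiled C++ loop
used for the physical model (the physiological scenario takes $10^6$ steps),
and a plain-R reference loop that additionally supports sources and per-step
hooks. They agree to round-off and a test asserts it; reruns of either are
bit-identical because nothing in the integrator is randomized.

## Stability limits

`stability_limits()` reports three bounds and a recommendation:

* **diffusion**: $\Delta t \le \Delta x^2 / (2 d_{\max})$ with $d_{\max} =
  \max\{d_C, d_P, d_I, d_O\}$. This is the explicit-Euler amplification bound
  on the extreme eigenvalue $-4/\Delta x^2$; for RK4, whose real-axis
  stability interval is $[-2.785, 0]$, it is conservative by a factor
  $\approx 1.39$. The tests verify both facts empirically: integrations at
  $0.95\times$ and even $1.3\times$ the bound stay bounded, while
  $1.45\times$ (beyond the RK4 limit) blows up by orders of magnitude.
* **advection (CFL)**: $\Delta t \le C_{CFL} \Delta x$. The model theory
  leaves $C_{CFL}$ unquantified, so when a state is available the package
  *measures* the maximum taxis speed $\max_j |\alpha_1 (D_x F)_j - \alpha_2
  (D_x I)_j + \alpha_3 (d\phi/dx)_j|$ and uses its reciprocal; speeds at
  round-off level yield an `Inf` sentinel (bound inactive). Without a state a
  configurable constant (default 1) is used.
* **invariant region**: $\Delta t \le \min\{\Delta x^2/(2 d_{\max}),\,
  1/L_R,\, \Delta x/\alpha_{\max}\}$. The Lipschitz constant $L_R$ of the
  reaction map over the invariant region is never stated numerically in the
  theory, so it is estimated as the maximum $\infty$-norm of
  finite-difference Jacobians over a $3^5$-point sample of the region (worst
  case $T = 1$), and the estimate is exposed in the report.

`dt_recommended` is 0.9 (a conventional explicit-scheme safety factor) times
the minimum of the applicable bounds. `run_simulation()` refuses steps above
it unless explicitly overridden, in which case it warns; the override exists
because the temporal convergence study deliberately probes the region between
the Euler-derived bound and the RK4 limit.

## Verification by manufactured solutions

`manufactured_solution()` ships closed-form fields for all five components
with symbolically derived time/space derivatives, and `mms_sources()` builds
compensating sources $S_u = \partial_t u_e - \mathrm{RHS}(u_e)$ so the forced
system has the chosen fields as exact solution. The residual
$\partial_t u_e - \mathrm{RHS}(u_e) - S_u$ is zero by construction and
spot-checked at random points to $10^{-12}$.

Two variants exist for a reason. The verbatim (`"paper"`) fields include
$\tfrac12(1 + \sin \pi x)$ and $0.2\sin(2\pi x)$ terms whose boundary slope
is *nonzero* ($\partial_x C(0, t) = \tfrac{\pi}{2} e^{-0.1t}$), conflicting
with the zero-flux boundary rows built into the discrete operators.
Incompatible boundary data degrades accuracy near the endpoints
unpredictably, so spatial-order studies default to a `"neumann_compatible"`
variant that swaps only those two fields for cosines of the same amplitude
and decay ($\tfrac12(1 + \cos\pi x) e^{-0.1t}$, $0.2\cos(2\pi x) e^{-0.3t}$).

**Spatial study.** `run_spatial_convergence()` integrates the forced system
from exact initial data on doubling grids with the step slaved to the grid,
$\Delta t = 0.5 \cdot \Delta x^2/(2 d_{\max})$, so temporal error
($O(\Delta t^4) = O(\Delta x^8)$) is negligible; the error is the
$\Delta x$-weighted discrete $L^2$ difference at $T_f = 1$. The norm
convention is the package's own choice (the published tables do not state
one), which is why only *rates*, never absolute error magnitudes, are treated
as checkable. Measured rates on $M = 32..256$ are $\approx 2.0$ for $C$, $I$,
$O$. The $P$ component converges *faster* than 2 at coarse grids (observed
rate $\approx 2.8$ between $M=32$ and $64$, settling toward 2 by $M = 256$):
its own truncation error is an order of magnitude smaller than the other
fields' (small $d_P$ on a near-eigenvector field), so error transported into
$P$ through the $k_3 P I$ and $k_4 T C$ couplings partially cancels it at
coarse resolution. The per-component *truncation* of the semi-discrete
right-hand side is cleanly second order for every field, and a test asserts
that directly; another test checks the evolved errors against an independent
stiff integrator (`deSolve::lsoda` at $10^{-10}$ tolerance) on the same
semi-discrete system, which reproduces them to well under one percent, so
the superconvergent transient is a property of the study, not of the
implementation.

**Temporal study.** `run_temporal_convergence()` fixes one grid and halves
$\Delta t$; in its default *self-reference* mode the error is measured
against a run at $\min(\Delta t)/4$ on the same grid, isolating temporal
error from the fixed spatial error. Two regime choices matter and were made
deliberately:

* the *verbatim* fields are used, because their boundary-flux mismatch
  continuously populates the fast diffusive grid modes, making the
  $O(\Delta t^4)$ error measurable; the fully compatible fields are so smooth
  on the grid that their temporal error sits at machine precision for every
  stable step, leaving nothing to measure;
* the default steps ($M = 64$, $\Delta t = 1.6\times10^{-3}, 8\times10^{-4},
  4\times10^{-4}$, $T_f = 1$) sit just inside the RK4 stability limit, where
  the stiff-mode amplification error is well above round-off. Measured
  orders are $4.05$–$4.13$.

In *exact-reference* mode the error instead plateaus at the grid's spatial
floor once temporal error drops beneath it, and a test asserts the plateau.
The published temporal table reports rates near 2 at step sizes that exceed
the RK4 stability limit for its stated grid, so its measurement protocol
cannot be inferred; the package checks that table's internal rate arithmetic
(each printed rate is the $\log_2$ ratio of adjacent printed errors) but does
not attempt to re-simulate its absolute values.

## Invariant region and energy monitoring

The continuous theory bounds each component: $C \in [0, 1]$,
$P \in [0, \max\{\xi_1, (k_4 + k_5)/k_6\}]$, $I \in [0, \xi_2]$ and
$F \in [0, \xi_3]$ (no positive sources, so initial uniform values are
ceilings), $O \in [0, \max\{O_0 + \xi_4, O_{\max}\}]$. `invariant_region()`
recomputes these from the current parameters and initial conditions on every
call. Monitoring is purely observational: the scheme never clips or projects
a state, because region preservation is a *claim to verify*, not a constraint
to enforce. Violations are detected with an absolute tolerance ($10^{-10}$ by
default) to absorb round-off; `run_simulation()` tracks per-component global
extrema at every accepted step, so the check covers the whole trajectory, not
just monitored snapshots.

The energy functional
$E = \tfrac12 \int_\Omega (C^2 + P^2 + I^2 + F^2 + O^2/(\gamma_2\beta))\,dx$
is evaluated by trapezoidal quadrature (the same weights under which the
discrete Laplacian conserves mass) and recorded as a dissipativity
diagnostic. The decay-rate constants of the underlying dissipation
inequality are not computed; the trace is diagnostic only.

## The physiological scenario

The default `run_config()` reproduces the angiogenesis experiment: domain
$[0, 1]$, $M = 256$, $\Delta t = 10^{-5}$ (far below the $7.6\times10^{-5}$
diffusion bound), $T_f = 10$, endothelial cells seeded at density 1 on
$[0, 0.1]$ (the node at the cutoff is included — the seeding interval is
closed), $P = 0.1$, $I = 0.2$, $F = 1$, and oxygen $0.5 e^{-5x} + 0.1$
decaying away from the parent vessel. Snapshots default to
$t = 0, 2, 5, 10$. Over the full run every component stays inside its
invariant box to the $10^{-10}$ tolerance, the ECM is pointwise
nonincreasing, and the energy trace stays finite; the acceptance tests
assert all of this on the full-resolution run.

Under these equations and defaults the endothelial front (threshold 0.5, the
mid-amplitude of the admissible range; configurable) advances slowly: the
TAF gradient is concentrated in the thin tumor rim, so cells near the parent
vessel move chiefly by motility and proliferation. Sweep metrics
(`sensitivity_sweep()`: final front position, arrival time at $0.9 L_f$,
oxygen range, endothelial mass) are package definitions chosen to quantify
the qualitative behaviors of interest; they are not published quantities.

## What the fixtures emulate — and what they do not

The manufactured fields and the scenario initial conditions are the package's
synthetic inputs. They exercise smooth coupled dynamics, boundary-layer
effects (verbatim variant), a discontinuous initial condition (the seeded
endothelial step), and the stiffness range of the reference parameters. They
do **not** emulate multi-dimensional vessel morphology, stochastic tip-cell
dynamics, or parameter regimes far outside the reference table; passing
tests demonstrate correctness of the discretization and integrator, not
biological validity of the model in those regimes.

## Numerical choices and degenerate inputs

* Discrete norm: $\|e\| = (\Delta x \sum_j e_j^2)^{1/2}$ everywhere.
* Rates: $\log_2(e_{\text{coarse}}/e_{\text{fine}})$, defined only from the
  second row of a study on.
* A run whose horizon is not a step multiple takes one smaller final step to
  land on $T_f$ exactly; $T_f = 0$ returns the initial state.
* Non-finite values anywhere (inputs, RK4 stages, states) abort immediately
  with the offending component or stage named; negative transients are
  reported, never clamped.
* Zeroed decay rate $k_6$ (relaxed mode only) contributes no production
  ceiling to the invariant region rather than a 0/0.
* Failures inside a convergence study or sweep are recorded per row/value;
  the study continues.
* Problem sizes in the shipped tests were chosen to keep the default suite
  comfortably interactive while still covering the full-resolution scenario
  once: module tests run on $M \le 64$ grids, the convergence studies on
  $M = 32..256$, and the invariant-region acceptance check on the full
  $M = 256$, $10^6$-step run.

## Known limitations

* One spatial dimension only; no operator splitting, IMEX or adaptive
  stepping (deliberately out of scope — the explicit bound is manageable at
  the reference resolutions).
* $L_R$ is a sampled numerical estimate, not a certified bound.
* The published absolute error tables are not reproducible without their
  norm and step policy; only their rate arithmetic is checked.
* The six package-default parameters mean quantitative trajectories (front
  speeds, arrival times) are conditional on those choices; the provenance
  flags travel with every output so downstream users can audit them.
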