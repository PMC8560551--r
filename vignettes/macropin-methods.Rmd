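---
title: "Phase-field modeling of macropinocytic cup formation: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-field modeling of macropinocytic cup formation: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macropin)
```

## The model

`macropin` simulates how a cell builds and closes a macropinocytic cup — a
micrometer-scale, self-enclosing membrane extension that swallows
extracellular fluid — from nothing but two coupled processes:

1. **Membrane mechanics.** The plasma membrane is the moving level set of a
   phase field $\phi(\mathbf r, t)$ ($\phi = 1$ inside the cell, $0$
   outside, interface width $\varepsilon$):
   $$\tau \partial_t \phi = \eta\left(\nabla^2\phi -
   \frac{G'(\phi)}{\varepsilon^2}\right) - M_V (V - V_0)\,|\nabla\phi| +
   F_{\mathrm{poly}}\,|\nabla\phi|,$$
   with $G'(\phi) = 16\phi(1-\phi)(1-2\phi)$, cell volume
   $V = \int \phi\, d\mathbf r$ constrained softly to $V_0 = 4\pi R_0^3/3$,
   cortical tension $\eta$, deformation timescale $\tau$, and an
   actin-driven protrusive force $F_{\mathrm{poly}}$ normal to the
   membrane. Tension shrinks a free sphere at $\dot R = -2\eta/(\tau R)$
   (a property the test suite checks against the closed form); there is no
   surface-area constraint and no explicit bending term — for micrometer
   protrusions the bending-to-surface energy ratio
   $K_b/(2\eta r^2) \sim 10^{-3}$ is negligible.

2. **Patch reaction–diffusion on the membrane.** An activator $A$
   (Ras/PIP3-like "active patch" marker) interconverts with a fast-diffusing
   cytosolic pool $B$ and is suppressed by a slow inhibitor $I$
   (a coronin-like factor):
   $$\partial_t A = \frac{A^2 B}{1 + A^2/\alpha^2}\,\frac{1}{1 + I} - A +
   D_A \nabla^2 A, \qquad
   \partial_t I = k_1 A^p - k_2 I + D_I \nabla^2 I,$$
   with $p = 2$ by default, and conservation $\langle A\rangle + B = a_t$
   expressed through the algebraic pool
   $B = A_t/S - \langle A\rangle$ ($A_t = a_t \cdot 4\pi R_0^2$, $S$ the
   instantaneous surface area). For $k_1 = 0$ this is a wave-pinning
   bistable system: an ignited patch spreads and stalls as the pool
   depletes. Unsaturated activation ($\alpha \to \infty$, handled as a
   first-class value, not a large number) with quadratic inhibitor
   production makes the kinetics excitable and allows patch splitting.

The two processes are glued together by an auxiliary membrane indicator
$\psi = (1 + e^{-\beta(\phi(1-\phi)-\theta)})^{-1}$, equal to 1 on a band
of width $\varepsilon$ around the interface ($\beta = 100$,
$\theta = 0.105$; with the $\tanh$ interface kernel these values make the
$\psi > 1/2$ band exactly $\varepsilon$ wide, which the tests verify). $A$
and $I$ live on this band: the solver integrates the band-restricted
transport form with advection by the interface velocity, a confinement
drift $D\,\beta(1-\psi)(1-2\phi)\nabla\phi\cdot\nabla A$
(the operational form of $D\,\nabla\psi/\psi \cdot \nabla A$), and bulk
diffusion. Outside the band ($\psi \le 10^{-3}$) both species decay at
$\gamma_2 = 10\,\mathrm{s}^{-1}$. The activator is clamped at 50 after
each step — that cap matters only transiently, when an internalized
vesicle shrinks and concentrates its cargo. The inhibitor carries its own,
much higher guard (1000 by default): its natural excursion in the
unsaturated excitable regime reaches $I \sim 500$, and capping it at the
activator's value would create a spurious joint fixed point ($A = I = 50$
with $\dot A > 0$) that freezes the excitable dynamics outright —
`clamp_max_I` must stay well above the excursion peak.

The protrusive force is restricted to the patch *edge* by a concentration
window,
$$F_{\mathrm{poly}}(A) = F\,\frac{(A/K)^{n_h}}{1 + (A/K)^{n_h}}\,
\frac{1}{1 + (A^2/K')^{n_h}},$$
high only for $K \lesssim A \lesssim K'$: the patch interior (where
$A \approx 2$) generates no force, the rim does. The suppression factor is
implemented with $A^2/K'$ exactly as defined, although its units differ
from the $A/K$ factor; a variant with $A/K'$ (`force_law = "edge_linear"`)
is exposed for comparison and behaves very similarly. A second variant
(`force_law = "inhibited"`) replaces the $A$-window suppression with
competitive inhibition by $I$, $1/(1 + (I/K')^{n_h})$, which sharpens the
force to the leading edge (high $A$, low $I$) and is what permits daughter
cups after patch splitting.

## Well-mixed analysis

`fixed_points()`, `stability_boundary_k2()`, `annihilation_condition()`,
and `simulate_wellmixed()` analyze the space-free kinetics. The nonzero
fixed points solve $aB = (1 + a^2/\alpha^2)(1 + \kappa a^2)$,
$\kappa = k_1/k_2$; for $\alpha \to \infty$,
$A_\pm = (B \pm \sqrt{B^2 - 4\kappa})/(2\kappa)$. At $A_+$ the Jacobian
trace is $1 - k_2$, so the upper state is stable for $k_2 > 1$ (bistable
regime) and unstable for $k_2 < 1$ (excitable regime); the numerical
bisection in `stability_boundary_k2()` recovers $k_2^\ast = 1$ to $10^{-6}$.
The closed-form annihilation condition
$\kappa > \tfrac{9}{32}a_t^2 - 1/\alpha^2$ is *sufficient* for the decay of
any patch (it implies $\kappa + 1/\alpha^2 > a_t^2/4$, which rules out any
nonzero fixed point for every $b \le a_t$); the necessary-and-sufficient
test (`exact = TRUE`) maximizes
$f(a) = a\,a_t - (1+a^2/\alpha^2)(1+\kappa a^2)$ numerically. The test
suite checks both against a brute-force root scan.

## Numerical scheme

Everything is explicit Euler on uniform grids, in compiled code:

* **Quasi-3D (axisymmetric) solver** — the workhorse for cup phase
  diagrams. Fields live on the $z$–$r$ half-plane with
  $\nabla^2 = r^{-1}\partial_r(r\partial_r) + \partial_z^2$ (on-axis limit
  $2\partial_r^2 + \partial_z^2$), mirror symmetry at $r = 0$, Dirichlet
  $\phi = A = I = 0$ on the outer boundaries, and all integrals by the
  midpoint rule with the $2\pi r$ Jacobian. The reference resolution is
  $dx = 0.1\,\mu m$, $dt = 4\times 10^{-4}\,$s; coarser grids rescale
  $dt \propto dx^2$ and `sim_params()` refuses anything larger.
* **Spatial stencils.** Second-order central differences for the membrane
  equation; conservative first-order upwinding for the interface-velocity
  advection $-\nabla\cdot(A\mathbf v)$ (positivity at cusps). The
  confinement drift and the species Laplacian are discretized *together* as
  the conservative flux form of the banded diffusion they jointly
  represent, $\psi^{-1}\nabla\cdot(\psi\nabla A)$, with geometric-mean
  face weights $\sqrt{\psi_i\psi_{i+1}}$. The expanded drift form has cell
  Péclet number $\beta(1-\psi)|1-2\phi||\nabla\phi|\,dx$ above 2 on grids
  coarser than $dx \approx 0.15\,\mu m$, where central differencing
  destroys the banded mass within seconds and upwinding leaks a few
  percent per second at every resolution; the flux form retains 98–99% of
  a reaction-free banded blob over 10 s from $dx = 0.05$ to $0.2\,\mu m$
  (a property the test suite checks) and reduces to the standard scheme
  where $\psi$ is flat.
* **Velocity regularization.** $\mathbf v = 0$ wherever
  $|\nabla\phi| \le 10^{-3}$.
* **Cup-closure detection** scans the line $r = dx$ (the innermost
  off-axis column) from the domain top downward and counts
  vacant$\to$occupied transitions of $\phi$ across $0.5$: two transitions
  mean an enclosed extracellular region. Events are debounced — a new
  closure is registered only after the count has returned below two. The
  enclosed volume integrates, slice by slice between the two transition
  heights, the vacant region bounded outside by cell material (a disk, or
  an annulus when the slice has cell material at the center). An enclosed
  fraction $\ge 10^{-5}$ of $V_0$ counts as successful enclosure.
* **3-D solver** — same physics on a Cartesian grid (7-point Laplacian,
  no-flux faces), used for representative runs, bead engulfment, and
  stochastic multi-cup dynamics. Closure detection in 3-D is topological:
  connected components of the vacant region not touching the boundary.
  The default production grid is $128^3$ at $dx = 0.2\,\mu m$; tests use
  smaller cells on coarser grids, which exercise every term at unit-test
  cost.
* **Bead.** A static indicator
  $\chi = (1+\tanh((R_b - |\mathbf r - \mathbf r_b|)/(\varepsilon/2)))/2$
  adds $-A_{\mathrm{rep}}\chi^2\phi + A_{\mathrm{att}}|\nabla\chi||\nabla\phi|$
  to the force balance, and a uniform drift velocity
  $\tilde{\mathbf v} = -\frac{1}{V}\int (\mathbf r - \mathbf r_c)\,
  f\,d\mathbf r$ (with $f$ the scalar force density) is subtracted so the
  cell centroid stays put. Bead phase sweeps run in the axisymmetric
  solver with the bead on the patch axis; full 3-D runs are for
  representative cases.
* **Termination.** A run ends at `t_max`, after an optional number of
  closures, or when the patch is extinct (max $A < 10^{-3}$ sustained for
  5 s).

## Geometry and domain defaults

The cell has $R_0 = 10\,\mu m$. The axisymmetric domain defaults to
$L_r = 15\,\mu m$, $L_z = 40\,\mu m$ with the cell center 15 um above the
bottom boundary: the grid must contain the deformed cell, and cups grow
$5$–$8\,\mu m$ beyond the seeded (top) pole, so the headroom sits above
it. Runs that elongate the cell strongly can pass a taller grid. The 3-D
default is a $25.6\,\mu m$ cube. The seed patch sets $A \sim U(0,5)$
i.i.d. on membrane-band nodes within $r_{\mathrm{init}}$
($1.0$ or $1.5\,\mu m$) of the top pole.

## Stochastic nucleation

With `noise_params()`, nucleation events arrive as a Poisson process at
rate $\lambda$ per $\mu m^3$ per second ($3\times 10^{-5}$ by default);
each adds $N_0 e^{-|\mathbf x - \mathbf x_c|^2/2d^2}$ to $A$ on the
membrane band, $N_0 \sim$ Exponential(mean $\sigma = 8$), $\mathbf x_c$
uniform in the domain volume. The envelope width is stored in micrometers
($d = 1.5\,\mu m$, the reference lattice value of 15 cells at the
reference spacing) so that the physics does not change with resolution.
One RNG drives a run (R's generator, seeded per run); identical
configuration and seed reproduce results bit for bit.

## Reduced patch-boundary model

`run_reduced()` strips the reaction–diffusion system down to a single
patch-boundary marker $\mathbf r_b$ on the interface contour:
$\partial_t \mathbf r_b = \mathbf v + v_t\,(A - A_0)\,\mathbf T$, where
$A$ is the normalized area of revolution between the marker and the top
pole ($A = 2\pi\int_C r\,ds / 4\pi R_0^2$, computed on the marching-squares
$\phi = 0.5$ contour with piecewise-linear arc length) and $\mathbf T$ is
the tangent toward the patch — the sign convention is fixed by requiring
the patch to expand while $A < A_0$. The protrusion site sits a fixed arc
length $\Delta l$ outside the marker and carries a sigmoidal force profile
$F/(1 + e^{-2.5(r_f - d)})$. The marker is re-projected onto the contour
every refresh cycle (20 Euler steps by default; the membrane moves well
under $10^{-2}\,\mu m$ per cycle). The model's own parameters
($v_t = 0.3\,\mu m/s$, $A_0 = 0.35$, $\Delta l = 0.8\,\mu m$,
$r_f = 0.5\,\mu m$) are artifact defaults — the reduction defines no
canonical values — chosen so the three qualitative outcomes (closure at
high $F/\eta$, repetitive cups at intermediate, failure at low) appear in
that order; only the ordering is asserted anywhere, not the phase-boundary
positions.

## What the simulations do and do not show

The synthetic initial conditions (a perfect sphere, a single seeded patch,
axisymmetry) emulate the idealized cup experiment: they reproduce patch
ignition and spreading, rim protrusion, inward curling, topological
closure with a measurable enclosed volume, patch annihilation by the
inhibitor, bead engulfment, and noise-driven multi-cup interference.
They do not emulate real-cell features such as substrate contact,
cortical flow, heterogeneous tension, or organelle crowding, and the
axisymmetric solver by construction cannot show azimuthal instabilities
(ruffle undulations, off-axis daughter cups) — those require the 3-D
solver.

Two quantitative caveats, measured with this implementation and worth
stating plainly. First, resolution: production figures in the source
literature use $dx = 0.1\,\mu m$ on GPUs; the test suite and the
acceptance script run the same physics mostly at $dx = 0.2\,\mu m$.
The characteristic timings survive the coarsening well — first closure at
the standard point arrives at $t \approx 66$ s, repetitive closures at the
intermediate-force point at $t \approx 229$ and $466$ s, complete bead
engulfment at $t \approx 80$ s — while enclosed fractions (about
$10^{-2}$ of $V_0$ at the standard point) are order-of-magnitude
quantities. Second, patch *splitting* — the breakup of one expanding
patch into daughter patches in the unsaturated excitable regime — is an
azimuthal symmetry breaking at the scale of the reaction front width
($\sim 0.3\,\mu m$): it cannot occur in the axisymmetric solver at all,
and resolving it in 3-D requires the reference GPU-scale grid. The
kinetic prerequisites (excitability, large excursions, instability of the
upper state for $k_2 < 1$) are verified in the well-mixed suite, but no
simulation in the test suite exhibits splitting itself, and the
corresponding end-to-end check is expected to fail until a full-resolution
3-D run is feasible. Test problem sizes (grid spacing, horizons, and cell
radii for the 3-D unit checks) are chosen so the full suite exercises
every physical term in minutes; they are stated in each test.
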