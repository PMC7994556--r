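---
title: "Hemodynamics of stenosis microfluidics: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hemodynamics of stenosis microfluidics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Microfluidic channels with hump-shaped contractions are the workhorse
in-vitro model for studying how disturbed blood flow drives platelet
aggregation and thrombosis. A platelet carried through the contraction
experiences a rapid rise and fall of shear — its *shear history* — and the
channel walls carry a wall-shear-stress (WSS) hot spot at the narrowing.
Three geometric/operating dials control this mechanical dose: the bulk wall
shear rate $\gamma_0$ of the unobstructed channel (set by the syringe-pump
flow rate), the stenosis level $S$ (fraction of the width occluded), and the
contraction angle $\alpha$. `stenoflow` computes, for any setting of these
dials, the steady laminar flow field and the derived hemodynamic
observables: the shear-rate field $\gamma = \sqrt{2\,\mathbf{D}:\mathbf{D}}$
(with $\mathbf{D}$ the rate-of-strain tensor), the WSS
$\tau = \mu\,\gamma_{\text{wall}}$, and the shear and shear-gradient history
$\gamma(x)$, $\gamma'(x) = d\gamma/dx$ along the streamline a platelet
would ride 1 µm above the stenosis apex.

## Geometry model

The channel is $Y_0 = 100$ µm wide and $Z_0 = 130$ µm tall; the analysis
window spans $X_0 = 200$ µm around the apex, with straight entrance and exit
runs of $3 Y_0$ so inflow is fully developed. The solved plane is x–y: in
these devices the geometry and flow vary only across the width, so the
midplane flow is two-dimensional to a good approximation, and $Z_0$ enters
only through the closed-form operating-point formulas.

Published device drawings specify $S$ and $\alpha$ but not the exact hump
profile, so the profile is this package's own (documented) choice: linear
ramps inclined at $\alpha$ to the wall, joined by a circular crest arc whose
apex sits at $x = 0$, with matching concave fillets where the ramps meet the
flat walls, so the whole profile is C¹. An `eccentric` placement puts the
full hump (height $S Y_0$) on one wall; `concentric` splits it into two
mirrored humps. Both give a throat width of exactly $Y_0 (1 - S)$.

Two rounding radii deserve comment:

* **Base fillets.** The exact creeping-flow shear *vanishes* in a concave
  wall corner, but a slope-discontinuous corner makes the discrete WSS spike
  spuriously; rounding the ramp feet removes a numerical pathology without
  changing the physics.
* **Crest radius (default 6 µm).** The crest rounding exists to keep the WSS
  regular at the narrowest point. A sensitivity study (radii 2, 4, 6, 10 µm
  at $S = 80\%$, $\alpha = 85°$) showed that very small radii concentrate
  the computed WSS at the ramp–crest tangency — the wall graph curvature
  there scales as $(1 + \tan^2\alpha)^{3/2}/r$ and becomes unresolvable —
  while radii of 4 µm and above move the WSS peak onto the crest middle,
  where experimental reports place it, and leave the platelet-streamline
  peak shear essentially unchanged (few-percent level). The default of 6 µm
  is the smallest radius with a comfortable margin at the steepest study
  angle. Users can set any radius per geometry.

At $\alpha = 90°$ a ramp face would be vertical and cannot be represented as
a single-valued wall profile $y(x)$; the constructor rejects angles
indistinguishable from 90° when $S > 0$. The study range (30–85°) is
unaffected.

## Flow model and solver

The flow is steady, laminar and incompressible (Reynolds numbers for the
whole study envelope are below 2, and the Womersley number at a 120-bpm
pulse is 0.128, so the steady assumption is safe). Working fluids are water
and blood as Newtonian fluids (Table: water 998 kg/m³, 1.003 mPa s; blood
1060 kg/m³, 3.45 mPa s) and blood as a Generalized Power-Law (GPL)
shear-thinning fluid,
$\mu = K(\gamma)\, \gamma^{\,n(\gamma) - 1}$, whose consistency and index
relax from $K \to 0.25345$, $n \to 0.55$ at vanishing shear to the Newtonian
plateau $\mu_\infty = 3.45$ mPa s, $n_\infty = 1$ above ~500 1/s. Shear
rates are floored at $10^{-3}$ 1/s inside the constitutive law so the
power-law factor stays finite in quiescent corners; the floor is orders of
magnitude below any shear of interest.

The discretization is a **pure streamfunction** scheme rather than a
pressure–velocity (SIMPLE-type) iteration: eliminating the pressure and the
vorticity leaves one fourth-order equation in $\psi$,
$$\rho\,(\mathbf{u}\cdot\nabla)(-\nabla^2\psi) =
(\partial_{xx}-\partial_{yy})\!\left[\mu(\psi_{yy}-\psi_{xx})\right]
- 4\,\partial_{xy}(\mu\,\psi_{xy}),$$
which reduces to the $\mu\nabla^4\psi$ balance for constant viscosity.
The reasons are specific to this problem and to R:

* With $\psi$ fixed on the walls, the flux between the walls is a boundary
  value: mass is conserved *exactly*, station by station, which is the
  property the verification suite demands at the $10^{-8}$ level.
* No-slip enters as a one-sided condition on $\partial\psi/\partial\eta$
  and is exact at wall nodes; the wall shear rate is then $|\omega| =
  |\nabla^2\psi|$ at the wall — an exact identity under no-slip that
  avoids the first-order bias of differentiating a reconstructed velocity
  a second time.
* *Every* viscous term is implicit; only the convective velocities and the
  viscosity itself are lagged (Picard). This matters for shear-thinning
  blood: between the wall layers and the plug core the apparent viscosity
  spans about three decades, and any scheme that lags part of the elliptic
  operator oscillates there. The fully implicit form converges in ~5
  iterations for Newtonian and ~25–60 for GPL runs, with the viscosity
  update relaxed in log space (factor 0.5).
* Each Picard iteration is one direct sparse LU solve (Matrix package) —
  sparse direct solves are R's strong numerical primitive.

A fourth-order operator needs two boundary conditions per boundary: the two
node columns nearest the inlet pin the developed cubic profile carrying the
target flux; each wall contributes its streamline value and the no-slip
row; the outlet imposes zero axial gradient of $\psi$ and of the vorticity
(the steady-state equivalent of the pressure-inlet / flow-rate-outlet pair
used on the bench, and numerically better posed). Convection is central —
at cell Peclet numbers far below 2 upwinding would only add numerical
diffusion. Convergence requires the scaled streamfunction update to fall
below $10^{-7}$ and, for GPL runs, the viscosity field to settle within
0.1%. Initialization is deterministic (Stokes solve from rest), so repeated
runs are bit-identical. Pressure is recovered after the fact from the
momentum balance by an area-weighted sparse least-squares gradient
reconstruction; it is a diagnostic field, not part of the solve (without
the area weights, the tiny clustered throat cells dominate the normal
equations and corrupt the recovered drop).

### The two-dimensional flux convention

The 2D model must decide what "the same operating point" means. We set the
line flux to $q = \gamma_0 Y_0^2 / 6$, which makes the wall shear rate of
the *unobstructed* 2D channel exactly $\gamma_0$ — preserving the meaning of
the experimental dial. The bench flow rate from the rectangular-duct formula
$Q = 0.12\,A D_h \gamma_0 / \lambda$ (with the bench unit convention: $A$ in
µm², $D_h$ in m, $Q$ in µL/min) is carried alongside in every run record
for traceability. The printed formula relating Re to $\gamma_0$ via $\rho^2$
is dimensionally inconsistent; the package computes the standard
$Re = \rho Q D_h / (\mu A)$ in SI units.

## Mesh

The mesh is a boundary-fitted structured grid built in three steps, each of
which was forced by a concrete failure mode at the steepest study angle:

1. **Axial stations by wall arc length.** At $\alpha = 85°$ the wall graph
   slope is ~11.4; stations equidistributed in $x$ either starve the ramp
   face or waste thousands of points. Equidistribution along the wall arc
   (with a smooth sinh clustering toward the apex, strength `cluster = 5`)
   refines $\Delta x$ in proportion to the steepness automatically.
2. **Transverse tanh clustering** (`eta_cluster = 1.5`) of the node
   placement toward both walls, resolving the wall shear layers; the
   throat always carries the full `ny` cells because the map interpolates
   between the wall profiles.
3. **Winslow elliptic smoothing with Thomas–Middlecoff control functions**
   bends the interior grid lines toward wall orthogonality while the
   control functions preserve the boundary clustering. Without it the
   transverse grid direction is nearly tangent to a steep ramp face and the
   wall-vorticity closure degrades there. The sweep loop checkpoints the
   mesh and stops before the discrete Jacobian at any boundary node
   degrades past a safety factor, so the output mesh is always valid —
   partially smoothed if necessary.

All mapping metrics are evaluated **discretely**, with the same stencils
that act on the solution: the discrete $\partial/\partial x$ applied to the
coordinate fields returns exactly 1 and 0 ("freestream preservation"), so
steep, curved walls inject no spurious momentum sources. Second derivatives
use compact central stencils; composing first-derivative operators instead
leaves weakly damped odd–even modes that show up as node-to-node noise in
the shear field (this was observed, not conjectured). One-sided stencils
close the boundaries at second order, except the no-slip row, which uses a
third-order one-sided stencil because it sets the wall vorticity and hence
every reported WSS value.

## Post-processing

Streamlines are integrated with fixed-step RK4 (bilinear velocity
interpolation on the curvilinear mesh, cell located by walking); the step is
a quarter of the local cell size — a global minimum step would waste two
orders of magnitude of work in the entrance run. The platelet trajectory is
found by bisection on the inlet seed ordinate until the traced line's
minimum distance to the apex-bearing wall equals the 1 µm clearance (half a
platelet diameter) within 0.05 µm; the streamfunction level through the
point 1 µm above the apex provides a near-exact initial bracket. Peaks are
refined by a parabola through the three samples around the discrete
maximum, with ties broken toward the apex. The shear-rate gradient is
reported as $d\gamma/dx$ (per µm of axial distance), matching the axis
convention of shear-history plots; WSS is reported in both Pa and dyn/cm²
(1 Pa = 10 dyn/cm²). In 2D the experimental seeding rule "1 µm above the
apex, 30 µm from the floor" collapses to the apex-clearance rule alone;
this is an approximation of the 3D protocol.

## Verification

The `verification_report()` battery and the test suite check, among others:

* plane-Poiseuille oracle: velocity and wall shear within 1% at `ny = 64`
  (uniform grid), mass imbalance at round-off;
* exact mirror symmetry of concentric solutions (at the $10^{-6} U$ level);
* creeping-flow linearity: scaling $\gamma_0$ by 20 scales the fields by 20
  within 3% (the residual is genuine convective nonlinearity, Re reaches
  ~1.6 at $\gamma_0 = 3000$ 1/s);
* grid convergence with refinement ratio 2 on the smooth oracle: observed
  order ≈ 2 with Richardson extrapolation recovering the exact wall shear
  to 0.2%. On the stenotic case the C¹ (curvature-jumping) walls and peak
  extraction reduce the observed order; the sequence remains monotone with
  shrinking differences and the convergence report flags non-asymptotic
  sequences instead of failing.

## Problem sizes

Defaults were chosen as the smallest resolutions at which the reported
contrasts are grid-stable: parametric-study runs use 192×48 cells; the
quantitative eccentric-vs-concentric contrasts use 240×60 (the
placement contrasts change by under 1 percentage point between 192×48,
240×60 and 288×72); the mesh-sensitivity default triple is
(128×32)–(512×128). The test suite runs reduced grids (96×24 – 144×36)
where only behavior, not accuracy, is under test.

## What the model does and does not capture

The 2D model reproduces the in-plane mechanics: the ~20-fold linear scaling
of peak shear with $\gamma_0$, the super-exponential growth of peak shear
beyond $S = 70\%$, the insensitivity of peak shear to $\alpha$ alongside the
strong $\alpha$-dependence of the upstream acceleration zone, the
indistinguishability of GPL and Newtonian blood above ~1000 1/s, and the
eccentric-vs-concentric contrast in the platelet-streamline peak shear
(about 11% at desk resolutions). The corresponding peak-WSS contrast
converges near 12% in plane flow; a real rectangular duct spreads part of
the wall stress onto its ceiling and floor, which the plane model cannot
represent, so three-dimensional channels can show a smaller WSS contrast
between placements. The model also does not capture: absolute 3D peak
values at production resolutions (the ceiling and floor shave the midplane
peaks), pointwise field linearity in the slow wake regions at the top of
the $\gamma_0$ range (peaks scale to within 3% at 20-fold flux scaling;
near-stagnant structures shift by more), pulsatility, deformable or
particle-resolved blood elements, and viscoelastic stresses. Those belong
to full 3D solves outside desk scope.

## A worked example

```{r}
library(stenoflow)

geom <- stenosis_geometry(S = 0.8, alpha = 85, placement = "eccentric")
grid <- generate_grid(geom, nx = 192, ny = 48)
flow <- solve_flow(geom, blood_newtonian(), gamma0 = 2000, grid)
map  <- shear_rate_field(flow)
prof <- platelet_trajectory_profile(flow, map)
peak_summary(prof, map)

plot(prof$x_um, prof$gamma_s, type = "l",
     xlab = "x (um)", ylab = "shear rate (1/s)")
```
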