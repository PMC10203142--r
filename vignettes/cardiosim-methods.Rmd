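---
title: "Models and numerical methods in cardiosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in cardiosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiosim)
```

cardiosim is a desk-scale toolkit for the three coupled physics of the
beating heart — electrophysiology, tissue mechanics and hemodynamics —
plus the synthetic surface ECG and the statistics of in-silico trial
cohort sizing.  "Desk scale" is a design commitment, not an apology:
every solver runs on one CPU in seconds to minutes on synthetic
geometries (cables, sheets, slabs, an idealized ventricle, a membrane in
a channel), and every physical claim the package makes is backed by a
test against an independent oracle (closed forms, finite-difference
gradients, step-halving, analytic PDE solutions).  Whole-organ
anatomical meshes, hundred-million-node grids and GPU execution are out
of scope.

# Electrophysiology

## Membrane models

The action potential of a cardiac cell is described by an ionic model
`ds/dt = F(s, v)` coupled to the transmembrane potential `v`.  The
registry ships:

* **`minimal`** — a dimensionless two-variable polynomial
  (Aliev–Panfilov-type) model,
  `dv/dt = k v (v - a)(1 - v) - v r + I`, with the recovery variable
  `dr/dt = (gamma + mu1 r / (mu2 + v)) (-r - k v (v - b - 1))` and the
  classical constants `k = 8, a = b = 0.15, gamma = 0.002, mu1 = 0.2,
  mu2 = 0.3`.  Its clock and amplitude are dimensionless; the
  conventional rescaling (1 time unit = 12.9 ms, 100 mV amplitude above
  a −80 mV rest) is available through the `t_scale` parameter.
* **`atrial`, `ventricular`, `purkinje`** — dimensional two-variable
  gate models with Mitchell–Schaeffer-type kinetics.  These are
  *synthetic stand-ins* for the biophysical atrial, ventricular and
  Purkinje formulations used by whole-heart codes: those models' full
  equation sets are not reproduced here, so the surrogates instead match
  tissue-typical resting potentials (−81 / −86 / −69 mV), amplitudes and
  APD90 ordering (≈ 250 / 300 / 380 ms).  Each carries a true gating
  variable in [0, 1], so the Rush–Larsen exponential update path is
  exercised exactly as it would be by a biophysical model.

Time integration uses the Rush–Larsen rule for gates (exact for the
piecewise-constant rates of the surrogates) and forward Euler for all
other states, with defaults of 0.02 ms (dimensional) and 0.1 (minimal).
Tests verify rest-state fixed points, gate bounds, first-order
self-convergence and step-halving consistency against a fixed-step RK4
oracle of the same right-hand side.

## Active tension

Contractile stress follows the two-level switching linear relaxation
`dTa/dt = eps(v) (k_Ta v - Ta)` on the normalized potential, with
`eps = eps0` below `v* = 0.05` and `eps1` above.  The constants are not
universal; the single-cell defaults are `eps0 = 1, eps1 = 10,
k_Ta = 47.9 kPa` and every consumer states its own values.  The
closed-form step response `Ta(t) = k_Ta (1 - exp(-eps1 t))` is a test.

## Tissue propagation

Propagation is solved with a cell-centred two-point-flux finite-volume
method.  Orthotropic conductivity tensors are assembled per cell from
the fiber/sheet/normal triad,
`M = m_par e_f e_f' + m_sheet e_s e_s' + m_normal e_n e_n'`; the flux
across a face combines the two face-normal components harmonically.  In
monodomain mode the diffusion step is implicit (unconditionally stable,
one cached sparse Cholesky per time step size); bidomain mode adds the
gauged elliptic solve for the extracellular potential (zero-mean
Lagrange multiplier, cached sparse LU) and treats its contribution to
the parabolic step explicitly.  Outer boundaries are zero-flux
everywhere.  Operator splitting is first-order (reaction then
diffusion).

The surface-to-volume ratio and membrane capacitance enter only through
the product `chi*Cm`, which the source tables do not print; it is a
single calibration scalar per tissue.  `calibrate_chi_cm()` bisects it
(log scale) against a stated conduction velocity on a 20 mm / 0.1 mm
cable.  The headline check of the whole EP stack is a *transfer*
experiment: calibrate on the atrial-equivalent cable (harmonic-mean
conductivity 0.1414 mS/mm) to 0.5 m/s, re-run the identical setup with
the internodal-bundle conductivity 1.29 mS/mm, and compare the measured
velocity with the independently tabulated 1.54 m/s.  Pure diffusion
scaling predicts `0.5 sqrt(1.29/0.1414) = 1.51 m/s`; the measured value
(≈ 1.506 m/s) agrees with the tabulated speed to ≈ 2%.

## Conduction system

The fast conduction network is a graph of slender 1D bundles (internodal
pathway, AV node, His bundle, left/right branches) meshed as chains of
finite-volume cells and coupled to a host myocardial mesh only at
insertion cells.  Geometry is not printed in any source table, so the
defaults are desk-scale choices, all configurable: 0.1 mm² bundle
cross-section (thick enough that a plateau-phase bundle can source the
current a myocardial cell needs to ignite), an 8 mm AV segment at
0.025 mm resolution (so the ~100 ms transit delay is reachable by
lowering conductivity without triggering discrete conduction block), and
insertion junctions distributed over a 5-cell patch with 1 mm² coupling
area per cell — a stand-in for the arborized Purkinje–myocardial
junction.  `calibrate_av_delay()` bisects the AV conductivity to a
target transit delay (default 100 ms).  Conduction block switches
disable every face of a named segment; `lbbb_crt_study()` packages the
intact / left-branch-block / resynchronization comparison on a
two-ventricle sheet and reproduces the qualitative ordering
`intact < CRT < LBBB` of the activation-spread duration.

One ionic model spans a composite mesh (host + network); regions differ
by conductivity only.  This is a deliberate desk-scale simplification —
per-region membrane models would multiply the surrogate-model burden
without changing what the propagation tests establish.

# Tissue mechanics

The structure is a spring network: lumped-mass nodes and linear
elements — segments (2D membranes seen edge-on), triangles (membranes)
and tetrahedra (walls) — each storing its rest metric.  The constitutive
law is the orthotropic exponential (Fung) strain energy
`W = c/2 (exp(Q) - 1)`, `Q = a_par e_par^2 + a_sheet e_sheet^2 +
a_normal e_normal^2` in Green strains along the material triad.  Nodal
forces are the *exact* analytic gradient of the assembled energy on
linear elements (first Piola stress contracted with the rest-shape
inverse), verified against a central finite-difference oracle at 1e-6
relative — an energetically consistent stand-in for interaction-
potential spring discretizations whose constants are not published.
Active contraction adds a uniaxial Cauchy-like tension `Ta` along the
deformed fiber direction with the rest-area convention; it is
momentum- and torque-free per element by construction.

Dynamics is the per-node Newton equation advanced by a two-step
Adams–Bashforth update (velocity then position), with optional linear
velocity damping.  AB2 is not symplectic but its phase and energy errors
at the tested resolutions (period within 1%, energy drift < 1% over ten
periods at dt = T/1000) are far below the modelling error.  Tetrahedral
force assembly is vectorized (batch linear algebra plus `rowsum`
scatter), which is what makes sub-millisecond structural steps viable in
R.

Tissue density defaults to 1060 kg/m³ (blood-like), configurable.

# Hemodynamics

Blood (ρ = 1060 kg/m³, μ = 3.5 mPa·s Newtonian by default; a
Carreau–Yasuda shear-thinning law is available) obeys the incompressible
Navier–Stokes equations on a 2D staggered (MAC) grid: explicit
Adams–Bashforth convection, implicit Crank–Nicolson viscosity, and an
incremental pressure projection whose Poisson solve is gauged to zero
mean.  The discrete divergence after projection is at machine precision;
Taylor–Green decay is reproduced to 0.003% at 64² and the spatial order
is ≈ 2.  The fluid is 2D only: every fluid-side verification target
(Taylor–Green, Poiseuille, MLS reproduction, membrane coupling) is
two-dimensional, and the hydrostatic closed-surface load check uses the
2D analogue (a circle, resultant ρgA per unit depth).  Small-3D was
considered and dropped as pure surface area: nothing in the desk-scale
acceptance set exercises it.

Moving boundaries use moving-least-squares (MLS) immersed-boundary
transfer: linear-basis MLS with a compact quartic kernel over a
3-cell-wide support interpolates grid fields to markers (constants and
linears exact), and spreading is the scaled transpose, so the discrete
interpolation/spreading pair satisfies the inner-product identity to
machine precision and preserves the total transferred force.  Direct
forcing solves the small marker-coupling system exactly on the
provisional velocity, so the no-slip targets are met before projection;
the residual slip on a 64² flat-plate test is ≈ 3% of the free stream.
Hydrodynamic loads are probed at ±1.5 grid spacings along the marker
normals (two-sided jump for membranes, one-sided for closed surfaces);
the sampled pressure is corrected back to the surface with the local
pressure gradient, removing the first-order curvature bias (without it,
a circle of radius R picks up an O(h/R) systematic error).

Windkessel outlets are volume forcings over masked subdomains,
`-f_WK = alpha u + beta int u dt + gamma n`, with trapezoidal history
integrals stored in the flow state (reset per run) and constants from
the built-in registry.

# Coupling

Loose coupling solves fluid (and EP) first with the previous-step
structural kinematics and then advances the structure under the
resulting loads — cheap, first-order, conditionally stable (an energy
blow-up detector aborts with a diagnostic).  Strong coupling wraps an
Adams–Bashforth predictor with corrector iterations that re-solve the
flow against the updated structural kinematics until the maximum
relative change of node positions *and* velocities falls below the
tolerance (default 1e-4).  The corrector is stabilized by Aitken dynamic
under-relaxation; convergence speed is governed by the structure/fluid
added-mass ratio.  The membrane-in-channel fixture therefore uses a
10 mm myocardium-like flap (ρ_s t ≈ 10.6 kg/m²): that is the inertia
regime of a whole-heart wall, where the corrector settles at 3
iterations with strictly decreasing residuals; a 1.5 mm leaflet would
sit in the added-mass-dominated regime and need ~7.  Strong and loose
agree to O(dt) on this fixture.

The dry electromechanics driver (`run_heartbeat(type = "electromech")`)
couples EP, active tension and mechanics on the idealized ellipsoidal
ventricle and evaluates the ECG, but runs *without* a blood pool.  With
no afterload, full-rate 47.9 kPa tension inverts elements, so the driver
defaults to gentler kinetics (k_Ta = 15 kPa, eps = 0.01/0.05 per ms) and
mass-proportional damping with a 10 ms relaxation time; all are config
fields.  Full three-way coupling with fluid is exercised on the 2D
membrane fixture.

# Synthetic ECG

Under the isotropic-torso assumption the electrode potential is the
infinite-medium lead-field integral
`V_s = -K \int grad(v) . grad(1/|x - x_s|) dx` over the cardiac domain,
evaluated by one-point quadrature per finite-volume cell with
least-squares gradient reconstruction.  `K` lumps the unknown
conductivity ratio and defaults to 1 (arbitrary units); only relative
amplitudes and timings are meaningful, and only those are tested.  Leads
must stay at least 5 cell sizes clear of the tissue.  The default torso
pair sits 35 mm outside the mesh along the heart's vertical axis (the
average heart-to-skin distance), lead 1 basal and lead 2 apical, so
wavefronts travelling apexward deflect the difference negative.  A
propagating-front dipole on a cable matches the point-dipole closed form
`p/r²` to well under 5% in the far field and decays with exponent
2.00 ± 0.01.  QRS-like durations come either from the activation map
(last minus first ventricular activation) or from the trace (span above
5% of the beat maximum; threshold configurable).

# In-silico trial sizing

The cohort calculators implement the printed error models: plain Monte
Carlo `1/sqrt(N)`; Latin-hypercube `C/sqrt(N)` with `C <= 1`;
quasi-random `1/N^alpha`, `alpha` in [1/2, 1]; rare events of
probability p, `1/sqrt(pN)` for plain MC and
`sqrt(log10(1/p)^2 / N)` for Subset Simulation.  The logarithm base is
not stated in the source; base 10 is chosen because it reproduces the
canonical comparison exactly (p = 10⁻², 10% uncertainty: 10 000 patients
by plain MC, 400 by Subset Simulation — and `cohort_size()` returns both
integers exactly, as does N = 400 at 5% and N = 10 000 at 1% for plain
MC).  `cohort_size()` is the exact integer inverse of
`sampling_error()`, tested as such.  A published worked example for the
combined LHS/QMC setting (C = 0.08, alpha = 0.7 giving N = 50/500) does
not follow from the printed formulas; the formulas are implemented as
printed and that example is deliberately not asserted.

# What the synthetic fixtures do and do not establish

The generators (`make_fixture()`) emulate the *mechanisms* of the
whole-heart model — orthotropic propagation with transmural fiber
rotation from +60° to −60°, hierarchical conduction with an AV delay,
Fung-elastic walls contracting along fibers, pressure-driven flow
against Windkessel afterloads, far-field ECG — on geometries small
enough that every run fits in a test.  They do not emulate anatomical
chamber shapes, valve contact, transmembrane heterogeneity, or the
closed circulatory loop; a green test here establishes that the
numerics are faithful to the stated models at desk scale, not that the
package reproduces clinical ejection fractions or pressure traces.
Those whole-organ indicators require the full-resolution anatomical
model and are explicitly outside this package's claims.

# Numerical choices and degenerate inputs

* Activation time: first upward crossing of 0 mV (minimal model: 0.5),
  linearly interpolated within the step.
* CV measurement: least-squares slope of position on activation time;
  simultaneous activation or unactivated probes are errors, not NaNs.
* Bisection calibrations run on a log scale with a relative tolerance of
  1e-4 (CV) / 2e-2 (AV delay); unbracketed targets are errors.
* Fung energy overflows (`Q > 700`) and inverted elements (negative
  Jacobian) abort with diagnostics rather than propagate Inf/NaN.
* The atrial bidomain tensors are *not* proportional across axes, so
  atria default to full bidomain; 1D tests may use the harmonic-mean
  monodomain equivalent, which matches bidomain CV to < 1% on a cable.
* MLS moment matrices are checked for conditioning; markers outside the
  fluid fail loudly.
* All fixture generation is pure: identical spec + seed gives identical
  objects, tested byte-for-byte through the VTK writer.

# Known limitations

Single membrane model per mesh; 2D fluid; first-order operator
splitting and loose coupling; no valve contact mechanics, no
Holzapfel–Ogden law, no torso volume-conductor ECG, no closed-loop 0D
circulation — the latter four are future work also in the whole-heart
modelling literature this package mirrors at desk scale.
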