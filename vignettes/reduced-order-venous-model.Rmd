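---
title: "A reduced-order model of cerebral venous sinus pressure and flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced-order model of cerebral venous sinus pressure and flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sinusflow)
```

## The model

`sinusflow` treats the cerebral venous sinus system as a lumped-parameter
hydraulic network. Two inlets — the superior sagittal sinus (SSS) and the
straight sinus (StS) — meet at the torcula; the combined flow splits into
the left and right transverse (TS), proximal sigmoid (PSS), distal sigmoid
(DSS) and internal jugular vein (IJV) chains, which drain to outlets held
at gauge pressure zero. Each segment loses pressure through two
mechanisms:

* **Distributed friction** (Darcy–Weisbach): $\Delta P = f \frac{L}{D}
  \frac{\rho V^2}{2}$ with $f = 64/\mathrm{Re}$ for $\mathrm{Re} \le 2300$
  — where the drop reduces algebraically to the Poiseuille form
  $32 \mu L V / D^2$, linear in flow — and the Blasius correlation
  $f = 0.316\,\mathrm{Re}^{-1/4}$ above. The friction factor is
  discontinuous at the regime switch; we accept this, as the sweeps of
  interest stay almost entirely laminar (segment Reynolds numbers are a
  few hundred at physiological flows) and the quadratic behaviour is
  carried by the minor losses either way.
* **Bend/minor losses**: $\Delta P = K \rho V^2 / 2$, quadratic in flow.
  Bends use the classical smooth-bend correlation
  $K = \left(0.131 + 0.159\,(r/D)^{-3.5}\right)\,\theta/90$
  in bend angle $\theta$ (degrees) and radius-to-diameter ratio $r/D$;
  segments may carry extra $K$ values for junction or expansion losses
  (the jugular bulb gets $K = 0.5$ by default).

In the laminar regime a segment's drop is exactly $a_{seg} Q + b_{seg}
Q^2$, so the system-level pressure–flow relationship is quadratic by
construction — the network is a mechanistic surrogate for full 3D CFD,
reproducing the pressure–flow law without resolving the velocity field.

The left/right split is found by bisection on the left flow fraction so
the two parallel torcula-to-outlet drops agree to $10^{-9}$ relative
(branch drops are strictly increasing in branch flow, so the root is
unique; the solver is capped at 200 bisections). Mass conservation holds
by construction and is verified to $10^{-12}$ in the tests; on bend-free
(purely laminar) trees the solution reproduces the electrical
series/parallel closed forms to $10^{-9}$.

### Calibration

Bend-loss correlations for blood-carrying sinuses are not measurable
directly, so the network keeps one free parameter: a global scalar
multiplying every segment's minor-loss coefficients. `calibrate_tree()`
sets it so the solved system drop at a reference flow matches a reference
drop — by default the literature anchor of 4.5 mmHg at 620 mL/min (mean
sagittal flow in young patients). Friction terms are never rescaled.
Calibration is infeasible (and errors out) only if friction alone already
exceeds the reference drop. After calibration the model crosses the
IIH-inducing 8.3 mmHg drop near 880 mL/min; the steeper-than-measured
crossing reflects that the single-scalar calibration concentrates all the
measured drop onto the quadratic term. The cohort-average CFD-like curves
emulated by the surrogate generator (below) instead cross near 1500
mL/min; the two parameterisations bracket the plausible range, and every
conclusion the package draws (quadratic shape, threshold existence,
linear-model insufficiency) holds under both.

## Units and conventions

Internals are SI (m, Pa, m³/s); all user-facing interfaces accept and
emit mm, mmHg and mL/min, with 1 mmHg = 133.322 Pa and 1 mL/min =
$\tfrac{1}{60}\times10^{-6}$ m³/s. Cohort summary statistics use the
sample (n−1) standard deviation — the convention that reproduces the
published per-sinus SD row from the per-patient diameters (the distal
sigmoid SD of 2.45 mm only emerges with n−1). Fluid defaults are blood at
1055 kg/m³ and 0.0035 Pa·s; the straight sinus carries 30 % of the
sagittal flow; the flow sweep is 200–2000 mL/min in ten steps.

## The quadratic fit

`pq_fit()` fits $\Delta P = aQ + bQ^2$ by least squares. The intercept is
constrained to zero by default because $\Delta P(0)=0$ physically; a free
intercept is available since trend-line conventions vary. Goodness of fit
is reported as the Pearson correlation $r$ between fitted and observed
drops — with zero-intercept fits this differs from $R^2$, and the
correlation is the statistic conventionally quoted for such trend lines;
$R^2$ is emitted alongside. A fitted $b<0$ (concave curve) triggers a
warning, filtered through a roundoff guard so exactly-linear data fit
without complaint. `threshold_flow()` inverts the fit by the quadratic
formula; an optional `max_flow` lets a shallow linear model report the
threshold as unreachable (`Inf`) over a bounded physiological range,
which is how the constant-resistance reference behaves.

## Vorticity metrics

The planar curl $\omega = \partial v/\partial x - \partial u/\partial y$
(1/s) is evaluated on a masked regular grid: central differences where
both neighbours are in the lumen, first-order one-sided differences at
the mask boundary, and exclusion of points with no in-mask neighbour in
some direction. On linear fields (solid-body rotation, uniform shear)
both stencils are exact, so a rotation at rate $\Omega$ returns $2\Omega$
at machine precision regardless of resolution; on smooth fields the error
falls off at second order in the spacing.

The sectional statistic `average_curl()` is the mean of $|\omega|$ over
the lumen. The magnitude convention is deliberate: the reported sectional
averages are positive and grow monotonically with flow, whereas a signed
mean over a counter-rotating vortex pair would cancel toward zero. A
`signed = TRUE` option provides the signed normal component for users who
want it. Section placement (e.g. 1.5 cm below the sigmoid outlet, where
jugular-bulb vorticity is measured) is metadata on the plane; the module
analyses whatever plane it is given.

## Intracranial pressure coupling

Davson's equation $ICP = FR_{csf} R_{out} + SSS_p$ composes with the
venous Ohm analog $SSS_p = TCBF \cdot R_{ven} + CVP$. The network's
system drop maps onto the $TCBF \cdot R_{ven}$ term, so a quadratic fit
supplies a flow-dependent resistance $R_{ven}(Q) = a + bQ$ and makes ICP
strictly convex in flow; a constant `r_ven` gives the classical linear
model. The IIH criteria block defaults to the paediatric scenario:
baseline ICP 14.6 mmHg, required increase 3.8 mmHg, baseline venous drop
4.5 mmHg, hence a required drop of 8.3 mmHg; the diagnostic ICP
definition of 18.34 mmHg is carried verbatim even though baseline + delta
is 18.4 — the 0.06 mmHg inconsistency is in the source constants, and we
do not reconcile it. CSF formation rate and outflow resistance have no
cohort-measured values; they are user-supplied, and `icp_threshold_flow()`
only requires that the CSF and central-venous terms jointly complete the
baseline. Cross-module consistency — the flow at which ICP reaches the
IIH level equals the flow at which the fitted curve reaches 8.3 mmHg — is
tested to $10^{-6}$ relative. Cohort fractions (`proportion_above`) use
strict inequality ("above") and integer-rounded percentages, matching the
13/42 = 31 % reporting style.

## The synthetic-data generator

The generator defines the study conditions the tests run under; it
emulates three things:

* **Geometries** (`generate_tree`): per-sinus diameters drawn from
  truncated normals (floor 1 mm, preventing unphysical lumens) with the
  measured cohort statistics — SSS 5.49 ± 0.43, TS 6.28 ± 1.19, PSS 7.77
  ± 0.82, DSS 8.21 ± 2.45 mm — and lengths SSS 107.8 ± 11.5, StS 42.9 ±
  2.3 mm. Left and right branches are drawn independently (anatomy is
  asymmetric). The straight-sinus and jugular diameters (5.0 ± 0.5, 8.0 ±
  1.0 mm) and the transverse/sigmoid/jugular lengths (50/40/40/30 mm,
  SD 0) are not cohort-measured; they are plausible fixed defaults,
  exposed in `cohort_spec()`.
* **Velocity planes** (`generate_velocity_plane`): a circular lumen with
  solid-body in-plane swirl whose rim speed is `swirl` times the mean
  axial velocity, giving the closed-form average curl
  $2\,\mathrm{swirl}\,V/R$ against which the finite-difference pipeline
  is validated.
* **CFD-like series** (`generate_surrogate`): drops $(aQ+bQ^2)(1+
  \varepsilon_p)$ and curls $c\,Q^\gamma(1+\varepsilon_c)$ with Gaussian
  multiplicative noise. Noise is multiplicative, not additive: it
  preserves positivity and matches the relative-error character of a
  converged CFD solution (validation errors below 3 %). Defaults:
  $a = 0.003$ mmHg/(mL/min), $b = 1.5\times10^{-6}$ mmHg/(mL/min)²,
  chosen so the curve crosses the 8.3 mmHg threshold near 1500 mL/min
  (the observed cohort-average crossing); $\gamma = 1.4$, the midpoint of
  the 1.2–1.6 range bracketing the measured per-patient curl growth over
  the five-fold flow increase; $\sigma_p = 0.02$, $\sigma_c = 0.05$.
  A quadratic through the calibration anchor (620 mL/min, 4.5 mmHg)
  cannot also cross 8.3 mmHg as late as 1500 mL/min — the two anchors are
  mutually inconsistent for any convex $aQ+bQ^2$ — so the surrogate
  defaults honour the crossing and the network calibration honours the
  anchor.

All generators are bit-reproducible under their integer seed and restore
the caller's RNG state. What the surrogate does **not** emulate: secondary
flow structure, patient-specific vessel curvature, wall compliance,
pulsatility, non-Newtonian rheology, or cortical vein inflow. Passing
tests therefore demonstrate the statistical machinery and the network
model's internal consistency, not agreement with any individual patient's
3D flow field.

## Numerical choices

* **Mask perimeter** (for hydraulic diameter from pixel masks): the
  marching-squares contour length of the 0.5 level set (via base R's
  `contourLines`), computed on a box-smoothed copy of the binary mask
  with the number of smoothing passes scaled as the square root of the
  lumen's equivalent radius in pixels. Contouring the raw binary mask
  carries a ~6 % orientation-dependent digitisation bias that does not
  vanish under refinement; the resolution-scaled smoothing restores
  convergence (measured error < 0.3 % on disks of 25–200 px radius and on
  a 2:1 ellipse). A perimeter below the isoperimetric bound is clamped to
  it, since no planar shape can violate it.
* **Tolerances**: flow-split bisection to $10^{-9}$ relative on the
  branch-drop mismatch; calibration root-finding (`uniroot`) to
  $10^{-12}$; ICP threshold root-finding to $10^{-10}$.
* **Degenerate inputs**: single-pixel and disconnected masks, empty
  sweeps, duplicate flows (rank-deficient designs), zero-variance
  correlation inputs and sub-3-point fits all raise informative errors
  rather than returning numbers.

## Problem sizes

The test suite and the acceptance script run on the scale of the study
itself: 5–10 point flow sweeps per patient, cohorts of 2–5 trees (1000
single-segment draws for the distributional check), velocity grids of
41–161 points per side, and 20 replicate surrogate patients for the
correlation minima. The full suite completes in well under a minute on a
single CPU.

## Limitations

The network model shares the assumptions of the steady, rigid-wall,
Newtonian CFD it stands in for, and adds its own: one representative
diameter per segment, a correlation-based bend loss with a single global
calibration scalar, and no secondary-flow coupling between segments. The
curl module analyses planes it is given (or synthetic swirl planes); it
does not predict vorticity from the network state. These are the right
trade-offs for a desk-scale surrogate whose purpose is the shape of the
pressure–flow law and its ICP consequences, not patient-specific
hemodynamic prediction.
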