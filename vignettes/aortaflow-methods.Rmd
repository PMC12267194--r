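---
title: "Shape-model driven reduced-order hemodynamics of VA-ECMO: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-model driven reduced-order hemodynamics of VA-ECMO: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`aortaflow` studies how thoracic-aorta morphology interacts with
veno-arterial extracorporeal membrane oxygenation (VA-ECMO). During
peripheral VA-ECMO, oxygenated pump blood returns retrograde through the
descending aorta while the weakened ventricle still ejects antegrade; the
two streams meet at a *watershed zone* whose axial position decides which
supra-aortic branches — and hence the brain and upper body — receive which
blood. The package chains four stages: a synthetic, point-corresponded
aortic population; a PCA statistical shape model (SSM) with mode/SD
augmentation; centerline morphometry over the seven characteristic tracts;
and a lumped (0D/1D) hemodynamic model with three-element Windkessel
outlets, ECMO-fraction transport and watershed localization.

## 1. The synthetic population

No public corresponded aortic cohort exists, so the package generates its
own. Each subject is a swept-tube surface built from an anatomical
parameter set (`aorta_params()`): a straight ascending segment, a
circular-arc arch with an out-of-plane sinusoidal (`sin^2`) perturbation
that creates torsion, a straight descending segment with a linearly
tapering lumen, and three supra-aortic branches (BCA, LCCA, LSA) whose
centerlines blend from the local radial direction to a cranial direction.
Circular rings (48 samples each, 360 rings on the main vessel and 54 per
branch by default) are swept along the centerlines with a
parallel-transported frame, giving 25,056 surface points per subject — a
node budget of roughly 25,000, matching the scale of registered CT surface
meshes this emulates.

Defaults were chosen once so that the template's tract morphometry falls in
the range reported for healthy adults: ascending tract about 90 mm, arch
about 36-38 mm, descending about 125 mm, root radius 16 mm tapering to
about 12 mm, branch radii 6.3 / 3.4 / 5.3 mm, and a bovine-arch (shared
BCA/LCCA origin) prevalence of 15%. Per-subject variation is
truncated-normal at +/-3 coefficients of variation (CV about 5-10% for
lengths and radii, 30% for the torsional amplitude). Truncation at +/-3 CV
makes parameter validity a design property rather than a rejection loop:
the default CVs are small enough that no draw can reorder the branch
origins or push a branch radius past the root radius, and the sampler
verifies this on every draw.

Two things the generator deliberately does *not* emulate: non-circular
(oval, dilated) cross-sections, and the registration noise of real
template-to-subject correspondence. Correspondence here is exact by
construction — every subject shares one ring/sample layout, so point *i*
always sits at the same parametric location. Passing tests therefore
validate the algorithms on geometrically clean, perfectly corresponded
data; they do not certify robustness to registration error on real CT
meshes.

## 2. The shape model

`fit_pca()` is a plain sample-covariance PCA of the flattened coordinate
rows: mean shape, then modes and eigenvalues from the SVD of the centered
matrix with divisor *n* - 1. Three conventions are fixed because they
affect reproducibility:

* **Mode count.** All `n_subjects` components are retained by default, so a
  19-subject fit exposes 19 modes even though the centered matrix has rank
  18 and the last eigenvalue is numerically zero. This keeps the
  traditional "19 meshes, 19 modes" bookkeeping and makes the default
  augmentation scheme (which sweeps modes 0-18) well defined; sweeping the
  rank-deficient mode reproduces the template.
* **Sign convention.** Each mode is flipped so its largest-magnitude
  loading is positive; SVD signs are otherwise arbitrary and would scramble
  mode/SD labels between runs.
* **Labels.** Synthesized shapes are labeled `m<k>_sd<+/-v>` (0-based mode
  index, SD multiplier); labels parse back to their generating pair.

New shapes are `mean + sum_i sd_i sqrt(lambda_i) phi_i`. The default
augmentation scheme takes unit SD steps (-3..+3 without 0) for modes 0-4,
the +/-3 extremes for modes 5-7, and +3 only for modes 8-18: 47 novel
shapes, 48 geometries with the template. Later modes each explain under 1%
of variance, so denser sweeps there change little. SSM-generated shapes
inherit the template ring layout, which is what lets centerlines and ostia
propagate automatically.

## 3. Centerline morphometry

For the swept-tube geometry class, the centerline point of a ring is
exactly the centroid of its surface samples, and the maximal inscribed
sphere radius is the minimum centroid-to-ring distance.
`centerlines_from_geometry()` therefore replaces Voronoi-style
skeletonization with the ring-centroid rule — exact here, and testable
against the generator's stored ground truth (the tests require agreement
within half a local radius; observed agreement is at rounding level).

`split_tracts()` cuts the aortic centerline at the ostium projections into
ascending / arch / descending, which together with the three branches and
the total aorta gives the seven characteristic tracts. Boundary choices
worth knowing:

* Tract boundaries sit at the main-centerline points nearest each branch
  origin (ostium projection), not at inscribed-radius jumps.
* A bovine arch legitimately collapses the BCA-LCCA boundary; mode sweeps
  of a population mixing bovine and standard anatomies can also project the
  LCCA ostium marginally outside the [BCA, LSA] window, and the projection
  is then clamped to that window (shared-origin semantics). Explicitly
  supplied out-of-order ostia still fail loudly.

`compute_features()` reports the five quantities per tract: length,
tortuosity (length over endpoint chord, hence >= 1 by construction), and
mean/SD of inscribed radius, curvature and signed torsion. Curvature and
torsion use discrete Frenet formulas (central differences in arc length)
on a moving-average-smoothed copy of the polyline — discrete third
differences amplify noise, so smoothing is on by default with a 5-point
window, recorded in the output. Three numerical guards matter:

* the smoothing window tapers *symmetrically* near the ends (an asymmetric
  window drags boundary points sideways and manufactures spurious torsion);
* estimates whose stencil touches the tapered boundary are dropped from the
  tract statistics;
* torsion is set to zero where curvature < 1e-6 /mm, since the osculating
  plane is undefined on straight runs.

On analytic fixtures the estimators recover a semicircle's tortuosity
pi/2 to 1e-4 and a helix's curvature a/(a^2+b^2) and torsion b/(a^2+b^2)
to under 1% at 200 samples, converging at second order.

Percent differences from the template
(`compare_to_template()`) switch to absolute differences whenever the
template value is below 5% of the largest magnitude in that (tract,
quantity) cell — signed torsion of a near-planar tract has a near-zero
template value, and ratios against it would be meaningless.
`select_representatives()` ranks single-mode shapes from modes below
`mode_limit` by their maximum absolute percent deviation across all cells
(ties broken lexicographically, so selection is deterministic); this
max-deviation criterion is the package's concrete reading of "most
representative of the morphological changes induced by the modes". The
three result planes sit at 85% of the ascending tract and 10% / 90% of the
descending tract, with the local Frenet tangent as plane normal.

## 4. The hemodynamic model

The full 3D incompressible Navier-Stokes problem is deliberately replaced
by a reduced-order analogue sized for a desk: a resistive network with
Windkessel outlet ODEs and 1D scalar transport. The RCR outlet relation and
the cycle-mean flow definition are implemented exactly; everything tied to
3D flow structure (streamlines, total-pressure extremes, jet impingement)
is outside this model's reach and is treated as ordering/band properties
only.

**Network.** Nodes at the root, the three ostia and the descending end;
each segment's resistance is the Poiseuille value 8 mu L / (pi r^4) from
the tract's length and mean inscribed radius, with blood density 1060
kg/m^3 and dynamic viscosity 3.5e-3 Pa s. (The viscosity is used as
*dynamic* viscosity: Poiseuille resistance is dimensionally consistent only
with Pa s.)

**Windkessel outlets.** Each outlet integrates C dPd/dt = Q - (Pd - P0)/Rd
with outlet pressure P = Pd + Rp Q and time constant tau = Rd C. The
standalone stepper uses an exact exponential update (equivalent to the
convolution form of the RCR relation, which the tests verify to 1e-4);
inside the network solver the outlet ODEs are eliminated into the nodal
conductance matrix with a backward-Euler step, so each timestep solves a
small linear system exactly and instantaneous mass conservation holds to
solver precision (~1e-12). The venous reference P0 is 0.

**Inflow.** The cardiac waveform is a rectified two-term sinusoid: ejection
over 40% of the 0.8 s cycle with a 15% second harmonic (which skews the
upstroke without changing the cycle mean), zero diastolic inflow. Healthy
runs are scaled to a 5 L/min cycle mean; cardiogenic shock is a uniform
70% cardiac-output reduction (1.5 L/min). Scaling is multiplicative and
exact.

**Calibration.** The paper-style goal ("physiological pressure range,
appropriate flow split") has no published numbers, so the targets are
package conventions: mean root pressure 93 mmHg, peak root pressure inside
120-130 mmHg, split 70% descending / 15% BCA / 7.5% LCCA / 7.5% LSA,
Rp/(Rp+Rd) = 0.1, tau = 1.5 s. `calibrate_rcr()` seeds resistances from
MAP over cardiac output, then runs at most 20 fixed-point passes:
resistances are rescaled by the mean-pressure and split errors, compliances
by the pulse-pressure error (clamped to a factor of 4 per pass), and if the
compliance correction saturates with the peak still above the band the
proximal-resistance fraction is reduced stepwise — with all compliance in
the outlets, the systolic peak cannot fall below the Rp Qpeak floor any
other way. The procedure is deterministic and converges on the template in
one to three passes, landing near 129 mmHg peak.

**ECMO topology.** With support active, ECMO flow enters as a constant
retrograde source at the descending end, and distal perfusion leaves
through an appended abdominal segment whose Windkessel outlet reuses the
calibrated descending parameters (no separate abdominal calibration data
exist). The EF = 0 member of an ECMO sweep runs on this same topology —
cannula in place, zero flow — so that mean-flow-vs-EF comparisons are made
on one fixed linear network; the healthy configuration (descending RCR at
the outlet) is a separate mode. All healthy-stage geometries share the
template-calibrated outlet parameters: the paper provides no per-case
values, and holding the periphery fixed isolates the effect of morphology.

**Timestepping.** Default 1 ms steps, 3 cycles, analysis restricted to the
final cycle; Windkessel states start at their predicted cycle-mean
operating point (with tau = 1.5 s about three times the cycle length, a
cold start would not settle in three cycles; the operating-point start
leaves only a small pulse-shape transient).

**Fraction transport.** The two-phase mixture is reduced to 1D: the ECMO
volume fraction phi (0 = native, 1 = pump blood) is advected along the
aortic axis by a conservative first-order upwind finite-volume scheme (240
cells by default) with velocity Q(s,t)/A(s), native inflow at the root,
phi = 1 inflow at the descending end when flow there is retrograde, and
branch uptake of the ostium-cell fraction. Sub-stepping engages
automatically when the advective CFL bound (Courant 0.9, including the
branch draw of the ostium cells) would be violated. phi is clipped to
[0, 1] only against rounding; the phase-2 volume budget closes to well
under 1% over the final cycle. The aorta starts native-filled (phi = 0),
which is the ECMO start-up condition: steady-state fraction fields need
the transient to pass, and tests that assert saturated states run extra
cycles.

**Watershed.** The axial net flow profile is piecewise constant between
ostia (cardiac inflow minus the branch draws proximal of s), so its sign
change is located to one grid cell and classified against the ostium
positions: ascending, BCA-LCCA, LCCA-LSA, at-LSA (within one cell of the
LSA), descending, or none when flow is antegrade everywhere. Systolic peak
is the time of maximum cardiac inflow in the final cycle, diastolic the
time of minimum. With several crossings the most proximal is reported and
flagged. Because the reduced model has no jet inertia, shock systole drives
the watershed distal of the arch (often "none"/"descending") even at 6
L/min support — more distal than 3D CFD places it — while diastole is fully
retrograde ("ascending"); the orderings (higher EF at least as proximal,
diastole at least as proximal as systole) are the claims the model can
support, and those are what the tests assert.

**Mean flows.** Outlet means are the trapezoidal time integral of flow over
the final cycle divided by the period, in L/min. (The raw integral alone
would be a volume; dividing by the period yields the flow the study
tabulates.) Because the network is linear and the EF sweep shares one
topology, outlet mean flow is exactly affine in EF — the "approximately
linear" trend appears with R^2 = 1 here — and at 6 L/min support the
supra-aortic means exceed both their EF = 0 and their healthy values.

## 5. Pipeline and reproducibility

`run_all()` chains generate, fit, augment, morphometry, selection (k = 20
from the first 10 modes, plus the template), calibrated healthy runs, ECMO
subset selection (the 4 geometries with the largest absolute LCCA mean-flow
deviation from the template — LCCA, the smallest branch, is where
morphology shows up most), and the shock/ECMO sweep over EF in {0, 4, 6}
L/min with transport and watershed reports. Every stage writes plain CSV or
JSON under the output directory and the manifest records an md5 hash per
file; two runs with the same seed produce hash-identical artifacts. The
global seed fans out to per-stage seeds by a counter, and the only random
stage is population sampling. Pressures are reported in mmHg and flows in
L/min at every interface (1 mmHg = 133.322 Pa); computation is SI
internally.

The test suite runs the same stages at reduced problem sizes — typically 60
main rings x 12 ring samples (about 1,500 points per geometry), 6-10
subjects, 120 transport cells — because every geometric identity checked
(ring centroids, tract partitions, Poiseuille resistances, conservation) is
resolution-independent; the calibrated-pressure and watershed checks use a
finer 120-ring surface and the default 1 ms / 3-cycle simulation, and the
acceptance script runs the template pipeline at the full 25,056-point
resolution.

## 6. Known limitations

* The hemodynamics is 0D/1D: no secondary flows, no jet impingement, no
  wall shear or helicity, and node pressures are static pressures — the
  extreme total-pressure values a 3D solver reports under high support are
  outside this model's vocabulary.
* The systolic watershed position is biased distal relative to 3D CFD (see
  above); only orderings across EF and phase are claimed.
* The vasculature ends at the descending aorta plus a lumped abdominal
  outlet; iliac/femoral cannulation-site dynamics are not modeled.
* The synthetic population is an idealized swept-tube family; its PCA modes
  are not the modes of any real cohort, and morphometric deviations between
  geometries are correspondingly smoother than patient data would give.
* Windkessel targets and flow splits are conventions, not fitted patient
  values.
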