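---
title: "Sagittal spine instrumentation biomechanics: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sagittal spine instrumentation biomechanics: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rodspine)
```

`rodspine` simulates long thoracolumbar posterior fusion in the sagittal
plane and compares how rod section profiles (constant, stepped,
Bezier-smoothed variable diameter) redistribute load between the
instrumentation and the native spine. This vignette documents the model,
its assumptions, the tunable parameters, the numerical choices, and what
the shipped tests do and do not demonstrate.

## The mechanical model

**Kinematics.** Vertebrae T1–S1 are rigid bodies with three degrees of
freedom each (anterior `x`, cranial `z`, sagittal rotation `θ`,
counter-clockwise positive viewed from the patient's left). The sacrum and
pelvis form one fixed body: pelvic version does not change between stages,
so pelvic tilt (PT) and pelvic incidence (PI) are constants of a run and
correction is expressed entirely through the spinal curvature. Restricting
to the sagittal plane is deliberate: every comparative quantity of
interest here — thoracic kyphosis (TK), lumbar lordosis (LL), flexion
moments, screw pull-off in the sagittal plane, rod bending stress — is a
sagittal quantity. The bilateral screw pair at each level is lumped into
one sagittal tie whose force is reported per screw by symmetry (halved).

**Geometry synthesis.** `build_spine()` turns a radiographic profile
(PI, PT, TK, LL, body mass) into geometry. The sacral endplate tilts
anterior-down by the sacral slope SS = PI − PT; the aggregate Cobb angles
are apportioned to junction wedges with normative per-level fractions
(thoracic kyphosis peaking mid-thoracically; about two thirds of lordosis
at L4–S1). Default vertebral body and disc heights are an average-adult
table under `inst/extdata/`, uniformly scalable. Per-junction wedges above
25° are rejected as unreachable. `measure_profile()` reads TK (superior T4
vs inferior T12 endplate), LL (superior L1 vs superior S1), PT and PI back
from any state; build-then-measure round-trips to well under 0.5°.

**Joints.** Each functional spinal unit is a 3-DOF spring set: a flexion
moment–rotation law
\(M(\theta) = \kappa f \left(k_0 \theta + c\,\sinh(\theta/\theta_{\mathrm{ref}})\right)\)
— smooth, odd and monotonically stiffening, which keeps Newton iterations
well behaved — plus linear shear and axial springs at the disc centre. The
full 6×6 joint of a 3-D model reduces to this 3×3 in-plane set. `κ ≥ 1`
is the rib-cage stiffening multiplier, applied to thoracic junctions only
(default 2). `f` accumulates surgical release factors. Beyond a
physiologic range (±15° default) the curve continues linearly with the
boundary tangent and flags the extrapolation.

The cadaveric corridors behind the default parameters are not published at
a level that fixes them uniquely; the shipped table
(`inst/extdata/joint_laws_default.csv`) is chosen so that a lumbar FSU
rotates about 5° under a pure 7.5 N·m flexion moment and a thoracic unit
about 3.5° with the rib cage — representative corridor values. The
consequence, stated plainly: absolute simulated moments and forces are
calibration-dependent and are *not* comparable to any particular
reference data; scenario *rankings*, ratios and directions are the
meaningful outputs, and that is what the tests assert.

**Rods.** Corotational two-node beam elements with fiber-discretized
circular sections: 32 horizontal strips with exact circle-segment areas
and centroids, so the fiber-integrated elastic response matches
\(EI\kappa\) to about 0.1% and the elastic–perfectly-plastic limit moment
approaches \(\sigma_y d^3/6\) within 1%. The uniaxial law is multilinear:
elastic (E = 113 GPa) to the yield stress (950 MPa), linear hardening to
the ultimate strength (1180 MPa at 10% elongation), perfectly plastic
beyond with a rupture flag. Plastic state (per fiber, per Gauss point) is
committed after each converged load increment, so unloading is elastic and
residual deformation is path-dependent. Two Gauss points per element and
Hermite curvature interpolation give the standard displacement-based fiber
beam; eight elements per inter-screw segment is the default mesh, at which
the elastic cantilever benchmark is within 1% of \(PL^3/3EI\) and halves
its discretization error with each mesh doubling.

**Diameter profiles.** A profile assigns diameters by zone between named
disc junctions. `stepped_profile()` changes diameter abruptly at one
junction. `bezier_profile()` blends zone plateaus with a cubic smoothstep
over a transition span centred on the boundary junction — C1-continuous,
monotone within the transition, bounded by the zone diameters. The span is
not specified by rod vendors at the level we need, so it is a parameter
(default 20 mm); diameters within a zone are constant (the
plateau-with-smooth-transition reading). The five canned scenarios share
material and contour and differ only in the profile.

**Follower gravity.** Segmental weights (standard segmental anthropometry,
head/neck and arms lumped at T1, ~59% of body mass supported at the
sacrum) are applied along the deformed inter-vertebral tangents: with
cumulative supported weight \(P_i\) and caudal unit tangent \(t_i\),
vertebra *i* receives \(P_i t_i - P_{i-1} t_{i-1}\); the chain telescopes
so the sacrum transmits exactly the supported weight in any posture, and
on a straight vertical spine the scheme reduces to plain vertical gravity.
A design point worth recording: freezing the follower direction per load
increment is not an option here — the tangent stiffness of an
osteo-ligamentous spine (neutral-zone stiffness below 1 N·m/°) loses
definiteness under direction-frozen load well below body weight. That is
the classic ligamentous-spine instability that motivates follower loading
in the first place, so the load is configuration-dependent inside the
residual, with its exact derivative folded into the Newton tangent. A regression test demonstrates the contrast at a sub-critical
mass: follower loading produces far smaller intervertebral moments than
the same load applied vertically.

## The staged protocol

`run_protocol()` executes six stages, each starting from the previous
converged state:

1. **Pre-operative standing.** Joint rest angles are calibrated (three
   fixed-point iterations) so the gravity-loaded standing shape reproduces
   the radiographic profile — radiographs are, after all, standing images.
2. **Prone.** Gravity removed (supported prone positioning as unloading).
   For the kyphotic case TK decreases and signed LL increases; the
   magnitude of that relaxation is set by the joint calibration.
3. **Release.** Facetectomies halve flexion stiffness (configurable) at
   every instrumented junction except across the PSO level; the PSO is a
   rest-angle wedge split equally over the two junctions adjacent to the
   osteotomized vertebra (which also matches reporting conventions that
   leave both junctions blank post-fusion). The wedge equals the planned
   lordosis change, capped at 35°; it is applied in increments with
   equilibrium solves between.
4. **Reduction and locking.** The rod arrives pre-contoured and
   stress-free in its planned shape (residual contouring stresses are out
   of scope): a natural cubic spline through the planned screw-head
   positions, identical for all scenarios. Reduction is
   displacement-controlled: each screw tie's rest gap shrinks linearly
   from the initial head-to-rod mismatch to zero over the load steps at
   full tie stiffness. Ramping the tie *stiffness* instead passes through
   a genuine snap-through (indefinite tangent) halfway through a
   correction of this magnitude; pinning the configuration with stiff
   ties and moving the target — which is also what reduction instruments
   physically do — keeps the tangent positive definite throughout. Set-screw locking then
   stiffens the ties fivefold (reduction default 2000 N/mm translational
   per lumped pair), the PSO junctions are fused rigidly *at their
   achieved compressed angle* (fusing at the nominal wedge angle instead
   would inject a fictitious moment jump), and a residual screw gap above
   2 mm is an error.
5. **Post-operative standing.** Follower gravity restored. The measured
   LL lands near the 48° plan (the shortfall of ~2° is elastic springback
   of the released joints against the construct and is nearly identical
   across scenarios, so the correction-equivalence comparison is
   unaffected).
6. **Flexion.** The T1 rotation is prescribed 10° forward of its standing
   value (translations free), ramped over the load steps with gravity held
   at full magnitude. Whether functional flexion should be imposed
   kinematically or by a moment ramp is an open modelling question; the
   kinematic reading matches the protocol wording and makes the applied
   perturbation identical across scenarios, which is what a comparison
   needs.

## Numerical choices

Internal units are N, mm, N·mm and radians (degrees at every user-facing
surface; serialized quantities are N, mm, N·m, degrees, kg). Newton
iteration with exact analytic element tangents (verified against finite
differences in the tests), backtracking line search, and load stepping
(default 10). Convergence is declared at a relative residual of 1e-6 of
the external load norm with an absolute floor of 1e-3 N — the floor exists
because rigidly fused couplings (1e6 N·m/° ≈ 5.7e10 N·mm/rad) put
round-off force noise of order `k · ε_machine` in the residual. Fused
stiffness itself is a compromise: large enough that a fused junction
rotates less than 1e-6 degrees under any sub-newton-metre moment, small
enough not to swamp double precision. The corotational beam includes the
standard geometric stiffness terms; the element rigid rotation is kept
continuous relative to the initial chord, which is valid for the rotation
magnitudes that occur here (well under a half turn).

Degenerate inputs are rejected rather than absorbed: non-positive
diameters, stiffnesses and tolerances; wedges beyond the apportionment
cap; removing pelvis fixation (named rigid-body-mode error); conflicting
rotation constraints; unknown configuration keys and scenario names.

## The synthetic case and what the tests show

The default case descriptor (`inst/extdata/case_default.yaml`) is a severe
thoracolumbar kyphosis: TK 50°, LL −12°, PI 60°, PT 49°, 60 kg, with a
T10–pelvis construct, facetectomies T10–S1, a PSO at L3, a planned
post-operative LL of 48° (mid-range of the planning target; PI − LL ≈ 12°)
and 10° flexion. PI is printed inconsistently (59° vs 60°) in the source
case description; 60° is used so the pre-operative PI − LL mismatch is
exactly 72°. One comment on plausibility: this generator emulates a single
deformity case's sagittal numbers, masses and staged loading — it does not
emulate muscle forces, 3-D coronal/axial deformity, bone quality,
screw–bone interface failure, or contouring residual stresses. Passing
tests therefore demonstrate internal mechanical consistency and correct
comparative behaviour of rod profiles under the stated model, not
predictive accuracy for any patient.

On this case the suite asserts, per scenario set: UIV+1 flexion moments
rank exactly as the length-averaged flexural rigidity of the five rods
(constant 6.0 > stepped 6.0/5.0 > Bezier 6.0/5.5/5.0 > constant 5.5 >
Bezier 5.5/5.0/4.75); every instrumented junction moves at least ten times
less than the first free junction under flexion; post-operative LL spans
under 2° across scenarios with PI − LL within 2° of 12°; the stepped rod
carries a higher local outer-fiber stress near its step than the
corresponding Bezier rod; and prone unloading moves TK down and LL up.
Absolute reference moments and forces, rod yield occurrence, and the
scenario ordering of the (small, ~30 N) UIV screw forces are
calibration-dependent and deliberately not asserted; the benchmark tables
shipped with the package carry those reference magnitudes instead, and the
fixture arithmetic on them (construct means, UIV means, 16%/45%
offloading) is asserted exactly.

Problem sizes used throughout: 18 rigid bodies (51 free DOFs
uninstrumented), 57 rod nodes at the default mesh (222 free DOFs
instrumented), five scenarios per comparative run — a full five-scenario
protocol takes well under a minute on one CPU.

## Known limitations

* Single sagittal case; no population variability, no coronal/axial
  deformity (the coronal lumbar Cobb is carried as a scalar report only).
* No muscle forces; gravity plus follower path only. Stabilization by
  active musculature is outside the model, which is why the
  direction-frozen gravity variant buckles.
* Screw–bone interface is a linear tie; no toggling, loosening or pullout
  criterion — screw forces are load-transfer readouts, not failure
  predictions.
* Joint corridors are representative defaults, not a fitted calibration;
  absolute outputs move with them.
* The prone stage is pure unloading; positioning-frame forces are not
  modelled.
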