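---
title: "A quasi-static passive knee model with ligament bundles and lateral augmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A quasi-static passive knee model with ligament bundles and lateral augmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneeflex)
```

## The problem

After an anterior cruciate ligament (ACL) rupture, an isolated intra-articular
reconstruction (ACLR) often leaves residual anterolateral rotational laxity.
Surgeons therefore combine ACLR with a lateral extra-articular augmentation —
an anterolateral ligament reconstruction (ALLR), a deep-Lemaire or MacIntosh
tenodesis, or an Ellison transfer — and it is debated which procedure best
restores native rotational kinematics without over-constraining the joint.
`kneeflex` simulates this question on a synthetic parametric knee: it predicts
passive tibiofemoral kinematics and ligament-bundle strains for seven knee
states (intact; ACL-sectioned; isolated ACLR; ACLR plus each of the four
augmentations) over 0–100° of flexion under ±5 N·m of axial torque, and
validates the intact and ACL-sectioned predictions against reference
kinematics with the normalised-RMSE criterion used for cadaveric model
validation.

## Joint kinematics

The tibiofemoral joint has six degrees of freedom expressed in a Grood–Suntay
floating-axis convention: flexion about the femoral medio-lateral axis,
internal rotation about the tibial long axis, adduction about the floating
axis between them, plus anterior, proximal and lateral translations.  Body
frames are right-handed (x anterior, y proximal, z lateral on a right knee);
angles are in degrees and translations in millimetres.  `pose6()`,
`pose_to_transform()` and `grood_suntay_pose()` implement the convention; the
encode/decode pair round-trips to 1e-9 and the decode errors at the gimbal
configuration (|adduction| = 90°).

## Ligament bundles

Nineteen ligament and capsular bundles represent the soft tissues: two-bundle
ACL and PCL, three superficial and two deep MCL bundles, LCL, POPL, ALL, four
posterior-capsule bundles and three patellar-tendon bundles.  Each bundle is a
nonlinear spring parameterised by a normalised stiffness $K$ (N), a zero-load
length $L_0$ (mm) and a reference strain $\varepsilon_r$ (its strain at full
extension).  Tension follows the quadratic-toe/linear law

$$
f(\varepsilon) =
\begin{cases}
0 & \varepsilon \le 0 \\
K\,\varepsilon^2 / (4\varepsilon_l) & 0 < \varepsilon \le 2\varepsilon_l \\
K\,(\varepsilon - \varepsilon_l) & \varepsilon > 2\varepsilon_l
\end{cases}
$$

with transition strain $\varepsilon_l = 0.03$.  The two branches agree at
$2\varepsilon_l$, so the law is continuous and monotone; its integral (the
elastic energy) is what the equilibrium solver actually minimises.  The
patellar-tendon bundles are carried in the registry but are mechanically
inactive: passive flexion involves no quadriceps force and the model has no
patella body.

Bundle paths are straight lines between attachments except where a wrap
object is assigned: a sphere at each epicondyle (for the MCL group and for
the MacIntosh/Ellison graft routes) and an anterior cylinder (unused by the
active bundles).  Wrapped segments take the tangent–arc–tangent geodesic, so
the path length is continuous in the pose and never shorter than the chord.

## The synthetic specimen

No subject geometry ships with the package; `generate_specimen()` builds a
parametric stand-in.  Each femoral condyle is a sphere (default radii 25/21 mm
medial/lateral, 46 mm apart on the flexion axis) and each tibial plateau is a
shallow four-facet articular bowl: a coronal facet pair ("dish", default 14°)
and a sagittal pair (default 16°) superimposed on the posterior slope
(5°/7°).  The bowls cradle each condyle in every horizontal direction — the
parametric analogue of articular surfaces that keep both compartments located
and loaded throughout the motion.  Both plateaus are tilted into a varus
joint-line obliquity (default 6°), which biases the passive adduction curve
into the measured band.  All dimensions are calibration parameters; a left
knee is generated by mirroring every z coordinate.

Attachment points start from an anatomical template and are then *placed*:
`place_attachments()` slides each tibial attachment along the ray from its
femoral attachment until the full-extension path length equals
$L_0(1+\varepsilon_r)$, so every bundle's reference strain is reproduced
exactly (to 1e-3) at the reference pose.  This resolves the over-determination
between the published $L_0$ and $\varepsilon_r$ by construction.  The
template's azimuthal geometry is the model's main design content: bundle
obliquity about the tibial long axis sets the axial-rotation restraint (the
anterolateral ALL and posteromedial corner resist internal rotation; the
POPL, anterior MCL fibres and lateral capsule resist external rotation), and
the sagittal azimuth of each femoral attachment controls how the bundle
slackens or tightens with flexion (the posterior capsule slackens within
~30°, the collaterals gradually, producing the rising rotation envelope).

## Contact

Contact is a frictionless Hertz-type law per facet: penetration
$d$ = sphere radius − distance(centre, facet plane), normal force
$F = k_c d^{1.5}$ (default $k_c$ = 150 N/mm^1.5) along the facet normal, with
potential $(2/5)k_c d^{2.5}$.  The exponent keeps the force C1 in the pose, so
the total potential is twice differentiable almost everywhere and the
quasi-static solve is well posed.

## Quasi-static equilibrium

Only flexion is prescribed.  At each 1° increment the remaining five
coordinates are found at static equilibrium: the generalized residual
(ligament tensions through path-length gradients, contact forces, applied
axial torque of ±5 N·m) is driven below 0.1 N on forces and 1 N·mm on moments
by a damped Newton iteration with a finite-difference Jacobian, warm-started
from the previous flexion step (continuation from the full-extension
solution selects among multiple equilibria).  A quasi-Newton energy
minimisation serves as fall-back when a Newton step stalls.  Quasi-static
continuation replaces time integration deliberately: a passive, slowly moved
cadaver-rig motion has negligible inertia, and the static path is
deterministic and fast.  Each 101-step sweep takes a few seconds on one CPU.

"Measured-kinematics" strains are computed by `strains_along_kinematics()`:
purely geometric strain evaluation along an externally supplied trace, with
multi-bundle ligaments reported as the mean of their bundles' strains (the
reduction is a convention; maximum or a designated bundle would be defensible
alternatives).

## Reference kinematics and calibration

The synthetic reference generator (`generate_reference_kinematics()`)
emulates measured passive-flexion traces: C1 monotone smoothstep curves
constrained to the published per-DoF endpoint values for the intact and
ACL-sectioned knees under internal-rotation torque, with optional seeded
Gaussian jitter emulating marker noise.  It reproduces endpoint values and
ranges exactly at zero noise; it does *not* emulate cycle-to-cycle
variability, inflection patterns such as the screw-home transition, or
soft-tissue artefact, so passing the validation gate against it demonstrates
that the calibrated model tracks magnitude and monotone trend, not that it
would reproduce an arbitrary cadaveric curve shape.

`calibrate()` is the validation loop: a bounded, seeded compass (pattern)
search over per-group reference-strain deltas (±0.03), per-compartment
seating depths (±3 mm) and a log2 contact-stiffness scale (±1), minimising
the mean NRMSE of internal rotation and adduction for the intact and
ACL-sectioned models simultaneously, with soft penalties keeping the peak
bundle strain ≤ 10% and the peak external rotation ≤ 10°.  NRMSE is RMSE
normalised by the observed range; < 30% is the acceptance gate (a lenient
criterion appropriate when contact geometry is constructed rather than
imaged).  The search stops at the gate by default (`stop_at_gate = FALSE`
continues to the budget, useful for parameter-recovery studies).  Translations
are reported but not gated: with idealised spherical condyles the
anterior-posterior translation cannot be expected to track a real knee, the
same degree of freedom that fails the criterion in imaging-based models.

## Surgery

`apply_state()` always starts from the calibrated intact model.  Sectioning
removes both ACL bundles and the ALL (matching the cadaveric protocol).  The
ACL graft (quadrupled semitendinosus, default K = 4000 N) spans the native
footprint centroids; lateral grafts use gracilis (K = 2700 N) or an
iliotibial-band strip (Ellison, K = 2000 N).  Insertions follow the published
rules: ALLR tibial at the midpoint of Gerdy's tubercle (GT) and the anterior
fibular head, 10 mm distal to the joint line, femoral 5 mm proximal and
posterior to the LCL insertion; deep-Lemaire identical but inserting at GT;
MacIntosh from GT to 70 mm proximal to the lateral epicondyle; Ellison an ITB
strip from a proximal lateral-femur anchor under the LCL (lateral wrap
sphere) to GT.  Every graft is fixed with the knee at 30° in neutral rotation:
the zero-torque equilibrium pose is solved, the graft path length measured
there, and $L_0$ set by inverting the force law so the graft carries exactly
its fixation tension — 80 N for the ACL graft, 20 N for the lateral grafts
(the published fixation load is stated in torque units; it is interpreted
here as 20 N of tension, consistent with the 80 N ACL figure).  Graft
stiffnesses are literature-average defaults, overridable per run.

## Numerical choices and degenerate inputs

* Finite differences: residuals use central differences of the energy with a
  1e-4 step (degrees/mm); Jacobians forward differences with 1e-3.
* Newton steps are capped at 5°/5 mm per iteration with halving line search;
  non-convergence is flagged per step and the sweep continues from the best
  iterate rather than aborting.
* Attachment placement brackets its 1-D root by walking the lower end down
  until the wrapped length falls below target; an infeasible target (shorter
  than any realisable path) raises an error naming the bundle.
* A zero observed range makes NRMSE undefined and is an error, as is a
  fixation tension unreachable at the fixation pose.
* All randomness (reference noise, calibration exploration) flows from
  explicit integer seeds; repeated runs are bit-identical.

## Problem sizes

The shipped analyses use the full 0–100° grid at 1° for validation sweeps and
reported quantities, a 5° grid inside the calibration search (the final NRMSE
is always re-evaluated on the full grid), and a 60-evaluation calibration
budget.  These sizes keep a complete seven-state, two-torque study with
calibration in the range of a few minutes on a single core.

## Known limitations

* Spherical condyles and planar-facet bowls cannot reproduce subject-specific
  translation patterns; anterior-posterior and proximal-distal NRMSE are
  reported but routinely exceed the 30% gate, as they do for imaging-based
  models of this class.
* Menisci are absent; compartment pressures are not modelled, so the model
  does not rank procedures by lateral compartment load.
* The superficial-Lemaire augmentation is deliberately out of scope.
* One synthetic specimen is not a population: inter-state comparisons are
  regression statements about the shipped default calibration, not clinical
  claims.
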