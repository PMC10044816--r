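# kneeflex

Quasi-static simulation of the passive tibiofemoral joint for studying ACL
reconstruction combined with lateral extra-articular augmentation.

Isolated ACL reconstruction (ACLR) often leaves residual anterolateral
rotational laxity, and several lateral augmentations — anterolateral ligament
reconstruction (ALLR), deep-Lemaire, MacIntosh and Ellison procedures —
compete to correct it.  `kneeflex` builds a synthetic parametric knee
(spherical femoral condyles, four-facet dished tibial plateaus, nineteen
nonlinear ligament/capsular bundles with wrapping), sweeps it through 0–100°
of passive flexion under ±5 N·m of axial torque with only flexion prescribed,
and compares seven knee states: intact, ACL-sectioned, isolated ACLR, and
ACLR plus each of the four augmentations.

The core pieces:

* **Ligament bundles** — nonlinear springs with a quadratic toe and linear
  region: `f(ε) = 0` for `ε ≤ 0`, `K ε²/(4 ε_l)` for `0 < ε ≤ 2 ε_l`, and
  `K (ε − ε_l)` beyond, with transition strain `ε_l = 0.03`.  Each bundle
  carries a normalised stiffness `K` (N), zero-load length `L0` (mm) and
  reference strain `ε_r`; attachments are placed so the full-extension path
  length equals `L0 (1 + ε_r)` exactly.
* **Contact** — frictionless Hertz-type law per plateau facet,
  `F = k_c d^1.5`, derived from the potential `(2/5) k_c d^2.5`.
* **Equilibrium** — at each 1° flexion increment the five free Grood–Suntay
  coordinates (adduction, internal rotation, three translations) are solved
  to static equilibrium (residuals < 0.1 N / 1 N·mm) by damped Newton
  continuation.
* **Validation** — `NRMSE = RMSE / (max(o) − min(o))` against reference
  kinematics, with `NRMSE < 30%` as the acceptance gate; `calibrate()` drives
  the synthetic specimen toward that gate while keeping peak bundle strain
  ≤ 10% and peak external rotation ≤ 10°.

## Worked example

```r
library(kneeflex)

geom  <- place_attachments(generate_specimen(specimen_params()))
model <- build_knee_model(geom)
model
#> knee_model [INTACT]: 16 active bundles (5 wrapped), k_c = 150/150 N/mm^1.5

sweep <- run_flexion_sweep(model, simulation_protocol(direction = "ir"))
sweep
#> simulation_result [INTACT, ir torque]: 101 steps, 101 converged, IR 1.7 to 11.5 deg

round(sweep$kinematics[seq(1, 101, by = 25), ], 2)[1:5, ]
#>     flexion_deg ir_deg add_deg ant_mm prox_mm lat_mm
#> 1             0   1.67    4.26  -0.88    0.19   1.24
#> 26           25   6.99    3.74  -2.73   -0.39   0.11
#> 51           50  10.04    4.34  -2.07   -0.51  -0.09
#> 76           75  11.50    5.20  -0.65   -0.59  -0.22
#> 101         100   7.89    5.53   2.72   -0.84  -0.27

ref <- generate_reference_kinematics(reference_endpoints("intact"))
nrmse(ref$curves$ir_deg, sweep$kinematics$ir_deg)
#> NRMSE 22.6% over n=101 (observed range 9.80): acceptable (< 30%)
```

The uncalibrated specimen already tracks the measured internal-rotation trend
(rising from ~2° to ~12° across flexion under internal-rotation torque).
`calibrate()` then tunes reference-strain deltas, compartment seating and
contact stiffness until the intact *and* ACL-sectioned rotations pass the 30%
gate:

```r
cal <- calibrate(seed = 1)
cal
#> calibration_result: accepted (all rotation NRMSE < 30%) after 29 evaluations
#>   intact.ir_deg      NRMSE 8.3%
#>   intact.add_deg     NRMSE 23.2%
#>   sectioned.ir_deg   NRMSE 25.9%
#>   sectioned.add_deg  NRMSE 20.5%

states <- c("INTACT", "ACLR", "ACLR_ALLR", "ACLR_DL", "ACLR_MAC", "ACLR_ELL")
res <- lapply(setNames(states, states), function(st)
  run_flexion_sweep(apply_state(cal$model, st),
                    simulation_protocol(direction = "ir")))
compare_states(res)$ranking
#>       state nrmse_vs_intact_pct
#> 1 ACLR_ALLR                 7.4
#> 2   ACLR_DL                 8.8
#> 3  ACLR_ELL                 9.9
#> 4  ACLR_MAC                11.0
#> 5      ACLR                17.0
```

On the calibrated default specimen the combined ACLR + ALLR tracks the intact
internal-rotation curve most closely, every augmentation improves on the
isolated ACLR, and the deep-Lemaire/MacIntosh routes tend toward
over-constraint — the qualitative pattern seen in cadaveric comparisons of
these procedures.

A YAML-driven pipeline (`load_config()` / `run_pipeline()`) writes per-state
kinematics and strain CSVs, the calibration log and a JSON+Markdown
comparison report; `inst/cli/kneeflex.R` wraps it for shell use.

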