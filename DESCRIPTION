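Package: kneeflex
Title: Passive Tibiofemoral Knee Simulation with Ligament Bundles and
    Lateral Extra-Articular Augmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quasi-static simulation of the passive tibiofemoral joint on a
    synthetic parametric specimen. Nineteen nonlinear ligament and capsular
    bundles (piecewise quadratic-toe/linear force law), Hertz-type
    compartmental contact on spherical condyles and inclined tibial plateaus,
    and a six degree-of-freedom Grood-Suntay joint coordinate system.  The
    knee is swept through 0-100 degrees of flexion under +/- 5 Nm axial
    torque with only flexion prescribed; the remaining five coordinates are
    solved at static equilibrium.  Seven knee states are supported: intact,
    ACL-sectioned, isolated ACL reconstruction, and ACL reconstruction
    combined with four anterolateral augmentation procedures (ALL
    reconstruction, deep-Lemaire, MacIntosh, Ellison).  Includes NRMSE
    validation against reference kinematics, specimen calibration, strain
    evaluation along externally supplied kinematics, and rotation-envelope
    and inter-state comparison reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
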