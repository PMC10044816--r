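# generalized residual and quasi-static equilibrium solver

# one bundle along the anterior axis, joint distracted so contact is off;
# the bundle is taut or slack at the test pose depending on L0
single_bundle_model <- function(L0) {
  g <- generate_specimen(specimen_params())
  reg <- default_bundle_registry()[1, ]   # one row, aACL stiffness
  reg$L0_mm <- L0
  reg$eps_r <- 50 / L0 - 1                # strain at the test pose below
  g$attachments <- list(aACL = list(
    name = "aACL", femur = c(-30, -10, 0), tibia = c(20, 0, 0),
    via = NULL, wrap = NA, calibrated = TRUE))
  # bypass place_attachments: attach registry directly
  g$registry <- reg
  build_knee_model(g)
}

test_that("slack bundles, no contact and no torque give a zero residual", {
  m <- single_bundle_model(L0 = 60)
  # at prox = -10 the bundle is 50 mm long (slack) and the joint distracted
  q <- c(0, 0, 0, -10, 0)
  r <- generalized_residual(q, 0, m, torque_nmm = 0)
  expect_equal(unname(r), rep(0, 5), tolerance = 1e-6)
})

test_that("a single taut anterior bundle pulls with its tension on the anterior coordinate", {
  m <- single_bundle_model(L0 = 49)
  # at prox = -10 the tibial attachment sits at (20, -10, 0): the bundle runs
  # along +x with length 50 and strain 1/49
  q <- c(0, 0, 0, -10, 0)
  len <- path_length(m$bundles$aACL, m$geom, pose6(prox = -10))
  expect_equal(len, 50, tolerance = 1e-9)
  tension <- bundle_force((50 - 49) / 49, 3600)
  r <- generalized_residual(q, 0, m, torque_nmm = 0)
  expect_equal(r[["ant"]], -tension, tolerance = 1e-3)
  expect_equal(r[["lat"]], 0, tolerance = 1e-3)
})

test_that("applied torque superposes exactly on the internal-rotation component", {
  m <- intact_model()
  q <- c(1, 2, 0.5, -0.5, 0.3)
  r0 <- generalized_residual(q, 20, m, torque_nmm = 0)
  r5 <- generalized_residual(q, 20, m, torque_nmm = 5000)
  expect_equal(r5[["ir"]] - r0[["ir"]], 5000)
  expect_equal(r5[-2], r0[-2])
})

test_that("symmetric toy model stays on the sagittal plane at zero torque", {
  m <- toy_symmetric_model()
  sol <- solve_equilibrium(0, rep(0, 5), m,
                           simulation_protocol(direction = "none"))
  expect_true(sol$converged)
  expect_equal(sol$pose[["ir"]], 0, tolerance = 1e-3)
  expect_equal(sol$pose[["lat"]], 0, tolerance = 1e-3)
})

test_that("internal rotation is monotone in the applied torque", {
  m <- toy_symmetric_model()
  irs <- vapply(c("er", "none", "ir"), function(d) {
    solve_equilibrium(10, rep(0, 5), m,
                      simulation_protocol(direction = d))$pose[["ir"]]
  }, 0)
  expect_lt(irs[["er"]], irs[["none"]])
  expect_lt(irs[["none"]], irs[["ir"]])
})

test_that("nearby warm starts converge to the same equilibrium", {
  m <- intact_model()
  prot <- simulation_protocol(direction = "ir")
  s1 <- solve_equilibrium(30, c(3, 7, 0, 0, -1), m, prot)
  s2 <- solve_equilibrium(30, c(3.5, 7.5, 0.3, -0.3, -1.4), m, prot)
  expect_true(s1$converged && s2$converged)
  expect_equal(unclass(s1$pose), unclass(s2$pose), tolerance = 1e-3)
})

test_that("converged steps satisfy the protocol force and moment tolerances", {
  m <- intact_model()
  prot <- simulation_protocol(flexion_max = 40, step = 20, direction = "ir")
  r <- run_flexion_sweep(m, prot)
  expect_true(all(r$diagnostics$converged))
  expect_true(all(r$diagnostics$max_force_N < prot$tol_force))
  expect_true(all(r$diagnostics$max_moment_Nmm < prot$tol_moment))
})

test_that("sweep traces are continuous and fully populated", {
  m <- intact_model()
  prot <- simulation_protocol(flexion_max = 100, step = 2, direction = "ir")
  r <- run_flexion_sweep(m, prot)
  expect_equal(nrow(r$kinematics), 51)
  expect_true(all(r$diagnostics$converged))
  for (col in c("ir_deg", "add_deg"))
    expect_lt(max(abs(diff(r$kinematics[[col]]))), 2, label = col)
  for (col in c("ant_mm", "prox_mm", "lat_mm"))
    expect_lt(max(abs(diff(r$kinematics[[col]]))), 2, label = col)
  expect_false(anyNA(r$strains))
})

test_that("removing ligaments changes the sweep output", {
  m <- intact_model()
  prot <- simulation_protocol(flexion_max = 20, step = 10, direction = "ir")
  base <- run_flexion_sweep(m, prot)
  collaterals_only <- kneeflex:::remove_bundles(
    m, setdiff(names(m$bundles), c("aMCL", "iMCL", "pMCL", "LCL")))
  changed <- run_flexion_sweep(collaterals_only, prot)
  expect_gt(max(abs(changed$kinematics$ir_deg - base$kinematics$ir_deg)),
            0.5)
})

test_that("strains along a sweep's own kinematics reproduce the sweep strains", {
  m <- intact_model()
  prot <- simulation_protocol(flexion_max = 30, step = 10, direction = "ir")
  r <- run_flexion_sweep(m, prot)
  s <- strains_along_kinematics(r$kinematics, m, groups = FALSE)
  expect_equal(unname(s), unname(r$strains), tolerance = 1e-9)
})

test_that("strains along the zero reference trace equal the reference strains", {
  m <- intact_model()
  ref <- data.frame(flexion_deg = 0, ir_deg = 0, add_deg = 0,
                    ant_mm = 0, prox_mm = 0, lat_mm = 0)
  s <- strains_along_kinematics(ref, m, groups = FALSE)
  reg <- default_bundle_registry()
  er <- stats::setNames(reg$eps_r, reg$name)
  expect_equal(unname(s[1, ]), unname(er[colnames(s)]), tolerance = 1e-3)
})

test_that("grouped strain reporting averages each ligament's bundles", {
  m <- intact_model()
  ref <- generate_reference_kinematics(flexion_max = 10, step = 5)
  s <- strains_along_kinematics(ref, m, groups = TRUE)
  expect_equal(s[, "ACL"], rowMeans(s[, c("aACL", "pACL")]))
  expect_equal(s[, "MCL"], rowMeans(s[, c("aMCL", "iMCL", "pMCL")]))
  expect_equal(s[, "LCL"], s[, "LCL"])
})
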