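# synthetic specimen generation and attachment calibration

test_that("specimen generation is deterministic and validates parameters", {
  g1 <- generate_specimen(specimen_params())
  g2 <- generate_specimen(specimen_params())
  expect_identical(g1, g2)
  expect_error(specimen_params(medial_condyle_radius = -1),
               "medial_condyle_radius")
  expect_error(specimen_params(condyle_separation = 90),
               "condyle_separation")
})

test_that("epicondylar width is realised exactly by the landmarks", {
  g <- generate_specimen(specimen_params(epicondylar_width = 80))
  d <- sqrt(sum((g$landmarks$femoral_epicondyle_lateral -
                   g$landmarks$femoral_epicondyle_medial)^2))
  expect_equal(d, 80)
})

test_that("left and right specimens are mirror images with equal inter-landmark distances", {
  gr <- generate_specimen(specimen_params(side = "right"))
  gl <- generate_specimen(specimen_params(side = "left"))
  lm_names <- setdiff(names(gr$landmarks), "tibial_long_axis")
  for (nm in lm_names) {
    expect_equal(gl$landmarks[[nm]], gr$landmarks[[nm]] * c(1, 1, -1))
  }
  dist_mat <- function(g) {
    pts <- do.call(rbind, g$landmarks[lm_names])
    as.matrix(stats::dist(pts))
  }
  expect_equal(dist_mat(gl), dist_mat(gr), tolerance = 1e-12)
})

test_that("attachment placement hits L0(1+eps_r) for every bundle, wrapped included", {
  g <- default_geom()
  reg <- default_bundle_registry()
  for (i in seq_len(nrow(reg))) {
    nm <- reg$name[i]
    target <- reg$L0_mm[i] * (1 + reg$eps_r[i])
    got <- path_length(g$attachments[[nm]], g, pose6())
    expect_lt(abs(got - target), 0.01, label = nm)
  }
  # named placement examples
  expect_equal(path_length(g$attachments$aACL, g, pose6()), 32.96,
               tolerance = 0.01)
  expect_equal(path_length(g$attachments$aPCL, g, pose6()), 32.30,
               tolerance = 0.01)
})

test_that("strain at the reference pose reproduces the registry reference strain", {
  m <- intact_model()
  s <- model_strains(m, pose6())
  reg <- default_bundle_registry()
  er <- stats::setNames(reg$eps_r, reg$name)
  expect_equal(unname(s), unname(er[names(s)]), tolerance = 1e-3)
})

test_that("zero reference strain places the bundle at exactly L0", {
  g <- generate_specimen(specimen_params())
  reg <- default_bundle_registry()
  reg$eps_r[reg$name == "LCL"] <- 0
  g <- place_attachments(g, reg)
  expect_equal(path_length(g$attachments$LCL, g, pose6()),
               reg$L0_mm[reg$name == "LCL"], tolerance = 0.01)
})

test_that("placement rejects a non-extension reference pose", {
  g <- generate_specimen(specimen_params())
  expect_error(place_attachments(g, reference_pose = pose6(flex = 10)),
               "full extension")
})

test_that("mirror symmetry: left specimen flips internal rotation and lateral translation", {
  reg <- default_bundle_registry()
  mr <- build_knee_model(place_attachments(
    generate_specimen(specimen_params(side = "right")), reg))
  ml <- build_knee_model(place_attachments(
    generate_specimen(specimen_params(side = "left")), reg))
  prot <- simulation_protocol(flexion_max = 20, step = 10, direction = "ir")
  rr <- run_flexion_sweep(mr, prot)$kinematics
  rl <- run_flexion_sweep(ml, prot)$kinematics
  # a sagittal mirror negates every coordinate whose axis lies in the plane:
  # internal rotation, adduction and lateral translation flip sign
  # solver tolerances admit tiny residual asymmetry
  expect_equal(rl$ir_deg, -rr$ir_deg, tolerance = 1e-3)
  expect_equal(rl$add_deg, -rr$add_deg, tolerance = 1e-3)
  expect_equal(rl$lat_mm, -rr$lat_mm, tolerance = 1e-3)
  expect_equal(rl$ant_mm, rr$ant_mm, tolerance = 1e-3)
  expect_equal(rl$prox_mm, rr$prox_mm, tolerance = 1e-3)
})
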