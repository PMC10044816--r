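# knee states, insertion rules and graft fixation

test_that("state construction gives the documented active bundle counts", {
  m <- intact_model()
  expect_equal(length(apply_state(m, "INTACT")$bundles), 16)
  expect_equal(length(apply_state(m, "ACL_SECTIONED")$bundles), 13)
  expect_equal(length(apply_state(m, "ACLR")$bundles), 14)
  expect_equal(length(apply_state(m, "ACLR_ALLR")$bundles), 15)
  expect_error(apply_state(m, "LEMAIRE_SUP"), "unknown knee state")
  sect <- apply_state(m, "ACL_SECTIONED")
  expect_error(apply_state(sect, "ACLR"), "intact")
})

test_that("insertion rule arithmetic on toy landmarks", {
  lm <- list(gerdys_tubercle = c(0, 0, 0),
             fibular_head_anterior = c(10, 0, -4),
             tibial_long_axis = c(0, 0, 1))  # distal = -z here
  pt <- locate_insertion(list(
    midpoint_of = c("gerdys_tubercle", "fibular_head_anterior"),
    distal_mm = 10), lm)
  expect_equal(pt, c(5, 0, -12))
  expect_error(locate_insertion(list(base = "nonexistent"), lm),
               "missing landmark `nonexistent`")
})

test_that("graft insertion rules honour the anatomical constructions", {
  g <- default_geom()
  lm <- g$landmarks
  specs <- default_graft_specs()
  # MacIntosh femoral point exactly 70 mm proximal to the lateral epicondyle
  mac <- kneeflex:::graft_insertion_points(specs$MACgraft, g)
  expect_equal(mac$femur, lm$femoral_epicondyle_lateral + c(0, 70, 0))
  # deep-Lemaire tibial point at the centre of Gerdy's tubercle
  dl <- kneeflex:::graft_insertion_points(specs$DLgraft, g)
  expect_equal(dl$tibia, lm$gerdys_tubercle)
  # ALL reconstruction: midpoint of GT and fibular head, 10 mm distal; femoral
  # 5 mm proximal and posterior to the LCL insertion
  allr <- kneeflex:::graft_insertion_points(specs$ALLgraft, g)
  expect_equal(allr$tibia,
               (lm$gerdys_tubercle + lm$fibular_head_anterior) / 2 +
                 c(0, -10, 0))
  expect_equal(allr$femur, lm$lcl_femoral_insertion + c(-5, 5, 0))
})

test_that("graft fixation reaches the specified tension at the fixation pose", {
  m <- intact_model()
  sect <- apply_state(m, "ACL_SECTIONED")
  fx <- fix_graft(default_graft_specs()$ACLgraft, sect)
  expect_equal(fx$tension, 80, tolerance = 0.1)
  expect_equal(fx$pose[["flex"]], 30)
  # re-measuring the tension from the stored bundle reproduces it
  len <- path_length(fx$bundle, sect$geom, fx$pose)
  eps <- (len - fx$bundle$L0) / fx$bundle$L0
  expect_equal(bundle_force(eps, fx$bundle$K, fx$bundle$eps_l), 80,
               tolerance = 0.1)
})

test_that("all five graft-bearing states reproduce their fixation tensions by construction", {
  m <- intact_model()
  sect <- apply_state(m, "ACL_SECTIONED")
  specs <- default_graft_specs()
  fx_acl <- fix_graft(specs$ACLgraft, sect)
  aclr <- kneeflex:::add_graft_bundle(sect, fx_acl)
  aclr$label <- "ACLR"
  for (nm in c("ALLgraft", "DLgraft", "MACgraft", "ELLgraft")) {
    fx <- fix_graft(specs[[nm]], aclr)
    expect_equal(fx$tension, 20, tolerance = 0.1, label = nm)
  }
})

test_that("zero fixation tension leaves the graft exactly slack-taut", {
  m <- intact_model()
  sect <- apply_state(m, "ACL_SECTIONED")
  spec0 <- default_graft_specs(list(ACLgraft = list(fixation_tension = 0)))
  fx <- fix_graft(spec0$ACLgraft, sect)
  expect_equal(fx$strain, 0)
  expect_equal(fx$bundle$L0, path_length(fx$bundle, sect$geom, fx$pose),
               tolerance = 1e-9)
})

test_that("sectioning increases internal rotation under IR torque at every step", {
  m <- intact_model()
  sect <- apply_state(m, "ACL_SECTIONED")
  prot <- simulation_protocol(flexion_max = 100, step = 10, direction = "ir")
  ri <- run_flexion_sweep(m, prot)
  rs <- run_flexion_sweep(sect, prot)
  expect_true(all(rs$kinematics$ir_deg >= ri$kinematics$ir_deg - 1e-6))
})

test_that("lateral augmentation shifts internal rotation toward intact at 30 degrees", {
  m <- intact_model()
  prot <- simulation_protocol(flexion_max = 30, step = 10, direction = "ir")
  ir_at30 <- function(label) {
    r <- run_flexion_sweep(apply_state(m, label), prot)
    r$kinematics$ir_deg[r$kinematics$flexion_deg == 30]
  }
  intact <- ir_at30("INTACT")
  sect <- ir_at30("ACL_SECTIONED")
  for (label in c("ACLR_ALLR", "ACLR_DL", "ACLR_MAC", "ACLR_ELL")) {
    aug <- ir_at30(label)
    expect_lt(abs(aug - intact), abs(sect - intact), label = label)
  }
})
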