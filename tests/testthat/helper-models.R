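# shared fixtures, built once per test run and memoised

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

default_geom <- function() {
  memo("geom", place_attachments(generate_specimen()))
}

intact_model <- function() {
  memo("intact", build_knee_model(default_geom()))
}

# calibrated specimen shared by the acceptance tests (deterministic, seed 1)
calibrated <- function() {
  memo("calibration", calibrate(seed = 1))
}

# a small symmetric toy model: two mirror-paired vertical bundles and the
# default symmetric contact; closed-form behaviour for solver tests
toy_symmetric_model <- function() {
  memo("toy", {
    p <- specimen_params(medial_condyle_radius = 23,
                         lateral_condyle_radius = 23,
                         plateau_slope_medial = 6, plateau_slope_lateral = 6,
                         coronal_alignment = 0)
    g <- generate_specimen(p)
    reg <- default_bundle_registry()
    reg <- reg[reg$name %in% c("aMCL", "iMCL"), ]
    reg$name <- c("medL", "latL")
    reg$group <- c("MED", "LAT")
    reg$K_N <- 2000; reg$L0_mm <- 40; reg$eps_r <- 0.02
    g$attachments <- list(
      medL = list(name = "medL", femur = c(0, 0, -30),
                  tibia = c(0, -40, -30), via = NULL, wrap = NA,
                  calibrated = FALSE),
      latL = list(name = "latL", femur = c(0, 0, 30),
                  tibia = c(0, -40, 30), via = NULL, wrap = NA,
                  calibrated = FALSE))
    g <- place_attachments(g, reg)
    build_knee_model(g)
  })
}
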