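#' Parameters of the synthetic parametric specimen
#'
#' The specimen stands in for subject-specific bone/cartilage geometry: each
#' femoral condyle is a sphere, each tibial plateau an inclined plane with a
#' coronal dish inclination, and ligament attachments are placed from an
#' anatomical template and then calibrated (see [place_attachments()]).  All
#' dimensions are calibration parameters.
#'
#' @param medial_condyle_radius,lateral_condyle_radius condyle sphere radii, mm.
#' @param condyle_separation distance between condyle sphere centres, mm;
#'   must be smaller than `epicondylar_width`.
#' @param plateau_slope_medial,plateau_slope_lateral posterior slope of each
#'   tibial plateau, degrees.
#' @param plateau_dish coronal dish inclination of each plateau compartment,
#'   degrees (medio-lateral walls of the articular bowl).
#' @param plateau_dish_ap sagittal dish inclination of each compartment,
#'   degrees (anterior/posterior walls of the bowl, superimposed on the
#'   posterior slope).
#' @param coronal_alignment varus obliquity of the tibial joint line, degrees;
#'   both plateaus are tilted so the seated (equal-penetration) configuration
#'   lies at this adduction angle, biasing the passive adduction curve.
#' @param epicondylar_width distance between the femoral epicondyles, mm.
#' @param joint_line_height distance from the femoral origin (mid-condylar,
#'   on the flexion axis) down to the joint line, mm.
#' @param contact_clearance initial condyle-plateau penetration at the
#'   all-zero reference pose, mm.
#' @param side `"right"` or `"left"`; left specimens are mirrored across the
#'   sagittal plane.
#' @param rng_seed integer seed (the specimen itself is deterministic; the
#'   seed feeds downstream stochastic components such as reference-noise
#'   generation when a config carries it).
#' @return object of class `specimen_params`.
#' @export
specimen_params <- function(medial_condyle_radius = 25,
                            lateral_condyle_radius = 21,
                            condyle_separation = 46,
                            plateau_slope_medial = 5,
                            plateau_slope_lateral = 7,
                            plateau_dish = 14,
                            plateau_dish_ap = 16,
                            coronal_alignment = 6,
                            epicondylar_width = 84,
                            joint_line_height = 24,
                            contact_clearance = 0.3,
                            side = "right",
                            rng_seed = 1L) {
  p <- list(medial_condyle_radius = medial_condyle_radius,
            lateral_condyle_radius = lateral_condyle_radius,
            condyle_separation = condyle_separation,
            plateau_slope_medial = plateau_slope_medial,
            plateau_slope_lateral = plateau_slope_lateral,
            plateau_dish = plateau_dish,
            plateau_dish_ap = plateau_dish_ap,
            coronal_alignment = coronal_alignment,
            epicondylar_width = epicondylar_width,
            joint_line_height = joint_line_height,
            contact_clearance = contact_clearance,
            side = side, rng_seed = as.integer(rng_seed))
  for (f in c("medial_condyle_radius", "lateral_condyle_radius",
              "condyle_separation", "epicondylar_width",
              "joint_line_height")) {
    if (!is.numeric(p[[f]]) || p[[f]] <= 0)
      stop("specimen_params: `", f, "` must be strictly positive")
  }
  if (p$condyle_separation >= p$epicondylar_width)
    stop("specimen_params: `condyle_separation` must be < `epicondylar_width`")
  if (!side %in% c("right", "left"))
    stop("specimen_params: `side` must be \"right\" or \"left\"")
  class(p) <- "specimen_params"
  p
}

# Anatomical attachment template (right knee, mm): femoral point, tibial
# direction point and wrap assignment per bundle.  The tibial point only sets
# the direction of the bundle; place_attachments() rescales it along the ray
# from the femoral point so the full-extension path length equals
# L0 (1 + eps_r).  Small anterior/posterior staggering of the femoral points
# relative to the flexion axis controls how each bundle slackens or tightens
# through flexion.
attachment_template <- function(params) {
  zl <- params$epicondylar_width / 2    # lateral epicondyle z
  ze <- params$condyle_separation / 2   # condylar z offset
  t <- rbind(
    #          fx    fy    fz        tx    ty    tz
    aACL  = c(  -5,  -2,   0.18 * ze,  14, -30,  -2),
    pACL  = c(  -7,  -4,   0.15 * ze,   6, -32,   2),
    aPCL  = c(   0,  -3,  -0.15 * ze, -18, -33,   1),
    pPCL  = c(  -6,  -2,  -0.13 * ze, -20, -31,   3),
    aMCL  = c(   3,   1,  -(zl - 1),   28, -74, -10),
    iMCL  = c(   0,   0,  -zl,         10, -78, -16),
    pMCL  = c(  -6,   2,  -(zl - 1),  -30, -38,  -2),
    aDMCL = c(  -2,  -4,  -(zl - 4),   18, -52, -16),
    pDMCL = c( -10,  -2,  -(zl - 4),  -26, -40,  -2),
    LCL   = c(  -2,   0,   zl - 1,     -4, -46,  38),
    POPL  = c(  -7,  -4,   zl - 6,    -34, -30,  20),
    ALL   = c(  -5,   5,   zl - 1,      6, -44,  26),
    CAPa  = c( -16,   2,  -8,         -26, -30,  12),
    CAPo  = c( -16,   2,   8,         -28, -28, -14),
    CAPm  = c( -17,   4, -19,         -30, -22,  -2),
    CAPl  = c( -17,   4,  19,         -28, -26,   6),
    cPT   = c(  28,   2,   0,          32, -45,   0),
    mPT   = c(  27,   2,  -5,          31, -44,  -5),
    lPT   = c(  27,   2,   5,          31, -44,   5)
  )
  wrap <- c(aACL = NA, pACL = NA, aPCL = NA, pPCL = NA,
            aMCL = "medial_epicondyle", iMCL = "medial_epicondyle",
            pMCL = "medial_epicondyle", aDMCL = "medial_epicondyle",
            pDMCL = "medial_epicondyle",
            LCL = NA, POPL = NA, ALL = NA,
            CAPa = NA, CAPo = NA, CAPm = NA, CAPl = NA,
            cPT = "patellofemoral", mPT = "patellofemoral",
            lPT = "patellofemoral")
  list(points = t, wrap = wrap)
}

#' Generate the synthetic parametric specimen
#'
#' Builds condylar spheres, tibial plateau planes, bony landmarks, wrap
#' objects and template ligament attachments from a [specimen_params()].
#' The femoral body frame has its origin midway between the condylar sphere
#' centres, which both lie on the flexion (z) axis; x is anterior, y proximal,
#' z lateral (right knee).  The tibial frame coincides with the femoral frame
#' at the all-zero reference pose.  Left specimens mirror every z coordinate.
#'
#' Attachments are template-positioned only; call [place_attachments()] to
#' calibrate them against a ligament registry.
#'
#' @param params a [specimen_params()].
#' @return object of class `specimen_geometry`.
#' @export
generate_specimen <- function(params = specimen_params()) {
  stopifnot(inherits(params, "specimen_params"))
  s <- params$condyle_separation / 2
  rm_ <- params$medial_condyle_radius
  rl_ <- params$lateral_condyle_radius
  d0 <- params$contact_clearance
  sm <- params$plateau_slope_medial * DEG
  sl <- params$plateau_slope_lateral * DEG
  dish <- params$plateau_dish * DEG

  # Each plateau compartment is a shallow four-facet articular bowl: a
  # medio-lateral facet pair (coronal dish) and an anterior-posterior pair
  # (sagittal dish superimposed on the posterior slope), so each condyle is
  # cradled in every horizontal direction by its own compartment.  The whole
  # joint line is then tilted into varus by `coronal_alignment`.
  ap <- params$plateau_dish_ap * DEG
  Rv <- rot_x(-params$coronal_alignment * DEG)
  facet <- function(center, radius, n) {
    p <- center - (radius - d0) * n
    list(point = as.numeric(Rv %*% p), normal = as.numeric(Rv %*% n))
  }
  bowl <- function(center, radius, slope) {
    lapply(list(
      c(sin(slope), cos(slope) * cos(dish), -cos(slope) * sin(dish)),
      c(sin(slope), cos(slope) * cos(dish), +cos(slope) * sin(dish)),
      c(sin(slope + ap), cos(slope + ap), 0),
      c(sin(slope - ap), cos(slope - ap), 0)
    ), function(n) facet(center, radius, n))
  }
  facets_med <- bowl(c(0, 0, -s), rm_, sm)
  facets_lat <- bowl(c(0, 0, +s), rl_, sl)

  zl <- params$epicondylar_width / 2
  yj <- -params$joint_line_height
  landmarks <- list(
    femoral_epicondyle_medial  = c(0, 0, -zl),
    femoral_epicondyle_lateral = c(0, 0, +zl),
    lcl_femoral_insertion      = c(0, 0, zl - 1),
    gerdys_tubercle            = c(24, yj - 15, 20),
    fibular_head_anterior      = c(-5, yj - 18, 30),
    joint_line                 = c(0, yj, 0),
    tibial_long_axis           = c(0, 1, 0)
  )
  landmark_body <- c(femoral_epicondyle_medial = "femur",
                     femoral_epicondyle_lateral = "femur",
                     lcl_femoral_insertion = "femur",
                     gerdys_tubercle = "tibia",
                     fibular_head_anterior = "tibia",
                     joint_line = "femur",
                     tibial_long_axis = "tibia")

  wrap_objects <- list(
    medial_epicondyle = list(name = "medial_epicondyle", shape = "sphere",
                             center = c(-4, -12, -(s + 5)), radius = 8,
                             body = "femur"),
    lateral_epicondyle = list(name = "lateral_epicondyle", shape = "sphere",
                              center = c(-4, -12, (s + 5)), radius = 8,
                              body = "femur"),
    patellofemoral = list(name = "patellofemoral", shape = "cylinder",
                          center = c(8, 10, 0), axis = c(0, 0, 1),
                          radius = 10, body = "femur")
  )

  tpl <- attachment_template(params)
  attachments <- lapply(rownames(tpl$points), function(nm) {
    row <- tpl$points[nm, ]
    list(name = nm, femur = as.numeric(row[1:3]),
         tibia = as.numeric(row[4:6]),
         via = NULL,
         wrap = unname(tpl$wrap[nm]),
         calibrated = FALSE)
  })
  names(attachments) <- rownames(tpl$points)

  geom <- list(params = params,
               condyles = list(
                 medial = list(center = c(0, 0, -s), radius = rm_),
                 lateral = list(center = c(0, 0, +s), radius = rl_)),
               plateaus = list(
                 medial = list(facets = facets_med),
                 lateral = list(facets = facets_lat)),
               landmarks = landmarks,
               landmark_body = landmark_body,
               wrap_objects = wrap_objects,
               attachments = attachments)
  class(geom) <- "specimen_geometry"
  if (params$side == "left") geom <- mirror_specimen(geom)
  geom
}

# mirror every z coordinate (sagittal-plane reflection) for a left knee
mirror_specimen <- function(geom) {
  mz <- function(v) v * c(1, 1, -1)
  geom$condyles <- lapply(geom$condyles, function(c.) {
    c.$center <- mz(c.$center); c.
  })
  geom$plateaus <- lapply(geom$plateaus, function(p.) {
    p.$facets <- lapply(p.$facets, function(f.) {
      f.$point <- mz(f.$point); f.$normal <- mz(f.$normal); f.
    })
    p.
  })
  geom$landmarks <- lapply(geom$landmarks, mz)
  geom$wrap_objects <- lapply(geom$wrap_objects, function(w) {
    w$center <- mz(w$center)
    if (!is.null(w$axis)) w$axis <- mz(w$axis)
    w
  })
  geom$attachments <- lapply(geom$attachments, function(a) {
    a$femur <- mz(a$femur); a$tibia <- mz(a$tibia)
    if (!is.null(a$via)) a$via <- lapply(a$via, function(v) {
      v$point <- mz(v$point); v
    })
    a
  })
  geom
}

#' @export
print.specimen_geometry <- function(x, ...) {
  cat(sprintf("specimen_geometry (%s knee): condyle radii %.1f/%.1f mm, %d attachments, %d wrap objects\n",
              x$params$side, x$condyles$medial$radius, x$condyles$lateral$radius,
              length(x$attachments), length(x$wrap_objects)))
  invisible(x)
}

#' Calibrate attachment points against a ligament registry
#'
#' For every bundle in the registry, the tibial attachment is moved along the
#' ray from the femoral attachment through its template position until the
#' bundle path length at the reference pose (full extension, all coordinates
#' zero) equals `L0 (1 + eps_r)`, so the bundle's strain at the reference pose
#' is exactly its reference strain.  Wrapped bundles are solved with a 1-D
#' root find on the wrapped path length.
#'
#' @param geom a [generate_specimen()] geometry.
#' @param registry a ligament registry (see [default_bundle_registry()]).
#' @param reference_pose the reference pose; must be full extension (all six
#'   coordinates zero).
#' @param tol placement tolerance on the path length, mm.
#' @return the geometry with calibrated attachments.
#' @export
place_attachments <- function(geom, registry = default_bundle_registry(),
                              reference_pose = pose6(), tol = 1e-3) {
  stopifnot(inherits(geom, "specimen_geometry"))
  validate_registry(registry)
  if (any(abs(unclass(reference_pose)) > 1e-9))
    stop("place_attachments: reference pose must be full extension (all zero)")
  for (i in seq_len(nrow(registry))) {
    nm <- registry$name[i]
    a <- geom$attachments[[nm]]
    if (is.null(a))
      stop("place_attachments: no attachment template for bundle ", nm)
    target <- registry$L0_mm[i] * (1 + registry$eps_r[i])
    u <- a$tibia - a$femur
    un <- sqrt(sum(u^2))
    if (un < 1e-9)
      stop("place_attachments: degenerate template for bundle ", nm)
    u <- u / un
    plen_at <- function(sc) {
      b <- a
      b$tibia <- a$femur + sc * u
      path_length(b, geom, reference_pose)
    }
    # path length >= straight distance = sc, and increases with sc, so a
    # bracket [lo, target] contains the root when placement is feasible; the
    # lower end is walked down until the wrapped length drops below target
    f_hi <- plen_at(target) - target
    if (f_hi < -tol)
      stop("place_attachments: infeasible placement for bundle ", nm)
    sc <- target
    if (f_hi > 1e-12) {
      lo <- 0.9 * target
      repeat {
        f_lo <- tryCatch(plen_at(lo) - target, error = function(e) NA_real_)
        if (!is.na(f_lo) && f_lo < 0) break
        lo <- lo * 0.9
        if (lo < 0.05 * target)
          stop("place_attachments: infeasible placement for bundle ", nm)
      }
      sc <- stats::uniroot(function(s) plen_at(s) - target,
                           lower = lo, upper = target, tol = 1e-9)$root
    }
    a$tibia <- a$femur + sc * u
    a$calibrated <- TRUE
    achieved <- path_length(a, geom, reference_pose)
    if (abs(achieved - target) > max(tol, 0.01))
      stop("place_attachments: calibration failed for bundle ", nm,
           sprintf(" (%.4f vs %.4f mm)", achieved, target))
    geom$attachments[[nm]] <- a
  }
  geom$registry <- registry
  geom
}
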