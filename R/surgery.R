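#' Knee state labels
#'
#' The seven modelled knee states: intact; ACL-sectioned (the ALL is
#' sectioned with the ACL, matching the cadaveric protocol); isolated ACL
#' reconstruction; and ACLR combined with four anterolateral augmentations
#' (ALL reconstruction, deep-Lemaire, MacIntosh, Ellison).  The superficial
#' Lemaire procedure is deliberately absent.
#'
#' @return character vector of the seven labels.
#' @export
knee_state_labels <- function() {
  c("INTACT", "ACL_SECTIONED", "ACLR",
    "ACLR_ALLR", "ACLR_DL", "ACLR_MAC", "ACLR_ELL")
}

#' Locate a graft insertion point from landmarks
#'
#' Symbolic construction: a base landmark (or the midpoint of two), then
#' offsets measured along the bone's anatomical axes.  Femoral offsets use
#' the femoral frame axes (x anterior, y proximal); tibial distal offsets run
#' along the negative tibial long axis landmark.
#'
#' @param rule list with `base` (landmark name) or `midpoint_of` (two
#'   landmark names), and optional offsets `distal_mm`, `proximal_mm`,
#'   `anterior_mm`, `posterior_mm` (numbers, mm).
#' @param landmarks named list of landmark coordinates (see
#'   [generate_specimen()]; must include `tibial_long_axis` when a distal
#'   offset is used).
#' @return 3-vector, mm.
#' @export
locate_insertion <- function(rule, landmarks) {
  get_lm <- function(nm) {
    if (is.null(landmarks[[nm]]))
      stop("locate_insertion: missing landmark `", nm, "`")
    landmarks[[nm]]
  }
  pt <- if (!is.null(rule$midpoint_of)) {
    (get_lm(rule$midpoint_of[1]) + get_lm(rule$midpoint_of[2])) / 2
  } else if (!is.null(rule$base)) {
    get_lm(rule$base)
  } else stop("locate_insertion: rule needs `base` or `midpoint_of`")
  if (!is.null(rule$distal_mm)) {
    ax <- get_lm("tibial_long_axis")
    pt <- pt - rule$distal_mm * ax / sqrt(sum(ax^2))
  }
  if (!is.null(rule$proximal_mm)) pt <- pt + c(0, rule$proximal_mm, 0)
  if (!is.null(rule$anterior_mm)) pt <- pt + c(rule$anterior_mm, 0, 0)
  if (!is.null(rule$posterior_mm)) pt <- pt - c(rule$posterior_mm, 0, 0)
  pt
}

#' Graft specifications
#'
#' Material stiffness and fixation conditions for the intra-articular ACL
#' graft and the four lateral extra-articular grafts.  The ACL graft takes a
#' quadrupled-semitendinosus stiffness and is fixed at 30 degrees of flexion
#' under 80 N; the lateral grafts take gracilis (ALL, deep-Lemaire,
#' MacIntosh) or iliotibial-band-strip (Ellison) stiffness and are fixed at
#' 30 degrees under 20 N in neutral rotation.  Stiffness values are
#' literature-average defaults and may be overridden.
#'
#' @param overrides optional named list of lists overriding fields of a graft
#'   entry (e.g. `list(ACLgraft = list(K = 4500))`).
#' @return named list of graft specs.
#' @export
default_graft_specs <- function(overrides = NULL) {
  specs <- list(
    ACLgraft = list(name = "ACLgraft", K = 4000, eps_l = 0.03,
                    fixation_flexion = 30, fixation_tension = 80,
                    insertion = "acl_native", wrap = NA),
    ALLgraft = list(name = "ALLgraft", K = 2700, eps_l = 0.03,
                    fixation_flexion = 30, fixation_tension = 20,
                    insertion = "allr", wrap = NA),
    DLgraft = list(name = "DLgraft", K = 2700, eps_l = 0.03,
                   fixation_flexion = 30, fixation_tension = 20,
                   insertion = "dl", wrap = NA),
    MACgraft = list(name = "MACgraft", K = 2700, eps_l = 0.03,
                    fixation_flexion = 30, fixation_tension = 20,
                    insertion = "mac", wrap = "lateral_epicondyle"),
    ELLgraft = list(name = "ELLgraft", K = 2000, eps_l = 0.03,
                    fixation_flexion = 30, fixation_tension = 20,
                    insertion = "ell", wrap = "lateral_epicondyle")
  )
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      if (is.null(specs[[nm]])) stop("unknown graft: ", nm)
      for (f in names(overrides[[nm]])) specs[[nm]][[f]] <- overrides[[nm]][[f]]
    }
  }
  specs
}

# anatomical insertion rules per graft (femoral, tibial)
graft_insertion_points <- function(spec, geom) {
  lm <- geom$landmarks
  switch(spec$insertion,
    acl_native = {
      a <- geom$attachments
      list(femur = (a$aACL$femur + a$pACL$femur) / 2,
           tibia = (a$aACL$tibia + a$pACL$tibia) / 2)
    },
    allr = list(
      femur = locate_insertion(list(base = "lcl_femoral_insertion",
                                    proximal_mm = 5, posterior_mm = 5), lm),
      tibia = locate_insertion(list(
        midpoint_of = c("gerdys_tubercle", "fibular_head_anterior"),
        distal_mm = 10), lm)),
    dl = list(
      femur = locate_insertion(list(base = "lcl_femoral_insertion",
                                    proximal_mm = 5, posterior_mm = 5), lm),
      tibia = locate_insertion(list(base = "gerdys_tubercle"), lm)),
    mac = list(
      femur = locate_insertion(list(base = "femoral_epicondyle_lateral",
                                    proximal_mm = 70), lm),
      tibia = locate_insertion(list(base = "gerdys_tubercle"), lm)),
    ell = list(
      femur = locate_insertion(list(base = "femoral_epicondyle_lateral",
                                    proximal_mm = 60, anterior_mm = 5), lm),
      tibia = locate_insertion(list(base = "gerdys_tubercle"), lm)),
    stop("unknown insertion rule: ", spec$insertion)
  )
}

#' Fix a graft in the current model
#'
#' Solves the model's zero-torque equilibrium pose at the fixation flexion
#' angle (neutral rotation), measures the graft path length there, and
#' inverts the bundle force law so the graft carries exactly the fixation
#' tension at that pose.  With zero fixation tension the graft is exactly
#' slack-taut (`L0` equals the fixation-pose path length).
#'
#' @param graft a graft spec (see [default_graft_specs()]).
#' @param model the model the graft is added to (already in its pre-fixation
#'   state).
#' @param protocol solver settings (torque direction is forced to `"none"`).
#' @return list with the resulting bundle (`name`, `femur`, `tibia`, `wrap`,
#'   `K`, `L0`, `eps_l`), the fixation pose and the fixation strain.
#' @export
fix_graft <- function(graft, model, protocol = simulation_protocol()) {
  if (graft$fixation_tension < 0)
    stop("fix_graft: fixation tension must be >= 0")
  pts <- graft_insertion_points(graft, model$geom)
  # neutral rotation at the fixation angle: continuation from extension
  prot0 <- simulation_protocol(flexion_max = graft$fixation_flexion,
                               step = 5, torque_nm = 0, direction = "none",
                               tol_force = protocol$tol_force,
                               tol_moment = protocol$tol_moment,
                               max_iter = protocol$max_iter)
  sweep0 <- run_flexion_sweep(model, prot0)
  k <- nrow(sweep0$kinematics)
  pose_fix <- pose6(flex = graft$fixation_flexion,
                    add = sweep0$kinematics$add_deg[k],
                    ir = sweep0$kinematics$ir_deg[k],
                    ant = sweep0$kinematics$ant_mm[k],
                    prox = sweep0$kinematics$prox_mm[k],
                    lat = sweep0$kinematics$lat_mm[k])
  bundle <- list(name = graft$name, femur = pts$femur, tibia = pts$tibia,
                 via = NULL, wrap = graft$wrap, K = graft$K,
                 eps_l = graft$eps_l, group = graft$name)
  L_fix <- path_length(bundle, model$geom, pose_fix)
  Tfix <- graft$fixation_tension
  eps_fix <- if (Tfix == 0) 0
  else if (Tfix <= graft$K * graft$eps_l)          # toe region
    sqrt(4 * graft$eps_l * Tfix / graft$K)
  else Tfix / graft$K + graft$eps_l                # linear region
  bundle$L0 <- L_fix / (1 + eps_fix)
  check <- bundle_force((L_fix - bundle$L0) / bundle$L0, graft$K, graft$eps_l)
  if (abs(check - Tfix) > 0.1)
    stop("fix_graft: could not reach fixation tension for ", graft$name)
  list(bundle = bundle, pose = pose_fix, strain = eps_fix, tension = check)
}

# add a fixed graft bundle to a model
add_graft_bundle <- function(model, fixed) {
  b <- fixed$bundle
  model$bundles[[b$name]] <- b
  row <- data.frame(name = b$name, K_N = b$K, L0_mm = b$L0,
                    eps_r = NA_real_, eps_l = b$eps_l, damping_c = 0,
                    group = b$group, active = TRUE,
                    stringsAsFactors = FALSE)
  model$registry <- rbind(model$registry, row)
  model$geom$attachments[[b$name]] <-
    list(name = b$name, femur = b$femur, tibia = b$tibia, via = NULL,
         wrap = b$wrap, calibrated = TRUE)
  rebuild_fast(model)
}

remove_bundles <- function(model, names_) {
  model$bundles[names_] <- NULL
  model$registry$active[model$registry$name %in% names_] <- FALSE
  rebuild_fast(model)
}

#' Build one of the seven knee states from the intact base model
#'
#' The calibrated intact model is always the base.  Sectioning removes the
#' two ACL bundles and the ALL; reconstruction adds an ACL graft fixed at 30
#' degrees under 80 N; augmented states additionally fix their lateral graft
#' (at 30 degrees, 20 N) on the ACL-reconstructed knee.
#'
#' @param base_model the calibrated intact [build_knee_model()].
#' @param label one of [knee_state_labels()].
#' @param graft_specs graft overrides (see [default_graft_specs()]).
#' @param protocol solver settings used for the fixation poses.
#' @return a `knee_model` for the requested state.
#' @export
apply_state <- function(base_model, label,
                        graft_specs = default_graft_specs(),
                        protocol = simulation_protocol()) {
  if (!label %in% knee_state_labels())
    stop("apply_state: unknown knee state label `", label, "`")
  if (base_model$label != "INTACT")
    stop("apply_state: base model must be the intact knee")
  m <- base_model
  m$label <- label
  if (label == "INTACT") return(m)
  m <- remove_bundles(m, c("aACL", "pACL", "ALL"))
  if (label == "ACL_SECTIONED") return(m)
  m <- add_graft_bundle(m, fix_graft(graft_specs$ACLgraft, m, protocol))
  if (label == "ACLR") return(m)
  lateral <- switch(label, ACLR_ALLR = "ALLgraft", ACLR_DL = "DLgraft",
                    ACLR_MAC = "MACgraft", ACLR_ELL = "ELLgraft")
  add_graft_bundle(m, fix_graft(graft_specs[[lateral]], m, protocol))
}
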