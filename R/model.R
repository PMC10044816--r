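#' Simulation protocol
#'
#' Flexion grid, applied axial torque and solver tolerances for a passive
#' flexion sweep.  The torque acts about the tibial long axis; `"ir"` is
#' internal rotation (positive for a right knee), `"er"` external rotation.
#'
#' @param flexion_max end of the flexion grid, degrees.
#' @param step flexion increment, degrees (1 degree reproduces the standard
#'   comparison grid).
#' @param torque_nm axial torque magnitude, N m.
#' @param direction `"ir"`, `"er"` or `"none"`.
#' @param tol_force residual force tolerance, N.
#' @param tol_moment residual moment tolerance, N mm.
#' @param max_iter maximum solver iterations per flexion step.
#' @return object of class `simulation_protocol`.
#' @export
simulation_protocol <- function(flexion_max = 100, step = 1, torque_nm = 5,
                                direction = c("ir", "er", "none"),
                                tol_force = 0.1, tol_moment = 1,
                                max_iter = 60) {
  direction <- match.arg(direction)
  if (torque_nm < 0) stop("simulation_protocol: torque_nm must be >= 0")
  structure(list(grid = seq(0, flexion_max, by = step),
                 torque_nm = torque_nm, direction = direction,
                 tol_force = tol_force, tol_moment = tol_moment,
                 max_iter = max_iter),
            class = "simulation_protocol")
}

#' Assemble a knee model from calibrated geometry
#'
#' Binds a calibrated specimen geometry (see [place_attachments()]), its
#' ligament registry and contact parameters into a model ready for the
#' equilibrium solver.  Only mechanically active bundles enter the mechanics;
#' patellar-tendon bundles stay in the registry but carry no force.
#'
#' @param geom a calibrated [generate_specimen()] geometry.
#' @param contact a [contact_params()].
#' @param label knee-state label (see [knee_state_labels()]).
#' @return object of class `knee_model`.
#' @export
build_knee_model <- function(geom, contact = contact_params(),
                             label = "INTACT") {
  if (is.null(geom$registry))
    stop("build_knee_model: geometry has no calibrated registry; run place_attachments()")
  reg <- geom$registry
  act <- reg[reg$active, , drop = FALSE]
  bundles <- lapply(seq_len(nrow(act)), function(i) {
    nm <- act$name[i]
    a <- geom$attachments[[nm]]
    list(name = nm, femur = a$femur, tibia = a$tibia, via = a$via,
         wrap = a$wrap, K = act$K_N[i], L0 = act$L0_mm[i],
         eps_l = act$eps_l[i], group = act$group[i])
  })
  names(bundles) <- act$name
  model <- list(geom = geom, registry = reg, bundles = bundles,
                contact = contact, label = label,
                side_sign = if (geom$params$side == "left") -1 else 1)
  class(model) <- "knee_model"
  rebuild_fast(model)
}

# split bundles into a vectorised straight set and a per-bundle wrapped set
rebuild_fast <- function(model) {
  b <- model$bundles
  straight <- vapply(b, function(x) is.null(x$via) &&
                       (is.null(x$wrap) || is.na(x$wrap)), logical(1))
  sb <- b[straight]
  model$fast <- list(
    Fm = if (length(sb)) do.call(rbind, lapply(sb, `[[`, "femur")) else NULL,
    Tt = if (length(sb)) do.call(rbind, lapply(sb, `[[`, "tibia")) else NULL,
    K = vapply(sb, `[[`, 0, "K"),
    L0 = vapply(sb, `[[`, 0, "L0"),
    eps_l = vapply(sb, `[[`, 0, "eps_l"),
    names = names(sb),
    wrapped = b[!straight])
  model
}

#' @export
print.knee_model <- function(x, ...) {
  cat(sprintf("knee_model [%s]: %d active bundles (%d wrapped), k_c = %.0f/%.0f N/mm^1.5\n",
              x$label, length(x$bundles), length(x$fast$wrapped),
              x$contact$k_c[["medial"]], x$contact$k_c[["lateral"]]))
  invisible(x)
}

# all active bundle lengths at a transform (named vector, mm)
model_lengths_tf <- function(model, tf) {
  f <- model$fast
  out <- numeric(0)
  if (length(f$K)) {
    Tf <- f$Tt %*% t(tf$R)
    Tf <- sweep(Tf, 2, tf$p, "+")
    d <- f$Fm - Tf
    out <- sqrt(rowSums(d * d))
    names(out) <- f$names
  }
  for (wb in f$wrapped) {
    pts <- bundle_polyline(wb, tf)
    wrap <- if (!is.null(wb$wrap) && !is.na(wb$wrap))
      model$geom$wrap_objects[[wb$wrap]] else NULL
    tot <- 0
    for (i in seq_len(nrow(pts) - 1))
      tot <- tot + wrapped_segment_length(pts[i, ], pts[i + 1, ], wrap)
    out[wb$name] <- tot
  }
  out
}

#' Strains of all active bundles at a pose
#'
#' @param model a [build_knee_model()].
#' @param pose a [pose6()].
#' @return named numeric vector of engineering strains.
#' @export
model_strains <- function(model, pose) {
  tf <- pose_to_transform(pose)
  len <- model_lengths_tf(model, tf)[names(model$bundles)]
  L0 <- vapply(model$bundles, `[[`, 0, "L0")
  (len - L0) / L0
}

# total potential energy (N mm) at free coordinates q (add, ir, ant, prox,
# lat) and prescribed flexion; torque enters as -tau * ir
model_energy <- function(q, flex, model, torque_nmm) {
  pose <- pose6(flex = flex, add = q[1], ir = q[2],
                ant = q[3], prox = q[4], lat = q[5])
  tf <- pose_to_transform(pose)
  len <- model_lengths_tf(model, tf)
  f <- model$fast
  K <- c(f$K, vapply(f$wrapped, `[[`, 0, "K"))
  L0 <- c(f$L0, vapply(f$wrapped, `[[`, 0, "L0"))
  el <- c(f$eps_l, vapply(f$wrapped, `[[`, 0, "eps_l"))
  eps <- (len - L0) / L0
  e_lig <- sum(bundle_energy(eps, K, L0, el))
  e_con <- contact_energy_pose(tf, model$geom, model$contact$k_c)
  e_lig + e_con - torque_nmm * q[2] * DEG
}

#' Generalized residual forces on the free coordinates
#'
#' Net generalized force on (adduction, internal rotation, anterior,
#' proximal, lateral) at a trial configuration: ligament tensions acting
#' through path-length gradients, compartmental contact, and the applied
#' axial torque.  Rotational components are in N mm (per radian), translational
#' in N.  At equilibrium all five vanish within the protocol tolerances.
#'
#' @param free_coords numeric length-5 `(add, ir, ant, prox, lat)`
#'   (degrees / mm).
#' @param flexion prescribed flexion, degrees.
#' @param model a [build_knee_model()].
#' @param torque_nmm applied torque about the tibial long axis, N mm
#'   (positive internal for a right knee).
#' @param h finite-difference step (degrees / mm).
#' @return numeric length-5, named.
#' @export
generalized_residual <- function(free_coords, flexion, model,
                                 torque_nmm = 0, h = 1e-4) {
  if (!all(is.finite(free_coords)))
    stop("generalized_residual: non-finite coordinates at flexion ", flexion)
  g <- numeric(5)
  for (i in 1:5) {
    qp <- free_coords; qm <- free_coords
    qp[i] <- qp[i] + h; qm[i] <- qm[i] - h
    g[i] <- (model_energy(qp, flexion, model, 0) -
               model_energy(qm, flexion, model, 0)) / (2 * h)
  }
  # energy gradient is per degree for rotations; residual is per radian
  r <- -g
  r[1:2] <- r[1:2] / DEG
  r[2] <- r[2] + torque_nmm
  names(r) <- c("add", "ir", "ant", "prox", "lat")
  r
}

protocol_torque_nmm <- function(model, protocol) {
  sgn <- switch(protocol$direction, ir = 1, er = -1, none = 0)
  sgn * model$side_sign * protocol$torque_nm * 1000
}

#' Solve static equilibrium at one flexion angle
#'
#' Damped Newton iteration on the five-component generalized residual with a
#' finite-difference Jacobian, warm-started from a trial pose; falls back to
#' a quasi-Newton energy minimisation when the damped step stalls.
#' Equilibria are stationary points of the total potential (ligament elastic
#' energy + contact potential - torque work), so converged solutions are
#' deterministic given the warm start.
#'
#' @param flexion prescribed flexion, degrees.
#' @param warm_start a [pose6()] (its flexion component is ignored) or a
#'   numeric length-5 vector of free coordinates.
#' @param model a [build_knee_model()].
#' @param protocol a [simulation_protocol()].
#' @return list with `pose` ([pose6()]), `converged`, `iterations`,
#'   `residual` (named length-5), `max_force_N`, `max_moment_Nmm`.
#' @export
solve_equilibrium <- function(flexion, warm_start, model,
                              protocol = simulation_protocol()) {
  q <- if (inherits(warm_start, "pose6"))
    as.numeric(unclass(warm_start)[c("add", "ir", "ant", "prox", "lat")])
  else as.numeric(warm_start)
  if (length(q) != 5 || !all(is.finite(q)))
    stop("solve_equilibrium: warm start must be 5 finite free coordinates")
  tau <- protocol_torque_nmm(model, protocol)

  res_norms <- function(r) c(force = max(abs(r[3:5])),
                             moment = max(abs(r[1:2])))
  ok <- function(r) {
    n <- res_norms(r)
    n[["force"]] < protocol$tol_force && n[["moment"]] < protocol$tol_moment
  }
  r <- generalized_residual(q, flexion, model, tau)
  it <- 0
  stalled <- 0
  while (!ok(r) && it < protocol$max_iter) {
    it <- it + 1
    J <- matrix(0, 5, 5)
    hj <- 1e-3
    for (i in 1:5) {
      qp <- q; qp[i] <- qp[i] + hj
      J[, i] <- (generalized_residual(qp, flexion, model, tau) - r) / hj
    }
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) step <- r * 1e-4
    # trust-region style cap: 5 deg / 5 mm per iteration
    sc <- max(abs(step)) / 5
    if (sc > 1) step <- step / sc
    improved <- FALSE
    n0 <- sum(r^2)
    lam <- 1
    for (k in 1:8) {
      qt <- q + lam * step
      rt <- tryCatch(generalized_residual(qt, flexion, model, tau),
                     error = function(e) NULL)
      if (!is.null(rt) && all(is.finite(rt)) && sum(rt^2) < n0) {
        q <- qt; r <- rt; improved <- TRUE
        break
      }
      lam <- lam / 2
    }
    if (!improved) {
      stalled <- stalled + 1
      # fall back to energy minimisation to escape a bad basin
      opt <- stats::optim(q, function(x) model_energy(x, flexion, model, tau),
                          method = "BFGS",
                          control = list(maxit = 100, reltol = 1e-12))
      q <- opt$par
      r <- generalized_residual(q, flexion, model, tau)
      if (stalled >= 2) break
    }
  }
  n <- res_norms(r)
  list(pose = pose6(flex = flexion, add = q[1], ir = q[2],
                    ant = q[3], prox = q[4], lat = q[5]),
       converged = ok(r), iterations = it, residual = r,
       max_force_N = unname(n[["force"]]),
       max_moment_Nmm = unname(n[["moment"]]))
}

#' Passive flexion sweep under axial torque
#'
#' Continuation sweep over the protocol flexion grid: each step is solved at
#' static equilibrium warm-started from the previous solution.  Strains of
#' all active bundles are evaluated at every converged pose.  Steps that fail
#' to converge are flagged and the sweep continues from the best iterate.
#'
#' @param model a [build_knee_model()].
#' @param protocol a [simulation_protocol()].
#' @return object of class `simulation_result`: list with `label`,
#'   `direction`, `kinematics` (data.frame `flexion_deg, ir_deg, add_deg,
#'   ant_mm, prox_mm, lat_mm`), `strains` (matrix, one column per active
#'   bundle), `diagnostics` (per-step data.frame).
#' @export
run_flexion_sweep <- function(model, protocol = simulation_protocol()) {
  grid <- protocol$grid
  q <- c(0, 0, 0, 0, 0)
  kin <- matrix(NA_real_, length(grid), 6,
                dimnames = list(NULL, c("flexion_deg", "ir_deg", "add_deg",
                                        "ant_mm", "prox_mm", "lat_mm")))
  strains <- matrix(NA_real_, length(grid), length(model$bundles),
                    dimnames = list(NULL, names(model$bundles)))
  diag_ <- data.frame(flexion_deg = grid, converged = NA,
                      iterations = NA_integer_, max_force_N = NA_real_,
                      max_moment_Nmm = NA_real_)
  for (i in seq_along(grid)) {
    sol <- solve_equilibrium(grid[i], q, model, protocol)
    q <- as.numeric(unclass(sol$pose)[c("add", "ir", "ant", "prox", "lat")])
    kin[i, ] <- c(grid[i], sol$pose[["ir"]], sol$pose[["add"]],
                  sol$pose[["ant"]], sol$pose[["prox"]], sol$pose[["lat"]])
    strains[i, ] <- model_strains(model, sol$pose)
    diag_$converged[i] <- sol$converged
    diag_$iterations[i] <- sol$iterations
    diag_$max_force_N[i] <- sol$max_force_N
    diag_$max_moment_Nmm[i] <- sol$max_moment_Nmm
  }
  structure(list(label = model$label, direction = protocol$direction,
                 kinematics = as.data.frame(kin), strains = strains,
                 diagnostics = diag_, protocol = protocol),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("simulation_result [%s, %s torque]: %d steps, %d converged, IR %.1f to %.1f deg\n",
              x$label, x$direction, nrow(x$kinematics),
              sum(x$diagnostics$converged),
              min(x$kinematics$ir_deg), max(x$kinematics$ir_deg)))
  invisible(x)
}

#' Evaluate bundle strains along externally supplied kinematics
#'
#' Purely geometric: at each pose of the reference trace the active bundle
#' strains are computed from path lengths; no equilibrium solve is involved.
#' This mirrors driving the joint with measured kinematics and reading the
#' ligament strains off the model.
#'
#' @param reference a [reference_kinematics()] object or a data.frame with
#'   columns `flexion_deg, ir_deg, add_deg, ant_mm, prox_mm, lat_mm`.
#' @param model a [build_knee_model()].
#' @param groups if TRUE, append per-ligament group columns (mean of the
#'   group's bundle strains).
#' @return matrix of strains, one row per grid point.
#' @export
strains_along_kinematics <- function(reference, model, groups = TRUE) {
  df <- if (inherits(reference, "reference_kinematics")) reference$curves
  else as.data.frame(reference)
  need <- c("flexion_deg", "ir_deg", "add_deg", "ant_mm", "prox_mm", "lat_mm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("strains_along_kinematics: missing columns ",
         paste(miss, collapse = ", "))
  out <- t(vapply(seq_len(nrow(df)), function(i) {
    pose <- pose6(flex = df$flexion_deg[i], add = df$add_deg[i],
                  ir = df$ir_deg[i], ant = df$ant_mm[i],
                  prox = df$prox_mm[i], lat = df$lat_mm[i])
    model_strains(model, pose)
  }, numeric(length(model$bundles))))
  colnames(out) <- names(model$bundles)
  if (groups) out <- cbind(out, group_strains(out, model))
  out
}

#' Per-ligament grouped strain columns
#'
#' Multi-bundle ligaments are reported as one curve per group, reduced as the
#' mean of the group's bundle strains (ACL = mean of aACL and pACL, and so
#' on).
#'
#' @param strain_mat strain matrix with bundle columns.
#' @param model a [build_knee_model()].
#' @return matrix of grouped strain columns.
#' @export
group_strains <- function(strain_mat, model) {
  grp <- vapply(model$bundles, `[[`, "", "group")
  grp <- grp[intersect(names(grp), colnames(strain_mat))]
  out <- sapply(unique(grp), function(g) {
    cols <- names(grp)[grp == g]
    rowMeans(strain_mat[, cols, drop = FALSE])
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(NULL, unique(grp)))
  out
}
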