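#' Compartmental contact parameters
#'
#' Hertz-type sphere-on-plane contact per compartment: normal force
#' `F = k_c d^1.5` at penetration depth `d`, frictionless.  The associated
#' potential is `(2/5) k_c d^2.5`, which keeps the quasi-static solve
#' well-posed (the force law is C1 in the pose).
#'
#' @param k_c contact stiffness, N/mm^1.5, per compartment (scalar or named
#'   vector `c(medial =, lateral =)`).
#' @return object of class `contact_params`.
#' @export
contact_params <- function(k_c = 150) {
  k_c <- unlist(k_c)
  if (!is.numeric(k_c)) stop("contact_params: k_c must be numeric")
  if (length(k_c) == 1) k_c <- c(medial = unname(k_c), lateral = unname(k_c))
  if (any(k_c <= 0)) stop("contact_params: k_c must be > 0")
  structure(list(k_c = k_c), class = "contact_params")
}

#' Compartmental contact state at a pose
#'
#' Each tibial plateau is a shallow two-facet gutter.  For every facet the
#' penetration depth is the condylar sphere radius minus the distance from
#' the sphere centre to the facet plane (clamped at zero) and the normal
#' force is `k_c d^1.5` along the facet normal.  Per compartment the facet
#' forces are summed; the reported penetration is the maximum over facets and
#' the centre of pressure is the penetration-weighted projection of the
#' sphere centre.
#'
#' @param pose a [pose6()].
#' @param geom a [generate_specimen()] geometry.
#' @param params a [contact_params()].
#' @return data.frame with one row per compartment: `compartment`,
#'   `penetration_mm`, `force_N`, and centre-of-pressure coordinates
#'   `cop_x`, `cop_y`, `cop_z` (femur frame; NA when out of contact).
#' @export
contact_state <- function(pose, geom, params = contact_params()) {
  tf <- pose_to_transform(pose)
  out <- lapply(c("medial", "lateral"), function(side) {
    sph <- geom$condyles[[side]]
    fvec <- c(0, 0, 0); dmax <- 0; cop <- c(0, 0, 0); wsum <- 0
    for (fc in geom$plateaus[[side]]$facets) {
      p_f <- as.numeric(tf$R %*% fc$point + tf$p)
      n_f <- as.numeric(tf$R %*% fc$normal)
      dist <- sum((sph$center - p_f) * n_f)
      d <- max(0, sph$radius - dist)
      if (d > 0) {
        fvec <- fvec + params$k_c[[side]] * d^1.5 * n_f
        cop <- cop + d * (sph$center - dist * n_f)
        wsum <- wsum + d
        dmax <- max(dmax, d)
      }
    }
    cop <- if (wsum > 0) cop / wsum else c(NA_real_, NA_real_, NA_real_)
    data.frame(compartment = side, penetration_mm = dmax,
               force_N = sqrt(sum(fvec^2)),
               cop_x = cop[1], cop_y = cop[2], cop_z = cop[3],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# contact potential energy (N mm), used by the equilibrium solver
contact_energy_pose <- function(tf, geom, k_c) {
  e <- 0
  for (side in c("medial", "lateral")) {
    sph <- geom$condyles[[side]]
    for (fc in geom$plateaus[[side]]$facets) {
      p_f <- as.numeric(tf$R %*% fc$point + tf$p)
      n_f <- as.numeric(tf$R %*% fc$normal)
      d <- sph$radius - sum((sph$center - p_f) * n_f)
      if (d > 0) e <- e + 0.4 * k_c[[side]] * d^2.5
    }
  }
  e
}
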