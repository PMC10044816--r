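#' Endpoint values of the cadaveric reference kinematics
#'
#' Per-DoF values at 0 and 100 degrees of flexion measured on the source
#' specimen under 5 N m internal-rotation torque (inverse-kinematics traces),
#' for the intact and ACL-sectioned knee states.  These endpoints drive the
#' synthetic reference-kinematics generator.
#'
#' @param state `"intact"` or `"acl_sectioned"`.
#' @return named list of `c(start, end)` pairs for `ir_deg`, `add_deg`,
#'   `ant_mm`, `prox_mm`, `lat_mm`.
#' @export
reference_endpoints <- function(state = c("intact", "acl_sectioned")) {
  state <- match.arg(state)
  if (state == "intact") {
    list(ir_deg = c(2.7, 12.5), add_deg = c(3.3, 6.4),
         ant_mm = c(1.3, 9.3), prox_mm = c(2.5, -20.3),
         lat_mm = c(-0.8, -5.7))
  } else {
    list(ir_deg = c(3.9, 13.4), add_deg = c(2.5, 6.5),
         ant_mm = c(1.6, 11.1), prox_mm = c(-3.2, -24.3),
         lat_mm = c(-0.9, -6.2))
  }
}

smoothstep <- function(t) t * t * (3 - 2 * t)

#' Generate synthetic reference kinematics
#'
#' Smooth monotone curves on a uniform flexion grid, constrained to the given
#' per-DoF endpoint values, with optional Gaussian jitter emulating marker
#' noise.  With `noise_sd = 0` each curve is C1, monotone, and passes exactly
#' through its endpoints, so its range equals the endpoint difference.
#'
#' @param endpoints named list of `c(value at 0, value at flexion_max)` for
#'   each of `ir_deg`, `add_deg`, `ant_mm`, `prox_mm`, `lat_mm` (see
#'   [reference_endpoints()]).
#' @param flexion_max,step flexion grid settings, degrees.
#' @param shape `"smoothstep"` (C1 sigmoidal, default) or `"linear"`.
#' @param noise_sd Gaussian jitter standard deviation; scalar or named
#'   per-DoF vector (degrees / mm).  Must be >= 0.
#' @param rng_seed integer seed; with a fixed seed the jitter is reproducible.
#' @return object of class `reference_kinematics` with a `curves` data.frame
#'   (`flexion_deg, ir_deg, add_deg, ant_mm, prox_mm, lat_mm`).
#' @export
generate_reference_kinematics <- function(endpoints = reference_endpoints(),
                                          flexion_max = 100, step = 1,
                                          shape = c("smoothstep", "linear"),
                                          noise_sd = 0, rng_seed = 1L) {
  shape <- match.arg(shape)
  dofs <- c("ir_deg", "add_deg", "ant_mm", "prox_mm", "lat_mm")
  miss <- setdiff(dofs, names(endpoints))
  if (length(miss))
    stop("generate_reference_kinematics: missing endpoints for ",
         paste(miss, collapse = ", "))
  if (any(!is.finite(unlist(endpoints[dofs]))))
    stop("generate_reference_kinematics: endpoints must be finite")
  if (length(noise_sd) == 1) noise_sd <- stats::setNames(rep(noise_sd, 5), dofs)
  if (any(noise_sd < 0))
    stop("generate_reference_kinematics: noise_sd must be >= 0")
  grid <- seq(0, flexion_max, by = step)
  t <- grid / flexion_max
  s <- if (shape == "smoothstep") smoothstep(t) else t
  curves <- data.frame(flexion_deg = grid)
  set.seed(as.integer(rng_seed))
  for (d in dofs) {
    v <- endpoints[[d]][1] + (endpoints[[d]][2] - endpoints[[d]][1]) * s
    if (noise_sd[[d]] > 0)
      v <- v + stats::rnorm(length(v), 0, noise_sd[[d]])
    curves[[d]] <- v
  }
  structure(list(curves = curves, endpoints = endpoints,
                 noise_sd = noise_sd, rng_seed = as.integer(rng_seed),
                 provenance = "synthetic", shape = shape),
            class = "reference_kinematics")
}

#' Read / write kinematics traces as CSV
#'
#' CSV dialect: header `flexion_deg,ir_deg,add_deg,ant_mm,prox_mm,lat_mm`,
#' one row per flexion increment.
#'
#' @param path file path.
#' @return `read_kinematics_csv`: a `reference_kinematics` object with
#'   provenance `"file"`.
#' @export
read_kinematics_csv <- function(path) {
  if (!file.exists(path)) stop("kinematics file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("flexion_deg", "ir_deg", "add_deg", "ant_mm", "prox_mm", "lat_mm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("kinematics CSV missing columns: ", paste(miss, collapse = ", "))
  dg <- diff(df$flexion_deg)
  if (any(dg <= 0)) stop("kinematics CSV: flexion grid must be increasing")
  structure(list(curves = df[need], endpoints = NULL, noise_sd = NA,
                 rng_seed = NA_integer_, provenance = "file"),
            class = "reference_kinematics")
}

#' @rdname read_kinematics_csv
#' @param x a `reference_kinematics`, `simulation_result`, or kinematics
#'   data.frame.
#' @export
write_kinematics_csv <- function(x, path) {
  df <- if (inherits(x, "reference_kinematics")) x$curves
  else if (inherits(x, "simulation_result")) x$kinematics
  else as.data.frame(x)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a strain trace as CSV
#'
#' One column per active bundle plus grouped per-ligament columns, preceded
#' by the flexion grid.
#'
#' @param result a [run_flexion_sweep()] result.
#' @param model the model that produced it (for grouping).
#' @param path file path.
#' @export
write_strains_csv <- function(result, model, path) {
  mat <- cbind(flexion_deg = result$kinematics$flexion_deg,
               result$strains, group_strains(result$strains, model))
  utils::write.csv(as.data.frame(mat), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
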