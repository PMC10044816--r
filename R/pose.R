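#' Tibiofemoral pose in the Grood--Suntay convention
#'
#' A `pose6` is the six degree-of-freedom configuration of the tibia relative
#' to the femur: three rotations in degrees (flexion, adduction, internal
#' rotation) and three translations in millimetres (anterior, proximal,
#' lateral).  The body frames are right-handed with x anterior, y proximal
#' and z lateral (right knee).  Flexion is the rotation about the femoral
#' medio-lateral axis, internal rotation the rotation about the tibial long
#' axis, and adduction the rotation about the floating axis between them
#' (Euler sequence z-x-y applied femur-to-tibia).  Translations are the
#' components of the tibial origin in the flexion-rotated femoral frame.
#'
#' @param flex,add,ir rotations in degrees.
#' @param ant,prox,lat translations in mm.
#' @return an object of class `pose6` (named numeric vector of length 6).
#' @export
#' @examples
#' pose6(flex = 30, ir = 5)
pose6 <- function(flex = 0, add = 0, ir = 0, ant = 0, prox = 0, lat = 0) {
  p <- c(flex = flex, add = add, ir = ir, ant = ant, prox = prox, lat = lat)
  if (!all(is.finite(p))) stop("pose6: all coordinates must be finite")
  structure(p, class = "pose6")
}

#' @export
print.pose6 <- function(x, ...) {
  cat(sprintf(
    "pose6: flex %.2f deg, add %.2f deg, ir %.2f deg | ant %.2f, prox %.2f, lat %.2f mm\n",
    x[["flex"]], x[["add"]], x[["ir"]], x[["ant"]], x[["prox"]], x[["lat"]]))
  invisible(x)
}

rot_x <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}
rot_y <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}
rot_z <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

DEG <- pi / 180

#' Rigid transform of the tibia frame relative to the femur frame
#'
#' Maps tibia-frame coordinates to femur-frame coordinates:
#' `x_femur = R %*% x_tibia + p`.  The rotation is the Euler chain
#' `Rz(-flex) Rx(add) Ry(ir)` and the translation is the anterior/proximal/
#' lateral vector expressed in the flexion-rotated femoral frame.
#'
#' @param pose a [pose6()].
#' @return list with 3x3 rotation `R` and 3-vector `p` (mm).
#' @export
pose_to_transform <- function(pose) {
  f <- pose[["flex"]] * DEG
  a <- pose[["add"]] * DEG
  g <- pose[["ir"]] * DEG
  Rf <- rot_z(-f)
  R <- Rf %*% rot_x(a) %*% rot_y(g)
  p <- Rf %*% c(pose[["ant"]], pose[["prox"]], pose[["lat"]])
  list(R = R, p = as.numeric(p))
}

#' Decode a rigid transform into Grood--Suntay coordinates
#'
#' Inverse of [pose_to_transform()].  Errors at the gimbal configuration
#' (|adduction| = 90 degrees), where flexion and internal rotation are not
#' separable.
#'
#' @param R 3x3 rotation matrix (tibia axes in femur coordinates).
#' @param p 3-vector translation, mm.
#' @return a [pose6()].
#' @export
transform_to_pose <- function(R, p) {
  sa <- max(-1, min(1, R[3, 2]))
  a <- asin(sa)
  if (abs(cos(a)) < 1e-8)
    stop("transform_to_pose: degenerate pose (|adduction| = 90 degrees)")
  g <- atan2(-R[3, 1], R[3, 3])
  f <- atan2(R[1, 2], R[2, 2])
  t_loc <- crossprod(rot_z(-f), p)
  pose6(flex = f / DEG, add = a / DEG, ir = g / DEG,
        ant = t_loc[1], prox = t_loc[2], lat = t_loc[3])
}

#' Pose of the tibia relative to the femur from two body frames
#'
#' Both frames are given as rigid transforms from body to world coordinates
#' (`list(R =, p =)`).  The relative transform `inv(femur) o tibia` is decoded
#' into Grood--Suntay coordinates.
#'
#' @param femur_frame,tibia_frame lists with fields `R` (3x3 rotation) and
#'   `p` (3-vector, mm).
#' @return a [pose6()].
#' @export
#' @examples
#' id <- list(R = diag(3), p = c(0, 0, 0))
#' grood_suntay_pose(id, id)   # all six coordinates zero
grood_suntay_pose <- function(femur_frame, tibia_frame) {
  for (fr in list(femur_frame, tibia_frame)) {
    R <- fr$R
    if (max(abs(crossprod(R) - diag(3))) > 1e-8 || det(R) < 0)
      stop("grood_suntay_pose: frames must be proper rigid transforms")
  }
  Rrel <- crossprod(femur_frame$R, tibia_frame$R)
  prel <- as.numeric(crossprod(femur_frame$R, tibia_frame$p - femur_frame$p))
  transform_to_pose(Rrel, prel)
}
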