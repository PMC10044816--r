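#' Shortest wrapped segment length around a sphere
#'
#' Length of the shortest path from `a` to `b` that does not enter the sphere
#' `(center, radius)`.  When the straight segment clears the sphere the chord
#' length is returned; otherwise the tangent--arc--tangent geodesic in the
#' plane through `a`, `b` and the centre.
#'
#' @param a,b segment endpoints (3-vectors, mm).
#' @param center sphere centre (3-vector, mm).
#' @param radius sphere radius, mm.
#' @return path length, mm; never less than the chord length.
#' @keywords internal
segment_length_sphere <- function(a, b, center, radius) {
  ab <- b - a
  chord <- sqrt(sum(ab^2))
  da <- sqrt(sum((a - center)^2))
  db <- sqrt(sum((b - center)^2))
  if (da < radius || db < radius)
    stop("path_length: attachment or via point inside wrap sphere")
  if (chord < 1e-12) return(chord)
  # closest approach of the segment to the centre
  t <- sum((center - a) * ab) / chord^2
  t <- max(0, min(1, t))
  dmin <- sqrt(sum((a + t * ab - center)^2))
  if (dmin >= radius) return(chord)
  phi <- acos(max(-1, min(1, sum((a - center) * (b - center)) / (da * db))))
  alpha <- acos(max(-1, min(1, radius / da)))
  beta <- acos(max(-1, min(1, radius / db)))
  arc <- phi - alpha - beta
  if (arc <= 0) return(chord)  # tangent lines meet outside the sphere
  sqrt(da^2 - radius^2) + sqrt(db^2 - radius^2) + radius * arc
}

#' Shortest wrapped segment length around an infinite cylinder
#'
#' The segment is projected onto the plane perpendicular to the cylinder
#' axis; the planar tangent--arc--tangent length around the circle is combined
#' with the axial travel by unrolling the cylinder (the geodesic is straight
#' on the unrolled surface).
#'
#' @param a,b segment endpoints (3-vectors, mm).
#' @param point a point on the axis; `axis` a unit 3-vector.
#' @param radius cylinder radius, mm.
#' @keywords internal
segment_length_cylinder <- function(a, b, point, axis, radius) {
  axis <- axis / sqrt(sum(axis^2))
  za <- sum((a - point) * axis)
  zb <- sum((b - point) * axis)
  pa <- (a - point) - za * axis
  pb <- (b - point) - zb * axis
  ra <- sqrt(sum(pa^2)); rb <- sqrt(sum(pb^2))
  if (ra < radius || rb < radius)
    stop("path_length: attachment or via point inside wrap cylinder")
  chord2 <- sqrt(sum((pb - pa)^2))
  straight <- sqrt(sum((b - a)^2))
  if (chord2 < 1e-12) return(straight)
  t <- sum((-pa) * (pb - pa)) / chord2^2
  t <- max(0, min(1, t))
  dmin <- sqrt(sum((pa + t * (pb - pa))^2))
  if (dmin >= radius) return(straight)
  phi <- acos(max(-1, min(1, sum(pa * pb) / (ra * rb))))
  alpha <- acos(max(-1, min(1, radius / ra)))
  beta <- acos(max(-1, min(1, radius / rb)))
  arc <- phi - alpha - beta
  if (arc <= 0) return(straight)
  s_plane <- sqrt(ra^2 - radius^2) + sqrt(rb^2 - radius^2) + radius * arc
  sqrt(s_plane^2 + (zb - za)^2)
}

wrapped_segment_length <- function(a, b, wrap) {
  if (is.null(wrap)) return(sqrt(sum((b - a)^2)))
  if (wrap$shape == "sphere") {
    segment_length_sphere(a, b, wrap$center, wrap$radius)
  } else if (wrap$shape == "cylinder") {
    segment_length_cylinder(a, b, wrap$center, wrap$axis, wrap$radius)
  } else {
    stop("unknown wrap shape: ", wrap$shape)
  }
}

#' Path length of a ligament bundle at a pose
#'
#' Transforms the tibial attachment (and any tibia-fixed via points) into the
#' femoral frame at the given pose and accumulates segment lengths through
#' the ordered via points.  Each segment assigned a wrap object takes the
#' shortest path around it; the result is never less than the straight-line
#' polyline length.
#'
#' @param bundle a bundle entry of a knee model (list with `femur`, `tibia`,
#'   optional `via` list of `list(point=, body=)`, optional `wrap` name).
#' @param geom a [generate_specimen()] geometry (supplies wrap objects).
#' @param pose a [pose6()].
#' @return path length in mm.
#' @export
path_length <- function(bundle, geom, pose) {
  tf <- pose_to_transform(pose)
  pts <- bundle_polyline(bundle, tf)
  wrap <- if (!is.null(bundle$wrap) && !is.na(bundle$wrap))
    geom$wrap_objects[[bundle$wrap]] else NULL
  total <- 0
  for (i in seq_len(nrow(pts) - 1)) {
    total <- total + wrapped_segment_length(pts[i, ], pts[i + 1, ], wrap)
  }
  total
}

# polyline points in the femur frame (femur attachment first)
bundle_polyline <- function(bundle, tf) {
  pts <- list(bundle$femur)
  if (!is.null(bundle$via)) {
    for (v in bundle$via) {
      pts[[length(pts) + 1]] <-
        if (v$body == "femur") v$point
        else as.numeric(tf$R %*% v$point + tf$p)
    }
  }
  pts[[length(pts) + 1]] <- as.numeric(tf$R %*% bundle$tibia + tf$p)
  do.call(rbind, pts)
}
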