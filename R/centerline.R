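# Tube center-line construction for derived structures.
#
# Frame convention: the cut plane is the x-z plane; hemisphere A occupies
# y >= 0 and B y <= 0; the polar axis of hemisphere A's tori is z; the
# hemisphere rotation axis is y (perpendicular to the cut plane).  Meridian
# position i sits at angle alpha_i (see derived_connectivity) on the circle
# of radius R_c in the cut plane: P_i = R_c (cos a, 0, sin a).

# rotate points about the y axis so the in-plane angle alpha advances by phi
rot_y <- function(pts, phi) {
  cbind(pts[, 1] * cos(phi) - pts[, 3] * sin(phi),
        pts[, 2],
        pts[, 1] * sin(phi) + pts[, 3] * cos(phi))
}

# half-circle of the (possibly rotated) latitude torus joining meridian
# positions with angles a1 -> pi - a1, traversed through hemisphere `side`
arc_points <- function(a1, R_c, side, phi, npts) {
  b1 <- a1 - phi                       # angle in the hemisphere's own frame
  f <- seq(0, pi, length.out = npts)
  ysign <- if (side == "A") 1 else -1
  pts <- cbind(R_c * cos(b1) * cos(f),
               ysign * R_c * abs(cos(b1)) * sin(f),
               rep(R_c * sin(b1), npts))
  if (side == "A") pts else rot_y(pts, phi)
}

#' Center-lines of a derived structure
#'
#' Builds the 3-D tube center-lines on the mid-shell sphere: half-circles of
#' the original tori in hemisphere A, the rotated half-circles in hemisphere
#' B, and isolated polar points for sphere components. Consecutive arcs of a
#' component join continuously at the cut plane.
#'
#' @param structure a [derived_connectivity()] result.
#' @param shell a [shell_geometry()] (sets R_c).
#' @param points_per_arc sampling density of each half-circle.
#' @return List of components; each is a list with `type` ("closed", "open"
#'   or "sphere"), `points` (matrix of 3-D points; first equals last for
#'   closed loops; a single point for spheres) and `length` (polyline arc
#'   length).
#' @export
generate_centerline <- function(structure, shell, points_per_arc = 40) {
  R_c <- shell$R_c
  ang <- structure$position_angle
  phi <- structure$m * structure$theta / 2
  side_phi <- function(side) if (side == "A") 0 else phi
  out <- lapply(structure$components, function(cc) {
    if (cc$type == "sphere") {
      a <- ang[cc$positions[1] + 1]
      pts <- matrix(c(R_c * cos(a), 0, R_c * sin(a)), ncol = 3)
      return(list(type = "sphere", points = pts, length = 0))
    }
    pos <- cc$positions
    k <- length(cc$edges)
    pts <- NULL
    for (e in seq_len(k)) {
      p <- pos[e]
      side <- cc$edges[e]
      a1 <- ang[p + 1]
      seg <- arc_points(a1, R_c, side, side_phi(side), points_per_arc)
      pts <- if (is.null(pts)) seg else rbind(pts, seg[-1, , drop = FALSE])
    }
    len <- sum(sqrt(rowSums(diff(pts)^2)))
    list(type = if (cc$type == "closed") "closed" else "open",
         points = pts, length = len)
  })
  out
}

# discrete torsion sign of a polyline: mean sign of the triple products of
# consecutive tangents; flips under mirror reflection
polyline_torsion <- function(pts) {
  if (nrow(pts) < 4) return(0)
  v <- diff(pts)
  n <- nrow(v)
  tp <- vapply(seq_len(n - 2), function(i) {
    cr <- c(v[i, 2] * v[i + 1, 3] - v[i, 3] * v[i + 1, 2],
            v[i, 3] * v[i + 1, 1] - v[i, 1] * v[i + 1, 3],
            v[i, 1] * v[i + 1, 2] - v[i, 2] * v[i + 1, 1])
    sum(cr * v[i + 2, ])
  }, 0)
  mean(tp)
}

#' Handedness of a derived structure's center-lines
#'
#' Sign of the average discrete torsion over all tube components; positive
#' and negative rotations give mirror-image (opposite-handed) structures.
#'
#' @param centerlines result of [generate_centerline()].
#' @return -1, 0 or +1.
#' @export
centerline_handedness <- function(centerlines) {
  tau <- sum(vapply(centerlines,
                    function(cl) if (nrow(cl$points) >= 4) polyline_torsion(cl$points) else 0,
                    0))
  if (abs(tau) < 1e-10) 0 else sign(tau)
}
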