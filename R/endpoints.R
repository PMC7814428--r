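# Planar trigonometric endpoint model of the slope change.
#
# Each slope end-point P rotates on a circle about its foot H on the hinge
# line, in the plane perpendicular to the hinge axis. Within that plane the
# height of P above the osteotomy plane is kappa = r sin(theta_i) before
# correction and kappa' = r sin(theta_i + theta) after opening the wedge by
# theta. The posterior slope is unchanged exactly when the two end-points
# share the same angle theta_i with the osteotomy-plane line.

#' Endpoint specification for the planar slope-change model
#'
#' @param r1,r2 radii (mm) of the anterior (P1) and posterior (P2) slope
#'   end-points about their feet H1, H2 on the hinge line; must be positive.
#' @param theta1,theta2 angles (degrees) of P1, P2 with the osteotomy-plane
#'   line, measured in the plane perpendicular to the hinge axis; must lie in
#'   (-90, 90).
#' @return an object of class `endpoint_spec`.
#' @export
endpoint_spec <- function(r1, r2, theta1, theta2) {
  if (r1 <= 0 || r2 <= 0) stop("radii must be positive")
  if (abs(theta1) >= 90 || abs(theta2) >= 90)
    stop("endpoint angles must lie strictly between -90 and 90 degrees")
  structure(list(r1 = r1, r2 = r2, theta1 = theta1, theta2 = theta2),
            class = "endpoint_spec")
}

#' @export
print.endpoint_spec <- function(x, ...) {
  cat(sprintf("Endpoint spec: r1 = %.3f, r2 = %.3f mm; theta1 = %.4f, theta2 = %.4f deg\n",
              x$r1, x$r2, x$theta1, x$theta2))
  invisible(x)
}

#' Height of a rotating end-point above the osteotomy plane
#'
#' kappa'(theta) = r sin(theta_i + theta); theta = 0 gives the pre-correction
#' height r sin(theta_i).
#'
#' @param r radius, mm (> 0).
#' @param theta_i initial angle of the end-point with the osteotomy-plane
#'   line, degrees.
#' @param theta correction angle, degrees.
#' @return offset in mm (vectorised over `theta`).
#' @export
endpoint_offset <- function(r, theta_i, theta) {
  if (any(r <= 0)) stop("radius must be positive")
  r * sin(deg2rad(theta_i + theta))
}

#' Endpoint model derived from the column geometry
#'
#' Computes (r1, theta1) for the anterior slope end-point and (r2, theta2)
#' for the posterior one. Each end-point sits on the top-surface midline of
#' the column; its foot H_i is its orthogonal projection onto the hinge line
#' (lateral edge of the cut, through (0, 0, cut_height) along the hinge
#' axis), so the rotation by the correction angle is planar in the plane
#' perpendicular to the axis through H_i. theta_i is measured from the
#' osteotomy-plane trace (the medial direction) towards the proximal side.
#'
#' @param column a [column_model()].
#' @param plan an [osteotomy_plan()].
#' @param cut_height height of the hinge point on the lateral face, mm.
#' @return an [endpoint_spec()].
#' @export
endpoints_from_column <- function(column, plan, cut_height = column$height / 2) {
  stopifnot(inherits(column, "column_model"), inherits(plan, "osteotomy_plan"))
  phi <- deg2rad(plan$spoi)
  a0 <- deg2rad(column$alpha0)
  axis <- hinge_axis(plan$spoi)
  h0 <- c(0, 0, cut_height)
  half <- column$depth_ap / 2
  p1 <- c(column$width_ml / 2,  half, column$height + half * tan(a0))
  p2 <- c(column$width_ml / 2, -half, column$height - half * tan(a0))
  u <- c(1, 0, 0)                      # osteotomy-plane trace, medial
  n <- c(0, -sin(phi), cos(phi))       # proximal-side normal of the plane
  polar <- function(p) {
    q <- p - h0
    q <- q - sum(q * axis) * axis      # component perpendicular to the hinge
    c(r = sqrt(sum(q^2)), th = rad2deg(atan2(sum(q * n), sum(q * u))))
  }
  e1 <- polar(p1)
  e2 <- polar(p2)
  endpoint_spec(r1 = e1[["r"]], r2 = e2[["r"]],
                theta1 = e1[["th"]], theta2 = e2[["th"]])
}

#' Is the posterior slope preserved under wedge opening?
#'
#' True exactly when the two end-point angles coincide: then both heights
#' change by the same factor under theta -> theta_i + theta and the slope of
#' the line through them is unchanged. This happens precisely when the
#' osteotomy plane parallels the posterior slope.
#'
#' @param spec an [endpoint_spec()].
#' @param tol equality tolerance in degrees.
#' @return logical scalar.
#' @export
slope_preserved <- function(spec, tol = 1e-9) {
  stopifnot(inherits(spec, "endpoint_spec"))
  abs(spec$theta1 - spec$theta2) < tol
}
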