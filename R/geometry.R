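DEG <- pi / 180

#' Convert between degrees and radians
#' @noRd
deg2rad <- function(x) x * DEG
rad2deg <- function(x) x / DEG

#' Round half away from zero
#'
#' Fixed-point rounding used when comparing computed slopes with printed
#' tables. Unlike [base::round()], ties are rounded away from zero
#' (10.05 -> 10.1), the convention of most clinical software.
#'
#' @param x numeric vector.
#' @param digits decimal places to keep.
#' @return numeric vector rounded to `digits` places.
#' @export
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Square-column tibia surrogate
#'
#' The proximal tibia is idealised as a square column whose top surface is
#' inclined posteriorly by `alpha0` degrees (the initial posterior slope).
#' Coordinate frame (right-handed): x = medial+, y = anterior+, z = superior+.
#' The column occupies x in [0, width_ml], y in [-depth_ap/2, depth_ap/2],
#' z from 0 up to the top plane z = height + y * tan(alpha0), so the lateral
#' face sits at x = 0 and the slope line rises anteriorly for positive
#' `alpha0`.
#'
#' @param width_ml medial-lateral width, mm.
#' @param depth_ap anterior-posterior depth, mm.
#' @param height column height at the mid-depth line, mm.
#' @param alpha0 initial posterior slope, degrees; must lie in (-90, 90).
#' @return an object of class `column_model`.
#' @examples
#' col <- column_model()
#' col$alpha0
#' @export
column_model <- function(width_ml = 50, depth_ap = 50, height = 100,
                         alpha0 = 10) {
  stopifnot(is.numeric(width_ml), is.numeric(depth_ap), is.numeric(height),
            is.numeric(alpha0))
  if (width_ml <= 0 || depth_ap <= 0 || height <= 0)
    stop("column dimensions must be positive")
  if (abs(alpha0) >= 90)
    stop("alpha0 must lie strictly between -90 and 90 degrees")
  structure(list(width_ml = width_ml, depth_ap = depth_ap, height = height,
                 alpha0 = alpha0),
            class = "column_model")
}

#' @export
print.column_model <- function(x, ...) {
  cat(sprintf(
    "Square column model: %g x %g x %g mm, posterior slope %g deg\n",
    x$width_ml, x$depth_ap, x$height, x$alpha0))
  invisible(x)
}

#' One simulated medial open-wedge osteotomy
#'
#' @param spoi sagittal plane osteotomy inclination, degrees. Positive values
#'   descend posteriorly, the same sign convention as the posterior slope, so
#'   `spoi == alpha0` means the cut parallels the plateau.
#' @param correction opening-wedge (correction) angle, degrees; must be >= 0.
#' @param hinge_axis_override optional length-3 unit vector replacing the
#'   true-lateral hinge direction derived from `spoi`.
#' @return an object of class `osteotomy_plan`.
#' @examples
#' osteotomy_plan(spoi = 20, correction = 30)
#' @export
osteotomy_plan <- function(spoi, correction, hinge_axis_override = NULL) {
  if (!is.numeric(spoi) || abs(spoi) >= 90)
    stop("invalid plan: |spoi| must be < 90 degrees")
  if (!is.numeric(correction) || correction < 0)
    stop("invalid plan: correction angle must be >= 0")
  if (!is.null(hinge_axis_override)) {
    stopifnot(is.numeric(hinge_axis_override),
              length(hinge_axis_override) == 3)
    if (abs(sqrt(sum(hinge_axis_override^2)) - 1) > 1e-12)
      stop("hinge_axis_override must be a unit vector")
  }
  structure(list(spoi = spoi, correction = correction,
                 hinge_axis_override = hinge_axis_override),
            class = "osteotomy_plan")
}

#' @export
print.osteotomy_plan <- function(x, ...) {
  cat(sprintf("Osteotomy plan: SPOI %g deg, correction %g deg%s\n",
              x$spoi, x$correction,
              if (is.null(x$hinge_axis_override)) " (true lateral hinge)"
              else " (custom hinge axis)"))
  invisible(x)
}

#' True-lateral hinge axis direction
#'
#' A true lateral hinge is parallel to the osteotomy line in the axial view:
#' it lies in the osteotomy plane, has no medial-lateral component, and makes
#' angle `spoi` with the axial plane, descending posteriorly for positive
#' `spoi`. In the fixed frame (x medial+, y anterior+, z superior+) this is
#' the unit vector (0, cos(spoi), sin(spoi)).
#'
#' @param spoi sagittal plane osteotomy inclination, degrees, |spoi| < 90.
#' @return unit direction vector of length 3.
#' @examples
#' hinge_axis(0)   # (0, 1, 0)
#' hinge_axis(10)
#' @export
hinge_axis <- function(spoi) {
  if (!is.numeric(spoi) || abs(spoi) >= 90)
    stop("invalid plan: |spoi| must be < 90 degrees")
  c(0, cos(deg2rad(spoi)), sin(deg2rad(spoi)))
}

#' Rodrigues rotation of a vector about a unit axis
#'
#' v cos(t) + (axis x v) sin(t) + axis (axis . v)(1 - cos(t)); preserves
#' length to machine precision.
#'
#' @param v numeric length-3 vector.
#' @param axis unit direction, length 3.
#' @param angle rotation angle in degrees (right-hand rule about `axis`).
#' @return rotated vector, length 3.
#' @export
rotate_about_axis <- function(v, axis, angle) {
  stopifnot(is.numeric(v), length(v) == 3,
            is.numeric(axis), length(axis) == 3)
  if (abs(sqrt(sum(axis^2)) - 1) > 1e-9)
    stop("axis must be unit length")
  t <- deg2rad(angle)
  cx <- c(axis[2] * v[3] - axis[3] * v[2],
          axis[3] * v[1] - axis[1] * v[3],
          axis[1] * v[2] - axis[2] * v[1])
  v * cos(t) + cx * sin(t) + axis * sum(axis * v) * (1 - cos(t))
}

#' Slope-line direction after wedge opening
#'
#' Takes the top-surface slope-line direction (0, cos(alpha0), sin(alpha0)),
#' rotates it about the hinge axis by the plan's correction angle, and
#' returns the unit result. Only directions matter here; the hinge point
#' cancels out of the slope measurement.
#'
#' @param alpha0 initial posterior slope, degrees.
#' @param plan an [osteotomy_plan()].
#' @return unit direction, length 3.
#' @export
opened_slope_direction <- function(alpha0, plan) {
  stopifnot(inherits(plan, "osteotomy_plan"))
  axis <- if (is.null(plan$hinge_axis_override)) hinge_axis(plan$spoi)
          else plan$hinge_axis_override
  s <- c(0, cos(deg2rad(alpha0)), sin(deg2rad(alpha0)))
  r <- rotate_about_axis(s, axis, plan$correction)
  r / sqrt(sum(r^2))
}

#' Sagittal-plane inclination of a direction
#'
#' The posterior slope is measured in the sagittal (y-z) plane: the direction
#' is projected onto that plane and its inclination to the horizontal is
#' atan(d_z / d_y), positive when the line rises anteriorly. This is the
#' projected angle, not the 3D elevation angle asin(d_z).
#'
#' @param d numeric length-3 direction with nonzero anteroposterior component.
#' @return angle in degrees.
#' @export
sagittal_slope_angle <- function(d) {
  stopifnot(is.numeric(d), length(d) == 3)
  if (abs(d[2]) < 1e-300)
    stop("degenerate direction: zero anteroposterior component")
  rad2deg(atan(d[3] / d[2]))
}

#' Posterior slope after correction, closed form
#'
#' Analytic collapse of the Rodrigues pipeline: for initial slope alpha0,
#' osteotomy inclination spoi (phi) and correction theta (all degrees), the
#' post-correction sagittal slope is
#' atan( (sin a0 cos t + sin phi cos(a0 - phi)(1 - cos t)) /
#'       (cos a0 cos t + cos phi cos(a0 - phi)(1 - cos t)) ).
#' Vectorised over its arguments (recycled to a common length).
#'
#' @param alpha0 initial posterior slope, degrees.
#' @param spoi osteotomy inclination, degrees.
#' @param theta correction angle, degrees.
#' @return slope in degrees (unrounded).
#' The expression is evaluated in the equivalent form
#' atan( (sin a0 + (1 - cos t) dz) / (cos a0 + (1 - cos t) dy) ) with
#' dz = sin phi cos(a0 - phi) - sin a0, dy = cos phi cos(a0 - phi) - cos a0,
#' so that when the cut parallels the slope (dz = dy = 0, the theta-dependence
#' vanishes identically) the analytic reduction to alpha0 is returned exactly.
#'
#' @examples
#' closed_form_pts(10, 20, 30)  # 11.317...
#' closed_form_pts(10, 10, 0:30)  # constant 10: cut parallel to the slope
#' @export
closed_form_pts <- function(alpha0, spoi, theta) {
  n <- max(length(alpha0), length(spoi), length(theta))
  a0 <- deg2rad(rep_len(alpha0, n))
  ph <- deg2rad(rep_len(spoi, n))
  th <- deg2rad(rep_len(theta, n))
  cc <- cos(a0 - ph)
  dz <- sin(ph) * cc - sin(a0)
  dy <- cos(ph) * cc - cos(a0)
  z <- sin(a0) + (1 - cos(th)) * dz
  y <- cos(a0) + (1 - cos(th)) * dy
  if (any(y <= 0))
    stop("out of domain: anteroposterior component not positive")
  out <- rad2deg(atan(z / y))
  parallel <- dz == 0 & dy == 0
  out[parallel] <- rep_len(alpha0, n)[parallel]
  out
}

# Slope-line direction after rotating by `theta` about the true-lateral hinge
# axis of `spoi`, in the algebraically reduced component form. Exact for the
# parallel cut (spoi == alpha0): all theta-dependent terms vanish identically,
# so the direction is bit-for-bit (0, cos a0, sin a0) at every theta.
slope_direction_reduced <- function(alpha0, spoi, theta) {
  a0 <- deg2rad(alpha0); ph <- deg2rad(spoi); th <- deg2rad(theta)
  cc <- cos(a0 - ph)
  c(sin(a0 - ph) * sin(th),
    cos(a0) + (1 - cos(th)) * (cos(ph) * cc - cos(a0)),
    sin(a0) + (1 - cos(th)) * (sin(ph) * cc - sin(a0)))
}

#' Rigid motion of a proximal-fragment point
#'
#' Rotates a point about the hinge line (through `hinge_point` along the plan's
#' hinge axis) by the correction angle, with the sign that elevates the medial
#' side of the fragment (the wedge opens medially). Callers apply this only to
#' proximal-fragment points; the distal fragment stays fixed.
#'
#' @param p numeric length-3 point, mm.
#' @param plan an [osteotomy_plan()].
#' @param hinge_point a point on the hinge line, length 3, mm.
#' @return transformed point, length 3.
#' @export
transform_point <- function(p, plan, hinge_point) {
  stopifnot(inherits(plan, "osteotomy_plan"),
            is.numeric(p), length(p) == 3,
            is.numeric(hinge_point), length(hinge_point) == 3)
  axis <- if (is.null(plan$hinge_axis_override)) hinge_axis(plan$spoi)
          else plan$hinge_axis_override
  # negative angle about (0, cos phi, sin phi) lifts +x (medial) points
  hinge_point + rotate_about_axis(p - hinge_point, axis, -plan$correction)
}
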