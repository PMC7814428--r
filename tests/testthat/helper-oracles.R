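# Independent oracles used by the tests. These deliberately avoid the code
# paths they check.

DEG <- pi / 180

# Slope of the opened fragment measured from the rigid motion of the four
# top-surface corners: rotate the corners about the actual hinge line, rebuild
# the slope line through the anterior/posterior edge midpoints, project to the
# sagittal plane.
mesh_oracle_slope <- function(alpha0, spoi, theta, column = column_model()) {
  plan <- osteotomy_plan(spoi, theta)
  hp <- c(0, 0, column$height / 2)
  half <- column$depth_ap / 2
  ta <- tan(alpha0 * DEG)
  corners <- rbind(
    c(0, -half, column$height - half * ta),
    c(column$width_ml, -half, column$height - half * ta),
    c(column$width_ml, half, column$height + half * ta),
    c(0, half, column$height + half * ta))
  rot <- t(apply(corners, 1, transform_point, plan = plan, hinge_point = hp))
  d <- colMeans(rot[3:4, ]) - colMeans(rot[1:2, ])
  atan2(d[3], d[2]) / DEG
}

# Explicit rotation matrix about a unit axis (independent of the package's
# vector-form Rodrigues implementation).
rotation_matrix <- function(axis, angle_deg) {
  t <- angle_deg * DEG
  k <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(t) * k + (1 - cos(t)) * (k %*% k)
}

# Brute-force Kruskal-Wallis: the H statistic computed directly from its
# definition via group mean ranks, and the exact permutation p-value obtained
# by enumerating every assignment of pooled observations to groups.
bf_kw_h <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  h <- 12 / (n * (n + 1)) * sum(ns * (rbar - (n + 1) / 2)^2)
  tt <- table(x)
  denom <- 1 - sum(tt^3 - tt) / (n^3 - n)
  if (denom <= 0) 0 else h / denom
}

bf_kw_perm_p <- function(groups) {
  x <- unlist(groups)
  sizes <- lengths(groups)
  h_obs <- bf_kw_h(groups)
  assign_rec <- function(idx, sizes) {
    if (length(sizes) == 1) return(list(list(idx)))
    unlist(lapply(utils::combn(idx, sizes[1], simplify = FALSE), function(g1) {
      lapply(assign_rec(setdiff(idx, g1), sizes[-1]), function(r) c(list(g1), r))
    }), recursive = FALSE)
  }
  hs <- vapply(assign_rec(seq_along(x), sizes), function(a) {
    bf_kw_h(lapply(a, function(ii) x[ii]))
  }, numeric(1))
  mean(hs >= h_obs - 1e-12)
}

# Convenience: zero-noise model.
exact_noise <- function(seed = 1L) noise_model(sigma_point = 0, sigma_mount = 0,
                                               seed = seed)
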