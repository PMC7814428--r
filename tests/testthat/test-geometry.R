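test_that("true-lateral hinge axis lies in the sagittal plane at the cut inclination", {
  expect_equal(hinge_axis(0), c(0, 1, 0))
  expect_equal(hinge_axis(10), c(0, cos(10 * DEG), sin(10 * DEG)))
  expect_equal(hinge_axis(-10), c(0, cos(10 * DEG), -sin(10 * DEG)))
  expect_error(hinge_axis(90), "invalid plan")
  expect_error(osteotomy_plan(95, 10), "invalid plan")
  expect_error(osteotomy_plan(10, -5), "correction")
})

test_that("rotation about an axis behaves as a rigid rotation", {
  v <- c(0.3, -1.2, 2.5)
  expect_equal(rotate_about_axis(v, c(0, 1, 0), 0), v)
  axis <- c(1, 2, 2) / 3
  expect_equal(rotate_about_axis(axis * 4.2, axis, 73), axis * 4.2)
  expect_equal(rotate_about_axis(c(0, 0, 1), c(0, 1, 0), 90), c(1, 0, 0))
  expect_error(rotate_about_axis(v, c(1, 1, 0), 10), "unit")
  # length preservation and agreement with an explicit rotation matrix
  set.seed(11)
  for (i in 1:25) {
    a <- rnorm(3); a <- a / sqrt(sum(a^2))
    w <- rnorm(3); ang <- runif(1, -180, 180)
    r <- rotate_about_axis(w, a, ang)
    expect_equal(sqrt(sum(r^2)), sqrt(sum(w^2)), tolerance = 1e-12)
    expect_equal(r, as.vector(rotation_matrix(a, ang) %*% w), tolerance = 1e-12)
  }
})

test_that("sagittal slope is the projected inclination, positive rising anteriorly", {
  expect_equal(sagittal_slope_angle(c(0, cos(10 * DEG), sin(10 * DEG))), 10)
  expect_equal(sagittal_slope_angle(c(0, 1, 0)), 0)
  expect_equal(sagittal_slope_angle(c(0.7, 1, tan(25 * DEG))), 25)
  expect_error(sagittal_slope_angle(c(1, 0, 1)), "degenerate")
})

test_that("a cut parallel to the plateau preserves the slope exactly; other cuts follow the closed form", {
  # parallel invariance, exact at every correction
  expect_identical(closed_form_pts(10, 10, seq(0, 30, 0.5)),
                   rep(10, 61))
  d <- opened_slope_direction(10, osteotomy_plan(10, 17))
  expect_equal(sagittal_slope_angle(d), 10, tolerance = 1e-12)
  # identity at zero correction for any inclination
  set.seed(4)
  phis <- runif(20, -60, 60)
  expect_equal(closed_form_pts(10, phis, 0), rep(10, 20), tolerance = 1e-12)
  # printed-table spot values (0.1-degree rounding)
  expect_equal(round_half_away(closed_form_pts(10, 20, 30)), 11.3)
  expect_equal(round_half_away(closed_form_pts(10, 0, 30)), 8.7)
  expect_equal(round_half_away(closed_form_pts(10, -10, 20)), 8.9)
  expect_equal(round_half_away(closed_form_pts(10, 20, 25)), 10.9)
})

test_that("closed form, Rodrigues pipeline and corner-rotation oracle agree", {
  set.seed(7)
  for (i in 1:200) {
    a0 <- runif(1, -30, 30); ph <- runif(1, -30, 30); th <- runif(1, 0, 30)
    cf <- closed_form_pts(a0, ph, th)
    rod <- sagittal_slope_angle(opened_slope_direction(a0, osteotomy_plan(ph, th)))
    expect_equal(cf, rod, tolerance = 1e-10)
    expect_equal(cf, mesh_oracle_slope(a0, ph, th, column_model(alpha0 = a0)),
                 tolerance = 1e-9)
  }
})

test_that("the measured slope is invariant to the rotation sign and to column dimensions", {
  for (ph in c(20, 0, -10)) {
    axis <- hinge_axis(ph)
    s <- c(0, cos(10 * DEG), sin(10 * DEG))
    plus <- rotate_about_axis(s, axis, 25)
    minus <- rotate_about_axis(s, axis, -25)
    expect_equal(plus[2:3], minus[2:3], tolerance = 1e-12)
    expect_equal(plus[1], -minus[1], tolerance = 1e-12)
  }
  # dimension independence, via the noise-free digitized measurement
  slopes <- sapply(list(column_model(), column_model(20, 80, 60),
                        column_model(120, 35, 200)), function(col) {
    measure_slope(digitize_endpoints(col, osteotomy_plan(20, 30), exact_noise()))
  })
  expect_equal(max(slopes) - min(slopes), 0, tolerance = 1e-10)
})

test_that("slope change is monotone in the correction angle, direction set by the cut inclination", {
  th <- seq(0, 30, by = 5)
  expect_true(all(diff(closed_form_pts(10, 20, th)) > 0))
  expect_true(all(diff(closed_form_pts(10, 0, th)) < 0))
  expect_true(all(diff(closed_form_pts(10, -10, th)) < 0))
  expect_true(all(closed_form_pts(10, -10, th[-1]) <
                    closed_form_pts(10, 0, th[-1])))
})

test_that("small corrections obey the quadratic law d(slope) ~ (theta^2/4) sin(2(phi - alpha0))", {
  set.seed(21)
  for (i in 1:20) {
    a0 <- runif(1, -25, 25); ph <- runif(1, -25, 25)
    lim <- sin(2 * (ph - a0) * DEG) / 4
    for (th in c(0.1, 0.05)) {
      ratio <- (closed_form_pts(a0, ph, th) - a0) * DEG / (th * DEG)^2
      expect_lt(abs(ratio - lim), 1e-4)
    }
  }
})

test_that("rigid fragment motion fixes the hinge line and elevates the medial side", {
  plan <- osteotomy_plan(10, 12)
  hp <- c(0, 0, 50)
  p <- c(37, 12, 88)
  expect_equal(transform_point(p, osteotomy_plan(10, 0), hp), p)
  on_hinge <- hp + 3.7 * hinge_axis(10)
  expect_equal(transform_point(on_hinge, plan, hp), on_hinge, tolerance = 1e-12)
  medial_top <- c(50, 0, 95)
  moved <- transform_point(medial_top, plan, hp)
  expect_gt(moved[3], medial_top[3])
  # agrees with an explicit rotation-matrix computation
  expected <- hp + as.vector(rotation_matrix(hinge_axis(10), -12) %*% (p - hp))
  expect_equal(transform_point(p, plan, hp), expected, tolerance = 1e-12)
})
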