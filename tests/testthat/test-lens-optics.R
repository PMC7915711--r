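test_that("vector refraction obeys Snell's law and handles its edge cases", {
  # normal incidence: direction unchanged for any index pair
  r <- refract(c(0, 1), c(0, -1), 1, 1.7)
  expect_false(r$tir)
  expect_equal(r$direction, c(0, 1), tolerance = 1e-12)

  # 45 degrees into n = 1.519 -> 27.744 degrees (scalar closed form)
  d <- c(sin(pi / 4), cos(pi / 4))
  r <- refract(d, c(0, -1), 1, 1.519)
  expect_equal(asin(r$direction[1]) * 180 / pi, 27.744, tolerance = 1e-3)

  # 45 degrees from glass to air exceeds the 41.17 degree critical angle
  r <- refract(d, c(0, -1), 1.519, 1)
  expect_true(r$tir)
  expect_null(r$direction)

  expect_error(refract(c(0, 2), c(0, -1), 1, 1.5), "unit")
  expect_error(refract(c(0, 1), c(0, 0), 1, 1.5), "zero length")
})

test_that("vector refraction matches the scalar closed form on random cases", {
  set.seed(42)
  for (i in 1:1000) {
    theta_n <- runif(1, 0, 2 * pi)             # normal orientation
    theta_i <- runif(1, -pi / 2 + 0.01, pi / 2 - 0.01)
    ns <- sort(runif(2, 1, 2))
    if (runif(1) < 0.5) ns <- rev(ns)
    normal <- c(cos(theta_n), sin(theta_n))
    # incident direction at angle theta_i from the inward normal
    inward <- -normal
    rot <- matrix(c(cos(theta_i), sin(theta_i), -sin(theta_i), cos(theta_i)), 2)
    d <- as.numeric(rot %*% inward)
    r <- refract(d, normal, ns[1], ns[2])
    expected <- snell_oracle_angle(theta_i, ns[1], ns[2])
    if (is.na(expected)) {
      expect_true(r$tir)
    } else {
      expect_false(r$tir)
      # signed angle of refracted direction about the inward normal
      got <- atan2(inward[1] * r$direction[2] - inward[2] * r$direction[1],
                   sum(inward * r$direction))
      expect_equal(got, expected, tolerance = 1e-9)
      expect_equal(sqrt(sum(r$direction^2)), 1, tolerance = 1e-12)
    }
  }
})

test_that("lens_design validates its invariants", {
  expect_error(lens_design(inner_radius_mm = 12), "outer_radius_mm")
  expect_error(lens_design(aperture_lateral_mm = 17), "marginal ray")
  expect_error(lens_design(refractive_index = 0.9), "refractive_index")
  expect_error(lens_design(oblique_inclination_deg = 0), "oblique")
  expect_error(lens_design(source_na = 1), "source_na")
})

test_that("the default lateral fan reproduces the designed field of view", {
  tr <- trace_lateral(lens_design(), n_rays = 1001)
  expect_gt(tr$fov_full_angle_deg, 105 * 0.9)
  expect_lt(tr$fov_full_angle_deg, 105 * 1.1)
  # chief ray exits undeviated
  chief <- tr$rays[tr$rays$h_mm == 0, ]
  expect_equal(chief$exit_angle_deg, 0, tolerance = 1e-9)
})

test_that("an index-matched lens does not deviate the fan", {
  tr <- trace_lateral(lens_design(refractive_index = 1 + 1e-12), n_rays = 101)
  expect_equal(tr$fov_full_angle_deg, 0, tolerance = 1e-6)
})

test_that("the concentric variant conserves Bouguer's invariant", {
  lens <- lens_design(geometry = "concentric")
  tr <- trace_lateral(lens, n_rays = 201)
  n <- lens$refractive_index
  rays <- tr$rays[!tr$rays$tir & !tr$rays$vignetted, ]
  # n * r * sin(phi), phi measured from the radial direction about the
  # shared arc center (origin); equals the entry height h for a beam
  # parallel to the axis.
  invariant_at <- function(px, pz, dx, dz, nn) {
    r <- sqrt(px^2 + pz^2)
    sin_phi <- (px * dz - pz * dx) / r      # cross product with unit dir
    nn * r * abs(sin_phi)
  }
  inside <- invariant_at(rays$entry_x, rays$entry_z,
                         (rays$exit_x - rays$entry_x) /
                           sqrt((rays$exit_x - rays$entry_x)^2 +
                                (rays$exit_z - rays$entry_z)^2),
                         (rays$exit_z - rays$entry_z) /
                           sqrt((rays$exit_x - rays$entry_x)^2 +
                                (rays$exit_z - rays$entry_z)^2), n)
  outside <- invariant_at(rays$exit_x, rays$exit_z, rays$dir_x, rays$dir_z, 1)
  skip_h0 <- abs(rays$h_mm) > 1e-9        # chief ray has zero invariant
  expect_equal(inside[skip_h0], abs(rays$h_mm[skip_h0]), tolerance = 1e-9)
  expect_equal(outside[skip_h0], abs(rays$h_mm[skip_h0]), tolerance = 1e-9)
})

test_that("concentric marginal-ray incidence follows the chord geometry", {
  lens <- lens_design(geometry = "concentric")
  tr <- trace_lateral(lens, n_rays = 201)
  marg <- tr$rays[which.max(tr$rays$h_mm), ]
  # angle between the axial ray and the radial entry normal
  cos_i <- marg$entry_z / lens$inner_radius_mm
  expect_equal(acos(cos_i) * 180 / pi, asin(6.5 / 8) * 180 / pi,
               tolerance = 1e-9)
})

test_that("concentric divergence grows as the entry arc tightens", {
  fovs <- vapply(c(7, 7.5, 8), function(ri) {
    trace_lateral(lens_design(inner_radius_mm = ri, geometry = "concentric"),
                  n_rays = 101)$fov_full_angle_deg
  }, 0)
  expect_true(all(diff(fovs) < 0))
})

test_that("reversed exit rays trace back to their entry heights", {
  lens <- lens_design()
  geom <- patrus:::lens_surfaces(lens)
  n <- lens$refractive_index
  tr <- trace_lateral(lens, n_rays = 41)
  rays <- tr$rays[!tr$rays$tir & !tr$rays$vignetted, ]
  # travelling backwards, the nearest intersection is the right one for
  # both surfaces
  back_exit <- geom$exit; back_exit$branch <- "near"
  back_entry <- geom$entry; back_entry$branch <- "near"
  back_surfaces <- list(back_exit, back_entry)
  for (i in seq_len(nrow(rays))) {
    start <- c(rays$exit_x[i], rays$exit_z[i]) +
      0.5 * c(rays$dir_x[i], rays$dir_z[i])
    bt <- patrus:::trace_ray_2d(start, -c(rays$dir_x[i], rays$dir_z[i]),
                                back_surfaces, list(c(1, n), c(n, 1)))
    expect_true(is.na(bt$loss))
    # back at the entry plane the ray must sit at height h going straight
    expect_equal(bt$direction, c(0, -1), tolerance = 1e-9)
    t_back <- (geom$z_start - bt$origin[2]) / bt$direction[2]
    x_back <- bt$origin[1] + t_back * bt$direction[1]
    expect_equal(x_back, rays$h_mm[i], tolerance = 1e-6)
  }
})

test_that("ray weights are conserved through the tracer", {
  tr <- trace_lateral(lens_design(), n_rays = 1001)
  surv <- sum(tr$rays$weight[!tr$rays$tir & !tr$rays$vignetted])
  lost <- sum(tr$rays$weight[tr$rays$tir | tr$rays$vignetted])
  expect_identical(surv + lost, sum(tr$rays$weight))
  expect_identical(tr$n_tir + tr$n_vignetted,
                   sum(tr$rays$tir) + sum(tr$rays$vignetted))
})

test_that("the oblique elevation profile deflects per the prism closed form", {
  el <- trace_elevation(lens_design(), beam_center_offset_mm = 2.316)
  apex <- 10 * pi / 180
  expected <- (asin(1.519 * sin(apex)) - apex) * 180 / pi
  expect_equal(el$deviation_angle_deg, expected, tolerance = 1e-9)
  expect_equal(el$deviation_angle_deg, 5.294, tolerance = 1e-3)
  expect_equal(el$crossing_depth_mm, 25, tolerance = 0.01)

  # parallel faces: no deviation, crossing at infinity
  el90 <- trace_elevation(lens_design(oblique_inclination_deg = 90))
  expect_equal(el90$deviation_angle_deg, 0)
  expect_identical(el90$crossing_depth_mm, Inf)
})

test_that("fwhm uses outermost half-maximum crossings", {
  # rectangular profile of width w
  x <- seq(-20, 20, by = 0.1)
  y <- as.numeric(abs(x) <= 5)
  expect_equal(fwhm(profile_of(x, y), smooth = FALSE), 10, tolerance = 0.1)

  # Gaussian sigma = 10 -> 2 sqrt(2 ln 2) sigma = 23.548
  x <- seq(-60, 60, by = 0.1)
  y <- exp(-x^2 / 200)
  expect_equal(fwhm(profile_of(x, y), smooth = FALSE), 23.548, tolerance = 0.1)

  # bimodal: two disjoint equal rectangles span outermost crossings,
  # against the independent linear-scan oracle
  y2 <- as.numeric((x > -30 & x < -20) | (x > 15 & x < 30))
  expect_equal(fwhm(profile_of(x, y2), smooth = FALSE), fwhm_oracle(x, y2),
               tolerance = 1e-9)
  expect_gt(fwhm(profile_of(x, y2), smooth = FALSE), 45)
})

test_that("screen profiles bin all surviving weight", {
  tr <- trace_lateral(lens_design(), n_rays = 501)
  pr <- screen_profile(tr, depth_mm = 25, bin_width_mm = 1)
  surv <- sum(!tr$rays$tir & !tr$rays$vignetted)
  expect_equal(sum(pr$intensity), surv)
  expect_true(all(pr$intensity >= 0))
  expect_true(all(diff(pr$positions_mm) > 0))
  spacing <- diff(pr$positions_mm)
  expect_equal(max(spacing), min(spacing), tolerance = 1e-9)
})
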