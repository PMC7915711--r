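test_that("the walking aperture clips at the array edges", {
  expect_identical(active_channels(1, 128, 64)$count, 32L)
  expect_identical(active_channels(65, 128, 64)$count, 64L)
  expect_identical(active_channels(128, 128, 64)$count, 33L)
  # an aperture wider than the array keeps every element
  for (idx in c(1, 50, 128)) {
    expect_identical(active_channels(idx, 128, 256)$count, 128L)
  }
  expect_error(active_channels(0, 128, 64), "scanline_index")
  expect_error(active_channels(5, 128, 63), "even")
})

test_that("sector geometry inversion round-trips to machine precision", {
  arr <- default_array
  angs <- c(-60, -12.3, 0, 45.7, 67.25)
  rngs <- c(0.5, 10, 33.3, 55)
  for (a in angs) {
    for (r in rngs) {
      p <- patrus:::beam_to_cartesian(a, r, arr)
      b <- patrus:::cartesian_to_beam(p[1], p[2], arr)
      expect_equal(as.numeric(b), c(a, r), tolerance = 1e-9)
    }
  }
})

test_that("DAS focuses a point target at its true position", {
  arr <- default_array
  ph <- point_phantom(data.frame(x_mm = 3, z_mm = 25, strength = 1))
  rf <- simulate_pa_rf(ph, arr, default_pulse)
  sl <- das_beamform(rf, arr, range_step_mm = 0.1)
  pk <- locate_peak(sl, arr, 3, 25, refine = FALSE)
  # within one scanline and one range sample of the truth
  b_true <- patrus:::cartesian_to_beam(3, 25, arr)
  pitch_mm <- (arr$radius_mm + b_true[2]) * arr$pitch_deg * pi / 180
  expect_lt(pk$error_mm, pitch_mm + 0.1)
})

test_that("all-zero RF beamforms to all-zero scanlines", {
  empty <- point_phantom(data.frame(x_mm = numeric(), z_mm = numeric(),
                                    strength = numeric()))
  rf <- simulate_pa_rf(empty, default_array, default_pulse, t_max_us = 20)
  sl <- das_beamform(rf, default_array, range_step_mm = 0.5)
  expect_true(all(sl$amplitude == 0))
  env <- envelope_logcompress(sl, 35)
  expect_true(all(env$amplitude == 0))
})

test_that("coherence weighting preserves coherent peaks and crushes noise", {
  arr <- default_array
  ph <- point_phantom(data.frame(x_mm = 0, z_mm = 20, strength = 1))
  rf <- simulate_pa_rf(ph, arr, default_pulse)
  plain <- das_beamform(rf, arr, range_step_mm = 0.1)
  cf <- das_beamform(rf, arr, weighting = "coherence", range_step_mm = 0.1)
  ppk <- locate_peak(plain, arr, 0, 20)
  cpk <- locate_peak(cf, arr, 0, 20)
  # at the focus the channels are delay-aligned (coherence factor near 1,
  # below 1 only through the 1/r amplitude taper across the aperture)
  expect_gt(cpk$amplitude / ppk$amplitude, 0.6)

  # identical channel samples are perfectly coherent: CF = 1 exactly
  rf_ones <- rf
  rf_ones$samples <- matrix(1, 200, arr$n_elements)
  p1 <- das_beamform(rf_ones, arr, range_max_mm = 5, range_step_mm = 0.5,
                     scanlines = 65)
  c1 <- das_beamform(rf_ones, arr, weighting = "coherence",
                     range_max_mm = 5, range_step_mm = 0.5, scanlines = 65)
  expect_equal(c1$amplitude, p1$amplitude, tolerance = 1e-12)

  # pure-noise channels: the mean coherence factor approaches 1/N
  set.seed(9)
  n_t <- 400L
  noise <- matrix(rnorm(n_t * arr$n_elements), n_t, arr$n_elements)
  rf_n <- rf; rf_n$samples <- noise
  pn <- das_beamform(rf_n, arr, range_step_mm = 0.2, scanlines = 65)
  cn <- das_beamform(rf_n, arr, weighting = "coherence", range_step_mm = 0.2,
                     scanlines = 65)
  ratio <- abs(cn$amplitude) / pmax(abs(pn$amplitude), 1e-12)
  keep <- pn$amplitude != 0
  n_ap <- active_channels(65, 128, 64)$count
  expect_lt(mean(ratio[keep]), 3 / n_ap)
})

test_that("log compression maps amplitudes to the display range", {
  compress <- function(a, dr) pmax(0, 1 + 20 * log10(a) / dr)
  expect_identical(compress(1, 35), 1)
  expect_equal(compress(10^(-35 / 20), 35), 0)
  expect_equal(compress(0.5, 35), 1 - 6.0206 / 35, tolerance = 1e-4)
  expect_equal(compress(0.5, 35), 0.828, tolerance = 1e-3)

  # end to end: bounded in [0, 1], global max exactly 1, monotone in input
  ph <- point_phantom(data.frame(x_mm = c(0, 5), z_mm = c(20, 30),
                                 strength = c(1, 0.3)))
  rf <- simulate_pa_rf(ph, default_array, default_pulse)
  sl <- das_beamform(rf, default_array, range_step_mm = 0.2)
  env <- envelope_logcompress(sl, 35)
  expect_true(all(env$amplitude >= 0 & env$amplitude <= 1))
  expect_identical(max(env$amplitude), 1)
})

test_that("scan conversion stays in range and flags the sector", {
  ph <- point_phantom(data.frame(x_mm = 0, z_mm = 20, strength = 1))
  rf <- simulate_pa_rf(ph, default_array, default_pulse, t_max_us = 25)
  sl <- envelope_logcompress(das_beamform(rf, default_array,
                                          range_step_mm = 0.2), 35)
  img <- scan_convert(sl, default_array, pixel_spacing_mm = 0.5)
  expect_true(all(img$intensity >= 0 & img$intensity <= 1))
  expect_true(all(img$intensity[!img$in_sector] == 0))
  # corner pixels lie outside the +/- 67.25 degree sector
  expect_false(img$in_sector[nrow(img$intensity), 1])
  # the bright spot appears near (0, 20)
  pk <- which(img$intensity == max(img$intensity), arr.ind = TRUE)[1, ]
  expect_lt(abs(img$z_mm[pk[1]] - 20), 1.5)
  expect_lt(abs(img$x_mm[pk[2]]), 1.5)
  expect_error(scan_convert(das_beamform(rf, default_array,
                                         range_step_mm = 0.5),
                            default_array), "log-compressed")
})

test_that("overlaying an empty PA image returns the US grayscale", {
  ph <- point_phantom(data.frame(x_mm = 0, z_mm = 15, strength = 1))
  rf <- simulate_pa_rf(ph, default_array, default_pulse, t_max_us = 20)
  sl <- envelope_logcompress(das_beamform(rf, default_array,
                                          range_step_mm = 0.3), 35)
  us_img <- scan_convert(sl, default_array, pixel_spacing_mm = 0.5)
  pa_img <- us_img
  pa_img$intensity[] <- 0
  ov <- overlay(us_img, pa_img, threshold = 0.3)
  for (k in 1:3) expect_equal(ov$rgb[, , k], us_img$intensity)
})

test_that("two-way delays halve the apparent depth of one-way data", {
  # misuse guard for the one-way/two-way contract: photoacoustic data run
  # through the pulse-echo beamformer mislocates a 25 mm target to ~12.5 mm
  arr <- default_array
  s <- which.min(abs(arr$element_angles_deg))
  ph <- point_phantom(data.frame(x_mm = arr$element_positions[s, 1] +
                                   25 * arr$element_normals[s, 1],
                                 z_mm = arr$element_positions[s, 2] +
                                   25 * arr$element_normals[s, 2],
                                 strength = 1))
  pa <- simulate_pa_rf(ph, arr, default_pulse)
  fake_us <- structure(list(mode = "us", samples = list(pa$samples),
                            scanlines = s,
                            sampling_rate_mhz = pa$sampling_rate_mhz,
                            sound_speed_m_s = pa$sound_speed_m_s, t0_us = 0,
                            array_n_elements = arr$n_elements),
                       class = "rf_frame")
  sl <- das_beamform(fake_us, arr, range_step_mm = 0.1, scanlines = s)
  env <- patrus:::analytic_envelope(sl$amplitude[, 1])
  r_peak <- sl$ranges_mm[which.max(env)]
  expect_equal(r_peak, 12.5, tolerance = 1)
})
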