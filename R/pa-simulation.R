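#' Radial wire phantom
#'
#' Builds the point-target phantom used for imaging-performance tests: one
#' 100 um tungsten wire per (angle, radius) pair on a polar grid about the
#' probe face center, inclusive endpoints, with 0 degrees along the probe
#' axis.  The printed layout (-75 to 75 degrees in 15 degree steps, 5 to
#' 55 mm in 10 mm steps) yields 11 x 6 = 66 wires.
#'
#' @param angle_start_deg,angle_stop_deg,angle_step_deg polar angle range.
#' @param radius_start_mm,radius_stop_mm,radius_step_mm radial range.
#' @param strength common target strength (> 0).
#' @param wire_diameter_mm metadata; 0.1 mm wires are far below the 6.75 MHz
#'   acoustic wavelength (~0.23 mm), so targets are treated as points.
#' @return An object of class `point_phantom` whose `targets` data frame has
#'   columns `x_mm`, `z_mm`, `angle_deg`, `radius_mm`, `strength`.
#' @examples
#' nrow(make_wire_phantom()$targets)   # 66
#' @export
make_wire_phantom <- function(angle_start_deg = -75, angle_stop_deg = 75,
                              angle_step_deg = 15,
                              radius_start_mm = 5, radius_stop_mm = 55,
                              radius_step_mm = 10,
                              strength = 1, wire_diameter_mm = 0.1) {
  stopifnot(angle_step_deg > 0, radius_step_mm > 0,
            angle_stop_deg >= angle_start_deg,
            radius_stop_mm >= radius_start_mm, strength > 0)
  angles <- seq(angle_start_deg, angle_stop_deg, by = angle_step_deg)
  radii <- seq(radius_start_mm, radius_stop_mm, by = radius_step_mm)
  gr <- expand.grid(angle_deg = angles, radius_mm = radii)
  targets <- data.frame(x_mm = gr$radius_mm * sin(deg2rad(gr$angle_deg)),
                        z_mm = gr$radius_mm * cos(deg2rad(gr$angle_deg)),
                        angle_deg = gr$angle_deg,
                        radius_mm = gr$radius_mm,
                        strength = strength)
  point_phantom(targets, wire_diameter_mm)
}

#' Point-target phantom container
#'
#' @param targets data frame with `x_mm`, `z_mm`, `strength` (> 0) columns.
#' @param wire_diameter_mm metadata, mm.
#' @return An object of class `point_phantom`.
#' @export
point_phantom <- function(targets, wire_diameter_mm = 0.1) {
  stopifnot(is.data.frame(targets),
            all(c("x_mm", "z_mm", "strength") %in% names(targets)))
  if (nrow(targets) && (!all(is.finite(targets$x_mm)) ||
                        !all(is.finite(targets$z_mm)) ||
                        any(targets$strength <= 0))) {
    stop("target positions must be finite and strengths > 0", call. = FALSE)
  }
  structure(list(targets = targets, wire_diameter_mm = wire_diameter_mm),
            class = "point_phantom")
}

#' @export
print.point_phantom <- function(x, ...) {
  cat(sprintf("<point_phantom> %d targets, wire diameter %.2f mm\n",
              nrow(x$targets), x$wire_diameter_mm))
  invisible(x)
}

# Resolve the illumination argument to a weight function of (x, z).
illumination_weight <- function(illumination) {
  if (is.function(illumination)) return(illumination)
  if (inherits(illumination, "fluence_grid")) {
    fg <- illumination
    # imaging-plane slab: average the voxel layers nearest y = 0 (the wire
    # integrates light over the beam height, which also tames MC variance)
    iy <- order(abs(fg$y_mm))[seq_len(min(3L, length(fg$y_mm)))]
    slab <- apply(fg$fluence[, iy, , drop = FALSE], c(1, 3), mean)
    return(function(x, z) {
      ix <- approx(fg$x_mm, seq_along(fg$x_mm), x, rule = 2)$y
      iz <- approx(fg$z_mm, seq_along(fg$z_mm), z, rule = 2)$y
      i0 <- pmin(pmax(floor(ix), 1), nrow(slab) - 1L)
      k0 <- pmin(pmax(floor(iz), 1), ncol(slab) - 1L)
      fx <- ix - i0; fz <- iz - k0
      slab[cbind(i0, k0)] * (1 - fx) * (1 - fz) +
        slab[cbind(i0 + 1L, k0)] * fx * (1 - fz) +
        slab[cbind(i0, k0 + 1L)] * (1 - fx) * fz +
        slab[cbind(i0 + 1L, k0 + 1L)] * fx * fz
    })
  }
  if (identical(illumination, "uniform")) return(function(x, z) rep(1, length(x)))
  stop("'illumination' must be \"uniform\", a fluence_grid, or a function(x, z)",
       call. = FALSE)
}

# Add 'pulse' into column 'ch' of 'samples' at arrival time tau_us with
# linear fractional-delay interpolation, scaled by amp.
insert_pulse <- function(samples, ch, tau_us, amp, pulse_w, pulse_t0, dt) {
  i0 <- (tau_us + pulse_t0) / dt           # index (0-based) of first pulse sample
  k <- floor(i0)
  frac <- i0 - k
  idx <- k + seq_along(pulse_w)            # 0-based target samples
  shifted <- (1 - frac) * c(pulse_w, 0) + frac * c(0, pulse_w)
  idx <- c(idx, idx[length(idx)] + 1L)
  keep <- idx >= 0 & idx < nrow(samples)
  samples[idx[keep] + 1L, ch] <- samples[idx[keep] + 1L, ch] +
    amp * shifted[keep]
  samples
}

#' Simulate per-channel photoacoustic RF data
#'
#' One-way acquisition model: every illuminated point target emits a
#' spherical wave at t = 0; channel `e` records the pulse waveform at
#' arrival time `|p_t - x_e| / c` with spherical spreading `1 / r` and an
#' illumination weight evaluated at the target position.  Fractional delays
#' use linear interpolation.  Optional additive white Gaussian noise with a
#' stated seed emulates the laser-induced noise floor.
#'
#' @param phantom a [point_phantom()].
#' @param array a [convex_array()].
#' @param pulse a [pulse_model()][synthesize_pulse()].
#' @param illumination `"uniform"`, a `fluence_grid`, or a `function(x, z)`
#'   returning relative weights.
#' @param sound_speed_m_s speed of sound (default 1540).
#' @param t_max_us recording window (default: farthest target + pulse).
#' @param noise_db peak-signal-to-noise ratio in dB for the additive noise
#'   floor, or `NULL` for noise-free data.
#' @param noise_seed RNG seed used when `noise_db` is set.
#' @return An object of class `rf_frame` (mode `"pa"`): `samples` is an
#'   `n_samples x n_elements` matrix, with `sampling_rate_mhz`, `t0_us = 0`,
#'   `sound_speed_m_s` metadata.
#' @examples
#' ph <- make_wire_phantom(0, 0, 15, 25, 25, 10)
#' rf <- simulate_pa_rf(ph, convex_array(), synthesize_pulse(), "uniform")
#' @export
simulate_pa_rf <- function(phantom, array, pulse, illumination = "uniform",
                           sound_speed_m_s = 1540, t_max_us = NULL,
                           noise_db = NULL, noise_seed = 1) {
  stopifnot(inherits(phantom, "point_phantom"), inherits(array, "convex_array"),
            inherits(pulse, "pulse_model"))
  tg <- phantom$targets
  if (nrow(tg) && any(tg$z_mm <= 0)) {
    stop("all targets must lie in front of the array (z > 0)", call. = FALSE)
  }
  c_mm_us <- sound_speed_m_s / 1000
  dt <- 1 / pulse$sampling_rate_mhz
  if (is.null(t_max_us)) {
    far <- if (nrow(tg)) max(sqrt(tg$x_mm^2 + tg$z_mm^2)) + array$radius_mm else 10
    t_max_us <- far / c_mm_us + pulse$duration_us
  }
  n_t <- ceiling(t_max_us / dt) + 1L
  samples <- matrix(0, n_t, array$n_elements)
  wfun <- illumination_weight(illumination)
  if (nrow(tg)) {
    illum <- wfun(tg$x_mm, tg$z_mm)
    ep <- array$element_positions
    for (k in seq_len(nrow(tg))) {
      d <- sqrt((tg$x_mm[k] - ep[, 1])^2 + (tg$z_mm[k] - ep[, 2])^2)
      tau <- d / c_mm_us
      amp <- tg$strength[k] * illum[k] / d
      for (e in seq_len(array$n_elements)) {
        samples <- insert_pulse(samples, e, tau[e], amp[e],
                                pulse$waveform, pulse$t_us[1], dt)
      }
    }
  }
  if (!is.null(noise_db)) {
    set.seed(noise_seed)
    peak <- max(abs(samples))
    if (peak == 0) peak <- 1
    samples <- samples + matrix(rnorm(length(samples),
                                      sd = peak * 10^(-noise_db / 20)),
                                n_t, array$n_elements)
  }
  structure(list(mode = "pa", samples = samples,
                 sampling_rate_mhz = pulse$sampling_rate_mhz,
                 sound_speed_m_s = sound_speed_m_s, t0_us = 0,
                 noise_db = noise_db, noise_seed = if (is.null(noise_db)) NA
                 else noise_seed,
                 array_n_elements = array$n_elements),
            class = "rf_frame")
}

#' Simulate per-scanline pulse-echo ultrasound RF data
#'
#' Simplified single-scattering pulse-echo model with one transmit per
#' scanline (beams co-located with the elements, radial): for scanline `s`
#' with center element `x_s`, the echo of a target at `p` arrives on
#' channel `e` at `(|p - x_s| + |p - x_e|) / c` (two-way) with two-way
#' spreading `1 / (d_tx * d_rx)`.  Optional diffuse background scatterers
#' provide speckle.
#'
#' @inheritParams simulate_pa_rf
#' @param scanlines element indices to transmit on (default: all).
#' @param n_background number of random diffuse scatterers (0 = none).
#' @param background_strength relative scattering strength of the diffuse
#'   background.
#' @param background_seed seed for the background draw.
#' @return An object of class `rf_frame` (mode `"us"`): `samples` is a list
#'   of `n_samples x n_elements` matrices, one per transmit scanline.
#' @export
simulate_us_rf <- function(phantom, array, pulse, sound_speed_m_s = 1540,
                           t_max_us = NULL, scanlines = NULL,
                           n_background = 0, background_strength = 0.05,
                           background_seed = 1,
                           noise_db = NULL, noise_seed = 1) {
  stopifnot(inherits(phantom, "point_phantom"), inherits(array, "convex_array"),
            inherits(pulse, "pulse_model"))
  tg <- phantom$targets
  if (nrow(tg) && any(tg$z_mm <= 0)) {
    stop("all targets must lie in front of the array (z > 0)", call. = FALSE)
  }
  if (n_background > 0) {
    set.seed(background_seed)
    rmax <- if (nrow(tg)) max(sqrt(tg$x_mm^2 + tg$z_mm^2)) else 40
    ang <- runif(n_background, -array$angular_span_deg / 2,
                 array$angular_span_deg / 2)
    rad <- sqrt(runif(n_background)) * rmax
    tg <- rbind(tg[, c("x_mm", "z_mm", "strength")],
                data.frame(x_mm = rad * sin(deg2rad(ang)),
                           z_mm = pmax(rad * cos(deg2rad(ang)), 0.5),
                           strength = background_strength *
                             runif(n_background, 0.2, 1)))
  }
  if (is.null(scanlines)) scanlines <- seq_len(array$n_elements)
  c_mm_us <- sound_speed_m_s / 1000
  dt <- 1 / pulse$sampling_rate_mhz
  if (is.null(t_max_us)) {
    far <- if (nrow(tg)) max(sqrt(tg$x_mm^2 + tg$z_mm^2)) + array$radius_mm else 10
    t_max_us <- 2 * far / c_mm_us + pulse$duration_us
  }
  n_t <- ceiling(t_max_us / dt) + 1L
  ep <- array$element_positions
  frames <- lapply(scanlines, function(s) {
    samples <- matrix(0, n_t, array$n_elements)
    if (nrow(tg)) {
      d_tx <- sqrt((tg$x_mm - ep[s, 1])^2 + (tg$z_mm - ep[s, 2])^2)
      for (k in seq_len(nrow(tg))) {
        d_rx <- sqrt((tg$x_mm[k] - ep[, 1])^2 + (tg$z_mm[k] - ep[, 2])^2)
        tau <- (d_tx[k] + d_rx) / c_mm_us
        amp <- tg$strength[k] / (d_tx[k] * d_rx)
        for (e in seq_len(array$n_elements)) {
          samples <- insert_pulse(samples, e, tau[e], amp[e],
                                  pulse$waveform, pulse$t_us[1], dt)
        }
      }
    }
    samples
  })
  if (!is.null(noise_db)) {
    set.seed(noise_seed)
    peak <- max(1e-300, max(vapply(frames, function(m) max(abs(m)), 0)))
    frames <- lapply(frames, function(m) {
      m + matrix(rnorm(length(m), sd = peak * 10^(-noise_db / 20)),
                 nrow(m), ncol(m))
    })
  }
  structure(list(mode = "us", samples = frames, scanlines = scanlines,
                 sampling_rate_mhz = pulse$sampling_rate_mhz,
                 sound_speed_m_s = sound_speed_m_s, t0_us = 0,
                 noise_db = noise_db, noise_seed = if (is.null(noise_db)) NA
                 else noise_seed,
                 array_n_elements = array$n_elements),
            class = "rf_frame")
}

#' @export
print.rf_frame <- function(x, ...) {
  cat(sprintf("<rf_frame> mode '%s', fs %.1f MHz, c %.0f m/s\n",
              x$mode, x$sampling_rate_mhz, x$sound_speed_m_s))
  invisible(x)
}

# Transmission-vs-wavelength preset for a ~3 mm intestinal wall layer.
# Synthetic piecewise-linear table anchored to two measured summaries: the
# 780 nm peak (0.263) and the 650-975 nm (25 nm grid) grand mean (0.219).
# Intermediate node values are a smooth unimodal stand-in, not measurements.
intestine_table <- data.frame(
  wavelength_nm = c(650, 675, 700, 725, 750, 775, 780, 800, 825,
                    850, 875, 900, 925, 950, 975),
  fraction = c(0.158, 0.183, 0.205, 0.225, 0.244, 0.259, 0.263, 0.258,
               0.247, 0.236, 0.226, 0.218, 0.210, 0.202, 0.195))

#' Laser energy transmission through the intestinal wall
#'
#' Piecewise-linear preset for the fraction of pulse energy transmitted
#' through a ~3 mm intestinal wall as a function of wavelength, anchored so
#' that the value at 780 nm is 0.263 and the mean over the 650--975 nm grid
#' (25 nm steps) is 0.219.  Values between the anchors are a synthetic
#' stand-in with a plausible unimodal shape.  Used to scale photoacoustic
#' target strengths when imaging through a covering wall layer.
#'
#' @param wavelength_nm wavelength(s) in \[650, 975\] nm.
#' @return Transmitted fraction(s) in (0, 1).
#' @examples
#' intestine_transmission(780)                      # 0.263
#' mean(intestine_transmission(seq(650, 975, 25)))  # ~0.219
#' @export
intestine_transmission <- function(wavelength_nm) {
  if (any(!is.finite(wavelength_nm)) ||
      any(wavelength_nm < 650 | wavelength_nm > 975)) {
    stop("wavelength must lie in [650, 975] nm", call. = FALSE)
  }
  approx(intestine_table$wavelength_nm, intestine_table$fraction,
         xout = wavelength_nm)$y
}
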