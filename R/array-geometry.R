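#' Build a convex transrectal array geometry
#'
#' Places element centers on a circular arc whose radius follows from the
#' printed footprint: `radius = arc_width / angular_span` (span in radians),
#' with elements equally spaced in angle and the first-to-last angular
#' separation equal to the span.  Defaults are the fabricated transducer's
#' values: 128 elements, 134.5 degree field of view, 11.4 mm lateral arc
#' width, 5 mm elevation, 30 mm elevational geometric focus.
#'
#' Coordinates: the origin is the probe face center (the chief element), the
#' depth axis `z` points into the tissue, `x` is lateral.  The arc center
#' therefore sits at `(0, -radius)`.
#'
#' @param n_elements number of elements (`>= 2`).
#' @param angular_span_deg angular span between first and last element
#'   centers, degrees (0, 360).
#' @param arc_width_mm lateral footprint measured along the arc.
#' @param elevation_mm element height (metadata).
#' @param elevational_focus_mm geometric elevation focus (metadata).
#' @return An object of class `convex_array` with `radius_mm`,
#'   `pitch_deg`, `element_angles_deg`, `element_positions` (n x 2 matrix,
#'   x/z in mm) and `element_normals` (unit outward radials).
#' @examples
#' arr <- convex_array()
#' arr$radius_mm            # 4.856 mm
#' arr$pitch_deg            # 1.0591 deg
#' @export
convex_array <- function(n_elements = 128, angular_span_deg = 134.5,
                         arc_width_mm = 11.4, elevation_mm = 5,
                         elevational_focus_mm = 30) {
  n_elements <- as.integer(n_elements)
  if (n_elements < 2L) stop("'n_elements' must be >= 2", call. = FALSE)
  check_scalar(angular_span_deg, "angular_span_deg", lower = 0, upper = 360,
               strict_lower = TRUE, strict_upper = TRUE)
  check_scalar(arc_width_mm, "arc_width_mm", lower = 0, strict_lower = TRUE)
  span <- deg2rad(angular_span_deg)
  radius <- arc_width_mm / span
  angles <- seq(-angular_span_deg / 2, angular_span_deg / 2,
                length.out = n_elements)
  a <- deg2rad(angles)
  positions <- cbind(x = radius * sin(a), z = radius * cos(a) - radius)
  normals <- cbind(x = sin(a), z = cos(a))
  structure(list(n_elements = n_elements,
                 angular_span_deg = angular_span_deg,
                 arc_width_mm = arc_width_mm,
                 radius_mm = radius,
                 pitch_deg = angular_span_deg / (n_elements - 1),
                 elevation_mm = elevation_mm,
                 elevational_focus_mm = elevational_focus_mm,
                 element_angles_deg = angles,
                 element_positions = positions,
                 element_normals = normals,
                 center_mm = c(0, -radius)),
            class = "convex_array")
}

#' @export
print.convex_array <- function(x, ...) {
  cat("<convex_array>\n")
  cat(sprintf("  %d elements, span %.1f deg, arc width %.2f mm -> radius %.4f mm\n",
              x$n_elements, x$angular_span_deg, x$arc_width_mm, x$radius_mm))
  cat(sprintf("  pitch %.4f deg, elevation %.1f mm (focus %.0f mm)\n",
              x$pitch_deg, x$elevation_mm, x$elevational_focus_mm))
  invisible(x)
}

#' Synthesize a band-limited acquisition pulse
#'
#' Gaussian-enveloped cosine whose amplitude spectrum has a -6 dB
#' (half-amplitude) full width of `fractional_bandwidth * center frequency`.
#' The spectral Gaussian sigma is `fbw * fc / (2 sqrt(2 ln 2))` and the
#' time-domain envelope sigma its Fourier pair `1 / (2 pi sigma_f)`; the
#' waveform spans +/- 4 time sigmas and is peak-normalized to 1.  Defaults
#' are the fabricated transducer's measured values, 6.75 MHz and 66%.
#'
#' @param center_frequency_mhz pulse center frequency, MHz.
#' @param fractional_bandwidth -6 dB fractional bandwidth in (0, 2).
#' @param sampling_rate_mhz sampling rate; must be at least 4x the center
#'   frequency (Nyquist guard).
#' @return An object of class `pulse_model` with `waveform`, `t_us`, and the
#'   generating parameters.
#' @examples
#' p <- synthesize_pulse(6.75, 0.66, 100)
#' characterize_pulse(p$waveform, 100)
#' @export
synthesize_pulse <- function(center_frequency_mhz = 6.75,
                             fractional_bandwidth = 0.66,
                             sampling_rate_mhz = 100) {
  check_scalar(center_frequency_mhz, "center_frequency_mhz", lower = 0,
               strict_lower = TRUE)
  check_scalar(fractional_bandwidth, "fractional_bandwidth", lower = 0,
               upper = 2, strict_lower = TRUE, strict_upper = TRUE)
  if (sampling_rate_mhz < 4 * center_frequency_mhz) {
    stop("'sampling_rate_mhz' must be at least 4x the center frequency",
         call. = FALSE)
  }
  sigma_f <- fractional_bandwidth * center_frequency_mhz / (2 * sqrt(2 * log(2)))
  sigma_t <- 1 / (2 * pi * sigma_f)          # microseconds
  dt <- 1 / sampling_rate_mhz
  t <- seq(-4 * sigma_t, 4 * sigma_t, by = dt)
  w <- exp(-t^2 / (2 * sigma_t^2)) * cos(2 * pi * center_frequency_mhz * t)
  w <- w / max(abs(w))
  structure(list(waveform = w, t_us = t,
                 center_frequency_mhz = center_frequency_mhz,
                 fractional_bandwidth = fractional_bandwidth,
                 sampling_rate_mhz = sampling_rate_mhz,
                 sigma_t_us = sigma_t,
                 duration_us = diff(range(t))),
            class = "pulse_model")
}

#' @export
print.pulse_model <- function(x, ...) {
  cat("<pulse_model>\n")
  cat(sprintf("  fc %.3f MHz, -6 dB fractional bandwidth %.1f%%, fs %.1f MHz, %.2f us\n",
              x$center_frequency_mhz, 100 * x$fractional_bandwidth,
              x$sampling_rate_mhz, x$duration_us))
  invisible(x)
}

#' Spectral characterization of a pulse
#'
#' Recovers center frequency and -6 dB fractional bandwidth from a sampled
#' waveform: the zero-padded amplitude spectrum is scanned for the outermost
#' crossings of half the peak amplitude (-6 dB), linearly interpolated; the
#' center frequency is the midpoint of the band edges and the fractional
#' bandwidth the band width divided by the center frequency.  The estimate
#' is invariant to amplitude scaling.
#'
#' @param waveform sampled amplitudes (non-zero).
#' @param sampling_rate_mhz sampling rate, MHz.
#' @return A list with `center_frequency_mhz` and `fractional_bandwidth`.
#' @export
characterize_pulse <- function(waveform, sampling_rate_mhz) {
  if (!length(waveform) || all(waveform == 0)) {
    stop("'waveform' must be non-zero", call. = FALSE)
  }
  check_scalar(sampling_rate_mhz, "sampling_rate_mhz", lower = 0,
               strict_lower = TRUE)
  n <- length(waveform)
  nfft <- 2^ceiling(log2(max(16 * n, 4096)))
  spec <- Mod(fft(c(waveform, numeric(nfft - n))))
  half <- floor(nfft / 2)
  amp <- spec[seq_len(half)]
  freq <- (seq_len(half) - 1) * sampling_rate_mhz / nfft
  pk <- which.max(amp)
  thr <- amp[pk] / 2                        # -6 dB on the amplitude spectrum
  above <- which(amp >= thr)
  lo <- above[1]
  hi <- above[length(above)]
  if (lo == 1L || hi == half) {
    stop("spectrum never falls 6 dB below its peak inside the Nyquist band",
         call. = FALSE)
  }
  f_lo <- freq[lo - 1] + (thr - amp[lo - 1]) / (amp[lo] - amp[lo - 1]) *
    (freq[lo] - freq[lo - 1])
  f_hi <- freq[hi] + (amp[hi] - thr) / (amp[hi] - amp[hi + 1]) *
    (freq[hi + 1] - freq[hi])
  fc <- (f_lo + f_hi) / 2
  list(center_frequency_mhz = fc,
       fractional_bandwidth = (f_hi - f_lo) / fc)
}
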