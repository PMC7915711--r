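#' Walking-aperture active channel window
#'
#' Returns the receive aperture for a scanline: a symmetric window of
#' `aperture_size` elements centered on the scanline's element, clipped at
#' the array edges.  With 128 elements and a 64-element aperture the
#' outermost scanline keeps 32 channels and the center scanline 64.
#'
#' @param scanline_index scanline (= element) index, 1-based.
#' @param n_elements element count of the array.
#' @param aperture_size even aperture size.
#' @return A list with `count`, `first`, `last` (element indices).
#' @examples
#' active_channels(1, 128, 64)$count    # 32
#' active_channels(65, 128, 64)$count   # 64
#' @export
active_channels <- function(scanline_index, n_elements, aperture_size) {
  scanline_index <- as.integer(scanline_index)
  n_elements <- as.integer(n_elements)
  aperture_size <- as.integer(aperture_size)
  if (scanline_index < 1L || scanline_index > n_elements) {
    stop("'scanline_index' must lie in [1, n_elements]", call. = FALSE)
  }
  if (aperture_size < 2L || aperture_size %% 2L != 0L) {
    stop("'aperture_size' must be even and >= 2", call. = FALSE)
  }
  first <- max(1L, scanline_index - aperture_size %/% 2L)
  last <- min(n_elements, scanline_index + aperture_size %/% 2L - 1L)
  list(count = last - first + 1L, first = first, last = last)
}

# Geometry inversion helpers for the convex sector: (beam angle, range from
# the element arc) <-> Cartesian (x, z) with the origin at the probe face.
beam_to_cartesian <- function(angle_deg, range_mm, array) {
  a <- deg2rad(angle_deg)
  r <- array$radius_mm + range_mm
  cbind(x = r * sin(a), z = r * cos(a) - array$radius_mm)
}

cartesian_to_beam <- function(x, z, array) {
  zc <- z + array$radius_mm
  cbind(angle_deg = rad2deg(atan2(x, zc)),
        range_mm = sqrt(x^2 + zc^2) - array$radius_mm)
}

#' Delay-and-sum beamforming for convex arrays
#'
#' Reconstructs radial scanlines (co-located with the array elements) by
#' summing active-channel samples at analytic times of flight: one-way
#' delays `|p - x_e| / c` for photoacoustic frames and two-way delays
#' `(r + |p - x_e|) / c` for pulse-echo frames.  Fractional delays use
#' linear interpolation; focal points beyond the recorded window contribute
#' zero and are counted.  Optional coherence-factor weighting
#' `|sum s|^2 / (N sum s^2)` is provided as an explicitly labelled stand-in
#' for adaptive beamforming.
#'
#' @param rf an `rf_frame` from [simulate_pa_rf()] or [simulate_us_rf()].
#' @param array the matching [convex_array()].
#' @param aperture_size walking receive aperture (even; default 64).
#' @param weighting `"none"` (plain DAS, rectangular apodization) or
#'   `"coherence"` (coherence-factor weighted DAS).
#' @param range_max_mm deepest focal range (default from the record length).
#' @param range_step_mm focal range spacing (default `c / (2 fs)`).
#' @param scanlines subset of scanline indices (default all elements; for
#'   pulse-echo frames, the transmitted scanlines).
#' @return An object of class `scanline_set`: `amplitude`
#'   (`n_ranges x n_scanlines`), `beam_angles_deg`, `ranges_mm`,
#'   `aperture_size`, `mode`, and `n_outside` (focal points beyond the
#'   record).
#' @export
das_beamform <- function(rf, array, aperture_size = 64,
                         weighting = c("none", "coherence"),
                         range_max_mm = NULL, range_step_mm = NULL,
                         scanlines = NULL) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(rf, "rf_frame"), inherits(array, "convex_array"))
  if (rf$array_n_elements != array$n_elements) {
    stop("RF channel count does not match the array", call. = FALSE)
  }
  c_mm_us <- rf$sound_speed_m_s / 1000
  dt <- 1 / rf$sampling_rate_mhz
  pa <- identical(rf$mode, "pa")
  n_t <- if (pa) nrow(rf$samples) else nrow(rf$samples[[1]])
  t_axis <- rf$t0_us + (seq_len(n_t) - 1) * dt
  t_end <- t_axis[n_t]
  if (is.null(range_step_mm)) range_step_mm <- c_mm_us * dt / 2
  if (is.null(range_max_mm)) {
    range_max_mm <- if (pa) c_mm_us * t_end else c_mm_us * t_end / 2
  }
  if (is.null(scanlines)) {
    scanlines <- if (pa) seq_len(array$n_elements) else rf$scanlines
  }
  ranges <- seq(0, range_max_mm, by = range_step_mm)
  ep <- array$element_positions
  en <- array$element_normals
  amp <- matrix(0, length(ranges), length(scanlines))
  n_outside <- 0L
  for (j in seq_along(scanlines)) {
    s <- scanlines[j]
    ac <- active_channels(s, array$n_elements, aperture_size)
    chans <- ac$first:ac$last
    px <- ep[s, 1] + ranges * en[s, 1]
    pz <- ep[s, 2] + ranges * en[s, 2]
    series <- if (pa) rf$samples else rf$samples[[match(s, rf$scanlines)]]
    acc <- numeric(length(ranges))
    acc2 <- numeric(length(ranges))
    for (e in chans) {
      d_rx <- sqrt((px - ep[e, 1])^2 + (pz - ep[e, 2])^2)
      tau <- if (pa) d_rx / c_mm_us else (ranges + d_rx) / c_mm_us
      out <- tau > t_end | tau < rf$t0_us
      n_outside <- n_outside + sum(out)
      v <- approx(t_axis, series[, e], xout = tau, rule = 1)$y
      v[is.na(v)] <- 0
      acc <- acc + v
      if (weighting == "coherence") acc2 <- acc2 + v^2
    }
    if (weighting == "coherence") {
      cf <- ifelse(acc2 > 0, acc^2 / (ac$count * acc2), 0)
      acc <- acc * cf
    }
    amp[, j] <- acc
  }
  structure(list(amplitude = amp,
                 beam_angles_deg = array$element_angles_deg[scanlines],
                 ranges_mm = ranges,
                 aperture_size = aperture_size,
                 mode = rf$mode,
                 weighting = weighting,
                 n_outside = n_outside,
                 normalized = FALSE),
            class = "scanline_set")
}

#' @export
print.scanline_set <- function(x, ...) {
  cat(sprintf("<scanline_set> %s, %d scanlines x %d ranges (0..%.1f mm)%s\n",
              x$mode, ncol(x$amplitude), nrow(x$amplitude),
              max(x$ranges_mm),
              if (x$normalized) ", log-compressed" else ""))
  invisible(x)
}

#' Envelope detection and log compression
#'
#' Computes the envelope of each scanline as the magnitude of its analytic
#' signal along range, normalizes to the global maximum, and maps to
#' display intensity `max(0, 1 + 20 log10(env / max) / DR)`, so the global
#' maximum maps to 1 and amplitudes `DR` dB below it map to 0.
#'
#' @param scanlines a `scanline_set` from [das_beamform()].
#' @param dynamic_range_db displayed dynamic range in dB (> 0); the
#'   wire-phantom photoacoustic images use 35 dB.
#' @return The `scanline_set` with `amplitude` replaced by normalized
#'   intensities in \[0, 1\] and `normalized = TRUE`.
#' @export
envelope_logcompress <- function(scanlines, dynamic_range_db = 35) {
  stopifnot(inherits(scanlines, "scanline_set"))
  check_scalar(dynamic_range_db, "dynamic_range_db", lower = 0,
               strict_lower = TRUE)
  env <- apply(scanlines$amplitude, 2, analytic_envelope)
  env <- matrix(env, nrow(scanlines$amplitude), ncol(scanlines$amplitude))
  mx <- max(env)
  if (mx == 0) {
    scanlines$amplitude <- env
  } else {
    out <- pmax(0, 1 + 20 * log10(pmax(env / mx, 1e-300)) / dynamic_range_db)
    dim(out) <- dim(env)
    scanlines$amplitude <- out
  }
  scanlines$dynamic_range_db <- dynamic_range_db
  scanlines$normalized <- TRUE
  scanlines
}

#' Scan conversion to a Cartesian sector image
#'
#' Maps normalized scanline intensities onto a Cartesian pixel grid by
#' bilinear interpolation in (beam angle, range) after inverting the convex
#' geometry (range measured from the element arc).  Pixels outside the
#' sector are flagged as background.
#'
#' @param scanlines a normalized `scanline_set` (see
#'   [envelope_logcompress()]).
#' @param array the matching [convex_array()].
#' @param pixel_spacing_mm Cartesian pixel pitch.
#' @return An object of class `bmode_image`: `intensity` (`n_z x n_x`, in
#'   \[0, 1\]), axes `x_mm`/`z_mm`, logical `in_sector` mask, and the
#'   dynamic range used.
#' @export
scan_convert <- function(scanlines, array, pixel_spacing_mm = 0.2) {
  stopifnot(inherits(scanlines, "scanline_set"), inherits(array, "convex_array"))
  if (!isTRUE(scanlines$normalized)) {
    stop("scanlines must be envelope-detected and log-compressed first",
         call. = FALSE)
  }
  rmax <- max(scanlines$ranges_mm)
  xmax <- (array$radius_mm + rmax) * sin(deg2rad(max(abs(scanlines$beam_angles_deg))))
  xs <- seq(-xmax, xmax, by = pixel_spacing_mm)
  zs <- seq(0, rmax, by = pixel_spacing_mm)
  gx <- matrix(xs, length(zs), length(xs), byrow = TRUE)
  gz <- matrix(zs, length(zs), length(xs))
  beam <- cartesian_to_beam(as.numeric(gx), as.numeric(gz), array)
  ang <- beam[, 1]; rng <- beam[, 2]
  angs <- scanlines$beam_angles_deg
  inside <- ang >= angs[1] & ang <= angs[length(angs)] &
    rng >= 0 & rng <= rmax
  ai <- approx(angs, seq_along(angs), ang, rule = 2)$y
  ri <- approx(scanlines$ranges_mm, seq_along(scanlines$ranges_mm), rng,
               rule = 2)$y
  a0 <- pmin(pmax(floor(ai), 1), length(angs) - 1L)
  r0 <- pmin(pmax(floor(ri), 1), length(scanlines$ranges_mm) - 1L)
  fa <- ai - a0; fr <- ri - r0
  A <- scanlines$amplitude
  vals <- A[cbind(r0, a0)] * (1 - fr) * (1 - fa) +
    A[cbind(r0 + 1L, a0)] * fr * (1 - fa) +
    A[cbind(r0, a0 + 1L)] * (1 - fr) * fa +
    A[cbind(r0 + 1L, a0 + 1L)] * fr * fa
  vals[!inside] <- 0
  structure(list(intensity = matrix(vals, length(zs), length(xs)),
                 x_mm = xs, z_mm = zs,
                 in_sector = matrix(inside, length(zs), length(xs)),
                 pixel_spacing_mm = pixel_spacing_mm,
                 dynamic_range_db = scanlines$dynamic_range_db),
            class = "bmode_image")
}

#' @export
print.bmode_image <- function(x, ...) {
  cat(sprintf("<bmode_image> %d x %d px (%.2f mm), dynamic range %s dB\n",
              nrow(x$intensity), ncol(x$intensity), x$pixel_spacing_mm,
              format(x$dynamic_range_db)))
  invisible(x)
}

#' Locate a point-target peak in a beamformed scanline set
#'
#' Finds the envelope peak nearest an expected target position and refines
#' it to sub-sample precision with a parabolic (three-point) fit in beam
#' angle and range, the standard sub-pixel localization used for
#' point-spread-function measurements on wire phantoms.
#'
#' @param scanlines a `scanline_set`; raw amplitudes are envelope-detected
#'   internally, normalized sets are used as-is.
#' @param array the matching [convex_array()].
#' @param x_mm,z_mm expected target position (Cartesian, probe-face origin).
#' @param window_deg,window_mm search half-window around the expected
#'   position in beam angle and range.
#' @param refine apply the parabolic sub-sample refinement (default TRUE).
#' @return A list with the peak position `x_mm`, `z_mm`, its envelope
#'   `amplitude`, and `error_mm`, the distance to the expected position.
#' @export
locate_peak <- function(scanlines, array, x_mm, z_mm,
                        window_deg = 6, window_mm = 3, refine = TRUE) {
  stopifnot(inherits(scanlines, "scanline_set"), inherits(array, "convex_array"))
  A <- scanlines$amplitude
  if (!isTRUE(scanlines$normalized)) {
    A <- apply(A, 2, analytic_envelope)
    dim(A) <- dim(scanlines$amplitude)
  }
  b <- cartesian_to_beam(x_mm, z_mm, array)
  ai <- which(abs(scanlines$beam_angles_deg - b[1]) <= window_deg)
  ri <- which(abs(scanlines$ranges_mm - b[2]) <= window_mm)
  if (!length(ai) || !length(ri)) {
    stop("expected position lies outside the scanline set", call. = FALSE)
  }
  sub <- A[ri, ai, drop = FALSE]
  pk <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  ia <- ai[pk[2]]
  ir <- ri[pk[1]]
  parab <- function(y) {
    den <- y[1] - 2 * y[2] + y[3]
    if (den >= 0) return(0)                      # not a local maximum
    max(-0.5, min(0.5, (y[1] - y[3]) / (2 * den)))
  }
  da <- dr <- 0
  if (refine) {
    if (ia > 1L && ia < ncol(A)) da <- parab(A[ir, (ia - 1L):(ia + 1L)])
    if (ir > 1L && ir < nrow(A)) dr <- parab(A[(ir - 1L):(ir + 1L), ia])
  }
  pitch <- if (length(scanlines$beam_angles_deg) > 1) {
    scanlines$beam_angles_deg[2] - scanlines$beam_angles_deg[1]
  } else 0
  dstep <- if (length(scanlines$ranges_mm) > 1) {
    scanlines$ranges_mm[2] - scanlines$ranges_mm[1]
  } else 0
  p <- beam_to_cartesian(scanlines$beam_angles_deg[ia] + da * pitch,
                         scanlines$ranges_mm[ir] + dr * dstep, array)
  list(x_mm = p[1], z_mm = p[2], amplitude = max(sub),
       error_mm = sqrt((p[1] - x_mm)^2 + (p[2] - z_mm)^2))
}

#' Overlay a photoacoustic image on an ultrasound image
#'
#' Paints photoacoustic pixels above a display threshold over the
#' ultrasound grayscale with a red--yellow map; both images must share the
#' same pixel grid.
#'
#' @param us_image,pa_image `bmode_image`s on identical grids.
#' @param threshold display threshold in \[0, 1\] above which PA pixels are
#'   painted.
#' @return An object of class `overlay_image` with an `rgb` array
#'   (`n_z x n_x x 3`).
#' @export
overlay <- function(us_image, pa_image, threshold = 0.3) {
  stopifnot(inherits(us_image, "bmode_image"), inherits(pa_image, "bmode_image"))
  if (!identical(dim(us_image$intensity), dim(pa_image$intensity))) {
    stop("images must share one pixel grid", call. = FALSE)
  }
  check_scalar(threshold, "threshold", lower = 0, upper = 1)
  g <- us_image$intensity
  rgb <- array(rep(g, 3), dim = c(dim(g), 3L))
  sel <- pa_image$intensity > threshold
  pa <- pa_image$intensity
  r <- rgb[, , 1]; gg <- rgb[, , 2]; b <- rgb[, , 3]
  r[sel] <- 1
  gg[sel] <- pa[sel]
  b[sel] <- 0
  rgb[, , 1] <- r; rgb[, , 2] <- gg; rgb[, , 3] <- b
  structure(list(rgb = rgb, x_mm = us_image$x_mm, z_mm = us_image$z_mm),
            class = "overlay_image")
}
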