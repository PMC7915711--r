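# Shared small fixtures, built in code.

default_array <- convex_array()
default_pulse <- synthesize_pulse(6.75, 0.66, 40)

# beam profile with arbitrary samples, for fwhm() unit tests
profile_of <- function(positions, intensity, window = 1) {
  structure(list(positions_mm = positions, intensity = intensity,
                 depth_mm = 25, smoothing_window = window),
            class = "beam_profile")
}

# independent brute-force FWHM oracle: outermost half-maximum crossings by
# linear scan over segments
fwhm_oracle <- function(x, y) {
  half <- max(y) / 2
  first <- NA
  last <- NA
  for (i in seq_len(length(y) - 1)) {
    y1 <- y[i]; y2 <- y[i + 1]
    if ((y1 < half && y2 >= half) || (i == 1 && y1 >= half)) {
      cross <- if (y1 >= half) x[1] else x[i] + (half - y1) / (y2 - y1) * (x[i + 1] - x[i])
      if (is.na(first)) first <- cross
    }
    if (y1 >= half && y2 < half) {
      last <- x[i] + (y1 - half) / (y1 - y2) * (x[i + 1] - x[i])
    }
  }
  if (y[length(y)] >= half) last <- x[length(x)]
  last - first
}

# scalar Snell oracle: signed angles in one plane
snell_oracle_angle <- function(theta_in, n_in, n_out) {
  s <- n_in * sin(theta_in) / n_out
  if (abs(s) > 1) return(NA_real_)
  asin(s)
}
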