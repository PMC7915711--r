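# Internal helpers shared across modules.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v^2))

is_unit <- function(v, tol = 1e-8) abs(vnorm(v) - 1) <= tol

stop_if_not_unit <- function(v, what, tol = 1e-8) {
  if (length(v) != 2L || !all(is.finite(v))) {
    stop(sprintf("'%s' must be a finite 2-vector", what), call. = FALSE)
  }
  if (vnorm(v) == 0) stop(sprintf("'%s' has zero length", what), call. = FALSE)
  if (!is_unit(v, tol)) {
    stop(sprintf("'%s' must have unit norm (got %.10f)", what, vnorm(v)),
         call. = FALSE)
  }
  invisible(v)
}

check_scalar <- function(x, what, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", what), call. = FALSE)
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop(sprintf("'%s' = %g is outside its valid range %s%g, %g%s", what, x,
                 if (strict_lower) "(" else "[", lower, upper,
                 if (strict_upper) ")" else "]"), call. = FALSE)
  }
  invisible(x)
}

# Centered moving average; partial windows at the edges are renormalized by
# the number of samples actually covered, so no values are dropped.
moving_average <- function(x, window) {
  n <- length(x)
  window <- as.integer(min(max(window, 1L), n))
  if (window <= 1L) return(x)
  kern <- rep(1, window)
  num <- stats::filter(x, kern, sides = 2)
  den <- stats::filter(rep(1, n), kern, sides = 2)
  # stats::filter leaves NA where the window overhangs; recompute those edges
  na <- which(is.na(num))
  half <- window %/% 2
  for (i in na) {
    lo <- max(1L, i - half)
    hi <- min(n, i + (window - 1L) %/% 2)
    num[i] <- sum(x[lo:hi])
    den[i] <- hi - lo + 1L
  }
  as.numeric(num / den)
}

# Magnitude of the analytic signal (FFT construction); standard envelope
# detector for RF scanlines.
analytic_envelope <- function(x) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  if (all(x == 0)) return(numeric(n))
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}
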