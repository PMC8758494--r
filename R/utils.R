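# Internal helpers shared across modules.

#' Wrap angles to the interval (-pi, pi]
#'
#' The package-wide phase convention places the oscillation peak at 0 and the
#' trough at +/- pi.
#'
#' @param x numeric vector of angles in radians.
#' @return numeric vector with every value in `(-pi, pi]`.
#' @export
#' @examples
#' wrapPhase(c(0, pi, -pi, 3 * pi / 2))
wrapPhase <- function(x) {
  p <- x %% (2 * pi)
  p[p > pi] <- p[p > pi] - 2 * pi
  p
}

#' Circular mean of a set of angles
#'
#' Arithmetic averaging of angles is ill-defined near the +/- pi wrap point;
#' the circular mean (argument of the mean resultant vector) is used for
#' group-level preferred phase angles.
#'
#' @param angles numeric vector of angles in radians.
#' @return single angle in `(-pi, pi]`, or `NA` for empty input.
#' @export
circularMean <- function(angles) {
  if (length(angles) == 0L) return(NA_real_)
  atan2(mean(sin(angles)), mean(cos(angles)))
}

# Deterministic per-cell seed derived from a master seed plus group and cell
# indices. Values stay below 2^31 - 1 and well within exact double-integer
# range, so the mapping is reproducible across platforms.
deriveSeed <- function(masterSeed, group, cell) {
  as.integer((abs(masterSeed) %% 2147483647 * 20011 +
                group * 4093 + cell * 211) %% 2147483629)
}

# Stationary Ornstein-Uhlenbeck process, sd `sigma`, correlation time `tau`
# seconds, sampled at dt. Implemented as an AR(1) recursion via
# stats::filter so long traces stay fast.
ouProcess <- function(n, dt, sigma, tau) {
  if (sigma <= 0) return(numeric(n))
  a <- exp(-dt / tau)
  innov <- rnorm(n, sd = sigma * sqrt(1 - a^2))
  as.numeric(stats::filter(innov, a, method = "recursive",
                           init = rnorm(1, sd = sigma)))
}

# 1/f^beta background noise by spectral shaping of white Gaussian noise,
# shaped over fLow..Nyquist (DC and sub-fLow content removed), rescaled to
# the requested RMS amplitude.
oneOverFNoise <- function(n, samplingRate, exponent, rmsAmp, fLow = 0.5) {
  if (rmsAmp <= 0) return(numeric(n))
  w <- rnorm(n)
  f <- samplingRate * (seq_len(n) - 1) / n
  f <- pmin(f, samplingRate - f)           # two-sided |frequency|
  gain <- ifelse(f >= fLow, f^(-exponent / 2), 0)
  x <- Re(fft(fft(w) * gain, inverse = TRUE)) / n
  s <- sqrt(mean(x^2))
  if (s > 0) x <- x * rmsAmp / s
  x
}

# Argument validation helpers --------------------------------------------

assertScalar <- function(x, name, lower = -Inf, upper = Inf,
                         strictLower = FALSE, strictUpper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  okLow <- if (strictLower) x > lower else x >= lower
  okHigh <- if (strictUpper) x < upper else x <= upper
  if (!okLow || !okHigh)
    stop(sprintf("'%s' = %g is outside the allowed range %s%g, %g%s", name, x,
                 if (strictLower) "(" else "[", lower, upper,
                 if (strictUpper) ")" else "]"), call. = FALSE)
  invisible(x)
}

assertChoice <- function(x, name, choices) {
  if (!is.character(x) || length(x) != 1L || !(x %in% choices))
    stop(sprintf("'%s' must be one of: %s", name,
                 paste(choices, collapse = ", ")), call. = FALSE)
  invisible(x)
}
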