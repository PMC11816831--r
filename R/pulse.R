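#' Log-normal hemodynamic pulse
#'
#' Smooth, asymmetric, strictly causal unimodal pulse used for all injected
#' transients (slow potential changes, vasomotor components, CBF elevations).
#' The shape is \code{A * exp(-log(x/m)^2 / (2 s^2))} for \code{x = t - t0 > 0}
#' and 0 otherwise, so the pulse has strictly positive support, a rounded peak
#' at \code{t0 + m} and a longer tail than rise, like observed hemodynamic
#' transients.
#'
#' The pulse is parameterized by its peak value, its full width at half
#' maximum (FWHM) and the time of its *leading half-maximum crossing*, which
#' is the package-wide onset convention shared with the detectors, so that an
#' injected pulse with half-max onset at time \code{t} is recovered with onset
#' \code{t}.
#'
#' @param t numeric vector of times (s).
#' @param onset time (s) of the leading half-maximum crossing.
#' @param peak signed peak value (pulse is scaled by this, so negative peaks
#'   give troughs).
#' @param fwhm_s full width at half maximum (s), > 0.
#' @param shape log-sd of the pulse; larger values give stronger asymmetry.
#' @return numeric vector, same length as \code{t}.
#' @examples
#' t <- seq(0, 600, by = 1)
#' p <- lognormal_pulse(t, onset = 100, peak = -5, fwhm_s = 90)
#' range(p)
#' @export
lognormal_pulse <- function(t, onset, peak, fwhm_s, shape = 0.35) {
  stopifnot(fwhm_s > 0, shape > 0)
  c1 <- sqrt(2 * log(2))                 # half-max log-offset factor
  m <- fwhm_s / (2 * sinh(c1 * shape))   # mode delay after support start
  t0 <- onset - m * exp(-c1 * shape)     # support start: half-max rise at `onset`
  x <- t - t0
  out <- numeric(length(t))
  pos <- x > 0
  out[pos] <- peak * exp(-(log(x[pos] / m))^2 / (2 * shape^2))
  out
}

#' Analytic FWHM of the log-normal pulse (inverse of the parameterization)
#' @noRd
pulse_mode_delay <- function(fwhm_s, shape = 0.35) {
  c1 <- sqrt(2 * log(2))
  fwhm_s / (2 * sinh(c1 * shape))
}

#' Leading/trailing half-maximum crossings of a sampled deflection
#'
#' Linear-interpolated times at which \code{abs(x)} crosses half of the
#' extremum around a given extremum index.  Used by every detector so that
#' onsets are comparable with the generator's half-max onset convention.
#'
#' @param t sample times (s).
#' @param x sampled deflection (any sign).
#' @param i_peak index of the extremum.
#' @param lo,hi indices bounding the search (defaults: whole trace).
#' @return list with `onset`, `offset` (s; NA when the trace never falls below
#'   half max inside the bounds) and `fwhm` (s).
#' @keywords internal
half_max_crossings <- function(t, x, i_peak, lo = 1L, hi = length(x)) {
  s <- sign(x[i_peak])
  y <- s * x                     # make the extremum a positive peak
  half <- y[i_peak] / 2
  onset <- NA_real_
  offset <- NA_real_
  i <- i_peak
  while (i > lo && y[i - 1] >= half) i <- i - 1L
  if (i > lo) {
    # interpolate between i-1 (below) and i (above)
    onset <- t[i - 1] + (t[i] - t[i - 1]) * (half - y[i - 1]) / (y[i] - y[i - 1])
  } else if (y[lo] < half) {
    onset <- t[lo]
  }
  j <- i_peak
  while (j < hi && y[j + 1] >= half) j <- j + 1L
  if (j < hi) {
    offset <- t[j] + (t[j + 1] - t[j]) * (half - y[j]) / (y[j + 1] - y[j])
  }
  list(onset = onset, offset = offset,
       fwhm = if (is.na(onset) || is.na(offset)) NA_real_ else offset - onset)
}
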