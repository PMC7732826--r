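# canonical double-gamma hemodynamic response function

# raw (unnormalized) kernel value at time t (s)
hrf_raw <- function(t, spec) {
  stats::dgamma(t, shape = spec$response_delay / spec$response_dispersion,
                scale = spec$response_dispersion) -
    stats::dgamma(t, shape = spec$undershoot_delay / spec$undershoot_dispersion,
                  scale = spec$undershoot_dispersion) / spec$ratio
}

# analytic peak height, used so kernels sampled at any dt share one scale
hrf_peak <- function(spec) {
  stats::optimize(function(t) hrf_raw(t, spec),
                  c(0, spec$length), maximum = TRUE)$objective
}

#' Closed-form canonical HRF, normalized to unit peak
#'
#' @param t time(s) in seconds (vectorized); zero outside `[0, length)`.
#' @param spec an [hrf_spec()].
#' @return kernel value(s).
#' @export
hrf_value <- function(t, spec = hrf_spec()) {
  v <- ifelse(t >= 0 & t < spec$length, hrf_raw(pmax(t, 0), spec), 0)
  v / hrf_peak(spec)
}

#' Running integral of the canonical HRF
#'
#' `H(t) = integral of the unit-peak kernel over [0, t]`; the response of a
#' boxcar of duration `D` starting at `o` is `H(t - o) - H(t - o - D)`.
#' Used for exact epoch synthesis in the BOLD generator.
#'
#' @param t time(s) in seconds.
#' @param spec an [hrf_spec()].
#' @return integral value(s).
#' @export
hrf_integral <- function(t, spec = hrf_spec()) {
  tc <- pmin(pmax(t, 0), spec$length)
  (stats::pgamma(tc, shape = spec$response_delay / spec$response_dispersion,
                 scale = spec$response_dispersion) -
     stats::pgamma(tc, shape = spec$undershoot_delay / spec$undershoot_dispersion,
                   scale = spec$undershoot_dispersion) / spec$ratio) /
    hrf_peak(spec)
}

#' Sampled canonical HRF kernel
#'
#' Difference of two gamma densities with the spec's parameters, normalized
#' to unit peak (by the analytic peak height, so the scale is independent
#' of `dt`), sampled on `[0, length)` at step `dt`.  The value at `t = 0`
#' is 0 and the kernel is finitely supported.
#'
#' @param spec an [hrf_spec()].
#' @param dt sampling step in seconds.
#' @return numeric vector of kernel samples.
#' @export
canonical_hrf <- function(spec = hrf_spec(), dt) {
  if (dt <= 0) stop("dt must be positive")
  t <- seq(0, spec$length - dt / 2, by = dt)
  hrf_value(t, spec)
}
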