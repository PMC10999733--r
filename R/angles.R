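# Axial (orientation) angle arithmetic.
#
# Fiber angles are orientations, not directions: an angle a and a + 180 deg
# describe the same fiber axis. All means and differences are therefore
# computed on doubled angles, the standard trick for axial data.

#' Wrap angles into the axial range [0, 180)
#'
#' @param a angles in degrees.
#' @return angles in degrees in `[0, 180)`.
#' @export
wrap_axial <- function(a) {
  a %% 180
}

#' Wrapped axial difference
#'
#' Minimal signed difference `a - b` between two fiber orientations, in
#' degrees in `(-90, 90]`. `axial_diff(10, 170)` is `20`, not `-160`.
#'
#' @param a,b angles in degrees (recycled).
#' @return signed differences in degrees in `(-90, 90]`.
#' @export
axial_diff <- function(a, b) {
  d <- (a - b) %% 180
  ifelse(d > 90, d - 180, d)
}

#' Weighted axial circular mean
#'
#' Mean orientation of axial data, computed on doubled angles.
#'
#' @param a angles in degrees.
#' @param w non-negative weights (default equal).
#' @return mean orientation in degrees in `[0, 180)`, or `NA` if the
#'   resultant vector vanishes (e.g. perfectly isotropic input).
#' @export
axial_mean <- function(a, w = NULL) {
  if (length(a) == 0L) return(NA_real_)
  if (is.null(w)) w <- rep(1, length(a))
  stopifnot(length(w) == length(a), all(w >= 0))
  rad2 <- 2 * a * pi / 180
  s <- sum(w * sin(rad2))
  c <- sum(w * cos(rad2))
  if (sqrt(s^2 + c^2) < 1e-12 * max(sum(w), 1e-300)) return(NA_real_)
  wrap_axial(atan2(s, c) * 90 / pi)
}

#' Axial resultant length
#'
#' Mean resultant length of the doubled angles; 1 for perfectly aligned
#' orientations, 0 for isotropic ones.
#'
#' @inheritParams axial_mean
#' @return scalar in `[0, 1]`.
#' @export
axial_concentration <- function(a, w = NULL) {
  if (length(a) == 0L) return(NA_real_)
  if (is.null(w)) w <- rep(1, length(a))
  rad2 <- 2 * a * pi / 180
  sqrt(sum(w * sin(rad2))^2 + sum(w * cos(rad2))^2) / sum(w)
}

#' Sample axial von Mises orientations
#'
#' Draws fiber orientations whose doubled angles follow a von Mises
#' distribution with concentration `kappa` (Best-Fisher rejection sampler).
#' `kappa = Inf` returns `mu` exactly; `kappa = 0` is uniform on [0, 180).
#'
#' @param n number of draws.
#' @param mu mean orientation in degrees.
#' @param kappa concentration of the doubled-angle von Mises distribution.
#' @return orientations in degrees in `[0, 180)`.
#' @export
rvonmises_axial <- function(n, mu, kappa) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0L) return(numeric(0))
  if (is.infinite(kappa)) return(rep(wrap_axial(mu), n))
  if (kappa == 0) return(stats::runif(n, 0, 180))
  mu2 <- 2 * mu * pi / 180
  # Best & Fisher (1979) wrapped-Cauchy envelope rejection sampler
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  rr <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + rr * z) / (rr + z)
    ccap <- kappa * (rr - f)
    ok <- (ccap * (2 - ccap) - u2 > 0) | (log(ccap / u2) + 1 - ccap >= 0)
    k <- sum(ok)
    if (k > 0) {
      th <- sign(u3[ok] - 0.5) * acos(f[ok])
      out[(got + 1L):(got + k)] <- th
      got <- got + k
    }
  }
  wrap_axial((mu2 + out) * 90 / pi)
}
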