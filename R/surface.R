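# Surfaces of revolution: profile representation, constant-mean-curvature
# (Delaunay) solver, principal curvatures and Euler-theorem normal curvature.
#
# Geometry conventions
# --------------------
# A surface of revolution is X(z, phi) = (r(z) cos phi, r(z) sin phi, z),
# lengths in micrometres, z along the rotation axis with z = 0 at the neck
# centre. Curvatures are signed so that the surface normal points OUT OF THE
# TISSUE INTO THE CULTURE MEDIUM and a direction in which the surface falls
# away from that normal (a valley seen from the medium) has NEGATIVE normal
# curvature. On a capillary bridge (tissue outside the scaffold, medium
# outside; sense = "bridge") this gives, at a waist, meridional kappa_m < 0
# and circumferential kappa_c > 0; inside a pore (sense = "pore") the signs
# swap.

#' Construct a surface of revolution
#'
#' @param r function of `z` (micrometres) returning the profile radius
#'   `r(z) > 0` in micrometres.
#' @param z_range numeric length-2 domain `c(z_min, z_max)` in micrometres.
#' @param sense `"bridge"` (tissue grows outwards; capillary bridge) or
#'   `"pore"` (tissue grows inwards from the pore wall). Determines the sign
#'   of the second fundamental form (normal out of the tissue into the
#'   medium).
#' @param dr,d2r optional first/second derivative functions; when omitted
#'   they are computed by central finite differences with step `fd_h`.
#' @param fd_h finite-difference step in micrometres for numeric derivatives.
#' @param units `"um"` or `"mm"`; with `"mm"` all lengths (including the
#'   values returned by `r`) are converted to micrometres on the way in.
#' @return object of class `surface_of_revolution`.
#' @export
surface_of_revolution <- function(r, z_range, sense = c("bridge", "pore"),
                                  dr = NULL, d2r = NULL, fd_h = 1e-3,
                                  units = c("um", "mm")) {
  sense <- match.arg(sense)
  units <- match.arg(units)
  stopifnot(is.function(r), length(z_range) == 2, z_range[1] < z_range[2])
  scale <- if (units == "mm") 1000 else 1
  z_range <- as.numeric(z_range) * scale
  rf <- if (scale == 1) r else function(z) scale * r(z / scale)
  if (is.null(dr)) {
    h <- fd_h
    dr <- function(z) (rf(z + h) - rf(z - h)) / (2 * h)
  } else if (scale != 1) {
    dr0 <- dr; dr <- function(z) dr0(z / scale)
  }
  if (is.null(d2r)) {
    h <- max(fd_h, 1e-3)
    d2r <- function(z) (rf(z + h) - 2 * rf(z) + rf(z - h)) / h^2
  } else if (scale != 1) {
    d2r0 <- d2r; d2r <- function(z) d2r0(z / scale) / scale
  }
  zs <- seq(z_range[1], z_range[2], length.out = 257)
  rv <- rf(zs)
  if (any(!is.finite(rv)) || any(rv <= 0)) {
    stop("profile r(z) must be finite and strictly positive on the domain")
  }
  structure(
    list(r = rf, dr = dr, d2r = d2r, z_range = z_range, sense = sense),
    class = "surface_of_revolution"
  )
}

#' @export
print.surface_of_revolution <- function(x, ...) {
  w <- neck_z(x)
  cat(sprintf(
    "surface_of_revolution (%s): z in [%.1f, %.1f] um, r(neck %.1f) = %.2f um\n",
    x$sense, x$z_range[1], x$z_range[2], w, x$r(w)))
  invisible(x)
}

check_z_domain <- function(surface, z) {
  if (any(z < surface$z_range[1] - 1e-9 | z > surface$z_range[2] + 1e-9)) {
    stop("z outside the surface domain [", surface$z_range[1], ", ",
         surface$z_range[2], "] um")
  }
}

#' Axial position of the neck (extremum of the profile)
#'
#' The neck centre defines z = 0 for the exclusion rules; for fitted
#' profiles it is located numerically as the interior extremum of r(z).
#'
#' @param surface a `surface_of_revolution`.
#' @return z position of the profile extremum in micrometres.
#' @export
neck_z <- function(surface) {
  f <- if (surface$sense == "bridge") surface$r else function(z) -surface$r(z)
  zs <- seq(surface$z_range[1], surface$z_range[2], length.out = 513)
  z0 <- zs[which.min(f(zs))]
  lo <- max(surface$z_range[1], z0 - diff(surface$z_range) / 256)
  hi <- min(surface$z_range[2], z0 + diff(surface$z_range) / 256)
  stats::optimize(f, c(lo, hi))$minimum
}

#' Cylinder surface helper
#'
#' @param radius cylinder radius in micrometres.
#' @param half_height half of the axial extent in micrometres.
#' @inheritParams surface_of_revolution
#' @return a `surface_of_revolution` with constant profile.
#' @export
cylinder_surface <- function(radius, half_height, sense = "bridge") {
  force(radius)
  surface_of_revolution(
    r = function(z) rep(radius, length(z)),
    dr = function(z) rep(0, length(z)),
    d2r = function(z) rep(0, length(z)),
    z_range = c(-half_height, half_height), sense = sense
  )
}

#' Catenoid surface helper
#'
#' Minimal surface r(z) = c cosh(z / c).
#'
#' @param c_waist waist radius `c` in micrometres.
#' @param half_height half of the axial extent in micrometres.
#' @inheritParams surface_of_revolution
#' @return a `surface_of_revolution`.
#' @export
catenoid_surface <- function(c_waist, half_height, sense = "bridge") {
  force(c_waist)
  surface_of_revolution(
    r = function(z) c_waist * cosh(z / c_waist),
    dr = function(z) sinh(z / c_waist),
    d2r = function(z) cosh(z / c_waist) / c_waist,
    z_range = c(-half_height, half_height), sense = sense
  )
}

#' Sphere (cap) surface helper
#'
#' Profile r(z) = sqrt(R^2 - z^2) restricted to `|z| <= frac * R`; useful as
#' an umbilic test surface.
#'
#' @param radius sphere radius in micrometres.
#' @param frac fraction of the radius kept on either side of the equator.
#' @inheritParams surface_of_revolution
#' @return a `surface_of_revolution`.
#' @export
sphere_surface <- function(radius, frac = 0.7, sense = "bridge") {
  force(radius)
  surface_of_revolution(
    r = function(z) sqrt(radius^2 - z^2),
    dr = function(z) -z / sqrt(radius^2 - z^2),
    d2r = function(z) -radius^2 / (radius^2 - z^2)^1.5,
    z_range = c(-frac * radius, frac * radius), sense = sense
  )
}

#' Principal curvatures of a surface of revolution
#'
#' Meridional (`kappa_m`) and circumferential (`kappa_c`) principal
#' curvatures at axial position(s) `z`, signed with the
#' normal-into-the-medium convention (see package conventions): with
#' `s = +1` for a bridge and `s = -1` for a pore,
#' `kappa_m = -s r'' / (1 + r'^2)^(3/2)` and
#' `kappa_c =  s / (r sqrt(1 + r'^2))`.
#'
#' @param surface a `surface_of_revolution`.
#' @param z axial positions in micrometres.
#' @return data.frame with columns `z`, `kappa_m`, `kappa_c` (1/um).
#' @export
principal_curvatures <- function(surface, z) {
  check_z_domain(surface, z)
  r <- surface$r(z); rp <- surface$dr(z); rpp <- surface$d2r(z)
  s <- if (surface$sense == "bridge") 1 else -1
  data.frame(
    z = z,
    kappa_m = -s * rpp / (1 + rp^2)^1.5,
    kappa_c = s / (r * sqrt(1 + rp^2))
  )
}

#' Mean curvature H = (kappa_m + kappa_c) / 2
#'
#' @inheritParams principal_curvatures
#' @return mean curvature in 1/um (signed, normal into the medium).
#' @export
mean_curvature <- function(surface, z) {
  pc <- principal_curvatures(surface, z)
  (pc$kappa_m + pc$kappa_c) / 2
}

#' Gaussian curvature K = kappa_m * kappa_c
#'
#' @inheritParams principal_curvatures
#' @return Gaussian curvature in 1/um^2 (sign-convention independent).
#' @export
gaussian_curvature <- function(surface, z) {
  pc <- principal_curvatures(surface, z)
  pc$kappa_m * pc$kappa_c
}

#' Normal curvature along a surface direction (Euler's theorem)
#'
#' Curvature of the normal section in the tangent direction at angle `theta`
#' from the circumferential (equatorial) direction:
#' `k_theta = kappa_c cos^2(theta) + kappa_m sin^2(theta)`.
#'
#' @param surface a `surface_of_revolution`.
#' @param z axial positions in micrometres.
#' @param theta angles in degrees in `[0, 180)`, 0 = equatorial,
#'   90 = meridional. `z` and `theta` are recycled to a common length.
#' @return normal curvatures in 1/um.
#' @export
normal_curvature <- function(surface, z, theta) {
  n <- max(length(z), length(theta))
  z <- rep_len(z, n); theta <- rep_len(theta, n)
  pc <- principal_curvatures(surface, z)
  t <- theta * pi / 180
  pc$kappa_c * cos(t)^2 + pc$kappa_m * sin(t)^2
}

# ---------------------------------------------------------------------------
# Constant-mean-curvature (Delaunay) profiles
# ---------------------------------------------------------------------------

# ODE for a CMC profile with mean curvature H taken with the normal pointing
# AWAY from the axis (the usual Delaunay convention; a cylinder of radius R
# has H = 1/(2R)):  r'' = (1 + r'^2)/r - 2 H (1 + r'^2)^(3/2).
cmc_rhs <- function(state, h_target) {
  r <- state[1]; rp <- state[2]
  c(rp, (1 + rp^2) / r - 2 * h_target * (1 + rp^2)^1.5)
}

# Integrate the symmetric half-profile from the waist r(0) = r0, r'(0) = 0
# to z = half_span with fixed-step RK4. Returns r on the grid or NA rows
# after a blow-up.
cmc_integrate <- function(r0, h_target, half_span, n_steps = 2000L) {
  h <- half_span / n_steps
  z <- seq(0, half_span, length.out = n_steps + 1L)
  out <- matrix(NA_real_, n_steps + 1L, 2L)
  s <- c(r0, 0)
  out[1L, ] <- s
  for (i in seq_len(n_steps)) {
    k1 <- cmc_rhs(s, h_target)
    k2 <- cmc_rhs(s + h / 2 * k1, h_target)
    k3 <- cmc_rhs(s + h / 2 * k2, h_target)
    k4 <- cmc_rhs(s + h * k3, h_target)
    s <- s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!all(is.finite(s)) || s[1] <= r0 * 1e-6 || s[1] > r0 * 1e6) break
    out[i + 1L, ] <- s
  }
  list(z = z, r = out[, 1L], rp = out[, 2L])
}

# End radius r(half_span) for a waist radius r0 (Inf once the integration
# blows up, so bisection can still bracket).
cmc_end_radius <- function(r0, h_target, half_span, n_steps = 2000L) {
  tr <- cmc_integrate(r0, h_target, half_span, n_steps)
  rend <- tr$r[length(tr$r)]
  if (is.na(rend)) Inf else rend
}

# Shooting on the waist radius for given H: coarse grid scan + bisection at
# reduced step count, then a secant polish at full resolution. Of the two
# Delaunay branches the outer (largest waist radius) one is returned.
cmc_solve_waist <- function(pillar_radius, half_span, h_target,
                            tol = 1e-8, n_steps = 2000L) {
  n_coarse <- max(100L, min(n_steps, 250L))
  f_at <- function(r0, n) cmc_end_radius(r0, h_target, half_span, n) -
    pillar_radius
  r0_grid <- pillar_radius * exp(seq(log(1e-3), log(3), length.out = 80))
  fv <- vapply(r0_grid, f_at, numeric(1), n = n_coarse)
  sgn <- sign(fv)
  fin <- is.finite(fv)
  br <- which(sgn[-1] * sgn[-length(sgn)] < 0 & fin[-1] & fin[-length(fv)])
  if (length(br) == 0) {
    rng <- if (any(fin)) range(fv[fin]) + pillar_radius else c(NA_real_, NA_real_)
    stop(sprintf(
      paste0("no CMC bridge solution for H = %.4g 1/um at d/R = %.3f; ",
             "end radii attainable span [%.4g, %.4g] um"),
      h_target, 2 * half_span / pillar_radius, rng[1], rng[2]))
  }
  i <- br[length(br)]
  lo <- r0_grid[i]; hi <- r0_grid[i + 1L]
  flo <- fv[i]
  while (hi - lo > 1e-4 * max(1, pillar_radius)) {
    mid <- (lo + hi) / 2
    fm <- f_at(mid, n_coarse)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  # secant polish at full resolution
  a <- lo; b <- hi
  fa <- f_at(a, n_steps); fb <- f_at(b, n_steps)
  for (it in 1:60) {
    if (abs(b - a) < tol * max(1, pillar_radius)) break
    m <- b - fb * (b - a) / (fb - fa)
    if (!is.finite(m) || m <= 0) m <- (a + b) / 2
    fm <- f_at(m, n_steps)
    a <- b; fa <- fb; b <- m; fb <- fm
    if (fb == 0) break
  }
  b
}

#' Solve a constant-mean-curvature bridge/pore profile
#'
#' Finds the rotationally symmetric constant-mean-curvature (Delaunay)
#' profile spanning two coaxial pillars: `r(+-pillar_distance/2) =
#' pillar_radius`, waist at z = 0 by symmetry. Either the mean curvature
#' `h` (normal away from the axis, so a cylinder of radius R has
#' `h = 1/(2R)`) or the enclosed volume `volume` must be given; with a
#' volume target the solver bisects on `h`.
#'
#' Shooting method: fixed-step RK4 on the first-order Delaunay ODE from the
#' waist, bisection on the waist radius until the boundary condition is met
#' to `tol`. Of the (generically two) Delaunay branches the outer one -
#' larger waist radius, the area-minimizing branch - is returned.
#'
#' @param pillar_radius pillar radius in micrometres (paper scaffold: 1000).
#' @param pillar_distance distance between the pillars in micrometres
#'   (paper scaffold: 1250).
#' @param h target mean curvature in 1/um, or `NULL`.
#' @param volume target enclosed volume in um^3 (`pi * integral r^2 dz`), or
#'   `NULL`.
#' @param sense passed to [surface_of_revolution()].
#' @param tol absolute tolerance on the boundary radius in micrometres.
#' @param n_steps RK4 steps per half-profile.
#' @param units `"um"` or `"mm"` for `pillar_radius` / `pillar_distance`
#'   (`h` then in 1/mm, `volume` in mm^3).
#' @return a `surface_of_revolution` whose profile interpolates the solved
#'   half-profile (mirrored about z = 0) with a natural cubic spline;
#'   attributes `h` (solved mean curvature) and `waist_radius` are attached.
#' @export
solve_cmc_profile <- function(pillar_radius, pillar_distance,
                              h = NULL, volume = NULL,
                              sense = "bridge", tol = 1e-8, n_steps = 2000L,
                              units = c("um", "mm")) {
  units <- match.arg(units)
  if (units == "mm") {
    pillar_radius <- pillar_radius * 1000
    pillar_distance <- pillar_distance * 1000
    if (!is.null(h)) h <- h / 1000
    if (!is.null(volume)) volume <- volume * 1e9
  }
  stopifnot(pillar_radius > 0, pillar_distance > 0)
  if (is.null(h) == is.null(volume)) {
    stop("give exactly one of 'h' (mean curvature) or 'volume'")
  }
  half <- pillar_distance / 2
  if (!is.null(volume)) {
    # coarse waist solves while bisecting on h; full-resolution final solve
    waist_of_h <- function(hh) cmc_solve_waist(pillar_radius, half, hh,
                                               tol = 1e-6, n_steps = 250L)
    vol_of_h <- function(hh) {
      r0 <- waist_of_h(hh)
      tr <- cmc_integrate(r0, hh, half, 500L)
      2 * pi * sum((tr$r[-1]^2 + tr$r[-length(tr$r)]^2) / 2) * diff(tr$z)[1]
    }
    h_grid <- seq(-1 / pillar_radius, 1 / pillar_radius, length.out = 25)
    vols <- vapply(h_grid, function(hh) {
      tryCatch(vol_of_h(hh), error = function(e) NA_real_)
    }, numeric(1))
    ok <- which(is.finite(vols))
    if (length(ok) < 2 || volume < min(vols[ok]) || volume > max(vols[ok])) {
      stop(sprintf(
        "no CMC solution for volume %.4g um^3; admissible range [%.4g, %.4g] um^3",
        volume, suppressWarnings(min(vols[ok])), suppressWarnings(max(vols[ok]))))
    }
    # volume is monotone in h on the solvable set; bracket and bisect
    i <- ok[which(vols[ok] <= volume)]
    j <- ok[which(vols[ok] >= volume)]
    lo <- h_grid[i[which.max(vols[i])]]
    hi <- h_grid[j[which.min(vols[j])]]
    hstar <- stats::uniroot(function(hh) vol_of_h(hh) - volume,
                            lower = min(lo, hi), upper = max(lo, hi),
                            tol = 1e-10)$root
    return(solve_cmc_profile(pillar_radius, pillar_distance, h = hstar,
                             sense = sense, tol = tol, n_steps = n_steps))
  }
  r0 <- cmc_solve_waist(pillar_radius, half, h, tol = tol, n_steps = n_steps)
  tr <- cmc_integrate(r0, h, half, n_steps)
  zz <- c(-rev(tr$z[-1]), tr$z)
  rr <- c(rev(tr$r[-1]), tr$r)
  pp <- c(-rev(tr$rp[-1]), tr$rp)          # r is even, r' odd about the waist
  sf <- stats::splinefun(zz, rr, method = "fmm")
  sp <- stats::splinefun(zz, pp, method = "fmm")
  surf <- surface_of_revolution(
    r = sf,
    dr = sp,
    d2r = function(z) sp(z, deriv = 1),
    z_range = c(-half, half), sense = sense
  )
  attr(surf, "h") <- h
  attr(surf, "waist_radius") <- r0
  surf
}

# ---------------------------------------------------------------------------
# Silhouette fitting and profile I/O
# ---------------------------------------------------------------------------

# Otsu threshold on a 256-bin histogram; images are assumed non-negative.
otsu_threshold <- function(x) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = 257)
  h <- tabulate(findInterval(x, br, all.inside = TRUE), 256)
  p <- h / sum(h)
  mids <- (br[-1] + br[-257]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[256]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Fit a profile r(z) from an image silhouette
#'
#' Extracts the sample silhouette from a maximum intensity projection and
#' fits a smoothing spline to the half-width per image row, giving the
#' rotationally symmetric representation onto which fiber angles are lifted.
#' z = 0 is assigned to the profile minimum (bridge) or maximum (pore).
#'
#' @param mip 2D image matrix; first index = horizontal image coordinate x,
#'   second index = axial image coordinate (along the rotation axis).
#' @param pixel_size pixel size in micrometres.
#' @param sense `"bridge"` or `"pore"`.
#' @param threshold foreground threshold; default Otsu.
#' @param spar smoothing parameter for [stats::smooth.spline()]; the default
#'   lets GCV choose it (residuals are typically about one pixel).
#' @param min_coverage minimum fraction of rows with a detectable silhouette
#'   before the fit is attempted.
#' @return a `surface_of_revolution` in neck-centred coordinates, with
#'   attributes `z_offset_px` (axial pixel index of the neck) and
#'   `axis_x_px` (horizontal pixel coordinate of the rotation axis).
#' @export
fit_profile_from_silhouette <- function(mip, pixel_size,
                                        sense = c("bridge", "pore"),
                                        threshold = NULL, spar = NULL,
                                        min_coverage = 0.8) {
  sense <- match.arg(sense)
  stopifnot(is.matrix(mip), pixel_size > 0)
  if (is.null(threshold)) threshold <- otsu_threshold(mip)
  fg <- mip > threshold
  nz <- ncol(fg)
  left <- right <- rep(NA_real_, nz)
  for (j in seq_len(nz)) {
    w <- which(fg[, j])
    if (length(w) >= 2) { left[j] <- min(w); right[j] <- max(w) }
  }
  found <- is.finite(left)
  if (mean(found) < min_coverage) {
    stop("silhouette-not-found: edges detected on only ",
         round(100 * mean(found)), "% of rows")
  }
  width <- right - left
  # reject rows whose width jumps away from the local trend (dust etc.)
  med <- stats::runmed(width[found], k = min(21L, 2L * (sum(found) %/% 2L) - 1L))
  bad <- found
  bad[found] <- abs(width[found] - med) > pmax(4, 0.05 * med)
  use <- found & !bad
  if (mean(use) < min_coverage * 0.9) use <- found
  j_use <- which(use)
  r_px <- width[use] / 2
  axis_x <- mean((left[use] + right[use]) / 2)
  fit <- if (is.null(spar)) {
    stats::smooth.spline(j_use, r_px)
  } else {
    stats::smooth.spline(j_use, r_px, spar = spar)
  }
  j_all <- seq_len(nz)
  r_all <- stats::predict(fit, j_all)$y
  j0 <- if (sense == "bridge") j_all[which.min(r_all)] else j_all[which.max(r_all)]
  z_um <- (j_all - j0) * pixel_size
  r_um <- r_all * pixel_size
  sf <- stats::splinefun(z_um, r_um, method = "natural")
  surf <- surface_of_revolution(
    r = sf,
    dr = function(z) sf(z, deriv = 1),
    d2r = function(z) sf(z, deriv = 2),
    z_range = range(z_um), sense = sense
  )
  attr(surf, "z_offset_px") <- j0
  attr(surf, "axis_x_px") <- axis_x
  surf
}

#' Export a profile as two-column CSV (z_um, r_um)
#'
#' @param surface a `surface_of_revolution`.
#' @param path output CSV path.
#' @param n number of sample points.
#' @export
profile_to_csv <- function(surface, path, n = 501) {
  z <- seq(surface$z_range[1], surface$z_range[2], length.out = n)
  utils::write.csv(data.frame(z_um = z, r_um = surface$r(z)), path,
                   row.names = FALSE)
  invisible(path)
}

#' Import a profile from two-column CSV (z_um, r_um)
#'
#' @param path CSV with columns `z_um`, `r_um`.
#' @inheritParams surface_of_revolution
#' @return a `surface_of_revolution` (natural-spline interpolant).
#' @export
profile_from_csv <- function(path, sense = "bridge") {
  d <- utils::read.csv(path)
  stopifnot(all(c("z_um", "r_um") %in% names(d)))
  sf <- stats::splinefun(d$z_um, d$r_um, method = "natural")
  surface_of_revolution(
    r = sf, dr = function(z) sf(z, deriv = 1),
    d2r = function(z) sf(z, deriv = 2),
    z_range = range(d$z_um), sense = sense
  )
}

#' Export the revolved surface as a Wavefront OBJ triangle mesh
#'
#' @param surface a `surface_of_revolution`.
#' @param path output `.obj` path.
#' @param n_z,n_phi axial / angular resolution.
#' @export
surface_to_obj <- function(surface, path, n_z = 100, n_phi = 72) {
  z <- seq(surface$z_range[1], surface$z_range[2], length.out = n_z)
  phi <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  r <- surface$r(z)
  v <- character(n_z * n_phi)
  for (i in seq_len(n_z)) {
    v[((i - 1) * n_phi + 1):(i * n_phi)] <- sprintf(
      "v %.6f %.6f %.6f", r[i] * cos(phi), r[i] * sin(phi), z[i])
  }
  idx <- function(i, j) (i - 1) * n_phi + ((j - 1) %% n_phi) + 1
  f <- character(2 * (n_z - 1) * n_phi)
  k <- 0L
  for (i in seq_len(n_z - 1)) for (j in seq_len(n_phi)) {
    a <- idx(i, j); b <- idx(i, j + 1); cc <- idx(i + 1, j); d <- idx(i + 1, j + 1)
    f[k + 1L] <- sprintf("f %d %d %d", a, b, d)
    f[k + 2L] <- sprintf("f %d %d %d", a, d, cc)
    k <- k + 2L
  }
  writeLines(c(v, f), path)
  invisible(path)
}
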