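# Independent oracles used across the test suite. These deliberately avoid
# the package's own curvature/projection code paths.

# Finite-difference normal-section curvature oracle.
#
# Cuts the surface of revolution with the plane spanned by the tangent
# direction at angle theta (from the circumferential direction) and the
# surface normal, and measures the curvature of the resulting 3D curve as
# the limit 2 s(t) / t^2, where s(t) is the offset along the
# into-the-tissue normal at tangent parameter t. Richardson-extrapolated.
oracle_normal_section_curvature <- function(surface, z, theta_deg, h = NULL) {
  r <- surface$r(z); rp <- surface$dr(z)
  den <- sqrt(1 + rp^2)
  # point at phi = pi/2: P = (0, r, z)
  e_m <- c(0, rp, 1) / den              # meridional tangent
  e_c <- c(-1, 0, 0)                    # circumferential tangent
  th <- theta_deg * pi / 180
  tv <- cos(th) * e_c + sin(th) * e_m
  n_med <- c(0, 1, -rp) / den           # away from axis
  s_tis <- if (surface$sense == "bridge") -1 else 1
  nrm <- s_tis * n_med                  # into the tissue
  if (is.null(h)) h <- 1e-2 * min(r, diff(surface$z_range) / 4)
  offset_at <- function(t) {
    g <- function(s) {
      q <- c(0, r, z) + t * tv + s * nrm
      sqrt(q[1]^2 + q[2]^2) - surface$r(q[3])
    }
    smax <- 0.75 * r
    stats::uniroot(g, c(-smax, smax), tol = 1e-13)$root
  }
  k_of <- function(hh) (offset_at(hh) + offset_at(-hh)) / hh^2
  k1 <- k_of(h); k2 <- k_of(h / 2)
  (4 * k2 - k1) / 3
}

# Brute-force constant-mean-curvature bridge profile: direct minimization of
# the surface area of a piecewise-linear profile at fixed enclosed volume
# (quadratic penalty), fixed end radii. Independent of the shooting solver.
oracle_cmc_profile_minimization <- function(pillar_radius, pillar_distance,
                                            volume, n_nodes = 61,
                                            penalty = 1e7) {
  zs <- seq(-pillar_distance / 2, pillar_distance / 2, length.out = n_nodes)
  dz <- diff(zs)[1]
  scale_r <- pillar_radius
  area_vol <- function(rfull) {
    rmid2 <- (rfull[-1] + rfull[-n_nodes]) / 2
    seg <- sqrt(dz^2 + diff(rfull)^2)
    a <- sum(2 * pi * rmid2 * seg)
    v <- sum(pi * (rfull[-1]^2 + rfull[-n_nodes]^2) / 2) * dz
    c(a, v)
  }
  a_scale <- 2 * pi * pillar_radius * pillar_distance
  obj <- function(rfree) {
    rfull <- c(pillar_radius, rfree * scale_r, pillar_radius)
    av <- area_vol(rfull)
    av[1] / a_scale + penalty * ((av[2] - volume) / volume)^2
  }
  init <- rep(0.9, n_nodes - 2)
  fit <- stats::optim(init, obj, method = "L-BFGS-B",
                      lower = rep(0.05, n_nodes - 2),
                      control = list(maxit = 2000, factr = 1e4))
  rfull <- c(pillar_radius, fit$par * scale_r, pillar_radius)
  list(z = zs, r = rfull, waist = min(rfull), convergence = fit$convergence)
}

# Dominant orientation of an image from its Fourier power spectrum (axial,
# degrees in [0, 180)): energy-weighted axial mean of spectral angles.
# Independent of the structure-tensor estimator.
oracle_fourier_orientation <- function(im) {
  im <- im - mean(im)
  nx <- nrow(im); ny <- ncol(im)
  wx <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nx) - 1) / (nx - 1))
  wy <- 0.5 - 0.5 * cos(2 * pi * (seq_len(ny) - 1) / (ny - 1))
  p <- Mod(stats::fft(im * outer(wx, wy)))^2
  fx <- ifelse(seq_len(nx) - 1 > nx / 2, seq_len(nx) - 1 - nx, seq_len(nx) - 1) / nx
  fy <- ifelse(seq_len(ny) - 1 > ny / 2, seq_len(ny) - 1 - ny, seq_len(ny) - 1) / ny
  FX <- matrix(fx, nx, ny); FY <- matrix(fy, nx, ny, byrow = TRUE)
  rad <- sqrt(FX^2 + FY^2)
  keep <- rad > 0.02 & rad < 0.45
  # spectral energy of a stripe pattern is perpendicular to the stripes
  ang_perp <- atan2(FY[keep], FX[keep]) * 180 / pi
  w <- p[keep]
  fib <- (ang_perp + 90) * 2 * pi / 180
  wrap_axial(atan2(sum(w * sin(fib)), sum(w * cos(fib))) * 90 / pi)
}

# Forward orthographic projection of a surface tangent direction: returns
# the image position x and the image-plane angle alpha for a point (z, phi)
# and surface angle theta. Built from the parametrization directly, not from
# the package's lifting Jacobian.
oracle_forward_project <- function(surface, z, phi, theta_deg) {
  r <- surface$r(z); rp <- surface$dr(z)
  th <- theta_deg * pi / 180
  p_phi <- c(-r * sin(phi), r * cos(phi), 0)
  p_z <- c(rp * cos(phi), rp * sin(phi), 1)
  e_c <- -p_phi / r                       # projects to +x at phi = pi/2
  e_m <- p_z / sqrt(1 + rp^2)
  tv <- cos(th) * e_c + sin(th) * e_m
  d_img <- c(tv[1], tv[3])                # image (x, vertical=z) components
  list(
    x = r * cos(phi),
    alpha = wrap_axial(atan2(d_img[2], d_img[1]) * 180 / pi)
  )
}

# Synthetic stripe image: sin grating at a given fiber orientation (degrees).
make_stripes <- function(n = 128, angle_deg = 30, period = 8, noise_sd = 0) {
  a <- angle_deg * pi / 180
  x <- matrix(seq_len(n), n, n)
  y <- matrix(seq_len(n), n, n, byrow = TRUE)
  # stripes run along (cos a, sin a); phase varies along the perpendicular
  ph <- (-sin(a) * x + cos(a) * y) * 2 * pi / period
  im <- 0.5 + 0.5 * sin(ph)
  if (noise_sd > 0) im <- im + matrix(stats::rnorm(n * n, 0, noise_sd), n, n)
  im
}
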