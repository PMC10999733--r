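# Synthetic renderer: helical multilayer fiber textures on surfaces of
# revolution, imaged as fluorescence-like voxel stacks.
#
# Fibers are laid down as constant-angle curves (loxodromes) at a fixed
# depth below the tissue surface, rasterized into the voxel grid, blurred
# with an anisotropic Gaussian PSF, attenuated exponentially with depth
# below the surface, and corrupted with Poisson shot noise plus Gaussian
# read noise. The ground truth (layer table, view, seed) travels with the
# stack, so every downstream estimator can be tested by render-and-recover.

#' Configuration for the synthetic renderer
#'
#' @param surface a `surface_of_revolution` to grow the tissue on.
#' @param view `"outside"` (bridge) or `"inside"` (opened pore). The inside
#'   view mirrors the image x axis, exactly as looking at the same wall
#'   from the other side does.
#' @param layers data.frame with columns `depth_min`, `depth_max` (um below
#'   the tissue surface; contiguous, starting at 0) and `theta` (surface
#'   fiber angle in degrees, `[0, 180)`, outside-view convention).
#' @param fiber_density fibers per um^2 of (half-)shell area, per layer.
#' @param fiber_width fiber diameter in um (adds to the PSF in quadrature).
#' @param psf_sigma c(lateral, axial) Gaussian PSF sigma in um; axial acts
#'   along the camera axis.
#' @param attenuation_length exponential decay length (um) of fluorescence
#'   with depth below the tissue surface. Default 15 um keeps the maximum
#'   intensity projection dominated by the top one or two cell layers.
#' @param noise list with `poisson_gain` (expected photons at unit
#'   intensity; `Inf` disables shot noise) and `gaussian_sigma` (additive
#'   read noise sd; 0 disables).
#' @param voxel_size c(x, z, y) voxel size in um; default c(0.63, 0.63, 1.2)
#'   mirrors the light-sheet acquisition geometry.
#' @param collagen_offset onset depth offset delta (um) of the collagen
#'   channel below the actin onset, or `NULL` for single-channel renders.
#' @param collagen_softness softness (um) of the sigmoidal collagen onset.
#' @param seed integer RNG seed; renders are bitwise reproducible given the
#'   seed and config.
#' @param fiber_length total arc length of each rendered fiber in um.
#' @param z_crop optional c(z_min, z_max) (um) restricting the rendered
#'   axial window; default is the surface domain.
#' @param pad lateral padding of the field of view in um.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(surface,
                             view = c("outside", "inside"),
                             layers = data.frame(depth_min = 0,
                                                 depth_max = 12,
                                                 theta = 80),
                             fiber_density = 0.003,
                             fiber_width = 1.5,
                             psf_sigma = c(0.8, 2.0),
                             attenuation_length = 15,
                             noise = list(poisson_gain = 200,
                                          gaussian_sigma = 0.01),
                             voxel_size = c(0.63, 0.63, 1.2),
                             collagen_offset = NULL,
                             collagen_softness = 1,
                             seed = 1L,
                             fiber_length = 250,
                             z_crop = NULL,
                             pad = 4) {
  view <- match.arg(view)
  stopifnot(inherits(surface, "surface_of_revolution"))
  req <- c("depth_min", "depth_max", "theta")
  if (!all(req %in% names(layers))) {
    stop("config-invalid: layers needs columns depth_min, depth_max, theta")
  }
  layers <- layers[order(layers$depth_min), , drop = FALSE]
  if (nrow(layers) < 1 || layers$depth_min[1] != 0) {
    stop("config-invalid: layers must start at depth 0 (tissue surface)")
  }
  if (any(layers$depth_max <= layers$depth_min)) {
    stop("config-invalid: empty depth interval")
  }
  if (nrow(layers) > 1 &&
      any(abs(layers$depth_min[-1] - layers$depth_max[-nrow(layers)]) > 1e-9)) {
    stop("config-invalid: depth intervals must be contiguous and non-overlapping")
  }
  if (any(layers$theta < 0 | layers$theta >= 180)) {
    stop("config-invalid: theta must lie in [0, 180)")
  }
  if (fiber_density <= 0) stop("config-invalid: non-positive fiber density")
  if (!is.null(collagen_offset) && collagen_offset < 0) {
    stop("config-invalid: collagen_offset must be >= 0")
  }
  stopifnot(length(voxel_size) == 3, all(voxel_size > 0),
            length(psf_sigma) == 2, all(psf_sigma >= 0),
            attenuation_length > 0, fiber_length > 0)
  structure(
    list(surface = surface, view = view, layers = layers,
         fiber_density = fiber_density, fiber_width = fiber_width,
         psf_sigma = psf_sigma, attenuation_length = attenuation_length,
         noise = noise, voxel_size = voxel_size,
         collagen_offset = collagen_offset,
         collagen_softness = collagen_softness, seed = as.integer(seed),
         fiber_length = fiber_length, z_crop = z_crop, pad = pad),
    class = "synthetic_config"
  )
}

# Half-shell area of the surface between z limits (integral of
# pi r sqrt(1 + r'^2) dz).
half_shell_area <- function(surface, z_lim) {
  zs <- seq(z_lim[1], z_lim[2], length.out = 401)
  f <- pi * surface$r(zs) * sqrt(1 + surface$dr(zs)^2)
  sum((f[-1] + f[-length(f)]) / 2) * diff(zs)[1]
}

# Trace constant-theta loxodromes at given depths below the surface.
# Vectorized midpoint integration of
#   dz/ds = sin(theta) / sqrt(1 + r'^2),  dphi/ds = -cos(theta) / rho,
# where rho(z) = r(z) -+ depth / sqrt(1 + r'^2) is the offset-shell radius
# (minus: bridge, tissue depth towards the axis; plus: pore). The sign of
# dphi makes theta the angle from the +x image direction at the front
# meridian in the outside view, increasing counterclockwise, so a layer
# rendered with theta < 90 is a left-handed helix seen from outside.
trace_loxodromes <- function(surface, z0, phi0, depth, theta_deg, ds,
                             n_steps, z_lim) {
  n <- length(z0)
  th <- theta_deg * pi / 180
  sgn_d <- if (surface$sense == "bridge") -1 else 1
  rho_of <- function(z, d) surface$r(z) + sgn_d * d / sqrt(1 + surface$dr(z)^2)
  out_z <- matrix(NA_real_, n, 2 * n_steps + 1)
  out_phi <- matrix(NA_real_, n, 2 * n_steps + 1)
  out_z[, n_steps + 1] <- z0
  out_phi[, n_steps + 1] <- phi0
  for (dir in c(1, -1)) {
    z <- z0; phi <- phi0
    alive <- rep(TRUE, n)
    for (i in seq_len(n_steps)) {
      h <- dir * ds
      rp <- surface$dr(z)
      dz1 <- sin(th) / sqrt(1 + rp^2)
      dphi1 <- -cos(th) / rho_of(z, depth)
      zm <- z + h / 2 * dz1
      zm <- pmin(pmax(zm, z_lim[1]), z_lim[2])
      rpm <- surface$dr(zm)
      dz2 <- sin(th) / sqrt(1 + rpm^2)
      dphi2 <- -cos(th) / rho_of(zm, depth)
      z_new <- z + h * dz2
      phi <- phi + h * dphi2
      alive <- alive & z_new >= z_lim[1] & z_new <= z_lim[2]
      z <- pmin(pmax(z_new, z_lim[1]), z_lim[2])
      col <- n_steps + 1 + dir * i
      out_z[alive, col] <- z[alive]
      out_phi[alive, col] <- phi[alive]
    }
  }
  list(z = out_z, phi = out_phi)
}

# Rasterize one channel into the voxel grid. Returns the raw (pre-noise)
# intensity array.
render_channel <- function(config, channel = c("actin", "collagen")) {
  channel <- match.arg(channel)
  surface <- config$surface
  vx <- config$voxel_size
  z_lim <- if (is.null(config$z_crop)) surface$z_range else config$z_crop
  zs_probe <- seq(z_lim[1], z_lim[2], length.out = 101)
  rmax <- max(surface$r(zs_probe))
  x_lim <- c(-(rmax + config$pad), rmax + config$pad)
  y_lim <- c(0, rmax + config$pad)
  nx <- ceiling(diff(x_lim) / vx[1])
  nz <- ceiling(diff(z_lim) / vx[2])
  ny <- ceiling(diff(y_lim) / vx[3])
  arr <- array(0, c(nx, nz, ny))
  origin <- c(x_lim[1] + vx[1] / 2, z_lim[1] + vx[2] / 2, y_lim[1] + vx[3] / 2)
  ds <- 0.6 * min(vx[1], vx[2])
  n_steps <- ceiling(config$fiber_length / 2 / ds)
  area <- half_shell_area(surface, z_lim)
  sgn_d <- if (surface$sense == "bridge") -1 else 1
  for (li in seq_len(nrow(config$layers))) {
    lay <- config$layers[li, ]
    n_fib <- max(1L, round(config$fiber_density * area))
    z0 <- stats::runif(n_fib, z_lim[1], z_lim[2])
    phi0 <- stats::runif(n_fib, 0, pi)
    depth <- stats::runif(n_fib, lay$depth_min, lay$depth_max)
    tr <- trace_loxodromes(surface, z0, phi0, depth, lay$theta, ds,
                           n_steps, z_lim)
    keep <- !is.na(tr$z)
    z <- tr$z[keep]; phi <- tr$phi[keep]
    d <- matrix(depth, nrow(tr$z), ncol(tr$z))[keep]
    rho <- surface$r(z) + sgn_d * d / sqrt(1 + surface$dr(z)^2)
    x <- rho * cos(phi); y <- rho * sin(phi)
    w <- exp(-d / config$attenuation_length) * ds
    if (channel == "collagen") {
      delta <- config$collagen_offset
      w <- w / (1 + exp(-(d - delta) / config$collagen_softness))
    }
    ix <- floor((x - x_lim[1]) / vx[1]) + 1L
    iz <- floor((z - z_lim[1]) / vx[2]) + 1L
    iy <- floor((y - y_lim[1]) / vx[3]) + 1L
    ok <- ix >= 1 & ix <= nx & iz >= 1 & iz <= nz & iy >= 1 & iy <= ny
    lin <- ix[ok] + (iz[ok] - 1) * nx + (iy[ok] - 1) * nx * nz
    arr <- arr + array(accumulate_at(lin, w[ok], nx * nz * ny), c(nx, nz, ny))
  }
  sig_fib <- config$fiber_width / 2
  sig <- c(sqrt(config$psf_sigma[1]^2 + sig_fib^2) / vx[1],
           sqrt(config$psf_sigma[1]^2 + sig_fib^2) / vx[2],
           sqrt(config$psf_sigma[2]^2 + sig_fib^2) / vx[3])
  arr <- gauss_blur_3d(arr, sig)
  if (max(arr) > 0) arr <- arr / max(arr)
  list(arr = arr, origin = origin)
}

apply_noise <- function(arr, noise) {
  gain <- noise$poisson_gain
  if (is.finite(gain) && gain > 0) {
    arr <- array(stats::rpois(length(arr), gain * arr) / gain, dim(arr))
  }
  if (noise$gaussian_sigma > 0) {
    arr <- arr + array(stats::rnorm(length(arr), 0, noise$gaussian_sigma),
                       dim(arr))
  }
  arr[arr < 0] <- 0
  arr
}

finish_stack <- function(config, channels, origin) {
  if (config$view == "inside") {
    # mirror the image x axis (looking at the same wall from the other
    # side); origin is restated in the mirrored image frame so that the
    # rotation axis stays at x = 0
    nx <- dim(channels[[1]])[1]
    channels <- lapply(channels, function(a) a[rev(seq_len(nx)), , ,
                                               drop = FALSE])
    origin[1] <- -(origin[1] + (nx - 1) * config$voxel_size[1])
  }
  truth <- list(
    layers = config$layers, view = config$view, seed = config$seed,
    sense = config$surface$sense,
    collagen_offset = config$collagen_offset,
    attenuation_length = config$attenuation_length
  )
  image_stack(channels, voxel_size = config$voxel_size, view = config$view,
              origin = origin, truth = truth, surface = config$surface)
}

#' Render a single-channel helical tissue stack
#'
#' @param config a [synthetic_config()].
#' @return an `image_stack` with an `actin` channel and ground truth.
#' @export
render_helical_tissue <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    ch <- render_channel(config, "actin")
    actin <- apply_noise(ch$arr, config$noise)
    finish_stack(config, list(actin = actin), ch$origin)
  })
}

#' Render a two-channel (actin + collagen) stack
#'
#' The collagen channel shares every layer's fiber angle but its intensity
#' onset sits `collagen_offset` um deeper below the tissue surface; both
#' channels share the attenuation model.
#'
#' @param config a [synthetic_config()] with non-`NULL` `collagen_offset`.
#' @return an `image_stack` with `actin` and `collagen` channels.
#' @export
render_two_channel <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(config$collagen_offset)) {
    stop("config-invalid: collagen_offset required for two-channel renders")
  }
  with_seed(config$seed, {
    a <- render_channel(config, "actin")
    actin <- apply_noise(a$arr, config$noise)
    co <- render_channel(config, "collagen")
    collagen <- apply_noise(co$arr, config$noise)
    finish_stack(config, list(actin = actin, collagen = collagen), a$origin)
  })
}

#' Render a synthetic time series of samples
#'
#' Emulates the fixed-time-point experiment design: for each day a set of
#' biological replicates whose surface fiber angle jitters around the
#' day's mean angle (axial von Mises noise with concentration `kappa`).
#' The ground-truth table is attached as the `"truth"` attribute; no
#' synthetic stack exists without its truth record.
#'
#' @param config_template a [synthetic_config()] used for every sample; its
#'   layer table is replaced by a single layer at the sampled angle.
#' @param theta_by_day data.frame with columns `day` and `theta` (degrees).
#' @param n_samples replicates per day (recycled over days).
#' @param seed integer master seed.
#' @param kappa von Mises concentration of the per-sample angle jitter
#'   (doubled-angle scale); `Inf` = no jitter.
#' @param depth_max tissue thickness (um) of the rendered single layer.
#' @param render if `FALSE`, skip rasterization and return only the
#'   ground-truth table (fast path for statistical checks).
#' @return list with `stacks` (list of `image_stack`, or `NULL` if
#'   `render = FALSE`) and `truth` (data.frame: day, sample_id, theta_day,
#'   theta_sample, seed).
#' @export
make_time_series <- function(config_template, theta_by_day, n_samples,
                             seed = 1L, kappa = 20, depth_max = 12,
                             render = TRUE) {
  stopifnot(inherits(config_template, "synthetic_config"),
            all(c("day", "theta") %in% names(theta_by_day)),
            n_samples >= 1)
  n_samples <- rep_len(n_samples, nrow(theta_by_day))
  truth <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(nrow(theta_by_day)), function(i) {
      th <- rvonmises_axial(n_samples[i], theta_by_day$theta[i], kappa)
      data.frame(
        day = theta_by_day$day[i],
        sample_id = sprintf("d%02d_s%02d", theta_by_day$day[i],
                            seq_len(n_samples[i])),
        theta_day = theta_by_day$theta[i],
        theta_sample = th,
        seed = seed + 1000L * i + seq_len(n_samples[i])
      )
    }))
  })
  stacks <- NULL
  if (render) {
    stacks <- lapply(seq_len(nrow(truth)), function(k) {
      cfg <- config_template
      cfg$layers <- data.frame(depth_min = 0, depth_max = depth_max,
                               theta = truth$theta_sample[k])
      cfg$seed <- truth$seed[k]
      st <- render_helical_tissue(cfg)
      st$truth$sample_id <- truth$sample_id[k]
      st$truth$day <- truth$day[k]
      st
    })
    names(stacks) <- truth$sample_id
  }
  structure(list(stacks = stacks, truth = truth), class = "time_series")
}
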