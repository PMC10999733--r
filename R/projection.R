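# Lifting image-plane fiber angles onto the 3D surface.
#
# The camera is orthographic (sample size << working distance at 20x). A
# point at image position (x, z) with |x| < r(z) is lifted to the visible
# hemisphere, azimuth phi = acos(x / r(z)) in (0, pi) with phi = pi/2 on the
# midline. The image direction (cos alpha, sin alpha) is pulled back through
# the 2x2 Jacobian of the orthographic projection restricted to the tangent
# plane; theta is the axial angle of the resulting tangent vector from the
# circumferential direction (the one that projects to +x). The same formulas
# serve both views: an inside image is the mirror image of the outside one,
# and mirroring is an isometry of the surface of revolution, so each view is
# lifted in its own image frame.

#' Lift image positions onto the surface
#'
#' @param surface a `surface_of_revolution`.
#' @param x,z image positions in micrometres (x across the axis, z along
#'   it, neck-centred); vectors of equal length.
#' @return data.frame with columns `z` and `phi` (radians, in `(0, pi)`,
#'   front pole at `pi/2`).
#' @export
lift_point <- function(surface, x, z) {
  check_z_domain(surface, z)
  r <- surface$r(z)
  if (any(abs(x) >= r)) {
    stop("outside-silhouette: |x| >= r(z) cannot be lifted")
  }
  data.frame(z = z, phi = acos(x / r))
}

#' Lift image-plane fiber angles to surface angles theta
#'
#' @param surface a `surface_of_revolution`.
#' @param x,z image positions in micrometres.
#' @param alpha image-plane fiber angles in degrees, `[0, 180)`.
#' @param cond_cap samples whose projection Jacobian has a condition number
#'   above this are returned as `NA` (they are counted by the caller's QC);
#'   the Jacobian degenerates at the silhouette.
#' @return data.frame with columns `z`, `phi`, `theta` (degrees in
#'   `[0, 180)`, 0 = equatorial), `cond` (Jacobian condition number) and
#'   `ok` (FALSE where the condition cap was exceeded).
#' @export
lift_angle <- function(surface, x, z, alpha, cond_cap = 25) {
  lp <- lift_point(surface, x, z)
  r <- surface$r(z); rp <- surface$dr(z)
  phi <- lp$phi
  a <- alpha * pi / 180
  s <- sqrt(1 + rp^2)
  # Orthonormal tangent basis: e_c = -P_phi / r (projects to +x at the
  # front pole), e_m = P_z / s. Their orthographic images form
  #   M = [[sin phi, r' cos phi / s], [0, 1 / s]],
  # and the lift solves M (c, m)^T = (cos a, sin a)^T; theta is the axial
  # angle atan2(m, c) of the tangent vector in the (e_c, e_m) frame.
  m <- s * sin(a)
  ccomp <- (cos(a) - rp * cos(phi) * sin(a)) / sin(phi)
  theta <- wrap_axial(atan2(m, ccomp) * 180 / pi)
  # condition number of M (unit-consistent: both columns are images of
  # unit tangent vectors); degenerates like 1/sin(phi) at the silhouette
  cn <- vapply(seq_along(phi), function(i) {
    kappa <- svd(matrix(c(sin(phi[i]), 0, rp[i] * cos(phi[i]) / s[i],
                          1 / s[i]), 2, 2))$d
    kappa[1] / kappa[2]
  }, numeric(1))
  ok <- cn <= cond_cap
  theta[!ok] <- NA_real_
  data.frame(z = z, phi = phi, theta = theta, cond = cn, ok = ok)
}

#' Extract lifted fiber samples from an image stack
#'
#' Convenience pipeline: maximum intensity projection, artifact masking,
#' structure-tensor orientation field, then lifting of every valid window
#' onto the surface. Returns the raw sample table; apply
#' [apply_exclusions()] and [attach_curvature()] before aggregation.
#'
#' @param stack an `image_stack`.
#' @param surface surface to lift onto; default the surface attached to the
#'   stack.
#' @param channel channel name.
#' @param rois optional exclusion polygons for [mask_artifacts()].
#' @param window_sigma,coherence_floor passed to [local_orientation()].
#' @param cond_cap passed to [lift_angle()].
#' @return data.frame of class `fiber_samples` with columns `x_um`, `z_um`,
#'   `phi_rad`, `alpha_deg`, `theta_deg`, `weight`, `valid`, `view`;
#'   attribute `qc` counts windows discarded by the Jacobian condition cap.
#' @export
fiber_samples <- function(stack, surface = NULL, channel = "actin",
                          rois = NULL, window_sigma = 10,
                          coherence_floor = 0.2, cond_cap = 25) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(surface)) surface <- stack$surface
  if (is.null(surface)) stop("no surface attached to the stack; pass one")
  mp <- max_intensity_projection(stack, channel)
  mask <- mask_artifacts(mp$image, rois = rois)
  of <- local_orientation(mp$image, mask = mask, window_sigma = window_sigma,
                          pixel_size = mp$pixel_size[1],
                          coherence_floor = coherence_floor)
  xw <- stack_axis(stack, 1)[of$x_px]
  zw <- stack_axis(stack, 2)[of$z_px]
  g <- expand.grid(x_um = xw, z_um = zw)
  alpha <- as.vector(of$alpha)
  weight <- as.vector(of$weight)
  valid <- as.vector(of$valid)
  # only windows strictly inside the silhouette and the z domain can lift
  inside <- abs(g$x_um) < surface$r(pmin(pmax(g$z_um, surface$z_range[1]),
                                         surface$z_range[2])) &
    g$z_um > surface$z_range[1] & g$z_um < surface$z_range[2]
  keep <- valid & inside
  la <- lift_angle(surface, g$x_um[keep], g$z_um[keep], alpha[keep],
                   cond_cap = cond_cap)
  out <- data.frame(
    x_um = g$x_um[keep], z_um = g$z_um[keep], phi_rad = la$phi,
    alpha_deg = alpha[keep], theta_deg = la$theta, weight = weight[keep],
    valid = la$ok, view = stack$view
  )
  attr(out, "qc") <- list(n_windows = length(valid),
                          n_masked_or_low_coherence = sum(!valid),
                          n_outside_silhouette = sum(valid & !inside),
                          n_cond_discarded = sum(!la$ok))
  class(out) <- c("fiber_samples", "data.frame")
  out
}

#' Apply the spatial exclusion rules
#'
#' Drops samples more than `z_max` above/below the neck centre, samples in
#' the silhouette edge region (`|x| > edge_frac * r(z)`, where the
#' projection Jacobian conditioning degrades), and invalid windows.
#'
#' @param samples a `fiber_samples` data.frame.
#' @param surface the lifting surface.
#' @param z_max exclusion half-window along the axis in um (default the
#'   300 um evaluation window around the neck).
#' @param edge_frac silhouette margin fraction.
#' @return filtered `fiber_samples`; warns (not errors) when empty.
#' @export
apply_exclusions <- function(samples, surface, z_max = 300,
                             edge_frac = 0.85) {
  keep <- !is.na(samples$theta_deg) & samples$valid &
    abs(samples$z_um) <= z_max &
    abs(samples$x_um) <= edge_frac * surface$r(samples$z_um)
  out <- samples[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("no samples survive the exclusion rules")
  attr(out, "qc") <- attr(samples, "qc")
  class(out) <- c("fiber_samples", "data.frame")
  out
}

#' Attach the normal curvature along the fiber direction
#'
#' For every sample, evaluates k_theta at its (z, theta) via Euler's
#' theorem.
#'
#' @param samples a `fiber_samples` data.frame.
#' @param surface the lifting surface.
#' @return `samples` with a `k_theta` column (1/um).
#' @export
attach_curvature <- function(samples, surface) {
  samples$k_theta <- normal_curvature(surface, samples$z_um,
                                      samples$theta_deg)
  samples
}

#' Classify the handedness of the helical pattern
#'
#' In the outside view a left-handed helix shows theta < 90; in the inside
#' view the same helix shows theta > 90.
#'
#' @param theta surface fiber angles in degrees, `[0, 180)`.
#' @param view `"outside"` or `"inside"`.
#' @param tol angles within `tol` degrees of 0 or 90 are classified
#'   achiral (equatorial/meridional).
#' @return factor with levels `left`, `right`, `achiral`.
#' @export
handedness <- function(theta, view = c("outside", "inside"), tol = 1) {
  view <- match.arg(view)
  stopifnot(all(theta >= 0 & theta < 180))
  d <- abs(axial_diff(theta, 90))
  e <- abs(axial_diff(theta, 0))
  out <- ifelse(
    d <= tol | e <= tol, "achiral",
    ifelse(xor(theta < 90, view == "inside"), "left", "right"))
  factor(out, levels = c("left", "right", "achiral"))
}

#' Export fiber samples as CSV
#'
#' @param samples a `fiber_samples` data.frame (optionally with metadata
#'   columns `sample_id`, `day`, `group`).
#' @param path output CSV path.
#' @export
samples_to_csv <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE)
  invisible(path)
}
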