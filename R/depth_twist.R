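# Depth-resolved twist, actin-collagen signal offset and co-alignment.

#' Twist of an angle series along the growth direction
#'
#' Wrapped axial step differences (each in `(-90, 90]`) summed along a
#' series ordered old -> new tissue; the caller supplies the growth
#' ordering (for both bridges and pores: deep -> surface, since both grow
#' away from the scaffold). A positive twist means theta increases with
#' growth, a negative twist that it decreases.
#'
#' @param angles ordered angle series in degrees (old -> new).
#' @param noise_threshold minimal |total wrapped change| in degrees before
#'   a twist sign is declared (default 10, about five times the synthetic
#'   estimator bias).
#' @return list of class `twist_result` with `sign` (`"positive"`,
#'   `"negative"` or `"none"`), `total_wrapped_change` (degrees) and
#'   `steps` (per-step wrapped differences).
#' @export
twist_from_series <- function(angles, noise_threshold = 10) {
  angles <- angles[!is.na(angles)]
  if (length(angles) < 2) stop("too-few-points: need >= 2 confident angles")
  steps <- axial_diff(angles[-1], angles[-length(angles)])
  total <- sum(steps)
  sgn <- if (abs(total) <= noise_threshold) "none"
         else if (total > 0) "positive" else "negative"
  structure(list(sign = sgn, total_wrapped_change = total, steps = steps),
            class = "twist_result")
}

#' @export
print.twist_result <- function(x, ...) {
  cat(sprintf("twist: %s (total wrapped change %.1f deg over %d steps)\n",
              x$sign, x$total_wrapped_change, length(x$steps)))
  invisible(x)
}

#' Twist of a depth profile
#'
#' Convenience wrapper: orders the confident slices of a [slice_orientation()]
#' profile deep -> surface (old -> new tissue) and calls
#' [twist_from_series()].
#'
#' @param profile a `depth_profile`.
#' @inheritParams twist_from_series
#' @return a `twist_result`.
#' @export
twist_from_profile <- function(profile, noise_threshold = 10) {
  p <- profile[profile$confident & !is.na(profile$alpha_deg), ]
  p <- p[order(-p$depth_um), ]           # deep (old) -> surface (new)
  twist_from_series(p$alpha_deg, noise_threshold)
}

# Depth of the half-max onset of an intensity profile, by linear
# interpolation of the first upward crossing. Plateau = maximum intensity.
half_max_onset <- function(depth, intensity) {
  plateau <- max(intensity)
  hm <- plateau / 2
  above <- which(intensity >= hm)
  if (length(above) == 0 || plateau <= 0) return(NA_real_)
  i <- above[1]
  if (i == 1) return(depth[1])
  frac <- (hm - intensity[i - 1]) / (intensity[i] - intensity[i - 1])
  depth[i - 1] + frac * (depth[i] - depth[i - 1])
}

#' Depth offset between the collagen and actin signal onsets
#'
#' Offset = depth of the collagen half-max onset minus depth of the actin
#' half-max onset (half-max relative to each channel's own plateau, so the
#' measure is invariant to per-channel intensity rescaling); positive =
#' collagen deeper.
#'
#' @param actin_profile,collagen_profile `depth_profile` data.frames (or
#'   any data.frame with `depth_um` and `intensity` columns) sharing the
#'   depth axis orientation (surface -> deep).
#' @return offset in micrometres.
#' @export
channel_offset <- function(actin_profile, collagen_profile) {
  oa <- half_max_onset(actin_profile$depth_um, actin_profile$intensity)
  oc <- half_max_onset(collagen_profile$depth_um, collagen_profile$intensity)
  if (is.na(oa) || is.na(oc)) {
    stop("onset-not-found: a channel never exceeds its half-max")
  }
  oc - oa
}

#' Actin-collagen co-alignment summary
#'
#' Per-slice wrapped axial differences between the two channels' dominant
#' angles over mutually confident slices, plus an axial circular
#' correlation (Fisher-Lee correlation on doubled angles).
#'
#' @param theta_actin,theta_collagen per-slice angles in degrees.
#' @param confident logical vector of mutually confident slices (default:
#'   slices where both angles are finite).
#' @return list with `n`, `mean_abs_diff` (degrees), `diffs` and
#'   `correlation` (1 for identical varying series; for zero-variance
#'   series it is 1 when the series agree and `NA` otherwise).
#' @export
coalignment <- function(theta_actin, theta_collagen, confident = NULL) {
  stopifnot(length(theta_actin) == length(theta_collagen))
  if (is.null(confident)) confident <- rep(TRUE, length(theta_actin))
  use <- confident & is.finite(theta_actin) & is.finite(theta_collagen)
  if (sum(use) < 3) stop("insufficient-overlap: need >= 3 confident slices")
  a <- theta_actin[use]; b <- theta_collagen[use]
  d <- axial_diff(a, b)
  a2 <- 2 * a * pi / 180; b2 <- 2 * b * pi / 180
  am <- atan2(sum(sin(a2)), sum(cos(a2)))
  bm <- atan2(sum(sin(b2)), sum(cos(b2)))
  sa <- sin(a2 - am); sb <- sin(b2 - bm)
  den <- sqrt(sum(sa^2) * sum(sb^2))
  rho <- if (den > 1e-12) {
    sum(sa * sb) / den
  } else if (max(abs(d)) < 1e-9) 1 else NA_real_
  list(n = sum(use), mean_abs_diff = mean(abs(d)), diffs = d,
       correlation = rho)
}

#' Export a depth profile as CSV
#'
#' @param profile a `depth_profile`.
#' @param path output CSV path.
#' @export
depth_profile_to_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
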