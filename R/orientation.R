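# Orientation analysis: maximum intensity projections, artifact masking and
# structure-tensor estimation of the local in-plane fiber angle alpha.
#
# Angle convention: for an image matrix im[x, z] (dim 1 horizontal, dim 2
# vertical/axial) the fiber angle alpha is measured from the +x direction
# towards +z, as an orientation in [0, 180). The estimator is the classical
# 2D structure tensor: Gaussian-derivative gradients, tensor smoothing with
# window_sigma, fiber axis = minor eigenvector, weight = coherence x local
# gradient energy.

#' Maximum intensity projection along the camera axis
#'
#' @param stack an `image_stack`.
#' @param channel channel name.
#' @return list of class `mip` with `image` (matrix `[x, z]`), `argmax_k`
#'   (slice index of the maximum per pixel, for depth-aware masking),
#'   `pixel_size` (um, x and z), `origin` (um) and `view`.
#' @export
max_intensity_projection <- function(stack, channel = "actin") {
  stopifnot(inherits(stack, "image_stack"))
  a <- stack$channels[[channel]]
  if (is.null(a) || length(a) == 0) stop("empty stack or unknown channel")
  d <- dim(a)
  m <- matrix(a, d[1] * d[2], d[3])
  img <- matrix(apply(m, 1, max), d[1], d[2])
  amk <- matrix(max.col(m, ties.method = "first"), d[1], d[2])
  structure(
    list(image = img, argmax_k = amk, pixel_size = stack$voxel_size[1:2],
         origin = stack$origin, voxel_size = stack$voxel_size,
         view = stack$view),
    class = "mip"
  )
}

# Even-odd rule point-in-polygon, vectorized over points.
points_in_polygon <- function(px, pz, poly_x, poly_z) {
  n <- length(poly_x)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((poly_z[i] > pz) != (poly_z[j] > pz)) &
      (px < (poly_x[j] - poly_x[i]) * (pz - poly_z[i]) /
         (poly_z[j] - poly_z[i]) + poly_x[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Build a validity mask excluding artifacts
#'
#' Union of user-supplied exclusion polygons (e.g. dust particles) and
#' auto-detected saturated pixels; masked pixels are excluded from all
#' downstream statistics.
#'
#' @param image 2D image matrix `[x, z]`.
#' @param rois list of polygons in pixel coordinates, each a matrix or
#'   data.frame with columns `x` and `z` (vertices in order).
#' @param saturation_level intensities `>= saturation_level` are masked;
#'   `NULL` uses 0.999 of the theoretical cap 1 if the image is normalized,
#'   otherwise 0.999 of the maximum.
#' @return logical matrix, `TRUE` = valid pixel.
#' @export
mask_artifacts <- function(image, rois = NULL, saturation_level = NULL) {
  stopifnot(is.matrix(image))
  if (is.null(saturation_level)) {
    saturation_level <- if (max(image) <= 1) 0.999 else 0.999 * max(image)
  }
  mask <- image < saturation_level
  if (!is.null(rois)) {
    if (!is.list(rois)) stop("malformed ROI list: expected a list of polygons")
    px <- as.vector(row(image)); pz <- as.vector(col(image))
    for (poly in rois) {
      poly <- as.data.frame(poly)
      if (!all(c("x", "z") %in% names(poly)) || nrow(poly) < 3) {
        stop("malformed ROI: polygons need >= 3 vertices with columns x, z")
      }
      inside <- points_in_polygon(px, pz, poly$x, poly$z)
      mask[matrix(inside, nrow(image), ncol(image))] <- FALSE
    }
  }
  mask
}

#' Read exclusion ROIs from a JSON polygon file
#'
#' Expects a JSON array of objects, each with `x` and `z` vertex arrays in
#' pixel coordinates.
#'
#' @param path JSON file path.
#' @return list of data.frames with columns `x`, `z`.
#' @export
read_roi_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(raw)) raw <- split(raw, seq_len(nrow(raw)))
  lapply(raw, function(p) data.frame(x = unlist(p$x), z = unlist(p$z)))
}

#' Structure-tensor local fiber orientation
#'
#' @param image 2D image matrix `[x, z]`; globally normalized to `[0, 1]`
#'   before gradient computation (the only rescaling the pipeline performs).
#' @param mask optional logical validity matrix from [mask_artifacts()].
#' @param window_sigma tensor-smoothing scale in micrometres (the
#'   evaluation window; default 10 um, about the scale of a stress-fiber
#'   bundle).
#' @param pixel_size pixel size in micrometres.
#' @param grad_sigma pre-smoothing sigma in pixels for the Gaussian
#'   derivative.
#' @param coherence_floor windows with coherence below this are invalidated.
#' @param stride window-centre spacing in pixels; default ~ one
#'   window sigma.
#' @return list of class `orientation_field`: vectors `x_px`, `z_px` of
#'   window centres plus matrices `alpha` (degrees in `[0, 180)`), `weight`
#'   (coherence x normalized energy; 0 where invalid), `coherence`, `valid`,
#'   and `pixel_size`. A flat image yields an all-invalid field.
#' @export
local_orientation <- function(image, mask = NULL, window_sigma = 10,
                              pixel_size = 1, grad_sigma = 1,
                              coherence_floor = 0.2, stride = NULL) {
  stopifnot(is.matrix(image))
  sigma_w <- window_sigma / pixel_size
  if (sigma_w < 2) stop("window_sigma must be at least 2 pixels")
  if (is.null(stride)) stride <- max(1L, round(sigma_w / 2))
  rng <- range(image)
  im <- if (diff(rng) > 0) (image - rng[1]) / diff(rng) else image * 0
  im <- gauss_blur_2d(im, grad_sigma)
  nx <- nrow(im); nz <- ncol(im)
  # 4th-order central differences: the 3-tap stencil biases the gradient
  # *direction* by >1 degree at stripe periods below ~10 px
  dk <- c(-1, 8, 0, -8, 1) / 12
  gx <- conv_cols(im, dk)
  gz <- t(conv_cols(t(im), dk))
  if (!is.null(mask)) {        # keep masked pixels out of the tensor average
    gx[!mask] <- 0; gz[!mask] <- 0
  }
  jxx <- gauss_blur_2d(gx * gx, sigma_w)
  jxz <- gauss_blur_2d(gx * gz, sigma_w)
  jzz <- gauss_blur_2d(gz * gz, sigma_w)
  tr <- jxx + jzz
  dif <- sqrt((jxx - jzz)^2 + 4 * jxz^2)
  coh <- ifelse(tr > 0, dif / tr, 0)
  beta <- 0.5 * atan2(2 * jxz, jxx - jzz) * 180 / pi  # dominant gradient dir
  alpha <- wrap_axial(beta + 90)                       # fiber axis
  energy_floor <- 1e-8
  valid <- coh >= coherence_floor & tr > energy_floor
  if (!is.null(mask)) valid <- valid & mask
  emax <- max(tr)
  weight <- if (emax > 0) coh * tr / emax else tr * 0
  weight[!valid] <- 0
  # sample window centres on a stride grid, away from the image border
  # (replicate padding corrupts the tensor within ~2.5 window sigmas)
  b <- max(2L, ceiling(2.5 * sigma_w))
  xi <- seq(b + 1L, nx - b, by = stride)
  zi <- seq(b + 1L, nz - b, by = stride)
  if (length(xi) == 0 || length(zi) == 0) {
    stop("image too small for the requested window_sigma")
  }
  structure(
    list(x_px = xi, z_px = zi,
         alpha = alpha[xi, zi, drop = FALSE],
         weight = weight[xi, zi, drop = FALSE],
         coherence = coh[xi, zi, drop = FALSE],
         valid = valid[xi, zi, drop = FALSE],
         pixel_size = pixel_size),
    class = "orientation_field"
  )
}

#' @export
as.data.frame.orientation_field <- function(x, ...) {
  g <- expand.grid(x_px = x$x_px, z_px = x$z_px)
  data.frame(g, alpha_deg = as.vector(x$alpha),
             weight = as.vector(x$weight),
             coherence = as.vector(x$coherence),
             valid = as.vector(x$valid))
}

#' Export an orientation field as CSV
#'
#' @param field an `orientation_field`.
#' @param path output CSV path.
#' @export
orientation_field_to_csv <- function(field, path) {
  utils::write.csv(as.data.frame(field), path, row.names = FALSE)
  invisible(path)
}

#' Per-slice dominant orientation in a region of interest
#'
#' Measures one dominant fiber angle per stack slice (coherence-weighted
#' axial circular mean of the structure-tensor field) inside a region
#' centred on the neck, together with the mean slice intensity, ordered
#' from the tissue surface into the depth. Depth 0 is the first slice whose
#' mean intensity exceeds `onset_frac` of the channel plateau; slices below
#' `confidence_frac` of the plateau are flagged low-confidence.
#'
#' @param stack an `image_stack`.
#' @param channel channel name.
#' @param roi_size_um c(width_x, height_z) of the region in um (default the
#'   200 x 200 um window used for depth profiling).
#' @param center_um world (x, z) centre of the region; default c(0, 0), the
#'   neck centre on the axis.
#' @param window_sigma passed to [local_orientation()].
#' @param onset_frac fraction of the plateau intensity defining depth 0.
#' @param confidence_frac intensity fraction below which a slice is flagged
#'   low-confidence.
#' @param coherence_floor passed to [local_orientation()].
#' @param reference_channel channel whose intensity defines the depth-0
#'   onset (default: the analysed channel itself). Pass `"actin"` when
#'   profiling a collagen channel so both profiles share one depth axis,
#'   as required by [channel_offset()].
#' @return data.frame of class `depth_profile` with columns `slice`
#'   (original stack index), `depth_um`, `alpha_deg`, `intensity`,
#'   `confident`; attribute `channel`.
#' @export
slice_orientation <- function(stack, channel = "actin",
                              roi_size_um = c(200, 200), center_um = c(0, 0),
                              window_sigma = 10, onset_frac = 0.1,
                              confidence_frac = 0.1, coherence_floor = 0.2,
                              reference_channel = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  a <- stack$channels[[channel]]
  if (is.null(a)) stop("unknown channel ", channel)
  d <- dim(a)
  xw <- stack_axis(stack, 1)
  zw <- stack_axis(stack, 2)
  xi <- which(abs(xw - center_um[1]) <= roi_size_um[1] / 2)
  zi <- which(abs(zw - center_um[2]) <= roi_size_um[2] / 2)
  if (length(xi) < 8 || length(zi) < 8) stop("ROI outside image bounds")
  # slice order: from the tissue surface into the depth
  ks <- if (stack$view == "outside") rev(seq_len(d[3])) else seq_len(d[3])
  alpha <- intensity <- rep(NA_real_, length(ks))
  for (m in seq_along(ks)) {
    sl <- a[xi, zi, ks[m]]
    intensity[m] <- mean(sl)
    of <- tryCatch(
      local_orientation(sl, window_sigma = window_sigma,
                        pixel_size = stack$voxel_size[1],
                        coherence_floor = coherence_floor),
      error = function(e) NULL)
    if (!is.null(of) && any(of$valid)) {
      alpha[m] <- axial_mean(of$alpha[of$valid], of$weight[of$valid])
    }
  }
  ref_int <- intensity
  if (!is.null(reference_channel) && reference_channel != channel) {
    ref <- stack$channels[[reference_channel]]
    if (is.null(ref)) stop("unknown reference channel ", reference_channel)
    ref_int <- vapply(ks, function(k) mean(ref[xi, zi, k]), numeric(1))
  }
  plateau <- max(intensity)
  onset <- which(ref_int >= onset_frac * max(ref_int))[1]
  if (is.na(onset)) onset <- 1L
  depth <- (seq_along(ks) - onset) * stack$voxel_size[3]
  confident <- intensity >= confidence_frac * plateau & !is.na(alpha)
  out <- data.frame(slice = ks, depth_um = depth, alpha_deg = alpha,
                    intensity = intensity, confident = confident)
  attr(out, "channel") <- channel
  class(out) <- c("depth_profile", "data.frame")
  out
}
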