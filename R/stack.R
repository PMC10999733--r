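# ImageStack container and plain-text serialization.
#
# Array convention: channels are 3D arrays indexed [x, z, y] where
#   dim 1 (x): horizontal image coordinate, perpendicular to the rotation
#              axis in the projection plane;
#   dim 2 (z): vertical image coordinate, along the rotation axis;
#   dim 3 (y): camera / depth axis (world y, ascending).
# The maximum intensity projection collapses dim 3. `origin` gives the world
# coordinates (um) of the centre of voxel [1, 1, 1]; the rotation axis sits
# at world x = 0 and the neck centre at world z = 0.

#' Construct an image stack
#'
#' @param channels named list of non-negative 3D arrays with identical
#'   dimensions; names typically `"actin"` and optionally `"collagen"`.
#' @param voxel_size length-3 voxel size in micrometres for dims (x, z, y);
#'   default is the light-sheet acquisition geometry, 0.63 um lateral pixels
#'   and 1.2 um z-steps along the camera axis.
#' @param view `"outside"` (capillary bridge imaged from the medium) or
#'   `"inside"` (opened pore imaged from the axis side).
#' @param origin world coordinates (um) of voxel `[1, 1, 1]`.
#' @param truth optional ground-truth record (synthetic stacks always carry
#'   one); serialized alongside the voxels.
#' @param surface optional `surface_of_revolution` the stack was rendered
#'   on / should be analysed against.
#' @return object of class `image_stack`.
#' @export
image_stack <- function(channels, voxel_size = c(0.63, 0.63, 1.2),
                        view = c("outside", "inside"),
                        origin = c(0, 0, 0), truth = NULL, surface = NULL) {
  view <- match.arg(view)
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)))
  d <- dim(channels[[1]])
  for (ch in channels) {
    stopifnot(length(dim(ch)) == 3, identical(dim(ch), d))
    if (any(ch < 0)) stop("intensities must be non-negative")
  }
  stopifnot(length(voxel_size) == 3, all(voxel_size > 0),
            length(origin) == 3)
  structure(
    list(channels = channels, voxel_size = as.numeric(voxel_size),
         view = view, origin = as.numeric(origin), truth = truth,
         surface = surface),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf(
    "image_stack: %d x %d x %d voxels (%.2f x %.2f x %.2f um), view %s, channels: %s\n",
    d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
    x$view, paste(names(x$channels), collapse = ", ")))
  if (!is.null(x$truth)) cat("  carries synthetic ground truth\n")
  invisible(x)
}

# World coordinates of voxel centres along each dimension.
stack_axis <- function(stack, dim_idx) {
  d <- dim(stack$channels[[1]])[dim_idx]
  stack$origin[dim_idx] + (seq_len(d) - 1) * stack$voxel_size[dim_idx]
}

#' Write an image stack as plain text plus a JSON sidecar
#'
#' One whitespace-delimited text file per channel (header line with the
#' dimensions, then voxel values in column-major order) and a
#' `<name>_sidecar.json` carrying voxel size, view, origin and the ground
#' truth. A plain-text stand-in for multi-page TIFF, chosen because the
#' target R stack ships no TIFF codec; synthetic stacks are never written
#' without their truth record.
#'
#' @param stack an `image_stack`.
#' @param dir output directory (created if needed).
#' @param name basename for the files.
#' @param digits significant digits retained for voxel values.
#' @return the sidecar path, invisibly.
#' @export
write_image_stack <- function(stack, dir, name = "stack", digits = 5) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(stack$channels[[1]])
  files <- list()
  for (ch in names(stack$channels)) {
    f <- file.path(dir, sprintf("%s_%s.txt", name, ch))
    con <- file(f, "w")
    writeLines(sprintf("# fibertwist image_stack channel=%s dims=%d %d %d",
                       ch, d[1], d[2], d[3]), con)
    writeLines(paste(signif(as.vector(stack$channels[[ch]]), digits),
                     collapse = " "), con)
    close(con)
    files[[ch]] <- basename(f)
  }
  sidecar <- file.path(dir, sprintf("%s_sidecar.json", name))
  jsonlite::write_json(
    list(dims = d, voxel_size_um = stack$voxel_size, view = stack$view,
         origin_um = stack$origin, channels = files, truth = stack$truth),
    sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(sidecar)
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param sidecar path to the `_sidecar.json` file.
#' @return an `image_stack` (without a surface attached).
#' @export
read_image_stack <- function(sidecar) {
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  dir <- dirname(sidecar)
  d <- as.integer(meta$dims)
  channels <- lapply(meta$channels, function(f) {
    lines <- readLines(file.path(dir, f))
    array(as.numeric(strsplit(lines[2], " ", fixed = TRUE)[[1]]), d)
  })
  image_stack(channels, voxel_size = meta$voxel_size_um, view = meta$view,
              origin = meta$origin_um, truth = meta$truth)
}
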