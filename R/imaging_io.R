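#' @title Multi-channel image stacks and planar working images
#' @name imaging-types
#' @description
#' `image_stack()` wraps a nonnegative intensity array with axes fixed as
#' `(channel, z, row, col)` together with its channel labels and physical
#' in-plane pixel size in micrometres. `planar_image()` holds a single 2D
#' channel (one matrix) with its pixel size; it is what the segmentation and
#' metric stages consume. Coordinates are 1-based pixel centers with
#' `(x, y) = (col, row)`.
NULL

cond_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "invasionquant_error")))
}

#' Construct an image stack
#'
#' @param data numeric array with dimensions `(channel, z, row, col)`.
#'   A matrix is promoted to a 1-channel, 1-plane stack.
#' @param channel_labels character vector, one label per channel
#'   (e.g. `c("GFP", "BF")`).
#' @param pixel_size_um in-plane pixel size, micrometres per pixel
#'   (isotropic; anisotropic pixels are rejected at load time).
#' @param z_step_um optional z spacing in micrometres.
#' @return an `image_stack` object.
#' @export
image_stack <- function(data, channel_labels, pixel_size_um, z_step_um = NULL) {
  if (is.matrix(data)) data <- array(data, c(1L, 1L, nrow(data), ncol(data)))
  stopifnot(is.array(data), length(dim(data)) == 4L)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    cond_stop("pixel_size_um must be a single positive number",
              "missing_calibration_error")
  if (length(channel_labels) != dim(data)[1L])
    stop("channel_labels length must equal the channel count")
  if (any(!is.finite(data)) || any(data < 0))
    stop("intensities must be finite and nonnegative")
  structure(
    list(data = data, channel_labels = as.character(channel_labels),
         pixel_size_um = pixel_size_um, z_step_um = z_step_um),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d channel(s) [%s], %d z-plane(s), %d x %d px, %.4g um/px\n",
              d[1], paste(x$channel_labels, collapse = ", "), d[2], d[3], d[4],
              x$pixel_size_um))
  invisible(x)
}

#' Construct a planar (single-channel, 2D) image
#'
#' @param intensities numeric matrix `(row, col)` of nonnegative finite values.
#' @param pixel_size_um micrometres per pixel.
#' @param channel_label channel name carried along for provenance.
#' @return a `planar_image`: the matrix with attributes
#'   `pixel_size_um` and `channel_label`.
#' @export
planar_image <- function(intensities, pixel_size_um, channel_label = "channel1") {
  stopifnot(is.matrix(intensities))
  if (any(!is.finite(intensities)) || any(intensities < 0))
    stop("intensities must be finite and nonnegative")
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  structure(intensities, pixel_size_um = pixel_size_um,
            channel_label = channel_label,
            class = c("planar_image", "matrix", "array"))
}

#' @export
print.planar_image <- function(x, ...) {
  cat(sprintf("<planar_image> channel '%s', %d x %d px, %.4g um/px\n",
              attr(x, "channel_label"), nrow(x), ncol(x),
              attr(x, "pixel_size_um")))
  invisible(x)
}

## ---- calibration helpers ----------------------------------------------

## pixels-per-unit resolution tag -> um per pixel
res_to_um <- function(res, unit) {
  per_um <- switch(unit,
                   inch = res / 25400,
                   cm = res / 10000,
                   NA_real_)
  if (is.na(per_um) || per_um <= 0) return(NA_real_)
  1 / per_um
}

pixel_size_from_attrs <- function(at) {
  xr <- at[["x.resolution"]]; yr <- at[["y.resolution"]]
  unit <- at[["resolution.unit"]]
  if (!is.null(xr) && !is.null(unit)) {
    if (!is.null(yr) && abs(xr - yr) > 1e-6 * max(xr, yr))
      cond_stop("anisotropic in-plane pixels are not supported",
                "anisotropic_pixel_error")
    return(res_to_um(xr, unit))
  }
  desc <- at[["description"]]
  if (!is.null(desc)) {
    mx <- regmatches(desc, regexec('PhysicalSizeX="([0-9.eE+-]+)"', desc))[[1]]
    my <- regmatches(desc, regexec('PhysicalSizeY="([0-9.eE+-]+)"', desc))[[1]]
    if (length(mx) == 2) {
      px <- as.numeric(mx[2])
      if (length(my) == 2 && abs(as.numeric(my[2]) - px) > 1e-6 * px)
        cond_stop("anisotropic in-plane pixels are not supported",
                  "anisotropic_pixel_error")
      return(px)
    }
  }
  NA_real_
}

sidecar_path <- function(path) paste0(path, ".json")

#' Read a TIFF / OME-TIFF image into an image stack
#'
#' Planes are read with the `tiff` package and normalised to the internal
#' `(channel, z, row, col)` axis order. The pixel size is resolved, in order,
#' from (1) the JSON sidecar written by [write_image_stack()], (2) the TIFF
#' resolution tags or an OME-XML `PhysicalSizeX` entry in the image
#' description, (3) `pixel_size_override`. If none is available an explicit
#' missing-calibration error is raised -- a pixel size of 1 um is never
#' silently assumed.
#'
#' @param path path to a TIFF or OME-TIFF file.
#' @param pixel_size_override optional pixel size in micrometres, used only
#'   when the file itself carries no calibration.
#' @return an [image_stack()].
#' @export
load_image <- function(path, pixel_size_override = NULL) {
  if (!file.exists(path)) cond_stop(paste0("cannot read file: ", path), "io_error")
  planes <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE),
                     error = function(e)
                       cond_stop(paste0("unreadable TIFF: ", conditionMessage(e)),
                                 "io_error"))
  if (!is.list(planes)) planes <- list(planes)
  at <- attributes(planes[[1L]])

  meta <- NULL
  sc <- sidecar_path(path)
  if (file.exists(sc)) meta <- jsonlite::read_json(sc, simplifyVector = TRUE)

  ## 3D planes (interleaved samples) become channels of a single z-plane
  if (length(dim(planes[[1L]])) == 3L) {
    pl <- planes[[1L]]
    planes <- lapply(seq_len(dim(pl)[3L]), function(k) pl[, , k])
  }
  nplanes <- length(planes)
  nr <- nrow(planes[[1L]]); nc <- ncol(planes[[1L]])
  if (!all(vapply(planes, function(p) nrow(p) == nr && ncol(p) == nc, TRUE)))
    stop("all planes must share dimensions")

  if (!is.null(meta)) {
    channels <- as.character(meta$channel_labels)
    nz <- as.integer(meta$n_z)
    if (length(channels) * nz != nplanes)
      stop("sidecar layout does not match plane count")
  } else {
    channels <- paste0("channel", seq_len(nplanes))
    nz <- 1L
  }
  nchan <- length(channels)

  px <- if (!is.null(meta) && !is.null(meta$pixel_size_um))
    as.numeric(meta$pixel_size_um) else pixel_size_from_attrs(at)
  if (is.na(px) || is.null(px)) px <- pixel_size_override
  if (is.null(px) || is.na(px))
    cond_stop(paste0("no pixel-size calibration in ", path,
                     " and no override given"), "missing_calibration_error")

  data <- array(0, c(nchan, nz, nr, nc))
  for (ci in seq_len(nchan))
    for (zi in seq_len(nz))
      data[ci, zi, , ] <- planes[[(ci - 1L) * nz + zi]]

  z_step <- if (!is.null(meta)) meta$z_step_um else NULL
  image_stack(data, channels, px, z_step)
}

#' Write an image stack as 16-bit TIFF plus a JSON metadata sidecar
#'
#' Planes are stored channel-major (all z of channel 1, then channel 2, ...)
#' as 16-bit grayscale. Intensities must lie in `[0, 65535]` and are rounded
#' to integers, so a write/read round trip reproduces them exactly. The
#' sidecar `<path>.json` records channel labels, z layout and pixel size,
#' because the installed TIFF writer cannot emit resolution tags.
#'
#' @param stack an [image_stack()].
#' @param path output path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  if (max(stack$data) > 65535)
    stop("intensities exceed the 16-bit range")
  planes <- vector("list", d[1L] * d[2L])
  for (ci in seq_len(d[1L]))
    for (zi in seq_len(d[2L]))
      planes[[(ci - 1L) * d[2L] + zi]] <-
        round(stack$data[ci, zi, , ]) / 65535
  tiff::writeTIFF(planes, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(
    list(channel_labels = stack$channel_labels, n_z = d[2L],
         pixel_size_um = stack$pixel_size_um,
         z_step_um = stack$z_step_um),
    sidecar_path(path), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Maximum-intensity projection of one channel
#'
#' Collapses the z axis by the pointwise maximum, the standard projection for
#' visualising and quantifying confocal z-stacks; a single-plane stack is
#' returned unchanged.
#'
#' @param stack an [image_stack()].
#' @param channel channel label to project.
#' @return a [planar_image()] with the stack's pixel size.
#' @export
max_intensity_projection <- function(stack, channel) {
  stopifnot(inherits(stack, "image_stack"))
  ci <- match(channel, stack$channel_labels)
  if (is.na(ci))
    cond_stop(sprintf("channel '%s' not in stack (have: %s)", channel,
                      paste(stack$channel_labels, collapse = ", ")),
              "channel_lookup_error")
  d <- dim(stack$data)
  proj <- stack$data[ci, 1L, , ]
  if (d[2L] > 1L)
    for (zi in 2:d[2L]) proj <- pmax(proj, stack$data[ci, zi, , ])
  planar_image(matrix(proj, d[3L], d[4L]), stack$pixel_size_um, channel)
}
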