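#' Run configuration
#'
#' Bundles every tunable analysis parameter; the xxHash digest of the
#' configuration is stamped on every output row, so rows with equal hashes
#' were produced under identical parameters.
#'
#' @param channel_gfp,channel_bf channel labels of the tumor fluorophore and
#'   the reference channel.
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param threshold_value fixed threshold intensity (only for `"fixed"`).
#' @param tolerance region-growing tolerance (intensity units of the
#'   reference channel).
#' @param min_object_um2 minimum tumor-component area in um^2.
#' @param window_min speed-window length in minutes.
#' @param margin_um boundary margin for reversal detection in um.
#' @param seed top-level seed from which all randomness flows.
#' @return a `run_config` list with a `hash` field.
#' @export
run_config <- function(channel_gfp = "GFP", channel_bf = "BF",
                       threshold_method = "otsu", threshold_value = NULL,
                       tolerance = 2500, min_object_um2 = 20,
                       window_min = 40, margin_um = 15, seed = 1L) {
  cfg <- list(channel_gfp = channel_gfp, channel_bf = channel_bf,
              threshold_method = threshold_method,
              threshold_value = threshold_value, tolerance = tolerance,
              min_object_um2 = min_object_um2, window_min = window_min,
              margin_um = margin_um, seed = as.integer(seed))
  cfg$hash <- rlang::hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a JSON file
#'
#' @param path JSON file whose keys match [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' Quantify invasion in one confrontation image
#'
#' The full per-image pipeline: maximum-intensity projection of both
#' channels, seeded region growing on the reference channel to delineate
#' the merged cluster, contour extraction, neck-point decomposition into
#' brain and tumor ellipses, tumor-channel thresholding inside the cluster,
#' core/single-cell component classification, and the three invasion
#' metrics.
#'
#' @param stack an [image_stack()] with the configured channels.
#' @param brain_hint,tumor_hint `(x, y)` points inside the brain and tumor
#'   lobes (pixels).
#' @param config a [run_config()].
#' @param seed_rc optional `(row, col)` region-growing seed; defaults to the
#'   brain hint.
#' @param manual_ellipses optional `list(brain =, tumor =)` of [ellipse()]s
#'   for semi-automated use; skips the automated decomposition.
#' @param sample_id,arm,timepoint_h identifiers for the output row.
#' @return list: `metrics` ([compute_metrics()] row), `pair`, `seg`,
#'   `contour`, `cluster`.
#' @export
quantify_scene <- function(stack, brain_hint, tumor_hint, config = run_config(),
                           seed_rc = NULL, manual_ellipses = NULL,
                           sample_id = "sample", arm = "none",
                           timepoint_h = NA_real_) {
  gfp <- max_intensity_projection(stack, config$channel_gfp)
  bf <- max_intensity_projection(stack, config$channel_bf)
  px <- stack$pixel_size_um
  if (is.null(seed_rc)) seed_rc <- c(round(brain_hint[2]), round(brain_hint[1]))
  cluster <- region_grow(bf, seed_rc, config$tolerance)
  contour <- extract_contour(cluster)
  tm <- tumor_mask(gfp, cluster, method = config$threshold_method,
                   value = config$threshold_value)
  pair <- decompose_ellipses(contour, brain_hint, tumor_hint, gfp_mask = tm,
                             frame_shape = dim(bf), manual = manual_ellipses)
  seg <- classify_components(tm, c(round(tumor_hint[2]), round(tumor_hint[1])),
                             min_object_um2 = config$min_object_um2,
                             pixel_size_um = px)
  metrics <- compute_metrics(seg, pair, px, timepoint_h = timepoint_h,
                             sample_id = sample_id, arm = arm)
  metrics$config_hash <- config$hash
  list(metrics = metrics, pair = pair, seg = seg, contour = contour,
       cluster = cluster)
}

#' QC overlay of a quantified scene
#'
#' Writes a PNG with the reference channel, the cluster contour, and the
#' fitted brain/tumor ellipses.
#'
#' @param result a [quantify_scene()] result.
#' @param stack the quantified [image_stack()].
#' @param path output PNG path.
#' @param config the [run_config()] used.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(result, stack, path, config = run_config()) {
  bf <- max_intensity_projection(stack, config$channel_bf)
  grDevices::png(path, width = ncol(bf), height = nrow(bf))
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  m <- unclass(bf) / max(max(bf), 1)
  graphics::plot(NA, xlim = c(1, ncol(bf)), ylim = c(nrow(bf), 1),
                 asp = 1, axes = FALSE, xlab = "", ylab = "")
  graphics::rasterImage(m, 1, nrow(bf), ncol(bf), 1)
  graphics::lines(rbind(result$contour, result$contour[1, ]), col = "cyan")
  for (nm in c("brain", "tumor")) {
    pts <- ellipse_points(result$pair[[nm]])
    graphics::lines(rbind(pts, pts[1, ]),
                    col = ifelse(nm == "brain", "yellow", "red"), lwd = 2)
  }
  invisible(path)
}
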