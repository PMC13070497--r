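#' Seeded region growing
#'
#' Delineates the merged organoid cluster from a reference (brightfield-like)
#' channel by growing a region outward from a seed placed inside the cluster.
#' Growth is breadth-first over 4-connected neighbours; a pixel joins the
#' region when its intensity lies within `tolerance` of the running region
#' mean, which is updated after every accepted pixel. The frontier is a FIFO
#' queue with neighbours inserted in row-major order, so the result is
#' deterministic. The seed pixel is always accepted, so the region is never
#' empty.
#'
#' The criterion uses intensity differences only, so the segmentation is
#' invariant to adding a constant to the whole image.
#'
#' @param image a [planar_image()] (or plain matrix).
#' @param seed `c(row, col)` of a pixel inside the cluster (1-based).
#' @param tolerance maximum absolute deviation from the running region mean,
#'   in intensity units of `image`.
#' @return a `cluster_mask`: logical matrix with attribute `seed`.
#' @export
region_grow <- function(image, seed, tolerance) {
  stopifnot(is.matrix(image), length(seed) == 2L, tolerance >= 0)
  seed <- as.integer(round(seed))
  if (seed[1] < 1 || seed[1] > nrow(image) || seed[2] < 1 || seed[2] > ncol(image))
    stop("seed outside image bounds")
  member <- region_grow_cpp(unclass(image)[, , drop = FALSE], seed[1], seed[2],
                            tolerance)
  structure(member, seed = seed,
            pixel_size_um = attr(image, "pixel_size_um"),
            class = c("cluster_mask", "matrix", "array"))
}

#' Outer boundary contour of a cluster mask
#'
#' Fills interior holes, keeps the largest 4-connected region, and traces its
#' closed outer boundary through the boundary pixel centers. The returned
#' polygon is oriented counter-clockwise in `(x, y) = (col, row)` coordinates
#' (y down, as in image convention the cross-product test is adjusted
#' accordingly) and is simple by construction of the boundary walk.
#'
#' @param mask a `cluster_mask` (or logical matrix).
#' @return a `cluster_contour`: an `n x 2` matrix of `(x, y)` vertices with
#'   attributes `pixel_size_um` and `degenerate` (`TRUE` when the region has
#'   fewer than 3 boundary vertices, e.g. a single pixel).
#' @export
extract_contour <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  if (!any(m > 0)) stop("mask is empty")
  ## EBImage works on (x, y) = (row, col)-transposed images; transpose so
  ## that ocontour's (x, y) output matches our (col, row) convention.
  filled <- EBImage::fillHull(t(m))
  lab <- EBImage::bwlabel(filled)
  tab <- tabulate(lab[lab > 0])
  keep <- which.max(tab)
  oc <- EBImage::ocontour(matrix(as.integer(lab == keep), nrow(lab), ncol(lab)))[[1L]]
  verts <- oc + 1  # ocontour is 0-based
  colnames(verts) <- c("x", "y")
  degen <- nrow(verts) < 3L
  if (!degen && polygon_area(verts) < 0) verts <- verts[rev(seq_len(nrow(verts))), ]
  structure(verts,
            pixel_size_um = attr(mask, "pixel_size_um"),
            degenerate = degen,
            class = c("cluster_contour", "matrix", "array"))
}

#' Signed polygon area (shoelace), y-down image coordinates
#'
#' Positive for counter-clockwise traversal as seen on screen (x right,
#' y down).
#'
#' @param verts `n x 2` matrix of `(x, y)` vertices of a closed polygon
#'   (closing edge implied).
#' @return signed area in squared coordinate units.
#' @export
polygon_area <- function(verts) {
  x <- verts[, 1]; y <- verts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  ## y grows downward, so the usual shoelace sign is flipped
  -sum(x * yn - xn * y) / 2
}

#' Threshold the tumor-fluorescence channel inside the cluster
#'
#' Pixels outside the cluster mask are always `FALSE`; inside it, the
#' threshold is either computed by Otsu's method on the within-cluster
#' intensity histogram (the default, appropriate for a bright fluorophore on
#' a dark background) or fixed by the caller.
#'
#' @param gfp a [planar_image()] of the tumor channel, aligned with `cluster`.
#' @param cluster a `cluster_mask` from [region_grow()] (or logical matrix).
#' @param method `"otsu"` or `"fixed"`.
#' @param value threshold intensity when `method = "fixed"`; pixels with
#'   intensity `>=` the threshold are tumor-positive.
#' @return logical matrix of tumor-positive pixels.
#' @export
tumor_mask <- function(gfp, cluster, method = c("otsu", "fixed"), value = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(gfp), is.matrix(cluster),
            all(dim(gfp) == dim(cluster)))
  if (!any(cluster)) stop("cluster mask is empty")
  vals <- as.numeric(gfp)[as.logical(cluster)]
  thr <- if (method == "fixed") {
    if (is.null(value)) stop("method 'fixed' requires a threshold value")
    value
  } else {
    otsu_threshold(vals)
  }
  out <- unclass(gfp) >= thr & as.logical(cluster)
  matrix(out, nrow(gfp), ncol(gfp))
}

## Otsu threshold on a vector of intensities (256-bin histogram over the
## observed range), via EBImage's implementation on a rescaled 1-column image.
otsu_threshold <- function(vals) {
  lo <- min(vals); hi <- max(vals)
  if (hi <= lo) return(Inf)  # flat region: no signal to separate -> empty mask
  scaled <- (vals - lo) / (hi - lo)
  t01 <- EBImage::otsu(EBImage::Image(matrix(scaled, ncol = 1)),
                       range = c(0, 1), levels = 256)
  lo + t01 * (hi - lo)
}

#' Split tumor-positive pixels into core mass and detached single cells
#'
#' Labels the tumor mask with 8-connectivity (thin diagonal links, as formed
#' by tumor microtubes, keep fragments attached to the mass), discards
#' components smaller than `min_object_um2`, and declares the component
#' containing -- or, if the anchor pixel is tumor-negative, nearest to --
#' `tumor_anchor` the core. Every other surviving component is a detached
#' single cell (a detached clump counts once).
#'
#' @param gfp_mask logical matrix of tumor-positive pixels
#'   (from [tumor_mask()]).
#' @param tumor_anchor `c(row, col)` of a point inside (or near) the tumor
#'   mass.
#' @param min_object_um2 minimum component area in um^2 (default 20, about a
#'   nuclear cross-section); smaller specks are treated as noise.
#' @param pixel_size_um micrometres per pixel.
#' @return a `tumor_segmentation` list: `gfp_mask`, `component_labels`
#'   (integer matrix, 0 = background), `core_label` (NA when nothing
#'   survives), `single_cell_labels`, `min_object_um2`, `pixel_size_um`,
#'   and `empty` flag.
#' @export
classify_components <- function(gfp_mask, tumor_anchor, min_object_um2 = 20,
                                pixel_size_um = 1) {
  stopifnot(is.matrix(gfp_mask), length(tumor_anchor) == 2L)
  anchor <- as.integer(round(tumor_anchor))
  if (anchor[1] < 1 || anchor[1] > nrow(gfp_mask) ||
      anchor[2] < 1 || anchor[2] > ncol(gfp_mask))
    stop("tumor_anchor outside image bounds")
  gfp_mask <- matrix(as.logical(gfp_mask), nrow(gfp_mask), ncol(gfp_mask))
  lab <- label8_cpp(gfp_mask)
  px_area <- pixel_size_um^2
  n <- max(lab)
  if (n > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = n)
    drop <- which(sizes * px_area < min_object_um2)
    if (length(drop)) lab[lab %in% drop] <- 0L
  }
  surviving <- sort(unique(lab[lab > 0]))
  if (length(surviving) == 0L) {
    return(structure(list(gfp_mask = gfp_mask, component_labels = lab,
                          core_label = NA_integer_,
                          single_cell_labels = integer(0),
                          min_object_um2 = min_object_um2,
                          pixel_size_um = pixel_size_um, empty = TRUE),
                     class = "tumor_segmentation"))
  }
  core <- lab[anchor[1], anchor[2]]
  if (core == 0L) {
    ## nearest surviving component in pixel distance
    idx <- which(lab > 0, arr.ind = TRUE)
    d2 <- (idx[, 1] - anchor[1])^2 + (idx[, 2] - anchor[2])^2
    core <- lab[idx[which.min(d2), 1], idx[which.min(d2), 2]]
  }
  structure(list(gfp_mask = gfp_mask, component_labels = lab,
                 core_label = core,
                 single_cell_labels = setdiff(surviving, core),
                 min_object_um2 = min_object_um2,
                 pixel_size_um = pixel_size_um, empty = FALSE),
            class = "tumor_segmentation")
}

#' @export
print.tumor_segmentation <- function(x, ...) {
  cat(sprintf("<tumor_segmentation> core label %s, %d single cell(s), size filter %g um^2\n",
              ifelse(is.na(x$core_label), "none", x$core_label),
              length(x$single_cell_labels), x$min_object_um2))
  invisible(x)
}

#' Component table of a tumor segmentation
#'
#' @param seg a `tumor_segmentation`.
#' @return data.frame with one row per surviving component: `label`,
#'   `area_um2`, `centroid_x_um`, `centroid_y_um`, `class`
#'   (`"core"` or `"single"`).
#' @export
component_table <- function(seg) {
  stopifnot(inherits(seg, "tumor_segmentation"))
  labs <- c(if (!is.na(seg$core_label)) seg$core_label, seg$single_cell_labels)
  if (length(labs) == 0L)
    return(data.frame(label = integer(0), area_um2 = numeric(0),
                      centroid_x_um = numeric(0), centroid_y_um = numeric(0),
                      class = character(0)))
  px <- seg$pixel_size_um
  rows <- lapply(labs, function(l) {
    idx <- which(seg$component_labels == l, arr.ind = TRUE)
    data.frame(label = l, area_um2 = nrow(idx) * px^2,
               centroid_x_um = mean(idx[, 2]) * px,
               centroid_y_um = mean(idx[, 1]) * px,
               class = ifelse(l == seg$core_label, "core", "single"))
  })
  out <- do.call(rbind, rows)
  out[order(out$class, out$label), , drop = FALSE]
}
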