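#' Ellipse objects
#'
#' An ellipse in pixel coordinates: `center = c(x, y)`, semi-axes
#' `semi_major >= semi_minor > 0`, and `rotation` of the major axis in
#' radians, normalised to `[0, pi)`.
#'
#' @param center numeric `c(x, y)`.
#' @param semi_major,semi_minor semi-axis lengths in pixels.
#' @param rotation major-axis angle in radians.
#' @return an `ellipse` object.
#' @export
ellipse <- function(center, semi_major, semi_minor, rotation = 0) {
  stopifnot(length(center) == 2L, is.finite(semi_major), is.finite(semi_minor))
  if (semi_minor <= 0) stop("semi_minor must be positive")
  if (semi_major < semi_minor) {
    tmp <- semi_major; semi_major <- semi_minor; semi_minor <- tmp
    rotation <- rotation + pi / 2
  }
  rotation <- rotation %% pi
  structure(list(center = as.numeric(center), semi_major = semi_major,
                 semi_minor = semi_minor, rotation = rotation),
            class = "ellipse")
}

#' @export
print.ellipse <- function(x, ...) {
  cat(sprintf("<ellipse> center (%.2f, %.2f), a = %.2f, b = %.2f, rot = %.3f rad\n",
              x$center[1], x$center[2], x$semi_major, x$semi_minor, x$rotation))
  invisible(x)
}

## normalised radius: rho < 1 inside, = 1 on the boundary
ellipse_rho <- function(e, x, y) {
  ct <- cos(e$rotation); st <- sin(e$rotation)
  dx <- x - e$center[1]; dy <- y - e$center[2]
  u <- (ct * dx + st * dy) / e$semi_major
  v <- (-st * dx + ct * dy) / e$semi_minor
  sqrt(u^2 + v^2)
}

#' Points on an ellipse boundary
#'
#' @param e an [ellipse()].
#' @param angles parametric angles (radians); default 360 equally spaced.
#' @return `n x 2` matrix of `(x, y)`.
#' @export
ellipse_points <- function(e, angles = seq(0, 2 * pi, length.out = 361)[-361]) {
  ct <- cos(e$rotation); st <- sin(e$rotation)
  u <- e$semi_major * cos(angles); v <- e$semi_minor * sin(angles)
  cbind(x = e$center[1] + ct * u - st * v,
        y = e$center[2] + st * u + ct * v)
}

#' Rasterize an ellipse interior on a pixel grid
#'
#' Pixel `(r, c)` is set when its center `(x, y) = (c, r)` satisfies the
#' interior inequality; evaluation is exact per pixel center, so compartment
#' areas are always ratios of pixel counts.
#'
#' @param e an [ellipse()].
#' @param frame_shape `c(rows, cols)`.
#' @return logical matrix.
#' @export
ellipse_region <- function(e, frame_shape) {
  nr <- frame_shape[1]; nc <- frame_shape[2]
  stopifnot(nr >= 1, nc >= 1)
  x <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  y <- matrix(rep(seq_len(nr), times = nc), nr, nc)
  matrix(ellipse_rho(e, x, y) <= 1, nr, nc)
}

## ---- direct least-squares ellipse fitting ------------------------------

#' Direct least-squares ellipse fit (ellipse-specific conic constraint)
#'
#' Fits `A x^2 + B x y + C y^2 + D x + E y + F = 0` subject to
#' `4AC - B^2 = 1`, the numerically stable partitioned formulation of the
#' direct ellipse-specific fit, which always returns an ellipse. Data are
#' centered and scaled internally for conditioning. The reported residual is
#' the RMS Sampson (gradient-normalised algebraic) distance, a first-order
#' estimate of point-to-ellipse distance in pixels; it is ~0 for exact data.
#'
#' @param xy `n x 2` matrix of `(x, y)` points (`n >= 5`).
#' @return list with `ellipse` (an [ellipse()]) and `residual_px` (RMS).
#' @export
fit_ellipse <- function(xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 5L) stop("ellipse fit needs at least 5 points")
  mx <- mean(xy[, 1]); my <- mean(xy[, 2])
  s <- mean(sqrt((xy[, 1] - mx)^2 + (xy[, 2] - my)^2))
  if (s <= 0) stop("degenerate fit: all points coincide")
  x <- (xy[, 1] - mx) / s; y <- (xy[, 2] - my) / s

  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T3 <- tryCatch(-solve(S3, t(S2)), error = function(e)
    stop("degenerate fit: collinear points"))
  M <- S1 + S2 %*% T3
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  vecs <- Re(ev$vectors)
  cond <- 4 * vecs[1, ] * vecs[3, ] - vecs[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0L) stop("degenerate fit: no elliptical solution")
  v1 <- vecs[, ok[1L]]
  coef <- c(v1, as.numeric(T3 %*% v1))  # A B C D E F in scaled frame

  geom <- conic_to_ellipse(coef)
  ## undo centering/scaling
  e <- ellipse(center = c(geom$center[1] * s + mx, geom$center[2] * s + my),
               semi_major = geom$semi_major * s,
               semi_minor = geom$semi_minor * s,
               rotation = geom$rotation)

  ## Sampson distance in original pixels
  res <- sampson_distance(coef, x, y) * s
  list(ellipse = e, residual_px = sqrt(mean(res^2)))
}

conic_to_ellipse <- function(k) {
  A <- k[1]; B <- k[2]; C <- k[3]; D <- k[4]; E <- k[5]; F <- k[6]
  den <- B^2 - 4 * A * C
  if (den >= 0) stop("degenerate fit: conic is not an ellipse")
  x0 <- (2 * C * D - B * E) / den
  y0 <- (2 * A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 + F * B^2 - B * D * E - 4 * A * C * F)
  disc <- sqrt((A - C)^2 + B^2)
  a2 <- num / (den * (-disc - (A + C)))
  b2 <- num / (den * (disc - (A + C)))
  if (!is.finite(a2) || !is.finite(b2) || a2 <= 0 || b2 <= 0)
    stop("degenerate fit: nonpositive axis length")
  theta <- 0.5 * atan2(B, A - C)
  ## a2 corresponds to the axis along theta; ellipse() reorders as needed
  ellipse(c(x0, y0), sqrt(a2), sqrt(b2), theta)
}

sampson_distance <- function(k, x, y) {
  A <- k[1]; B <- k[2]; C <- k[3]; D <- k[4]; E <- k[5]; F <- k[6]
  q <- A * x^2 + B * x * y + C * y^2 + D * x + E * y + F
  gx <- 2 * A * x + B * y + D
  gy <- B * x + 2 * C * y + E
  abs(q) / pmax(sqrt(gx^2 + gy^2), .Machine$double.eps)
}

## ---- contour resampling, curvature, neck detection ---------------------

## closed-contour arc-length resampling to n points
resample_contour <- function(verts, n = 360L) {
  v <- rbind(verts, verts[1, , drop = FALSE])
  seg <- sqrt(diff(v[, 1])^2 + diff(v[, 2])^2)
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  if (L <= 0) stop("contour has zero length")
  s <- seq(0, L, length.out = n + 1L)[-(n + 1L)]
  xi <- approx(cum, v[, 1], xout = s)$y
  yi <- approx(cum, v[, 2], xout = s)$y
  cbind(x = xi, y = yi)
}

## circular moving average over a window of w vertices
smooth_closed <- function(p, w = 5L) {
  n <- nrow(p)
  h <- (w - 1L) %/% 2L
  idx <- function(i) ((i - 1L) %% n) + 1L
  out <- p
  for (d in seq_len(h)) out <- out + p[idx(seq_len(n) + d), ] + p[idx(seq_len(n) - d), ]
  out / (2L * h + 1L)
}

## signed discrete (Menger) curvature of a closed polyline over a +/- m
## vertex support; positive = convex for a counter-clockwise (on-screen,
## y down) contour
signed_curvature <- function(p, m = 2L) {
  n <- nrow(p)
  im <- function(i) ((i - 1L) %% n) + 1L
  a <- p[im(seq_len(n) - m), , drop = FALSE]
  b <- p
  d <- p[im(seq_len(n) + m), , drop = FALSE]
  v1 <- b - a; v2 <- d - b
  ## y-down frame: flip the sign so CCW-on-screen convex curvature is > 0
  cr <- -(v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])
  l1 <- sqrt(rowSums(v1^2)); l2 <- sqrt(rowSums(v2^2))
  l3 <- sqrt(rowSums((d - a)^2))
  2 * cr / pmax(l1 * l2 * l3, .Machine$double.eps)
}

#' Find the two concave neck points of a merged two-lobe contour
#'
#' The outline of two merging organoids is a "snowman": convex except at the
#' two concave notches where the lobes meet. The contour is resampled by arc
#' length to 360 points, smoothed over a 5-vertex window, and its signed
#' discrete curvature computed; concave candidates are local curvature minima
#' below zero. Among candidates, the pair farthest apart along the contour
#' (maximal circular arc separation) is returned, as indices into the
#' original contour.
#'
#' @param contour a `cluster_contour` (or `n x 2` vertex matrix, CCW).
#' @return list with `indices` (two indices into the original contour),
#'   `points` (2 x 2 matrix of their coordinates), and `resampled`
#'   (the 360-point contour with `neck_idx` attribute, used internally by
#'   [decompose_ellipses()]).
#' @export
find_neck_points <- function(contour) {
  verts <- as.matrix(contour)
  if (nrow(verts) < 8L)
    cond_stop("contour too short for neck detection", "no_neck_error")
  ## canonicalize to counter-clockwise so curvature signs are well defined
  if (polygon_area(verts) < 0) verts <- verts[rev(seq_len(nrow(verts))), ]
  rs <- resample_contour(verts, 360L)
  ## two passes of a 5-vertex moving average suppress the pixel staircase
  ## before curvature is estimated over a 5-vertex support
  sm <- smooth_closed(smooth_closed(rs, 5L), 5L)
  k <- signed_curvature(sm, 2L)
  n <- length(k)
  idx <- function(i) ((i - 1L) %% n) + 1L
  is_min <- k < 0 &
    k <= k[idx(seq_len(n) - 1L)] & k <= k[idx(seq_len(n) + 1L)] &
    k <= k[idx(seq_len(n) - 2L)] & k <= k[idx(seq_len(n) + 2L)]
  ## demand concavity clearly sharper than the convex lobes are curved
  kscale <- stats::quantile(k[k > 0], 0.9, names = FALSE)
  if (!is.finite(kscale) || kscale <= 0) kscale <- 2 * pi / n
  cand <- which(is_min & k < -1.5 * kscale)
  if (length(cand) < 2L)
    cond_stop("no concave neck found (convex or engulfed cluster)",
              "no_neck_error")
  ## pair with maximal circular separation
  best <- c(NA_integer_, NA_integer_); best_sep <- -1
  for (i in seq_along(cand)) {
    for (j in seq_along(cand)) {
      if (j <= i) next
      d <- abs(cand[i] - cand[j]); sep <- min(d, n - d)
      if (sep > best_sep) { best_sep <- sep; best <- c(cand[i], cand[j]) }
    }
  }
  pts <- rs[best, , drop = FALSE]
  orig_idx <- vapply(seq_len(2), function(m) {
    d2 <- (verts[, 1] - pts[m, 1])^2 + (verts[, 2] - pts[m, 2])^2
    which.min(d2)
  }, integer(1))
  attr(rs, "neck_idx") <- best
  list(indices = orig_idx, points = pts, resampled = rs)
}

#' Decompose a merged cluster contour into brain and tumor ellipses
#'
#' Splits the contour at its two neck points into two arcs and fits one
#' ellipse per arc by the direct least-squares ellipse fit, so each fitted
#' compartment follows the curvature of its lobe's periphery. Tumor identity
#' goes to the ellipse whose interior holds the greater fraction of
#' tumor-positive pixels when `gfp_mask` is supplied, otherwise to the
#' ellipse that contains (or is closest in normalised radius to)
#' `tumor_hint`. When `manual` ellipses are supplied (semi-automated use),
#' fitting is skipped and they are used verbatim.
#'
#' @param contour a `cluster_contour`.
#' @param brain_hint,tumor_hint `(x, y)` points inside the brain and tumor
#'   lobes.
#' @param gfp_mask optional logical matrix of tumor-positive pixels used for
#'   identity assignment.
#' @param frame_shape `c(rows, cols)` of the image frame, used to rasterize
#'   the overlap; defaults to the contour's bounding box plus a margin.
#' @param manual optional list `list(brain = ellipse, tumor = ellipse)`
#'   bypassing the automated decomposition.
#' @return an `ellipse_pair`: list with `brain`, `tumor` (ellipses),
#'   `overlap_area_px2`, `fit_residual_px` (named per compartment) and
#'   `manual` flag.
#' @export
decompose_ellipses <- function(contour, brain_hint, tumor_hint,
                               gfp_mask = NULL, frame_shape = NULL,
                               manual = NULL) {
  if (is.null(frame_shape)) {
    if (!is.null(gfp_mask)) frame_shape <- dim(gfp_mask)
    else frame_shape <- c(ceiling(max(contour[, 2])) + 5L,
                          ceiling(max(contour[, 1])) + 5L)
  }
  if (!is.null(manual)) {
    stopifnot(inherits(manual$brain, "ellipse"), inherits(manual$tumor, "ellipse"))
    pair <- list(brain = manual$brain, tumor = manual$tumor,
                 overlap_area_px2 = ellipse_overlap_px2(manual$brain, manual$tumor,
                                                       frame_shape),
                 fit_residual_px = c(brain = NA_real_, tumor = NA_real_),
                 manual = TRUE)
    class(pair) <- "ellipse_pair"
    return(pair)
  }
  nk <- find_neck_points(contour)
  rs <- nk$resampled
  ni <- sort(attr(rs, "neck_idx"))
  n <- nrow(rs)
  arc1 <- rs[ni[1]:ni[2], , drop = FALSE]
  arc2 <- rs[c(ni[2]:n, 1:ni[1]), , drop = FALSE]
  f1 <- tryCatch(fit_ellipse(arc1), error = function(e)
    stop(paste0("arc 1 (vertices ", ni[1], "..", ni[2], "): ",
                conditionMessage(e))))
  f2 <- tryCatch(fit_ellipse(arc2), error = function(e)
    stop(paste0("arc 2 (vertices ", ni[2], "..", ni[1], "): ",
                conditionMessage(e))))

  tumor_first <- if (!is.null(gfp_mask)) {
    g1 <- gfp_fraction(f1$ellipse, gfp_mask)
    g2 <- gfp_fraction(f2$ellipse, gfp_mask)
    g1 >= g2
  } else {
    ellipse_rho(f1$ellipse, tumor_hint[1], tumor_hint[2]) <=
      ellipse_rho(f2$ellipse, tumor_hint[1], tumor_hint[2])
  }
  tum <- if (tumor_first) f1 else f2
  brn <- if (tumor_first) f2 else f1
  pair <- list(brain = brn$ellipse, tumor = tum$ellipse,
               overlap_area_px2 = ellipse_overlap_px2(brn$ellipse, tum$ellipse,
                                                      frame_shape),
               fit_residual_px = c(brain = brn$residual_px,
                                   tumor = tum$residual_px),
               manual = FALSE)
  class(pair) <- "ellipse_pair"
  pair
}

gfp_fraction <- function(e, gfp_mask) {
  reg <- ellipse_region(e, dim(gfp_mask))
  n <- sum(reg)
  if (n == 0) return(0)
  sum(gfp_mask & reg) / n
}

ellipse_overlap_px2 <- function(e1, e2, frame_shape) {
  sum(ellipse_region(e1, frame_shape) & ellipse_region(e2, frame_shape))
}

#' @export
print.ellipse_pair <- function(x, ...) {
  cat("<ellipse_pair>", if (isTRUE(x$manual)) "(manual)" else "", "\n brain: ")
  print(x$brain)
  cat(" tumor: ")
  print(x$tumor)
  cat(sprintf(" overlap %d px^2, residuals brain %.3g / tumor %.3g px\n",
              x$overlap_area_px2, x$fit_residual_px[["brain"]],
              x$fit_residual_px[["tumor"]]))
  invisible(x)
}

#' Serialize an ellipse pair to JSON
#'
#' @param pair an `ellipse_pair`.
#' @param path output path; when `NULL`, the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
ellipse_pair_json <- function(pair, path = NULL) {
  enc <- function(e) list(center_x = e$center[1], center_y = e$center[2],
                          semi_major = e$semi_major, semi_minor = e$semi_minor,
                          rotation_rad = e$rotation)
  obj <- list(brain = enc(pair$brain), tumor = enc(pair$tumor),
              overlap_area_px2 = pair$overlap_area_px2,
              fit_residual_px = as.list(pair$fit_residual_px),
              manual = isTRUE(pair$manual))
  if (is.null(path)) return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
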