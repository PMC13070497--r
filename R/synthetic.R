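## Synthetic confrontation scenes and trajectory sets with pixel-exact
## ground truth. The generator exists to give the estimator a known answer:
## it reproduces the structure the quantification assumes (a merged two-lobe
## cluster, a contiguous tumor front replacing brain area, detached single
## cells, persistent random walks confined to the organoid) without
## biophysical realism.

## run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic confrontation scene
#'
#' Defaults emulate a 48-h confrontation: a brain organoid lobe of roughly
#' 190 x 160 um and a smaller tumor lobe merged into a "snowman" cluster on
#' a 256 x 256 px frame at 1.5 um/px, a tumor front that has replaced 30\%
#' of the brain-ellipse area, and detached single cells totalling 5\% of it.
#'
#' @param frame `c(rows, cols)` in pixels.
#' @param brain,tumor [ellipse()] objects (pixel coordinates); they must
#'   overlap.
#' @param competition_true target replaced fraction of the brain-ellipse
#'   area in `[0, 1]`. The geometric lobe overlap is itself tumor-positive
#'   brain area, so the realized fraction cannot fall below it.
#' @param single_cell_true target detached-cell area fraction of the
#'   brain-ellipse area.
#' @param n_cells_true number of detached cells; must be 0 when
#'   `single_cell_true` is 0.
#' @param n_debris_true number of sub-filter specks (debris below a 20 um^2
#'   size filter) to scatter.
#' @param cell_radius_um admissible range of cell radii.
#' @param pixel_size_um micrometres per pixel.
#' @param gfp_signal mean tumor-fluorophore signal (16-bit scale).
#' @param background_mean,background_sd Gaussian read-noise floor.
#' @param bf_interior,bf_rim,bf_background,rim_width_px brightfield-like
#'   reference channel levels: cluster interior, darker boundary rim, and
#'   background.
#' @param jitter_amp fractional radial contour jitter (smooth low-order
#'   harmonics), emulating tissue boundary roughness.
#' @param seed integer seed; all outputs are pure functions of (spec, seed).
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(frame = c(256L, 256L),
                       brain = ellipse(c(92, 126), 62, 54, 0.15),
                       tumor = ellipse(c(192, 132), 48, 42, -0.2),
                       competition_true = 0.30,
                       single_cell_true = 0.05,
                       n_cells_true = 12L,
                       n_debris_true = 0L,
                       cell_radius_um = c(4, 14),
                       pixel_size_um = 1.5,
                       gfp_signal = 3000,
                       background_mean = 100, background_sd = 8,
                       bf_interior = 9000, bf_rim = 7000,
                       bf_background = 500, rim_width_px = 2,
                       jitter_amp = 0.01,
                       seed = 1L) {
  spec <- list(frame = as.integer(frame), brain = brain, tumor = tumor,
               competition_true = competition_true,
               single_cell_true = single_cell_true,
               n_cells_true = as.integer(n_cells_true),
               n_debris_true = as.integer(n_debris_true),
               cell_radius_um = cell_radius_um,
               pixel_size_um = pixel_size_um, gfp_signal = gfp_signal,
               background_mean = background_mean, background_sd = background_sd,
               bf_interior = bf_interior, bf_rim = bf_rim,
               bf_background = bf_background, rim_width_px = rim_width_px,
               jitter_amp = jitter_amp, seed = as.integer(seed))
  class(spec) <- "scene_spec"
  validate_scene_spec(spec)
  spec
}

validate_scene_spec <- function(spec) {
  if (spec$competition_true < 0 || spec$competition_true > 1)
    stop("invalid scene spec: competition_true must be in [0, 1]")
  if (spec$single_cell_true < 0)
    stop("invalid scene spec: single_cell_true must be nonnegative")
  if (spec$competition_true + spec$single_cell_true > 1)
    stop("invalid scene spec: competition_true + single_cell_true exceeds 1")
  if (spec$single_cell_true > 0 && spec$n_cells_true < 1)
    stop("invalid scene spec: n_cells_true must be >= 1 when single_cell_true > 0")
  if (spec$pixel_size_um <= 0)
    stop("invalid scene spec: pixel_size_um must be positive")
  ## the lobes must merge
  ov <- ellipse_overlap_px2(spec$brain, spec$tumor, spec$frame)
  if (ov == 0) stop("invalid scene spec: brain and tumor ellipses do not overlap")
  invisible(spec)
}

## jittered lobe mask: radial perturbation by smooth low-order harmonics
jittered_region <- function(e, frame, amp, rng_draw) {
  nr <- frame[1]; nc <- frame[2]
  x <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  y <- matrix(rep(seq_len(nr), times = nc), nr, nc)
  ct <- cos(e$rotation); st <- sin(e$rotation)
  dx <- x - e$center[1]; dy <- y - e$center[2]
  u <- (ct * dx + st * dy) / e$semi_major
  v <- (-st * dx + ct * dy) / e$semi_minor
  rho <- sqrt(u^2 + v^2)
  if (amp <= 0) return(matrix(rho <= 1, nr, nc))
  phi <- atan2(v, u)
  eta <- 0
  for (k in 2:5)
    eta <- eta + rng_draw$amp[k - 1] * cos(k * phi + rng_draw$phase[k - 1])
  matrix(rho <= 1 + amp * eta, nr, nc)
}

disk_pixels <- function(center_rc, radius_px, frame) {
  r0 <- center_rc[1]; c0 <- center_rc[2]
  rr <- max(1, floor(r0 - radius_px)):min(frame[1], ceiling(r0 + radius_px))
  cc <- max(1, floor(c0 - radius_px)):min(frame[2], ceiling(c0 + radius_px))
  g <- expand.grid(r = rr, c = cc)
  keep <- (g$r - r0)^2 + (g$c - c0)^2 <= radius_px^2
  as.matrix(g[keep, , drop = FALSE])
}

#' Render a synthetic confrontation scene
#'
#' Renders a two-channel (GFP tumor fluorophore + brightfield-like
#' reference) single-plane scene: both lobes with a darker boundary rim and
#' jittered contour in the reference channel; in the GFP channel the tumor
#' lobe plus an advancing front that floods the brain ellipse outward from
#' the lobe junction (geodesic distance order, so the replaced region stays
#' connected to the core) until the realized replaced fraction matches
#' `competition_true` to within one pixel of area, plus detached cells
#' (crisp disks) placed uniformly at random in the unreplaced brain region
#' with at least a 2-px clearance so components stay distinct. Per-cell
#' radii are chosen adaptively so the summed detached area hits
#' `single_cell_true`. Noise (signal-dependent Poisson plus a Gaussian
#' floor) is applied last; all ground truth is recomputed from the pre-noise
#' masks, never echoed from the spec.
#'
#' @param spec a [scene_spec()].
#' @return list with `stack` (an [image_stack()] with channels
#'   `"GFP", "BF"`), `truth` (realized fractions, counts, masks, hints) and
#'   `spec`.
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  validate_scene_spec(spec)
  with_seed(spec$seed, {
    frame <- spec$frame
    jit_b <- list(amp = runif(4, -1, 1), phase = runif(4, 0, 2 * pi))
    jit_t <- list(amp = runif(4, -1, 1), phase = runif(4, 0, 2 * pi))
    brain_lobe <- jittered_region(spec$brain, frame, spec$jitter_amp, jit_b)
    tumor_lobe <- jittered_region(spec$tumor, frame, spec$jitter_amp, jit_t)
    cluster <- brain_lobe | tumor_lobe

    R <- ellipse_region(spec$brain, frame)   # analytic brain compartment
    nR <- sum(R)

    ## advancing front: geodesic flood within R from the lobe junction
    seed_mask <- R & tumor_lobe
    k_target <- round(spec$competition_true * nR)
    if (k_target >= sum(seed_mask)) {
      ## the whole junction lens is replaced, plus a front flooding outward
      gd <- geodesic_dist_cpp(R, seed_mask)
      reach <- which(gd >= 0)
      if (length(reach) < k_target)
        stop("infeasible scene spec: requested competition fraction exceeds reachable brain area")
      ord <- reach[order(gd[reach], reach)]
      front <- matrix(FALSE, frame[1], frame[2])
      front[ord[seq_len(k_target)]] <- TRUE
      core <- tumor_lobe | front
    } else {
      ## less replacement than the geometric lens: the tumor mass sits
      ## outside the brain compartment and only a contiguous tongue of
      ## k_target junction pixels (flooded inward from the outer tumor
      ## mass) is replaced
      outer <- tumor_lobe & !R
      interface <- seed_mask & dilate_mask(outer, 1.5)
      core <- outer
      if (k_target > 0) {
        gd <- geodesic_dist_cpp(seed_mask, interface)
        reach <- which(gd >= 0)
        if (length(reach) < k_target)
          stop("infeasible scene spec: junction too small for requested competition fraction")
        ord <- reach[order(gd[reach], reach)]
        front <- matrix(FALSE, frame[1], frame[2])
        front[ord[seq_len(k_target)]] <- TRUE
        core <- outer | front
      }
    }

    ## detached cells in the unreplaced brain region
    px <- spec$pixel_size_um
    T_px <- round(spec$single_cell_true * nR)
    rmin <- spec$cell_radius_um[1] / px; rmax <- spec$cell_radius_um[2] / px
    gap <- 3  # px clearance between components (8-connectivity safe)
    cells <- matrix(FALSE, frame[1], frame[2])
    cell_info <- list()
    if (T_px > 0) {
      forbidden <- dilate_mask(core, gap)
      allowed <- R & !forbidden
      placed_px <- 0
      for (i in seq_len(spec$n_cells_true)) {
        left <- spec$n_cells_true - i + 1L
        r_t <- sqrt(max(T_px - placed_px, 1) / left / pi)
        r_i <- if (left == 1L) best_disk_radius(T_px - placed_px, rmin, rmax)
               else min(max(r_t * runif(1, 0.85, 1.15), rmin), rmax)
        ## crowded scenes: shrink the disk before giving up
        pos <- NULL
        while (is.null(pos) && r_i >= rmin * 0.8) {
          pos <- place_disk(allowed, R, r_i, frame)
          if (is.null(pos)) r_i <- r_i * 0.85
        }
        if (is.null(pos))
          stop("infeasible scene spec: could not place detached cells (area fraction too high)")
        dp <- disk_pixels(pos, r_i, frame)
        cells[dp] <- TRUE
        placed_px <- placed_px + nrow(dp)
        cell_info[[i]] <- c(row = pos[1], col = pos[2], radius_px = r_i)
        forb_new <- dilate_point_disk(pos, r_i + gap, frame)
        allowed[forb_new] <- FALSE
      }
    }
    debris <- matrix(FALSE, frame[1], frame[2])
    if (spec$n_debris_true > 0) {
      r_d <- 1.1  # ~5 px disk, well below the default 20 um^2 size filter
      forbidden <- dilate_mask(core | cells, gap)
      allowed <- R & !forbidden
      for (i in seq_len(spec$n_debris_true)) {
        pos <- place_disk(allowed, R, r_d, frame)
        if (is.null(pos)) stop("infeasible scene spec: could not place debris")
        debris[disk_pixels(pos, r_d, frame)] <- TRUE
        allowed[dilate_point_disk(pos, r_d + gap, frame)] <- FALSE
      }
    }

    ## pre-noise channels
    gfp_base <- matrix(0, frame[1], frame[2])
    gfp_base[core | cells | debris] <- spec$gfp_signal
    dm <- t(EBImage::distmap(t(+cluster)))
    rim <- cluster & dm <= spec$rim_width_px
    bf_base <- matrix(spec$bf_background, frame[1], frame[2])
    bf_base[cluster] <- spec$bf_interior
    bf_base[rim] <- spec$bf_rim

    noisy <- function(base) {
      n <- length(base)
      img <- rpois(n, lambda = as.numeric(base)) +
        rnorm(n, spec$background_mean, spec$background_sd)
      matrix(pmin(pmax(round(img), 0), 65535), nrow(base), ncol(base))
    }
    gfp <- noisy(gfp_base); bf <- noisy(bf_base)

    data <- array(0, c(2L, 1L, frame[1], frame[2]))
    data[1, 1, , ] <- gfp; data[2, 1, , ] <- bf
    stack <- image_stack(data, c("GFP", "BF"), spec$pixel_size_um)

    ## ground truth recomputed from the rendered (pre-noise) masks
    single_lab <- label8_cpp(cells)
    truth <- list(
      competition_realized = sum(core & R) / nR,
      single_cell_realized = sum(cells & R) / nR,
      n_cells_realized = max(single_lab),
      brain_area_px = nR,
      overlap_px = sum(seed_mask),
      cluster_mask = cluster, core_mask = core, single_mask = cells,
      debris_mask = debris, gfp_mask = core | cells | debris,
      cell_info = cell_info,
      brain_hint = spec$brain$center, tumor_hint = spec$tumor$center,
      seed_rc = c(round(spec$brain$center[2]), round(spec$brain$center[1])))
    list(stack = stack, truth = truth, spec = spec)
  })
}

## binary dilation by a disc of radius r (pixel-center metric)
dilate_mask <- function(mask, r) {
  k <- EBImage::makeBrush(2 * ceiling(r) + 1, shape = "disc")
  out <- EBImage::dilate(t(+mask), k)
  t(out) > 0
}

dilate_point_disk <- function(pos, r, frame) disk_pixels(pos, r, frame)

## radius whose pixel-center disk count best matches `target` pixels
best_disk_radius <- function(target, rmin, rmax) {
  grid <- seq(max(rmin, 1), max(rmax, rmin + 0.1), by = 0.05)
  counts <- vapply(grid, function(r) {
    d <- ceiling(r)
    g <- expand.grid(-d:d, -d:d)
    sum(g[, 1]^2 + g[, 2]^2 <= r^2)
  }, numeric(1))
  grid[which.min(abs(counts - target))]
}

## uniform-random placement of a disk fully inside R with clearance
place_disk <- function(allowed, R, r, frame, max_tries = 4000L) {
  cand <- which(allowed)
  if (!length(cand)) return(NULL)
  for (i in seq_len(max_tries)) {
    idx <- cand[sample.int(length(cand), 1L)]
    pos <- c((idx - 1L) %% frame[1] + 1L, (idx - 1L) %/% frame[1] + 1L)
    dp <- disk_pixels(pos, r, frame)
    if (all(R[dp]) && all(allowed[dp])) return(pos)
  }
  NULL
}
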