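#' Specification of a persistent-random-walk trajectory set
#'
#' Defaults emulate the tracked invasion behaviour of a fast glioblastoma
#' model inside a brain organoid: mean speed 23.8 um/h, directionally
#' persistent motion sampled every 4 min over a 120-min recording (three
#' 40-min speed windows per cell), specular reflection at the organoid
#' boundary, and optional mitotic events after which the parent pauses for
#' about 160 min and the two daughters set off in opposite directions.
#'
#' @param speed_true mean cell speed in um/h; per-step length is
#'   `speed_true * step_min / 60`, optionally gamma-jittered.
#' @param persistence directional persistence in `[0, 1)`: the new heading
#'   is the normalised blend `persistence * previous + (1 - persistence) *
#'   random unit vector` (0 = uncorrelated steps).
#' @param step_min sampling interval in minutes.
#' @param duration_min track duration in minutes.
#' @param brain reflecting-boundary [ellipse()] in um coordinates.
#' @param division_rate expected division events per track (Poisson over the
#'   track duration); daughters do not divide again.
#' @param pause_min stationary mitotic pause between the parent's last
#'   sample and the daughters' first moving sample (default 160 min).
#' @param speed_cv coefficient of variation of gamma-jittered step lengths
#'   (0 = constant step length).
#' @param seed integer seed.
#' @return a `walk_spec` list.
#' @export
walk_spec <- function(speed_true = 23.8, persistence = 0.6, step_min = 4,
                      duration_min = 120,
                      brain = ellipse(c(0, 0), 110, 90, 0),
                      division_rate = 0, pause_min = 160,
                      speed_cv = 0.15, seed = 1L) {
  if (speed_true < 0) stop("invalid walk spec: speed_true must be nonnegative")
  if (step_min <= 0) stop("invalid walk spec: step_min must be positive")
  if (persistence < 0 || persistence >= 1)
    stop("invalid walk spec: persistence must be in [0, 1)")
  structure(list(speed_true = speed_true, persistence = persistence,
                 step_min = step_min, duration_min = duration_min,
                 brain = brain, division_rate = division_rate,
                 pause_min = pause_min, speed_cv = speed_cv,
                 seed = as.integer(seed)),
            class = "walk_spec")
}

## reflect one step p -> p + d off the ellipse boundary (specular, in the
## original frame, so the step length is preserved exactly); returns the end
## point, the last movement direction, and any boundary hits
reflect_step <- function(e, p, d) {
  ct <- cos(e$rotation); st <- sin(e$rotation)
  Mfun <- function(q) c((ct * q[1] + st * q[2]) / e$semi_major,
                        (-st * q[1] + ct * q[2]) / e$semi_minor)
  hits <- list()
  for (iter in 1:12) {
    len <- sqrt(sum(d^2))
    if (len < 1e-12) break
    u0 <- Mfun(p - e$center)
    ud <- Mfun(d)  # linear map, no offset
    a <- sum(ud^2); b <- 2 * sum(u0 * ud); cc <- sum(u0^2) - 1
    disc <- b^2 - 4 * a * cc
    if (a < 1e-18 || disc < 0) { p <- p + d; d <- d * 0; break }
    tt <- (-b + sqrt(disc)) / (2 * a)  # exit parameter along the step
    if (tt >= 1 || tt < 0) { p <- p + d; break }
    hit <- p + tt * d
    ## outward normal: gradient of rho^2 at the hit point
    uh <- Mfun(hit - e$center)
    gx <- 2 * (uh[1] * ct / e$semi_major - uh[2] * st / e$semi_minor)
    gy <- 2 * (uh[1] * st / e$semi_major + uh[2] * ct / e$semi_minor)
    nrm <- c(gx, gy) / sqrt(gx^2 + gy^2)
    rem <- (1 - tt) * d
    d <- rem - 2 * sum(rem * nrm) * nrm
    p <- hit
    hits[[length(hits) + 1L]] <- hit
  }
  list(end = p, dir = d, hits = hits)
}

## One biological turn-around event can produce several boundary contacts in
## quick succession (grazing motion along the boundary). Contacts on the
## same track belong to one margin-zone visit -- and are logged as a single
## reversal event -- unless the cell moved farther than `margin_um` from the
## boundary between them; the event is placed at the visit's deepest
## excursion (the sample with maximal normalised radius).
dedupe_reflections <- function(df, tracks, e, margin_um = 15) {
  if (nrow(df) == 0) return(df)
  out <- lapply(split(df, df$track_id), function(d) {
    d <- d[order(d$sample_index), , drop = FALSE]
    s <- tracks[[d$track_id[1]]]$samples
    bd <- boundary_distance_um(e, s$x_um, s$y_um)
    breaks <- logical(nrow(d))
    if (nrow(d) > 1) {
      for (i in 2:nrow(d)) {
        i0 <- min(d$sample_index[i - 1], nrow(s))
        i1 <- min(d$sample_index[i], nrow(s))
        between <- if (i1 > i0 + 1) (i0 + 1):(i1 - 1) else integer(0)
        breaks[i] <- length(between) > 0 && any(bd[between] > margin_um)
      }
    }
    episode <- cumsum(c(1L, breaks[-1]))
    picked <- lapply(split(seq_len(nrow(d)), episode), function(ii) {
      ## turning point of the episode: the deepest excursion over the whole
      ## sample span covered by its contacts
      span <- min(d$sample_index[ii]):min(max(d$sample_index[ii]), nrow(s))
      rho <- ellipse_rho(e, s$x_um[span], s$y_um[span])
      row <- d[ii[1], , drop = FALSE]
      kbest <- span[which.max(rho)]
      row$sample_index <- kbest
      row$t_min <- s$t_min[kbest]
      row$x_um <- s$x_um[kbest]; row$y_um <- s$y_um[kbest]
      row
    })
    do.call(rbind, picked)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate persistent random walks inside a reflecting organoid boundary
#'
#' Tracks start uniformly inside the brain ellipse with random initial
#' headings. Each step moves `speed_true * step_min / 60` um (gamma-jittered
#' when `speed_cv > 0`) along a direction blended with the previous heading
#' by `persistence`; steps crossing the boundary are reflected specularly
#' (step length preserved) and logged. Division events arrive as a Poisson
#' process at `division_rate` per track: the parent track ends at the
#' division point and, after a stationary pause of `pause_min`, two
#' non-dividing daughter tracks start there with antiparallel initial
#' headings.
#'
#' Ground truth is recomputed from the generated samples: realized per-step
#' speeds, the reflection event log, and the division event log.
#'
#' @param spec a [walk_spec()].
#' @param n_tracks number of founder tracks.
#' @return list with `tracks` (a list of [cell_track()], daughters included
#'   with `parent_id` set) and `truth` (`step_speeds_um_per_h`,
#'   `mean_step_speed_um_per_h`, `reflections`, `divisions`).
#' @export
simulate_walks <- function(spec, n_tracks) {
  stopifnot(inherits(spec, "walk_spec"), n_tracks >= 1)
  with_seed(spec$seed, {
    e <- spec$brain
    step_len0 <- spec$speed_true * spec$step_min / 60
    n_steps <- floor(spec$duration_min / spec$step_min)
    p_div <- if (spec$division_rate > 0)
      min(spec$division_rate / n_steps, 1) else 0

    draw_len <- function() {
      if (spec$speed_cv <= 0 || step_len0 == 0) return(step_len0)
      shape <- 1 / spec$speed_cv^2
      rgamma(1, shape = shape, scale = step_len0 / shape)
    }
    rand_unit <- function() { a <- runif(1, 0, 2 * pi); c(cos(a), sin(a)) }
    start_point <- function() {
      repeat {
        q <- runif(2, -1, 1)
        if (sum(q^2) <= 1) {
          ct <- cos(e$rotation); st <- sin(e$rotation)
          u <- q[1] * e$semi_major; v <- q[2] * e$semi_minor
          return(c(e$center[1] + ct * u - st * v,
                   e$center[2] + st * u + ct * v))
        }
      }
    }

    tracks <- list()
    reflections <- list()
    divisions <- list()
    step_lens <- numeric(0)

    run_walk <- function(id, parent, t_start, p0, dir0, n, can_divide,
                         exact_start = FALSE) {
      t <- t_start + (0:n) * spec$step_min
      xs <- numeric(n + 1); ys <- numeric(n + 1)
      xs[1] <- p0[1]; ys[1] <- p0[2]
      p <- p0; dir_prev <- dir0
      for (k in seq_len(n)) {
        ## no division on the very first step (the parent must exist as a
        ## trajectory first), and none in immediate boundary contact -- the
        ## daughters must be able to take their opposite first steps without
        ## reflecting off the organoid margin
        if (can_divide && k > 1L && p_div > 0 && runif(1) < p_div &&
            boundary_distance_um(e, p[1], p[2]) > 3 * step_len0) {
          ## parent ends here; daughters start after the mitotic pause
          t_div <- t[k]
          phi <- runif(1, 0, 2 * pi)
          divisions[[length(divisions) + 1L]] <<- data.frame(
            parent_id = id, t_min = t_div, x_um = p[1], y_um = p[2],
            stringsAsFactors = FALSE)
          for (dgt in 1:2) {
            h <- if (dgt == 1) c(cos(phi), sin(phi)) else -c(cos(phi), sin(phi))
            run_walk(paste0(id, ".", dgt), id, t_div + spec$pause_min, p, h,
                     n, can_divide = FALSE, exact_start = TRUE)
          }
          t <- t[seq_len(k)]; xs <- xs[seq_len(k)]; ys <- ys[seq_len(k)]
          break
        }
        len <- draw_len()
        if (k == 1L && exact_start) {
          ## daughters leave the division point along their mitotic heading
          dir <- dir_prev
        } else {
          u <- rand_unit()
          blend <- spec$persistence * dir_prev + (1 - spec$persistence) * u
          nb <- sqrt(sum(blend^2))
          dir <- if (nb < 1e-12) u else blend / nb
        }
        rs <- reflect_step(e, p, dir * len)
        for (h in rs$hits)
          reflections[[length(reflections) + 1L]] <<- data.frame(
            track_id = id, sample_index = k + 1L, t_min = t[k + 1L],
            x_um = h[1], y_um = h[2], stringsAsFactors = FALSE)
        step_lens <<- c(step_lens, len)
        new_p <- rs$end
        dl <- rs$dir
        ndl <- sqrt(sum(dl^2))
        dir_prev <- if (ndl > 1e-12) dl / ndl else dir
        p <- new_p
        xs[k + 1L] <- p[1]; ys[k + 1L] <- p[2]
      }
      if (length(t) >= 2)
        tracks[[length(tracks) + 1L]] <<- cell_track(
          id, data.frame(t_min = t, x_um = xs[seq_along(t)],
                         y_um = ys[seq_along(t)]),
          parent_id = if (is.na(parent)) NA_character_ else parent)
      invisible(NULL)
    }

    for (i in seq_len(n_tracks))
      run_walk(sprintf("t%04d", i), NA_character_, 0, start_point(),
               rand_unit(), n_steps, can_divide = spec$division_rate > 0)

    names(tracks) <- vapply(tracks, function(tr) tr$track_id, character(1))
    truth <- list(
      step_speeds_um_per_h = step_lens * 60 / spec$step_min,
      mean_step_speed_um_per_h = if (length(step_lens))
        mean(step_lens) * 60 / spec$step_min else NA_real_,
      reflections = dedupe_reflections(
        if (length(reflections)) do.call(rbind, reflections)
        else data.frame(track_id = character(0), sample_index = integer(0),
                        t_min = numeric(0), x_um = numeric(0),
                        y_um = numeric(0)),
        tracks, e),
      divisions = if (length(divisions)) do.call(rbind, divisions)
        else data.frame(parent_id = character(0), t_min = numeric(0),
                        x_um = numeric(0), y_um = numeric(0)))
    list(tracks = tracks, truth = truth, spec = spec)
  })
}
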