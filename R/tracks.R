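#' Cell trajectory objects
#'
#' A `cell_track` holds one cell's trajectory: `track_id`, a samples
#' `data.frame` with strictly increasing `t_min` and coordinates
#' `x_um`, `y_um`, and an optional `parent_id` linking a daughter to the
#' track that divided. Time-lapse analysis is 2D; a `z_um` column, if
#' present on load, is dropped with a warning (speeds derive from projected
#' movies).
#'
#' @param track_id identifier.
#' @param samples data.frame with `t_min`, `x_um`, `y_um`.
#' @param parent_id optional parent track id.
#' @return a `cell_track`.
#' @export
cell_track <- function(track_id, samples, parent_id = NA_character_) {
  stopifnot(is.data.frame(samples),
            all(c("t_min", "x_um", "y_um") %in% names(samples)))
  samples <- samples[order(samples$t_min), c("t_min", "x_um", "y_um")]
  if (anyDuplicated(samples$t_min))
    stop("duplicate timestamps in track ", track_id)
  if (any(!is.finite(as.matrix(samples))))
    stop("non-finite coordinates in track ", track_id)
  structure(list(track_id = as.character(track_id), samples = samples,
                 parent_id = as.character(parent_id)),
            class = "cell_track")
}

#' @export
print.cell_track <- function(x, ...) {
  cat(sprintf("<cell_track> '%s', %d samples over %.1f min%s\n", x$track_id,
              nrow(x$samples), diff(range(x$samples$t_min)),
              if (!is.na(x$parent_id)) paste0(", parent ", x$parent_id) else ""))
  invisible(x)
}

#' Read cell tracks from a delimited file
#'
#' Expects a header with columns `track_id`, `t_min`, `x_um`, `y_um`
#' (`parent_id` optional). Rows are grouped by track and sorted by time;
#' duplicated `(track, t)` rows are an error.
#'
#' @param path CSV (or other `sep`-delimited) file.
#' @param sep field separator.
#' @return list of [cell_track()] objects, named by `track_id`.
#' @export
read_tracks <- function(path, sep = ",") {
  if (!file.exists(path)) cond_stop(paste0("cannot read file: ", path), "io_error")
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("track_id", "t_min", "x_um", "y_um")
  miss <- setdiff(need, names(df))
  if (length(miss))
    cond_stop(paste0("track table is missing column(s): ",
                     paste(miss, collapse = ", ")), "schema_error")
  if (nrow(df) == 0) cond_stop("track table is empty", "schema_error")
  if ("z_um" %in% names(df))
    warning("z_um column present: analysis is 2D, z is ignored")
  has_parent <- "parent_id" %in% names(df)
  ids <- unique(df$track_id)
  tracks <- lapply(ids, function(id) {
    sub <- df[df$track_id == id, , drop = FALSE]
    parent <- NA_character_
    if (has_parent) {
      p <- sub$parent_id[1]
      if (!is.na(p) && nzchar(p)) parent <- as.character(p)
    }
    cell_track(id, sub[, c("t_min", "x_um", "y_um")], parent)
  })
  names(tracks) <- as.character(ids)
  tracks
}

#' Write cell tracks to CSV
#'
#' @param tracks list of [cell_track()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  rows <- lapply(tracks, function(tr) {
    cbind(data.frame(track_id = tr$track_id, stringsAsFactors = FALSE),
          tr$samples,
          data.frame(parent_id = ifelse(is.na(tr$parent_id), "", tr$parent_id)))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Windowed invasion speeds of one track
#'
#' Partitions the track into consecutive non-overlapping windows of
#' `window_min` minutes anchored at the first sample, mirroring one speed
#' data point per cell per 40-min video recording. Within a window the path
#' length is the summed Euclidean step distance, with positions linearly
#' interpolated at window boundaries (splitting a straight step pro rata
#' preserves its length, so a straight constant-speed track yields exactly
#' its speed in every window regardless of sampling interval). Speed
#' converts as `path_length_um * 60 / window_min` (um/h). Windows containing
#' fewer than two original samples are skipped and listed in the
#' `skipped_windows` attribute; a track shorter than one window yields an
#' empty result.
#'
#' @param track a [cell_track()].
#' @param window_min window length in minutes (default 40).
#' @return `data.frame` with one row per complete window: `track_id`,
#'   `window`, `window_start_min`, `n_samples`, `path_length_um`,
#'   `net_displacement_um`, `straightness` (net/path, `NA` for zero path),
#'   `speed_um_per_h`.
#' @export
window_speeds <- function(track, window_min = 40) {
  stopifnot(inherits(track, "cell_track"), window_min > 0)
  s <- track$samples
  t0 <- s$t_min[1]
  span <- s$t_min[nrow(s)] - t0
  n_win <- floor(span / window_min + 1e-9)
  empty <- data.frame(track_id = character(0), window = integer(0),
                      window_start_min = numeric(0), n_samples = integer(0),
                      path_length_um = numeric(0),
                      net_displacement_um = numeric(0),
                      straightness = numeric(0), speed_um_per_h = numeric(0))
  if (n_win < 1) return(structure(empty, skipped_windows = integer(0)))

  interp <- function(tt) {
    c(x = approx(s$t_min, s$x_um, xout = tt)$y,
      y = approx(s$t_min, s$y_um, xout = tt)$y)
  }
  rows <- list(); skipped <- integer(0)
  for (w in seq_len(n_win)) {
    ta <- t0 + (w - 1) * window_min
    tb <- t0 + w * window_min
    inside <- s$t_min >= ta - 1e-9 & s$t_min <= tb + 1e-9
    n_orig <- sum(inside)
    if (n_orig < 2L) { skipped <- c(skipped, w); next }
    px <- c(interp(ta)[1], s$x_um[inside], interp(tb)[1])
    py <- c(interp(ta)[2], s$y_um[inside], interp(tb)[2])
    ## drop duplicated boundary points when a sample sits exactly on the edge
    tt <- c(ta, s$t_min[inside], tb)
    dup <- duplicated(round(tt / 1e-6))
    px <- px[!dup]; py <- py[!dup]
    path <- sum(sqrt(diff(px)^2 + diff(py)^2))
    net <- sqrt((px[length(px)] - px[1])^2 + (py[length(py)] - py[1])^2)
    rows[[length(rows) + 1L]] <- data.frame(
      track_id = track$track_id, window = w, window_start_min = ta,
      n_samples = n_orig, path_length_um = path,
      net_displacement_um = net,
      straightness = ifelse(path > 0, net / path, NA_real_),
      speed_um_per_h = path * 60 / window_min,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  structure(out, skipped_windows = skipped)
}

#' Windowed speeds for a list of tracks
#'
#' @param tracks list of [cell_track()].
#' @param window_min window length in minutes.
#' @return stacked [window_speeds()] rows.
#' @export
window_speeds_all <- function(tracks, window_min = 40) {
  out <- do.call(rbind, lapply(tracks, window_speeds, window_min = window_min))
  rownames(out) <- NULL
  out
}

## approximate distance from an interior point to the ellipse boundary,
## measured along the ray from the center (exact for circles, adequate for
## margins much smaller than the semi-axes)
boundary_distance_um <- function(e, x, y) {
  rho <- ellipse_rho(e, x, y)
  rp <- sqrt((x - e$center[1])^2 + (y - e$center[2])^2)
  d <- ifelse(rho < 1e-9, e$semi_minor, rp * (1 / pmax(rho, 1e-9) - 1))
  pmax(d, 0)
}

#' Detect boundary-reversal events along a track
#'
#' Invading cells that reach the organoid margin turn around and move back
#' toward the tumor rather than exiting. An event is emitted at sample `k`
#' when the cell is within `margin_um` of the brain-ellipse boundary and its
#' radial motion (normalised ellipse radius) turns from outward to inward
#' there: `rho[k] >= rho[k-1]` and `rho[k] > rho[k+1]`. A track that starts
#' at the margin already moving inward, or ends at the margin still moving
#' outward, is also scored at that endpoint -- the turn happened between
#' samples and is otherwise unobservable.
#'
#' @param track a [cell_track()] in the same coordinate frame as `brain`.
#' @param brain the brain-compartment [ellipse()] (um coordinates).
#' @param margin_um boundary margin in micrometres (default 15, about one
#'   cell diameter).
#' @return `data.frame` with `track_id`, `sample_index`, `t_min`, `x_um`,
#'   `y_um`, `boundary_distance_um`.
#' @export
detect_reversals <- function(track, brain, margin_um = 15) {
  stopifnot(inherits(track, "cell_track"), inherits(brain, "ellipse"))
  s <- track$samples
  n <- nrow(s)
  empty <- data.frame(track_id = character(0), sample_index = integer(0),
                      t_min = numeric(0), x_um = numeric(0), y_um = numeric(0),
                      boundary_distance_um = numeric(0))
  if (n < 3) return(empty)
  rho <- ellipse_rho(brain, s$x_um, s$y_um)
  bd <- boundary_distance_um(brain, s$x_um, s$y_um)
  events <- integer(0)
  if (bd[1] <= margin_um && rho[1] > rho[2]) events <- c(events, 1L)
  for (k in 2:(n - 1)) {
    if (bd[k] > margin_um) next
    if (rho[k] >= rho[k - 1] && rho[k] > rho[k + 1]) events <- c(events, k)
  }
  if (bd[n] <= margin_um && rho[n] >= rho[n - 1]) events <- c(events, n)
  if (!length(events)) return(empty)
  data.frame(track_id = track$track_id, sample_index = events,
             t_min = s$t_min[events], x_um = s$x_um[events],
             y_um = s$y_um[events], boundary_distance_um = bd[events],
             stringsAsFactors = FALSE)
}

#' Post-division divergence of daughter cells
#'
#' After mitosis the two daughter cells migrate away in opposite directions.
#' For every parent with exactly two daughters (linked via `parent_id`) the
#' angle between the daughters' initial displacement vectors is reported,
#' with `opposite = TRUE` when it exceeds 90 degrees (negative heading dot
#' product). A daughter's initial displacement is taken from its first
#' sample to the first later sample with nonzero displacement (daughters may
#' begin with a stationary mitotic pause). Parents with a different number
#' of daughters are flagged rather than scored.
#'
#' @param tracks list of [cell_track()] with lineage in `parent_id`.
#' @return `data.frame` with one row per parent: `parent_id`, `n_daughters`,
#'   `angle_deg` (`NA` when not scorable), `opposite`, `flagged`.
#' @export
division_check <- function(tracks) {
  ids <- vapply(tracks, function(t) t$track_id, character(1))
  parents <- vapply(tracks, function(t) t$parent_id, character(1))
  referenced <- unique(parents[!is.na(parents)])
  unknown <- setdiff(referenced, ids)
  if (length(unknown))
    cond_stop(paste0("daughter references unknown parent: ",
                     paste(unknown, collapse = ", ")), "lineage_error")
  if (!length(referenced))
    return(data.frame(parent_id = character(0), n_daughters = integer(0),
                      angle_deg = numeric(0), opposite = logical(0),
                      flagged = logical(0)))
  initial_heading <- function(tr) {
    s <- tr$samples
    if (nrow(s) < 2) return(NULL)
    d <- cbind(s$x_um - s$x_um[1], s$y_um - s$y_um[1])
    nz <- which(rowSums(d^2) > 1e-12)
    if (!length(nz)) return(NULL)
    d[nz[1], ]
  }
  rows <- lapply(referenced, function(p) {
    dts <- tracks[!is.na(parents) & parents == p]
    nd <- length(dts)
    if (nd != 2L)
      return(data.frame(parent_id = p, n_daughters = nd, angle_deg = NA_real_,
                        opposite = NA, flagged = TRUE))
    h1 <- initial_heading(dts[[1]]); h2 <- initial_heading(dts[[2]])
    if (is.null(h1) || is.null(h2))
      return(data.frame(parent_id = p, n_daughters = nd, angle_deg = NA_real_,
                        opposite = NA, flagged = TRUE))
    cosang <- sum(h1 * h2) / (sqrt(sum(h1^2)) * sqrt(sum(h2^2)))
    ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    data.frame(parent_id = p, n_daughters = nd, angle_deg = ang,
               opposite = ang > 90, flagged = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-group speed summary (mean and SD)
#'
#' @param speeds stacked [window_speeds()] rows with an added `group` column.
#' @return `data.frame` per group: `n_windows`, `mean_speed_um_per_h`,
#'   `sd_speed_um_per_h`.
#' @export
summarize_speed_groups <- function(speeds) {
  stopifnot("group" %in% names(speeds))
  groups <- unique(speeds$group)
  out <- do.call(rbind, lapply(groups, function(g) {
    v <- speeds$speed_um_per_h[speeds$group == g]
    data.frame(group = g, n_windows = length(v),
               mean_speed_um_per_h = mean(v),
               sd_speed_um_per_h = if (length(v) > 1) sd(v) else 0,
               stringsAsFactors = FALSE)
  }))
  out[order(out$group), , drop = FALSE]
}
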