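#' Invasion metrics for one image
#'
#' All three metrics are normalised to the brain-organoid compartment: with
#' `R` the pixel set of the brain ellipse,
#' \describe{
#'   \item{competition_ratio}{fraction of `R` covered by the contiguous core
#'     tumor mass -- brain tissue replaced by the advancing tumor front;}
#'   \item{single_cell_ratio}{fraction of `R` covered by tumor components
#'     detached from the core -- single-cell invasion;}
#'   \item{total_invasion}{their sum, by construction exactly.}
#' }
#' Every ratio is a ratio of pixel counts on the rasterized brain ellipse;
#' areas are converted to um^2 with `pixel_size_um^2`. Ratios are asserted,
#' not clipped: a competition ratio outside `[0, 1]` indicates a geometry or
#' segmentation failure and raises an error.
#'
#' @param seg a `tumor_segmentation` from [classify_components()].
#' @param pair an `ellipse_pair` from [decompose_ellipses()] sharing the
#'   same frame.
#' @param pixel_size_um micrometres per pixel.
#' @param timepoint_h hours since confrontation.
#' @param sample_id,arm identifiers carried into the output row.
#' @return one-row `data.frame` of class `invasion_metrics`: the three
#'   ratios, `brain_area_um2`, `core_in_brain_area_um2`,
#'   `single_cell_area_um2`, `n_single_cells` (components with at least one
#'   pixel in `R`), `timepoint_h`, `sample_id`, `arm`.
#' @export
compute_metrics <- function(seg, pair, pixel_size_um, timepoint_h = NA_real_,
                            sample_id = "sample", arm = "none") {
  stopifnot(inherits(seg, "tumor_segmentation"), inherits(pair, "ellipse_pair"))
  frame <- dim(seg$component_labels)
  R <- ellipse_region(pair$brain, frame)
  nR <- sum(R)
  if (nR == 0) stop("degenerate brain ellipse: empty rasterized region")

  lab <- seg$component_labels
  core_in_R <- if (is.na(seg$core_label)) 0L else
    sum(lab[R] == seg$core_label)
  single_in_R <- if (length(seg$single_cell_labels)) {
    labR <- lab[R]
    sum(labR %in% seg$single_cell_labels)
  } else 0L
  n_single <- if (length(seg$single_cell_labels)) {
    labR <- lab[R]
    length(intersect(seg$single_cell_labels, unique(labR[labR > 0])))
  } else 0L

  competition <- core_in_R / nR
  single_ratio <- single_in_R / nR
  if (competition < 0 || competition > 1)
    stop("competition_ratio outside [0, 1]: geometry/segmentation failure")
  px2 <- pixel_size_um^2
  out <- data.frame(
    sample_id = sample_id, arm = arm, timepoint_h = timepoint_h,
    competition_ratio = competition,
    single_cell_ratio = single_ratio,
    total_invasion = competition + single_ratio,
    brain_area_um2 = nR * px2,
    core_in_brain_area_um2 = core_in_R * px2,
    single_cell_area_um2 = single_in_R * px2,
    n_single_cells = n_single,
    stringsAsFactors = FALSE)
  class(out) <- c("invasion_metrics", "data.frame")
  out
}

#' Order per-sample metrics into time series and flag anomalies
#'
#' @param metrics a `data.frame` of stacked [compute_metrics()] rows.
#' @return `data.frame` sorted by `(sample_id, timepoint_h)` with logical
#'   column `nonmonotone_total` marking rows where `total_invasion` dropped
#'   relative to the sample's previous time point (allowed, but reported),
#'   and attribute `missing_timepoints` listing `(sample, timepoint)` gaps
#'   relative to the union of observed time points.
#' @export
timecourse <- function(metrics) {
  stopifnot(is.data.frame(metrics),
            all(c("sample_id", "timepoint_h", "total_invasion") %in%
                  names(metrics)))
  key <- paste(metrics$sample_id, metrics$timepoint_h, sep = "@")
  if (anyDuplicated(key))
    stop("duplicate (sample, timepoint): ", key[duplicated(key)][1])
  ord <- order(metrics$sample_id, metrics$timepoint_h)
  out <- metrics[ord, , drop = FALSE]
  out$nonmonotone_total <- FALSE
  all_t <- sort(unique(out$timepoint_h))
  missing <- list()
  for (s in unique(out$sample_id)) {
    i <- which(out$sample_id == s)
    if (length(i) > 1)
      out$nonmonotone_total[i[-1]] <- diff(out$total_invasion[i]) < 0
    gap <- setdiff(all_t, out$timepoint_h[i])
    if (length(gap)) missing[[s]] <- gap
  }
  attr(out, "missing_timepoints") <- missing
  rownames(out) <- NULL
  out
}

#' Percent inhibition of a metric by a treatment
#'
#' `100 * (1 - treated / control)`, the convention used to report, e.g., a
#' 63\% reduction of single-cell invasion under an AMPA-receptor antagonist.
#'
#' @param treated,control summary means of the metric (control must be > 0).
#' @return percent inhibition (positive = reduced by treatment).
#' @export
percent_inhibition <- function(treated, control) {
  if (!is.finite(control) || control <= 0)
    stop("percent inhibition undefined: control mean must be positive")
  100 * (1 - treated / control)
}

#' Summarise metrics per treatment arm and time point
#'
#' Means with SEM (`sd/sqrt(n)`, `n - 1` denominator in the SD) per
#' `(arm, timepoint_h)` over replicate images, the standard reporting form
#' for confrontation time courses.
#'
#' @param metrics stacked [compute_metrics()] rows.
#' @return `data.frame` with one row per `(arm, timepoint_h)`:
#'   `n_replicates`, then `<metric>_mean` and `<metric>_sem` for the three
#'   invasion metrics.
#' @export
summarize_arms <- function(metrics) {
  stopifnot(is.data.frame(metrics))
  cols <- c("competition_ratio", "single_cell_ratio", "total_invasion")
  ## NA time points (untimed single images) form their own group
  grp <- paste(metrics$arm, metrics$timepoint_h, sep = "\r")
  rows <- lapply(unique(grp), function(g) {
    sub <- metrics[grp == g, , drop = FALSE]
    n <- nrow(sub)
    stats <- unlist(lapply(cols, function(cl) {
      m <- mean(sub[[cl]])
      sem <- if (n > 1) sd(sub[[cl]]) / sqrt(n) else 0
      setNames(c(m, sem), paste0(cl, c("_mean", "_sem")))
    }))
    cbind(data.frame(arm = sub$arm[1], timepoint_h = sub$timepoint_h[1],
                     n_replicates = n, stringsAsFactors = FALSE),
          as.data.frame(as.list(stats)))
  })
  out <- do.call(rbind, rows)
  out[order(out$arm, out$timepoint_h), , drop = FALSE]
}
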