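straight_track <- function(v_um_h = 19.5, step_min = 4, n_steps = 10,
                           angle = 0.3, origin = c(5, -2), t0 = 0) {
  step <- v_um_h * step_min / 60
  k <- 0:n_steps
  cell_track("straight",
             data.frame(t_min = t0 + k * step_min,
                        x_um = origin[1] + k * step * cos(angle),
                        y_um = origin[2] + k * step * sin(angle)))
}

test_that("track tables parse, sort, and validate their schema", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("track_id,t_min,x_um,y_um",
               "c1,8,2.0,0.0", "c1,0,0.0,0.0", "c1,4,1.0,0.0"), path)
  tracks <- read_tracks(path)
  expect_length(tracks, 1)
  expect_equal(tracks[["c1"]]$samples$t_min, c(0, 4, 8))  # sorted on load
  expect_equal(tracks[["c1"]]$samples$x_um, c(0, 1, 2))

  writeLines(c("track_id,t_min,x_um,y_um", "c1,0,0,0", "c1,0,1,1"), path)
  expect_error(read_tracks(path), "duplicate")

  writeLines(c("track_id,t_min,x_um", "c1,0,0"), path)
  expect_error(read_tracks(path), class = "schema_error")

  ## round trip through the writer
  p2 <- withr::local_tempfile(fileext = ".csv")
  tr <- straight_track()
  write_tracks(list(tr), p2)
  back <- read_tracks(p2)
  expect_equal(back[[1]]$samples, tr$samples, ignore_attr = TRUE)
})

test_that("a 13.0-um path in a 40-min window gives exactly 19.5 um/h", {
  ## 4-min sampling, 1.3 um per step, 10 steps = 40 min
  tr <- cell_track("bg7", data.frame(t_min = seq(0, 40, by = 4),
                                     x_um = 1.3 * (0:10), y_um = 0))
  sp <- window_speeds(tr, window_min = 40)
  expect_equal(nrow(sp), 1)
  expect_equal(sp$path_length_um, 13.0)
  expect_equal(sp$speed_um_per_h, 19.5)
  expect_equal(sp$straightness, 1)

  ## stationary cell
  st <- cell_track("still", data.frame(t_min = seq(0, 80, 10),
                                       x_um = 3, y_um = 7))
  expect_true(all(window_speeds(st)$speed_um_per_h == 0))

  ## shorter than one window: empty result, not an error
  short <- cell_track("short", data.frame(t_min = c(0, 10), x_um = 0:1,
                                          y_um = 0))
  expect_equal(nrow(window_speeds(short)), 0)
})

test_that("straight constant-speed tracks give the exact speed in every window", {
  ## 7-min sampling does not divide the 40-min window; boundary
  ## interpolation must still give the exact speed
  tr <- straight_track(v_um_h = 24, step_min = 7, n_steps = 20)
  sp <- window_speeds(tr, window_min = 40)
  expect_equal(nrow(sp), 3)
  expect_equal(sp$speed_um_per_h, rep(24, 3))
})

test_that("windowed speed is invariant under rigid motions", {
  set.seed(9)
  s <- data.frame(t_min = seq(0, 120, 4),
                  x_um = cumsum(rnorm(31)), y_um = cumsum(rnorm(31)))
  sp0 <- window_speeds(cell_track("a", s))
  th <- 1.1
  rot <- data.frame(t_min = s$t_min,
                    x_um = cos(th) * s$x_um - sin(th) * s$y_um + 50,
                    y_um = sin(th) * s$x_um + cos(th) * s$y_um - 20)
  sp1 <- window_speeds(cell_track("a", rot))
  expect_equal(sp1$speed_um_per_h, sp0$speed_um_per_h, tolerance = 1e-12)
})

test_that("removing intermediate samples never increases the path length", {
  set.seed(13)
  for (rep in 1:10) {
    s <- data.frame(t_min = seq(0, 40, 2),
                    x_um = cumsum(rnorm(21)), y_um = cumsum(rnorm(21)))
    full <- window_speeds(cell_track("a", s))$path_length_um
    sub <- s[c(TRUE, FALSE), ]  # every other sample (keeps both endpoints)
    thin <- window_speeds(cell_track("a", sub))$path_length_um
    expect_lte(thin, full + 1e-12)
  }
})

test_that("reversal detection scores radial turnarounds at the margin", {
  brain <- ellipse(c(0, 0), 100, 100, 0)
  ## radius oscillating to the margin three times, well separated
  t <- seq(0, 360, by = 4)
  r <- 60 + 35 * sin(2 * pi * t / 120)  # peaks at 95 (5 um from boundary)
  tr <- cell_track("osc", data.frame(t_min = t, x_um = r, y_um = 0))
  ev <- detect_reversals(tr, brain, margin_um = 15)
  expect_equal(nrow(ev), 3)

  ## straight interior track: no events
  inner <- cell_track("in", data.frame(t_min = t, x_um = seq(-40, 40,
                                                             length.out = length(t)),
                                       y_um = 5))
  expect_equal(nrow(detect_reversals(inner, brain)), 0)
})

test_that("division check scores daughter divergence and lineage errors", {
  mk <- function(id, parent, dx, dy) cell_track(
    id, data.frame(t_min = c(0, 4, 8), x_um = c(0, dx, 2 * dx),
                   y_um = c(0, dy, 2 * dy)), parent_id = parent)
  tracks <- list(
    cell_track("p", data.frame(t_min = c(-8, -4), x_um = 0, y_um = 0)),
    mk("p.1", "p", 1, 0), mk("p.2", "p", -1, 0),    # 180 degrees
    cell_track("q", data.frame(t_min = c(-8, -4), x_um = 0, y_um = 0)),
    mk("q.1", "q", 1, 0), mk("q.2", "q", cos(pi / 6), sin(pi / 6)))  # 30 deg
  rep <- division_check(tracks)
  expect_equal(rep$angle_deg[rep$parent_id == "p"], 180)
  expect_true(rep$opposite[rep$parent_id == "p"])
  expect_equal(rep$angle_deg[rep$parent_id == "q"], 30, tolerance = 1e-6)
  expect_false(rep$opposite[rep$parent_id == "q"])

  ## a stationary mitotic pause before the first movement is tolerated
  paused <- list(
    cell_track("r", data.frame(t_min = c(-8, -4), x_um = 0, y_um = 0)),
    cell_track("r.1", data.frame(t_min = c(0, 4, 8), x_um = c(0, 0, 2),
                                 y_um = 0), parent_id = "r"),
    mk("r.2", "r", -1, 0))
  repp <- division_check(paused)
  expect_true(repp$opposite[repp$parent_id == "r"])

  ## parent with one daughter is flagged, unknown parent errors
  flagged <- division_check(list(
    cell_track("s", data.frame(t_min = 0:1, x_um = 0:1, y_um = 0)),
    mk("s.1", "s", 1, 1)))
  expect_true(flagged$flagged[flagged$parent_id == "s"])
  expect_error(division_check(list(mk("x.1", "ghost", 1, 0))),
               class = "lineage_error")
})
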