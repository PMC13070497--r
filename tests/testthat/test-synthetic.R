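test_that("rendered scenes realize the requested fractions almost exactly", {
  sp <- scene_spec(seed = 21, competition_true = 0.30, single_cell_true = 0.05)
  sc <- render_scene(sp)
  expect_lt(abs(sc$truth$competition_realized - 0.30), 0.002)
  expect_lt(abs(sc$truth$single_cell_realized - 0.05), 0.002)
  expect_equal(sc$truth$n_cells_realized, sp$n_cells_true)

  ## truth is recomputed from masks: fractions are exact pixel ratios
  R <- ellipse_region(sp$brain, sp$frame)
  expect_equal(sc$truth$competition_realized,
               sum(sc$truth$core_mask & R) / sum(R))
  ## the replaced region is contiguous with the core (one 8-connected
  ## component after thresholding the noise-free mask)
  seg <- classify_components(sc$truth$gfp_mask,
                             c(round(sp$tumor$center[2]), round(sp$tumor$center[1])),
                             min_object_um2 = 20, pixel_size_um = sp$pixel_size_um)
  expect_equal(length(seg$single_cell_labels), sp$n_cells_true)
})

test_that("the null scene has tumor fluorescence only outside the brain", {
  sp <- scene_spec(seed = 3, competition_true = 0, single_cell_true = 0,
                   n_cells_true = 0)
  sc <- render_scene(sp)
  expect_equal(sc$truth$competition_realized, 0)
  expect_equal(sc$truth$single_cell_realized, 0)
  R <- ellipse_region(sp$brain, sp$frame)
  expect_false(any(sc$truth$gfp_mask & R))

  ## metrics computed on the truth masks with the true ellipses read (0,0,0)
  seg <- classify_components(sc$truth$gfp_mask,
                             c(round(sp$tumor$center[2]), round(sp$tumor$center[1])),
                             20, sp$pixel_size_um)
  pair <- decompose_ellipses(NULL, NULL, NULL, frame_shape = sp$frame,
                             manual = list(brain = sp$brain, tumor = sp$tumor))
  m <- compute_metrics(seg, pair, sp$pixel_size_um)
  expect_equal(unlist(m[c("competition_ratio", "single_cell_ratio",
                          "total_invasion")], use.names = FALSE), c(0, 0, 0))
})

test_that("debris below the size filter is rendered but never counted", {
  sp <- scene_spec(seed = 8, single_cell_true = 0.06, n_cells_true = 12,
                   n_debris_true = 4)
  sc <- render_scene(sp)
  seg <- classify_components(sc$truth$gfp_mask,
                             c(round(sp$tumor$center[2]), round(sp$tumor$center[1])),
                             min_object_um2 = 20, pixel_size_um = sp$pixel_size_um)
  expect_equal(length(seg$single_cell_labels), 12)
  expect_gt(sum(sc$truth$debris_mask), 0)
})

test_that("infeasible scene specifications are rejected by name", {
  expect_error(scene_spec(competition_true = 0.9, single_cell_true = 0.2),
               "competition_true")
  expect_error(scene_spec(single_cell_true = 0.05, n_cells_true = 0),
               "n_cells_true")
  expect_error(scene_spec(brain = ellipse(c(50, 50), 20, 18, 0),
                          tumor = ellipse(c(200, 200), 20, 18, 0)),
               "overlap")
})

test_that("scene rendering is a pure function of (spec, seed)", {
  a <- render_scene(scene_spec(seed = 5))
  b <- render_scene(scene_spec(seed = 5))
  expect_identical(a$stack$data, b$stack$data)
  c <- render_scene(scene_spec(seed = 6))
  expect_false(identical(a$stack$data, c$stack$data))
})

test_that("walk steps have the prescribed mean length", {
  ## uncorrelated steps at 20 um/h: law of large numbers on the generator's
  ## own draws, ~25k steps
  sim <- simulate_walks(walk_spec(speed_true = 20, persistence = 0,
                                  duration_min = 400, seed = 2), 250)
  expect_lt(abs(sim$truth$mean_step_speed_um_per_h / 20 - 1), 0.01)
})

test_that("walks never escape the reflecting boundary", {
  e <- ellipse(c(10, -5), 70, 55, 0.8)
  sim <- simulate_walks(walk_spec(brain = e, persistence = 0.8,
                                  speed_true = 35, duration_min = 200,
                                  seed = 4), 25)
  for (tr in sim$tracks) {
    rho <- invasionquant:::ellipse_rho(e, tr$samples$x_um, tr$samples$y_um)
    expect_true(all(rho <= 1 + 1e-9))
  }
  expect_gt(nrow(sim$truth$reflections), 0)
})

test_that("divisions produce two antiparallel daughters after the pause", {
  sim <- simulate_walks(walk_spec(division_rate = 1.5, duration_min = 240,
                                  seed = 9), 40)
  div <- sim$truth$divisions
  expect_gt(nrow(div), 0)
  for (i in seq_len(nrow(div))) {
    d1 <- sim$tracks[[paste0(div$parent_id[i], ".1")]]
    d2 <- sim$tracks[[paste0(div$parent_id[i], ".2")]]
    expect_false(is.null(d1)); expect_false(is.null(d2))
    ## daughters start at the division point, pause_min later
    expect_equal(d1$samples$t_min[1], div$t_min[i] + 160)
    expect_equal(c(d1$samples$x_um[1], d1$samples$y_um[1]),
                 c(div$x_um[i], div$y_um[i]))
    h1 <- c(diff(d1$samples$x_um[1:2]), diff(d1$samples$y_um[1:2]))
    h2 <- c(diff(d2$samples$x_um[1:2]), diff(d2$samples$y_um[1:2]))
    expect_lt(sum(h1 * h2), 0)
  }
  ## the analysis-side check agrees with the generator's rule
  rep <- division_check(sim$tracks)
  scored <- rep[!rep$flagged, ]
  expect_true(all(scored$opposite))
})

test_that("track simulation is deterministic per seed", {
  a <- simulate_walks(walk_spec(seed = 12, division_rate = 0.5), 10)
  b <- simulate_walks(walk_spec(seed = 12, division_rate = 0.5), 10)
  expect_identical(lapply(a$tracks, function(t) t$samples),
                   lapply(b$tracks, function(t) t$samples))
  expect_identical(a$truth$reflections, b$truth$reflections)
})
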