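test_that("direct ellipse fit recovers exact arcs to numerical precision", {
  arcs <- list(
    list(e = ellipse(c(50, 40), 30, 18, 0.7), ang = seq(0.3, 3.5, length.out = 200)),
    list(e = ellipse(c(120, 80), 45, 44, 2.1), ang = seq(2.0, 5.9, length.out = 200)))
  for (a in arcs) {
    f <- fit_ellipse(ellipse_points(a$e, a$ang))
    expect_lt(max(abs(f$ellipse$center - a$e$center)), 0.5)
    expect_lt(abs(f$ellipse$semi_major / a$e$semi_major - 1), 0.01)
    expect_lt(abs(f$ellipse$semi_minor / a$e$semi_minor - 1), 0.01)
    rot_diff <- abs(f$ellipse$rotation - a$e$rotation) %% pi
    expect_lt(min(rot_diff, pi - rot_diff), pi / 180)
    expect_lt(f$residual_px, 1e-6)
  }
  expect_error(fit_ellipse(cbind(1:20, 2 * (1:20) + 3)), "degenerate")
})

test_that("ellipse rasterization is exact per pixel center", {
  e <- ellipse(c(32, 32), 10.5, 10.5, 0)
  reg <- ellipse_region(e, c(64, 64))
  expect_equal(sum(reg), pixel_count_oracle(e, 64, 64))

  ## entirely outside the frame
  expect_false(any(ellipse_region(ellipse(c(-50, -50), 10, 8, 1), c(32, 32))))

  ## circles are rotation invariant
  expect_identical(ellipse_region(ellipse(c(20, 20), 9, 9, 0), c(40, 40)),
                   ellipse_region(ellipse(c(20, 20), 9, 9, pi / 3), c(40, 40)))

  ## pixel-count area converges to pi*a*b within 1.5% for axes >= 15 px
  for (ab in list(c(15, 15), c(25, 16), c(40, 22))) {
    ee <- ellipse(c(100, 100), ab[1], ab[2], 0.6)
    expect_lt(abs(sum(ellipse_region(ee, c(200, 200))) / (pi * ab[1] * ab[2]) - 1),
              0.015)
  }
})

test_that("neck points land at the analytic circle intersections", {
  c1 <- c(100, 100); r1 <- 40; c2 <- c(155, 100); r2 <- 30; d <- 55
  ct <- extract_contour(make_snowman(c1, r1, c2, r2))
  nk <- find_neck_points(ct)
  a <- (r1^2 - r2^2 + d^2) / (2 * d); h <- sqrt(r1^2 - a^2)
  analytic <- rbind(c(c1[1] + a, c1[2] + h), c(c1[1] + a, c1[2] - h))
  perim <- sum(sqrt(rowSums(diff(rbind(ct, ct[1, ]))^2)))
  vert_step <- perim / 360  # resampled vertex spacing
  for (i in 1:2) {
    dists <- sqrt((analytic[, 1] - nk$points[i, 1])^2 +
                    (analytic[, 2] - nk$points[i, 2])^2)
    expect_lt(min(dists), 3 * vert_step)
  }

  ## convex contour: no neck
  conv <- ellipse_region(ellipse(c(80, 60), 60, 40, 0), c(120, 160))
  expect_error(find_neck_points(extract_contour(conv)), class = "no_neck_error")
})

test_that("neck detection tolerates boundary jitter", {
  ct <- extract_contour(make_snowman(c(100, 100), 40, c(155, 100), 30))
  nk0 <- find_neck_points(ct)
  ## smooth radial jitter of ~2 px amplitude around the contour centroid
  set.seed(5)
  cen <- colMeans(ct)
  ang <- atan2(ct[, 2] - cen[2], ct[, 1] - cen[1])
  jit <- 0
  for (k in 2:5) jit <- jit + runif(1, -1, 1) * cos(k * ang + runif(1, 0, 2 * pi))
  jit <- 2 * jit / max(abs(jit))
  rr <- sqrt((ct[, 1] - cen[1])^2 + (ct[, 2] - cen[2])^2) + jit
  ctj <- ct
  ctj[, 1] <- cen[1] + rr * cos(ang); ctj[, 2] <- cen[2] + rr * sin(ang)
  nkj <- find_neck_points(ctj)
  perim <- sum(sqrt(rowSums(diff(rbind(ct, ct[1, ]))^2)))
  for (i in 1:2) {
    dists <- sqrt((nk0$points[, 1] - nkj$points[i, 1])^2 +
                    (nk0$points[, 2] - nkj$points[i, 2])^2)
    expect_lt(min(dists), 5 * perim / 360)
  }
})

test_that("snowman decomposition recovers the generating circles", {
  c1 <- c(100, 100); r1 <- 40; c2 <- c(155, 100); r2 <- 30
  ct <- extract_contour(make_snowman(c1, r1, c2, r2))
  pair <- decompose_ellipses(ct, brain_hint = c1, tumor_hint = c2,
                             frame_shape = c(220, 220))
  expect_false(pair$manual)
  expect_lt(max(abs(pair$brain$center - c1)), 2)
  expect_lt(max(abs(pair$tumor$center - c2)), 2)
  for (ax in c("semi_major", "semi_minor")) {
    expect_lt(abs(pair$brain[[ax]] / r1 - 1), 0.03)
    expect_lt(abs(pair$tumor[[ax]] / r2 - 1), 0.03)
  }
  expect_gt(pair$overlap_area_px2, 0)

  ## identity from a GFP mask overrides the hint-based assignment
  gfp <- matrix(FALSE, 220, 220)
  gfp[(col(gfp) - c2[1])^2 + (row(gfp) - c2[2])^2 <= 20^2] <- TRUE
  pair2 <- decompose_ellipses(ct, brain_hint = c2, tumor_hint = c1,
                              gfp_mask = gfp)
  expect_lt(max(abs(pair2$tumor$center - c2)), 2)
})

test_that("decomposition is invariant to contour start vertex and direction", {
  ct <- extract_contour(make_snowman(c(100, 100), 40, c(155, 100), 30))
  pair0 <- decompose_ellipses(ct, c(100, 100), c(155, 100),
                              frame_shape = c(220, 220))
  n <- nrow(ct)
  rolled <- ct[c(151:n, 1:150), ]
  reversed <- ct[rev(seq_len(n)), ]
  for (variant in list(rolled, reversed)) {
    pairv <- decompose_ellipses(variant, c(100, 100), c(155, 100),
                                frame_shape = c(220, 220))
    expect_lt(max(abs(pairv$brain$center - pair0$brain$center)), 0.5)
    expect_lt(abs(pairv$brain$semi_major - pair0$brain$semi_major), 0.5)
    expect_lt(max(abs(pairv$tumor$center - pair0$tumor$center)), 0.5)
  }
})

test_that("manual ellipses bypass fitting and are used verbatim", {
  b <- ellipse(c(30, 30), 20, 15, 0.2); t <- ellipse(c(60, 30), 12, 10, 1.1)
  pair <- decompose_ellipses(NULL, NULL, NULL, frame_shape = c(90, 90),
                             manual = list(brain = b, tumor = t))
  expect_true(pair$manual)
  expect_identical(pair$brain, b)
  expect_true(is.na(pair$fit_residual_px[["brain"]]))
})
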