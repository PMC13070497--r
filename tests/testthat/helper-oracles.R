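# Independent oracles and small fixture builders used across the suite.

# Brute-force seeded flood fill implementing the same acceptance rule as
# region_grow (running-mean criterion, FIFO frontier, 4-neighbours pushed in
# row-major order) but written independently in plain R.
flood_oracle <- function(img, seed, tol) {
  nr <- nrow(img); nc <- ncol(img)
  member <- matrix(FALSE, nr, nc)
  queued <- matrix(FALSE, nr, nc)
  queue <- matrix(NA_integer_, nr * nc * 4, 2)
  head <- 1L; tail <- 0L
  push <- function(r, c) {
    if (r < 1 || r > nr || c < 1 || c > nc || queued[r, c]) return()
    tail <<- tail + 1L
    queue[tail, ] <<- c(r, c)
    queued[r, c] <<- TRUE
  }
  push(seed[1], seed[2])
  total <- 0; n <- 0
  while (head <= tail) {
    r <- queue[head, 1]; c <- queue[head, 2]; head <- head + 1L
    val <- img[r, c]
    if (n > 0 && abs(val - total / n) > tol) next
    member[r, c] <- TRUE
    total <- total + val; n <- n + 1
    push(r - 1, c); push(r, c - 1); push(r, c + 1); push(r + 1, c)
  }
  member
}

# plain shoelace area, y-down screen orientation (independent of
# polygon_area's implementation details)
shoelace_oracle <- function(verts) {
  n <- nrow(verts)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + verts[i, 1] * verts[j, 2] - verts[j, 1] * verts[i, 2]
  }
  as.numeric(-s / 2)
}

# logical matrix with all attributes stripped, for exact mask comparisons
bare_mask <- function(m) matrix(as.logical(m), nrow(m), ncol(m))

# binary mask of the union of two circles (the "snowman" of merging
# organoids)
make_snowman <- function(c1, r1, c2, r2, nr = 220, nc = 220) {
  x <- matrix(rep(seq_len(nc), each = nr), nr)
  y <- matrix(rep(seq_len(nr), times = nc), nr)
  ((x - c1[1])^2 + (y - c1[2])^2 <= r1^2) |
    ((x - c2[1])^2 + (y - c2[2])^2 <= r2^2)
}

# exhaustive pixel-center count of an ellipse interior
pixel_count_oracle <- function(e, nr, nc) {
  cnt <- 0L
  ct <- cos(e$rotation); st <- sin(e$rotation)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    dx <- c - e$center[1]; dy <- r - e$center[2]
    u <- (ct * dx + st * dy) / e$semi_major
    v <- (-st * dx + ct * dy) / e$semi_minor
    if (u^2 + v^2 <= 1) cnt <- cnt + 1L
  }
  cnt
}

# a tumor_segmentation built directly from a label matrix (bypassing
# classify_components) for constructed metric fixtures
manual_segmentation <- function(labels, core_label, singles, pixel_size_um = 1) {
  structure(list(gfp_mask = labels > 0, component_labels = labels,
                 core_label = core_label, single_cell_labels = singles,
                 min_object_um2 = 0, pixel_size_um = pixel_size_um,
                 empty = FALSE),
            class = "tumor_segmentation")
}

manual_pair <- function(brain, tumor, frame) {
  decompose_ellipses(NULL, NULL, NULL, frame_shape = frame,
                     manual = list(brain = brain, tumor = tumor))
}
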