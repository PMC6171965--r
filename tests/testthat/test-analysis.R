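test_that("divergence maps match hand finite differences", {
  # one-sided and central differences on a hand matrix
  M <- matrix(c(1, 2, 4,
                0, 1, 3,
                2, 2, 2), nrow = 3, byrow = TRUE)
  h <- 0.125
  d <- cortexsim:::central_diff_x(M, h)
  expect_equal(d[1, ], (M[2, ] - M[1, ]) / h)
  expect_equal(d[2, ], (M[3, ] - M[1, ]) / (2 * h))
  expect_equal(d[3, ], (M[3, ] - M[2, ]) / h)
  # three hand-placed filaments: per-box orientation sums are exact
  f <- make_filaments(c(0, 0, 0.2) - 0.5, c(0.2, 0.2, -0.3), c(0, 0, pi / 2))
  dm <- divergence_map(f, domain = hexagon_domain(2.2))
  expect_s3_class(dm, "divergence_map")
  # two plus-ends share one box: Vx sums to 2
  expect_equal(max(dm$Vx), 2)
  expect_equal(sum(dm$Vy), 1)
  expect_equal(dm$div, cortexsim:::central_diff_x(dm$Vx, dm$box_size) +
                 cortexsim:::central_diff_y(dm$Vy, dm$box_size))
})

test_that("divergence is ~0 for a uniform parallel field and box-additive", {
  # parallel filaments with plus-ends on a regular lattice
  g <- expand.grid(x = seq(-1, 1, by = 0.125), y = seq(-1, 1, by = 0.125))
  f <- make_filaments(g$x - 0.5, g$y, rep(0, nrow(g)))
  dm <- divergence_map(f, domain = hexagon_domain(2.2))
  occupied <- dm$Vx != 0
  interior <- occupied &
    cortexsim:::dilate1(cortexsim:::dilate1(!occupied)) == FALSE
  expect_true(all(abs(dm$div[interior]) < 1e-9))
  # linearity: the map of a union is the box-wise sum of the maps
  set.seed(7)
  a <- make_filaments(runif(40, -1, 1), runif(40, -1, 1),
                      runif(40, 0, 2 * pi))
  b <- make_filaments(runif(30, -1, 1), runif(30, -1, 1),
                      runif(30, 0, 2 * pi))
  ab <- dplyr::bind_rows(a, b)
  ab$id <- seq_len(nrow(ab))
  expect_equal(divergence_map(ab, domain = hexagon_domain(2.2))$div,
               divergence_map(a, domain = hexagon_domain(2.2))$div +
                 divergence_map(b, domain = hexagon_domain(2.2))$div)
})

test_that("aster detection finds constructed cores and rejects noise", {
  set.seed(21)
  dom <- hexagon_domain(2.2)
  # uniform random filaments: no sign-reversal locus
  f0 <- make_filaments(runif(1000, -1.5, 1.5), runif(1000, -1.2, 1.2),
                       runif(1000, 0, 2 * pi))
  expect_equal(nrow(detect_asters(divergence_map(f0, domain = dom))), 0)
  # one ideal aster at a known centre
  f1 <- ideal_aster_filaments(250, center = c(0.4, -0.3))
  a1 <- detect_asters(divergence_map(f1, domain = dom))
  expect_equal(nrow(a1), 1)
  expect_lt(abs(a1$x - 0.4), 0.25)
  expect_lt(abs(a1$y + 0.3), 0.25)
  # two well-separated asters
  f2 <- dplyr::bind_rows(ideal_aster_filaments(200, c(-1.1, 0)),
                         ideal_aster_filaments(200, c(1.1, 0)))
  f2$id <- seq_len(nrow(f2))
  expect_equal(nrow(detect_asters(divergence_map(f2, domain = dom))), 2)
})

test_that("rendering is additive and conserves filament coverage", {
  dom <- hexagon_domain(2.2)
  empty <- make_filaments(numeric(0), numeric(0), numeric(0))
  fr0 <- render_frame(empty, domain = dom)
  expect_true(all(fr0 == 0))
  # one horizontal 1-um filament at 0.05 um/px lights ~20 pixels in one row
  f1 <- make_filaments(0, 0, 0)
  fr1 <- render_frame(f1, pixel_size = 0.05, domain = dom)
  expect_equal(sum(fr1), 20, tolerance = 0.1)
  expect_lte(max(fr1), 1)
  # two identical filaments double every covered pixel
  f2 <- make_filaments(c(0, 0), c(0, 0), c(0, 0))
  fr2 <- render_frame(f2, pixel_size = 0.05, domain = dom)
  expect_equal(unname(as.vector(fr2)), unname(as.vector(fr1 * 2L)))
  # conservation: per-filament coverage is max(|dx|,|dy|)/px + 1, +- 2 px
  set.seed(8)
  fN <- make_filaments(runif(50, -1, 1), runif(50, -1, 1),
                       runif(50, 0, 2 * pi))
  frN <- render_frame(fN, pixel_size = 0.05, domain = dom)
  expected <- sum(pmax(abs(cos(fN$theta)), abs(sin(fN$theta))) / 0.05 + 1)
  expect_lte(abs(sum(frN) - expected), 2 * nrow(fN))
})

test_that("ROI intensity traces follow their definition", {
  mk_frame <- function(mat) {
    structure(mat, pixel_size = 0.1, x0 = -1, y0 = -1, channel = "filament",
              class = c("cortex_frame", "matrix", "array"))
  }
  const <- mk_frame(matrix(3, 20, 20))
  tr <- roi_mean_intensity(list(const, const, const), 0, 0, 0.4)
  expect_equal(tr$value, rep(1, 3))
  # ROI mean exactly twice the frame mean -> normalized value 2:
  # inside = a, outside = b = 1 with a chosen so a = 2 * mean(all)
  xs <- -1 + (1:20 - 0.5) * 0.1
  mask <- outer(xs, xs, function(x, y) x^2 + y^2 <= 0.4^2)
  n_in <- sum(mask)
  n_out <- 400 - n_in
  a <- 2 * n_out / (400 - 2 * n_in)
  m <- matrix(1, 20, 20)
  m[mask] <- a
  tr2 <- roi_mean_intensity(list(mk_frame(m)), 0, 0, 0.4)
  expect_equal(tr2$value, 2, tolerance = 1e-12)
  expect_error(roi_mean_intensity(list(const), 50, 50, 0.01), "empty ROI")
})

test_that("kymographs stack static profiles into identical columns", {
  set.seed(9)
  f <- make_filaments(runif(30, -1, 1), runif(30, -1, 1),
                      runif(30, 0, 2 * pi))
  fr <- render_frame(f, domain = hexagon_domain(2.2))
  ky <- kymograph(list(fr, fr, fr), -1, 0, 1, 0, width_px = 3)
  expect_equal(ncol(ky), 3)
  expect_equal(ky[, 1], ky[, 2])
  expect_equal(ky[, 2], ky[, 3])
  expect_gt(sum(ky), 0)
})

test_that("hexagon segmentation highlights and merges intensity blobs", {
  mk_frame <- function(mat) {
    structure(mat, pixel_size = 0.05, x0 = -2.2, y0 = -1.9,
              channel = "filament", class = c("cortex_frame", "matrix",
                                              "array"))
  }
  base <- matrix(1, 88, 76)
  # uniform stack: nothing reaches the 1.7-fold threshold
  seg0 <- coarse_hexagon_segmentation(list(mk_frame(base)),
                                      domain = hexagon_domain(2.2))
  expect_equal(seg0$n_regions, 0L)
  blob <- function(m, cx, cy, val, rad = 0.3) {
    xs <- -2.2 + (seq_len(nrow(m)) - 0.5) * 0.05
    ys <- -1.9 + (seq_len(ncol(m)) - 0.5) * 0.05
    hit <- outer(xs, ys, function(x, y) (x - cx)^2 + (y - cy)^2 <= rad^2)
    m[hit] <- val
    m
  }
  # one blob at ~3x the global mean: a single region away from the boundary
  one <- blob(base, 0, 0, 4)
  seg1 <- coarse_hexagon_segmentation(list(mk_frame(one)),
                                      domain = hexagon_domain(2.2))
  expect_equal(seg1$n_regions, 1L)
  expect_gt(seg1$min_boundary_distance, 0.5)
  expect_gt(seg1$area, 0)
  # two disjoint blobs: two regions; merging them into one: one region
  two <- blob(blob(base, -1.2, 0, 4), 1.2, 0, 4)
  seg2 <- coarse_hexagon_segmentation(list(mk_frame(two)),
                                      domain = hexagon_domain(2.2))
  expect_equal(seg2$n_regions, 2L)
  merged <- blob(base, 0, 0, 4, rad = 1.4)
  seg3 <- coarse_hexagon_segmentation(list(mk_frame(merged)),
                                      domain = hexagon_domain(2.2))
  expect_equal(seg3$n_regions, 1L)
})

test_that("mean motor force distinguishes exerting from idle motors", {
  f <- make_filaments(c(0, 0), c(0, 0.3), c(0, 0))
  # no two-bound motors: zero
  st <- make_state(f, make_free_motors(c(0, 1), c(0, 1)))
  expect_equal(mean_motor_force(st)$mean_all, 0)
  # one motor stretched to exactly r = 0.3 at k = 3: 0.9 pN per exerting
  m <- bind_head(make_free_motors(c(0, 1), c(0, 1)), 1, "a", 1, 0)
  m <- bind_head(m, 1, "b", 2, 0)
  st2 <- make_state(f, m)
  mf <- mean_motor_force(st2, stiffness = 3)
  expect_equal(mf$mean_exerting, 0.9)
  expect_equal(mf$n_exerting, 1)
  expect_equal(mf$mean_all, 0.45)     # averaged over both motors
})

test_that("plus-end connectedness equals the brute-force single linkage", {
  one <- make_filaments(rep(0.5, 8), rep(0, 8), rep(pi, 8))  # same plus-end
  expect_equal(plus_end_connectedness(one, radius = 0.1), 1)
  # pairwise farther apart than the radius: singletons
  apart <- make_filaments(seq(0, 9) * 2, rep(0, 10), rep(0, 10))
  expect_equal(plus_end_connectedness(apart, radius = 0.5), 1 / 10)
  # random sets match an independent union-find oracle
  set.seed(10)
  for (rep in 1:5) {
    f <- make_filaments(runif(40, -1, 1), runif(40, -1, 1),
                        runif(40, 0, 2 * pi))
    px <- f$x + 0.5 * cos(f$theta)
    py <- f$y + 0.5 * sin(f$theta)
    expect_equal(plus_end_connectedness(f, radius = 0.3),
                 brute_connectedness(px, py, 0.3))
  }
  # collapsing the same points into a disc strictly raises the fraction
  set.seed(11)
  spread <- make_filaments(runif(100, -2, 2), runif(100, -1.8, 1.8),
                           rep(0, 100))
  collapsed <- spread
  collapsed$x <- runif(100, -0.15, 0.15) - 0.5
  collapsed$y <- runif(100, -0.15, 0.15)
  expect_gt(plus_end_connectedness(collapsed, radius = 0.3),
            plus_end_connectedness(spread, radius = 0.3))
})

test_that("work-energy accounting matches closed forms", {
  cfg <- deterministic_config()
  drags <- drag_coefficients(1, 0.008, 1)
  # no connectors, no motion: all zeros
  f <- make_filaments(0, 0, 0)
  st <- make_state(f, make_free_motors(0.5, 0.5))
  e0 <- energy_accounting(st, st, cfg)
  expect_equal(e0$elastic, 0)
  expect_equal(e0$dissipation, 0)
  # one connector at extension 0.3, k = 3: elastic = 0.5 * 3 * 0.09
  f2 <- make_filaments(c(0, 0), c(0, 0.3), c(0, 0))
  m <- bind_head(make_free_motors(0, 0), 1, "a", 1, 0)
  m <- bind_head(m, 1, "b", 2, 0)
  st2 <- make_state(f2, m)
  e1 <- energy_accounting(st2, st2, cfg)
  expect_equal(e1$elastic, 0.135)
  expect_equal(e1$n_two_bound, 1)
  # pure parallel glide at speed u for one step dissipates G_par u^2 dt
  u <- 0.35
  before <- make_state(make_filaments(0, 0, 0))
  after <- make_state(make_filaments(u * cfg$timestep, 0, 0))
  e2 <- energy_accounting(before, after, cfg)
  expect_equal(e2$dissipation, drags$par * u^2 * cfg$timestep,
               tolerance = 1e-12)
})
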