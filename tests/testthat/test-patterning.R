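test_that("random initial states are contained, counted, and reproducible", {
  cfg <- cortex_config(n_filaments = 50, n_motors = 250, n_crosslinkers = 10)
  set.seed(1)
  st <- init_random(cfg)
  expect_equal(nrow(st$filaments), 50)
  expect_equal(nrow(st$motors), 250)
  expect_equal(nrow(st$crosslinkers), 10)
  expect_true(all(hexagon_contains(st$domain, st$filaments$x,
                                   st$filaments$y)))
  expect_true(all(hexagon_contains(st$domain, st$motors$a_x, st$motors$a_y)))
  expect_true(all(st$motors$a_state == "free"))
  set.seed(1)
  st2 <- init_random(cfg)
  expect_identical(st, st2)
})

test_that("aligned initial states respect the orientation window", {
  cfg <- cortex_config(n_filaments = 1000, n_motors = 10)
  set.seed(2)
  st <- init_aligned(cfg, 0, pi / 8)
  th <- st$filaments$theta
  expect_true(all(th >= 0 & th <= pi / 8))
  expect_lte(max(th) - min(th), pi / 8)
  # closed-form alignment order parameter: E cos 2(theta - mean) = sin(w)/w
  op <- mean(cos(2 * (th - mean(th))))
  expect_equal(op, sin(pi / 8) / (pi / 8), tolerance = 0.005)
  # degenerate window: perfectly parallel
  set.seed(2)
  st0 <- init_aligned(cfg, 0.7, 0.7 + 1e-15)
  expect_equal(sd(st0$filaments$theta), 0, tolerance = 1e-12)
})

test_that("bar initial states split inside and straddling filaments", {
  cfg <- cortex_config(n_filaments = 1000, n_motors = 100,
                       filament_turnover_rate = 0)
  R <- cfg$hexagon_circumradius
  h <- sqrt(3) * R
  bar <- rect_region(-0.6 * R, 0.6 * R, -0.075 * h, 0.075 * h)
  set.seed(3)
  st <- init_bar(cfg, bar, inside_fraction = 0.5)
  f <- st$filaments
  L <- cfg$filament_length
  plus_x <- f$x + L / 2 * cos(f$theta)
  plus_y <- f$y + L / 2 * sin(f$theta)
  minus_x <- f$x - L / 2 * cos(f$theta)
  minus_y <- f$y - L / 2 * sin(f$theta)
  inside <- in_region(bar, plus_x, plus_y) & in_region(bar, minus_x, minus_y)
  expect_equal(sum(inside), 500)
  straddle <- !inside
  expect_true(all(in_region(bar, minus_x[straddle], minus_y[straddle])))
  expect_true(all(!in_region(bar, plus_x[straddle], plus_y[straddle])))
  # all-inside degenerate case
  set.seed(3)
  st1 <- init_bar(cfg, bar, inside_fraction = 1)
  f1 <- st1$filaments
  expect_true(all(in_region(bar, f1$x + L / 2 * cos(f1$theta),
                            f1$y + L / 2 * sin(f1$theta))))
})

test_that("tethering anchors the expected motor fraction permanently", {
  cfg <- cortex_config(n_filaments = 20, n_motors = 4000, n_steps = 80,
                       seed = 4)
  set.seed(4)
  st <- init_random(cfg)
  reg <- bottom_region(st$domain, 1 / 8)
  st <- tether_motors(st, reg)
  frac <- attr(st, "tethered_fraction")
  expect_equal(frac, 1 / 8, tolerance = 0.15)
  expect_equal(mean(st$motors$tethered), frac)
  expect_true(all(st$motors$a_state[st$motors$tethered] == "anchored"))
  # the anchored head never moves over a run
  sim <- simulate_cortex(cfg, state = st)
  teth <- st$motors$tethered
  expect_equal(sim$final_state$motors$a_x[teth], st$motors$a_x[teth])
  expect_equal(sim$final_state$motors$a_y[teth], st$motors$a_y[teth])
  # empty region tethers nothing
  st0 <- tether_motors(init_random(cfg), rect_region(5, 6, 5, 6))
  expect_equal(sum(st0$motors$tethered), 0)
})

test_that("anchored filaments stay exactly in place but still bind heads", {
  cfg <- cortex_config(n_filaments = 1000, n_motors = 200, n_steps = 60,
                       seed = 6)
  set.seed(6)
  st <- init_random(cfg)
  reg <- bottom_region(st$domain, 1 / 4)
  st <- fix_filaments(st, 0.1, reg)
  fixed <- !st$filaments$mobile
  expect_equal(sum(fixed), 100)
  expect_true(all(in_region(reg, st$filaments$x[fixed],
                            st$filaments$y[fixed])))
  sim <- simulate_cortex(cfg, state = st)
  expect_identical(sim$final_state$filaments$x[fixed],
                   st$filaments$x[fixed])
  expect_identical(sim$final_state$filaments$theta[fixed],
                   st$filaments$theta[fixed])
  # immobile filaments participate in binding
  m <- sim$final_state$motors
  bound_to_fixed <- m$a_fil %in% st$filaments$id[fixed] |
    m$b_fil %in% st$filaments$id[fixed]
  expect_gt(sum(bound_to_fixed, na.rm = TRUE), 0)
  # fraction 0 is a no-op
  expect_identical(fix_filaments(st, 0, reg), st)
})
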