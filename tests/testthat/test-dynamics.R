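test_that("attachment points follow the filament frame", {
  f <- make_filaments(0, 0, 0)
  expect_equal(attachment_point(f, 0.5, L = 1), tibble::tibble(x = 0.5, y = 0))
  expect_equal(attachment_point(f, 0), tibble::tibble(x = 0, y = 0))
  f2 <- make_filaments(1, 1, pi / 2)
  p <- attachment_point(f2, 0.25)
  expect_equal(p$x, 1)
  expect_equal(p$y, 1.25)
  expect_error(attachment_point(f, 0.6, L = 1), "out of range")
})

test_that("motor springs are Hookean with the printed maximum force", {
  expect_equal(motor_force(0, 0, 0, 0, 3), tibble::tibble(fx = 0, fy = 0))
  f <- motor_force(0, 0, 0.3, 0, 3)
  expect_equal(f$fx, 0.9)     # k * r: the maximum motor exerted force
  expect_equal(f$fy, 0)
  f2 <- motor_force(1, 1, 1, 0.9, 3)
  expect_equal(c(f2$fx, f2$fy), c(0, -0.3))
})

test_that("slender-rod drag coefficients match closed-form evaluation", {
  d <- drag_coefficients(1, 0.008, 1)
  # p = 125, natural log: independent evaluation frozen to 6 digits
  expect_equal(d$perp, 2.2169504, tolerance = 1e-6)
  expect_equal(d$par, 1.2713044, tolerance = 1e-6)
  expect_equal(d$rot, 0.2513487, tolerance = 1e-6)
  # linear in viscosity
  d2 <- drag_coefficients(1, 0.008, 2)
  expect_equal(d2$par / d$par, 2)
  expect_equal(d2$perp / d$perp, 2)
  expect_equal(d2$rot / d$rot, 2)
  # slender-body limit: perpendicular/parallel ratio tends to 2
  dinf <- drag_coefficients(1, 1e-12, 1)
  expect_equal(dinf$perp / dinf$par, 2, tolerance = 0.05)
  expect_error(drag_coefficients(1, 0.6, 1), "aspect ratio")
})

test_that("drag ordering holds across the physical parameter range", {
  set.seed(5)
  for (i in 1:50) {
    L <- runif(1, 0.25, 3)
    di <- runif(1, 0.004, 0.02)
    eta <- runif(1, 0.1, 10)
    d <- drag_coefficients(L, di, eta)
    expect_gt(d$perp, d$par)
    expect_gt(d$par, 0)
    expect_gt(d$rot, 0)
  }
})

test_that("the overdamped filament update matches hand evaluation", {
  drags <- drag_coefficients(1, 0.008, 1)
  f <- make_filaments(0, 0, 0)
  # zero force: identity
  out <- step_filament(f, 0, 0, 0, drags, 0.01)
  expect_equal(out$x, 0)
  expect_equal(out$theta, 0)
  # parallel force: translation along the axis, no rotation
  out <- step_filament(f, 0.9, 0, 0, drags, 0.01)
  expect_equal(out$x, 0.01 * 0.9 / drags$par)
  expect_equal(out$x, 0.0070794, tolerance = 1e-4)
  expect_equal(out$y, 0)
  expect_equal(out$theta, 0)
  # perpendicular force at the plus-end: translation and rotation
  out <- step_filament(f, 0, 0.9, 0.5 * 0.9, drags, 0.01)
  expect_equal(out$y, 0.0040596, tolerance = 1e-4)
  expect_equal(out$theta, 0.0179033, tolerance = 1e-4)
  expect_equal(out$x, 0)
  # immobile filaments never move
  fi <- make_filaments(0, 0, 0, mobile = FALSE)
  out <- step_filament(fi, 5, 5, 5, drags, 0.01)
  expect_equal(out$x, 0)
  expect_equal(out$theta, 0)
})

test_that("treadmilling displacement reproduces the printed bounds", {
  expect_equal(treadmilling_displacement(0.21, 0.004, 1), 8.4e-4)
  expect_equal(treadmilling_displacement(0.21, 0.007, 1), 1.47e-3)
  expect_equal(treadmilling_displacement(0.21, 0.004, 0.01), 8.4e-6)
  expect_equal(treadmilling_displacement(0.21, 0.007, 0.01), 1.47e-5)
  expect_equal(treadmilling_displacement(0, 0.004, 1), 0)
})

test_that("walking advances bound heads and flags the plus-end", {
  cfg <- deterministic_config()
  f <- make_filaments(0, 0, 0)
  m <- bind_head(make_free_motors(0, 0), 1, "a", fil = 1, len = 0)
  st <- make_state(f, m)
  out <- motor_walk(st, cfg)
  expect_equal(out$motors$a_len, 0.01)
  expect_false(out$motors$a_plus)
  # a head at 0.495 crosses L/2 and is flagged for plus-end release
  m2 <- bind_head(make_free_motors(0, 0), 1, "a", fil = 1, len = 0.495)
  out2 <- motor_walk(make_state(f, m2), cfg)
  expect_equal(out2$motors$a_len, 0.5)
  expect_true(out2$motors$a_plus)
  rel <- motor_release(out2, cfg)
  expect_equal(rel$motors$a_state, "free")
  # v = 0 freezes the walk: a passive crosslink
  cfg0 <- deterministic_config(motor_velocity = 0)
  out3 <- motor_walk(st, cfg0)
  expect_equal(out3$motors$a_len, 0)
})

test_that("release triggers: certain, over-stretch, and none", {
  f <- make_filaments(c(0, 0), c(0, 0.31), c(0, 0))
  # both heads bound, extension 0.31 > r = 0.3: forced release of one head
  m <- bind_head(make_free_motors(0, 0), 1, "a", 1, 0, step = 1)
  m <- bind_head(m, 1, "b", 2, 0, step = 2)
  cfg <- deterministic_config()
  out <- motor_release(make_state(f, m), cfg)
  # the more recently bound head (b) is shed
  expect_equal(out$motors$b_state, "free")
  expect_equal(out$motors$a_state, "bound")
  # certain stochastic release
  cfg1 <- deterministic_config(motor_detach_rate = 100)
  out2 <- motor_release(make_state(f, m), cfg1)
  expect_equal(out2$motors$a_state, "free")
  expect_equal(out2$motors$b_state, "free")
  # no trigger: nothing happens
  f3 <- make_filaments(c(0, 0), c(0, 0.2), c(0, 0))
  out3 <- motor_release(make_state(f3, m), cfg)
  expect_equal(out3$motors$a_state, "bound")
  expect_equal(out3$motors$b_state, "bound")
})

test_that("binding is gated, excludes the partner filament, and respects reach", {
  cfg <- deterministic_config()
  # no filament within reach: motor unchanged
  f <- make_filaments(2, 2, 0)
  st <- make_state(f, make_free_motors(0, 0))
  out <- motor_search_and_bind(st, cfg, step = 1)
  expect_equal(out$motors$a_state, "free")
  # one filament at perpendicular distance 0.1: binds at the projection foot
  f2 <- make_filaments(0, 0.1, 0)
  st2 <- make_state(f2, make_free_motors(0.2, 0))
  out2 <- motor_search_and_bind(st2, cfg, step = 1)
  expect_equal(out2$motors$a_state, "bound")
  expect_equal(out2$motors$a_len, 0.2)    # signed along-filament projection
  # p1 = 0: binding never happens
  cfg0 <- deterministic_config(motor_attach_rate = 0,
                               deterministic_free_capture = FALSE)
  out3 <- motor_search_and_bind(st2, cfg0, step = 1)
  expect_equal(out3$motors$a_state, "free")
  # the partner's filament is never eligible for the second head
  f4 <- make_filaments(0, 0.05, 0)
  m4 <- bind_head(make_free_motors(0, 0), 1, "a", 1, 0)
  out4 <- motor_search_and_bind(make_state(f4, m4), cfg, step = 1)
  expect_equal(out4$motors$b_state, "free")
})

test_that("turnover replaces filaments and severs every bound head", {
  # p2 = 0 leaves everything unchanged
  cfg0 <- deterministic_config()
  f <- make_filaments(c(0, 0.5), c(0, 0), c(0, 1))
  m <- bind_head(make_free_motors(0, 0), 1, "a", 1, 0.1)
  st <- make_state(f, m)
  out <- filament_turnover(st, cfg0, step = 1)
  expect_equal(out$filaments, f)
  # certain turnover: all filaments replaced, all heads freed
  cfgT <- deterministic_config(filament_turnover_rate = 1000)
  set.seed(1)
  out2 <- filament_turnover(st, cfgT, step = 7)
  expect_true(all(out2$filaments$birth_step == 7L))
  expect_equal(out2$motors$a_state, "free")
  expect_true(all(hexagon_contains(st$domain, out2$filaments$x,
                                   out2$filaments$y)))
  # binomial mean: N * p2 * dt replacements per step on average
  cfg5 <- cortex_config(filament_turnover_rate = 5, seed = 1)
  set.seed(2)
  big <- make_state(make_filaments(rep(0, 1000), rep(0, 1000),
                                   rep(0, 1000)))
  counts <- replicate(20, {
    sum(filament_turnover(big, cfg5, step = 1)$filaments$birth_step == 1L)
  })
  expect_equal(mean(counts), 50, tolerance = 0.15)
})

test_that("boundary enforcement re-inserts leavers uniformly inside", {
  cfg <- deterministic_config()
  # all inside: no change
  f <- make_filaments(0, 0, 1)
  st <- make_state(f)
  expect_equal(enforce_boundary(st, cfg)$filaments, f)
  # a filament far outside comes back inside with its orientation preserved
  fo <- make_filaments(3.5, 0, 1.23)
  set.seed(4)
  out <- enforce_boundary(make_state(fo), cfg)
  expect_true(hexagon_contains(st$domain, out$filaments$x, out$filaments$y))
  expect_equal(out$filaments$theta, 1.23)
  # re-insertion positions are uniform over the hexagon (six-sector chi^2)
  set.seed(9)
  pts <- t(replicate(2000, {
    o <- enforce_boundary(make_state(make_filaments(3.5, 0, 0)), cfg)
    c(o$filaments$x, o$filaments$y)
  }))
  sector <- floor((atan2(pts[, 2], pts[, 1]) %% (2 * pi)) / (pi / 3))
  expect_gt(stats::chisq.test(table(sector))$p.value, 0.01)
})

test_that("every two-headed connector obeys Newton's third law", {
  cfg <- deterministic_config()
  set.seed(8)
  for (rep in 1:10) {
    f <- make_filaments(runif(4, -1, 1), runif(4, -1, 1), runif(4, 0, 2 * pi))
    m <- make_free_motors(runif(3, -1, 1), runif(3, -1, 1))
    for (i in 1:3) {
      fils <- sample(4, 2)
      m <- bind_head(m, i, "a", fils[1], runif(1, -0.5, 0.5))
      m <- bind_head(m, i, "b", fils[2], runif(1, -0.5, 0.5))
    }
    forces <- accumulate_forces(make_state(f, m), cfg)
    expect_lt(abs(sum(forces$fx)), 1e-12)
    expect_lt(abs(sum(forces$fy)), 1e-12)
  }
  # no connector spanning two filaments: identically zero
  f <- make_filaments(0, 0, 0)
  m <- bind_head(make_free_motors(0, 0), 1, "a", 1, 0)
  forces <- accumulate_forces(make_state(f, m), cfg)
  expect_equal(forces$fx, 0)
  expect_equal(forces$motor_force, 0)
})

test_that("bound heads only ever walk toward the plus-end", {
  cfg <- deterministic_config()
  f <- make_filaments(0, 0, 0)
  m <- bind_head(make_free_motors(0, 0), 1, "a", 1, -0.4)
  st <- make_state(f, m)
  lens <- numeric(30)
  for (k in 1:30) {
    st <- motor_walk(st, cfg)
    lens[k] <- st$motors$a_len
  }
  expect_true(all(diff(lens) >= 0))
})
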