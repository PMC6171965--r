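test_that("whole trajectories are bit-reproducible under a fixed seed", {
  cfg <- cortex_config(n_filaments = 40, n_motors = 150, n_steps = 120,
                       seed = 17)
  a <- simulate_cortex(cfg)
  b <- simulate_cortex(cfg)
  expect_identical(a$series, b$series)
  expect_identical(a$final_state$filaments, b$final_state$filaments)
  expect_identical(a$final_state$motors, b$final_state$motors)
  c <- simulate_cortex(cfg, seed = 18)
  expect_false(identical(a$series, c$series))
})

test_that("without motors or turnover the filament field is static", {
  cfg <- cortex_config(n_filaments = 25, n_motors = 0,
                       filament_turnover_rate = 0, n_steps = 60, seed = 2)
  sim <- simulate_cortex(cfg)
  expect_equal(sim$final_state$filaments$x, sim$initial_state$filaments$x)
  expect_equal(sim$final_state$filaments$theta,
               sim$initial_state$filaments$theta)
  expect_true(all(sim$series$mean_motor_force == 0))
  expect_true(all(sim$series$elastic_energy == 0))
})

test_that("the engine matches the straight-line reference step to 1e-12", {
  cfg <- deterministic_config(n_steps = 1)
  fil <- make_filaments(c(-0.3, 0.25, 0.1), c(0.05, -0.1, 0.45),
                        c(0.4, 2.2, 5.1))
  mot <- make_free_motors(c(0, 0.15), c(0, 0.2))
  st <- make_state(fil, mot)
  eng <- st
  ref <- st
  for (k in 1:6) {
    eng <- simulate_cortex(cfg, state = eng)$final_state
    ref <- reference_step(ref, cfg, step = k)
  }
  expect_equal(eng$filaments$x, ref$filaments$x, tolerance = 1e-12)
  expect_equal(eng$filaments$y, ref$filaments$y, tolerance = 1e-12)
  expect_equal(eng$filaments$theta, ref$filaments$theta, tolerance = 1e-12)
  expect_identical(eng$motors$a_state, ref$motors$a_state)
  expect_identical(eng$motors$b_state, ref$motors$b_state)
  expect_equal(eng$motors$a_len, ref$motors$a_len, tolerance = 1e-12)
  expect_equal(eng$motors$b_len, ref$motors$b_len, tolerance = 1e-12)
})

test_that("motor state bookkeeping stays sound through a stochastic run", {
  cfg <- cortex_config(n_filaments = 60, n_motors = 200, n_steps = 150,
                       filament_turnover_rate = 3, seed = 23)
  sim <- simulate_cortex(cfg)
  m <- sim$final_state$motors
  # no motor is simultaneously free and holding a filament id
  expect_true(all(is.na(m$a_fil[m$a_state == "free"])))
  expect_true(all(is.na(m$b_fil[m$b_state == "free"])))
  bound_a <- m$a_state == "bound"
  expect_true(all(m$a_fil[bound_a] %in% sim$final_state$filaments$id))
  expect_true(all(abs(m$a_len[bound_a]) <= cfg$filament_length / 2 + 1e-12))
  # state counts always partition the motor population
  expect_true(all(sim$series$n_two_bound + sim$series$n_one_bound +
                    sim$series$n_free == cfg$n_motors))
  # all agents inside the domain at the end
  expect_true(all(hexagon_contains(sim$final_state$domain,
                                   sim$final_state$filaments$x,
                                   sim$final_state$filaments$y)))
})

test_that("recorded motor forces never exceed the stretch threshold force", {
  cfg <- cortex_config(n_filaments = 80, n_motors = 300, n_steps = 200,
                       seed = 5)
  sim <- simulate_cortex(cfg)
  expect_lte(sim$max_motor_force,
             cfg$motor_stiffness * cfg$motor_reach + 1e-9)
  expect_gt(sim$max_motor_force, 0)
})

test_that("scheduled switches apply mid-run and a no-op schedule is inert", {
  base <- cortex_config(n_filaments = 40, n_motors = 120, n_steps = 100,
                        seed = 31)
  plain <- simulate_cortex(base)
  # an entry beyond the horizon changes nothing
  late <- schedule_switch(base, 1000, "motor_stiffness", 99)
  expect_identical(simulate_cortex(late)$series, plain$series)
  # freezing the motors mid-run kills binding afterwards
  off <- schedule_switch(base, 50, "motor_attach_rate", 0)
  soff <- simulate_cortex(off)
  expect_identical(soff$series$mean_motor_force[1:50],
                   plain$series$mean_motor_force[1:50])
  # a length switch releases heads stranded beyond the new tip
  shrink <- schedule_switch(base, 50, "filament_length", 0.5)
  sshr <- simulate_cortex(shrink)
  m <- sshr$final_state$motors
  bound <- m$a_state == "bound"
  expect_true(all(abs(m$a_len[bound]) <= 0.25 + 1e-12))
})
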