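# Small hand-built states used across the unit tests.

make_filaments <- function(x, y, theta, mobile = TRUE) {
  tibble::tibble(id = seq_along(x), x = x, y = y, theta = theta,
                 mobile = mobile, birth_step = 0L)
}

# motors placed fully free at given points
make_free_motors <- function(x, y) {
  m <- cortexsim:::empty_motors(length(x))
  m$a_x <- m$b_x <- x
  m$a_y <- m$b_y <- y
  m
}

make_state <- function(filaments, motors = make_free_motors(numeric(0), numeric(0)),
                       crosslinkers = cortexsim:::empty_crosslinkers(0),
                       R = 2.2) {
  cortex_state(filaments, motors, crosslinkers, hexagon_domain(R))
}

# bind a motor head by hand
bind_head <- function(motors, i, head, fil, len, step = 0L) {
  motors[[paste0(head, "_state")]][i] <- "bound"
  motors[[paste0(head, "_fil")]][i] <- fil
  motors[[paste0(head, "_len")]][i] <- len
  motors[[paste0(head, "_bind_step")]][i] <- as.integer(step)
  motors
}

# a configuration whose per-step event probabilities are all 0 or 1 and with
# no free diffusion: consumes no randomness, so engine and reference agree
# bit-for-bit
deterministic_config <- function(...) {
  defaults <- list(n_filaments = 3, n_motors = 2, n_steps = 1,
                   motor_attach_rate = 200, motor_detach_rate = 0,
                   filament_turnover_rate = 0,
                   free_motor_diffusion_step = 0,
                   binding_site = "nearest", record_stride = 0, seed = 1)
  dots <- list(...)
  defaults[names(dots)] <- dots
  do.call(cortex_config, defaults)
}

# an ideal synthetic aster: n filaments whose plus-ends cluster around
# `center` and whose orientations point into the cluster
ideal_aster_filaments <- function(n = 200, center = c(0, 0), core_r = 0.08,
                                  L = 1) {
  phi <- stats::runif(n, 0, 2 * pi)         # direction from which each comes
  rho <- stats::runif(n, 0, core_r)
  px <- center[1] + rho * cos(phi)
  py <- center[2] + rho * sin(phi)
  theta <- phi + pi                          # pointing inward
  make_filaments(px - (L / 2) * cos(theta), py - (L / 2) * sin(theta), theta)
}

# brute-force single-linkage largest-cluster fraction (union-find)
brute_connectedness <- function(px, py, radius) {
  n <- length(px)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && (px[i] - px[j])^2 + (py[i] - py[j])^2 <= radius^2) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  max(table(roots)) / n
}
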