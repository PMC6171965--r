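# Transparent single-step reference implementation of the engine. Written as
# straight-line R over the state tibbles with brute-force neighbour search; it
# shares no code path with the compiled engine and is used to validate it
# (small instances agree to 1e-12). The exported per-phase operations are also
# the unit-testable surface of the kinetics rules.

# search position of a free head: its own stored coordinates, or (when the
# spring is modelled taut, free_head_follows) the position of a load-bearing
# partner head
free_head_search_pos <- function(m, i, h, filaments, follows = TRUE) {
  o <- if (h == "a") "b" else "a"
  ost <- m[[paste0(o, "_state")]][i]
  if (follows && ost == "bound") {
    f <- filaments[match(m[[paste0(o, "_fil")]][i], filaments$id), ]
    attachment_point(f, m[[paste0(o, "_len")]][i])
  } else if (follows && ost == "anchored") {
    tibble::tibble(x = m[[paste0(o, "_x")]][i], y = m[[paste0(o, "_y")]][i])
  } else {
    tibble::tibble(x = m[[paste0(h, "_x")]][i], y = m[[paste0(h, "_y")]][i])
  }
}

#' Stochastic motor search and capture
#'
#' Each free head independently attaches, with per-step probability
#' `p1 * dt` (clipped to 1), to the nearest filament segment within the
#' search radius `r` of its current position, excluding the filament already
#' bound by the partner head. Binding sets the walk coordinate to the signed
#' along-filament coordinate of the closest point. A fully free motor can
#' capture two different filaments in one step.
#'
#' @param state A [cortex_state()].
#' @param config A [cortex_config()].
#' @param step Current step number (stored as the head's binding step).
#' @return The updated state.
#' @export
motor_search_and_bind <- function(state, config, step = 0L) {
  m <- state$motors
  f <- state$filaments
  P <- min(1, config$motor_attach_rate * config$timestep)
  L <- config$filament_length
  r <- config$motor_reach
  nearest_excl <- function(px, py, excl) {
    ps <- point_segment_distance(px, py, f$x, f$y, f$theta, L)
    d <- ps$dist
    d[!is.na(excl) & f$id == excl] <- Inf
    if (config$binding_site == "random") {
      cand <- which(d <= r)
      if (!length(cand)) return(NULL)
      pick <- cand[min(length(cand), floor(stats::runif(1) * length(cand)) + 1)]
      return(list(fil = f$id[pick], t = ps$t[pick]))
    }
    best <- which.min(d)
    if (length(best) && d[best] <= r) list(fil = f$id[best], t = ps$t[best])
    else NULL
  }
  for (i in seq_len(nrow(m))) {
    if (config$deterministic_free_capture &&
        m$a_state[i] == "free" && m$b_state[i] == "free") {
      hit <- nearest_excl(m$a_x[i], m$a_y[i], NA_integer_)
      if (!is.null(hit)) {
        m$a_state[i] <- "bound"; m$a_fil[i] <- hit$fil
        m$a_len[i] <- hit$t; m$a_bind_step[i] <- as.integer(step)
        if (rbern(P)) {
          hit2 <- nearest_excl(m$a_x[i], m$a_y[i], hit$fil)
          if (!is.null(hit2)) {
            m$b_state[i] <- "bound"; m$b_fil[i] <- hit2$fil
            m$b_len[i] <- hit2$t; m$b_bind_step[i] <- as.integer(step)
          }
        }
      }
      next
    }
    for (h in c("a", "b")) {
      if (m[[paste0(h, "_state")]][i] != "free") next
      if (!rbern(P)) next
      pos <- free_head_search_pos(m, i, h, f, config$free_head_follows)
      o <- if (h == "a") "b" else "a"
      excl <- if (m[[paste0(o, "_state")]][i] == "bound")
        m[[paste0(o, "_fil")]][i] else NA_integer_
      hit <- nearest_excl(pos$x, pos$y, excl)
      if (!is.null(hit)) {
        m[[paste0(h, "_state")]][i] <- "bound"
        m[[paste0(h, "_fil")]][i] <- hit$fil
        m[[paste0(h, "_len")]][i] <- hit$t
        m[[paste0(h, "_bind_step")]][i] <- as.integer(step)
      }
    }
  }
  state$motors <- m
  state
}

#' Plus-end directed motor walking
#'
#' Every bound head advances its walk coordinate by `v * dt`. A head reaching
#' the plus-end (`len >= L/2`) is clamped there and flagged for release in
#' the same step's release phase.
#'
#' @inheritParams motor_search_and_bind
#' @return The updated state; plus-end flags in columns `a_plus`, `b_plus`.
#' @export
motor_walk <- function(state, config) {
  m <- state$motors
  L <- config$filament_length
  dl <- config$motor_velocity * config$timestep
  for (h in c("a", "b")) {
    o <- if (h == "a") "b" else "a"
    st <- m[[paste0(h, "_state")]]
    lc <- paste0(h, "_len")
    bound <- st == "bound"
    m[[lc]][bound] <- m[[lc]][bound] + dl
    plus <- bound & m[[lc]] >= L / 2
    plus[is.na(plus)] <- FALSE
    m[[lc]][plus] <- L / 2
    if (isTRUE(config$tethered_tip_hold)) {
      plus <- plus & m[[paste0(o, "_state")]] != "anchored"
    }
    m[[paste0(h, "_plus")]] <- plus
  }
  state$motors <- m
  state
}

release_head_r <- function(m, i, h, filaments) {
  f <- filaments[match(m[[paste0(h, "_fil")]][i], filaments$id), ]
  pos <- attachment_point(f, m[[paste0(h, "_len")]][i])
  m[[paste0(h, "_state")]][i] <- "free"
  m[[paste0(h, "_fil")]][i] <- NA_integer_
  m[[paste0(h, "_len")]][i] <- NA_real_
  m[[paste0(h, "_bind_step")]][i] <- NA_integer_
  m[[paste0(h, "_x")]][i] <- pos$x
  m[[paste0(h, "_y")]][i] <- pos$y
  if (paste0(h, "_plus") %in% names(m)) m[[paste0(h, "_plus")]][i] <- FALSE
  m
}

#' Motor release rules
#'
#' A bound head detaches when flagged at the plus-end, or stochastically with
#' per-step probability `p0 * dt`. Afterwards, any motor whose two
#' load-bearing heads are separated by more than the stretch threshold `r`
#' force-releases one head: the more recently bound one (ties broken at
#' random; a tethered motor always sheds its filament-bound head). A motor
#' losing one head keeps walking on the other; losing both joins the
#' diffusing pool.
#'
#' @inheritParams motor_search_and_bind
#' @return The updated state.
#' @export
motor_release <- function(state, config) {
  m <- state$motors
  f <- state$filaments
  P0 <- min(1, config$motor_detach_rate * config$timestep)
  r <- config$motor_reach
  for (i in seq_len(nrow(m))) {
    for (h in c("a", "b")) {
      if (m[[paste0(h, "_state")]][i] != "bound") next
      plus_col <- paste0(h, "_plus")
      if (plus_col %in% names(m) && isTRUE(m[[plus_col]][i])) {
        m <- release_head_r(m, i, h, f)
        next
      }
      if (rbern(P0)) m <- release_head_r(m, i, h, f)
    }
    if (m$a_state[i] != "free" && m$b_state[i] != "free") {
      pa <- head_pos_r(m, i, "a", f)
      pb <- head_pos_r(m, i, "b", f)
      d <- sqrt((pa$x - pb$x)^2 + (pa$y - pb$y)^2)
      if (d > r) {
        h <- if (m$a_state[i] == "anchored") "b"
        else if (m$b_state[i] == "anchored") "a"
        else {
          ba <- m$a_bind_step[i]; bb <- m$b_bind_step[i]
          if (ba > bb) "a" else if (bb > ba) "b"
          else if (stats::runif(1) < 0.5) "a" else "b"
        }
        m <- release_head_r(m, i, h, f)
      }
    }
  }
  state$motors <- m
  state
}

head_pos_r <- function(m, i, h, filaments) {
  if (m[[paste0(h, "_state")]][i] == "bound") {
    f <- filaments[match(m[[paste0(h, "_fil")]][i], filaments$id), ]
    attachment_point(f, m[[paste0(h, "_len")]][i])
  } else {
    tibble::tibble(x = m[[paste0(h, "_x")]][i], y = m[[paste0(h, "_y")]][i])
  }
}

#' Stochastic whole-filament turnover
#'
#' Each eligible filament is independently replaced, with per-step
#' probability `p2 * dt`, by a new filament at a uniform-random position and
#' orientation; every motor and cross-linker head bound to it is released at
#' its old attachment point. Immobile filaments are exempt when
#' `turnover_exempt_immobile` is set (the patterned-substrate experiments).
#'
#' @inheritParams motor_search_and_bind
#' @return The updated state.
#' @export
filament_turnover <- function(state, config, step = 0L) {
  f <- state$filaments
  P <- min(1, config$filament_turnover_rate * config$timestep)
  turned <- logical(nrow(f))
  old <- f
  for (i in seq_len(nrow(f))) {
    eligible <- f$mobile[i] || !config$turnover_exempt_immobile
    if (!eligible) next
    if (rbern(P)) {
      turned[i] <- TRUE
      np <- sample_hexagon(state$domain, 1)
      f$x[i] <- np$x
      f$y[i] <- np$y
      f$theta[i] <- stats::runif(1, 0, 2 * pi)
      f$birth_step[i] <- as.integer(step)
    }
  }
  if (any(turned)) {
    turned_ids <- f$id[turned]
    m <- state$motors
    for (i in seq_len(nrow(m))) {
      for (h in c("a", "b")) {
        if (m[[paste0(h, "_state")]][i] == "bound" &&
            m[[paste0(h, "_fil")]][i] %in% turned_ids) {
          m <- release_head_r(m, i, h, old)
        }
      }
    }
    state$motors <- m
    x <- state$crosslinkers
    hit <- x$state == "bound" & (x$a_fil %in% turned_ids |
                                 x$b_fil %in% turned_ids)
    for (i in which(hit)) x <- release_xl_r(x, i, old)
    state$crosslinkers <- x
  }
  state$filaments <- f
  state
}

release_xl_r <- function(x, i, filaments) {
  fa <- filaments[match(x$a_fil[i], filaments$id), ]
  fb <- filaments[match(x$b_fil[i], filaments$id), ]
  pa <- attachment_point(fa, x$a_len[i])
  pb <- attachment_point(fb, x$b_len[i])
  x$state[i] <- "free"
  x$x[i] <- (pa$x + pb$x) / 2
  x$y[i] <- (pa$y + pb$y) / 2
  x$a_fil[i] <- NA_integer_; x$a_len[i] <- NA_real_
  x$b_fil[i] <- NA_integer_; x$b_len[i] <- NA_real_
  x
}

#' Open-boundary enforcement
#'
#' Any mobile filament whose centre has left the hexagon is re-inserted at a
#' uniform-random interior position (orientation preserved) and its bound
#' heads are severed first, so no spring is teleported. Fully free motors and
#' free cross-linkers outside the domain are re-inserted uniformly.
#'
#' @inheritParams motor_search_and_bind
#' @return The updated state.
#' @export
enforce_boundary <- function(state, config) {
  f <- state$filaments
  m <- state$motors
  x <- state$crosslinkers
  dom <- state$domain
  out <- f$mobile & !hexagon_contains(dom, f$x, f$y)
  for (i in which(out)) {
    for (j in seq_len(nrow(m))) {
      for (h in c("a", "b")) {
        if (m[[paste0(h, "_state")]][j] == "bound" &&
            m[[paste0(h, "_fil")]][j] == f$id[i]) {
          m <- release_head_r(m, j, h, f)
        }
      }
    }
    hit <- which(x$state == "bound" &
                 (x$a_fil == f$id[i] | x$b_fil == f$id[i]))
    for (j in hit) x <- release_xl_r(x, j, f)
    np <- sample_hexagon(dom, 1)
    f$x[i] <- np$x
    f$y[i] <- np$y
  }
  for (j in seq_len(nrow(m))) {
    if (m$a_state[j] == "free" && m$b_state[j] == "free" &&
        !hexagon_contains(dom, m$a_x[j], m$a_y[j])) {
      np <- sample_hexagon(dom, 1)
      m$a_x[j] <- m$b_x[j] <- np$x
      m$a_y[j] <- m$b_y[j] <- np$y
    }
  }
  for (j in which(x$state == "free")) {
    if (!hexagon_contains(dom, x$x[j], x$y[j])) {
      np <- sample_hexagon(dom, 1)
      x$x[j] <- np$x
      x$y[j] <- np$y
    }
  }
  state$filaments <- f
  state$motors <- m
  state$crosslinkers <- x
  state
}

#' Cross-linker search and capture
#'
#' A free cross-linker, with per-step probability `rate * dt`, scans the
#' filaments within the motor search radius of its position and binds both
#' heads atomically at the mutually closest points of the closest eligible
#' pair: inter-segment distance at most `crosslinker_reach` and polarity-aware
#' orientation difference at most `crosslinker_angle_tol` (anti-parallel
#' filaments never qualify). The walk coordinates are frozen at binding.
#'
#' @inheritParams motor_search_and_bind
#' @return The updated state.
#' @export
crosslinker_search_and_bind <- function(state, config) {
  x <- state$crosslinkers
  f <- state$filaments
  P <- min(1, config$crosslinker_attach_rate * config$timestep)
  L <- config$filament_length
  for (i in which(x$state == "free")) {
    if (!rbern(P)) next
    ps <- point_segment_distance(x$x[i], x$y[i], f$x, f$y, f$theta, L)
    near <- which(ps$dist <= config$motor_reach)
    best <- NULL
    best_d <- config$crosslinker_reach
    if (length(near) >= 2) {
      for (a in seq_len(length(near) - 1)) {
        for (b in (a + 1):length(near)) {
          fi <- near[a]; fj <- near[b]
          if (orientation_difference(f$theta[fi], f$theta[fj]) >
              config$crosslinker_angle_tol) next
          ss <- segment_segment_closest(f$x[fi], f$y[fi], f$theta[fi],
                                        f$x[fj], f$y[fj], f$theta[fj], L)
          ok <- if (is.null(best)) ss$dist <= best_d else ss$dist < best_d
          if (ok) {
            best <- list(fi = fi, fj = fj, t1 = ss$t1, t2 = ss$t2)
            best_d <- ss$dist
          }
        }
      }
    }
    if (!is.null(best)) {
      x$state[i] <- "bound"
      x$a_fil[i] <- f$id[best$fi]; x$a_len[i] <- best$t1
      x$b_fil[i] <- f$id[best$fj]; x$b_len[i] <- best$t2
    }
  }
  state$crosslinkers <- x
  state
}

#' Cross-linker release and spring force
#'
#' `crosslinker_release()` applies the stochastic unbinding rate (0 by
#' default: bound cross-linkers remain fixed) and force-releases any
#' cross-linker stretched past its reach. `crosslinker_force()` returns the
#' equal-and-opposite Hookean forces a bound cross-linker exerts at its two
#' attachment points.
#'
#' @inheritParams motor_search_and_bind
#' @return `crosslinker_release()`: the updated state;
#'   `crosslinker_force()`: a tibble with one row per bound cross-linker
#'   (`id`, attachment points, `fx_a`, `fy_a`, `fx_b`, `fy_b`, `magnitude`).
#' @export
crosslinker_release <- function(state, config) {
  x <- state$crosslinkers
  f <- state$filaments
  P0 <- min(1, config$crosslinker_detach_rate * config$timestep)
  for (i in which(x$state == "bound")) {
    if (rbern(P0)) { x <- release_xl_r(x, i, f); next }
    fa <- f[match(x$a_fil[i], f$id), ]
    fb <- f[match(x$b_fil[i], f$id), ]
    pa <- attachment_point(fa, x$a_len[i])
    pb <- attachment_point(fb, x$b_len[i])
    if (sqrt((pa$x - pb$x)^2 + (pa$y - pb$y)^2) > config$crosslinker_reach) {
      x <- release_xl_r(x, i, f)
    }
  }
  state$crosslinkers <- x
  state
}

#' @rdname crosslinker_release
#' @export
crosslinker_force <- function(state, config) {
  x <- state$crosslinkers
  f <- state$filaments
  k <- config$crosslinker_stiffness
  bound <- which(x$state == "bound")
  out <- lapply(bound, function(i) {
    fa <- f[match(x$a_fil[i], f$id), ]
    fb <- f[match(x$b_fil[i], f$id), ]
    pa <- attachment_point(fa, x$a_len[i])
    pb <- attachment_point(fb, x$b_len[i])
    tibble::tibble(
      id = x$id[i], ax = pa$x, ay = pa$y, bx = pb$x, by = pb$y,
      fx_a = k * (pb$x - pa$x), fy_a = k * (pb$y - pa$y),
      fx_b = k * (pa$x - pb$x), fy_b = k * (pa$y - pb$y),
      magnitude = k * sqrt((pa$x - pb$x)^2 + (pa$y - pb$y)^2))
  })
  dplyr::bind_rows(out)
}

#' Force accumulation over connectors
#'
#' Sums the Hookean forces of all load-bearing motors and bound cross-linkers
#' onto their filaments, together with the torque lever terms
#' `len * F_perp`, and tallies the per-motor force magnitudes and total
#' elastic energy. Motors exert force only when both heads are load-bearing.
#'
#' @inheritParams motor_search_and_bind
#' @return A list: per-filament `fx`, `fy`, `torque`; per-motor `motor_force`
#'   (pN); `elastic` (pN um).
#' @export
accumulate_forces <- function(state, config) {
  f <- state$filaments
  m <- state$motors
  n <- nrow(f)
  fx <- fy <- tq <- numeric(n)
  mf <- numeric(nrow(m))
  elastic <- 0
  add_force <- function(fid, len, fxc, fyc) {
    i <- match(fid, f$id)
    fx[i] <<- fx[i] + fxc
    fy[i] <<- fy[i] + fyc
    tq[i] <<- tq[i] + len * (-sin(f$theta[i]) * fxc + cos(f$theta[i]) * fyc)
  }
  for (i in seq_len(nrow(m))) {
    if (m$a_state[i] == "free" || m$b_state[i] == "free") next
    pa <- head_pos_r(m, i, "a", f)
    pb <- head_pos_r(m, i, "b", f)
    dx <- pb$x - pa$x
    dy <- pb$y - pa$y
    k <- config$motor_stiffness
    mf[i] <- k * sqrt(dx^2 + dy^2)
    elastic <- elastic + 0.5 * k * (dx^2 + dy^2)
    if (m$a_state[i] == "bound") add_force(m$a_fil[i], m$a_len[i],
                                           k * dx, k * dy)
    if (m$b_state[i] == "bound") add_force(m$b_fil[i], m$b_len[i],
                                           -k * dx, -k * dy)
  }
  xf <- crosslinker_force(state, config)
  if (nrow(xf)) {
    x <- state$crosslinkers
    for (j in seq_len(nrow(xf))) {
      i <- match(xf$id[j], x$id)
      add_force(x$a_fil[i], x$a_len[i], xf$fx_a[j], xf$fy_a[j])
      add_force(x$b_fil[i], x$b_len[i], xf$fx_b[j], xf$fy_b[j])
      elastic <- elastic +
        0.5 * config$crosslinker_stiffness *
          ((xf$ax[j] - xf$bx[j])^2 + (xf$ay[j] - xf$by[j])^2)
    }
  }
  list(fx = fx, fy = fy, torque = tq, motor_force = mf, elastic = elastic)
}

#' One reference step of the full model
#'
#' A transparent, brute-force implementation of a single engine step in the
#' documented phase order: free diffusion, motor search/bind, cross-linker
#' search/bind, walk, release checks, force accumulation, overdamped filament
#' update, turnover, boundary enforcement. It shares no code with the
#' compiled engine and exists to validate it; on deterministic
#' configurations (all per-step event probabilities 0 or 1 and zero free
#' diffusion) the two agree to machine precision.
#'
#' @inheritParams motor_search_and_bind
#' @return The updated state, with attributes `forces` (the
#'   [accumulate_forces()] output) and `dissipation` (pN um).
#' @export
reference_step <- function(state, config, step = 1L) {
  m <- state$motors
  ds <- config$free_motor_diffusion_step
  if (ds > 0) {
    for (i in seq_len(nrow(m))) {
      if (m$a_state[i] == "free" && m$b_state[i] == "free") {
        ang <- stats::runif(1, 0, 2 * pi)
        m$a_x[i] <- m$b_x[i] <- m$a_x[i] + ds * cos(ang)
        m$a_y[i] <- m$b_y[i] <- m$a_y[i] + ds * sin(ang)
      }
    }
    x <- state$crosslinkers
    for (i in which(x$state == "free")) {
      ang <- stats::runif(1, 0, 2 * pi)
      x$x[i] <- x$x[i] + ds * cos(ang)
      x$y[i] <- x$y[i] + ds * sin(ang)
    }
    state$crosslinkers <- x
  }
  state$motors <- m
  state <- motor_search_and_bind(state, config, step)
  state <- crosslinker_search_and_bind(state, config)
  state <- motor_walk(state, config)
  state <- motor_release(state, config)
  state <- crosslinker_release(state, config)
  forces <- accumulate_forces(state, config)
  drags <- drag_coefficients(config$filament_length,
                             config$filament_diameter,
                             config$dynamic_viscosity)
  state$filaments <- step_filament(state$filaments, forces$fx, forces$fy,
                                   forces$torque, drags, config$timestep)
  dissip <- attr(state$filaments, "dissipation")
  state <- filament_turnover(state, config, step)
  state <- enforce_boundary(state, config)
  attr(state, "forces") <- forces
  attr(state, "dissipation") <- dissip
  state
}
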