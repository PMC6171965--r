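#' Random initial configuration
#'
#' Places the configured number of filaments at uniform-random positions with
#' orientations uniform on `[0, 2*pi)`, and all motors and cross-linkers
#' fully free at uniform-random positions inside the hexagonal domain. This
#' is the disordered starting condition of every standard experiment.
#'
#' @param config A [cortex_config()].
#' @return A [cortex_state()].
#' @export
#' @examples
#' set.seed(1)
#' st <- init_random(cortex_config(n_filaments = 50, n_motors = 250))
init_random <- function(config) {
  domain <- hexagon_domain(config$hexagon_circumradius)
  fp <- sample_hexagon(domain, config$n_filaments)
  filaments <- tibble::tibble(
    id = seq_len(config$n_filaments),
    x = fp$x, y = fp$y,
    theta = stats::runif(config$n_filaments, 0, 2 * pi),
    mobile = TRUE, birth_step = 0L)
  motors <- empty_motors(config$n_motors)
  mp <- sample_hexagon(domain, config$n_motors)
  motors$a_x <- motors$b_x <- mp$x
  motors$a_y <- motors$b_y <- mp$y
  xl <- empty_crosslinkers(config$n_crosslinkers)
  xp <- sample_hexagon(domain, config$n_crosslinkers)
  xl$x <- xp$x
  xl$y <- xp$y
  cortex_state(filaments, motors, xl, domain)
}

#' Aligned initial filaments
#'
#' Like [init_random()] but with filament orientations drawn uniformly from
#' `[angle_lo, angle_hi]`, emulating a pre-aligned array (e.g. all filaments
#' co-oriented within 22.5 degrees).
#'
#' @param config A [cortex_config()].
#' @param angle_lo,angle_hi Orientation window (rad), `angle_lo <= angle_hi`.
#' @return A [cortex_state()].
#' @export
init_aligned <- function(config, angle_lo = 0, angle_hi = pi / 8) {
  stopifnot(angle_lo <= angle_hi)
  st <- init_random(config)
  st$filaments$theta <-
    stats::runif(nrow(st$filaments), angle_lo, angle_hi)
  st
}

#' Filaments nucleated on a fixed bar
#'
#' Emulates microcontact-printed nucleators: `inside_fraction` of the
#' filaments lie entirely inside a rectangular bar, and the remainder have
#' their minus-end uniform inside the bar with the plus-end pointing away
#' from the bar's long axis (outside it). Motors and cross-linkers start
#' uniform over the whole domain. In the reference experiment the nucleated
#' filaments are stabilised against depolymerisation but free to be
#' remodelled by motors, so the matching preset sets the turnover rate to
#' zero and leaves them mobile; pass `mobile = FALSE` to pin them in place
#' instead.
#'
#' @param config A [cortex_config()].
#' @param bar A [rect_region()] inside the hexagon. Default: a horizontal bar
#'   spanning 60% of the domain width and 15% of its height, centred.
#' @param inside_fraction Fraction of filaments entirely inside the bar.
#' @param mobile Whether the bar filaments may move once motors engage.
#' @return A [cortex_state()].
#' @export
init_bar <- function(config, bar = NULL, inside_fraction = 0.5,
                     mobile = TRUE) {
  stopifnot(inside_fraction >= 0, inside_fraction <= 1)
  domain <- hexagon_domain(config$hexagon_circumradius)
  if (is.null(bar)) {
    R <- config$hexagon_circumradius
    h <- sqrt(3) * R
    bar <- rect_region(-0.6 * R, 0.6 * R, -0.075 * h, 0.075 * h)
  }
  N <- config$n_filaments
  L <- config$filament_length
  n_in <- round(inside_fraction * N)
  runif_rect <- function(n) {
    tibble::tibble(x = stats::runif(n, bar$xmin, bar$xmax),
                   y = stats::runif(n, bar$ymin, bar$ymax))
  }
  # fully-inside filaments: centre margin L/2 from the bar edge where possible
  shrink <- rect_region(
    min(bar$xmin + L / 2, (bar$xmin + bar$xmax) / 2),
    max(bar$xmax - L / 2, (bar$xmin + bar$xmax) / 2),
    bar$ymin, bar$ymax)
  cin <- tibble::tibble(x = stats::runif(n_in, shrink$xmin, shrink$xmax),
                        y = stats::runif(n_in, shrink$ymin, shrink$ymax))
  th_in <- ifelse(stats::runif(n_in) < 0.5, 0, pi)   # lie along the bar
  # straddling filaments: minus-end in the bar, plus-end pointing outward
  n_out <- N - n_in
  minus <- runif_rect(n_out)
  mid_y <- (bar$ymin + bar$ymax) / 2
  th_out <- ifelse(minus$y >= mid_y,
                   stats::runif(n_out, pi / 4, 3 * pi / 4),       # upward
                   stats::runif(n_out, -3 * pi / 4, -pi / 4))     # downward
  filaments <- tibble::tibble(
    id = seq_len(N),
    x = c(cin$x, minus$x + (L / 2) * cos(th_out)),
    y = c(cin$y, minus$y + (L / 2) * sin(th_out)),
    theta = c(th_in, th_out),
    mobile = mobile, birth_step = 0L)
  motors <- empty_motors(config$n_motors)
  mp <- sample_hexagon(domain, config$n_motors)
  motors$a_x <- motors$b_x <- mp$x
  motors$a_y <- motors$b_y <- mp$y
  xl <- empty_crosslinkers(config$n_crosslinkers)
  if (config$n_crosslinkers > 0) {
    xp <- sample_hexagon(domain, config$n_crosslinkers)
    xl$x <- xp$x
    xl$y <- xp$y
  }
  cortex_state(filaments, motors, xl, domain)
}

#' Tether motors inside a region
#'
#' Every motor whose current position lies in `region` becomes tethered: its
#' `a` head is permanently anchored at that point (it never walks and never
#' releases) while the `b` head follows normal kinetics. Emulates
#' microcontact-printed myosin.
#'
#' @param state A [cortex_state()].
#' @param region A [cortex_region][rect_region()].
#' @return The state with tethered motors; the tethered fraction is attached
#'   as attribute `tethered_fraction`.
#' @export
tether_motors <- function(state, region) {
  m <- state$motors
  sel <- m$a_state == "free" & m$b_state == "free" &
    in_region(region, m$a_x, m$a_y)
  m$tethered[sel] <- TRUE
  m$a_state[sel] <- "anchored"
  state$motors <- m
  attr(state, "tethered_fraction") <- mean(sel)
  state
}

#' Anchor a fraction of filaments inside a region
#'
#' Re-places `fraction` of the filaments at uniform-random positions inside
#' `region` (rejection-sampled against the hexagon) and flags them immobile;
#' they still bind motors and cross-linkers, and under the default
#' configuration are exempt from turnover.
#'
#' @param state A [cortex_state()].
#' @param fraction Fraction of filaments to anchor, in `[0, 1]`.
#' @param region A [cortex_region][rect_region()].
#' @return The updated state.
#' @export
fix_filaments <- function(state, fraction, region) {
  stopifnot(fraction >= 0, fraction <= 1)
  n <- round(fraction * nrow(state$filaments))
  if (n == 0) return(state)
  idx <- seq_len(n)            # deterministic choice: the first n filaments
  pts <- matrix(NA_real_, n, 2)
  got <- 0
  while (got < n) {
    cand <- sample_hexagon(state$domain, 4 * (n - got))
    keep <- which(in_region(region, cand$x, cand$y))
    take <- utils::head(keep, n - got)
    if (length(take)) {
      pts[got + seq_along(take), ] <- cbind(cand$x[take], cand$y[take])
      got <- got + length(take)
    }
  }
  state$filaments$x[idx] <- pts[, 1]
  state$filaments$y[idx] <- pts[, 2]
  state$filaments$mobile[idx] <- FALSE
  state
}

#' Schedule a mid-run parameter switch
#'
#' Appends an entry to the configuration's switch schedule: at the end of
#' `step`, `field` is replaced by `value`. Switchable fields:
#' `motor_stiffness`, `motor_reach`, `filament_length`, `motor_velocity`,
#' `motor_detach_rate`, `motor_attach_rate`, `filament_turnover_rate`,
#' `dynamic_viscosity`. A filament-length switch rescales filaments about
#' their centres (drag coefficients are recomputed) and releases any head
#' whose walk coordinate would lie beyond the new tip.
#'
#' @param config A [cortex_config()].
#' @param step Step after which the new value applies.
#' @param field Parameter name.
#' @param value New value.
#' @return The updated configuration.
#' @export
#' @examples
#' cfg <- cortex_config(n_steps = 2000)
#' cfg <- schedule_switch(cfg, 1000, "filament_turnover_rate", 5)
schedule_switch <- function(config, step, field, value) {
  stopifnot(inherits(config, "cortex_config"))
  if (!field %in% switchable_fields) {
    stop("`", field, "` is not switchable; valid fields: ",
         paste(switchable_fields, collapse = ", "), call. = FALSE)
  }
  config$switch_schedule <- dplyr::bind_rows(
    config$switch_schedule,
    tibble::tibble(step = as.integer(step), field = field,
                   value = as.double(value)))
  config
}
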