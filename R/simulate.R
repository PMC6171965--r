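#' Run a cortical actomyosin simulation
#'
#' Advances the agent-based model for `config$n_steps` steps of
#' `config$timestep` seconds. Each step applies, in fixed order: free-motor
#' diffusion, motor search/bind, cross-linker search/bind, plus-end directed
#' walking, release checks (plus-end, stochastic, over-stretch), Hookean
#' force accumulation, the overdamped filament update against slender-rod
#' drag, stochastic filament turnover, open-boundary re-insertion, and any
#' scheduled parameter switches. Scalar series are recorded every step and
#' full state snapshots every `config$record_stride` steps.
#'
#' The run is seeded from `config$seed` (unless an explicit `seed` is given)
#' and is bit-reproducible: the same configuration and seed yield identical
#' trajectories.
#'
#' @param config A [cortex_config()].
#' @param state Optional initial [cortex_state()]; defaults to
#'   [init_random()] under the run's seed.
#' @param seed Overrides `config$seed` when given.
#' @return A `cortex_sim` object: a list with the resolved `config`, the
#'   per-step `series` tibble (`step`, `time`, `mean_motor_force`,
#'   `mean_exerting_force`, `max_motor_force`, motor state counts,
#'   `n_xl_bound`, `elastic_energy`, `dissipation`), `snapshots` (a list of
#'   [cortex_state()]s with a `step` attribute), the `final_state`, and
#'   `max_motor_force` over the whole run.
#' @export
#' @examples
#' sim <- simulate_cortex(cortex_config(n_filaments = 30, n_motors = 100,
#'                                      n_steps = 50, seed = 7))
#' tail(sim$series)
simulate_cortex <- function(config, state = NULL, seed = NULL) {
  stopifnot(inherits(config, "cortex_config"))
  validate_cortex_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  set.seed(config$seed)
  if (is.null(state)) {
    init <- attr(config, "init")
    state <- if (is.null(init)) init_random(config) else
      make_preset_state(init, config)
  }
  enc <- encode_state_for_engine(state)
  sched <- config$switch_schedule
  sched_enc <- data.frame(
    step = as.integer(sched$step),
    field = unname(switch_field_code[sched$field]),
    value = as.double(sched$value))
  raw <- sim_engine_cpp(unclass(config), sched_enc,
                        enc$filaments, enc$motors, enc$crosslinkers,
                        config$n_steps, 0L, config$record_stride)
  fil_ids <- state$filaments$id
  mot_ids <- state$motors$id
  xl_ids <- state$crosslinkers$id
  tethered <- state$motors$tethered
  domain <- state$domain
  series <- tibble::as_tibble(raw$series)
  series$time <- series$step * config$timestep
  series <- dplyr::relocate(series, "step", "time")
  snaps <- lapply(raw$snapshots, function(s) {
    st <- cortex_state(
      decode_filaments(s$filaments, fil_ids),
      decode_motors(s$motors, mot_ids, fil_ids, tethered),
      decode_crosslinkers(s$crosslinkers, xl_ids, fil_ids),
      domain)
    attr(st, "step") <- s$step
    st
  })
  final_state <- cortex_state(
    decode_filaments(raw$filaments, fil_ids),
    decode_motors(raw$motors, mot_ids, fil_ids, tethered),
    decode_crosslinkers(raw$crosslinkers, xl_ids, fil_ids),
    domain)
  structure(list(config = config, series = series, snapshots = snaps,
                 initial_state = state, final_state = final_state,
                 max_motor_force = raw$max_motor_force),
            class = "cortex_sim")
}

# presets that need a non-random initial state name their generator
make_preset_state <- function(init, config) {
  domain <- hexagon_domain(config$hexagon_circumradius)
  switch(init,
    aligned = init_aligned(config, 0, pi / 8),
    bar = init_bar(config),
    tethered = tether_motors(init_random(config),
                             bottom_region(domain, 1 / 8)),
    anchored = fix_filaments(init_random(config), 0.1,
                             bottom_region(domain, 1 / 4)),
    stop("unknown preset initial state '", init, "'", call. = FALSE))
}

#' @export
print.cortex_sim <- function(x, ...) {
  n <- nrow(x$series)
  cat(sprintf("<cortex_sim> %d steps (%.2f s), %d filaments, %d motors, %d cross-linkers\n",
              n, max(x$series$time), nrow(x$final_state$filaments),
              nrow(x$final_state$motors), nrow(x$final_state$crosslinkers)))
  cat(sprintf("  final mean motor force %.4f pN; max motor force %.3f pN; %d snapshots\n",
              x$series$mean_motor_force[n], x$max_motor_force,
              length(x$snapshots)))
  invisible(x)
}

#' Tidy and summarise simulation results
#'
#' `tidy()` returns the per-step series in long form (`step`, `time`,
#' `metric`, `value`); `glance()` returns a one-row summary with the
#' steady-state force (mean over the final 10% of steps), the final motor
#' state counts, the number of detected asters at the end of the run, and
#' total dissipated energy.
#'
#' @param x A `cortex_sim`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy cortex_sim
#' @export
tidy.cortex_sim <- function(x, ...) {
  tidyr::pivot_longer(x$series, -c("step", "time"),
                      names_to = "metric", values_to = "value")
}

#' @rdname tidy.cortex_sim
#' @method glance cortex_sim
#' @export
glance.cortex_sim <- function(x, ...) {
  s <- x$series
  n <- nrow(s)
  tail_idx <- seq.int(max(1, floor(0.9 * n)), n)
  dm <- divergence_map(x$final_state$filaments,
                       L = x$config$filament_length,
                       domain = x$final_state$domain)
  asters <- detect_asters(dm)
  tibble::tibble(
    n_steps = n,
    steady_state_force = mean(s$mean_motor_force[tail_idx]),
    final_mean_force = s$mean_motor_force[n],
    max_motor_force = x$max_motor_force,
    n_two_bound = s$n_two_bound[n],
    n_one_bound = s$n_one_bound[n],
    n_free = s$n_free[n],
    n_asters = nrow(asters),
    elastic_energy = s$elastic_energy[n],
    total_dissipation = sum(s$dissipation) * x$config$timestep)
}

#' Plot simulation outputs
#'
#' `autoplot()` on a `cortex_sim` draws the mean motor force trace with the
#' motor state counts; `plot_state()` draws a state: filaments as segments
#' (minus to plus end), motors as points coloured by state.
#'
#' @param object A `cortex_sim`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cortex_sim
#' @export
autoplot.cortex_sim <- function(object, ...) {
  long <- tidy.cortex_sim(object)
  keep <- c("mean_motor_force", "n_two_bound", "n_one_bound", "n_free")
  ggplot2::ggplot(dplyr::filter(long, .data$metric %in% keep),
                  ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
}

#' @rdname autoplot.cortex_sim
#' @param state A [cortex_state()].
#' @param L Filament length (um), for drawing the rods.
#' @export
plot_state <- function(state, L = 1, ...) {
  f <- state$filaments
  seg <- tibble::tibble(
    x = f$x - L / 2 * cos(f$theta), y = f$y - L / 2 * sin(f$theta),
    xend = f$x + L / 2 * cos(f$theta), yend = f$y + L / 2 * sin(f$theta))
  m <- motor_head_positions(state)
  bound <- m$a_state == "bound" | m$b_state == "bound"
  pts <- tibble::tibble(x = m$a_x, y = m$a_y,
                        state = ifelse(bound, "bound", "free"))
  R <- state$domain$circumradius
  hexv <- tibble::tibble(x = R * cos(seq(0, 2 * pi, length.out = 7)),
                         y = R * sin(seq(0, 2 * pi, length.out = 7)))
  ggplot2::ggplot() +
    ggplot2::geom_path(data = hexv, ggplot2::aes(.data$x, .data$y),
                       colour = "grey60") +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(.data$x, .data$y,
                                       xend = .data$xend,
                                       yend = .data$yend),
                          colour = "firebrick", linewidth = 0.3) +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(.data$x, .data$y,
                                     colour = .data$state),
                        size = 0.4, alpha = 0.5) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "x (um)", y = "y (um)")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
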