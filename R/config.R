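#' Simulation configuration
#'
#' Builds the full parameter set of the cortical actomyosin model. Units are
#' fixed globally: micrometres, seconds and piconewtons (energies therefore in
#' pN um). The defaults are the standard parameter set of the model: a dense
#' network of 1000 filaments and 5000 motors evolved for 1000 steps of 0.01 s
#' (10 s of model time).
#'
#' @param n_filaments Number of actin filaments (N).
#' @param n_motors Number of myosin motors (M).
#' @param n_crosslinkers Number of passive cross-linkers.
#' @param filament_length Filament length L (um). Filaments are rigid rods.
#' @param filament_diameter Filament diameter di (um); enters only through the
#'   aspect ratio p = L/di of the viscous drag coefficients.
#' @param motor_stiffness Motor spring stiffness k (pN/um).
#' @param motor_velocity Plus-end directed walking speed v (um/s).
#' @param motor_attach_rate Attachment rate p1 (1/s).
#' @param motor_detach_rate Stochastic detachment rate p0 (1/s).
#' @param filament_turnover_rate Whole-filament turnover rate p2 (1/s per
#'   filament): a turned-over filament is replaced at a uniform-random position
#'   and orientation and every head bound to it is severed.
#' @param motor_reach Search radius and maximum stretch r (um). A single length
#'   bounds both the binding search and the spring extension at which a motor
#'   is forced off.
#' @param dynamic_viscosity Dynamic viscosity of the medium eta (pN s/um^2).
#' @param timestep Integration step dt (s).
#' @param n_steps Number of steps to run.
#' @param hexagon_circumradius Circumradius of the open hexagonal domain (um).
#'   The default, 2.2 um, was calibrated once against the sparse-ensemble
#'   steady-state motor force and then frozen (see the methods vignette); it
#'   puts the dense standard network in the single-central-aster regime.
#' @param free_motor_diffusion_step Displacement of a fully free motor per step
#'   (um), taken in an isotropic random direction.
#' @param crosslinker_reach Maximum cross-linker binding distance and stretch
#'   (um); default 0.04 um (40 nm).
#' @param crosslinker_angle_tol Maximum orientation difference (rad) between
#'   the two filaments a cross-linker may bridge; default pi/8 (22.5 degrees).
#'   Polarity-aware: anti-parallel filaments are never co-oriented.
#' @param crosslinker_stiffness Cross-linker spring stiffness (pN/um); defaults
#'   to the motor stiffness.
#' @param crosslinker_attach_rate Cross-linker binding rate (1/s); defaults to
#'   the motor attachment rate.
#' @param crosslinker_detach_rate Stochastic cross-linker unbinding rate (1/s);
#'   0 by default (bound cross-linkers remain fixed).
#' @param seed Integer seed; with the same seed whole trajectories are
#'   bit-reproducible.
#' @param deterministic_free_capture If `TRUE` (the default), a free-diffusing
#'   motor that discovers one or two filaments within its search radius
#'   attaches immediately (to both when two are in reach), and only the
#'   second-filament binding of an already-attached motor is gated by the
#'   attachment rate `p1`. If `FALSE`, every head binds with probability
#'   `p1 * dt`. The default is what sustains the search-capture-traffic
#'   feedback under filament turnover.
#' @param free_head_follows If `TRUE` (default), the dangling head of a
#'   one-bound motor is carried along with its walking partner and searches
#'   around the partner's position (a taut zero-rest-length spring); if
#'   `FALSE` it searches around its own release point.
#' @param tethered_tip_hold If `TRUE` (default), the filament-binding leg of
#'   a spatially anchored motor dwells at the filament plus-end instead of
#'   being shed there, so tethered motors reel filaments in plus-end first
#'   (stochastic detachment and over-stretch release still apply). Ordinary
#'   motors always fall off at the plus-end.
#' @param binding_site Which candidate a searching motor head attaches to:
#'   `"random"` (the default) grabs a uniform-random filament among those in
#'   reach, at that filament's closest point; `"nearest"` binds the closest
#'   point of the closest candidate (the rule cross-linkers always use).
#' @param switch_schedule Data frame with columns `step`, `field`, `value`:
#'   each entry replaces a parameter at the end of the given step (see
#'   [schedule_switch()]).
#' @param record_stride Record a full state snapshot every this many steps
#'   (scalar time series are recorded every step regardless).
#' @param turnover_exempt_immobile If `TRUE`, immobile (anchored) filaments are
#'   exempt from turnover, as in the patterned-substrate experiments.
#'
#' @return A list with class `"cortex_config"`.
#' @seealso [read_cortex_config()], [preset_config()], [simulate_cortex()]
#' @export
#' @examples
#' cfg <- cortex_config(n_filaments = 50, n_motors = 250, seed = 1)
#' cfg$motor_stiffness * cfg$motor_reach # maximum motor force, 0.9 pN
cortex_config <- function(n_filaments = 1000,
                          n_motors = 5000,
                          n_crosslinkers = 0,
                          filament_length = 1,
                          filament_diameter = 0.008,
                          motor_stiffness = 3,
                          motor_velocity = 1,
                          motor_attach_rate = 10,
                          motor_detach_rate = 1,
                          filament_turnover_rate = 0.7,
                          motor_reach = 0.3,
                          dynamic_viscosity = 1,
                          timestep = 0.01,
                          n_steps = 1000,
                          hexagon_circumradius = 2.2,
                          free_motor_diffusion_step = 0.05,
                          crosslinker_reach = 0.04,
                          crosslinker_angle_tol = pi / 8,
                          crosslinker_stiffness = motor_stiffness,
                          crosslinker_attach_rate = motor_attach_rate,
                          crosslinker_detach_rate = 0,
                          deterministic_free_capture = TRUE,
                          binding_site = c("random", "nearest"),
                          free_head_follows = TRUE,
                          tethered_tip_hold = TRUE,
                          seed = 1L,
                          switch_schedule = NULL,
                          record_stride = 50,
                          turnover_exempt_immobile = TRUE) {
  cfg <- list(
    n_filaments = as.integer(n_filaments),
    n_motors = as.integer(n_motors),
    n_crosslinkers = as.integer(n_crosslinkers),
    filament_length = filament_length,
    filament_diameter = filament_diameter,
    motor_stiffness = motor_stiffness,
    motor_velocity = motor_velocity,
    motor_attach_rate = motor_attach_rate,
    motor_detach_rate = motor_detach_rate,
    filament_turnover_rate = filament_turnover_rate,
    motor_reach = motor_reach,
    dynamic_viscosity = dynamic_viscosity,
    timestep = timestep,
    n_steps = as.integer(n_steps),
    hexagon_circumradius = hexagon_circumradius,
    free_motor_diffusion_step = free_motor_diffusion_step,
    crosslinker_reach = crosslinker_reach,
    crosslinker_angle_tol = crosslinker_angle_tol,
    crosslinker_stiffness = crosslinker_stiffness,
    crosslinker_attach_rate = crosslinker_attach_rate,
    crosslinker_detach_rate = crosslinker_detach_rate,
    deterministic_free_capture = isTRUE(deterministic_free_capture),
    binding_site = match.arg(binding_site),
    free_head_follows = isTRUE(free_head_follows),
    tethered_tip_hold = isTRUE(tethered_tip_hold),
    seed = as.integer(seed),
    switch_schedule = normalize_switch_schedule(switch_schedule),
    record_stride = as.integer(record_stride),
    turnover_exempt_immobile = isTRUE(turnover_exempt_immobile)
  )
  class(cfg) <- "cortex_config"
  validate_cortex_config(cfg)
  cfg
}

# Parameters that a switch schedule entry may target.
switchable_fields <- c(
  "motor_stiffness", "motor_reach", "filament_length", "motor_velocity",
  "motor_detach_rate", "motor_attach_rate", "filament_turnover_rate",
  "dynamic_viscosity"
)

normalize_switch_schedule <- function(x) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0)) {
    return(tibble::tibble(step = integer(), field = character(),
                          value = double()))
  }
  stopifnot(is.data.frame(x), all(c("step", "field", "value") %in% names(x)))
  tibble::tibble(step = as.integer(x$step), field = as.character(x$field),
                 value = as.double(x$value))
}

validate_cortex_config <- function(cfg) {
  num <- function(f) cfg[[f]]
  nonneg <- c(
    "n_filaments", "n_motors", "n_crosslinkers", "motor_stiffness",
    "motor_velocity", "motor_attach_rate", "motor_detach_rate",
    "filament_turnover_rate", "motor_reach", "dynamic_viscosity",
    "free_motor_diffusion_step", "crosslinker_reach", "crosslinker_angle_tol",
    "crosslinker_stiffness", "crosslinker_attach_rate",
    "crosslinker_detach_rate", "n_steps"
  )
  for (f in nonneg) {
    if (!is.numeric(num(f)) || length(num(f)) != 1 || is.na(num(f)) ||
        num(f) < 0) {
      stop("`", f, "` must be a single non-negative number", call. = FALSE)
    }
  }
  if (cfg$timestep <= 0) stop("`timestep` must be > 0", call. = FALSE)
  if (cfg$hexagon_circumradius <= 0) {
    stop("`hexagon_circumradius` must be > 0", call. = FALSE)
  }
  if (!(cfg$filament_length > cfg$filament_diameter &&
        cfg$filament_diameter > 0)) {
    stop("need filament_length > filament_diameter > 0", call. = FALSE)
  }
  bad <- setdiff(cfg$switch_schedule$field, switchable_fields)
  if (length(bad)) {
    stop("non-switchable field(s) in switch_schedule: ",
         paste(bad, collapse = ", "), "; valid fields: ",
         paste(switchable_fields, collapse = ", "), call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.cortex_config <- function(x, ...) {
  cat("<cortex_config>\n")
  cat(sprintf("  %d filaments (L = %g um), %d motors, %d cross-linkers\n",
              x$n_filaments, x$filament_length, x$n_motors, x$n_crosslinkers))
  cat(sprintf("  k = %g pN/um, v = %g um/s, p1 = %g/s, p0 = %g/s, p2 = %g/s, r = %g um\n",
              x$motor_stiffness, x$motor_velocity, x$motor_attach_rate,
              x$motor_detach_rate, x$filament_turnover_rate, x$motor_reach))
  cat(sprintf("  eta = %g pN s/um^2, dt = %g s, %d steps, hexagon R = %g um, seed = %d\n",
              x$dynamic_viscosity, x$timestep, x$n_steps,
              x$hexagon_circumradius, x$seed))
  if (nrow(x$switch_schedule)) {
    cat(sprintf("  %d scheduled parameter switch(es)\n",
                nrow(x$switch_schedule)))
  }
  invisible(x)
}

#' Read and write configurations as YAML
#'
#' Configurations round-trip losslessly through a flat YAML file whose keys
#' are named exactly as the arguments of [cortex_config()]; the switch
#' schedule is stored as a list of `step`/`field`/`value` entries.
#'
#' @param path File path.
#' @param config A `cortex_config` object.
#' @param overrides Named list of fields replacing values read from file.
#' @return `read_cortex_config()` returns a `cortex_config`;
#'   `write_cortex_config()` returns `path` invisibly.
#' @export
read_cortex_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$switch_schedule)) {
    raw$switch_schedule <- dplyr::bind_rows(lapply(raw$switch_schedule,
                                                   tibble::as_tibble))
  }
  known <- names(formals(cortex_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         "; valid keys: ", paste(known, collapse = ", "), call. = FALSE)
  }
  raw[names(overrides)] <- overrides
  do.call(cortex_config, raw)
}

#' @rdname read_cortex_config
#' @export
write_cortex_config <- function(config, path) {
  stopifnot(inherits(config, "cortex_config"))
  out <- unclass(config)
  sched <- out$switch_schedule
  out$switch_schedule <- if (nrow(sched) == 0) NULL else
    lapply(seq_len(nrow(sched)), function(i) as.list(sched[i, ]))
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Named experiment presets
#'
#' Ready-made configurations for the package's reference experiments, shipped
#' as YAML under `inst/extdata/presets`. Available presets:
#' `sparse` (50 filaments / 250 motors), `dense` (1000 / 5000),
#' `dense_high_turnover` (p2 = 5/s, no asters), `xlink_25` and `xlink_75`
#' (25% / 75% of 5000 connectors as cross-linkers), `aligned` (initially
#' co-oriented filaments plus cross-linkers), `bar` (filaments nucleated on a
#' fixed bar), `tethered` (motors anchored in the bottom eighth), and
#' `anchored` (10% of filaments fixed in the bottom fourth).
#'
#' @param name Preset name.
#' @param ... Overrides passed to the underlying configuration.
#' @return A `cortex_config` (with attribute `init` naming the initial-state
#'   generator some presets need).
#' @export
preset_config <- function(name, ...) {
  dir <- system.file("extdata", "presets", package = "cortexsim")
  path <- file.path(dir, paste0(name, ".yaml"))
  if (!file.exists(path)) {
    stop("unknown preset '", name, "'; available: ",
         paste(sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$")),
               collapse = ", "), call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  init <- raw$init
  raw$init <- NULL
  if (!is.null(raw$switch_schedule)) {
    raw$switch_schedule <- dplyr::bind_rows(lapply(raw$switch_schedule,
                                                   tibble::as_tibble))
  }
  dots <- list(...)
  raw[names(dots)] <- dots
  cfg <- do.call(cortex_config, raw)
  attr(cfg, "init") <- init
  cfg
}
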