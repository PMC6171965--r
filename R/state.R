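#' Network state container
#'
#' A `cortex_state` bundles the three agent tables of the model, each a tibble
#' with one row per agent:
#'
#' * `filaments`: `id`, `x`, `y` (centre of mass, um), `theta` (orientation,
#'   rad; the plus-end sits at `center + (L/2)(cos theta, sin theta)`),
#'   `mobile` (anchored filaments never move but still bind heads),
#'   `birth_step`.
#' * `motors`: per head (`a_`/`b_` prefixes) a `state`
#'   (`"free"`/`"bound"`/`"anchored"`), the bound filament `fil` (id) and
#'   signed walk coordinate `len` (um from the filament centre toward the
#'   plus-end), the lab-frame position `x`/`y` (own coordinates for free and
#'   anchored heads; derived from the filament for bound heads), and
#'   `bind_step`; plus `tethered`.
#' * `crosslinkers`: `id`, `state` (`"free"`/`"bound"`), free position
#'   `x`/`y`, and the two frozen attachments `a_fil`/`a_len`, `b_fil`/`b_len`.
#'
#' @param filaments,motors,crosslinkers Agent tibbles as described above.
#' @param domain A [hexagon_domain()].
#' @return A list with class `"cortex_state"`.
#' @export
cortex_state <- function(filaments, motors, crosslinkers, domain) {
  structure(list(filaments = filaments, motors = motors,
                 crosslinkers = crosslinkers, domain = domain),
            class = "cortex_state")
}

#' @export
print.cortex_state <- function(x, ...) {
  nb <- sum(x$motors$a_state == "bound") + sum(x$motors$b_state == "bound")
  cat(sprintf(
    "<cortex_state> %d filaments, %d motors (%d bound heads), %d cross-linkers\n",
    nrow(x$filaments), nrow(x$motors), nb, nrow(x$crosslinkers)))
  invisible(x)
}

empty_motors <- function(n) {
  tibble::tibble(
    id = seq_len(n),
    a_state = rep("free", n), a_fil = NA_integer_, a_len = NA_real_,
    a_x = 0, a_y = 0, a_bind_step = NA_integer_,
    b_state = rep("free", n), b_fil = NA_integer_, b_len = NA_real_,
    b_x = 0, b_y = 0, b_bind_step = NA_integer_,
    tethered = rep(FALSE, n)
  )
}

empty_crosslinkers <- function(n) {
  tibble::tibble(
    id = seq_len(n), state = rep("free", n), x = 0, y = 0,
    a_fil = NA_integer_, a_len = NA_real_,
    b_fil = NA_integer_, b_len = NA_real_
  )
}

#' Resolved head positions
#'
#' Returns the motors table with lab-frame positions of both heads resolved:
#' bound heads sit at their attachment point on the filament, free and
#' anchored heads at their stored coordinates.
#'
#' @param state A [cortex_state()].
#' @return The motors tibble with refreshed `a_x`, `a_y`, `b_x`, `b_y`.
#' @export
motor_head_positions <- function(state) {
  m <- state$motors
  f <- state$filaments
  for (h in c("a", "b")) {
    st <- m[[paste0(h, "_state")]]
    bnd <- which(st == "bound")
    if (length(bnd)) {
      fi <- match(m[[paste0(h, "_fil")]][bnd], f$id)
      pos <- attachment_point(f[fi, ], m[[paste0(h, "_len")]][bnd])
      m[[paste0(h, "_x")]][bnd] <- pos$x
      m[[paste0(h, "_y")]][bnd] <- pos$y
    }
  }
  m
}

# ---- engine encoding ------------------------------------------------------

state_code <- c(free = 0L, bound = 1L, anchored = 2L)

encode_state_for_engine <- function(state) {
  f <- state$filaments
  m <- state$motors
  x <- state$crosslinkers
  mhp <- motor_head_positions(state)
  to_idx <- function(fil) {
    out <- match(fil, f$id) - 1L
    out[is.na(out)] <- -1L
    out
  }
  list(
    filaments = data.frame(
      x = f$x, y = f$y, theta = f$theta,
      mobile = as.integer(f$mobile), birth_step = as.integer(f$birth_step)),
    motors = data.frame(
      a_state = unname(state_code[m$a_state]), a_fil = to_idx(m$a_fil),
      a_len = ifelse(is.na(m$a_len), 0, m$a_len),
      a_x = mhp$a_x, a_y = mhp$a_y,
      a_bind_step = ifelse(is.na(m$a_bind_step), -1L,
                           as.integer(m$a_bind_step)),
      b_state = unname(state_code[m$b_state]), b_fil = to_idx(m$b_fil),
      b_len = ifelse(is.na(m$b_len), 0, m$b_len),
      b_x = mhp$b_x, b_y = mhp$b_y,
      b_bind_step = ifelse(is.na(m$b_bind_step), -1L,
                           as.integer(m$b_bind_step))),
    crosslinkers = data.frame(
      state = unname(state_code[x$state]), x = x$x, y = x$y,
      a_fil = to_idx(x$a_fil), a_len = ifelse(is.na(x$a_len), 0, x$a_len),
      b_fil = to_idx(x$b_fil), b_len = ifelse(is.na(x$b_len), 0, x$b_len)),
    tethered = m$tethered
  )
}

decode_filaments <- function(raw, ids, step0 = NULL) {
  tibble::tibble(
    id = ids, x = raw$x, y = raw$y, theta = raw$theta,
    mobile = as.logical(raw$mobile), birth_step = as.integer(raw$birth_step))
}

decode_motors <- function(raw, ids, fil_ids, tethered) {
  code_to_state <- c("free", "bound", "anchored")
  idx <- function(v) ifelse(v < 0, NA_integer_, fil_ids[v + 1L])
  na_if_unbound <- function(val, st) ifelse(st == 1L, val, NA_real_)
  m <- tibble::tibble(
    id = ids,
    a_state = code_to_state[raw$a_state + 1L],
    a_fil = idx(raw$a_fil), a_len = na_if_unbound(raw$a_len, raw$a_state),
    a_x = raw$a_x, a_y = raw$a_y,
    b_state = code_to_state[raw$b_state + 1L],
    b_fil = idx(raw$b_fil), b_len = na_if_unbound(raw$b_len, raw$b_state),
    b_x = raw$b_x, b_y = raw$b_y,
    tethered = tethered
  )
  if (!is.null(raw$a_bind_step)) {
    m$a_bind_step <- ifelse(raw$a_bind_step < 0, NA_integer_,
                            as.integer(raw$a_bind_step))
    m$b_bind_step <- ifelse(raw$b_bind_step < 0, NA_integer_,
                            as.integer(raw$b_bind_step))
  } else {
    m$a_bind_step <- NA_integer_
    m$b_bind_step <- NA_integer_
  }
  if (!is.null(raw$force)) m$force <- raw$force
  m
}

decode_crosslinkers <- function(raw, ids, fil_ids) {
  code_to_state <- c("free", "bound")
  idx <- function(v) ifelse(v < 0, NA_integer_, fil_ids[v + 1L])
  bound <- raw$state == 1L
  tibble::tibble(
    id = ids, state = code_to_state[raw$state + 1L],
    x = raw$x, y = raw$y,
    a_fil = idx(raw$a_fil), a_len = ifelse(bound, raw$a_len, NA_real_),
    b_fil = idx(raw$b_fil), b_len = ifelse(bound, raw$b_len, NA_real_))
}

switch_field_code <- c(
  motor_stiffness = 1L, motor_reach = 2L, filament_length = 3L,
  motor_velocity = 4L, motor_detach_rate = 5L, motor_attach_rate = 6L,
  filament_turnover_rate = 7L, dynamic_viscosity = 8L
)
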