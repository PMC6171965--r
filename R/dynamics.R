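#' Slender-rod viscous drag coefficients
#'
#' Translational and rotational drag of a rigid cylindrical rod of length `L`
#' and diameter `di` in a medium of dynamic viscosity `eta`, in the low
#' Reynolds number slender-body approximation with end corrections
#' `gamma_perp = 0.84`, `gamma_par = 0.114`, `gamma_rot = -0.662` (the
#' infinite-aspect-ratio values). Logarithms are natural:
#' \deqn{\Gamma_{perp} = 4\pi\eta L/(\ln p + 0.84),\quad
#'       \Gamma_{par} = 2\pi\eta L/(\ln p + 0.114),\quad
#'       \Gamma_{rot} = \tfrac{1}{3}\pi\eta L^3/(\ln p - 0.662)}
#' with aspect ratio `p = L/di`.
#'
#' @param L Rod length (um).
#' @param di Rod diameter (um).
#' @param eta Dynamic viscosity (pN s/um^2).
#' @return A list with elements `par`, `perp` (pN s/um) and `rot` (pN s um).
#' @export
#' @examples
#' drag_coefficients(1, 0.008, 1)
drag_coefficients <- function(L, di, eta) {
  stopifnot(L > di, di > 0, eta > 0)
  p <- L / di
  if (log(p) <= 0.662) {
    stop("aspect ratio too small: ln(L/di) must exceed 0.662", call. = FALSE)
  }
  list(
    par  = 2 * pi * eta * L   / (log(p) + 0.114),
    perp = 4 * pi * eta * L   / (log(p) + 0.84),
    rot  = (1 / 3) * pi * eta * L^3 / (log(p) - 0.662)
  )
}

#' Lab-frame position of a head bound along a filament
#'
#' A head bound at signed coordinate `len` (um, measured from the filament
#' centre of mass toward the plus-end) sits at
#' `(x + len cos(theta), y + len sin(theta))`.
#'
#' @param filaments Data frame with columns `x`, `y`, `theta`.
#' @param len Signed along-filament coordinate(s), `|len| <= L/2`.
#' @param L Filament length (um), used only to validate `len`.
#' @return A tibble with columns `x`, `y`.
#' @export
attachment_point <- function(filaments, len, L = NULL) {
  if (!is.null(L) && any(abs(len) > L / 2 + 1e-9, na.rm = TRUE)) {
    stop("`len` out of range: |len| must be <= L/2", call. = FALSE)
  }
  tibble::tibble(x = filaments$x + len * cos(filaments$theta),
                 y = filaments$y + len * sin(filaments$theta))
}

#' Hookean motor force on a filament
#'
#' The force a zero-rest-length spring of stiffness `k` exerts at its
#' attachment `(hx, hy)` on a filament, pointing toward the opposite head at
#' `(ox, oy)`: `k * (o - h)`. Motors exert force only when both heads are
#' load-bearing (bound to two filaments, or one head anchored in space).
#'
#' @param hx,hy Attachment point on this filament (um).
#' @param ox,oy Position of the opposite head (um).
#' @param k Spring stiffness (pN/um).
#' @return A tibble with columns `fx`, `fy` (pN).
#' @export
#' @examples
#' motor_force(0, 0, 0.3, 0, 3) # 0.9 pN: the maximum motor exerted force
motor_force <- function(hx, hy, ox, oy, k) {
  tibble::tibble(fx = k * (ox - hx), fy = k * (oy - hy))
}

#' Overdamped filament update
#'
#' Advances rigid filaments one step under summed motor/cross-linker forces.
#' The lab-frame force is rotated into the filament's parallel/perpendicular
#' frame; the centre of mass moves by `dt * F_par / Gamma_par` along the axis
#' and `dt * F_perp / Gamma_perp` across it, and the orientation advances by
#' `dt * torque / Gamma_rot`, where the torque is the sum of lever arm times
#' perpendicular force component over attached heads. Immobile filaments are
#' returned unchanged.
#'
#' @param filaments Tibble with columns `x`, `y`, `theta`, `mobile`.
#' @param fx,fy Summed lab-frame force per filament (pN).
#' @param torque Summed `len * F_perp` per filament (pN um).
#' @param drags Output of [drag_coefficients()].
#' @param dt Timestep (s).
#' @return The updated filaments tibble, with attribute `dissipation` (pN um):
#'   the viscous drag work of the realized displacements.
#' @export
step_filament <- function(filaments, fx, fy, torque, drags, dt) {
  ct <- cos(filaments$theta)
  st <- sin(filaments$theta)
  f_par  <- ct * fx + st * fy
  f_perp <- -st * fx + ct * fy
  mob <- filaments$mobile
  d_par  <- ifelse(mob, dt * f_par / drags$par, 0)
  d_perp <- ifelse(mob, dt * f_perp / drags$perp, 0)
  d_th   <- ifelse(mob, dt * torque / drags$rot, 0)
  out <- filaments
  out$x <- filaments$x + d_par * ct - d_perp * st
  out$y <- filaments$y + d_par * st + d_perp * ct
  out$theta <- filaments$theta + d_th
  attr(out, "dissipation") <-
    sum(drags$par * d_par^2 + drags$perp * d_perp^2 + drags$rot * d_th^2) / dt
  out
}

#' Treadmilling displacement bound
#'
#' Per-step forward displacement of a filament due to treadmilling (net
#' monomer addition at the plus-end): `subunit_rate * monomer_size * dt`.
#' At the physiological subunit rate of 0.21/s and monomer size 4-7 nm this
#' is 8.4e-6 to 1.47e-5 um per 0.01 s step, which is why the model neglects
#' treadmilling motion entirely; the utility exists for documentation and is
#' never applied to filaments.
#'
#' @param subunit_rate Monomer addition rate (1/s).
#' @param monomer_size G-actin monomer size (um).
#' @param dt Time interval (s).
#' @return Displacement (um).
#' @export
treadmilling_displacement <- function(subunit_rate, monomer_size, dt) {
  stopifnot(subunit_rate >= 0, monomer_size >= 0, dt >= 0)
  subunit_rate * monomer_size * dt
}

# ---- internal geometry helpers -------------------------------------------

# Distance from points to filament segments, with the clipped along-filament
# coordinate of the closest point. Vectorised over points against one segment
# or elementwise.
point_segment_distance <- function(px, py, cx, cy, theta, L) {
  ux <- cos(theta); uy <- sin(theta)
  t <- (px - cx) * ux + (py - cy) * uy
  t <- pmax(-L / 2, pmin(L / 2, t))
  dx <- px - (cx + t * ux)
  dy <- py - (cy + t * uy)
  list(dist = sqrt(dx^2 + dy^2), t = t)
}

# Closest approach of two filament segments: minimum distance and the signed
# along-filament coordinates of the mutually closest points.
segment_segment_closest <- function(c1x, c1y, th1, c2x, c2y, th2, L) {
  u1x <- cos(th1); u1y <- sin(th1)
  u2x <- cos(th2); u2y <- sin(th2)
  h <- L / 2
  wx <- c1x - c2x; wy <- c1y - c2y
  b <- u1x * u2x + u1y * u2y
  d <- u1x * wx + u1y * wy
  e <- u2x * wx + u2y * wy
  denom <- 1 - b * b
  if (denom > 1e-12) {
    t1 <- (b * e - d) / denom
    t2 <- (e - b * d) / denom
  } else {            # parallel: pick overlap midpoint projection
    t1 <- 0
    t2 <- e
  }
  # clamp and re-optimise the partner coordinate (standard two-pass clamp)
  t1 <- pmax(-h, pmin(h, t1))
  t2 <- (u2x * (c1x + t1 * u1x - c2x) + u2y * (c1y + t1 * u1y - c2y))
  t2 <- pmax(-h, pmin(h, t2))
  t1 <- (u1x * (c2x + t2 * u2x - c1x) + u1y * (c2y + t2 * u2y - c1y))
  t1 <- pmax(-h, pmin(h, t1))
  p1x <- c1x + t1 * u1x; p1y <- c1y + t1 * u1y
  p2x <- c2x + t2 * u2x; p2y <- c2y + t2 * u2y
  list(dist = sqrt((p1x - p2x)^2 + (p1y - p2y)^2), t1 = t1, t2 = t2)
}

# Acute, polarity-aware orientation difference: angular distance between the
# orientation vectors on the circle (mod 2*pi), in [0, pi]. Anti-parallel
# filaments score pi and are never co-oriented.
orientation_difference <- function(th1, th2) {
  d <- (th1 - th2) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

# Bernoulli event with per-step probability P = rate*dt clipped to [0, 1].
# A uniform draw is consumed only when 0 < P < 1, so fully deterministic
# configurations consume no randomness (the documented draw-order contract).
rbern <- function(P) {
  if (P <= 0) return(FALSE)
  if (P >= 1) return(TRUE)
  stats::runif(1) < P
}
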