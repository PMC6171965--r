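#' Plus-end divergence map
#'
#' Asters are identified from the divergence of filament orientations: the
#' domain is covered by square boxes of side `L/8`; each filament contributes
#' its unit orientation vector to the box containing its plus-end, giving a
#' per-box summed orientation field `V = (Vx, Vy)`. The divergence is then a
#' second-order central difference of `Vx` along x and `Vy` along y (one-sided
#' at the boundary boxes). For randomly oriented filaments the divergence is
#' ~0 everywhere; an aster shows a strongly negative core (orientations point
#' inward toward the plus-end cluster) with a positive surround.
#'
#' @param filaments Filaments tibble (`x`, `y`, `theta`).
#' @param box_size Box side (um); default `L/8`.
#' @param L Filament length (um).
#' @param domain A [hexagon_domain()] fixing the grid extent.
#' @return A `divergence_map`: list with matrices `Vx`, `Vy`, `div` (x index
#'   by y index), box centre coordinates `x`, `y`, and `box_size`.
#' @export
divergence_map <- function(filaments, box_size = L / 8, L = 1,
                           domain = hexagon_domain(5)) {
  R <- domain$circumradius
  hh <- sqrt(3) / 2 * R
  nx <- ceiling(2 * R / box_size)
  ny <- ceiling(2 * hh / box_size)
  px <- filaments$x + (L / 2) * cos(filaments$theta)
  py <- filaments$y + (L / 2) * sin(filaments$theta)
  ix <- pmin(pmax(floor((px + R) / box_size), 0), nx - 1) + 1
  iy <- pmin(pmax(floor((py + hh) / box_size), 0), ny - 1) + 1
  Vx <- matrix(0, nx, ny)
  Vy <- matrix(0, nx, ny)
  ux <- cos(filaments$theta)
  uy <- sin(filaments$theta)
  for (i in seq_along(px)) {
    Vx[ix[i], iy[i]] <- Vx[ix[i], iy[i]] + ux[i]
    Vy[ix[i], iy[i]] <- Vy[ix[i], iy[i]] + uy[i]
  }
  div <- central_diff_x(Vx, box_size) + central_diff_y(Vy, box_size)
  structure(list(Vx = Vx, Vy = Vy, div = div,
                 x = -R + (seq_len(nx) - 0.5) * box_size,
                 y = -hh + (seq_len(ny) - 0.5) * box_size,
                 box_size = box_size),
            class = "divergence_map")
}

# central difference along rows (x), one-sided truncation at the edges
central_diff_x <- function(M, h) {
  n <- nrow(M)
  out <- M * 0
  if (n >= 3) out[2:(n - 1), ] <- (M[3:n, ] - M[1:(n - 2), ]) / (2 * h)
  if (n >= 2) {
    out[1, ] <- (M[2, ] - M[1, ]) / h
    out[n, ] <- (M[n, ] - M[n - 1, ]) / h
  }
  out
}

central_diff_y <- function(M, h) t(central_diff_x(t(M), h))

#' @export
print.divergence_map <- function(x, ...) {
  cat(sprintf("<divergence_map> %d x %d boxes of %.3g um; DIV in [%.3g, %.3g]\n",
              nrow(x$div), ncol(x$div), x$box_size, min(x$div), max(x$div)))
  invisible(x)
}

#' @method autoplot divergence_map
#' @export
autoplot.divergence_map <- function(object, ...) {
  df <- tidyr::expand_grid(ix = seq_along(object$x),
                           iy = seq_along(object$y))
  df$x <- object$x[df$ix]
  df$y <- object$y[df$iy]
  df$div <- object$div[cbind(df$ix, df$iy)]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$div)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)", fill = "DIV")
}

#' Detect asters on a divergence map
#'
#' Gaussian-smooths the divergence field to amplify coherent regions, then
#' finds aster cores: connected components of boxes whose smoothed
#' divergence dives below `core_factor` times the field's ordinary negative
#' fluctuation depth (its 2nd percentile — a robust scale that a deep core
#' cannot inflate). Core components closer than `merge_distance` boxes are
#' merged (one aster can fragment into several sub-threshold pits), and each
#' core must sit inside a negative basin whose surround turns positive — the
#' negative-core / positive-ring aster signature.
#'
#' @param divmap A [divergence_map()].
#' @param smoothing_sigma Gaussian sigma in box units.
#' @param core_factor Core threshold as a multiple of the smoothed field's
#'   ordinary negative fluctuation depth (its 2nd percentile): an aster core
#'   must dive at least `core_factor` times deeper than the background.
#' @param min_core_boxes Minimum (merged) core size in boxes.
#' @param merge_distance Centre distance (boxes) below which two cores are
#'   one aster; defaults to one filament length (8 boxes of `L/8`).
#' @return A tibble with one row per aster: centre `x`, `y` (um, the box of
#'   deepest smoothed divergence), `n_boxes`, `min_div`, `depth`
#'   (`min_div` over the background fluctuation scale).
#' @export
detect_asters <- function(divmap, smoothing_sigma = 1, core_factor = 3,
                          min_core_boxes = 2, merge_distance = 8) {
  sm <- EBImage::gblur(divmap$div, sigma = smoothing_sigma)
  s <- -stats::quantile(sm, 0.02, names = FALSE)
  empty <- tibble::tibble(x = double(), y = double(), n_boxes = integer(),
                          min_div = double(), depth = double())
  if (!is.finite(s) || s <= 0) return(empty)
  core <- sm <= -core_factor * s
  if (!any(core)) return(empty)
  lab <- EBImage::bwlabel(EBImage::Image(core * 1))
  lab <- as.matrix(EBImage::imageData(lab))
  ncomp <- max(lab)
  cent <- t(vapply(seq_len(ncomp), function(g) {
    cells <- which(lab == g, arr.ind = TRUE)
    k <- cells[which.min(sm[cells]), , drop = TRUE]
    c(k[1], k[2], sum(lab == g))
  }, numeric(3)))
  # merge cores closer than merge_distance (single linkage on deep minima)
  group <- seq_len(ncomp)
  for (i in seq_len(ncomp)) {
    for (j in seq_len(ncomp)) {
      if (i >= j) next
      if (sqrt(sum((cent[i, 1:2] - cent[j, 1:2])^2)) <= merge_distance) {
        group[group == group[j]] <- group[i]
      }
    }
  }
  out <- list()
  for (g in unique(group)) {
    members <- which(group == g)
    mask <- matrix(lab %in% members, nrow(lab), ncol(lab))
    cells <- which(mask, arr.ind = TRUE)
    if (nrow(cells) < min_core_boxes) next
    # the surrounding field beyond the negative basin must turn positive
    basin <- basin_of(sm <= 0, mask)
    ring <- component_ring(basin)
    if (length(sm[ring]) == 0 || mean(sm[ring]) < 0) next
    k <- cells[which.min(sm[cells]), , drop = TRUE]
    out[[length(out) + 1]] <- tibble::tibble(
      x = divmap$x[k[1]], y = divmap$y[k[2]],
      n_boxes = nrow(cells), min_div = min(sm[cells]),
      depth = -min(sm[cells]) / s)
  }
  if (!length(out)) return(empty)
  dplyr::bind_rows(out)
}

# connected region of `negative` containing `seed` (flood fill by dilation)
basin_of <- function(negative, seed) {
  cur <- seed & negative
  repeat {
    grown <- (dilate1(cur) & negative) | cur
    if (identical(grown, cur)) return(cur)
    cur <- grown
  }
}

dilate1 <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  dil <- mask
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    sx <- pmin(pmax(seq_len(n) + dx, 1), n)
    sy <- pmin(pmax(seq_len(m) + dy, 1), m)
    dil <- dil | mask[sx, sy, drop = FALSE]
  }
  dil
}

# logical mask of the 8-connected one-box ring around a component
component_ring <- function(mask) {
  dilate1(mask) & !mask
}

#' Synthetic fluorescence rendering
#'
#' Rasterises a state the way an additive fluorescence image forms: each
#' filament lights every pixel its segment crosses by one count; each motor
#' adds one count at its position; overlapping agents sum. The raster covers
#' the bounding box of the hexagonal domain.
#'
#' @param state A [cortex_state()] (or a filaments tibble for
#'   `channel = "filament"`).
#' @param pixel_size Pixel size (um/px).
#' @param channel `"filament"` or `"motor"`.
#' @param L Filament length (um).
#' @param domain A [hexagon_domain()]; taken from `state` when available.
#' @return A `cortex_frame`: an intensity matrix (x index by y index) with
#'   attributes `pixel_size`, `x0`, `y0`, `channel`.
#' @export
render_frame <- function(state, pixel_size = 0.05, channel = "filament",
                         L = 1, domain = NULL) {
  if (inherits(state, "cortex_state")) {
    domain <- state$domain
    agents <- if (channel == "filament") state$filaments else
      motor_head_positions(state)
  } else {
    agents <- state
    if (is.null(domain)) domain <- hexagon_domain(5)
  }
  R <- domain$circumradius
  hh <- sqrt(3) / 2 * R
  nx <- ceiling(2 * R / pixel_size)
  ny <- ceiling(2 * hh / pixel_size)
  img <- matrix(0L, nx, ny)
  clamp_idx <- function(v, n) pmin(pmax(v, 1L), n)
  if (channel == "filament") {
    if (nrow(agents)) {
      for (i in seq_len(nrow(agents))) {
        dx <- L * cos(agents$theta[i])
        dy <- L * sin(agents$theta[i])
        # dominant-axis stepping: max(|dix|, |diy|) + 1 pixels per segment
        n_samp <- max(2L, ceiling(max(abs(dx), abs(dy)) / pixel_size) + 1L)
        tt <- seq(-0.5, 0.5, length.out = n_samp)
        sx <- agents$x[i] + tt * dx
        sy <- agents$y[i] + tt * dy
        ix <- clamp_idx(floor((sx + R) / pixel_size) + 1L, nx)
        iy <- clamp_idx(floor((sy + hh) / pixel_size) + 1L, ny)
        pix <- unique(cbind(ix, iy))
        img[pix] <- img[pix] + 1L
      }
    }
  } else {
    mx <- (agents$a_x + agents$b_x) / 2
    my <- (agents$a_y + agents$b_y) / 2
    ix <- clamp_idx(floor((mx + R) / pixel_size) + 1L, nx)
    iy <- clamp_idx(floor((my + hh) / pixel_size) + 1L, ny)
    for (i in seq_along(ix)) img[ix[i], iy[i]] <- img[ix[i], iy[i]] + 1L
  }
  structure(img, pixel_size = pixel_size, x0 = -R, y0 = -hh,
            channel = channel, class = c("cortex_frame", "matrix", "array"))
}

#' @rdname render_frame
#' @param sim A `cortex_sim`.
#' @param ... Passed to `render_frame()`.
#' @return `render_series()`: a list of `cortex_frame`s, one per snapshot,
#'   with attribute `steps`.
#' @export
render_series <- function(sim, channel = "filament", ...) {
  frames <- lapply(sim$snapshots, render_frame, channel = channel,
                   L = sim$config$filament_length, ...)
  attr(frames, "steps") <- vapply(sim$snapshots,
                                  function(s) attr(s, "step"), 0L)
  frames
}

#' Region-of-interest mean intensity
#'
#' Tracks the mean intensity inside a fixed circular ROI over a frame stack,
#' optionally normalised by the whole-frame mean (the `I_roi / I_frame`
#' convention of live-imaging contraction analysis).
#'
#' @param frames List of `cortex_frame`s (see [render_series()]).
#' @param cx,cy ROI centre (um).
#' @param radius ROI radius (um).
#' @param normalize Divide each frame's ROI mean by its whole-frame mean.
#' @return A tibble: `frame`, `step` (if known), `value`.
#' @export
roi_mean_intensity <- function(frames, cx, cy, radius, normalize = TRUE) {
  f1 <- frames[[1]]
  px <- attr(f1, "pixel_size")
  xs <- attr(f1, "x0") + (seq_len(nrow(f1)) - 0.5) * px
  ys <- attr(f1, "y0") + (seq_len(ncol(f1)) - 0.5) * px
  mask <- outer(xs, ys, function(x, y) (x - cx)^2 + (y - cy)^2 <= radius^2)
  if (!any(mask)) stop("empty ROI: no pixel centre falls inside the circle",
                       call. = FALSE)
  vals <- vapply(frames, function(fr) {
    v <- mean(fr[mask])
    if (normalize) v <- v / mean(fr)
    v
  }, 0.0)
  steps <- attr(frames, "steps")
  tibble::tibble(frame = seq_along(frames),
                 step = if (is.null(steps)) NA_integer_ else steps,
                 value = vals)
}

#' Kymograph along a line
#'
#' Stacks the intensity profile along a fixed line segment over time, the
#' standard position-versus-time visualisation of aster condensation.
#'
#' @param frames List of `cortex_frame`s.
#' @param x0,y0,x1,y1 Line segment endpoints (um).
#' @param width_px Number of parallel lines averaged across the segment's
#'   perpendicular (odd; 1 = the line itself).
#' @return A matrix (position along the line, by frame) with attribute
#'   `positions` (um along the line).
#' @export
kymograph <- function(frames, x0, y0, x1, y1, width_px = 1) {
  f1 <- frames[[1]]
  px <- attr(f1, "pixel_size")
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  n <- max(2L, ceiling(len / px) + 1L)
  tt <- seq(0, 1, length.out = n)
  ux <- (x1 - x0) / len; uy <- (y1 - y0) / len
  offs <- (seq_len(width_px) - (width_px + 1) / 2) * px
  idx_of <- function(fr, sx, sy) {
    ix <- pmin(pmax(floor((sx - attr(fr, "x0")) / px) + 1L, 1L), nrow(fr))
    iy <- pmin(pmax(floor((sy - attr(fr, "y0")) / px) + 1L, 1L), ncol(fr))
    cbind(ix, iy)
  }
  out <- vapply(frames, function(fr) {
    prof <- numeric(n)
    for (o in offs) {
      sx <- x0 + tt * (x1 - x0) - o * uy
      sy <- y0 + tt * (y1 - y0) + o * ux
      prof <- prof + fr[idx_of(fr, sx, sy)]
    }
    prof / length(offs)
  }, numeric(n))
  attr(out, "positions") <- tt * len
  out
}

#' Coarse-grained hexagon segmentation
#'
#' Tiles the domain with small hexagons and highlights, per frame, the
#' hexagons whose mean intensity is at least `fold_threshold` times the
#' global mean intensity of the whole stack (all frames, all pixels).
#' Adjacent highlighted hexagons merge into regions; the per-frame region
#' count, mean intensity, area and minimum distance to the domain boundary
#' are reported.
#'
#' @param frames List of `cortex_frame`s.
#' @param hex_size Circumradius of the tiling hexagons (um).
#' @param fold_threshold Highlight threshold (default 1.7-fold).
#' @param domain A [hexagon_domain()] for the boundary-distance calculation.
#' @return A tibble with one row per frame: `frame`, `step`, `n_regions`,
#'   `mean_intensity` (mean over highlighted regions, NA if none),
#'   `area` (um^2), `min_boundary_distance` (um).
#' @export
coarse_hexagon_segmentation <- function(frames, hex_size = 0.5,
                                        fold_threshold = 1.7,
                                        domain = hexagon_domain(5)) {
  f1 <- frames[[1]]
  px <- attr(f1, "pixel_size")
  xs <- attr(f1, "x0") + (seq_len(nrow(f1)) - 0.5) * px
  ys <- attr(f1, "y0") + (seq_len(ncol(f1)) - 0.5) * px
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  hexes <- axial_round(gx, gy, hex_size)
  hex_id <- paste(hexes$q, hexes$r)
  global_mean <- mean(vapply(frames, mean, 0.0))
  steps <- attr(frames, "steps")
  hex_area <- 3 * sqrt(3) / 2 * hex_size^2
  rows <- lapply(seq_along(frames), function(k) {
    mu <- tapply(as.vector(frames[[k]]), hex_id, mean)
    hot <- names(mu)[mu >= fold_threshold * global_mean & mu > 0]
    if (length(hot) == 0 || global_mean == 0) {
      return(tibble::tibble(frame = k,
                            step = if (is.null(steps)) NA_integer_
                                   else steps[k],
                            n_regions = 0L, mean_intensity = NA_real_,
                            area = 0, min_boundary_distance = NA_real_))
    }
    qr <- do.call(rbind, lapply(strsplit(hot, " "), as.integer))
    comp <- hex_components(qr)
    cx <- hex_size * (sqrt(3) * qr[, 1] + sqrt(3) / 2 * qr[, 2])
    cy <- hex_size * (3 / 2 * qr[, 2])
    bdist <- hex_boundary_distance(cx, cy, domain)
    tibble::tibble(
      frame = k, step = if (is.null(steps)) NA_integer_ else steps[k],
      n_regions = max(comp),
      mean_intensity = mean(mu[hot]),
      area = length(hot) * hex_area,
      min_boundary_distance = min(bdist))
  })
  dplyr::bind_rows(rows)
}

# axial hex coordinates (pointy-top) with cube rounding
axial_round <- function(x, y, s) {
  q <- (sqrt(3) / 3 * x - 1 / 3 * y) / s
  r <- (2 / 3 * y) / s
  xq <- q; zq <- r; yq <- -xq - zq
  rx <- round(xq); ry <- round(yq); rz <- round(zq)
  dx <- abs(rx - xq); dy <- abs(ry - yq); dz <- abs(rz - zq)
  fx <- dx > dy & dx > dz
  fz <- !fx & dz > dy
  rx[fx] <- -ry[fx] - rz[fx]
  rz[fz] <- -rx[fz] - ry[fz]
  list(q = as.integer(rx), r = as.integer(rz))
}

# connected components over axial hex neighbours (union-find, tiny n)
hex_components <- function(qr) {
  n <- nrow(qr)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  dirs <- rbind(c(1, 0), c(1, -1), c(0, -1), c(-1, 0), c(-1, 1), c(0, 1))
  key <- paste(qr[, 1], qr[, 2])
  lut <- stats::setNames(seq_len(n), key)
  for (i in seq_len(n)) {
    for (d in seq_len(6)) {
      nb <- paste(qr[i, 1] + dirs[d, 1], qr[i, 2] + dirs[d, 2])
      j <- lut[nb]
      if (!is.na(j)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  as.integer(factor(roots))
}

# distance from interior points to the domain hexagon's boundary
hex_boundary_distance <- function(x, y, domain) {
  apothem <- sqrt(3) / 2 * domain$circumradius
  d <- rep(Inf, length(x))
  for (k in 0:2) {
    a <- pi / 6 + k * pi / 3
    proj <- x * cos(a) + y * sin(a)
    d <- pmin(d, apothem - proj, apothem + proj)
  }
  d
}

#' Mean motor exerted force
#'
#' Mean over all motors of the spring-force magnitude each currently exerts;
#' motors not spanning two load-bearing attachments contribute zero. The
#' companion `mean_exerting` averages over force-exerting motors only.
#'
#' @param state A [cortex_state()].
#' @param stiffness Motor stiffness k (pN/um).
#' @return A list: `mean_all`, `mean_exerting`, `n_exerting`, and the
#'   per-motor `force` vector (pN).
#' @export
mean_motor_force <- function(state, stiffness = 3) {
  m <- motor_head_positions(state)
  loaded <- m$a_state != "free" & m$b_state != "free"
  d <- sqrt((m$a_x - m$b_x)^2 + (m$a_y - m$b_y)^2)
  force <- ifelse(loaded, stiffness * d, 0)
  exerting <- force > 0
  list(mean_all = if (nrow(m)) mean(force) else 0,
       mean_exerting = if (any(exerting)) mean(force[exerting]) else 0,
       n_exerting = sum(exerting),
       force = force)
}

#' Plus-end connectedness
#'
#' Fraction of filament plus-ends belonging to the largest single-linkage
#' cluster at the given linking radius. This is a reconstruction: the figure
#' quantity it mirrors was never defined by its source analysis, so the
#' single-linkage-largest-cluster reading is this package's own definition.
#'
#' @param filaments Filaments tibble.
#' @param radius Linking radius (um); 2x the motor reach by default.
#' @param L Filament length (um).
#' @return A fraction in `(0, 1]`.
#' @export
plus_end_connectedness <- function(filaments, radius = 0.6, L = 1) {
  stopifnot(radius > 0)
  n <- nrow(filaments)
  if (n <= 1) return(1)
  px <- filaments$x + (L / 2) * cos(filaments$theta)
  py <- filaments$y + (L / 2) * sin(filaments$theta)
  hc <- stats::hclust(stats::dist(cbind(px, py)), method = "single")
  cl <- stats::cutree(hc, h = radius)
  max(tabulate(cl)) / n
}

#' Work-energy accounting between two states
#'
#' The network is a dissipative system: motors inject work, part is stored
#' as spring elastic energy, and filament motion loses the rest to viscous
#' drag. For a pair of consecutive states this returns the elastic potential
#' energy of the later state (`sum over connectors of k*extension^2/2`), the
#' viscous dissipation implied by the realized filament displacements
#' (`sum of (G_par dx_par^2 + G_perp dx_perp^2 + G_rot dtheta^2)/dt`), and
#' the motor state counts.
#'
#' @param before,after Two [cortex_state()]s one step apart.
#' @param config The [cortex_config()] in force during the step.
#' @return A one-row tibble: `elastic`, `dissipation`, `n_two_bound`,
#'   `n_one_bound`, `n_free` (energies in pN um).
#' @export
energy_accounting <- function(before, after, config) {
  forces <- accumulate_forces(after, config)
  m <- after$motors
  loaded <- m$a_state != "free" & m$b_state != "free"
  nb <- (m$a_state != "free") + (m$b_state != "free")
  drags <- drag_coefficients(config$filament_length,
                             config$filament_diameter,
                             config$dynamic_viscosity)
  fb <- before$filaments
  fa <- after$filaments
  ct <- cos(fb$theta); st <- sin(fb$theta)
  dx <- fa$x - fb$x; dy <- fa$y - fb$y
  dpar <- ct * dx + st * dy
  dperp <- -st * dx + ct * dy
  dth <- fa$theta - fb$theta
  moved <- fb$mobile
  dissip <- sum((drags$par * dpar[moved]^2 + drags$perp * dperp[moved]^2 +
                 drags$rot * dth[moved]^2)) / config$timestep
  tibble::tibble(
    elastic = forces$elastic,
    dissipation = dissip,
    n_two_bound = sum(loaded),
    n_one_bound = sum(nb >= 1 & !loaded),
    n_free = sum(nb == 0))
}
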