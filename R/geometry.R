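#' Hexagonal simulation domain
#'
#' The model evolves inside an open regular hexagon centred at the origin,
#' oriented with a vertex on the positive x axis (flat top and bottom edges).
#' Its inradius (apothem) is `sqrt(3)/2` times the circumradius and its area
#' is `3*sqrt(3)/2 * circumradius^2`.
#'
#' @param circumradius Distance from the centre to a vertex (um).
#' @return A list with class `"hexagon_domain"`.
#' @export
#' @examples
#' dom <- hexagon_domain(5)
#' hexagon_area(dom)
hexagon_domain <- function(circumradius = 5) {
  stopifnot(is.numeric(circumradius), length(circumradius) == 1,
            circumradius > 0)
  structure(list(circumradius = circumradius, center = c(0, 0)),
            class = "hexagon_domain")
}

#' @rdname hexagon_domain
#' @param domain A `hexagon_domain`.
#' @export
hexagon_area <- function(domain) {
  3 * sqrt(3) / 2 * domain$circumradius^2
}

#' Exact hexagon membership test
#'
#' A point is inside iff its projection onto each of the six edge normals
#' (at angles 30 + 60k degrees for this vertex-right orientation) does not
#' exceed the inradius. Points on the boundary count as inside.
#'
#' @param domain A [hexagon_domain()].
#' @param x,y Point coordinates (um); vectorised.
#' @return Logical vector.
#' @export
hexagon_contains <- function(domain, x, y) {
  apothem <- sqrt(3) / 2 * domain$circumradius
  phi <- pi / 6 + pi / 3 * (0:2)
  inside <- rep(TRUE, length(x))
  tol <- 1e-12 * domain$circumradius
  for (a in phi) {
    inside <- inside & (abs(x * cos(a) + y * sin(a)) <= apothem + tol)
  }
  inside
}

#' Uniform sampling over the hexagon
#'
#' Samples points uniformly by picking one of the six centre-to-edge triangles
#' and sampling uniformly within it (square-root map, no rejection), so the
#' number of random draws per point is fixed (three).
#'
#' @param domain A [hexagon_domain()].
#' @param n Number of points.
#' @return A tibble with columns `x`, `y`.
#' @export
sample_hexagon <- function(domain, n) {
  if (n == 0) return(tibble::tibble(x = double(), y = double()))
  R <- domain$circumradius
  tri <- pmin(floor(stats::runif(n) * 6), 5)
  s <- sqrt(stats::runif(n))
  t <- stats::runif(n)
  a1 <- tri * pi / 3
  a2 <- (tri + 1) * pi / 3
  ax <- R * cos(a1); ay <- R * sin(a1)
  bx <- R * cos(a2); by <- R * sin(a2)
  tibble::tibble(x = s * ((1 - t) * ax + t * bx),
                 y = s * ((1 - t) * ay + t * by))
}

#' Horizontal band regions of the domain
#'
#' The patterned-substrate experiments anchor agents in the "bottom eighth" or
#' "bottom fourth" of the hexagon. The cut is placed so the band holds the
#' requested fraction of the hexagon's *area* (so uniformly distributed agents
#' land in it with that probability — an eighth of the motors are tethered by
#' the bottom-eighth band); `by = "height"` cuts the bounding box height
#' instead.
#'
#' @param domain A [hexagon_domain()].
#' @param fraction Fraction of the hexagon (area or height) taken from the
#'   bottom.
#' @param by Either `"area"` (default) or `"height"`.
#' @return A region list (class `"cortex_region"`) usable with [in_region()].
#' @export
bottom_region <- function(domain, fraction, by = c("area", "height")) {
  stopifnot(fraction >= 0, fraction <= 1)
  by <- match.arg(by)
  R <- domain$circumradius
  h <- sqrt(3) * R
  cut <- if (by == "height" || fraction %in% c(0, 1)) {
    -h / 2 + fraction * h
  } else {
    # width at height y is 2R - 2|y|/sqrt(3); invert the cumulative area
    target <- fraction * hexagon_area(domain)
    below <- function(y) {
      stats::integrate(function(u) 2 * R - 2 * abs(u) / sqrt(3),
                       -h / 2, y)$value - target
    }
    stats::uniroot(below, c(-h / 2 + 1e-9, h / 2 - 1e-9), tol = 1e-10)$root
  }
  rect_region(-R, R, -h / 2, cut)
}

#' @rdname bottom_region
#' @param xmin,xmax,ymin,ymax Rectangle bounds (um).
#' @export
rect_region <- function(xmin, xmax, ymin, ymax) {
  stopifnot(xmax >= xmin, ymax >= ymin)
  structure(list(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax),
            class = "cortex_region")
}

#' @rdname bottom_region
#' @param region A `cortex_region`.
#' @param x,y Point coordinates; vectorised.
#' @export
in_region <- function(region, x, y) {
  x >= region$xmin & x <= region$xmax & y >= region$ymin & y <= region$ymax
}
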