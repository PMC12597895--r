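#' Planar geometries for cell placement
#'
#' Geometries describe the regions in which synthetic initial conditions
#' place cells: a disc, an annulus, or an axis-aligned rectangle, all in
#' micrometers.
#'
#' @param center numeric length-2, `(x, y)` center in micrometers.
#' @param radius disc radius in micrometers, `> 0`.
#' @return An object of class `geometry`.
#' @export
geom_disc <- function(center = c(0, 0), radius) {
  stopifnot(length(center) == 2L, is.finite(center))
  if (!is.finite(radius) || radius <= 0) {
    stop("disc radius must be positive", call. = FALSE)
  }
  structure(list(variant = "disc", center = as.numeric(center),
                 radius = as.numeric(radius)),
            class = "geometry")
}

#' @rdname geom_disc
#' @param r_inner,r_outer annulus radii in micrometers,
#'   `0 <= r_inner < r_outer`.
#' @export
geom_annulus <- function(center = c(0, 0), r_inner, r_outer) {
  stopifnot(length(center) == 2L, is.finite(center))
  if (!is.finite(r_inner) || !is.finite(r_outer) ||
      r_inner < 0 || r_inner >= r_outer) {
    stop("annulus requires 0 <= r_inner < r_outer", call. = FALSE)
  }
  structure(list(variant = "annulus", center = as.numeric(center),
                 r_inner = as.numeric(r_inner), r_outer = as.numeric(r_outer)),
            class = "geometry")
}

#' @rdname geom_disc
#' @param x_min,y_min,x_max,y_max rectangle bounds in micrometers.
#' @export
geom_rect <- function(x_min, y_min, x_max, y_max) {
  if (!(x_min < x_max) || !(y_min < y_max)) {
    stop("rectangle requires x_min < x_max and y_min < y_max", call. = FALSE)
  }
  structure(list(variant = "rectangle",
                 x_min = as.numeric(x_min), y_min = as.numeric(y_min),
                 x_max = as.numeric(x_max), y_max = as.numeric(y_max)),
            class = "geometry")
}

#' @export
print.geometry <- function(x, ...) {
  desc <- switch(x$variant,
    disc = sprintf("disc center (%g, %g), radius %g um",
                   x$center[1], x$center[2], x$radius),
    annulus = sprintf("annulus center (%g, %g), radii [%g, %g] um",
                      x$center[1], x$center[2], x$r_inner, x$r_outer),
    rectangle = sprintf("rectangle [%g, %g] x [%g, %g] um",
                        x$x_min, x$x_max, x$y_min, x$y_max))
  cat("<geometry>", desc, "\n")
  invisible(x)
}

# Tight bounding box of a geometry, c(xmin, xmax, ymin, ymax).
geometry_bbox <- function(geom) {
  switch(geom$variant,
    disc = c(geom$center[1] - geom$radius, geom$center[1] + geom$radius,
             geom$center[2] - geom$radius, geom$center[2] + geom$radius),
    annulus = c(geom$center[1] - geom$r_outer, geom$center[1] + geom$r_outer,
                geom$center[2] - geom$r_outer, geom$center[2] + geom$r_outer),
    rectangle = c(geom$x_min, geom$x_max, geom$y_min, geom$y_max))
}

#' Sample points uniformly by area in a geometry
#'
#' Disc sampling uses the inverse-CDF radius transform `r = R * sqrt(u)`;
#' annulus sampling uses `r = sqrt(r_in^2 + u * (r_out^2 - r_in^2))`; the
#' rectangle uses independent uniforms. Both radial transforms make the
#' point density uniform per unit area.
#'
#' @param n number of points, `>= 0`.
#' @param geom a [geom_disc()], [geom_annulus()] or [geom_rect()].
#' @return A two-column matrix of `(x, y)` positions in micrometers. Draws
#'   come from R's global random stream; seed with [set.seed()] for
#'   reproducibility.
#' @export
sample_uniform_in_geometry <- function(n, geom) {
  stopifnot(inherits(geom, "geometry"))
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("`n` must be a non-negative count", call. = FALSE)
  if (n == 0L) {
    return(matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("x", "y"))))
  }
  out <- switch(geom$variant,
    disc = {
      r <- geom$radius * sqrt(stats::runif(n))
      th <- 2 * pi * stats::runif(n)
      cbind(geom$center[1] + r * cos(th), geom$center[2] + r * sin(th))
    },
    annulus = {
      r2 <- geom$r_inner^2 + stats::runif(n) * (geom$r_outer^2 - geom$r_inner^2)
      r <- sqrt(r2)
      th <- 2 * pi * stats::runif(n)
      cbind(geom$center[1] + r * cos(th), geom$center[2] + r * sin(th))
    },
    rectangle = cbind(stats::runif(n, geom$x_min, geom$x_max),
                      stats::runif(n, geom$y_min, geom$y_max)))
  colnames(out) <- c("x", "y")
  out
}
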