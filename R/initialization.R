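#' Initial states
#'
#' An `initial_state` is a set of placed model cells ready for simulation or
#' export: positions in micrometers, model type names, and rectangular
#' domain bounds that all cells lie within.
#'
#' @param x,y numeric position vectors (micrometers).
#' @param type character vector of model type names.
#' @param domain numeric length-4, `c(xmin, xmax, ymin, ymax)` in
#'   micrometers.
#' @return An object of class `initial_state` with elements `cells` (a data
#'   frame with columns `x`, `y`, `type`) and `domain`.
#' @export
initial_state <- function(x, y, type, domain) {
  x <- as.numeric(x); y <- as.numeric(y); type <- as.character(type)
  stopifnot(length(x) == length(y), length(x) == length(type))
  domain <- as.numeric(domain)
  if (length(domain) != 4L || domain[1] >= domain[2] || domain[3] >= domain[4]) {
    stop("`domain` must be c(xmin, xmax, ymin, ymax) with positive extent",
         call. = FALSE)
  }
  if (length(x) > 0L) {
    inside <- x >= domain[1] & x <= domain[2] & y >= domain[3] & y <= domain[4]
    if (!all(inside)) {
      stop(sum(!inside), " cell(s) fall outside the domain bounds",
           call. = FALSE)
    }
  }
  structure(list(cells = data.frame(x = x, y = y, type = type,
                                    stringsAsFactors = FALSE),
                 domain = domain),
            class = "initial_state")
}

#' @export
print.initial_state <- function(x, ...) {
  cat(sprintf("<initial_state> %d cells in domain [%g, %g] x [%g, %g] um\n",
              nrow(x$cells), x$domain[1], x$domain[2], x$domain[3],
              x$domain[4]))
  if (nrow(x$cells) > 0L) {
    tb <- table(x$cells$type)
    cat("  ", paste(sprintf("%s: %d", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.initial_state <- function(x, cex = 0.3, ...) {
  types <- sort(unique(x$cells$type))
  cols <- grDevices::hcl.colors(max(3L, length(types)), "Dark 3")[
    seq_along(types)]
  plot(x$cells$x, x$cells$y, col = cols[match(x$cells$type, types)],
       pch = 16, cex = cex, asp = 1, xlab = "x (um)", ylab = "y (um)",
       xlim = x$domain[1:2], ylim = x$domain[3:4], ...)
  graphics::legend("topright", legend = types, col = cols, pch = 16,
                   cex = 0.8, bg = "white")
  invisible(x)
}

.check_counts <- function(counts) {
  if (is.null(names(counts)) || any(names(counts) == "")) {
    stop("`counts` must be a named vector of per-type counts", call. = FALSE)
  }
  counts <- vapply(counts, as.integer, integer(1L))
  if (any(is.na(counts)) || any(counts < 0L)) {
    stop("per-type counts must be non-negative integers", call. = FALSE)
  }
  counts
}

#' Well-mixed initialization
#'
#' Places every cell type uniformly at random in a single disc, the
#' well-mixed initialization of the tumor-immune comparison. Per-type
#' counts are exact.
#'
#' @param counts named integer vector, model type name -> cell count.
#' @param disc a [geom_disc()].
#' @param domain optional domain bounds `c(xmin, xmax, ymin, ymax)`;
#'   defaults to the disc's bounding box padded by 50 um.
#' @return An [initial_state]. Uses R's global random stream.
#' @export
init_well_mixed <- function(counts, disc, domain = NULL) {
  stopifnot(inherits(disc, "geometry"))
  if (disc$variant != "disc") {
    stop("well-mixed initialization requires a disc geometry", call. = FALSE)
  }
  counts <- .check_counts(counts)
  pos <- lapply(names(counts), function(ty) {
    sample_uniform_in_geometry(counts[[ty]], disc)
  })
  xy <- do.call(rbind, pos)
  type <- rep(names(counts), counts)
  if (is.null(domain)) domain <- geometry_bbox(disc) + c(-50, 50, -50, 50)
  initial_state(x = xy[, 1L], y = xy[, 2L], type = type, domain = domain)
}

#' Structured initialization
#'
#' Places epithelial types (cancer and healthy cells interleaved) uniformly
#' in an inner disc and immune types uniformly in a surrounding annulus, the
#' structured initialization in which immune cells encircle the epithelium.
#'
#' @param counts named integer vector, model type name -> cell count.
#' @param inner a [geom_disc()] holding the epithelial compartment.
#' @param ring a [geom_annulus()] sharing the inner disc's center, with
#'   `r_inner >= inner$radius`.
#' @param epithelial_types,immune_types character vectors partitioning the
#'   names of `counts`: every counted type must be in exactly one set.
#' @param domain optional domain bounds; defaults to the annulus bounding
#'   box padded by 50 um.
#' @return An [initial_state]. Uses R's global random stream.
#' @export
init_structured <- function(counts, inner, ring, epithelial_types,
                            immune_types, domain = NULL) {
  stopifnot(inherits(inner, "geometry"), inherits(ring, "geometry"))
  if (inner$variant != "disc" || ring$variant != "annulus") {
    stop("structured initialization requires a disc plus an annulus",
         call. = FALSE)
  }
  if (any(abs(inner$center - ring$center) > 1e-9)) {
    stop("inner disc and annulus must share a center", call. = FALSE)
  }
  if (ring$r_inner < inner$radius) {
    stop("annulus r_inner must be >= inner disc radius", call. = FALSE)
  }
  counts <- .check_counts(counts)
  both <- intersect(epithelial_types, immune_types)
  neither <- setdiff(names(counts), union(epithelial_types, immune_types))
  if (length(both) > 0L || length(neither) > 0L) {
    stop("each counted type must be in exactly one of epithelial_types/",
         "immune_types; offending: ",
         paste(c(both, neither), collapse = ", "), call. = FALSE)
  }
  pos <- lapply(names(counts), function(ty) {
    geom <- if (ty %in% epithelial_types) inner else ring
    sample_uniform_in_geometry(counts[[ty]], geom)
  })
  xy <- do.call(rbind, pos)
  type <- rep(names(counts), counts)
  if (is.null(domain)) domain <- geometry_bbox(ring) + c(-50, 50, -50, 50)
  initial_state(x = xy[, 1L], y = xy[, 2L], type = type, domain = domain)
}

#' 2D similarity transforms
#'
#' A scale-rotation-translation map used to harmonize the coordinate frame
#' of measured spatial data with the simulation frame:
#' `p' = scale * R(rotation) p + translation`.
#'
#' @param scale positive unitless scale factor.
#' @param rotation rotation angle in radians (counter-clockwise).
#' @param translation numeric length-2 offset in micrometers.
#' @return An object of class `affine2d`.
#' @export
affine2d <- function(scale = 1, rotation = 0, translation = c(0, 0)) {
  if (!is.finite(scale) || scale <= 0) {
    stop("`scale` must be positive", call. = FALSE)
  }
  stopifnot(length(translation) == 2L, is.finite(translation),
            is.finite(rotation))
  structure(list(scale = as.numeric(scale), rotation = as.numeric(rotation),
                 translation = as.numeric(translation)),
            class = "affine2d")
}

#' @rdname affine2d
#' @param transform an `affine2d`.
#' @param xy two-column matrix of positions.
#' @return For `apply_affine2d`, the transformed two-column matrix.
#' @export
apply_affine2d <- function(transform, xy) {
  stopifnot(inherits(transform, "affine2d"))
  xy <- as.matrix(xy)
  if (transform$scale == 1 && transform$rotation == 0 &&
      all(transform$translation == 0)) {
    return(xy)  # identity must be bit-exact
  }
  cs <- cos(transform$rotation); sn <- sin(transform$rotation)
  out <- cbind(transform$scale * (cs * xy[, 1L] - sn * xy[, 2L]) +
                 transform$translation[1L],
               transform$scale * (sn * xy[, 1L] + cs * xy[, 2L]) +
                 transform$translation[2L])
  colnames(out) <- colnames(xy)
  out
}

#' Spatial-informed initialization
#'
#' Maps each measured cell directly into the model, preserving the original
#' coordinates and the local microenvironmental structure: one model cell
#' per record, no jitter, no resampling. An optional similarity transform
#' harmonizes units and frame; with the identity transform (the default)
#' positions equal the measured coordinates exactly. Cells sharing a spot
#' centroid stay coincident; the first mechanics steps of a simulation push
#' them apart.
#'
#' @param tab a spatial [cell_table] whose labels are already model type
#'   names (see [select_and_relabel()]).
#' @param transform an [affine2d], or `NULL` for the identity.
#' @param domain_padding margin in micrometers added around the transformed
#'   bounding box to form the simulation domain.
#' @return An [initial_state].
#' @export
init_spatial_informed <- function(tab, transform = NULL, domain_padding = 50) {
  stopifnot(inherits(tab, "cell_table"))
  if (!is_spatial(tab)) {
    stop("spatial-informed initialization requires a spatial cell table",
         call. = FALSE)
  }
  if (is.null(transform)) transform <- affine2d()
  if (nrow(tab) == 0L) {
    return(initial_state(numeric(0), numeric(0), character(0),
                         domain = c(-domain_padding, domain_padding,
                                    -domain_padding, domain_padding)))
  }
  xy <- apply_affine2d(transform, cbind(tab$x, tab$y))
  dom <- c(min(xy[, 1L]) - domain_padding, max(xy[, 1L]) + domain_padding,
           min(xy[, 2L]) - domain_padding, max(xy[, 2L]) + domain_padding)
  initial_state(x = xy[, 1L], y = xy[, 2L], type = tab$type, domain = dom)
}

# Largest-remainder apportionment of total_n seats by the weights in counts,
# ties on the fractional part broken by type-name order.
largest_remainder <- function(counts, total_n) {
  total <- sum(counts)
  quota <- total_n * counts / total
  alloc <- floor(quota)
  left <- total_n - sum(alloc)
  if (left > 0L) {
    rem <- quota - alloc
    ord <- order(-rem, names(counts))
    take <- ord[seq_len(left)]
    alloc[take] <- alloc[take] + 1L
  }
  stats::setNames(as.integer(alloc), names(counts))
}

#' Abundance-based placement for non-spatial data
#'
#' For non-spatial cell tables, assigns cells based on their relative
#' abundances in the measured data into user-specified spatial
#' distributions: each retained type receives
#' `round(total_n * abundance)` cells (largest-remainder rounding so the
#' counts sum exactly to `total_n`), placed uniformly in that type's
#' assigned geometry.
#'
#' @param tab a [cell_table] (its coordinates, if any, are ignored; only
#'   label abundances are used).
#' @param total_n total number of cells to place, `>= 0`.
#' @param assignments named list, model type name -> `geometry`; must cover
#'   every type present in `tab`.
#' @param domain optional domain bounds; defaults to the union bounding box
#'   of the assigned geometries padded by 50 um.
#' @return An [initial_state]. Uses R's global random stream.
#' @export
abundance_placement <- function(tab, total_n, assignments, domain = NULL) {
  stopifnot(inherits(tab, "cell_table"))
  total_n <- as.integer(total_n)
  if (is.na(total_n) || total_n < 0L) {
    stop("`total_n` must be a non-negative count", call. = FALSE)
  }
  if (total_n > 0L && nrow(tab) == 0L) {
    stop("cannot place cells from an empty table", call. = FALSE)
  }
  counts <- table(tab$type)
  missing_geom <- setdiff(names(counts), names(assignments))
  if (length(missing_geom) > 0L) {
    stop("no geometry assigned for type(s): ",
         paste(missing_geom, collapse = ", "), call. = FALSE)
  }
  if (is.null(domain)) {
    boxes <- lapply(assignments, geometry_bbox)
    bb <- Reduce(function(a, b) c(min(a[1], b[1]), max(a[2], b[2]),
                                  min(a[3], b[3]), max(a[4], b[4])), boxes)
    domain <- bb + c(-50, 50, -50, 50)
  }
  if (total_n == 0L || nrow(tab) == 0L) {
    return(initial_state(numeric(0), numeric(0), character(0), domain))
  }
  cvec <- stats::setNames(as.numeric(counts), names(counts))
  cvec <- cvec[order(names(cvec))]
  alloc <- largest_remainder(cvec, total_n)
  pos <- lapply(names(alloc), function(ty) {
    sample_uniform_in_geometry(alloc[[ty]], assignments[[ty]])
  })
  xy <- do.call(rbind, pos)
  initial_state(x = xy[, 1L], y = xy[, 2L],
                type = rep(names(alloc), alloc), domain = domain)
}
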