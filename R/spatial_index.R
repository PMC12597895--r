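#' Uniform-grid spatial index for neighbor queries
#'
#' Bins points into square cells of side `bin_size` so that range queries
#' only inspect the bins overlapping the query disc. The simulation engine
#' uses the same binning internally; this R-level index backs the neighbor
#' graph and ad-hoc queries, and is validated against brute-force all-pairs
#' search in the tests.
#'
#' @param x,y point coordinates (micrometers).
#' @param bin_size bin side length in micrometers; for interaction queries
#'   use at least twice the maximum interaction radius so neighbors are
#'   confined to adjacent bins.
#' @return An object of class `spatial_index`.
#' @export
build_spatial_index <- function(x, y, bin_size) {
  stopifnot(length(x) == length(y), bin_size > 0)
  n <- length(x)
  if (n == 0L) {
    return(structure(list(x = numeric(0), y = numeric(0),
                          bin_size = bin_size, bins = list()),
                     class = "spatial_index"))
  }
  ix <- floor(x / bin_size)
  iy <- floor(y / bin_size)
  key <- paste(ix, iy, sep = ",")
  bins <- split(seq_len(n), key)
  structure(list(x = x, y = y, bin_size = bin_size, bins = bins,
                 ix = ix, iy = iy),
            class = "spatial_index")
}

#' @rdname build_spatial_index
#' @param index a `spatial_index`.
#' @param point numeric length-2 query location.
#' @param r query radius; all points with distance `<= r` are returned.
#' @return For `query_spatial_index`, an integer vector of point indices
#'   (in the order given to `build_spatial_index`).
#' @export
query_spatial_index <- function(index, point, r) {
  stopifnot(inherits(index, "spatial_index"), length(point) == 2L, r >= 0)
  if (length(index$x) == 0L) return(integer(0))
  b <- index$bin_size
  span <- ceiling(r / b)
  cx <- floor(point[1L] / b)
  cy <- floor(point[2L] / b)
  cand <- integer(0)
  for (gx in (cx - span):(cx + span)) {
    for (gy in (cy - span):(cy + span)) {
      hit <- index$bins[[paste(gx, gy, sep = ",")]]
      if (!is.null(hit)) cand <- c(cand, hit)
    }
  }
  if (length(cand) == 0L) return(integer(0))
  d2 <- (index$x[cand] - point[1L])^2 + (index$y[cand] - point[2L])^2
  sort(cand[d2 <= r * r])
}
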