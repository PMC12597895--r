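#' Cross-pair correlation function between two cell types
#'
#' For each center cell, target cells are counted in annular distance bins;
#' the per-center count in bin `[r_k, r_{k+1})` is normalized by the
#' expected count under complete spatial randomness, `lambda_T * a_k` with
#' `a_k = pi (r_{k+1}^2 - r_k^2)` and `lambda_T = N_T / A`, and averaged
#' over centers:
#' `g_k = (1 / N_C) * sum_i n_i(k) / (lambda_T * a_k)`.
#' Values above 1 mean targets are enriched at that distance from centers,
#' below 1 depleted. No boundary edge-correction is applied, which biases
#' `g` downward in bins comparable to the distance of centers from the
#' domain boundary; interpret large-`r` bins accordingly.
#'
#' @param snap an [abm_snapshot] (or anything accepted by [abm_snapshot()]
#'   after conversion).
#' @param center_type,target_type model type names. A cell is never its own
#'   target, which only matters when the two types coincide.
#' @param bin_edges strictly increasing vector of annulus edges in
#'   micrometers, starting at `>= 0`.
#' @param domain_area domain area in square micrometers; defaults to the
#'   area of the snapshot's domain rectangle.
#' @return An object of class `cross_pcf`: list with `bin_edges`, `g`,
#'   `empty` (logical mask of bins containing no target anywhere),
#'   `center_type`, `target_type`, `n_centers`, `n_targets`,
#'   `domain_area`. With zero targets all `g` are 0 and the object carries
#'   `targets_absent = TRUE`.
#' @export
cross_pcf <- function(snap, center_type = "cancer", target_type = "CD8",
                      bin_edges = seq(0, 200, by = 10), domain_area = NULL) {
  stopifnot(inherits(snap, "abm_snapshot"))
  bin_edges <- as.numeric(bin_edges)
  if (length(bin_edges) < 2L || any(diff(bin_edges) <= 0) ||
      bin_edges[1L] < 0) {
    stop("`bin_edges` must be strictly increasing and start at >= 0",
         call. = FALSE)
  }
  if (is.null(domain_area)) {
    d <- snap$domain
    domain_area <- (d[2] - d[1]) * (d[4] - d[3])
  }
  if (domain_area <= 0) stop("domain_area must be positive", call. = FALSE)
  ag <- snap$agents
  ci <- which(ag$type == center_type)
  ti <- which(ag$type == target_type)
  n_c <- length(ci)
  n_t <- length(ti)
  if (n_c == 0L) {
    stop("no cells of center type '", center_type, "' in snapshot",
         call. = FALSE)
  }
  K <- length(bin_edges) - 1L
  out <- structure(
    list(bin_edges = bin_edges, g = numeric(K), empty = rep(TRUE, K),
         center_type = center_type, target_type = target_type,
         n_centers = n_c, n_targets = n_t, domain_area = domain_area,
         targets_absent = n_t == 0L),
    class = "cross_pcf")
  if (n_t == 0L) {
    warning("no cells of target type '", target_type,
            "'; g is 0 in every bin", call. = FALSE)
    return(out)
  }
  # bin all center-target distances; a cell is never its own target but
  # distinct coincident cells do count
  counts <- numeric(K)
  tx <- ag$x[ti]; ty <- ag$y[ti]
  rmax <- bin_edges[K + 1L]
  for (i in ci) {
    d <- sqrt((tx - ag$x[i])^2 + (ty - ag$y[i])^2)
    self <- which(ti == i)
    if (length(self) > 0L) d <- d[-self]
    d <- d[d < rmax]
    k <- findInterval(d, bin_edges)
    k <- k[k >= 1L & k <= K]
    if (length(k) > 0L) counts <- counts + tabulate(k, nbins = K)
  }
  areas <- pi * diff(bin_edges^2)
  lambda_t <- n_t / domain_area
  out$g <- counts / n_c / (lambda_t * areas)
  out$empty <- counts == 0
  out
}

#' @export
print.cross_pcf <- function(x, ...) {
  cat(sprintf(
    "<cross_pcf> %s -> %s, %d centers, %d targets, %d bins [%g, %g] um\n",
    x$center_type, x$target_type, x$n_centers, x$n_targets,
    length(x$g), x$bin_edges[1L], x$bin_edges[length(x$bin_edges)]))
  mid <- (utils::head(x$bin_edges, -1L) + utils::tail(x$bin_edges, -1L)) / 2
  print(utils::head(data.frame(r_mid = mid, g = signif(x$g, 4)), 8L))
  invisible(x)
}

#' Cross-PCF time series over a trajectory
#'
#' Computes [cross_pcf()] for every saved snapshot, producing the
#' time-by-distance enrichment matrix displayed as a heatmap of vertical
#' strips (one per time point). Snapshots with no center cells yield a
#' masked (all-`NA`) row.
#'
#' @param trajectory an [abm_trajectory].
#' @inheritParams cross_pcf
#' @return An object of class `cross_pcf_series`: list with `times` (min),
#'   `bin_edges`, matrix `G` (times x bins, `NA` rows masked), and the type
#'   names.
#' @export
cross_pcf_timeseries <- function(trajectory, center_type = "cancer",
                                 target_type = "CD8",
                                 bin_edges = seq(0, 200, by = 10)) {
  stopifnot(inherits(trajectory, "abm_trajectory"))
  snaps <- trajectory$snapshots
  K <- length(bin_edges) - 1L
  G <- matrix(NA_real_, nrow = length(snaps), ncol = K)
  for (s in seq_along(snaps)) {
    snap <- snaps[[s]]
    if (sum(snap$agents$type == center_type) == 0L) next
    p <- suppressWarnings(cross_pcf(snap, center_type, target_type,
                                    bin_edges))
    G[s, ] <- p$g
  }
  structure(list(times = vapply(snaps, `[[`, numeric(1), "time"),
                 bin_edges = bin_edges, G = G,
                 center_type = center_type, target_type = target_type),
            class = "cross_pcf_series")
}

#' @export
print.cross_pcf_series <- function(x, ...) {
  cat(sprintf("<cross_pcf_series> %s -> %s, %d time points x %d bins\n",
              x$center_type, x$target_type, nrow(x$G), ncol(x$G)))
  invisible(x)
}

#' @export
plot.cross_pcf_series <- function(x, zmax = NULL, ...) {
  G <- x$G
  if (is.null(zmax)) zmax <- max(2, stats::quantile(G, 0.98, na.rm = TRUE))
  Gc <- pmin(G, zmax)
  graphics::image(x = x$times / 60,
                  y = (utils::head(x$bin_edges, -1L) +
                       utils::tail(x$bin_edges, -1L)) / 2,
                  z = Gc, col = grDevices::hcl.colors(64, "Viridis"),
                  xlab = "time (h)", ylab = "distance (um)", ...)
  invisible(x)
}

#' Contact neighbor graph of a snapshot
#'
#' Connects every pair of cells whose center distance is at most
#' `contact_scale * (r_i + r_j)`. Edges are found with a uniform spatial
#' binning (identical results to all-pairs search, which the tests verify).
#'
#' @param snap an [abm_snapshot] with a `radius` column in its agents.
#' @param contact_scale unitless multiplier on summed radii, `>= 1`.
#' @return An object of class `neighbor_graph`: list with `ids` (agent ids,
#'   node order), `edges` (2-column matrix of node indices, `i < j`), and
#'   `types`.
#' @export
neighbor_graph <- function(snap, contact_scale = 1.25) {
  stopifnot(inherits(snap, "abm_snapshot"))
  if (contact_scale < 1) stop("contact_scale must be >= 1", call. = FALSE)
  ag <- snap$agents
  edges <- close_pairs_cpp(ag$x, ag$y, ag$radius, contact_scale)
  structure(list(ids = ag$id, edges = edges, types = ag$type,
                 contact_scale = contact_scale),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("<neighbor_graph> %d nodes, %d edges (contact_scale %g)\n",
              length(x$ids), nrow(x$edges), x$contact_scale))
  invisible(x)
}

#' Cancer-cell connected components
#'
#' Sizes of the connected components of the subgraph induced by cancer
#' cells (default), or of the full-graph components counting only their
#' cancer members (`induced = FALSE`), matching the two conventions for
#' counting cancer cells per cluster.
#'
#' @param graph a [neighbor_graph()].
#' @param cancer_type model type name of the malignant population.
#' @param induced if `TRUE` (default) components are computed on the
#'   cancer-cell-induced subgraph; if `FALSE` on the full graph, reporting
#'   each component's cancer-cell count (components without cancer cells
#'   are dropped).
#' @return Integer vector of cancer-cell counts per component (unordered).
#' @export
cancer_components <- function(graph, cancer_type = "cancer", induced = TRUE) {
  stopifnot(inherits(graph, "neighbor_graph"))
  is_cancer <- graph$types == cancer_type
  n <- length(graph$ids)
  if (sum(is_cancer) == 0L) return(integer(0))
  e <- graph$edges
  if (induced) {
    keep_nodes <- which(is_cancer)
    remap <- integer(n)
    remap[keep_nodes] <- seq_along(keep_nodes)
    ke <- e[is_cancer[e[, 1L]] & is_cancer[e[, 2L]], , drop = FALSE]
    g <- igraph::make_graph(t(cbind(remap[ke[, 1L]], remap[ke[, 2L]])),
                            n = length(keep_nodes), directed = FALSE)
    comp <- igraph::components(g)
    as.integer(tabulate(comp$membership, nbins = comp$no))
  } else {
    g <- igraph::make_graph(t(e), n = n, directed = FALSE)
    comp <- igraph::components(g)
    sizes <- vapply(seq_len(comp$no), function(k) {
      sum(is_cancer[comp$membership == k])
    }, integer(1))
    sizes[sizes > 0L]
  }
}

#' Cumulative distribution of cancer cells over component sizes
#'
#' `F(s)` is the fraction of all cancer cells that sit in components of
#' size at most `s`, evaluated at each distinct component size: a
#' cell-weighted (not component-weighted) cumulative distribution.
#'
#' @param sizes integer vector of per-component cancer-cell counts, each
#'   `>= 1` (as returned by [cancer_components()]).
#' @return An object of class `component_cdf`: list with `sizes` (sorted
#'   unique sizes) and `F` (cumulative cell fractions, reaching 1 at the
#'   largest size). An empty input yields an empty CDF with
#'   `empty = TRUE`.
#' @export
component_cdf <- function(sizes) {
  sizes <- as.integer(sizes)
  if (length(sizes) == 0L) {
    return(structure(list(sizes = integer(0), F = numeric(0), empty = TRUE),
                     class = "component_cdf"))
  }
  if (any(sizes < 1L)) stop("component sizes must be >= 1", call. = FALSE)
  u <- sort(unique(sizes))
  mass <- vapply(u, function(s) sum(sizes[sizes == s]), numeric(1))
  structure(list(sizes = u, F = cumsum(mass) / sum(sizes), empty = FALSE),
            class = "component_cdf")
}

#' @export
print.component_cdf <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat("<component_cdf> empty (no cancer cells)\n")
  } else {
    cat(sprintf("<component_cdf> %d distinct sizes, max %d\n",
                length(x$sizes), max(x$sizes)))
  }
  invisible(x)
}

# Right-continuous step evaluation of a component CDF at arbitrary sizes:
# F(s) = fraction of cells in components of size <= s, F == 0 below the
# smallest observed size.
eval_component_cdf <- function(cdf, at) {
  if (isTRUE(cdf$empty)) return(rep(NA_real_, length(at)))
  idx <- findInterval(at, cdf$sizes)
  out <- numeric(length(at))
  out[idx > 0L] <- cdf$F[idx[idx > 0L]]
  out
}

#' Aggregate replicate curves into mean and SD series
#'
#' `aggregate_series()` averages numeric vectors sharing a common grid;
#' `aggregate_component_cdfs()` first evaluates each replicate CDF on the
#' union of all observed component sizes by right-continuous step
#' interpolation, then aggregates. The SD is the sample standard deviation
#' (denominator `n - 1`), reported as 0 for a single replicate; curves are
#' shaded as mean +/- 1 SD in the report figures.
#'
#' @param curves list of numeric vectors, all the same length (one per
#'   replicate).
#' @return For `aggregate_series`, a list with `mean` and `sd` vectors.
#' @export
aggregate_series <- function(curves) {
  stopifnot(is.list(curves), length(curves) >= 1L)
  len <- lengths(curves)
  if (any(len != len[1L])) {
    stop("replicate curves are not on a common grid", call. = FALSE)
  }
  m <- do.call(rbind, curves)
  mean_v <- colMeans(m)
  sd_v <- if (nrow(m) > 1L) apply(m, 2L, stats::sd) else numeric(ncol(m))
  list(mean = mean_v, sd = sd_v)
}

#' @rdname aggregate_series
#' @param cdfs list of [component_cdf] objects (one per replicate).
#' @return For `aggregate_component_cdfs`, a list with `sizes` (union
#'   grid), `F_mean`, `F_sd`, and the per-replicate evaluated matrix `F`.
#' @export
aggregate_component_cdfs <- function(cdfs) {
  stopifnot(is.list(cdfs), length(cdfs) >= 1L)
  for (c0 in cdfs) stopifnot(inherits(c0, "component_cdf"))
  nonempty <- !vapply(cdfs, function(c0) isTRUE(c0$empty), logical(1))
  if (!any(nonempty)) {
    return(list(sizes = integer(0), F_mean = numeric(0), F_sd = numeric(0),
                F = matrix(numeric(0), nrow = length(cdfs), ncol = 0L)))
  }
  grid <- sort(unique(unlist(lapply(cdfs[nonempty], `[[`, "sizes"))))
  m <- do.call(rbind, lapply(cdfs, eval_component_cdf, at = grid))
  agg <- aggregate_series(lapply(seq_len(nrow(m)), function(i) m[i, ]))
  list(sizes = grid, F_mean = agg$mean, F_sd = agg$sd, F = m)
}
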