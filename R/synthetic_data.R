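#' Specification for the synthetic PDAC-like tissue sample
#'
#' Parameters of the synthetic spatial sample that emulates the salient
#' architecture of a pancreatic ductal adenocarcinoma biospecimen: a
#' near-confluent malignant core, a surrounding healthy epithelial ring,
#' and immune (CD8+ T) cells whose density peaks at the border of the
#' malignant compartment.
#'
#' @param n_cancer,n_healthy,n_immune per-type cell counts.
#' @param core_radius radius of the malignant core disc, um.
#' @param border_sd SD of the immune radial distribution around the core
#'   border, um.
#' @param healthy_ring_width width of the healthy annulus outside the
#'   core, um.
#' @param jitter_sd positional jitter applied to the cancer lattice, um.
#' @param seed integer seed making the sample deterministic.
#' @return A `pdac_sample_spec` list.
#' @details The defaults (1500 cancer, 800 healthy, 600 immune cells; core
#'   radius 350 um) are synthetic stand-ins chosen to give a desk-scale
#'   total of ~2900 agents; the real biospecimen's abundances are not
#'   published.
#' @export
pdac_sample_spec <- function(n_cancer = 1500, n_healthy = 800,
                             n_immune = 600, core_radius = 350,
                             border_sd = 50, healthy_ring_width = 200,
                             jitter_sd = 2, seed = 42) {
  counts <- c(n_cancer, n_healthy, n_immune)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  if (core_radius <= 0 || border_sd <= 0) {
    stop("core_radius and border_sd must be positive", call. = FALSE)
  }
  if (healthy_ring_width < 0 || jitter_sd < 0) {
    stop("healthy_ring_width and jitter_sd must be >= 0", call. = FALSE)
  }
  structure(list(n_cancer = as.integer(n_cancer),
                 n_healthy = as.integer(n_healthy),
                 n_immune = as.integer(n_immune),
                 core_radius = core_radius, border_sd = border_sd,
                 healthy_ring_width = healthy_ring_width,
                 jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "pdac_sample_spec")
}

# Triangular lattice points with given spacing covering a disc of radius R
# centered at the origin, ordered center-outward (ties by angle) so that
# truncation keeps a compact core.
triangular_lattice_in_disc <- function(R, spacing) {
  row_h <- spacing * sqrt(3) / 2
  rows <- seq(-ceiling(R / row_h), ceiling(R / row_h))
  pts <- do.call(rbind, lapply(rows, function(j) {
    yj <- j * row_h
    off <- if (j %% 2 == 0) 0 else spacing / 2
    is <- seq(-ceiling((R + spacing) / spacing),
              ceiling((R + spacing) / spacing))
    cbind(is * spacing + off, yj)
  }))
  r2 <- pts[, 1L]^2 + pts[, 2L]^2
  pts <- pts[r2 <= R^2, , drop = FALSE]
  r2 <- pts[, 1L]^2 + pts[, 2L]^2
  ang <- atan2(pts[, 2L], pts[, 1L])
  pts[order(r2, ang), , drop = FALSE]
}

#' Generate a synthetic PDAC-like spatial cell table
#'
#' Builds a spatial [cell_table] with the architecture of an
#' immune-infiltrated tumor border: cancer cells on a jittered triangular
#' lattice (16 um spacing, i.e. near-confluent for 8 um radii) filling the
#' core disc center-outward and truncated to `n_cancer`; healthy cells
#' uniform in the annulus `[core_radius, core_radius +
#' healthy_ring_width]`; immune cells at radius `Normal(core_radius,
#' border_sd)` (rejection-sampled to positive radii) with uniform angle, so
#' immune density peaks at the malignant border. Labels are `"cancer"`,
#' `"healthy"`, `"CD8"`.
#'
#' @param spec a [pdac_sample_spec()].
#' @return A spatial [cell_table], deterministic under `spec$seed`.
#' @examples
#' tab <- generate_pdac_like_sample(pdac_sample_spec(n_cancer = 200,
#'   n_healthy = 100, n_immune = 50, core_radius = 150))
#' table(tab$type)
#' @export
generate_pdac_like_sample <- function(spec = pdac_sample_spec()) {
  stopifnot(inherits(spec, "pdac_sample_spec"))
  spacing <- 16
  set.seed(spec$seed)
  lattice <- triangular_lattice_in_disc(spec$core_radius, spacing)
  if (spec$n_cancer > nrow(lattice)) {
    stop(sprintf(paste0(
      "core disc of radius %g um holds only %d lattice sites at %g um ",
      "spacing but n_cancer = %d; increase core_radius"),
      spec$core_radius, nrow(lattice), spacing, spec$n_cancer),
      call. = FALSE)
  }
  cx <- cy <- numeric(0)
  if (spec$n_cancer > 0L) {
    keep <- lattice[seq_len(spec$n_cancer), , drop = FALSE]
    cx <- keep[, 1L] + stats::rnorm(spec$n_cancer, 0, spec$jitter_sd)
    cy <- keep[, 2L] + stats::rnorm(spec$n_cancer, 0, spec$jitter_sd)
  }
  hxy <- matrix(numeric(0), ncol = 2L)
  if (spec$n_healthy > 0L) {
    hxy <- sample_uniform_in_geometry(
      spec$n_healthy,
      geom_annulus(c(0, 0), spec$core_radius,
                   spec$core_radius + spec$healthy_ring_width))
  }
  ix <- iy <- numeric(0)
  if (spec$n_immune > 0L) {
    r <- numeric(0)
    while (length(r) < spec$n_immune) {
      draw <- stats::rnorm(spec$n_immune, spec$core_radius, spec$border_sd)
      r <- c(r, draw[draw > 0])
    }
    r <- r[seq_len(spec$n_immune)]
    th <- 2 * pi * stats::runif(spec$n_immune)
    ix <- r * cos(th); iy <- r * sin(th)
  }
  n_tot <- spec$n_cancer + spec$n_healthy + spec$n_immune
  cell_table(
    id = sprintf("cell_%05d", seq_len(n_tot)),
    type = rep(c("cancer", "healthy", "CD8"),
               c(spec$n_cancer, spec$n_healthy, spec$n_immune)),
    x = c(cx, hxy[, 1L], ix),
    y = c(cy, hxy[, 2L], iy))
}
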