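#' Experiment configuration
#'
#' Describes the full initialization-comparison experiment: a set of named
#' scenarios (each an initialization strategy plus its geometry), the
#' number of replicates with their seeds, the simulated duration, and the
#' analysis settings. The default configuration reproduces the shipped
#' study design: three scenarios (well-mixed, structured,
#' spatial-informed) x three replicates x five simulated days.
#'
#' @param scenarios named list of scenario specs; see
#'   [default_experiment_config()] for the shipped shape. Each scenario is
#'   a list with a `strategy` field (`"wellmixed"`, `"structured"` or
#'   `"spatial"`) and strategy-specific geometry/counts fields.
#' @param replicates number of replicates per scenario.
#' @param seeds integer vector of per-replicate seeds,
#'   `length(seeds) == replicates`.
#' @param duration_days simulated duration in days, `> 0`.
#' @param save_interval_min snapshot interval, min.
#' @param sim a [simulation_config()] providing types, attack and mechanics
#'   parameters (its duration is overridden by `duration_days`).
#' @param pcf_bin_edges distance bin edges (um) for the cross-PCF series.
#' @param contact_scale contact multiplier for the endpoint neighbor graph.
#' @param output_dir directory receiving all artifacts.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(scenarios, replicates = 3L, seeds = 1:3,
                              duration_days = 5, save_interval_min = 60,
                              sim = default_simulation_config(),
                              pcf_bin_edges = seq(0, 200, by = 10),
                              contact_scale = 1.25,
                              output_dir = "spatabm_experiment") {
  stopifnot(is.list(scenarios), length(scenarios) >= 1L)
  if (is.null(names(scenarios)) || any(names(scenarios) == "")) {
    stop("`scenarios` must be a named list", call. = FALSE)
  }
  replicates <- as.integer(replicates)
  seeds <- as.integer(seeds)
  if (length(seeds) != replicates) {
    stop("length(seeds) must equal replicates", call. = FALSE)
  }
  if (duration_days <= 0) stop("duration_days must be > 0", call. = FALSE)
  for (nm in names(scenarios)) {
    sc <- scenarios[[nm]]
    if (is.null(sc$strategy) ||
        !sc$strategy %in% c("wellmixed", "structured", "spatial")) {
      stop("scenario '", nm, "' needs a strategy of wellmixed, structured ",
           "or spatial", call. = FALSE)
    }
  }
  structure(list(scenarios = scenarios, replicates = replicates,
                 seeds = seeds, duration_days = duration_days,
                 save_interval_min = save_interval_min, sim = sim,
                 pcf_bin_edges = as.numeric(pcf_bin_edges),
                 contact_scale = contact_scale, output_dir = output_dir),
            class = "experiment_config")
}

#' Shipped default experiment
#'
#' Three scenarios with a common cell census (1500 cancer, 800 healthy,
#' 600 CD8+ T cells):
#' \describe{
#'   \item{wellmixed}{all types uniform in a 335 um disc that nearly fills
#'     its [-340, 340]^2 um domain, so the mixed tissue starts at carrying
#'     capacity;}
#'   \item{structured}{epithelium (cancer + healthy interleaved) uniform in
#'     a 400 um disc, CD8 uniform in the annulus 400-520 um, with expansion
#'     room in a [-800, 800]^2 um domain;}
#'   \item{spatial}{spatial-informed initialization of the synthetic
#'     PDAC-like sample (identical placement across replicates; only the
#'     dynamics are stochastic).}
#' }
#' Three replicates with seeds 1-3, five simulated days.
#'
#' @inheritParams experiment_config
#' @param counts named per-type cell counts used by the synthetic
#'   scenarios.
#' @return An [experiment_config()].
#' @export
default_experiment_config <- function(counts = c(cancer = 1500,
                                                 healthy = 800, CD8 = 600),
                                      output_dir = "spatabm_experiment",
                                      duration_days = 5,
                                      replicates = 3L, seeds = 1:3) {
  scenarios <- list(
    wellmixed = list(strategy = "wellmixed", counts = as.list(counts),
                     center = c(0, 0), radius = 335,
                     domain = c(-340, 340, -340, 340)),
    structured = list(strategy = "structured", counts = as.list(counts),
                      center = c(0, 0), inner_radius = 400,
                      ring = c(400, 520),
                      epithelial_types = c("cancer", "healthy"),
                      immune_types = "CD8",
                      domain = c(-800, 800, -800, 800)),
    spatial = list(strategy = "spatial", sample = "synthetic",
                   domain_padding = 50))
  experiment_config(scenarios = scenarios, replicates = replicates,
                    seeds = seeds, duration_days = duration_days,
                    output_dir = output_dir)
}

# Build the initial state for one scenario. Synthetic placements draw from
# the current RNG stream (seeded per replicate); the spatial strategy is
# deterministic, so placement is identical across replicates.
build_scenario_init <- function(sc, config) {
  switch(sc$strategy,
    wellmixed = init_well_mixed(
      unlist(sc$counts), geom_disc(sc$center, sc$radius),
      domain = sc$domain),
    structured = init_structured(
      unlist(sc$counts), geom_disc(sc$center, sc$inner_radius),
      geom_annulus(sc$center, sc$ring[1], sc$ring[2]),
      epithelial_types = sc$epithelial_types,
      immune_types = sc$immune_types, domain = sc$domain),
    spatial = {
      tab <- if (identical(sc$sample, "synthetic") || is.null(sc$sample)) {
        do.call(generate_pdac_like_sample,
                list(spec = do.call(pdac_sample_spec,
                                    sc$sample_spec %||% list())))
      } else {
        read_cell_table_csv(sc$sample)
      }
      init_spatial_informed(tab, domain_padding = sc$domain_padding %||% 50)
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the initialization-comparison experiment
#'
#' For each scenario and replicate: build the initial state, simulate, and
#' write the initial `cells.csv`, endpoint snapshot and summary time
#' series. Per scenario it then writes replicate-aggregated artifacts: the
#' long-format count/attack time series, the per-replicate cross-PCF
#' series (tidy CSV), and the endpoint component-size CDF (mean and SD
#' across replicates). A manifest JSON listing every artifact with its
#' seed is written last and returned.
#'
#' Placement for the synthetic strategies is redrawn per replicate from the
#' replicate seed; the spatial-informed strategy maps the same measured
#' table every time, so its placement is identical across replicates and
#' only the dynamics vary.
#'
#' @param config an [experiment_config()].
#' @param quiet suppress progress messages.
#' @return Invisibly, the manifest as a list (also written to
#'   `output_dir/manifest.json`).
#' @export
run_experiment <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  sim <- config$sim
  sim$duration_min <- config$duration_days * 24 * 60
  sim$save_interval_min <- config$save_interval_min
  manifest <- list(scenarios = list(), seeds = as.list(config$seeds),
                   duration_days = config$duration_days)
  for (nm in names(config$scenarios)) {
    sc <- config$scenarios[[nm]]
    scdir <- file.path(out, nm)
    dir.create(scdir, recursive = TRUE, showWarnings = FALSE)
    trajs <- vector("list", config$replicates)
    entries <- vector("list", config$replicates)
    for (r in seq_len(config$replicates)) {
      seed <- config$seeds[r]
      if (!quiet) {
        message(sprintf("[%s] replicate %d (seed %d) ...", nm, r, seed))
      }
      ok <- try({
        set.seed(seed)
        init <- build_scenario_init(sc, config)
        tr <- simulate_abm(init, sim, seed = NULL)  # continue the stream
        tr
      }, silent = TRUE)
      if (inherits(ok, "try-error")) {
        stop("replicate failed in scenario '", nm, "' with seed ", seed,
             ": ", attr(ok, "condition")$message, call. = FALSE)
      }
      tr <- ok
      rdir <- file.path(scdir, sprintf("rep%d", r))
      dir.create(rdir, recursive = TRUE, showWarnings = FALSE)
      cells_csv <- file.path(rdir, "cells.csv")
      write_physicell_cells_csv(
        initial_state(tr$snapshots[[1]]$agents$x, tr$snapshots[[1]]$agents$y,
                      tr$snapshots[[1]]$agents$type, tr$domain),
        cells_csv)
      endpoint_csv <- file.path(rdir, "endpoint_snapshot.csv")
      write_snapshot_csv(tr$snapshots[[length(tr$snapshots)]], endpoint_csv)
      trajs[[r]] <- tr
      entries[[r]] <- list(seed = seed, cells_csv = cells_csv,
                           endpoint_snapshot = endpoint_csv)
    }
    ts_csv <- file.path(scdir, "timeseries.csv")
    write_timeseries_csv(trajs, ts_csv)
    # per-replicate cross-PCF series, tidy long format
    pcf_csv <- file.path(scdir, "cross_pcf.csv")
    pcf_rows <- list()
    for (r in seq_along(trajs)) {
      ser <- cross_pcf_timeseries(trajs[[r]], "cancer", "CD8",
                                  config$pcf_bin_edges)
      K <- ncol(ser$G)
      pcf_rows[[r]] <- data.frame(
        replicate = r,
        time_min = rep(ser$times, each = K),
        r_lo = rep(utils::head(ser$bin_edges, -1L), length(ser$times)),
        r_hi = rep(utils::tail(ser$bin_edges, -1L), length(ser$times)),
        g = as.vector(t(ser$G)))
    }
    utils::write.csv(do.call(rbind, pcf_rows), pcf_csv, row.names = FALSE,
                     quote = FALSE)
    # endpoint component CDF, aggregated
    cdfs <- lapply(trajs, function(tr) {
      snap <- tr$snapshots[[length(tr$snapshots)]]
      component_cdf(cancer_components(
        neighbor_graph(snap, config$contact_scale)))
    })
    agg <- aggregate_component_cdfs(cdfs)
    cdf_csv <- file.path(scdir, "component_cdf.csv")
    utils::write.csv(data.frame(size = agg$sizes, F_mean = agg$F_mean,
                                F_sd = agg$F_sd),
                     cdf_csv, row.names = FALSE, quote = FALSE)
    manifest$scenarios[[nm]] <- list(
      strategy = sc$strategy, replicates = entries,
      timeseries = ts_csv, cross_pcf = pcf_csv, component_cdf = cdf_csv)
  }
  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  if (!quiet) message("manifest written to ", manifest_path)
  invisible(manifest)
}

#' Render figures from an experiment manifest
#'
#' Reads the artifacts listed in a manifest and writes one PNG per readout:
#' endpoint scatter per scenario, cancer-count and ongoing-attack time
#' series with mean line and +/- 1 SD band, a cross-PCF heatmap per
#' scenario (replicate-averaged), and the endpoint component CDF with SD
#' shading.
#'
#' @param manifest_path path to a `manifest.json` written by
#'   [run_experiment()], or the manifest list itself.
#' @param fig_dir output directory for figures; defaults to `figures/`
#'   next to the manifest.
#' @return Invisibly, a character vector of figure paths.
#' @export
report_experiment <- function(manifest_path, fig_dir = NULL) {
  manifest <- if (is.character(manifest_path)) {
    if (!file.exists(manifest_path)) {
      stop("manifest not found: ", manifest_path, call. = FALSE)
    }
    jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  } else manifest_path
  if (length(manifest$scenarios) == 0L) {
    stop("manifest lists no scenarios", call. = FALSE)
  }
  if (is.null(fig_dir)) {
    base <- if (is.character(manifest_path)) dirname(manifest_path) else "."
    fig_dir <- file.path(base, "figures")
  }
  dir.create(fig_dir, recursive = TRUE, showWarnings = FALSE)
  sc_names <- names(manifest$scenarios)
  figures <- character(0)
  for (need in c("timeseries", "cross_pcf", "component_cdf")) {
    for (nm in sc_names) {
      f <- manifest$scenarios[[nm]][[need]]
      if (is.null(f) || !file.exists(f)) {
        stop("missing artifact for scenario '", nm, "': ", need,
             call. = FALSE)
      }
    }
  }
  cols <- grDevices::hcl.colors(max(3L, length(sc_names)), "Dark 3")

  band_plot <- function(column, ylab, path) {
    grDevices::png(path, width = 900, height = 600, res = 120)
    on.exit(grDevices::dev.off())
    series <- lapply(sc_names, function(nm) {
      ts <- utils::read.csv(manifest$scenarios[[nm]]$timeseries)
      sp <- split(ts[[column]], ts$replicate)
      agg <- aggregate_series(sp)
      list(time = sort(unique(ts$time_min)) / 60, agg = agg)
    })
    ylim <- range(unlist(lapply(series, function(s) {
      c(s$agg$mean - s$agg$sd, s$agg$mean + s$agg$sd)
    })), 0, na.rm = TRUE)
    plot(NULL, xlim = range(series[[1]]$time), ylim = ylim,
         xlab = "time (h)", ylab = ylab)
    for (i in seq_along(series)) {
      s <- series[[i]]
      graphics::polygon(c(s$time, rev(s$time)),
                        c(s$agg$mean - s$agg$sd,
                          rev(s$agg$mean + s$agg$sd)),
                        col = grDevices::adjustcolor(cols[i], 0.25),
                        border = NA)
      graphics::lines(s$time, s$agg$mean, col = cols[i], lwd = 2)
    }
    graphics::legend("topright", legend = sc_names, col = cols,
                     lwd = 2, bg = "white")
  }

  f1 <- file.path(fig_dir, "cancer_counts.png")
  band_plot("cancer_count", "cancer cells", f1)
  f2 <- file.path(fig_dir, "ongoing_attacks.png")
  band_plot("ongoing_attacks", "ongoing attacks", f2)
  figures <- c(figures, f1, f2)

  for (nm in sc_names) {
    pcf <- utils::read.csv(manifest$scenarios[[nm]]$cross_pcf)
    times <- sort(unique(pcf$time_min))
    edges <- sort(unique(c(pcf$r_lo, pcf$r_hi)))
    K <- length(edges) - 1L
    G <- matrix(NA_real_, length(times), K)
    for (ti in seq_along(times)) {
      sub <- pcf[pcf$time_min == times[ti], ]
      g <- tapply(sub$g, sub$r_lo, mean, na.rm = TRUE)
      G[ti, ] <- g[as.character(utils::head(edges, -1L))]
    }
    fp <- file.path(fig_dir, sprintf("cross_pcf_%s.png", nm))
    grDevices::png(fp, width = 900, height = 600, res = 120)
    ser <- structure(list(times = times, bin_edges = edges, G = G,
                          center_type = "cancer", target_type = "CD8"),
                     class = "cross_pcf_series")
    plot(ser, main = sprintf("cross-PCF cancer -> CD8 (%s)", nm))
    grDevices::dev.off()
    figures <- c(figures, fp)

    ep <- manifest$scenarios[[nm]]$replicates[[1]]$endpoint_snapshot
    if (!is.null(ep) && file.exists(ep)) {
      snap_df <- utils::read.csv(ep)
      fs <- file.path(fig_dir, sprintf("endpoint_%s.png", nm))
      grDevices::png(fs, width = 700, height = 700, res = 120)
      types <- sort(unique(snap_df$type))
      tcols <- grDevices::hcl.colors(max(3L, length(types)), "Dark 3")
      plot(snap_df$x, snap_df$y, col = tcols[match(snap_df$type, types)],
           pch = 16, cex = 0.3, asp = 1, xlab = "x (um)", ylab = "y (um)",
           main = sprintf("endpoint (%s)", nm))
      graphics::legend("topright", legend = types, col = tcols, pch = 16,
                       cex = 0.8, bg = "white")
      grDevices::dev.off()
      figures <- c(figures, fs)
    }
  }

  fc <- file.path(fig_dir, "component_cdf.png")
  grDevices::png(fc, width = 900, height = 600, res = 120)
  plot(NULL, xlim = c(1, 10^ceiling(log10(max(vapply(sc_names, function(nm) {
    cdf <- utils::read.csv(manifest$scenarios[[nm]]$component_cdf)
    if (nrow(cdf) > 0) max(cdf$size) else 1
  }, numeric(1)))))), ylim = c(0, 1), log = "x",
       xlab = "component size (cancer cells)",
       ylab = "cumulative fraction of cancer cells")
  for (i in seq_along(sc_names)) {
    cdf <- utils::read.csv(manifest$scenarios[[sc_names[i]]]$component_cdf)
    if (nrow(cdf) == 0L) next
    sx <- c(cdf$size, cdf$size[nrow(cdf)])
    graphics::polygon(c(cdf$size, rev(cdf$size)),
                      c(pmax(0, cdf$F_mean - cdf$F_sd),
                        rev(pmin(1, cdf$F_mean + cdf$F_sd))),
                      col = grDevices::adjustcolor(cols[i], 0.25),
                      border = NA)
    graphics::lines(cdf$size, cdf$F_mean, col = cols[i], lwd = 2, type = "s")
  }
  graphics::legend("bottomright", legend = sc_names, col = cols, lwd = 2,
                   bg = "white")
  grDevices::dev.off()
  figures <- c(figures, fc)
  invisible(figures)
}

#' Read and write experiment configurations as YAML
#'
#' The canonical configuration dialect is YAML with sections `scenarios`,
#' `run` (`replicates`, `seeds`, `duration_days`, `save_interval_min`,
#' `output_dir`), `analysis` (`pcf_bin_edges`, `contact_scale`) and
#' optional `types`, `attack`, `mechanics` overriding the default
#' simulation parameters.
#'
#' @param path YAML file path.
#' @return For `read_experiment_config`, an [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- default_simulation_config()
  types <- sim$types
  if (!is.null(raw$types)) {
    for (nm in names(raw$types)) {
      base <- if (nm %in% names(types)) unclass(types[[nm]]) else
        unclass(cell_type_params())
      base[names(raw$types[[nm]])] <- raw$types[[nm]]
      types[[nm]] <- do.call(cell_type_params, base)
    }
  }
  attack <- sim$attack
  if (!is.null(raw$attack)) {
    base <- unclass(attack)
    base[names(raw$attack)] <- raw$attack
    attack <- do.call(attack_params, base)
  }
  mech <- sim$mechanics
  if (!is.null(raw$mechanics)) {
    base <- unclass(mech)[c("repulsion_strength", "dt_mech", "dt_phen")]
    base[intersect(names(raw$mechanics), names(base))] <-
      raw$mechanics[intersect(names(raw$mechanics), names(base))]
    mech <- do.call(mechanics_params, base)
  }
  run <- raw$run %||% list()
  analysis <- raw$analysis %||% list()
  scenarios <- lapply(raw$scenarios, function(sc) {
    for (f in c("center", "domain", "ring")) {
      if (!is.null(sc[[f]])) sc[[f]] <- as.numeric(unlist(sc[[f]]))
    }
    for (f in c("epithelial_types", "immune_types")) {
      if (!is.null(sc[[f]])) sc[[f]] <- as.character(unlist(sc[[f]]))
    }
    sc
  })
  sim2 <- simulation_config(types = types, attack = attack, mechanics = mech,
                            duration_min = (run$duration_days %||% 5) * 1440,
                            save_interval_min = run$save_interval_min %||% 60)
  experiment_config(
    scenarios = scenarios,
    replicates = run$replicates %||% 3L,
    seeds = unlist(run$seeds) %||% seq_len(run$replicates %||% 3L),
    duration_days = run$duration_days %||% 5,
    save_interval_min = run$save_interval_min %||% 60,
    sim = sim2,
    pcf_bin_edges = unlist(analysis$pcf_bin_edges) %||% seq(0, 200, by = 10),
    contact_scale = analysis$contact_scale %||% 1.25,
    output_dir = run$output_dir %||% "spatabm_experiment")
}

#' @rdname read_experiment_config
#' @param config an [experiment_config()].
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  tp <- lapply(config$sim$types, unclass)
  raw <- list(
    scenarios = config$scenarios,
    run = list(replicates = config$replicates, seeds = config$seeds,
               duration_days = config$duration_days,
               save_interval_min = config$save_interval_min,
               output_dir = config$output_dir),
    analysis = list(pcf_bin_edges = config$pcf_bin_edges,
                    contact_scale = config$contact_scale),
    types = tp,
    attack = unclass(config$sim$attack),
    mechanics = unclass(config$sim$mechanics)[
      c("repulsion_strength", "dt_mech", "dt_phen")])
  yaml::write_yaml(raw, path)
  invisible(path)
}
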