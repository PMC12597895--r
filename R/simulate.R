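#' Simulate the tumor-immune agent-based model
#'
#' Runs the off-lattice model from an initial state: every phenotype epoch
#' (`dt_phen`) consists of `dt_phen / dt_mech` mechanics sub-steps followed
#' by migration, division/death, and attack updates, in that fixed order.
#' Snapshots are recorded at `t = 0` and every `save_interval_min`
#' thereafter. The same seed always yields the identical trajectory.
#'
#' @param init an [initial_state] whose type names are all configured in
#'   `config`.
#' @param config a [simulation_config()].
#' @param seed optional integer seed; when given, `set.seed(seed)` is
#'   called before the run so the trajectory is fully reproducible. When
#'   `NULL` the current global RNG stream is used.
#' @return An object of class `abm_trajectory` with elements:
#'   \describe{
#'     \item{snapshots}{list of [abm_snapshot] objects, time-ordered,
#'       starting at `t = 0` (identical to `init`).}
#'     \item{summary}{data frame: `time_min`, one count column per type,
#'       `ongoing_attacks`.}
#'     \item{log}{per-epoch bookkeeping: `time_min`, `divisions`, `deaths`,
#'       `kills`, `attacks_started`.}
#'     \item{config, domain, seed}{run metadata.}
#'   }
#' @examples
#' cfg <- default_simulation_config(duration_min = 120)
#' init <- init_well_mixed(c(cancer = 50, healthy = 20, CD8 = 10),
#'                         geom_disc(c(0, 0), 150),
#'                         domain = c(-200, 200, -200, 200))
#' tr <- simulate_abm(init, cfg, seed = 1)
#' summary(tr)
#' @export
simulate_abm <- function(init, config, seed = NULL) {
  stopifnot(inherits(init, "initial_state"),
            inherits(config, "simulation_config"))
  type_names <- names(config$types)
  unknown <- setdiff(unique(init$cells$type), type_names)
  if (length(unknown) > 0L) {
    stop("initial state contains unconfigured type(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  tp <- config$types
  res <- abm_run_cpp(
    x0 = init$cells$x, y0 = init$cells$y,
    type0 = match(init$cells$type, type_names),
    div_rate_h = vapply(tp, `[[`, numeric(1), "division_rate"),
    apo_rate_h = vapply(tp, `[[`, numeric(1), "apoptosis_rate"),
    speed = vapply(tp, `[[`, numeric(1), "motility_speed"),
    persistence = vapply(tp, `[[`, numeric(1), "persistence_time"),
    radius = vapply(tp, `[[`, numeric(1), "radius"),
    max_nb = vapply(tp, `[[`, integer(1), "max_neighbors_for_division"),
    attack_rate = config$attack$attack_rate,
    attack_duration = config$attack$attack_duration,
    kill_prob = config$attack$kill_probability,
    contact_scale = config$attack$contact_scale,
    attacker_type = match(config$attacker_type, type_names),
    target_type = match(config$target_type, type_names),
    repulsion = config$mechanics$repulsion_strength,
    dt_mech = config$mechanics$dt_mech,
    dt_phen = config$mechanics$dt_phen,
    domain = init$domain,
    duration = config$duration_min,
    save_interval = config$save_interval_min)

  radius_of <- vapply(tp, `[[`, numeric(1), "radius")
  snaps <- lapply(res$snapshots, function(s) {
    ag <- data.frame(id = s$id, type = type_names[s$type],
                     x = s$x, y = s$y, partner = s$partner,
                     timer = s$timer,
                     radius = radius_of[s$type],
                     stringsAsFactors = FALSE)
    new_snapshot(time = s$time, agents = ag, domain = init$domain,
                 ongoing_attacks = s$ongoing_attacks,
                 type_names = type_names)
  })
  counts <- matrix(unlist(lapply(snaps, `[[`, "counts")),
                   nrow = length(snaps), ncol = length(type_names),
                   byrow = TRUE, dimnames = list(NULL, type_names))
  summary_df <- data.frame(
    time_min = vapply(snaps, `[[`, numeric(1), "time"),
    counts,
    ongoing_attacks = vapply(snaps, `[[`, integer(1), "ongoing_attacks"),
    check.names = FALSE)
  log_df <- data.frame(time_min = res$log_time, res$log)
  structure(list(snapshots = snaps, summary = summary_df, log = log_df,
                 config = config, domain = init$domain,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "abm_trajectory")
}

#' Simulation snapshots
#'
#' A snapshot is the full agent state at one saved time point: one row per
#' agent with its id, type, position (um), attack partner (partner agent id,
#' `NA` when free) and attack timer (min). Snapshots can also be built
#' directly from a data frame, which is how external point patterns enter
#' the spatial statistics.
#'
#' @param time snapshot time in minutes.
#' @param agents data frame with columns `id`, `type`, `x`, `y` and
#'   optionally `partner`, `timer`, `radius` (radius defaults to 8 um).
#' @param domain domain bounds `c(xmin, xmax, ymin, ymax)`.
#' @param type_names optional character vector fixing the type universe
#'   (types with zero cells then still appear in `counts`).
#' @return An object of class `abm_snapshot`.
#' @export
abm_snapshot <- function(agents, time = 0, domain = NULL, type_names = NULL) {
  stopifnot(is.data.frame(agents),
            all(c("id", "type", "x", "y") %in% names(agents)))
  if (is.null(agents$partner)) agents$partner <- NA_integer_
  if (is.null(agents$timer)) agents$timer <- 0
  if (is.null(agents$radius)) agents$radius <- 8
  if (is.null(domain)) {
    pad <- 50
    domain <- if (nrow(agents) > 0L) {
      c(min(agents$x) - pad, max(agents$x) + pad,
        min(agents$y) - pad, max(agents$y) + pad)
    } else c(-pad, pad, -pad, pad)
  }
  new_snapshot(time = time, agents = agents, domain = domain,
               ongoing_attacks = sum(!is.na(agents$partner)) %/% 2L,
               type_names = type_names)
}

new_snapshot <- function(time, agents, domain, ongoing_attacks, type_names) {
  if (is.null(type_names)) type_names <- sort(unique(agents$type))
  counts <- vapply(type_names, function(ty) sum(agents$type == ty),
                   numeric(1))
  structure(list(time = time, agents = agents, domain = domain,
                 counts = counts,
                 ongoing_attacks = as.integer(ongoing_attacks)),
            class = "abm_snapshot")
}

#' @export
print.abm_snapshot <- function(x, ...) {
  cat(sprintf("<abm_snapshot> t = %g min, %d agents, %d ongoing attack(s)\n",
              x$time, nrow(x$agents), x$ongoing_attacks))
  cat("  ", paste(sprintf("%s: %d", names(x$counts), x$counts),
                  collapse = ", "), "\n")
  invisible(x)
}

#' Count ongoing immune attacks in a snapshot
#'
#' An ongoing attack is an attacker-target pair whose attack timer has not
#' yet reached the configured attack duration (completed attacks are
#' resolved and dissolved within the step, so recorded pairs are always
#' ongoing).
#'
#' @param snap an [abm_snapshot].
#' @param attack_duration the configured attack duration in minutes.
#' @return Integer count of attacker-target pairs.
#' @export
count_ongoing_attacks <- function(snap, attack_duration = Inf) {
  stopifnot(inherits(snap, "abm_snapshot"))
  ag <- snap$agents
  paired <- !is.na(ag$partner) & ag$timer < attack_duration
  as.integer(sum(paired) %/% 2L)
}

#' @export
print.abm_trajectory <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<abm_trajectory> %g min simulated, %d snapshots\n",
              max(s$time_min), nrow(s)))
  type_cols <- setdiff(names(s), c("time_min", "ongoing_attacks"))
  first <- s[1L, type_cols, drop = FALSE]
  last <- s[nrow(s), type_cols, drop = FALSE]
  for (ty in type_cols) {
    cat(sprintf("  %s: %d -> %d\n", ty, as.integer(first[[ty]]),
                as.integer(last[[ty]])))
  }
  invisible(x)
}

#' @export
summary.abm_trajectory <- function(object, ...) {
  s <- object$summary
  type_cols <- setdiff(names(s), c("time_min", "ongoing_attacks"))
  out <- list(
    duration_min = max(s$time_min),
    n_snapshots = nrow(s),
    initial = vapply(s[1L, type_cols], as.integer, integer(1)),
    final = vapply(s[nrow(s), type_cols], as.integer, integer(1)),
    total_divisions = sum(object$log$divisions),
    total_deaths = sum(object$log$deaths),
    total_kills = sum(object$log$kills),
    peak_ongoing_attacks = max(s$ongoing_attacks))
  class(out) <- "summary.abm_trajectory"
  out
}

#' @export
print.summary.abm_trajectory <- function(x, ...) {
  cat(sprintf("ABM trajectory: %g min, %d snapshots\n", x$duration_min,
              x$n_snapshots))
  for (ty in names(x$initial)) {
    cat(sprintf("  %-8s %6d -> %6d\n", ty, x$initial[[ty]], x$final[[ty]]))
  }
  cat(sprintf("  divisions %d, apoptoses %d, immune kills %d, peak attacks %d\n",
              x$total_divisions, x$total_deaths, x$total_kills,
              x$peak_ongoing_attacks))
  invisible(x)
}

#' @export
plot.abm_trajectory <- function(x, which = c("counts", "attacks"), ...) {
  which <- match.arg(which)
  s <- x$summary
  if (which == "counts") {
    type_cols <- setdiff(names(s), c("time_min", "ongoing_attacks"))
    cols <- grDevices::hcl.colors(max(3L, length(type_cols)), "Dark 3")
    graphics::matplot(s$time_min / 60, as.matrix(s[type_cols]), type = "l",
                      lty = 1, col = cols[seq_along(type_cols)],
                      xlab = "time (h)", ylab = "cell count", ...)
    graphics::legend("topright", legend = type_cols, lty = 1,
                     col = cols[seq_along(type_cols)], bg = "white")
  } else {
    plot(s$time_min / 60, s$ongoing_attacks, type = "s",
         xlab = "time (h)", ylab = "ongoing attacks", ...)
  }
  invisible(x)
}

#' @export
as.data.frame.abm_trajectory <- function(x, ...) x$summary
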