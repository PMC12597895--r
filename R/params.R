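#' Per-type phenotype parameters
#'
#' Rates are per hour; motility is in micrometers per minute. In the
#' tumor-immune model only cancer cells proliferate or undergo apoptosis,
#' CD8+ T cells migrate and kill, and healthy epithelial cells neither
#' divide nor die, so the defaults for each type zero out the behaviors it
#' does not have.
#'
#' @param division_rate division rate, 1/h (`>= 0`).
#' @param apoptosis_rate apoptosis rate, 1/h (`>= 0`).
#' @param motility_speed migration speed, um/min (`>= 0`).
#' @param persistence_time mean time between direction redraws of the
#'   persistent random walk, min; must be positive whenever
#'   `motility_speed > 0`.
#' @param radius cell radius, um (`> 0`).
#' @param max_neighbors_for_division contact-inhibition threshold: a cell
#'   divides only while its neighbor count (any type, within
#'   `contact_scale * (r_i + r_j)`) is at most this.
#' @return A `cell_type_params` list.
#' @export
cell_type_params <- function(division_rate = 0, apoptosis_rate = 0,
                             motility_speed = 0, persistence_time = 10,
                             radius = 8, max_neighbors_for_division = 5L) {
  if (division_rate < 0 || apoptosis_rate < 0 || motility_speed < 0) {
    stop("rates and speeds must be non-negative", call. = FALSE)
  }
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  if (motility_speed > 0 && persistence_time <= 0) {
    stop("persistence_time must be positive for motile types", call. = FALSE)
  }
  structure(list(division_rate = division_rate,
                 apoptosis_rate = apoptosis_rate,
                 motility_speed = motility_speed,
                 persistence_time = persistence_time,
                 radius = radius,
                 max_neighbors_for_division =
                   as.integer(max_neighbors_for_division)),
            class = "cell_type_params")
}

#' Immune attack parameters
#'
#' A free CD8+ T cell in contact with a cancer cell (center distance within
#' `contact_scale * (r_i + r_j)`) begins an attack with probability
#' `attack_rate * dt_phen` per phenotype step, targeting the nearest
#' untargeted cancer cell (ties broken by lowest agent id). Both members of
#' the pair are immobilized for `attack_duration` minutes, after which the
#' target dies with probability `kill_probability` and the pair dissolves
#' either way. Attacks are exclusive one-to-one.
#'
#' @param attack_rate attack initiation rate, 1/min.
#' @param attack_duration attack length, min (`> 0`).
#' @param kill_probability probability the target dies when the attack
#'   completes, in `[0, 1]`.
#' @param contact_scale unitless multiplier (`>= 1`) on summed radii
#'   defining contact; also used by the neighbor graph and contact
#'   inhibition.
#' @return An `attack_params` list.
#' @export
attack_params <- function(attack_rate = 0.0003, attack_duration = 30,
                          kill_probability = 0.8, contact_scale = 1.25) {
  if (attack_rate < 0) stop("attack_rate must be >= 0", call. = FALSE)
  if (attack_duration <= 0) stop("attack_duration must be > 0", call. = FALSE)
  if (kill_probability < 0 || kill_probability > 1) {
    stop("kill_probability must be in [0, 1]", call. = FALSE)
  }
  if (contact_scale < 1) stop("contact_scale must be >= 1", call. = FALSE)
  structure(list(attack_rate = attack_rate, attack_duration = attack_duration,
                 kill_probability = kill_probability,
                 contact_scale = contact_scale),
            class = "attack_params")
}

#' Mechanics parameters
#'
#' Overdamped pairwise repulsion: two cells whose center distance `d` falls
#' below the sum of radii `R = r_i + r_j` push each other apart along the
#' separation axis with speed `repulsion_strength * (1 - d/R)^2` each.
#' Mechanics runs on the fine step `dt_mech`; phenotype updates (migration,
#' division, death, attack) on the coarser `dt_phen`, which must be an
#' integer multiple of `dt_mech`. Domain walls are reflecting.
#'
#' @param repulsion_strength displacement speed at full overlap, um/min.
#' @param dt_mech mechanics time step, min.
#' @param dt_phen phenotype time step, min; integer multiple of `dt_mech`.
#' @return A `mechanics_params` list.
#' @export
mechanics_params <- function(repulsion_strength = 10, dt_mech = 0.5,
                             dt_phen = 6) {
  if (repulsion_strength < 0) stop("repulsion_strength must be >= 0",
                                   call. = FALSE)
  if (dt_mech <= 0 || dt_phen <= 0 || dt_mech > dt_phen) {
    stop("need 0 < dt_mech <= dt_phen", call. = FALSE)
  }
  k <- dt_phen / dt_mech
  if (abs(k - round(k)) > 1e-9) {
    stop("dt_phen must be an integer multiple of dt_mech", call. = FALSE)
  }
  structure(list(repulsion_strength = repulsion_strength, dt_mech = dt_mech,
                 dt_phen = dt_phen, boundary = "reflecting"),
            class = "mechanics_params")
}

#' Simulation configuration
#'
#' Bundles per-type phenotype parameters, attack parameters, mechanics
#' parameters, and run control. Probability overflow (`rate * dt_phen >= 1`
#' for any division, apoptosis, or attack rate) is rejected here, before a
#' run starts.
#'
#' @param types named list of [cell_type_params()], one per model type.
#' @param attack an [attack_params()].
#' @param mechanics a [mechanics_params()].
#' @param attacker_type,target_type model type names for the attack
#'   interaction (attacker must be motile or not; no constraint imposed).
#' @param duration_min total simulated time, min.
#' @param save_interval_min snapshot interval, min; must divide
#'   `duration_min` and be a multiple of `dt_phen`.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(types, attack = attack_params(),
                              mechanics = mechanics_params(),
                              attacker_type = "CD8", target_type = "cancer",
                              duration_min = 5 * 24 * 60,
                              save_interval_min = 60) {
  stopifnot(is.list(types), length(types) >= 1L)
  if (is.null(names(types)) || any(names(types) == "")) {
    stop("`types` must be a named list of cell_type_params", call. = FALSE)
  }
  for (ty in names(types)) {
    if (!inherits(types[[ty]], "cell_type_params")) {
      stop("types[['", ty, "']] is not a cell_type_params object",
           call. = FALSE)
    }
  }
  stopifnot(inherits(attack, "attack_params"),
            inherits(mechanics, "mechanics_params"))
  dt <- mechanics$dt_phen
  for (ty in names(types)) {
    p <- types[[ty]]
    if (p$division_rate / 60 * dt >= 1 || p$apoptosis_rate / 60 * dt >= 1) {
      stop("probability overflow: division/apoptosis rate x dt_phen >= 1 ",
           "for type '", ty, "'; reduce dt_phen or the rate", call. = FALSE)
    }
  }
  if (attack$attack_rate * dt >= 1) {
    stop("probability overflow: attack_rate x dt_phen >= 1", call. = FALSE)
  }
  if (save_interval_min <= 0 ||
      abs(save_interval_min / dt - round(save_interval_min / dt)) > 1e-9) {
    stop("save_interval_min must be a positive multiple of dt_phen",
         call. = FALSE)
  }
  if (duration_min < 0 ||
      abs(duration_min / save_interval_min -
          round(duration_min / save_interval_min)) > 1e-9) {
    stop("duration_min must be divisible by save_interval_min", call. = FALSE)
  }
  if (!attacker_type %in% names(types) || !target_type %in% names(types)) {
    stop("attacker_type and target_type must name configured types",
         call. = FALSE)
  }
  structure(list(types = types, attack = attack, mechanics = mechanics,
                 attacker_type = attacker_type, target_type = target_type,
                 duration_min = duration_min,
                 save_interval_min = save_interval_min),
            class = "simulation_config")
}

#' Default tumor-immune model configuration
#'
#' The shipped parameterization of the three-type tumor-immune model:
#' cancer cells divide at 0.03/h under contact inhibition (at most 5
#' neighbors within contact range, which pins the tissue's carrying
#' capacity at confluence for 8 um radii) and apoptose at 0.004/h; CD8+ T
#' cells migrate at 2 um/min with a 10 min persistence time and attack
#' cancer cells in contact (rate 0.0003/min, 30 min duration, kill
#' probability 0.8); healthy epithelial cells are inert. All radii 8 um;
#' repulsion 10 um/min; dt 0.5/6 min; snapshots every hour over five
#' simulated days. The magnitudes are standard for off-lattice cell-scale
#' models; the attack rate and contact-inhibition threshold are calibrated
#' jointly with the default well-mixed geometry so that scenario shows an
#' early decline that stabilizes near 90% of the initial cancer
#' population (see the methods vignette).
#'
#' @param duration_min total simulated time, min.
#' @param save_interval_min snapshot interval, min.
#' @return A [simulation_config()].
#' @export
default_simulation_config <- function(duration_min = 5 * 24 * 60,
                                      save_interval_min = 60) {
  simulation_config(
    types = list(
      cancer = cell_type_params(division_rate = 0.03, apoptosis_rate = 0.004,
                                motility_speed = 0, radius = 8,
                                max_neighbors_for_division = 5L),
      healthy = cell_type_params(radius = 8),
      CD8 = cell_type_params(motility_speed = 2, persistence_time = 10,
                             radius = 8)),
    attack = attack_params(),
    mechanics = mechanics_params(),
    attacker_type = "CD8", target_type = "cancer",
    duration_min = duration_min, save_interval_min = save_interval_min)
}
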