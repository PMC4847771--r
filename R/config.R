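#' World (arena) configuration
#'
#' Geometry of the cubic toroidal arena the agents live in: side length,
#' sensing radius of the directional signal sensors, and the constant speed at
#' which every agent moves.
#'
#' @param arena_side Side of the cubic arena, in arbitrary length units.
#' @param sensing_radius Maximum distance at which an emitted signal is
#'   perceived, same units.  Also the default neighbourhood radius for the
#'   analysis statistics.
#' @param speed Constant norm of every agent's velocity, length units per
#'   iteration.
#' @param sense_floor Attenuation floor: received intensity is
#'   `intensity / max(d, sense_floor)`, so signals from emitters closer than
#'   `sense_floor` are not amplified without bound before clipping.
#'
#' @return A list of class `world_config`.
#' @examples
#' world_config()
#' @export
world_config <- function(arena_side = 600, sensing_radius = 100, speed = 1,
                         sense_floor = 1) {
  stopifnot(is.numeric(arena_side), arena_side > 0,
            is.numeric(sensing_radius), sensing_radius > 0,
            sensing_radius < arena_side,
            is.numeric(speed), speed > 0,
            is.numeric(sense_floor), sense_floor > 0)
  structure(list(arena_side = as.numeric(arena_side),
                 sensing_radius = as.numeric(sensing_radius),
                 speed = as.numeric(speed),
                 sense_floor = as.numeric(sense_floor)),
            class = "world_config")
}

#' Neural controller configuration
#'
#' @param beta Slope of the logistic activation
#'   \eqn{\sigma(x) = 1 / (1 + e^{-\beta x})}.
#'
#' @return A list of class `controller_config`.
#' @export
controller_config <- function(beta = 1) {
  stopifnot(is.numeric(beta), beta > 0)
  structure(list(beta = as.numeric(beta)), class = "controller_config")
}

#' Steering (kinematics) configuration
#'
#' Controller outputs in \[0, 1\] are mapped affinely onto yaw and pitch
#' angles in `[-alpha_max, alpha_max]`; the velocity update adds
#' `c1 * tan(theta)` along the body-frame right axis and `c2 * tan(psi)` along
#' the body-frame up axis, then renormalises to the world speed.
#'
#' @param c1 Yaw steering gain (dimensionless).
#' @param c2 Pitch steering gain (dimensionless).
#' @param alpha_max Half-range of the output-to-angle map, radians; must stay
#'   inside the tangent domain `(0, pi/2)`.  Large values permit the fast
#'   on-the-spot rotations that evolved swarms rely on.
#'
#' @return A list of class `kinematics_config`.
#' @export
kinematics_config <- function(c1 = 1, c2 = 1, alpha_max = pi / 4) {
  stopifnot(is.numeric(c1), c1 > 0, is.numeric(c2), c2 > 0,
            is.numeric(alpha_max), alpha_max > 0, alpha_max < pi / 2)
  structure(list(c1 = as.numeric(c1), c2 = as.numeric(c2),
                 alpha_max = as.numeric(alpha_max)),
            class = "kinematics_config")
}

#' Evolutionary dynamics configuration
#'
#' Parameters of the asynchronous steady-state genetic algorithm: the energy
#' ledger, reproduction, ageing, the population homeostat and resource
#' relocation.  Defaults are the published simulation parameters.
#'
#' @param c_mov Base survival (movement) cost per iteration, energy units.
#' @param c_sig_coef Signaling cost per unit emitted intensity per iteration.
#' @param birth_energy Energy a newborn starts with.
#' @param reproduce_threshold Energy at which an agent replicates.
#' @param reproduce_cost Energy the parent pays on replication.
#' @param max_energy Energy ceiling per agent.
#' @param max_absorb Maximum energy absorbed from the resource per iteration.
#' @param age_cap Maximum age in iterations; older agents are removed.
#' @param pop_lo,pop_hi Homeostat band: below `pop_lo` the cost factor is
#'   divided by `cost_down`, above `pop_hi` it is multiplied by `cost_up`.
#' @param pop_min,pop_max Hard population bounds: no removal at or below
#'   `pop_min`, no reproduction at or above `pop_max`.
#' @param cost_up Multiplier applied to the cost factor when the population
#'   exceeds `pop_hi`.
#' @param cost_down Divisor applied when the population is below `pop_lo`.
#' @param resource_period Iterations between random relocations of the
#'   resource site.
#' @param reward Reward scale `r` of the distance-decaying gain `r / d`.
#' @param mutation_rate Per-gene mutation probability.
#' @param mutation_offset Half-width of the uniform mutation offset.
#' @param cost_factor0 Initial value of the global cost factor `c`; chosen so
#'   that mean energy influx for a uniformly dispersed population roughly
#'   balances the base cost (see the methods vignette).
#'
#' @return A list of class `evolution_config`.
#' @examples
#' evolution_config()$reproduce_threshold
#' @export
evolution_config <- function(c_mov = 0.01, c_sig_coef = 0.001,
                             birth_energy = 2, reproduce_threshold = 10,
                             reproduce_cost = 8, max_energy = 100,
                             max_absorb = 1, age_cap = 5000,
                             pop_lo = 150, pop_hi = 250,
                             pop_min = 100, pop_max = 1000,
                             cost_up = 1.0001, cost_down = 1.01,
                             resource_period = 5000, reward = 10,
                             mutation_rate = 0.05, mutation_offset = 0.05,
                             cost_factor0 = 3) {
  stopifnot(c_mov >= 0, c_sig_coef >= 0, birth_energy > 0,
            reproduce_threshold > birth_energy,
            reproduce_cost > 0, reproduce_cost < reproduce_threshold,
            max_energy > reproduce_threshold, max_absorb > 0, age_cap >= 1,
            pop_lo < pop_hi, pop_min <= pop_lo, pop_hi <= pop_max,
            cost_up > 1, cost_down > 1, resource_period >= 1, reward > 0,
            mutation_rate >= 0, mutation_rate <= 1, mutation_offset >= 0,
            cost_factor0 >= 0)
  structure(list(c_mov = as.numeric(c_mov),
                 c_sig_coef = as.numeric(c_sig_coef),
                 birth_energy = as.numeric(birth_energy),
                 reproduce_threshold = as.numeric(reproduce_threshold),
                 reproduce_cost = as.numeric(reproduce_cost),
                 max_energy = as.numeric(max_energy),
                 max_absorb = as.numeric(max_absorb),
                 age_cap = as.integer(age_cap),
                 pop_lo = as.integer(pop_lo), pop_hi = as.integer(pop_hi),
                 pop_min = as.integer(pop_min), pop_max = as.integer(pop_max),
                 cost_up = as.numeric(cost_up),
                 cost_down = as.numeric(cost_down),
                 resource_period = as.integer(resource_period),
                 reward = as.numeric(reward),
                 mutation_rate = as.numeric(mutation_rate),
                 mutation_offset = as.numeric(mutation_offset),
                 cost_factor0 = as.numeric(cost_factor0)),
            class = "evolution_config")
}

#' Transfer entropy estimator configuration
#'
#' @param history Length `h` of the past window conditioned on.
#' @param delay Time delay `d` between the past window and the predicted
#'   sample (`d = 1` is the usual "previous step" convention).
#' @param bins Number of equal-width bins per velocity component used to
#'   symbolise continuous series.
#' @param base Logarithm base for the estimate (natural log by default).
#' @param window Default window length, in samples, for windowed
#'   neighbourhood statistics.
#'
#' @return A list of class `te_config`.
#' @export
te_config <- function(history = 1, delay = 1, bins = 2, base = exp(1),
                      window = 1000) {
  stopifnot(history >= 1, delay >= 1, bins >= 2, base > 1, window > 2)
  structure(list(history = as.integer(history), delay = as.integer(delay),
                 bins = as.integer(bins), base = as.numeric(base),
                 window = as.integer(window)),
            class = "te_config")
}

#' Genotypic diversity configuration
#'
#' @param classes Number of equal-width classes each allele value in \[0, 1\]
#'   is discretised into.
#' @param base Logarithm base; 10 gives hartleys.
#'
#' @return A list of class `diversity_config`.
#' @export
diversity_config <- function(classes = 5, base = 10) {
  stopifnot(classes >= 2, base > 1)
  structure(list(classes = as.integer(classes), base = as.numeric(base)),
            class = "diversity_config")
}

#' Write / read a run configuration as JSON
#'
#' Serialises every tunable of a run (world, evolution, kinematics and
#' controller configuration plus seed, mode and duration) so a run can be
#' reproduced from its config echo.
#'
#' @param path File path of the JSON document.
#' @param world,evo,kin,ctrl Configuration objects.
#' @param seed Integer RNG seed.
#' @param mode `"training"` or `"testing"`.
#' @param iters Number of iterations.
#' @param silenced Logical: global signal silencing flag.
#'
#' @return `write_run_config()` returns `path` invisibly; `read_run_config()`
#'   returns a list with the reconstructed configuration objects.
#' @export
write_run_config <- function(path, world = world_config(),
                             evo = evolution_config(),
                             kin = kinematics_config(),
                             ctrl = controller_config(),
                             seed = NA_integer_, mode = "training",
                             iters = NA_integer_, silenced = FALSE) {
  doc <- list(world = unclass(world), evolution = unclass(evo),
              kinematics = unclass(kin), controller = unclass(ctrl),
              seed = seed, mode = mode, iters = iters, silenced = silenced)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(world = do.call(world_config, doc$world),
       evo = do.call(evolution_config, doc$evolution),
       kin = do.call(kinematics_config, doc$kinematics),
       ctrl = do.call(controller_config, doc$controller),
       seed = doc$seed, mode = doc$mode, iters = doc$iters,
       silenced = isTRUE(doc$silenced))
}
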