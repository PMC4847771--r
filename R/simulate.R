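#' Run the simulation engine
#'
#' Advances a population through `iters` iterations of the compiled engine
#' (identical semantics to [simulation_step()], iterated).  In training mode
#' the full asynchronous genetic algorithm runs: foraging gains, reproduction
#' above the energy threshold, death at zero energy or at the age cap, the
#' population homeostat and periodic resource relocation.  In testing mode
#' the resource term is replaced by a per-agent allowance exactly covering
#' costs, and reproduction, death and the homeostat are switched off, so the
#' same individuals persist.
#'
#' All randomness comes from R's RNG: `set.seed()` before the call makes runs
#' bit-reproducible.
#'
#' @param pop A [new_population()] object (consumed; the advanced population
#'   is returned in the result).
#' @param resource A [new_resource()] object.
#' @param iters Number of iterations to run.
#' @param mode `"training"` or `"testing"`.
#' @param silenced Logical; force all emitted signal intensities to 0
#'   (sensors then read zero and signaling costs vanish).
#' @param world,evo,kin,ctrl Configuration objects.
#' @param sample_every Stride, in iterations, for per-agent snapshots.
#' @param record_agents Logical; record per-agent rows (`t`, `id`, position,
#'   velocity, signal, energy) every `sample_every` iterations.
#' @param t0 Iteration offset (for chaining runs; events and logs are stamped
#'   `t0 + 1 ... t0 + iters`).
#'
#' @return A list of class `swarm_run`:
#' \describe{
#'   \item{population}{the final `swarm_population`}
#'   \item{resource}{the resource with its current centre}
#'   \item{stats}{per-iteration data frame: `t`, `pop`, `cost_factor`,
#'     `mean_signal`, `mean_goal_dist` (raw Euclidean), `total_energy`,
#'     `gains`, `costs`, `births`, `deaths`, `removed_energy`}
#'   \item{agents}{per-agent snapshot data frame, or `NULL`}
#'   \item{events}{list of data frames `births`, `deaths`, `relocations`}
#'   \item{lineage}{lineage table for every agent seen during the run
#'     (see [lineage_from_run()])}
#'   \item{t_end}{final iteration number}
#' }
#' @examples
#' set.seed(42)
#' pop <- new_population(20)
#' res <- new_resource()
#' run <- run_simulation(pop, res, iters = 100)
#' tail(run$stats[, c("t", "pop", "mean_goal_dist")], 3)
#' @export
run_simulation <- function(pop, resource, iters,
                           mode = c("training", "testing"),
                           silenced = FALSE,
                           world = world_config(),
                           evo = evolution_config(),
                           kin = kinematics_config(),
                           ctrl = controller_config(),
                           sample_every = 100L, record_agents = FALSE,
                           t0 = 0L) {
  mode <- match.arg(mode)
  stopifnot(inherits(pop, "swarm_population"), inherits(resource, "resource"),
            iters >= 1, sample_every >= 1)
  initial <- data.frame(id = pop$id, parent = pop$parent, birth = pop$birth)
  out <- .sim_run_cpp(unclass(pop), resource$center, resource$reward,
                      unclass(world), unclass(kin), unclass(ctrl),
                      unclass(evo),
                      as.integer(iters), as.integer(t0),
                      mode == "training", isTRUE(silenced),
                      as.integer(sample_every), isTRUE(record_agents))
  newpop <- structure(out$population, class = "swarm_population")
  resource$center <- out$resource_center
  lineage <- build_lineage(initial, out$events$births, out$events$deaths)
  structure(list(population = newpop, resource = resource,
                 stats = out$stats, agents = out$agents,
                 events = out$events, lineage = lineage,
                 t_end = as.integer(t0 + iters), mode = mode,
                 silenced = isTRUE(silenced)),
            class = "swarm_run")
}

#' @export
print.swarm_run <- function(x, ...) {
  s <- x$stats
  cat("<swarm_run> ", x$mode, if (x$silenced) " (silenced)", ": ",
      nrow(s), " iterations ending at t = ", x$t_end, "\n", sep = "")
  cat("  final population ", population_size(x$population),
      ", births ", sum(s$births), ", deaths ", sum(s$deaths), "\n", sep = "")
  cat("  mean goal distance ", signif(mean(s$mean_goal_dist, na.rm = TRUE), 5),
      ", mean signal ", signif(mean(s$mean_signal, na.rm = TRUE), 4),
      "\n", sep = "")
  invisible(x)
}

build_lineage <- function(initial, births, deaths) {
  lin <- rbind(
    data.frame(id = initial$id, parent = initial$parent,
               birth = initial$birth),
    data.frame(id = births$child, parent = births$parent, birth = births$t))
  lin$death <- rep(NA_integer_, nrow(lin))
  if (nrow(deaths)) {
    idx <- match(deaths$id, lin$id)
    lin$death[idx] <- deaths$t
  }
  class(lin) <- c("lineage_table", "data.frame")
  lin
}
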