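# Asynchronous steady-state genetic algorithm: reference (pure R)
# implementation of one simulation iteration.  The compiled engine in
# src/sim_core.cpp implements the same semantics and the same RNG draw order;
# the two are cross-checked in the test suite.

#' Per-iteration energy update
#'
#' In training mode each agent absorbs `min(r / d, max_absorb)` from the
#' resource (`d` = plain Euclidean distance to the site) and pays
#' `cost_factor * (c_mov + c_sig_coef * signal)`.  Energy is capped at
#' `max_energy`; the returned `gain` is net of that cap so the energy ledger
#' closes exactly.  In testing mode the resource term is replaced by an
#' allowance equal to each agent's cost, keeping energy constant.
#'
#' @param energy Numeric vector of agent energies.
#' @param signal Emitted intensities this iteration.
#' @param goal_dist Raw distances to the resource centre.
#' @param cost_factor Global cost factor `c`.
#' @param evo [evolution_config()].
#' @param mode `"training"` or `"testing"`.
#' @return List with updated `energy` and the ledger entries `gain`, `cost`.
#' @export
energy_step <- function(energy, signal, goal_dist, cost_factor,
                        evo = evolution_config(),
                        mode = c("training", "testing")) {
  mode <- match.arg(mode)
  cost <- cost_factor * (evo$c_mov + evo$c_sig_coef * signal)
  if (mode == "testing") {
    return(list(energy = energy, gain = cost, cost = cost))
  }
  gain <- pmin(evo$reward / goal_dist, evo$max_absorb)  # d = 0 -> capped
  e2 <- energy + gain - cost
  over <- pmax(e2 - evo$max_energy, 0)
  list(energy = e2 - over, gain = gain - over, cost = cost)
}

#' Population homeostat
#'
#' Nudges the global cost factor to keep the population inside the homeostat
#' band: above `pop_hi` the factor is multiplied by `cost_up` (slow increase),
#' below `pop_lo` it is divided by `cost_down` (fast relief).
#'
#' @param pop_size Current population count.
#' @param cost_factor Current cost factor.
#' @param evo [evolution_config()].
#' @return Updated cost factor.
#' @examples
#' homeostat(251, 1)  # 1.0001
#' homeostat(149, 1)  # 1 / 1.01
#' @export
homeostat <- function(pop_size, cost_factor, evo = evolution_config()) {
  if (pop_size > evo$pop_hi) {
    cost_factor * evo$cost_up
  } else if (pop_size < evo$pop_lo) {
    cost_factor / evo$cost_down
  } else {
    cost_factor
  }
}

#' Periodic resource relocation
#'
#' At iterations that are multiples of `resource_period` the site centre is
#' resampled uniformly in the arena; otherwise it is returned unchanged.
#'
#' @param res A [new_resource()] object.
#' @param t Current iteration (1-based within a run).
#' @param world [world_config()].
#' @param evo [evolution_config()].
#' @return List with the (possibly moved) `resource` and logical `relocated`.
#' @export
relocate_resource <- function(res, t, world = world_config(),
                              evo = evolution_config()) {
  if (t %% evo$resource_period == 0L) {
    res$center <- runif(3, 0, world$arena_side)
    list(resource = res, relocated = TRUE)
  } else {
    list(resource = res, relocated = FALSE)
  }
}

#' Remove dead and over-aged agents
#'
#' Agents with energy at or below zero, or age at or above the cap, are
#' removed in index order -- except that removal is suppressed once the
#' population is at or below the hard floor `pop_min`.
#'
#' @param pop A `swarm_population`.
#' @param evo [evolution_config()].
#' @return List with the surviving `pop`, integer vector `removed_id` and the
#'   total `removed_energy` they carried.
#' @export
cull_population <- function(pop, evo = evolution_config()) {
  n <- population_size(pop)
  keep <- rep(TRUE, n)
  alive <- n
  removed_energy <- 0
  for (i in seq_len(n)) {
    if (alive <= evo$pop_min) break
    if (pop$energy[i] <= 0 || pop$age[i] >= evo$age_cap) {
      keep[i] <- FALSE
      alive <- alive - 1L
      removed_energy <- removed_energy + pop$energy[i]
    }
  }
  removed <- pop$id[!keep]
  list(pop = subset_population(pop, keep), removed_id = removed,
       removed_energy = removed_energy)
}

subset_population <- function(pop, keep) {
  pop$id <- pop$id[keep]
  pop$genes <- pop$genes[keep, , drop = FALSE]
  pop$pos <- pop$pos[keep, , drop = FALSE]
  pop$vel <- pop$vel[keep, , drop = FALSE]
  pop$context <- pop$context[keep, , drop = FALSE]
  pop$energy <- pop$energy[keep]
  pop$age <- pop$age[keep]
  pop$signal <- pop$signal[keep]
  pop$parent <- pop$parent[keep]
  pop$birth <- pop$birth[keep]
  pop$freerider <- pop$freerider[keep]
  pop
}

#' One full simulation iteration (reference implementation)
#'
#' Pure-R mirror of the compiled engine, mainly useful for inspection and for
#' verifying the engine on small populations.  The per-iteration stage order
#' is: (1) all agents sense the previous iteration's positions and signals;
#' (2) controllers step; (3) velocities then positions update; (4) emitted
#' signals are set to the third controller output (0 when silenced or for
#' freeriders); (5) energy ledger; (6) reproduction; (7) culling;
#' (8) homeostat; (9) resource relocation; (10) ages increment.  Stages 6-8
#' are skipped in testing mode.
#'
#' @param pop A `swarm_population`.
#' @param resource A [new_resource()] object.
#' @param t Iteration number being executed (1-based).
#' @param world,evo,kin,ctrl Configuration objects.
#' @param mode `"training"` or `"testing"`.
#' @param silenced Logical: force all emitted intensities to 0.
#' @return A list with the updated `pop`, `resource`, data frames `births`
#'   (`t`, `child`, `parent`) and `deaths` (`t`, `id`), logical `relocated`,
#'   and the ledger entries `gain_sum`, `cost_sum`, `removed_energy`.
#' @export
simulation_step <- function(pop, resource, t,
                            world = world_config(),
                            evo = evolution_config(),
                            kin = kinematics_config(),
                            ctrl = controller_config(),
                            mode = c("training", "testing"),
                            silenced = FALSE) {
  mode <- match.arg(mode)
  n <- population_size(pop)
  births <- data.frame(t = integer(), child = integer(), parent = integer())
  deaths <- data.frame(t = integer(), id = integer())
  gain_sum <- 0; cost_sum <- 0; removed_energy <- 0

  if (n > 0) {
    # (1) sense from previous positions/signals
    inputs <- if (silenced) matrix(0, n, 6) else
      sense_all(pop$pos, pop$vel, pop$signal, world)
    # (2)-(4) think, move, emit
    for (i in seq_len(n)) {
      w <- decode_genotype(pop$genes[i, ])
      st <- list(hidden = NULL, context = pop$context[i, ])
      res_c <- step_controller(w, st, inputs[i, ], ctrl)
      pop$context[i, ] <- res_c$state$context
      ang <- outputs_to_angles(res_c$outputs[1], res_c$outputs[2], kin)
      frame <- body_frame(pop$vel[i, ])
      pop$vel[i, ] <- update_velocity(pop$vel[i, ], ang$theta, ang$psi,
                                      frame, kin, world)
      pop$pos[i, ] <- update_position(pop$pos[i, ], pop$vel[i, ], world)
      pop$signal[i] <- if (silenced || pop$freerider[i]) 0 else
        res_c$outputs[3]
    }
    # (5) energy ledger
    gd <- unname(raw_distance(pop$pos,
                              matrix(resource$center, n, 3, byrow = TRUE)))
    es <- energy_step(pop$energy, pop$signal, gd, pop$cost_factor, evo, mode)
    pop$energy <- es$energy
    gain_sum <- sum(es$gain); cost_sum <- sum(es$cost)

    if (mode == "training") {
      # (6) asynchronous reproduction
      for (i in seq_len(n)) {
        if (pop$energy[i] >= evo$reproduce_threshold &&
            population_size(pop) < evo$pop_max) {
          child_genes <- mutate_genotype(pop$genes[i, ], evo$mutation_rate,
                                         evo$mutation_offset)
          child_pos <- runif(3, 0, world$arena_side)
          repeat {
            h <- rnorm(3)
            if (sum(h * h) > 1e-24) break
          }
          child_vel <- h / sqrt(sum(h * h)) * world$speed
          cid <- as.integer(pop$next_id)
          pop$next_id <- cid + 1L
          pop$energy[i] <- pop$energy[i] - evo$reproduce_cost
          pop$id <- c(pop$id, cid)
          pop$genes <- rbind(pop$genes, child_genes)
          pop$pos <- rbind(pop$pos, child_pos)
          pop$vel <- rbind(pop$vel, child_vel)
          pop$context <- rbind(pop$context, rep(0.5, N_CONTEXT))
          pop$energy <- c(pop$energy, evo$birth_energy)
          pop$age <- c(pop$age, 0L)
          pop$signal <- c(pop$signal, 0)
          pop$parent <- c(pop$parent, pop$id[i])
          pop$birth <- c(pop$birth, as.integer(t))
          pop$freerider <- c(pop$freerider, pop$freerider[i])
          births <- rbind(births, data.frame(t = as.integer(t), child = cid,
                                             parent = pop$id[i]))
        }
      }
      dimnames(pop$genes) <- dimnames(pop$pos) <- dimnames(pop$vel) <-
        dimnames(pop$context) <- NULL
      # (7) culling
      cu <- cull_population(pop, evo)
      pop <- cu$pop
      removed_energy <- cu$removed_energy
      if (length(cu$removed_id)) {
        deaths <- data.frame(t = as.integer(t), id = cu$removed_id)
      }
      # (8) homeostat
      pop$cost_factor <- homeostat(population_size(pop), pop$cost_factor, evo)
    }
  }
  # (9) resource relocation
  rl <- relocate_resource(resource, t, world, evo)
  # (10) ageing
  pop$age <- pop$age + 1L

  list(pop = pop, resource = rl$resource, births = births, deaths = deaths,
       relocated = rl$relocated, gain_sum = gain_sum, cost_sum = cost_sum,
       removed_energy = removed_energy)
}
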