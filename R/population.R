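#' Create an initial population
#'
#' Agents start at uniform random positions with uniform random headings,
#' i.i.d. `U(0, 1)` genes, age 0, neutral controller state (all activations
#' 0.5) and zero emitted signal (an agent is silent until its first
#' controller step).  Founder energies are drawn uniformly between the
#' newborn energy and the replication threshold: a founding cohort with
#' identical energies reaches its first deaths and replications in
#' near-synchrony, which kicks the population homeostat hard at start-up;
#' spreading the energies desynchronises the cohort.  Newborns during a run
#' always start at exactly the newborn energy.
#'
#' @param n Number of founder agents.
#' @param world [world_config()].
#' @param evo [evolution_config()] (sets the founders' energy and the initial
#'   cost factor carried by the population).
#' @return A list of class `swarm_population` with per-agent fields `id`,
#'   `genes` (`n x 290`), `pos`, `vel`, `context`, `energy`, `age`, `signal`,
#'   `parent` (`NA` for founders), `birth`, `freerider`, plus the bookkeeping
#'   scalars `next_id` and `cost_factor`.
#' @examples
#' set.seed(1)
#' pop <- new_population(10)
#' pop
#' @export
new_population <- function(n = 200, world = world_config(),
                           evo = evolution_config()) {
  stopifnot(n >= 0)
  genes <- matrix(runif(n * genotype_length()), nrow = n)
  pos <- matrix(runif(n * 3, 0, world$arena_side), nrow = n)
  vel <- matrix(rnorm(n * 3), nrow = n)
  vel <- vel / sqrt(rowSums(vel^2)) * world$speed
  structure(list(id = seq_len(n),
                 genes = genes, pos = pos, vel = vel,
                 context = matrix(0.5, n, N_CONTEXT),
                 energy = runif(n, evo$birth_energy, evo$reproduce_threshold),
                 age = rep(0L, n),
                 signal = rep(0, n),
                 parent = rep(NA_integer_, n),
                 birth = rep(0L, n),
                 freerider = rep(FALSE, n),
                 next_id = as.integer(n) + 1L,
                 cost_factor = evo$cost_factor0),
            class = "swarm_population")
}

#' @export
print.swarm_population <- function(x, ...) {
  cat("<swarm_population> ", length(x$id), " agents, cost factor ",
      signif(x$cost_factor, 5), "\n", sep = "")
  cat("  energy: mean ", signif(mean(x$energy), 4),
      ", signal: mean ", signif(mean(x$signal), 4),
      ", max age ", if (length(x$age)) max(x$age) else 0, "\n", sep = "")
  invisible(x)
}

#' Number of agents in a population
#' @param pop A `swarm_population`.
#' @return Integer count.
#' @export
population_size <- function(pop) length(pop$id)

#' Place a resource (goal) site
#'
#' @param center Length-3 position of the site; by default drawn uniformly in
#'   the arena.
#' @param reward Reward scale `r` of the gain law `r / d`.
#' @param world [world_config()].
#' @return A list of class `resource` with `center` and `reward`.
#' @export
new_resource <- function(center = NULL, reward = evolution_config()$reward,
                         world = world_config()) {
  if (is.null(center)) center <- runif(3, 0, world$arena_side)
  stopifnot(length(center) == 3, all(is.finite(center)), reward > 0)
  structure(list(center = as.numeric(center), reward = as.numeric(reward)),
            class = "resource")
}

#' Inject silent freeriders
#'
#' Picks `k` agents at random and silences them: the 10 genes encoding the
#' hidden-to-signal-output weights are set to 0 (decoding to the saturating
#' weight -1), and the agents are flagged so their *emitted* intensity is
#' forced to exactly 0.  All other genes, and hence the motor behaviour, are
#' untouched.  The flag (like the edited genes) is inherited by offspring.
#'
#' @param pop A `swarm_population`.
#' @param k Number of agents to convert.
#' @return The modified population.
#' @export
inject_freeriders <- function(pop, k = 5) {
  stopifnot(k >= 0, k <= population_size(pop))
  if (k == 0) return(pop)
  pick <- sample.int(population_size(pop), k)
  pop$genes[pick, o3_gene_indices()] <- 0
  pop$freerider[pick] <- TRUE
  pop$signal[pick] <- 0
  pop
}
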