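# Long simulation fixtures shared by the acceptance-style tests.  Each run is
# computed once per session and cached; seeds are fixed study conditions.

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, fn) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- fn()
  .run_cache[[key]]
}

# 50k-iteration training run (signaling on), agent snapshots every 500
# iterations for neighbourhood statistics
training_run_50k <- function() {
  cached_run("train50k", function() {
    set.seed(20160427)
    pop <- new_population(200)
    res <- new_resource()
    run_simulation(pop, res, 50000, mode = "training",
                   sample_every = 500, record_agents = TRUE)
  })
}

# matched silenced control of the same length and seed
silenced_run_50k <- function() {
  cached_run("silent50k", function() {
    set.seed(20160427)
    pop <- new_population(200)
    res <- new_resource()
    run_simulation(pop, res, 50000, mode = "training", silenced = TRUE,
                   sample_every = 500, record_agents = TRUE)
  })
}

mean_neighbors_of_run <- function(run, after = 0) {
  a <- run$agents
  a <- a[a$t > after, ]
  times <- unique(a$t)
  mean(vapply(times, function(tt) {
    avg_neighbors(as.matrix(a[a$t == tt, c("x", "y", "z")]))
  }, numeric(1)))
}

# density-corrected clustering signal, averaged over snapshots
mean_excess_neighbors_of_run <- function(run, after = 0) {
  a <- run$agents
  a <- a[a$t > after, ]
  times <- unique(a$t)
  mean(vapply(times, function(tt) {
    excess_neighbors(as.matrix(a[a$t == tt, c("x", "y", "z")]))
  }, numeric(1)))
}
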