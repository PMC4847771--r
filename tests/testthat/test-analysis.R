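test_that("average neighbour count follows the radius-100 definition", {
  w <- world_config()
  expect_equal(avg_neighbors(matrix(c(1, 2, 3), 1), world = w), 0)
  two <- rbind(c(0, 0, 0), c(50, 0, 0))
  expect_equal(avg_neighbors(two, world = w), 1)
  three <- rbind(c(0, 0, 0), c(200, 0, 0), c(0, 250, 0))
  expect_equal(avg_neighbors(three, world = w), 0)
  # torus wrap counts as proximity
  pair <- rbind(c(1, 0, 0), c(599, 0, 0))
  expect_equal(avg_neighbors(pair, world = w), 1)
  # invariance under global translation on the torus
  set.seed(60)
  pos <- matrix(runif(60, 0, 600), ncol = 3)
  shift <- c(431.7, -123.4, 950.2)
  shifted <- wrap_position(sweep(pos, 2, shift, "+"), 600)
  expect_equal(avg_neighbors(shifted, world = w), avg_neighbors(pos, world = w))
})

test_that("entropy of a probability vector matches closed forms", {
  expect_equal(shannon_entropy(c(1, 0, 0)), 0)
  expect_equal(shannon_entropy(rep(0.1, 10), base = 10), 1)
  expect_equal(shannon_entropy(rep(0.2, 5), base = 10), log10(5))
  expect_error(shannon_entropy(c(0.5, 0.2)), "probability")
})

test_that("mutual information: identity coupling, symmetry, independence", {
  set.seed(61)
  x <- sample.int(3, 1e4, replace = TRUE) - 1L
  expect_equal(mutual_information(x, x), oracle_entropy(x))
  y <- sample.int(3, 1e4, replace = TRUE) - 1L
  expect_identical(mutual_information(x, y), mutual_information(y, x))
  # independent streams: within a few times the plug-in bias (k-1)^2 / (2T)
  expect_lt(mutual_information(x, y), 5 * (3 - 1)^2 / (2 * 1e4))
})

test_that("plug-in estimators equal the brute-force histogram oracle", {
  set.seed(62)
  for (k in 2:3) {
    for (T_ in c(20, 60, 200)) {
      x <- sample.int(k, T_, replace = TRUE) - 1L
      y <- as.integer((x + sample.int(k, T_, replace = TRUE) - 1L) %% k)
      expect_equal(mutual_information(x, y), oracle_mi(x, y),
                   tolerance = 1e-12)
      te <- transfer_entropy(x, y, te_config(bins = k))
      expect_equal(te, max(oracle_te(x, y), 0), tolerance = 1e-12)
      te_rev <- transfer_entropy(y, x, te_config(bins = k))
      expect_equal(te_rev, max(oracle_te(y, x), 0), tolerance = 1e-12)
    }
  }
  # longer history / delay also match the oracle
  set.seed(63)
  x <- sample.int(2, 300, replace = TRUE) - 1L
  y <- c(0L, 0L, 0L, x[seq_len(297)])
  cfg <- te_config(history = 2, delay = 2)
  expect_equal(transfer_entropy(x, y, cfg),
               max(oracle_te(x, y, h = 2, d = 2), 0), tolerance = 1e-12)
})

test_that("transfer entropy of a copy channel approaches log k", {
  set.seed(64)
  for (k in 2:3) {
    x <- sample.int(k, 1e4, replace = TRUE) - 1L
    y <- c(0L, x[-1e4])
    te <- transfer_entropy(x, y, te_config(bins = k))
    expect_lt(abs(te - log(k)) / log(k), 0.02)
    # directionality: the reverse direction carries (almost) nothing
    expect_lt(transfer_entropy(y, x, te_config(bins = k)), 0.05 * te)
  }
  # independent i.i.d. streams: estimate within plug-in bias of zero
  set.seed(65)
  a <- sample.int(2, 1e4, replace = TRUE) - 1L
  b <- sample.int(2, 1e4, replace = TRUE) - 1L
  expect_lt(transfer_entropy(a, b), 5e-3)
  # degenerate constant series
  expect_warning(te0 <- transfer_entropy(rep(0L, 100), rep(1L, 100)),
                 "degenerate")
  expect_equal(te0, 0)
})

test_that("symbolisation composes per-component equal-width bins", {
  v <- cbind(c(0, 1, 0.49, 0.51), c(0, 0, 1, 1))
  s <- symbolize_series(v, 2)
  expect_identical(s, c(0L, 1L, 2L, 3L))
  expect_identical(symbolize_series(rep(3.3, 10), 4), rep(0L, 10))
})

test_that("neighbourhood TE separates leaders from followers", {
  set.seed(66)
  T_ <- 600
  lead <- matrix(0, T_, 3)
  lead[, 1] <- sample(c(-1, 1), T_, replace = TRUE)
  lead[, 2] <- sample(c(-1, 1), T_, replace = TRUE)
  lead[, 3] <- 1
  follow <- rbind(lead[1, ], lead[-T_, ])   # copies the leader, lag 1
  # third agent far away and independent
  indep <- matrix(sample(c(-1, 1), T_ * 3, replace = TRUE), T_, 3)
  pos_mid <- rbind(c(0, 0, 0), c(50, 0, 0), c(300, 300, 300))
  win <- make_window(list(lead, follow, indep), pos_mid)
  inw <- inward_nte(win, radius = 100)
  outw <- outward_nte(win, radius = 100)
  # follower's inward NTE dominates the leader's
  expect_gt(inw$per_agent[2], 5 * max(inw$per_agent[1], 1e-6))
  # leader's outward NTE dominates the follower's
  expect_gt(outw$per_agent[1], 5 * max(outw$per_agent[2], 1e-6))
  # isolated agent exchanges nothing
  expect_equal(unname(inw$per_agent[3]), 0)
  # bookkeeping: total inward flow equals total outward flow
  expect_equal(sum(inw$per_agent), sum(outw$per_agent))
  # all agents isolated -> all zero
  far <- rbind(c(0, 0, 0), c(300, 0, 0), c(0, 300, 0))
  win2 <- make_window(list(lead, follow, indep), far)
  expect_equal(unname(inward_nte(win2, radius = 100)$per_agent), rep(0, 3))
})

test_that("genotypic diversity is the per-locus class entropy, summed", {
  clonal <- matrix(0.42, 30, 290)
  expect_equal(genotypic_diversity(clonal), 0)
  # one locus uniform over the 5 classes, all others clonal
  g <- matrix(0.42, 30, 290)
  g[, 17] <- rep(c(0.1, 0.3, 0.5, 0.7, 0.9), 6)
  expect_equal(genotypic_diversity(g), log10(5))
  # bounded by 290 * log10(5); random genotypes approach it
  set.seed(67)
  big <- matrix(runif(500 * 290), 500)
  h <- genotypic_diversity(big)
  expect_lt(h, 290 * log10(5))
  expect_gt(h, 0.95 * 290 * log10(5))
  # permutation invariance in agents and loci
  expect_equal(genotypic_diversity(big[sample(500), sample(290)]), h)
})

test_that("distance-to-goal statistics use raw distances", {
  res <- new_resource(c(100, 100, 100))
  at_goal <- matrix(100, 4, 3)
  st <- distance_to_goal_stats(at_goal, res)
  expect_equal(st$mean, 0)
  set.seed(68)
  pos <- matrix(runif(300, 0, 600), ncol = 3)
  st <- distance_to_goal_stats(pos, res)
  expect_lte(st$min, st$mean)
  expect_lte(st$mean, st$max)
  # corner-to-corner raw distance can exceed the toroidal diameter
  far <- distance_to_goal_stats(matrix(c(550, 550, 550), 1),
                                new_resource(c(0, 0, 0)))
  expect_equal(far$mean, sqrt(3) * 550)
})

test_that("response surfaces expose the steering policy", {
  flat <- response_surface(decode_genotype(rep(0.5, 290)),
                           s_grid = seq(0, 1, 0.25), c_grid = seq(0, 1, 0.25))
  expect_true(all(flat == 0.5))
  # positive front-sensor -> hidden -> O1 chain: nondecreasing in s
  g <- rep(0.5, 290)
  g[1] <- 1      # W_IH[1,1] = 1
  g[261] <- 1    # W_HO[1,1] = 1
  surf <- response_surface(decode_genotype(g), s_grid = seq(0, 1, 0.1),
                           c_grid = c(0, 0.5, 1))
  expect_true(all(diff(surf[, 2]) >= 0))
  # grid endpoints reproduce direct single-step evaluations
  w <- decode_genotype(g)
  direct <- step_controller(w, list(hidden = rep(0.5, 10),
                                    context = rep(1, 10)),
                            c(1, 0, 0, 0, 0, 0))$outputs[1]
  expect_equal(surf["1", "1"], direct)
})

test_that("PCA embedding fixes sign and orders variance", {
  same <- matrix(0.3, 20, 290)
  emb <- pca_embed(same)
  expect_equal(max(abs(emb$scores)), 0)
  # genotypes on a line: PC1 captures everything
  set.seed(69)
  direction <- runif(290)
  tvals <- seq(-1, 1, length.out = 25)
  line <- 0.5 + outer(tvals, direction) * 0.3
  emb <- pca_embed(line)
  expect_gt(emb$variance[1] / sum(emb$variance), 1 - 1e-10)
  # random cloud: ordered variances, orthonormal loadings, positive max load
  cloud <- matrix(runif(50 * 290), 50)
  emb <- pca_embed(cloud)
  expect_gte(emb$variance[1], emb$variance[2])
  expect_equal(sum(emb$loadings[, 1] * emb$loadings[, 2]), 0,
               tolerance = 1e-12)
  for (j in 1:2) {
    expect_gt(emb$loadings[which.max(abs(emb$loadings[, j])), j], 0)
  }
})

test_that("mean emitted signal tracks the controller output", {
  # all-0.5 genes give sigma(0) = 0.5 on every output, hence signal 0.5
  set.seed(70)
  pop <- new_population(8)
  pop$genes <- matrix(0.5, 8, 290)
  run <- run_simulation(pop, new_resource(), 5, mode = "testing")
  ms <- mean_signal_intensity(run)
  expect_equal(ms$mean_signal, rep(0.5, 5))
  expect_equal(ms$t, 1:5)
})

test_that("trajectory windows extract co-alive agents at stride", {
  set.seed(71)
  pop <- new_population(6)
  run <- run_simulation(pop, new_resource(), 40, mode = "testing",
                        sample_every = 1, record_agents = TRUE)
  win <- trajectory_window(run, 10, 30)
  expect_equal(length(win$ids), 6L)
  expect_equal(dim(win$vel), c(21, 6, 3))
  # velocities in the window have unit norm (engine invariant)
  expect_equal(max(abs(sqrt(rowSums(win$vel[5, , ]^2)) - 1)), 0,
               tolerance = 1e-9)
})
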