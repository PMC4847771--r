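# Measurement machinery: neighbourhood statistics, plug-in information
# estimators (entropy / mutual information / transfer entropy), genotypic
# diversity, distance to goal, controller response surfaces, PCA embedding.

#' Average number of neighbours
#'
#' Mean over agents of the number of other agents within `radius` (toroidal
#' distance), the swarming order parameter used throughout the analyses.
#'
#' @param pos `n x 3` matrix of positions (a population snapshot).
#' @param radius Neighbourhood radius.
#' @param world [world_config()].
#' @return Numeric scalar (0 for a single agent or empty snapshot).
#' @export
avg_neighbors <- function(pos, radius = world$sensing_radius,
                          world = world_config()) {
  pos <- matrix(pos, ncol = 3)
  n <- nrow(pos)
  if (n < 2L) return(0)
  d <- pairwise_torus_distance(pos, world$arena_side)
  mean(rowSums(d <= radius) - 1L)
}

#' Density-corrected neighbour excess
#'
#' [avg_neighbors()] minus its expectation for a uniformly dispersed
#' population of the same size, `(n - 1) * (4/3) pi radius^3 / L^3`.  When
#' the population size varies (training runs), the raw neighbour count mostly
#' tracks density; the excess isolates clustering.
#'
#' @inheritParams avg_neighbors
#' @return Numeric scalar; 0 expected for a uniform population, positive for
#'   clustering.
#' @export
excess_neighbors <- function(pos, radius = world$sensing_radius,
                             world = world_config()) {
  pos <- matrix(pos, ncol = 3)
  n <- nrow(pos)
  if (n < 2L) return(0)
  expected <- (n - 1) * (4 / 3) * pi * radius^3 / world$arena_side^3
  avg_neighbors(pos, radius, world) - expected
}

#' Plug-in Shannon entropy of a probability vector
#'
#' \eqn{H = -\sum_i p_i \log_b p_i} with the convention \eqn{0 \log 0 = 0}.
#'
#' @param p Probability vector (non-negative, summing to 1).
#' @param base Logarithm base.
#' @return Entropy in units of `log base`.
#' @examples
#' shannon_entropy(rep(0.2, 5), base = 10)  # log10(5) hartleys
#' @export
shannon_entropy <- function(p, base = exp(1)) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("`p` must be a probability vector")
  }
  p <- p[p > 0]
  -sum(p * log(p)) / log(base)
}

entropy_of_labels <- function(labels, base) {
  counts <- table(labels)
  shannon_entropy(as.numeric(counts) / sum(counts), base)
}

#' Symbolise a continuous series
#'
#' Each column (component) is discretised into `k` equal-width bins over its
#' observed range, and the per-component bins are composed into a single
#' symbol in `0 .. k^m - 1`.  A constant component maps to bin 0.
#'
#' @param x Numeric vector or `T x m` matrix (e.g. a velocity series).
#' @param k Bins per component.
#' @return Integer vector of symbols.
#' @export
symbolize_series <- function(x, k = 2) {
  x <- as.matrix(x)
  m <- ncol(x)
  sym <- integer(nrow(x))
  for (c in seq_len(m)) {
    rng <- range(x[, c])
    if (rng[2] > rng[1]) {
      b <- pmin(floor((x[, c] - rng[1]) / (rng[2] - rng[1]) * k), k - 1)
    } else {
      b <- integer(nrow(x))
    }
    sym <- sym + as.integer(b) * k^(c - 1L)
  }
  as.integer(sym)
}

as_symbols <- function(x, k) {
  if (is.integer(x)) x else symbolize_series(x, k)
}

# past-history block labels: for each prediction time t, the h values
# z[t - delay], z[t - delay - 1], ..., z[t - delay - h + 1] pasted together
history_labels <- function(z, times, history, delay) {
  lab <- rep("", length(times))
  for (j in 0:(history - 1L)) {
    lab <- paste(lab, z[times - delay - j], sep = ".")
  }
  lab
}

#' Plug-in mutual information between two series
#'
#' Both series are symbolised ([symbolize_series()]) unless already integer,
#' and \eqn{I(X;Y) = H(X) + H(Y) - H(X,Y)} is estimated from the joint
#' histogram.  The estimator is exactly symmetric in its arguments.
#'
#' @param x,y Series of equal length (vectors or matrices of components).
#' @param bins Bins per component for symbolisation.
#' @param base Logarithm base.
#' @return Non-negative mutual information estimate.
#' @export
mutual_information <- function(x, y, bins = 2, base = exp(1)) {
  sx <- as_symbols(x, bins)
  sy <- as_symbols(y, bins)
  stopifnot(length(sx) == length(sy))
  entropy_of_labels(sx, base) + entropy_of_labels(sy, base) -
    entropy_of_labels(paste(sx, sy, sep = "."), base)
}

#' Plug-in transfer entropy from one series to another
#'
#' Estimates \eqn{T_{X \to Y} = H(Y_t \mid Y^{(h,d)}) - H(Y_t \mid Y^{(h,d)},
#' X^{(h,d)})} where \eqn{Z^{(h,d)}} is the block of `h` past values delayed
#' by `d` steps, from the joint symbol histogram.  Continuous (velocity)
#' series are symbolised by per-component equal-width binning into
#' `config$bins` bins; the estimate is reported in base `config$base`.
#'
#' @param source,target Series of equal length: numeric vectors, `T x m`
#'   component matrices, or pre-symbolised integer vectors.
#' @param config [te_config()].
#' @return Non-negative transfer entropy estimate (0, with a warning, for
#'   degenerate constant input).
#' @examples
#' set.seed(1)
#' x <- sample.int(2, 500, replace = TRUE) - 1L
#' y <- c(0L, x[-500])  # y copies x with lag 1
#' transfer_entropy(x, y)  # close to log(2)
#' @export
transfer_entropy <- function(source, target, config = te_config()) {
  sx <- as_symbols(source, config$bins)
  sy <- as_symbols(target, config$bins)
  stopifnot(length(sx) == length(sy))
  h <- config$history; d <- config$delay
  T_ <- length(sy)
  if (T_ <= h + d + 1L) stop("series too short for the requested history")
  if (length(unique(sy)) < 2L || length(unique(sx)) < 2L) {
    warning("degenerate (constant) series; transfer entropy is 0")
    return(0)
  }
  times <- (h + d):T_
  yt <- sy[times]
  ypast <- history_labels(sy, times, h, d)
  xpast <- history_labels(sx, times, h, d)
  b <- config$base
  te <- entropy_of_labels(paste(yt, ypast, sep = "|"), b) -
    entropy_of_labels(ypast, b) -
    entropy_of_labels(paste(yt, ypast, xpast, sep = "|"), b) +
    entropy_of_labels(paste(ypast, xpast, sep = "|"), b)
  max(te, 0)
}

#' Extract a trajectory window from a run
#'
#' Collects, from a run recorded with `record_agents = TRUE`, the velocity
#' series of every agent alive throughout `[from, to]` at the run's sampling
#' stride, together with positions at the window midpoint (used to freeze the
#' neighbourhood graph).
#'
#' @param run A `swarm_run` with an `agents` log.
#' @param from,to Iteration bounds (inclusive) of the window.
#' @return A list of class `trajectory_window`: `ids`, `times`, `vel`
#'   (`T x n x 3` array), `pos_mid` (`n x 3`).
#' @export
trajectory_window <- function(run, from = min(run$agents$t),
                              to = max(run$agents$t)) {
  a <- run$agents
  if (is.null(a)) stop("run has no agent log; rerun with record_agents = TRUE")
  a <- a[a$t >= from & a$t <= to, ]
  times <- sort(unique(a$t))
  keep_ids <- Reduce(intersect, split(a$id, a$t))
  if (length(keep_ids) == 0L) stop("no agent is alive throughout the window")
  a <- a[a$id %in% keep_ids, ]
  a <- a[order(a$t, a$id), ]
  n <- length(keep_ids); T_ <- length(times)
  vel <- array(NA_real_, c(T_, n, 3))
  ids <- sort(keep_ids)
  for (k in 1:3) {
    vel[, , k] <- matrix(a[[c("vx", "vy", "vz")[k]]], T_, n, byrow = TRUE)
  }
  t_mid <- times[ceiling(T_ / 2)]
  mid <- a[a$t == t_mid, ]
  mid <- mid[order(mid$id), ]
  structure(list(ids = ids, times = times, vel = vel,
                 pos_mid = as.matrix(mid[, c("x", "y", "z")])),
            class = "trajectory_window")
}

nte_pairs <- function(window, radius, world) {
  d <- pairwise_torus_distance(window$pos_mid, world$arena_side)
  which(d <= radius & upper.tri(d), arr.ind = TRUE)
}

#' Neighbourhood transfer entropy (NTE)
#'
#' For every agent, transfer entropy between its velocity series and those of
#' its neighbours (toroidal distance at the window midpoint below `radius`).
#' The *inward* direction sums neighbour-to-self terms ("how much the agent
#' follows its neighbourhood"); the *outward* direction sums self-to-neighbour
#' terms (leadership).
#'
#' @param window A [trajectory_window()].
#' @param radius Neighbourhood radius.
#' @param config [te_config()].
#' @param world [world_config()].
#' @return A list with `per_agent` (named numeric vector, one sum per agent)
#'   and `mean` (its population average).
#' @export
inward_nte <- function(window, radius = world$sensing_radius,
                       config = te_config(), world = world_config()) {
  nte_directional(window, radius, config, world, inward = TRUE)
}

#' @rdname inward_nte
#' @export
outward_nte <- function(window, radius = world$sensing_radius,
                        config = te_config(), world = world_config()) {
  nte_directional(window, radius, config, world, inward = FALSE)
}

nte_directional <- function(window, radius, config, world, inward) {
  n <- length(window$ids)
  per <- structure(numeric(n), names = window$ids)
  pairs <- nte_pairs(window, radius, world)
  if (nrow(pairs)) {
    sym <- lapply(seq_len(n), function(i)
      symbolize_series(window$vel[, i, ], config$bins))
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      t_ij <- transfer_entropy(sym[[i]], sym[[j]], config)
      t_ji <- transfer_entropy(sym[[j]], sym[[i]], config)
      if (inward) {
        per[i] <- per[i] + t_ji; per[j] <- per[j] + t_ij
      } else {
        per[i] <- per[i] + t_ij; per[j] <- per[j] + t_ji
      }
    }
  }
  list(per_agent = per, mean = if (n) mean(per) else NA_real_)
}

#' Sliding-window NTE series
#'
#' Computes the mean inward or per-agent outward NTE over consecutive windows
#' of a recorded run, for take-off curves and leadership-burst plots.
#'
#' @param run A `swarm_run` recorded with `record_agents = TRUE`.
#' @param window_length Window length in recorded samples.
#' @param by Step between window starts, in samples.
#' @param direction `"inward"` or `"outward"`.
#' @param radius,config,world As in [inward_nte()].
#' @return A data frame with `t` (window midpoint iteration), `id` (agent, or
#'   `NA` for the population mean in the inward case) and `nte`.
#' @export
nte_sliding <- function(run, window_length = te_config()$window, by = window_length,
                        direction = c("inward", "outward"),
                        radius = world$sensing_radius,
                        config = te_config(), world = world_config()) {
  direction <- match.arg(direction)
  times <- sort(unique(run$agents$t))
  starts <- seq(1L, length(times) - window_length + 1L, by = by)
  out <- list()
  for (s in starts) {
    from <- times[s]; to <- times[s + window_length - 1L]
    w <- trajectory_window(run, from, to)
    t_mid <- w$times[ceiling(length(w$times) / 2)]
    if (direction == "inward") {
      v <- inward_nte(w, radius, config, world)
      out[[length(out) + 1L]] <- data.frame(t = t_mid, id = NA_integer_,
                                            nte = v$mean)
    } else {
      v <- outward_nte(w, radius, config, world)
      out[[length(out) + 1L]] <- data.frame(t = t_mid,
                                            id = as.integer(names(v$per_agent)),
                                            nte = unname(v$per_agent))
    }
  }
  do.call(rbind, out)
}

#' Genotypic Shannon diversity
#'
#' Each allele (gene value in \[0, 1\]) is discretised into `classes`
#' equal-width classes; the plug-in Shannon entropy of the class frequencies
#' is computed per locus and summed over the 290 loci.  With the default
#' base-10 logarithm the result is in hartleys, with a theoretical maximum of
#' `290 * log10(5)` (about 202.7) and 0 for a clonal population.
#'
#' @param genes `n x 290` genotype matrix (one agent per row).
#' @param config [diversity_config()].
#' @return Diversity in units of `log(config$base)`.
#' @export
genotypic_diversity <- function(genes, config = diversity_config()) {
  genes <- as.matrix(genes)
  k <- config$classes
  cls <- pmin(floor(genes * k), k - 1)
  total <- 0
  n <- nrow(cls)
  for (locus in seq_len(ncol(cls))) {
    counts <- tabulate(cls[, locus] + 1L, nbins = k)
    total <- total + shannon_entropy(counts / n, config$base)
  }
  total
}

#' Distance-to-goal summary
#'
#' Raw (non-wrapped) Euclidean distances from every agent to the resource
#' centre.  The non-wrapped convention makes the uniform-wander baseline the
#' mean random point-pair distance of the cube, about 0.6617 times the side
#' (≈ 397 units in the 600-cube).
#'
#' @param pos `n x 3` position matrix (snapshot).
#' @param resource A [new_resource()] object.
#' @return List with `mean`, `min`, `max`.
#' @export
distance_to_goal_stats <- function(pos, resource) {
  pos <- matrix(pos, ncol = 3)
  d <- raw_distance(pos, matrix(resource$center, nrow(pos), 3, byrow = TRUE))
  list(mean = mean(d), min = min(d), max = max(d))
}

#' Controller response surface
#'
#' Motor response of a controller over a grid of front-sensor input levels
#' and uniform context activation levels: at each grid point the controller
#' is stepped once from inputs `(s, 0, 0, 0, 0, 0)` and all-`c` context, and
#' the first motor output is recorded.  Characterises evolved steering
#' policies (signal-dependent turning).
#'
#' @param w `controller_weights` from [decode_genotype()].
#' @param s_grid Front-sensor input levels in \[0, 1\].
#' @param c_grid Context activation levels in \[0, 1\].
#' @param cfg [controller_config()].
#' @return Matrix of `O1` responses, rows indexed by `s_grid`, columns by
#'   `c_grid`.
#' @export
response_surface <- function(w, s_grid = seq(0, 1, length.out = 21),
                             c_grid = seq(0, 1, length.out = 21),
                             cfg = controller_config()) {
  out <- matrix(NA_real_, length(s_grid), length(c_grid),
                dimnames = list(signif(s_grid, 4), signif(c_grid, 4)))
  for (i in seq_along(s_grid)) {
    for (j in seq_along(c_grid)) {
      st <- list(hidden = rep(0.5, 10), context = rep(c_grid[j], 10))
      out[i, j] <- step_controller(w, st, c(s_grid[i], 0, 0, 0, 0, 0),
                                   cfg)$outputs[1]
    }
  }
  out
}

#' PCA embedding of genotypes
#'
#' Mean-centred principal component analysis of a genotype matrix; returns
#' the first two component scores with a fixed sign convention (the loading
#' of largest magnitude on each component is positive).
#'
#' @param genes `n x 290` genotype matrix.
#' @return A list with `scores` (`n x 2`, columns `PC1`, `PC2`), `loadings`
#'   (`290 x 2`) and `variance` (explained variance of each component).
#' @export
pca_embed <- function(genes) {
  genes <- as.matrix(genes)
  pc <- prcomp(genes, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    top <- which.max(abs(load[, j]))
    if (load[top, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  if (k < 2L) {  # degenerate single-column input
    scores <- cbind(scores, 0)
    load <- cbind(load, 0)
  }
  colnames(scores) <- colnames(load) <- c("PC1", "PC2")
  list(scores = scores, loadings = load,
       variance = pc$sdev[seq_len(k)]^2)
}

#' Population-mean emitted signal over time
#'
#' @param run A `swarm_run` (uses the per-iteration stats log).
#' @return Data frame with `t` and `mean_signal`.
#' @export
mean_signal_intensity <- function(run) {
  s <- if (inherits(run, "swarm_run")) run$stats else run
  data.frame(t = s$t, mean_signal = s$mean_signal)
}
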