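# Independent brute-force oracles for the plug-in information estimators.
# These take the "sum over observed contexts of weighted conditional
# entropies" route, deliberately different from the package's joint-entropy
# decomposition.

oracle_cond_entropy <- function(target, ctx, base = exp(1)) {
  total <- 0
  for (cv in unique(ctx)) {
    sel <- ctx == cv
    p_ctx <- mean(sel)
    tab <- table(target[sel])
    p <- as.numeric(tab) / sum(tab)
    p <- p[p > 0]
    total <- total + p_ctx * (-sum(p * log(p)))
  }
  total / log(base)
}

oracle_entropy <- function(x, base = exp(1)) {
  tab <- table(x)
  p <- as.numeric(tab) / sum(tab)
  p <- p[p > 0]
  -sum(p * log(p)) / log(base)
}

oracle_mi <- function(x, y, base = exp(1)) {
  oracle_entropy(y, base) - oracle_cond_entropy(y, x, base)
}

oracle_te <- function(x, y, h = 1, d = 1, base = exp(1)) {
  T_ <- length(y)
  times <- (h + d):T_
  block <- function(z, t) paste(z[(t - d):(t - d - h + 1)], collapse = ",")
  ypast <- vapply(times, function(t) block(y, t), character(1))
  xpast <- vapply(times, function(t) block(x, t), character(1))
  yt <- y[times]
  oracle_cond_entropy(yt, ypast, base) -
    oracle_cond_entropy(yt, paste(ypast, xpast), base)
}

# hand construction of a trajectory window (bypasses the agent log)
make_window <- function(vel_list, pos_mid, ids = seq_along(vel_list)) {
  T_ <- nrow(vel_list[[1]])
  n <- length(vel_list)
  vel <- array(NA_real_, c(T_, n, 3))
  for (i in seq_len(n)) vel[, i, ] <- vel_list[[i]]
  structure(list(ids = ids, times = seq_len(T_), vel = vel,
                 pos_mid = pos_mid),
            class = "trajectory_window")
}

# rotation matrix about the world z axis
rot_z <- function(angle) {
  matrix(c(cos(angle), sin(angle), 0,
           -sin(angle), cos(angle), 0,
           0, 0, 1), 3, 3)
}
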