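# Shared fixtures: small ground-truth parameter sets and toy data builders.

experimental_temps <- c(15, 20, 24, 28, 32, 35)
nitrogen_levels <- c(0.5, 1, 2, 5, 20, 80, 400, 800)

# a well-behaved double-exponential curve peaking at 28 C
toy_tpc <- list(b1 = 0.2, b2 = 0.08, d0 = 0.1, d2 = 0.25, Topt = 28)

# draw `n` random but hump-shaped TPC parameter sets
random_tpc_draws <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    b2 <- runif(1, 0.03, 0.15)
    d2 <- b2 + runif(1, 0.05, 0.3)
    d0 <- runif(1, 0.01, 0.3)
    Topt <- runif(1, 18, 33)
    peak <- runif(1, 0.3, 2)
    b1 <- (peak + d0) / (exp(b2 * Topt) * (1 - b2 / d2))
    list(b1 = b1, b2 = b2, d0 = d0, d2 = d2, Topt = Topt)
  })
}

# replicated noisy rates on the experimental temperature grid
toy_tpc_rates <- function(tr, noise = 0.05, reps = 4, seed = 1,
                          temps = experimental_temps) {
  set.seed(seed)
  d <- data.frame(temperature = rep(temps, each = reps))
  d$mu <- tpc_mu(d$temperature, tr$b1, tr$b2, tr$d0, tr$d2, tr$Topt) +
    rnorm(nrow(d), 0, noise)
  d
}

# replicated noisy Monod rates on the nitrogen design levels
toy_monod_rates <- function(mu_max = 1, Ks = 5, m = 0.1, noise = 0.02,
                            reps = 4, seed = 1, levels = nitrogen_levels) {
  set.seed(seed)
  d <- data.frame(resource_level = rep(levels, each = reps))
  d$mu <- monod_mu(d$resource_level, mu_max, Ks, m) + rnorm(nrow(d), 0, noise)
  d
}

# posterior-draw matrix whose per-level mean follows `f`, with iid jitter
toy_draw_matrix <- function(f, x = experimental_temps, n = 300, jitter = 0.02,
                            seed = 1) {
  set.seed(seed)
  y <- f(x)
  matrix(rep(y, each = n), n, length(x)) +
    matrix(rnorm(n * length(x), 0, jitter), n, length(x))
}

# brute-force Kendall tau-b from concordant/discordant pair counts
kendall_tau_b_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) next
      if (dx == 0) { tx <- tx + 1; next }
      if (dy == 0) { ty <- ty + 1; next }
      if (dx * dy > 0) conc <- conc + 1 else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx_total(x)) * (n0 - tx_total(y)))
}
tx_total <- function(v) {
  tt <- table(v)
  sum(tt * (tt - 1) / 2)
}

# ANOSIM R from its defining formula on rank-transformed distances
anosim_R_oracle <- function(X, grouping) {
  d <- as.matrix(dist(X))
  iu <- which(upper.tri(d), arr.ind = TRUE)
  dv <- d[upper.tri(d)]
  rk <- rank(dv)
  same <- grouping[iu[, 1]] == grouping[iu[, 2]]
  M <- length(dv)
  (mean(rk[!same]) - mean(rk[same])) / (M / 2)
}
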