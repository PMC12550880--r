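make_summary_fixture <- function() {
  # three populations x one resource with hand-computable summaries
  monod <- expand.grid(population = c("a", "b", "c"),
                       temperature = experimental_temps,
                       stringsAsFactors = FALSE)
  monod$phylum <- c(a = "Chlorophyta", b = "Cyanobacteria",
                    c = "Bacillariophyta")[monod$population]
  monod$resource_type <- "light"
  rstar_by_pop <- list(a = c(0.2, 0.1, 0.4, 0.3, 0.5, 0.9),
                       b = c(2, 1, 4, 3, 5, 9),
                       c = c(20, 10, 40, 30, 50, 90))
  monod$rstar <- NA_real_
  for (p in names(rstar_by_pop)) {
    monod$rstar[monod$population == p] <- rstar_by_pop[[p]]
  }
  monod$net_mu_max <- ave(seq_len(nrow(monod)), monod$population,
                          FUN = seq_along) / 10
  monod$retained <- TRUE
  tpc <- expand.grid(population = c("a", "b", "c"),
                     resource_level = c(1, 8, 18, 40),
                     stringsAsFactors = FALSE)
  tpc$resource_type <- "light"
  tpc$phylum <- c(a = "Chlorophyta", b = "Cyanobacteria",
                  c = "Bacillariophyta")[tpc$population]
  tpc$Topt <- 20 + as.numeric(factor(tpc$population)) * 2 + tpc$resource_level / 40
  tpc$Tmax <- tpc$Topt + 6
  tpc$Tbr <- 8 + as.numeric(factor(tpc$population))
  tpc$Topt_excluded <- FALSE
  tpc$Tmax_excluded <- FALSE
  tpc$Tbr_excluded <- FALSE
  list(monod = monod, tpc = tpc)
}

test_that("trait summaries take extremes over retained estimates only", {
  fx <- make_summary_fixture()
  s <- summarize_traits(fx$monod, fx$tpc)
  a <- s[s$population == "a", ]
  # minimum R* is at 20 C for every population in the fixture
  expect_equal(unique(s$TRstar_min), 20)
  expect_equal(a$logRstar_min, log(0.1))
  # R*_min of (0.1, 1, 10) across populations: log then z-score gives
  # equally spaced values (-1, 0, 1) times the sd factor
  expected <- (log(c(0.1, 1, 10)) - mean(log(c(0.1, 1, 10)))) /
    sd(log(c(0.1, 1, 10)))
  expect_equal(s$scaled_logRstar_min[order(s$population)], expected,
               tolerance = 1e-12)
  # TPC maxima respect exclusion flags
  expect_equal(a$Tmax_max, max(fx$tpc$Tmax[fx$tpc$population == "a"]))
  fx2 <- fx
  worst <- which.max(fx2$tpc$Tmax * (fx2$tpc$population == "a"))
  fx2$tpc$Tmax_excluded[worst] <- TRUE
  s2 <- summarize_traits(fx2$monod, fx2$tpc)
  expect_lt(s2$Tmax_max[s2$population == "a"], a$Tmax_max)
  # non-retained Monod fits do not contribute
  fx3 <- fx
  fx3$monod$retained[fx3$monod$population == "a" &
                       fx3$monod$temperature == 20] <- FALSE
  s3 <- summarize_traits(fx3$monod, fx3$tpc)
  expect_equal(s3$TRstar_min[s3$population == "a"], 15)  # next-lowest R*
  expect_error(summarize_traits(fx$monod[0, ], fx$tpc[0, ]), "empty")
})

test_that("PCA matches a direct eigendecomposition and reconstructs its input", {
  set.seed(4)
  n <- 10
  tab <- data.frame(scaled_logRstar_min = rnorm(n), TRstar_min = rnorm(n),
                    net_mu_max_max = rnorm(n), Topt_max = rnorm(n),
                    Tmax_max = rnorm(n), Tbr_max = rnorm(n),
                    population = letters[1:n], resource_type = "light",
                    phylum = "x")
  p <- run_pca(tab)
  expect_equal(sum(p$var_explained), 100, tolerance = 1e-9)
  X <- scale(as.matrix(tab[, thermotraits:::trait_columns]))
  ev <- eigen(cov(X))$values
  expect_equal(p$var_explained, 100 * ev / sum(ev), tolerance = 1e-9)
  # scores %*% t(loadings) reconstructs the scaled data
  expect_equal(unname(p$scores %*% t(p$loadings)), unname(X[, ]),
               tolerance = 1e-9)
  # perfectly correlated columns load together on PC1
  tab2 <- tab
  tab2$Tbr_max <- 2 * tab2$Topt_max + 3
  p2 <- run_pca(tab2)
  l <- p2$loadings
  expect_equal(l["Tbr_max", 1], l["Topt_max", 1], tolerance = 1e-6)
  tab3 <- tab; tab3$Tbr_max <- 1
  expect_error(run_pca(tab3), "constant")
})

test_that("ANOSIM separates separated clouds and matches its defining formula", {
  set.seed(10)
  cloud1 <- matrix(rnorm(20, 0, 0.2), 10, 2)
  cloud2 <- matrix(rnorm(20, 5, 0.2), 10, 2)
  X <- rbind(cloud1, cloud2)
  g <- rep(c("p", "q"), each = 10)
  res <- anosim_groups(X, g, n_perm = 199, seed = 5)
  expect_gt(res$R, 0.9)
  expect_lt(res$p, 0.05)
  expect_equal(res$R, anosim_R_oracle(X, g), tolerance = 1e-12)
  # random labels on one cloud: R near zero on average
  rs <- vapply(1:20, function(s) {
    set.seed(s)
    anosim_groups(cloud1, sample(rep(c("p", "q"), each = 5)),
                  n_perm = 49, seed = s)$R
  }, 0)
  expect_lt(abs(mean(rs)), 0.1)
  # rank-based: invariant to monotone transforms of the distances
  d <- dist(X)
  expect_equal(anosim_groups(d, g, n_perm = 49, seed = 1)$R,
               anosim_groups(d^2, g, n_perm = 49, seed = 1)$R)
  expect_error(anosim_groups(X, rep("p", 20)), "2 groups")
})

test_that("Welch ANOVA and Games-Howell calibrate known group differences", {
  # identical group distributions: p near 1
  x <- rep(c(1, 2, 3, 4), 3)
  g <- rep(c("a", "b", "c"), each = 4)
  res <- welch_games_howell(x, g)
  expect_gt(res$welch$p.value, 0.95)
  expect_true(all(res$pairs$p > 0.95))
  # two groups 10 sds apart: matches Welch t-test exactly, tiny p
  set.seed(2)
  y1 <- rnorm(8, 0, 1); y2 <- rnorm(8, 10, 1)
  res2 <- welch_games_howell(c(y1, y2), rep(c("a", "b"), each = 8))
  tt <- t.test(y1, y2)
  expect_equal(res2$welch$p.value, tt$p.value, tolerance = 1e-9)
  expect_lt(res2$pairs$p, 1e-4)
  # three groups, one shifted: only the two shifted pairs significant
  set.seed(3)
  z <- c(rnorm(10), rnorm(10), rnorm(10, 4))
  gz <- rep(c("a", "b", "c"), each = 10)
  res3 <- welch_games_howell(z, gz)
  pr <- res3$pairs
  expect_gt(pr$p[pr$group1 == "a" & pr$group2 == "b"], 0.05)
  expect_lt(pr$p[pr$group1 == "a" & pr$group2 == "c"], 0.05)
  expect_lt(pr$p[pr$group1 == "b" & pr$group2 == "c"], 0.05)
})

test_that("Kendall tau-b equals the brute-force pair-count oracle", {
  cols <- thermotraits:::trait_columns
  mk_tab <- function(X) {
    tab <- as.data.frame(X)
    names(tab) <- cols[seq_len(ncol(X))]
    for (cc in setdiff(cols, names(tab))) tab[[cc]] <- rnorm(nrow(X))
    tab
  }
  # exact concordance / reversal
  tab <- mk_tab(cbind(1:6, 1:6 * 2, 7 - (1:6)))
  km <- kendall_matrix(tab)
  expect_equal(km$tau[1, 2], 1)
  expect_equal(km$tau[1, 3], -1)
  # ties: compare to the O(n^2) oracle at several sizes
  for (n in c(5, 20, 50)) {
    set.seed(n)
    x <- round(rnorm(n), 1)   # rounding induces ties
    y <- round(x + rnorm(n), 1)
    tab <- mk_tab(cbind(x, y))
    km <- kendall_matrix(tab)
    expect_equal(km$tau[1, 2], kendall_tau_b_oracle(x, y), tolerance = 1e-12)
  }
  # constant column: undefined, reported missing
  tabc <- mk_tab(cbind(1:5, rep(2, 5)))
  expect_true(is.na(kendall_matrix(tabc)$tau[1, 2]))
})

test_that("the resource-interaction test gates pooling of regressions", {
  x <- rep(1:10, 2)
  res_lab <- rep(c("light", "nitrogen"), each = 10)
  # identical slopes, noiseless: no interaction, pooled slope exact
  y_same <- 2 * x + ifelse(res_lab == "light", 0, 1)
  it <- interaction_test(y_same, x, res_lab)
  expect_gt(it$p_interaction, 0.99)
  expect_false(is.null(it$pooled))
  expect_equal(unname(coef(it$pooled)["x"]), 2, tolerance = 1e-9)
  # opposite slopes: strong interaction
  set.seed(1)
  y_opp <- ifelse(res_lab == "light", x, -x) + rnorm(20, 0, 0.1)
  it2 <- interaction_test(y_opp, x, res_lab)
  expect_lt(it2$p_interaction, 0.01)
  expect_null(it2$pooled)
  expect_error(interaction_test(y_same[1:10], x[1:10], res_lab[1:10]),
               "2 resource")
})

test_that("the constrained-resampling null reproduces the sampling artifact", {
  set.seed(5)
  tmax <- runif(12, 25, 40)
  # shared sampling bounds: no artifact, null centered at zero
  nt0 <- null_tau_distribution(tmax, lower = 15, upper = 35, n_sims = 1000,
                               seed = 1)
  expect_lt(abs(mean(nt0$null_tau)), 0.05)
  # heterogeneous upper bounds: positive correlation by construction
  nt1 <- null_tau_distribution(tmax, lower = 15, n_sims = 1000, seed = 2)
  expect_gt(mean(nt1$null_tau), 0.1)
  # observed tau beyond the null maximum scores at the top percentile
  nt2 <- null_tau_distribution(tmax, lower = 15,
                               observed_tau = max(nt1$null_tau) + 0.01,
                               n_sims = 500, seed = 3)
  expect_equal(nt2$percentile, 1)
  expect_error(null_tau_distribution(c(20, 30), lower = 25), "below")
  # calibration: under the constrained null itself, percentiles are uniform
  percs <- vapply(1:200, function(s) {
    set.seed(1000 + s)
    obs <- runif(length(tmax), 15, tmax)
    obs_tau <- cor(obs, tmax, method = "kendall")
    null_tau_distribution(tmax, lower = 15, observed_tau = obs_tau,
                          n_sims = 200, seed = s)$percentile
  }, 0)
  ks <- suppressWarnings(ks.test(percs, "punif"))
  expect_gt(ks$p.value, 0.01)
})
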