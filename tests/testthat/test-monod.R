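test_that("the Monod curve and its derived traits obey their identities", {
  expect_equal(monod_mu(5, 1.2, 5, 0.1), 1.2 / 2 - 0.1)
  expect_equal(monod_mu(0, 1.2, 5, 0.1), -0.1)
  expect_equal(monod_mu(20, 1.2, 5, 0.1), 1.2 * 20 / 25 - 0.1)
  expect_equal(monod_mu(20, 1.2, 5, 0.1), 0.86)
  expect_error(monod_mu(1, 1, 0, 0.1), "Ks")

  expect_equal(affinity(1.0, 2.5), 0.4)
  expect_equal(affinity(3, 2.5), 3 * affinity(1, 2.5))  # homogeneity in mu_max
  expect_lt(affinity(1, 1e12), 1e-10)                   # Ks -> Inf limit
  expect_error(affinity(1, -1))

  expect_equal(net_mu_max(1.2, 0.2), 1.0)
  expect_equal(net_mu_max(1.2, 0), 1.2)
})

test_that("closed-form R* matches the bisection root of mu(R) = m_ext", {
  bisect_rstar <- function(mu_max, Ks, m, m_ext) {
    f <- function(R) monod_mu(R, mu_max, Ks, m) - m_ext
    hi <- 10 * Ks + 2 * r_star(mu_max, Ks, m, m_ext)  # bracket the root
    if (!is.finite(hi) || f(hi) <= 0) return(Inf)
    uniroot(f, c(0, hi), tol = 1e-10)$root
  }
  set.seed(11)
  worst <- 0
  for (i in 1:1000) {
    mu_max <- runif(1, 0.2, 3)
    Ks <- 10^runif(1, -2, 2)
    m <- runif(1, 0, 0.4)
    m_ext <- 0.1
    if (mu_max <= m + m_ext + 0.02) next
    r1 <- r_star(mu_max, Ks, m, m_ext)
    r2 <- bisect_rstar(mu_max, Ks, m, m_ext)
    worst <- max(worst, abs(r1 - r2))
  }
  expect_lt(worst, 1e-8)
  # monotonicity: increasing in m_tot and Ks, decreasing in mu_max
  expect_gt(r_star(1, 2.5, 0.05, 0.1), r_star(1, 2.5, 0, 0.1))
  expect_gt(r_star(1, 3, 0, 0.1), r_star(1, 2.5, 0, 0.1))
  expect_lt(r_star(1.2, 2.5, 0, 0.1), r_star(1, 2.5, 0, 0.1))
  # worked value and edge cases
  expect_equal(r_star(1, 2.5, 0, 0.1), 0.1 * 2.5 / 0.9)
  expect_equal(r_star(1, 2.5, 0, 0.1), 0.27778, tolerance = 1e-4)
  expect_equal(r_star(1, 2.5, 0, 0), 0)
  expect_identical(r_star(0.05, 2.5, 0, 0.1), Inf)
})

test_that("derived traits are computed per draw, not from summaries", {
  # asymmetric toy posterior: median of differences != difference of medians
  set.seed(3)
  mu_max <- rlnorm(1000, 0, 0.5)
  m <- rlnorm(1000, -2, 1)
  per_draw <- median(net_mu_max(mu_max, m))
  of_medians <- net_mu_max(median(mu_max), median(m))
  expect_false(isTRUE(all.equal(per_draw, of_medians, tolerance = 1e-3)))
  # fit summaries use the per-draw ordering
  rates <- toy_monod_rates(seed = 5)
  f <- fit_monod(rates, monod_priors("nitrogen"), iterations = 400, seed = 2)
  med <- setNames(f$summary$median, f$summary$parameter)
  expect_equal(med[["net_mu_max"]], median(f$draws$mu_max - f$draws$m))
  expect_equal(med[["alpha"]], median(f$draws$mu_max / f$draws$Ks))
  # credible intervals are ordered
  expect_true(all(f$summary$lower <= f$summary$median + 1e-12))
  expect_true(all(f$summary$median <= f$summary$upper + 1e-12))
  # R* draws are positive or the no-growth sentinel
  expect_true(all(f$draws$rstar > 0 | is.infinite(f$draws$rstar)))
})

test_that("retention requires growth above external losses at three levels", {
  mk <- function(mus) data.frame(resource_level = seq_along(mus), mu = mus)
  expect_true(monod_retention(mk(rep(0.5, 8))))
  expect_true(monod_retention(mk(c(0.2, 0.15, 0.11, rep(0.05, 5)))))
  expect_false(monod_retention(mk(c(0.2, 0.15, rep(0.05, 6)))))
  # boundary: exactly m_ext does not count as above
  expect_false(monod_retention(mk(c(0.2, 0.15, 0.1, rep(0.05, 5)))))
})

test_that("posterior medians recover known Monod parameters", {
  rates <- toy_monod_rates(mu_max = 1.0, Ks = 5, m = 0.1, noise = 0.02, seed = 1)
  f <- fit_monod(rates, monod_priors("nitrogen"), iterations = 2000, seed = 7)
  med <- setNames(f$summary$median, f$summary$parameter)
  expect_lt(abs(med[["mu_max"]] - 1.0) / 1.0, 0.1)
  expect_lt(abs(med[["Ks"]] - 5) / 5, 0.1)
  expect_lt(abs(med[["m"]] - 0.1), 0.05)
  expect_true(f$retained)
  # same seed, same data: bit-identical summaries
  f2 <- fit_monod(rates, monod_priors("nitrogen"), iterations = 2000, seed = 7)
  expect_identical(f$summary, f2$summary)
  # fewer than 3 distinct levels is an error
  few <- rates[rates$resource_level %in% c(0.5, 800), ]
  expect_error(fit_monod(few, monod_priors("nitrogen")), "3 distinct")
})

test_that("with flat priors the posterior agrees with least squares", {
  set.seed(2)
  R <- rep(nitrogen_levels, each = 4)
  mu <- monod_mu(R, 1.0, 5, 0.1) + rnorm(length(R), 0, 0.005)
  pr <- monod_priors("nitrogen")
  pr$mu_max[2] <- pr$mu_max[2] * 10
  pr$Ks[2] <- pr$Ks[2] * 10
  pr$m[2] <- pr$m[2] * 10
  f <- fit_monod(data.frame(resource_level = R, mu = mu), pr,
                 iterations = 4000, seed = 5)
  ls <- nls(mu ~ a * R / (K + R) - m0, start = list(a = 1, K = 5, m0 = 0.1),
            data = data.frame(R = R, mu = mu))
  cf <- coef(ls)
  med <- setNames(f$summary$median, f$summary$parameter)
  expect_lt(abs(med[["mu_max"]] - cf[["a"]]) / cf[["a"]], 0.02)
  expect_lt(abs(med[["Ks"]] - cf[["K"]]) / cf[["K"]], 0.02)
})
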