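test_that("the double-exponential curve matches an independent evaluation", {
  # independent coding: birth and death written separately
  tpc_oracle <- function(T_C, b1, b2, d0, d2, Topt, g = 1) {
    birth <- b1 * exp(b2 * T_C) * g
    death_coef <- b1 * b2 / d2 * exp((b2 - d2) * Topt)
    birth - d0 - death_coef * exp(d2 * T_C)
  }
  tr <- toy_tpc
  for (T_C in seq(-5, 45, by = 2.5)) {
    expect_equal(tpc_mu(T_C, tr$b1, tr$b2, tr$d0, tr$d2, tr$Topt),
                 tpc_oracle(T_C, tr$b1, tr$b2, tr$d0, tr$d2, tr$Topt),
                 tolerance = 1e-12)
  }
  # derivative vanishes at Topt when resource is replete
  h <- 1e-4
  for (dr in random_tpc_draws(10, seed = 2)) {
    d1 <- (tpc_mu(dr$Topt + h, dr$b1, dr$b2, dr$d0, dr$d2, dr$Topt) -
             tpc_mu(dr$Topt - h, dr$b1, dr$b2, dr$d0, dr$d2, dr$Topt)) / (2 * h)
    expect_lt(abs(d1), 1e-6)
  }
  # death dominates at high temperature
  expect_lt(tpc_mu(200, tr$b1, tr$b2, tr$d0, tr$d2, tr$Topt), -1e3)
  expect_error(tpc_mu(20, 0.2, 0.08, 0.1, 0, 28), "d2")
})

test_that("thermal limits from root finding match a fine grid scan", {
  grid_scan_zero <- function(dr, lo, hi) {
    tt <- seq(lo, hi, by = 0.001)
    mu <- tpc_mu(tt, dr$b1, dr$b2, dr$d0, dr$d2, dr$Topt)
    flips <- which(diff(sign(mu)) != 0)
    if (!length(flips)) return(c(NA_real_, NA_real_))
    c(tt[flips[1]], tt[flips[length(flips)]])
  }
  worst_root <- 0; worst_tbr <- 0; n_checked <- 0
  for (dr in random_tpc_draws(200, seed = 42)) {
    mu_opt <- tpc_mu(dr$Topt, dr$b1, dr$b2, dr$d0, dr$d2, dr$Topt)
    lim <- derive_tmax_tmin(dr)
    if (mu_opt <= 0) {
      expect_true(all(is.na(lim)))
      next
    }
    scan <- grid_scan_zero(dr, dr$Topt - 150, dr$Topt + 100)
    if (!is.na(lim[["Tmax"]])) {
      worst_root <- max(worst_root, abs(lim[["Tmax"]] - scan[2]))
      expect_lt(abs(tpc_mu(lim[["Tmax"]], dr$b1, dr$b2, dr$d0, dr$d2, dr$Topt)),
                1e-6)
    }
    if (!is.na(lim[["Tmin"]])) {
      worst_root <- max(worst_root, abs(lim[["Tmin"]] - scan[1]))
    }
    # thermal breadth equals the measure of {T: mu >= 0.8 mu(Topt)}
    tbr <- derive_tbr(dr)
    tt <- seq(dr$Topt - 150, dr$Topt + 150, by = 0.001)
    mu <- tpc_mu(tt, dr$b1, dr$b2, dr$d0, dr$d2, dr$Topt)
    measure <- sum(mu >= 0.8 * mu_opt) * 0.001
    worst_tbr <- max(worst_tbr, abs(tbr - measure))
    # orderings
    if (!anyNA(lim)) {
      expect_lt(lim[["Tmin"]], dr$Topt)
      expect_gt(lim[["Tmax"]], dr$Topt)
      expect_lt(tbr, lim[["Tmax"]] - lim[["Tmin"]])
    }
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 150)
  expect_lt(worst_root, 0.01)
  expect_lt(worst_tbr, 0.01)
  # a curve with no temperature-independent loss never crosses zero below Topt
  no_d0 <- list(b1 = 0.2, b2 = 0.08, d0 = 0, d2 = 0.25, Topt = 28)
  expect_true(is.na(derive_tmax_tmin(no_d0)[["Tmin"]]))
  expect_false(is.na(derive_tmax_tmin(no_d0)[["Tmax"]]))
})

test_that("trait medians outside the measured range are flagged, inclusively", {
  tab <- data.frame(Topt = c(14.9, 15, 35, 35.1, 25),
                    Tmax = c(40, 40.1, 39, 41, 30),
                    Tmin = c(0, -0.1, 5, -20, 10),
                    Tbr = c(20, 20.1, 19.9, 47, NA))
  out <- apply_tpc_exclusions(tab)
  expect_equal(out$Topt_excluded, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(out$Tmax_excluded, c(FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(out$Tmin_excluded, c(FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(out$Tbr_excluded, c(FALSE, TRUE, FALSE, TRUE, TRUE))
  # rows are flagged, never deleted
  expect_equal(nrow(out), nrow(tab))
})

test_that("posterior sampling recovers the thermal optimum and is seeded", {
  rates <- toy_tpc_rates(toy_tpc, noise = 0.02, seed = 4)
  f <- fit_tpc(rates, iterations = 2000, seed = 11, max_derived_draws = 500)
  med <- setNames(f$summary$median, f$summary$parameter)
  expect_lt(abs(med[["Topt"]] - 28), 1)
  truth_lim <- derive_tmax_tmin(toy_tpc)
  expect_lt(abs(med[["Tmax"]] - truth_lim[["Tmax"]]), 1)
  f2 <- fit_tpc(rates, iterations = 2000, seed = 11, max_derived_draws = 500)
  expect_identical(f$summary, f2$summary)
  # growth above m_ext at fewer than 3 temperatures: skipped
  dead <- rates
  dead$mu[dead$temperature > 20] <- -0.5
  expect_error(fit_tpc(dead), "fewer than 3")
})

test_that("the collapsed sampler agrees with an independent joint sampler", {
  rates <- toy_tpc_rates(toy_tpc, noise = 0.05, seed = 4)
  f <- fit_tpc(rates, iterations = 4000, seed = 11)
  lp <- thermotraits:::tpc_log_post(rates$temperature, rates$mu, tpc_priors())
  init_fun <- function(ch) {
    c(logw = log(1.2 + 0.05 * ch), logb2 = log(0.05 + 0.02 * ch),
      logd0 = log(0.1), logd2 = log(0.2 + 0.05 * ch),
      zTopt = qlogis((26 + ch) / 50), logsigma = log(0.1))
  }
  am <- adaptive_metropolis(lp, init_fun, iterations = 20000, seed = 3)
  topt_am <- median(50 * plogis(as.numeric(am$draws$zTopt)))
  w_am <- median(exp(as.numeric(am$draws$logw)))
  med <- setNames(f$summary$median, f$summary$parameter)
  topt_f <- median(f$draws$Topt)
  expect_lt(abs(topt_f - topt_am), 0.2)
  expect_lt(abs(median(f$draws$w) - w_am) / w_am, 0.1)
  expect_lt(abs(med[["sigma"]] -
                  median(exp(as.numeric(am$draws$logsigma)))) / med[["sigma"]],
            0.15)
})
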