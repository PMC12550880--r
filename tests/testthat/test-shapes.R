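test_that("degenerate ensembles behave predictably", {
  x <- experimental_temps
  # all draws identical and linear: every fit has EDF ~ 1, band collapses
  line <- matrix(rep(2 * x + 1, each = 50), 50, length(x))
  ens <- bootstrap_fits(gradient_series(x, line), n_boot = 30, seed = 1)
  expect_true(all(abs(ens$edf - 1) < 0.05, na.rm = TRUE))
  expect_lt(max(ens$mean_curve$upper - ens$mean_curve$lower), 1e-6)
  expect_equal(max(abs(ens$mean_curve$mean - (2 * ens$grid + 1))), 0,
               tolerance = 1e-6)
  v <- classify_shape(ens)
  expect_equal(v$label, "increasing")
  expect_equal(v$pathway, "LM")
  expect_equal(unname(v$probability), 1)
  # three gradient values force the straight-line pathway
  s3 <- gradient_series(c(1, 2, 3),
                        toy_draw_matrix(function(x) x, x = c(1, 2, 3),
                                        jitter = 0.01))
  e3 <- bootstrap_fits(s3, n_boot = 40, seed = 2)
  expect_equal(e3$pathway, "LM")
  # seeded runs are identical
  ser <- gradient_series(x, toy_draw_matrix(function(x) 0.01 * (x - 25)^2))
  e1 <- bootstrap_fits(ser, n_boot = 40, seed = 9)
  e2 <- bootstrap_fits(ser, n_boot = 40, seed = 9)
  expect_identical(e1$pred, e2$pred)
  # degenerate gradient rejected
  expect_error(gradient_series(rep(5, 4), matrix(1, 10, 4)), "all equal")
  # gamma family guards against non-positive draws
  expect_error(gradient_series(x, line - 100, family = "gamma"), "positive")
})

test_that("canonical shapes are labelled with high probability", {
  x <- experimental_temps
  cases <- list(
    list(f = function(x) 0.01 * (x - 25)^2 + 1, want = "U-shaped"),
    list(f = function(x) -0.01 * (x - 25)^2 + 5, want = "hump-shaped"),
    list(f = function(x) 2 * x, want = "increasing"),
    list(f = function(x) -0.5 * x + 20, want = "decreasing"))
  for (cs in cases) {
    ser <- gradient_series(x, toy_draw_matrix(cs$f, jitter = 0.02, seed = 7))
    v <- classify_shape(bootstrap_fits(ser, n_boot = 200, seed = 42))
    expect_equal(v$label, cs$want)
    expect_gte(v$probability, 0.9)
    if (cs$want %in% c("U-shaped", "hump-shaped")) {
      expect_lt(abs(v$critical - 25), 2)
    }
  }
  # label frequencies form a probability distribution
  ser <- gradient_series(x, toy_draw_matrix(cases[[1]]$f, jitter = 0.02))
  v <- classify_shape(bootstrap_fits(ser, n_boot = 100, seed = 5))
  expect_equal(sum(v$shape_freq), 1, tolerance = 1e-12)
})

test_that("pure noise is called uncertain most of the time", {
  x <- experimental_temps
  n_uncertain <- 0
  for (s in 1:20) {
    set.seed(s)
    draws <- matrix(rnorm(200 * 6), 200, 6)
    v <- classify_shape(bootstrap_fits(gradient_series(x, draws),
                                       n_boot = 100, seed = s))
    if (v$label == "uncertain") n_uncertain <- n_uncertain + 1
  }
  expect_gte(n_uncertain, 10)
})

test_that("classification is invariant to affine rescaling of the gradient", {
  x <- experimental_temps
  for (f in list(function(x) 0.01 * (x - 25)^2 + 1, function(x) 2 * x)) {
    draws <- toy_draw_matrix(f, jitter = 0.02, seed = 3)
    v1 <- classify_shape(bootstrap_fits(gradient_series(x, draws),
                                        n_boot = 100, seed = 4))
    x2 <- 10 * x - 100
    v2 <- classify_shape(bootstrap_fits(gradient_series(x2, draws),
                                        n_boot = 100, seed = 4))
    expect_equal(v1$label, v2$label)
  }
})

test_that("smooth EDF tracks the penalty from line to full basis", {
  set.seed(6)
  x <- seq(0, 10, length.out = 30)
  y <- sin(x) + rnorm(30, 0, 0.1)
  edfs <- vapply(c(1e8, 1, 1e-4, 1e-12), function(sp) {
    fit <- mgcv::gam(y ~ s(x, k = 8, bs = "cr"), sp = sp)
    thermotraits:::smooth_edf(fit)
  }, 0)
  expect_lt(abs(edfs[1] - 1), 0.05)          # infinite penalty: straight line
  expect_gt(edfs[4], 6.5)                    # no penalty: near basis dimension
  expect_true(all(diff(edfs) > -1e-8))       # monotone in decreasing penalty
})

test_that("the mean-species curve applies the same gating rules", {
  x <- experimental_temps
  # population medians on a common line: linear refit, slope exact
  meds <- rbind(2 * x + 1, 2 * x + 3, 2 * x - 1)
  mc <- mean_species_curve(meds, x)
  expect_equal(mc$pathway, "LM")
  expect_equal(mc$slope, 2, tolerance = 1e-9)
  expect_equal(mc$label, "increasing")
  # symmetric U: interior critical point near the vertex
  meds_u <- rbind(0.05 * (x - 25)^2 + 1, 0.05 * (x - 25)^2 + 2)
  mu_c <- mean_species_curve(meds_u, x)
  expect_equal(mu_c$label, "U-shaped")
  expect_lt(abs(mu_c$critical - 25), 2)
  expect_error(mean_species_curve(meds[1, , drop = FALSE], x), "2 populations")
})
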