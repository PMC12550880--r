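#' Double-exponential thermal performance curve
#'
#' Net growth rate at temperature `T_C`:
#' `mu = b1*exp(b2*T)*g - [d0 + (b1*b2/d2)*exp((b2-d2)*Topt)*exp(d2*T)]`
#' where `b1` is the birth rate at 0 C, `b2` the exponential increase of
#' birth with temperature, `d0` the temperature-independent loss, `d2` the
#' exponential increase of death with temperature, and `g` in (0, 1] a
#' resource-limitation multiplier on birth. The death coefficient is
#' parameterized through `Topt` so that, at `g = 1`, the curve's interior
#' critical point sits exactly at `Topt` (a maximum when `d2 > b2`).
#'
#' @param T_C temperature, Celsius (vectorized).
#' @param b1,b2,d0,d2,Topt curve parameters; `d2 > 0`.
#' @param g resource term in (0, 1], default 1 (replete).
#' @return Growth rate(s), d^-1.
#' @export
tpc_mu <- function(T_C, b1, b2, d0, d2, Topt, g = 1) {
  if (any(d2 <= 0)) stop("d2 must be positive")
  stopifnot(all(g > 0), all(g <= 1))
  b1 * exp(b2 * T_C) * g -
    (d0 + (b1 * b2 / d2) * exp((b2 - d2) * Topt) * exp(d2 * T_C))
}

#' Default TPC priors
#'
#' Weakly informative truncated normals on the sampled parameterization
#' (`w`, `b2`, `d0`, `d2`, `Topt`), where `w = b1*exp(b2*Topt)` is the birth
#' rate at `Topt` — sampling `w` instead of `b1` decorrelates the birth scale
#' from `Topt`. All parameters are bounded below at 0; `Topt` is bounded to
#' [0, 50] C.
#'
#' @return list of `c(mean, sd)` per parameter.
#' @export
tpc_priors <- function() {
  list(w = c(1, 1), b2 = c(0.1, 0.1), d0 = c(0.1, 0.5), d2 = c(0.3, 0.3),
       Topt = c(27, 8))
}

# Sampled parameterization: with w = b1*exp(b2*Topt),
#   mu(T) = w*exp(b2*(T - Topt)) - d0 - (w*b2/d2)*exp(d2*(T - Topt))
#         = w*A(T; b2, d2, Topt) - d0
# (algebraically identical to tpc_mu at g = 1). The sampler works on
# unconstrained coordinates (log w, log b2, log d0, log d2, logit(Topt/50),
# log sigma) with the Jacobian included, so positivity and the Topt bound
# hold by construction. Used as the full-joint log posterior for the
# independent cross-check sampler; the production fit marginalizes (w, d0).
tpc_log_post <- function(T_obs, y_obs, priors, topt_upper = 50) {
  function(z) {
    w <- exp(z[1]); b2 <- exp(z[2]); d0 <- exp(z[3]); d2 <- exp(z[4])
    Topt <- topt_upper / (1 + exp(-z[5])); sigma <- exp(z[6])
    if (!all(is.finite(c(w, b2, d0, d2, Topt, sigma))) || sigma <= 0) return(-Inf)
    if (b2 >= d2) return(-Inf)   # identifiability: Topt must be a maximum
    dt <- T_obs - Topt
    mhat <- w * exp(b2 * dt) - d0 - (w * b2 / d2) * exp(d2 * dt)
    if (!all(is.finite(mhat))) return(-Inf)
    ll <- sum(dnorm(y_obs, mhat, sigma, log = TRUE))
    lp <- dtnorm_log(w, priors$w[1], priors$w[2]) +
      dtnorm_log(b2, priors$b2[1], priors$b2[2]) +
      dtnorm_log(d0, priors$d0[1], priors$d0[2]) +
      dtnorm_log(d2, priors$d2[1], priors$d2[2], lower = 1e-4) +
      dtnorm_log(Topt, priors$Topt[1], priors$Topt[2], lower = 0, upper = topt_upper) +
      dtnorm_log(sigma, 0, 1)
    jac <- z[1] + z[2] + z[3] + z[4] + z[6] +
      log(Topt * (topt_upper - Topt) / topt_upper)
    ll + lp + jac
  }
}

# Collapsed TPC sampler. The curve is linear in beta = (w, d0) given
# (b2, d2, Topt, sigma): mu = w*A(T) - d0. MH therefore runs on the
# marginal posterior of theta = (log b2, log d2, logit(Topt/50), log sigma)
# with (w, d0) integrated out under their (untruncated) normal priors; each
# proposal carries a draw of w from its conditional normal (kept only when
# positive — w sits far from 0, so this indicator costs nothing) and of d0
# from its *truncated* conditional given w, with the truncation probability
# entering the acceptance ratio. The kernel is exact for the truncated-
# normal priors and stays mobile even when the posterior piles d0 against
# the zero boundary (a cold-adapted, monotone-declining curve does this),
# while removing the w/b2/d0 posterior ridge that defeats plain
# componentwise or random-walk samplers on this model family.
tpc_sample_posterior <- function(T_obs, y_obs, priors, iterations,
                                 n_chains = 4, seed = 1L, topt_upper = 50) {
  n <- length(y_obs)
  b0 <- c(priors$w[1], priors$d0[1])
  B <- diag(c(priors$w[2]^2, priors$d0[2]^2))
  Bi <- diag(1 / c(priors$w[2]^2, priors$d0[2]^2))
  log_det_B <- sum(log(diag(B)))

  marg <- function(th) {
    b2 <- exp(th[1]); d2 <- exp(th[2])
    Topt <- topt_upper * plogis(th[3]); sig <- exp(th[4])
    if (!all(is.finite(c(b2, d2, Topt, sig))) || d2 < 1e-4) return(NULL)
    if (b2 >= d2) return(NULL)   # identifiability: Topt must be a maximum
    dt <- T_obs - Topt
    A <- exp(b2 * dt) - (b2 / d2) * exp(d2 * dt)
    # growth rates are O(1) d^-1: basis values beyond 1e6 can only arise in
    # parameter corners where the marginal-likelihood algebra cancels
    # catastrophically and fabricates density spikes
    if (!all(is.finite(A)) || max(abs(A)) > 1e6) return(NULL)
    X <- cbind(A, -1)
    P <- crossprod(X) / sig^2 + Bi
    Pc <- tryCatch(chol(P), error = function(e) NULL)
    if (is.null(Pc)) return(NULL)
    rhs <- crossprod(X, y_obs) / sig^2 + Bi %*% b0
    mean_beta <- backsolve(Pc, forwardsolve(t(Pc), rhs))
    r <- y_obs - X %*% b0
    quad <- sum(r^2) / sig^2 -
      sum(forwardsolve(t(Pc), crossprod(X, r) / sig^2)^2)
    if (quad < 0) return(NULL)   # r' Sigma^-1 r >= 0; negative = cancellation
    logdet <- n * log(sig^2) + log_det_B + 2 * sum(log(diag(Pc)))
    logm <- -0.5 * (n * log(2 * pi) + logdet + quad)
    lp <- dtnorm_log(b2, priors$b2[1], priors$b2[2]) +
      dtnorm_log(d2, priors$d2[1], priors$d2[2], lower = 1e-4) +
      dtnorm_log(Topt, priors$Topt[1], priors$Topt[2], 0, topt_upper) +
      dtnorm_log(sig, 0, 1)
    jac <- th[1] + th[2] + th[4] + log(Topt * (topt_upper - Topt) / topt_upper)
    if (!is.finite(logm + lp + jac)) return(NULL)
    list(lp = as.numeric(logm + lp + jac), mean = as.numeric(mean_beta),
         cov = chol2inv(Pc))
  }

  # sample z ~ N(0,1) conditioned on z > a (Robert's method in the far tail)
  rtruncnorm_std <- function(a) {
    if (a < 0.5) {
      repeat { z <- rnorm(1); if (z > a) return(z) }
    }
    repeat {
      z <- a + rexp(1, a + sqrt(a^2 + 4) / 2)
      if (runif(1) < exp(-(z - a)^2 / 2)) return(z)
    }
  }
  # draw (w, d0): w from its untruncated conditional (NA when negative),
  # d0 truncated at 0 given w; returns the log truncation probability
  draw_beta <- function(m) {
    s11 <- m$cov[1, 1]; s21 <- m$cov[2, 1]; s22 <- m$cov[2, 2]
    w <- rnorm(1, m$mean[1], sqrt(max(s11, 1e-20)))
    if (w <= 0) return(NULL)
    mu_d <- m$mean[2] + s21 / s11 * (w - m$mean[1])
    sd_d <- sqrt(max(s22 - s21^2 / s11, 1e-20))
    a <- -mu_d / sd_d
    lp0 <- pnorm(a, lower.tail = FALSE, log.p = TRUE)
    if (!is.finite(lp0) || lp0 < -700) return(NULL)
    d0 <- mu_d + sd_d * rtruncnorm_std(a)
    list(w = w, d0 = max(d0, 0), lp0 = lp0)
  }

  means <- tapply(y_obs, T_obs, mean)
  t_best <- as.numeric(names(means)[which.max(means)])
  init1 <- c(log(0.07), log(0.25),
             qlogis(min(max(t_best, 1), topt_upper - 1) / topt_upper),
             log(max(sd(y_obs), 0.05)))
  opt <- tryCatch(
    optim(init1, function(z) { m <- marg(z); if (is.null(m)) 1e10 else -m$lp },
          method = "BFGS", hessian = TRUE, control = list(maxit = 500)),
    error = function(e) NULL)
  if (is.null(opt) || !all(is.finite(opt$par))) {
    opt <- list(par = init1, hessian = diag(100, 4))
  }
  Sigma0 <- tryCatch(solve(opt$hessian + 1e-8 * diag(4)), error = function(e) NULL)
  ok <- !is.null(Sigma0) && all(is.finite(Sigma0)) &&
    all(eigen(Sigma0, symmetric = TRUE, only.values = TRUE)$values > 0)
  if (!ok) Sigma0 <- diag(0.01, 4)

  sc <- 2.38^2 / 4
  burn <- floor(iterations / 2)
  chains <- vector("list", n_chains)
  acc_all <- numeric(n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(derive_seed(seed, "tpc-chain", ch))
    th <- drop(opt$par + 0.3 * (rnorm(4) %*% chol(Sigma0)))
    m <- marg(th)
    if (is.null(m)) { th <- opt$par; m <- marg(th) }
    if (is.null(m)) stop("could not initialize the TPC sampler")
    state <- NULL
    for (k in seq_len(100)) {
      state <- draw_beta(m)
      if (!is.null(state)) break
    }
    if (is.null(state)) {
      state <- list(w = max(m$mean[1], 0.1), d0 = max(m$mean[2], 1e-6), lp0 = 0)
    }
    hist <- matrix(NA_real_, iterations, 6)
    chol_C <- chol(sc * Sigma0 + 1e-10 * diag(4))
    log_s <- 0; n_acc <- 0
    for (i in seq_len(iterations)) {
      thp <- th + exp(log_s) * drop(rnorm(4) %*% chol_C)
      mp <- marg(thp)
      acc <- FALSE
      if (!is.null(mp)) {
        cand <- draw_beta(mp)
        if (!is.null(cand) &&
            log(runif(1)) < mp$lp + cand$lp0 - m$lp - state$lp0) {
          th <- thp; m <- mp; state <- cand; acc <- TRUE; n_acc <- n_acc + 1
        }
      }
      hist[i, ] <- c(th, state$w, state$d0)
      if (i <= burn) {
        log_s <- log_s + (as.numeric(acc) - 0.234) / max(i, 50)^0.6
        if (i >= 500 && i %% 200 == 0) {
          C <- sc * cov(hist[seq(100, i), 1:4, drop = FALSE]) + 1e-10 * diag(4)
          ct <- tryCatch(chol(C), error = function(e) NULL)
          if (!is.null(ct)) chol_C <- ct
        }
      }
    }
    chains[[ch]] <- hist[(burn + 1):iterations, , drop = FALSE]
    acc_all[ch] <- n_acc / iterations
  }
  get <- function(j) sapply(chains, function(h) h[, j])
  raw <- list(logb2 = get(1), logd2 = get(2), zTopt = get(3),
              logsigma = get(4), w = get(5), d0 = get(6))
  draws <- list(w = as.numeric(raw$w),
                b2 = exp(as.numeric(raw$logb2)),
                d0 = as.numeric(raw$d0),
                d2 = exp(as.numeric(raw$logd2)),
                Topt = topt_upper * plogis(as.numeric(raw$zTopt)),
                sigma = exp(as.numeric(raw$logsigma)))
  rhat <- c(w = split_rhat(raw$w), b2 = split_rhat(raw$logb2),
            d0 = split_rhat(raw$d0), d2 = split_rhat(raw$logd2),
            Topt = split_rhat(raw$zTopt), sigma = split_rhat(raw$logsigma))
  list(draws = draws, rhat = rhat, accept = mean(acc_all))
}

#' Fit the double-exponential TPC by posterior sampling
#'
#' Same chain contract as [fit_monod()] (4 chains, burn-in = first half,
#' pooled retained draws, positivity truncation, split-Rhat diagnostic with
#' threshold 1.05). The resource term `g` is fixed at 1 within a resource
#' level: level-specific limitation is absorbed into the birth scale. Derived
#' thermal traits (`Tmax`, `Tmin`, `Tbr`) are computed per retained draw by
#' root finding; draws whose curve never exceeds zero contribute no roots.
#'
#' @param rates data.frame with columns `temperature` and `mu` (one row per
#'   replicate well). Growth must exceed `m_ext` at >= 3 temperatures
#'   (mean over replicates), otherwise the fit is skipped with an error.
#' @param priors list as from [tpc_priors()].
#' @param m_ext external loss rate used by the qualification rule.
#' @param iterations,n_chains,seed,rhat_threshold,keep_draws as in
#'   [fit_monod()].
#' @param max_derived_draws derived-trait root finding is done on at most
#'   this many pooled draws (evenly thinned) to bound compute; medians/CIs of
#'   the primitive parameters always use all pooled draws.
#' @return list of class `tpc_fit`: `summary` (lower/median/upper for b1,
#'   b2, d0, d2, Topt, sigma, Tmax, Tmin, Tbr), `draws`, `derived` (per-draw
#'   Tmax/Tmin/Tbr, NA where undefined), `rhat`, `converged`, `n_obs`.
#' @export
fit_tpc <- function(rates, priors = tpc_priors(), m_ext = 0.1,
                    iterations = 10000, n_chains = 4, seed = 1L,
                    rhat_threshold = 1.05, keep_draws = TRUE,
                    max_derived_draws = 2000) {
  rates <- rates[is.finite(rates$mu) & is.finite(rates$temperature), , drop = FALSE]
  means <- tapply(rates$mu, rates$temperature, mean)
  if (sum(means > m_ext) < 3) {
    stop("growth rate exceeds m_ext at fewer than 3 temperatures; fit skipped")
  }
  res <- tpc_sample_posterior(rates$temperature, rates$mu, priors,
                              iterations = iterations, n_chains = n_chains,
                              seed = seed)
  d <- res$draws
  d$b1 <- d$w * exp(-d$b2 * d$Topt)
  n_draws <- length(d$w)
  use <- if (n_draws > max_derived_draws) {
    unique(round(seq(1, n_draws, length.out = max_derived_draws)))
  } else seq_len(n_draws)
  derived <- t(vapply(use, function(i) {
    dr <- list(b1 = d$b1[i], b2 = d$b2[i], d0 = d$d0[i], d2 = d$d2[i],
               Topt = d$Topt[i])
    lim <- derive_tmax_tmin(dr)
    c(Tmax = lim[["Tmax"]], Tmin = lim[["Tmin"]], Tbr = derive_tbr(dr))
  }, numeric(3)))
  pars <- c("b1", "b2", "d0", "d2", "Topt", "sigma")
  summ <- rbind(
    as.data.frame(t(vapply(d[pars], post_summary, numeric(3)))),
    as.data.frame(t(apply(derived, 2, post_summary))))
  summ$parameter <- c(pars, colnames(derived))
  summ <- summ[, c("parameter", "lower", "median", "upper")]
  rownames(summ) <- NULL
  structure(list(summary = summ,
                 draws = if (keep_draws) d else NULL,
                 derived = as.data.frame(derived),
                 rhat = res$rhat, converged = max(res$rhat) <= rhat_threshold,
                 n_obs = nrow(rates)),
            class = "tpc_fit")
}

#' @export
print.tpc_fit <- function(x, ...) {
  cat(sprintf("TPC fit (%d obs, converged: %s, max Rhat %.3f)\n",
              x$n_obs, x$converged, max(x$rhat)))
  print(x$summary, digits = 4)
  invisible(x)
}

tpc_eval <- function(draw, T_C) {
  tpc_mu(T_C, draw$b1, draw$b2, draw$d0, draw$d2, draw$Topt, g = 1)
}

#' Thermal limits of a TPC draw
#'
#' `Tmax` is the zero crossing of the curve above `Topt` (bracketed in
#' `(Topt, Topt + 100]`), `Tmin` the crossing below (bracketed in
#' `[Topt - 150, Topt)`). Either is `NA` when the curve does not change sign
#' on its bracket; both are `NA` when the curve is non-positive at `Topt`.
#'
#' @param draw list with `b1`, `b2`, `d0`, `d2`, `Topt`.
#' @param tol root tolerance in C (default 1e-8).
#' @return Named numeric `c(Tmax = , Tmin = )`, possibly NA.
#' @export
derive_tmax_tmin <- function(draw, tol = 1e-8) {
  mu_opt <- tpc_eval(draw, draw$Topt)
  if (!is.finite(mu_opt) || mu_opt <= 0) return(c(Tmax = NA_real_, Tmin = NA_real_))
  f <- function(T_C) tpc_eval(draw, T_C)
  root_in <- function(lo, hi) {
    flo <- f(lo); fhi <- f(hi)
    if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) return(NA_real_)
    uniroot(f, c(lo, hi), tol = tol)$root
  }
  c(Tmax = root_in(draw$Topt, draw$Topt + 100),
    Tmin = root_in(draw$Topt - 150, draw$Topt))
}

#' Thermal breadth of a TPC draw
#'
#' Width of the temperature interval over which growth is at least 80% of
#' its value at `Topt`: `Tbr = T_hi - T_lo` where `T_lo`, `T_hi` solve
#' `mu(T) = 0.8 * mu(Topt)` on either side of `Topt`.
#'
#' @param draw list with `b1`, `b2`, `d0`, `d2`, `Topt`.
#' @param level performance fraction defining the breadth (default 0.8).
#' @param tol root tolerance in C (default 1e-6).
#' @return Tbr in C, or NA when the curve is non-positive at `Topt` or a
#'   root is not bracketed within 150 C of `Topt`.
#' @export
derive_tbr <- function(draw, level = 0.8, tol = 1e-6) {
  mu_opt <- tpc_eval(draw, draw$Topt)
  if (!is.finite(mu_opt) || mu_opt <= 0) return(NA_real_)
  target <- level * mu_opt
  f <- function(T_C) tpc_eval(draw, T_C) - target
  root_in <- function(lo, hi) {
    flo <- f(lo); fhi <- f(hi)
    if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) return(NA_real_)
    uniroot(f, c(lo, hi), tol = tol)$root
  }
  t_hi <- root_in(draw$Topt, draw$Topt + 150)
  t_lo <- root_in(draw$Topt - 150, draw$Topt)
  if (is.na(t_hi) || is.na(t_lo)) return(NA_real_)
  t_hi - t_lo
}

#' Flag TPC trait medians outside the credible experimental range
#'
#' Posterior medians are excluded (flagged, never deleted) when they fall
#' beyond the measured design: `Topt` outside [15, 35] C; `Tmax` more than
#' 5 C above the highest measured temperature (> 40 C); `Tmin` more than
#' 15 C below the lowest (< 0 C); `Tbr` wider than the 20 C experimental
#' range. Bounds are inclusive for retention: a median exactly on a bound is
#' kept.
#'
#' @param fit_table data.frame with median columns `Topt`, `Tmax`, `Tmin`,
#'   `Tbr` (NA allowed).
#' @param temp_range measured temperature range, default `c(15, 35)`.
#' @param tmax_margin allowance above the range for `Tmax` (default 5 C).
#' @param tmin_margin allowance below the range for `Tmin` (default 15 C).
#' @return `fit_table` with logical columns `Topt_excluded`, `Tmax_excluded`,
#'   `Tmin_excluded`, `Tbr_excluded` (NA medians flagged excluded).
#' @export
apply_tpc_exclusions <- function(fit_table, temp_range = c(15, 35),
                                 tmax_margin = 5, tmin_margin = 15) {
  lo <- temp_range[1]; hi <- temp_range[2]
  excl <- function(x, bad) ifelse(is.na(x), TRUE, bad)
  fit_table$Topt_excluded <- excl(fit_table$Topt,
                                  fit_table$Topt < lo | fit_table$Topt > hi)
  fit_table$Tmax_excluded <- excl(fit_table$Tmax, fit_table$Tmax > hi + tmax_margin)
  fit_table$Tmin_excluded <- excl(fit_table$Tmin, fit_table$Tmin < lo - tmin_margin)
  fit_table$Tbr_excluded <- excl(fit_table$Tbr, fit_table$Tbr > hi - lo)
  fit_table
}

#' Fit TPCs for every population x resource level of a rate table
#'
#' @param rate_table data.frame with columns `population`, `resource_type`,
#'   `resource_level`, `temperature`, `mu` (optionally `phylum`).
#' @param priors,m_ext,iterations,n_chains,seed,rhat_threshold,keep_draws,max_derived_draws
#'   as in [fit_tpc()]; per-fit seeds derived from `seed` and unit labels.
#' @return list with `fits` (keyed `population|level`) and `table` (one row
#'   per fit: trait medians and CI bounds, convergence, exclusion flags from
#'   [apply_tpc_exclusions()], skip notes).
#' @export
batch_tpc <- function(rate_table, priors = tpc_priors(), m_ext = 0.1,
                      iterations = 10000, n_chains = 4, seed = 1L,
                      rhat_threshold = 1.05, keep_draws = TRUE,
                      max_derived_draws = 2000) {
  resource <- unique(rate_table$resource_type)
  stopifnot(length(resource) == 1)
  units <- unique(rate_table[, c("population", "resource_level"), drop = FALSE])
  fits <- list(); rows <- list()
  for (i in seq_len(nrow(units))) {
    pop <- units$population[i]; lev <- units$resource_level[i]
    d <- rate_table[rate_table$population == pop &
                    rate_table$resource_level == lev, , drop = FALSE]
    fit <- tryCatch(
      fit_tpc(d, priors = priors, m_ext = m_ext, iterations = iterations,
              n_chains = n_chains,
              seed = derive_seed(seed, "tpc", pop, lev, resource),
              rhat_threshold = rhat_threshold, keep_draws = keep_draws,
              max_derived_draws = max_derived_draws),
      error = function(e) e)
    key <- paste(pop, lev, sep = "|")
    meta <- data.frame(
      population = pop, resource_level = lev, resource_type = resource,
      phylum = if ("phylum" %in% names(d)) d$phylum[1] else NA_character_)
    if (inherits(fit, "error")) {
      rows[[key]] <- cbind(meta, data.frame(
        Topt = NA_real_, Tmax = NA_real_, Tmin = NA_real_, Tbr = NA_real_,
        Topt_lower = NA_real_, Topt_upper = NA_real_, converged = NA,
        rhat_max = NA_real_, note = conditionMessage(fit)))
      next
    }
    fits[[key]] <- fit
    med <- setNames(fit$summary$median, fit$summary$parameter)
    to <- fit$summary[fit$summary$parameter == "Topt", ]
    rows[[key]] <- cbind(meta, data.frame(
      Topt = med[["Topt"]], Tmax = med[["Tmax"]], Tmin = med[["Tmin"]],
      Tbr = med[["Tbr"]], Topt_lower = to$lower, Topt_upper = to$upper,
      converged = fit$converged, rhat_max = max(fit$rhat),
      note = NA_character_))
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  table <- apply_tpc_exclusions(table)
  list(fits = fits, table = table)
}
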