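#' Monod growth rate
#'
#' Net specific growth rate at resource amount `R`:
#' `mu = mu_max * R / (Ks + R) - m`, where `mu_max` is the gross maximum
#' specific growth rate (d^-1), `Ks` the half-saturation constant (resource
#' units) and `m` the intrinsic loss rate (d^-1).
#'
#' @param R resource amount, `>= 0` (vectorized).
#' @param mu_max,Ks,m Monod parameters; `Ks > 0`.
#' @return Growth rate(s), d^-1.
#' @export
monod_mu <- function(R, mu_max, Ks, m = 0) {
  if (any(Ks <= 0)) stop("Ks must be positive")
  stopifnot(all(R >= 0))
  mu_max * R / (Ks + R) - m
}

#' Resource affinity
#'
#' Initial slope of the Monod curve, `alpha = mu_max / Ks`: competitive
#' ability at very low resource, decoupled from the asymptote.
#'
#' @param mu_max,Ks Monod parameters; `Ks > 0`.
#' @return alpha, d^-1 per resource unit.
#' @export
affinity <- function(mu_max, Ks) {
  if (any(Ks <= 0)) stop("Ks must be positive")
  mu_max / Ks
}

#' Minimum resource requirement R*
#'
#' The resource level at which net growth exactly balances total losses
#' `m_tot = m + m_ext`: `R* = m_tot * Ks / (mu_max - m_tot)`. Lower R* means
#' better equilibrium competitive ability. When `mu_max <= m_tot` growth can
#' never offset losses and `Inf` is returned as a sentinel.
#'
#' @param mu_max,Ks,m Monod parameters; `Ks > 0`.
#' @param m_ext external, system-specific loss rate (dilution/sinking),
#'   default 0.1 d^-1.
#' @return R*, resource units (vectorized; `Inf` where no positive growth is
#'   possible).
#' @export
r_star <- function(mu_max, Ks, m = 0, m_ext = 0.1) {
  if (any(Ks <= 0)) stop("Ks must be positive")
  m_tot <- m + m_ext
  if (any(m_tot < 0)) stop("m + m_ext must be >= 0")
  out <- m_tot * Ks / (mu_max - m_tot)
  out[mu_max <= m_tot] <- Inf
  out
}

#' Net maximum growth rate
#'
#' `mu_max` corrected for the intrinsic loss rate: `net_mu_max = mu_max - m`.
#' Applied per posterior draw (then summarized), not to summaries.
#'
#' @param mu_max,m Monod parameters.
#' @return d^-1.
#' @export
net_mu_max <- function(mu_max, m) mu_max - m

#' Default Monod priors
#'
#' Truncated-normal (at 0) prior means and sds. `mu_max` (1, 0.9) and `m`
#' (0, 0.7) are shared across resources; `Ks` priors are resource-specific:
#' light (2.5, 0.7), nitrogen (2.5, 0.9), phosphorus (0.001, 0.8).
#'
#' @param resource_type one of `"light"`, `"nitrogen"`, `"phosphorus"`.
#' @return list with elements `mu_max`, `Ks`, `m`, each `c(mean, sd)`.
#' @export
monod_priors <- function(resource_type = c("light", "nitrogen", "phosphorus")) {
  resource_type <- match.arg(resource_type)
  ks <- switch(resource_type,
               light = c(2.5, 0.7), nitrogen = c(2.5, 0.9),
               phosphorus = c(0.001, 0.8))
  list(mu_max = c(1, 0.9), Ks = ks, m = c(0, 0.7))
}

monod_model_string <- "
model {
  for (i in 1:N) {
    mhat[i] <- mu_max * R[i] / (Ks + R[i]) - m
    y[i] ~ dnorm(mhat[i], tau)
  }
  mu_max ~ dnorm(p_mu_max[1], pow(p_mu_max[2], -2)) T(0,)
  Ks ~ dnorm(p_Ks[1], pow(p_Ks[2], -2)) T(1e-09,)
  m ~ dnorm(p_m[1], pow(p_m[2], -2)) T(0,)
  sigma ~ dnorm(0, 1) T(0,)
  tau <- pow(sigma, -2)
}"

#' Fit the Monod equation by posterior sampling
#'
#' Samples (`mu_max`, `Ks`, `m`) with a Gaussian likelihood (half-normal
#' prior, sd 1, on the residual sd), truncated-normal priors bounded below at
#' 0, 4 chains, burn-in = first half of `iterations`, pooled retained draws
#' (20,000 at the default `iterations = 10000`). Derived traits are computed
#' per retained draw: affinity `alpha`, minimum requirement `rstar` (using
#' `m_tot = m + m_ext`), and `net_mu_max`. Replicates enter as independent
#' observations.
#'
#' @param rates data.frame with columns `resource_level` and `mu` (one row
#'   per replicate well); at least 3 distinct resource levels.
#' @param priors list as returned by [monod_priors()].
#' @param m_ext external loss rate used for R* and retention (default 0.1).
#' @param iterations iterations per chain (paper-scale default 10,000;
#'   reduced runs use e.g. 2,000).
#' @param n_chains number of chains (default 4).
#' @param seed integer seed (per-chain RNG seeds are derived from it).
#' @param rhat_threshold convergence flag threshold (default 1.05).
#' @param keep_draws if TRUE (default) the pooled draws are kept on the fit.
#' @return list of class `monod_fit`: `summary` (data.frame, one row per
#'   parameter/derived trait with lower/median/upper), `draws`, `rhat`,
#'   `converged`, `retained` (retention rule from [monod_retention()]),
#'   `m_ext`, `n_obs`.
#' @export
fit_monod <- function(rates, priors = monod_priors("light"), m_ext = 0.1,
                      iterations = 10000, n_chains = 4, seed = 1L,
                      rhat_threshold = 1.05, keep_draws = TRUE) {
  rates <- rates[is.finite(rates$mu) & is.finite(rates$resource_level), , drop = FALSE]
  if (length(unique(rates$resource_level)) < 3) {
    stop("need data at >= 3 distinct resource levels to fit the Monod model")
  }
  data <- list(N = nrow(rates), R = rates$resource_level, y = rates$mu,
               p_mu_max = priors$mu_max, p_Ks = priors$Ks, p_m = priors$m)
  init_fun <- function(ch) {
    list(mu_max = max(max(rates$mu), 0.1) * (1 + 0.1 * ch),
         Ks = max(priors$Ks[1], median(rates$resource_level) / (2 * ch)),
         m = 0.05 * ch, sigma = max(sd(rates$mu), 0.05))
  }
  res <- run_jags(monod_model_string, data,
                  c("mu_max", "Ks", "m", "sigma"),
                  iterations = iterations, n_chains = n_chains, seed = seed,
                  inits = init_fun)
  d <- lapply(res$draws, as.numeric)
  d$alpha <- affinity(d$mu_max, d$Ks)
  d$rstar <- r_star(d$mu_max, d$Ks, d$m, m_ext)
  d$net_mu_max <- net_mu_max(d$mu_max, d$m)
  pars <- c("mu_max", "Ks", "m", "sigma", "alpha", "rstar", "net_mu_max")
  summ <- as.data.frame(t(vapply(d[pars], post_summary, numeric(3))))
  summ$parameter <- pars
  summ <- summ[, c("parameter", "lower", "median", "upper")]
  rownames(summ) <- NULL
  rhat_max <- max(res$rhat)
  structure(list(summary = summ,
                 draws = if (keep_draws) d else NULL,
                 rhat = res$rhat, converged = rhat_max <= rhat_threshold,
                 retained = monod_retention(rates, m_ext),
                 m_ext = m_ext, n_obs = nrow(rates)),
            class = "monod_fit")
}

#' @export
print.monod_fit <- function(x, ...) {
  cat(sprintf("Monod fit (%d obs, retained: %s, converged: %s, max Rhat %.3f)\n",
              x$n_obs, x$retained, x$converged, max(x$rhat)))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Monod retention rule
#'
#' A population x temperature x resource fit enters downstream analyses only
#' if the observed mean growth rate exceeds `m_ext` at three or more resource
#' levels.
#'
#' @param rates data.frame with `resource_level` and `mu`.
#' @param m_ext external loss rate (default 0.1).
#' @return TRUE/FALSE.
#' @export
monod_retention <- function(rates, m_ext = 0.1) {
  means <- tapply(rates$mu, rates$resource_level, mean, na.rm = TRUE)
  sum(means > m_ext, na.rm = TRUE) >= 3
}

#' Fit Monod curves for every population x temperature of a rate table
#'
#' @param rate_table data.frame with columns `population`, `resource_type`,
#'   `resource_level`, `temperature`, `mu` (and optionally `phylum`).
#' @param m_ext,iterations,n_chains,seed,rhat_threshold passed to
#'   [fit_monod()]; per-fit seeds are derived from `seed` and the unit labels.
#' @param priors optional priors list; defaults to the resource-specific
#'   [monod_priors()].
#' @param keep_draws keep pooled posterior draws per fit (needed for the
#'   shape-classification stage).
#' @return list with `fits` (nested list keyed population/temperature) and
#'   `table` (one summary row per fit: medians, CIs, retention, rhat).
#' @export
batch_monod <- function(rate_table, m_ext = 0.1, iterations = 10000,
                        n_chains = 4, seed = 1L, priors = NULL,
                        rhat_threshold = 1.05, keep_draws = TRUE) {
  resource <- unique(rate_table$resource_type)
  stopifnot(length(resource) == 1)
  pr <- priors %||% monod_priors(resource)
  units <- unique(rate_table[, c("population", "temperature"), drop = FALSE])
  fits <- list(); rows <- list()
  for (i in seq_len(nrow(units))) {
    pop <- units$population[i]; temp <- units$temperature[i]
    d <- rate_table[rate_table$population == pop &
                    rate_table$temperature == temp, , drop = FALSE]
    fit <- tryCatch(
      fit_monod(d, priors = pr, m_ext = m_ext, iterations = iterations,
                n_chains = n_chains,
                seed = derive_seed(seed, "monod", pop, temp, resource),
                rhat_threshold = rhat_threshold, keep_draws = keep_draws),
      error = function(e) e)
    key <- paste(pop, temp, sep = "|")
    if (inherits(fit, "error")) {
      rows[[key]] <- data.frame(
        population = pop, temperature = temp, resource_type = resource,
        phylum = if ("phylum" %in% names(d)) d$phylum[1] else NA_character_,
        mu_max = NA_real_, Ks = NA_real_, m = NA_real_, alpha = NA_real_,
        rstar = NA_real_, net_mu_max = NA_real_, rstar_lower = NA_real_,
        rstar_upper = NA_real_, retained = FALSE, converged = NA,
        rhat_max = NA_real_, note = conditionMessage(fit))
      next
    }
    fits[[key]] <- fit
    med <- setNames(fit$summary$median, fit$summary$parameter)
    rs <- fit$summary[fit$summary$parameter == "rstar", ]
    rows[[key]] <- data.frame(
      population = pop, temperature = temp, resource_type = resource,
      phylum = if ("phylum" %in% names(d)) d$phylum[1] else NA_character_,
      mu_max = med[["mu_max"]], Ks = med[["Ks"]], m = med[["m"]],
      alpha = med[["alpha"]], rstar = med[["rstar"]],
      net_mu_max = med[["net_mu_max"]],
      rstar_lower = rs$lower, rstar_upper = rs$upper,
      retained = fit$retained, converged = fit$converged,
      rhat_max = max(fit$rhat), note = NA_character_)
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  list(fits = fits, table = table)
}
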