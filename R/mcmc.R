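#' Split-chain potential scale reduction factor (Rhat)
#'
#' Each chain is split in half and the usual between/within variance ratio is
#' computed over the resulting 2m half-chains. Values near 1 indicate
#' convergence; fits with Rhat above 1.05 are flagged downstream.
#'
#' @param draws matrix of posterior draws, iterations x chains.
#' @return Numeric Rhat (NA if fewer than 4 draws per chain).
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, var)
  W <- mean(vars)
  B <- half * var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# Run a JAGS model with the package's chain contract: n_chains chains,
# adapt+burn over the first half of `iterations`, sample the second half.
# Per-chain RNG seeds are derived from `seed` so reruns are bit-stable.
# Returns list(draws = named list of iterations x chains matrices, rhat).
run_jags <- function(model_string, data, params, iterations = 10000,
                     n_chains = 4, seed = 1L, inits = NULL) {
  stopifnot(iterations >= 4)
  burn <- floor(iterations / 2)
  keep <- iterations - burn
  init_list <- lapply(seq_len(n_chains), function(ch) {
    ii <- list(.RNG.name = "base::Mersenne-Twister",
               .RNG.seed = derive_seed(seed, "chain", ch))
    if (!is.null(inits)) ii <- c(inits(ch), ii)
    ii
  })
  model <- rjags::jags.model(textConnection(model_string), data = data,
                             inits = init_list, n.chains = n_chains,
                             n.adapt = 0, quiet = TRUE)
  # adaptation plus burn-in over the first half of the iterations
  adapt_n <- min(1000, burn)
  invisible(rjags::adapt(model, adapt_n, end.adaptation = TRUE, progress.bar = "none"))
  if (burn > adapt_n) update(model, burn - adapt_n, progress.bar = "none")
  samp <- rjags::coda.samples(model, params, n.iter = keep, progress.bar = "none")
  draws <- lapply(params, function(p)
    sapply(samp, function(ch) as.numeric(ch[, p])))
  names(draws) <- params
  rhat <- vapply(draws, split_rhat, 0)
  list(draws = draws, rhat = rhat)
}

post_summary <- function(x, probs = c(0.025, 0.5, 0.975)) {
  x <- x[is.finite(x)]
  if (!length(x)) return(c(lower = NA_real_, median = NA_real_, upper = NA_real_))
  q <- unname(quantile(x, probs))
  c(lower = q[1], median = q[2], upper = q[3])
}

#' Adaptive Metropolis sampler
#'
#' Random-walk Metropolis with a full multivariate-normal proposal whose
#' covariance is adapted to the chain history during burn-in (scaled by
#' 2.38^2/d) and frozen afterwards. Used where univariate samplers mix
#' poorly along correlated posterior ridges. Runs `n_chains` chains with
#' per-chain seeds derived from `seed`; the first half of `iterations` is
#' burn-in, the second half is retained.
#'
#' @param log_post function(theta) -> log posterior density (unnormalized),
#'   on the (unconstrained) sampling scale; must return `-Inf` outside the
#'   support.
#' @param init function(chain) -> numeric start vector for a chain.
#' @param iterations iterations per chain.
#' @param n_chains number of chains (default 4).
#' @param seed integer seed.
#' @param init_step initial proposal sd (isotropic), default 0.1.
#' @return list: `draws` (named list of iterations/2 x chains matrices, one
#'   per parameter), `rhat` (per parameter), `accept` (mean acceptance rate).
#' @export
adaptive_metropolis <- function(log_post, init, iterations = 10000,
                                n_chains = 4, seed = 1L, init_step = 0.1) {
  stopifnot(iterations >= 20)
  burn <- floor(iterations / 2)
  d <- length(init(1))
  sc <- 2.38^2 / d
  eps <- 1e-8 * diag(d)

  # Laplace initialization: posterior mode and curvature give the starting
  # proposal covariance and chain starting points.
  opt <- tryCatch(
    optim(init(1), function(z) -log_post(z), method = "BFGS",
          hessian = TRUE, control = list(maxit = 500)),
    error = function(e) NULL)
  if (is.null(opt) || !all(is.finite(opt$par))) {
    opt <- list(par = init(1), hessian = diag(1 / init_step^2, d))
  }
  Sigma0 <- tryCatch(solve(opt$hessian + eps), error = function(e) NULL)
  ok <- !is.null(Sigma0) && all(is.finite(Sigma0)) &&
    all(eigen(Sigma0, symmetric = TRUE, only.values = TRUE)$values > 0)
  if (!ok) Sigma0 <- diag(init_step^2, d)

  chains <- vector("list", n_chains)
  acc_all <- numeric(n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(derive_seed(seed, "am-chain", ch))
    L0 <- chol(Sigma0)
    theta <- drop(opt$par + 0.3 * (rnorm(d) %*% L0))
    names(theta) <- names(init(1))
    lp <- log_post(theta)
    tries <- 0
    while (!is.finite(lp) && tries < 20) {  # fall back toward the mode
      theta <- drop(opt$par + 0.01 * (rnorm(d) %*% L0))
      lp <- log_post(theta); tries <- tries + 1
    }
    if (!is.finite(lp)) { theta <- opt$par; lp <- log_post(theta) }
    if (!is.finite(lp)) stop("could not find a starting value with finite posterior density")
    hist <- matrix(NA_real_, iterations, d)
    chol_C <- chol(sc * Sigma0 + eps)
    log_s <- 0
    n_acc <- 0
    for (i in seq_len(iterations)) {
      prop <- theta + exp(log_s) * drop(rnorm(d) %*% chol_C)
      lp_prop <- log_post(prop)
      acc <- is.finite(lp_prop) && log(runif(1)) < lp_prop - lp
      if (acc) { theta <- prop; lp <- lp_prop; n_acc <- n_acc + 1 }
      hist[i, ] <- theta
      if (i <= burn) {
        # Robbins-Monro step-size tuning toward 23.4% acceptance
        log_s <- log_s + (as.numeric(acc) - 0.234) / max(i, 50)^0.6
        # periodic covariance re-estimation from the full chain history
        # (Haario-style growing window)
        if (i >= 500 && i %% 200 == 0) {
          C <- sc * cov(hist[seq(100, i), , drop = FALSE]) + eps
          ch_try <- tryCatch(chol(C), error = function(e) NULL)
          if (!is.null(ch_try)) chol_C <- ch_try
        }
      }
    }
    chains[[ch]] <- hist[(burn + 1):iterations, , drop = FALSE]
    acc_all[ch] <- n_acc / iterations
  }
  draws <- lapply(seq_len(d), function(j)
    sapply(chains, function(h) h[, j]))
  names(draws) <- names(init(1)) %||% paste0("theta", seq_len(d))
  rhat <- vapply(draws, split_rhat, 0)
  list(draws = draws, rhat = rhat, accept = mean(acc_all))
}

# log density of a normal truncated below at `lower` (normalizing constant
# dropped where it does not depend on parameters being sampled)
dtnorm_log <- function(x, mean, sd, lower = 0, upper = Inf) {
  ifelse(x < lower | x > upper, -Inf, dnorm(x, mean, sd, log = TRUE))
}
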