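#' Default resource levels for the resource-limitation experiments
#'
#' Eight levels per resource. Light is photosynthetically active radiation in
#' umol photons m^-2 s^-1; nitrogen (NaNO3) and phosphorus (K2HPO4) are in
#' umol L^-1.
#'
#' @format Named list of three numeric vectors of length 8.
#' @export
default_resource_levels <- function() {
  list(
    light      = c(1, 8, 18, 40, 70, 108, 164, 240),
    nitrogen   = c(0.5, 1, 2, 5, 20, 80, 400, 800),
    phosphorus = c(0.01, 0.1, 0.5, 1.5, 5, 10, 35, 50)
  )
}

#' Background (non-manipulated) conditions of the experiments
#'
#' When a resource is not the manipulated one it is held replete: light at
#' 110 umol photons m^-2 s^-1, nitrogen at 800 umol L^-1, phosphorus at
#' 50 umol L^-1.
#'
#' @return Named numeric vector.
#' @export
background_conditions <- function() {
  c(light = 110, nitrogen = 800, phosphorus = 50)
}

default_temperatures <- function() c(15, 20, 24, 28, 32, 35)

#' Build the factorial design grid for one resource experiment
#'
#' Enumerates populations x temperatures x resource levels x replicates for
#' one resource type. With defaults this is 6 temperatures x 8 levels = 48
#' unique treatments per population, and 19 x 6 x 8 x 4 = 3648 wells.
#'
#' @param resource_type one of `"light"`, `"nitrogen"`, `"phosphorus"`.
#' @param n_populations number of populations (default 19).
#' @param overrides optional named list replacing any of `resource_levels`
#'   (strictly increasing, positive), `temperatures` (strictly increasing),
#'   `replicates` (count), `populations` (character ids), `phyla` (character,
#'   recycled over populations).
#' @return An object of class `design_grid`: a data.frame with columns
#'   `population`, `phylum`, `resource_type`, `resource_level`,
#'   `temperature`, `replicate`, plus attributes `resource_levels`,
#'   `temperatures`, and `background` (the constant non-manipulated
#'   conditions).
#' @export
make_design <- function(resource_type = c("light", "nitrogen", "phosphorus"),
                        n_populations = 19, overrides = list()) {
  resource_type <- match.arg(resource_type)
  stopifnot(n_populations >= 1)

  levels <- overrides$resource_levels %||% default_resource_levels()[[resource_type]]
  temps <- overrides$temperatures %||% default_temperatures()
  reps <- overrides$replicates %||% 4L
  if (any(diff(levels) <= 0) || any(levels <= 0)) {
    stop("resource levels must be positive and strictly increasing")
  }
  if (any(diff(temps) <= 0)) stop("temperatures must be strictly increasing")

  pops <- overrides$populations %||% sprintf("pop%02d", seq_len(n_populations))
  phyla_pool <- c("Chlorophyta", "Bacillariophyta", "Cyanobacteria")
  phyla <- overrides$phyla %||% rep_len(phyla_pool, length(pops))

  grid <- expand.grid(
    replicate = seq_len(reps),
    resource_level = levels,
    temperature = temps,
    population = pops,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid$phylum <- phyla[match(grid$population, pops)]
  grid$resource_type <- resource_type
  grid <- grid[, c("population", "phylum", "resource_type", "resource_level",
                   "temperature", "replicate")]
  background <- background_conditions()
  background <- background[setdiff(names(background), resource_type)]
  structure(grid,
            class = c("design_grid", "data.frame"),
            resource_levels = levels, temperatures = temps,
            background = background)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw ground-truth population traits for the simulator
#'
#' Each population x resource type gets a parameter set for the
#' birth-minus-death thermal performance surface coupled to Monod resource
#' dependence: birth `b1 * exp(b2 * T) * R / (Ks + R)` minus death
#' `d0 + (b1 * b2 / d2) * exp((b2 - d2) * Topt) * exp(d2 * T)`. The death
#' coefficient is parameterized through `Topt` so the replete curve peaks at
#' `Topt` exactly; `d2 > b2` guarantees a hump shape. Ranges span the trait
#' ranges observed in temperate lake phytoplankton (Topt roughly 18-33 C,
#' peak net growth 0.6-1.8 d^-1, half-saturation constants spanning orders
#' of magnitude and resource-specific).
#'
#' @param populations character vector of population ids.
#' @param resource_type resource the traits apply to (sets the Ks range).
#' @param seed integer seed.
#' @return data.frame with one row per population: `b1`, `b2`, `d0`, `d2`,
#'   `Topt_true`, `Ks_true`, `K_cap`, `lag_days`.
#' @export
sample_population_traits <- function(populations,
                                     resource_type = c("light", "nitrogen", "phosphorus"),
                                     seed = 1L) {
  resource_type <- match.arg(resource_type)
  n <- length(populations)
  set.seed(derive_seed(seed, "traits", resource_type))
  Topt <- runif(n, 18, 33)
  b2 <- runif(n, 0.05, 0.12)
  d2 <- b2 + runif(n, 0.08, 0.25)
  d0 <- runif(n, 0.05, 0.2)
  mu_peak <- runif(n, 0.6, 1.8)    # replete net growth rate at Topt
  # solve b1 from mu(Topt) = b1*exp(b2*Topt)*(1 - b2/d2) - d0 = mu_peak
  b1 <- (mu_peak + d0) / (exp(b2 * Topt) * (1 - b2 / d2))
  Ks <- switch(resource_type,
               light = runif(n, 1, 30),
               nitrogen = 10^runif(n, -1, 1.3),
               phosphorus = 10^runif(n, -2.5, 0))
  data.frame(
    population = populations, resource_type = resource_type,
    b1 = b1, b2 = b2, d0 = d0, d2 = d2, Topt_true = Topt,
    Ks_true = Ks, K_cap = runif(n, 300, 900),
    lag_days = sample(c(0, 0.5, 1), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Ground-truth growth rate surface
#'
#' Net specific growth rate (d^-1) at temperature `T_C` and resource amount
#' `R` for one trait set:
#' `b1*exp(b2*T)*g(R) - [d0 + (b1*b2/d2)*exp((b2-d2)*Topt)*exp(d2*T)]`
#' with Monod resource coupling `g(R) = R / (Ks + R)`. Negative rates are
#' valid (death exceeds birth).
#'
#' @param traits one-row data.frame (or list) with `b1`, `b2`, `d0`, `d2`,
#'   `Topt_true`, `Ks_true`.
#' @param T_C temperature in Celsius (vectorized).
#' @param R resource amount, `>= 0` (vectorized).
#' @return Numeric growth rate(s), d^-1.
#' @export
true_growth_rate <- function(traits, T_C, R) {
  stopifnot(all(R >= 0))
  g <- R / (traits$Ks_true + R)
  birth <- traits$b1 * exp(traits$b2 * T_C) * g
  death <- traits$d0 + (traits$b1 * traits$b2 / traits$d2) *
    exp((traits$b2 - traits$d2) * traits$Topt_true) * exp(traits$d2 * T_C)
  birth - death
}

#' Simulate a per-well growth-rate table (fast path)
#'
#' Bypasses time-series simulation: one observed rate per design row equal to
#' the true surface plus additive Gaussian noise.
#'
#' @param grid a `design_grid`.
#' @param traits trait table from [sample_population_traits()] for the same
#'   populations and resource type.
#' @param noise_sd additive Gaussian noise sd on rates (d^-1).
#' @param seed integer seed.
#' @return data.frame: grid columns plus `mu` (observed) and `mu_true`.
#' @export
simulate_rate_table <- function(grid, traits, noise_sd = 0.05, seed = 1L) {
  stopifnot(noise_sd >= 0)
  idx <- match(grid$population, traits$population)
  if (anyNA(idx)) stop("traits missing for some populations in the grid")
  tr <- traits[idx, , drop = FALSE]
  mu_true <- true_growth_rate(tr, grid$temperature, grid$resource_level)
  set.seed(derive_seed(seed, "rates", grid$resource_type[1]))
  out <- as.data.frame(grid)
  out$mu_true <- mu_true
  out$mu <- mu_true + rnorm(nrow(out), 0, noise_sd)
  out
}

#' Default fluorescence reading schedule
#'
#' Two readings per day (9 h apart) over days 0-4, then one daily reading on
#' days 5-7: 13 time points in days since inoculation.
#'
#' @return Numeric vector of length 13.
#' @export
default_schedule <- function() {
  sort(c(0:4, 0:4 + 9 / 24, 5, 6, 7))
}

#' Simulate RFU time series for every well of a design
#'
#' Relative fluorescence is flat at the inoculum for `lag_days`, then grows
#' exponentially at the well's true rate until capped at the population's
#' carrying capacity `K_cap`; negative rates decay exponentially.
#' Multiplicative lognormal measurement noise with coefficient of variation
#' `noise_cv` (mean 1); readings are floored at 0.1 RFU so logs stay
#' defined.
#'
#' @param grid a `design_grid`.
#' @param traits trait table from [sample_population_traits()].
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed integer seed.
#' @param schedule reading times in days (default [default_schedule()]).
#' @param inoculum starting density, RFU (default 20).
#' @return Long data.frame: grid columns plus `day` and `rfu`, with the
#'   per-well true rate in column `mu_true`.
#' @export
simulate_timeseries <- function(grid, traits, noise_cv = 0.05, seed = 1L,
                                schedule = default_schedule(), inoculum = 20) {
  stopifnot(noise_cv >= 0, all(diff(schedule) > 0), schedule[1] == 0)
  idx <- match(grid$population, traits$population)
  if (anyNA(idx)) stop("traits missing for some populations in the grid")
  tr <- traits[idx, , drop = FALSE]
  rate <- true_growth_rate(tr, grid$temperature, grid$resource_level)
  n_t <- length(schedule)
  set.seed(derive_seed(seed, "timeseries", grid$resource_type[1]))

  sdlog <- sqrt(log(1 + noise_cv^2))
  out <- grid[rep(seq_len(nrow(grid)), each = n_t), , drop = FALSE]
  out$day <- rep(schedule, nrow(grid))
  rfu <- numeric(nrow(out))
  for (i in seq_len(nrow(grid))) {
    te <- pmax(schedule - tr$lag_days[i], 0)   # time in exponential phase
    r <- rate[i]
    n <- pmin(inoculum * exp(r * te), tr$K_cap[i])
    rfu[(i - 1) * n_t + seq_len(n_t)] <- n
  }
  if (noise_cv > 0) {
    rfu <- rfu * exp(rnorm(length(rfu), -sdlog^2 / 2, sdlog))
  }
  out$rfu <- pmax(rfu, 0.1)
  out$mu_true <- rep(rate, each = n_t)
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

#' Simulate the full three-resource study
#'
#' Convenience wrapper producing the complete default design (3 resources x
#' 19 populations x 6 temperatures x 8 levels x 4 replicates = 10,944 wells)
#' as either a rate table or time series, with its ground-truth trait tables.
#'
#' @param n_populations number of populations (default 19).
#' @param seed integer seed.
#' @param noise_sd rate-table noise sd (used when `what = "rates"`).
#' @param noise_cv time-series noise cv (used when `what = "timeseries"`).
#' @param what `"rates"` or `"timeseries"`.
#' @param resources resource experiments to simulate (default all three).
#' @return list with `data` (row-bound across resources) and `traits`.
#' @export
simulate_study <- function(n_populations = 19, seed = 1L, noise_sd = 0.05,
                           noise_cv = 0.05, what = c("rates", "timeseries"),
                           resources = c("light", "nitrogen", "phosphorus")) {
  what <- match.arg(what)
  resources <- match.arg(resources, several.ok = TRUE)
  pops <- sprintf("pop%02d", seq_len(n_populations))
  traits <- do.call(rbind, lapply(resources, function(rt)
    sample_population_traits(pops, rt, seed = seed)))
  data <- do.call(rbind, lapply(resources, function(rt) {
    grid <- make_design(rt, n_populations = n_populations)
    tr <- traits[traits$resource_type == rt, ]
    if (what == "rates") {
      simulate_rate_table(grid, tr, noise_sd = noise_sd, seed = seed)
    } else {
      simulate_timeseries(grid, tr, noise_cv = noise_cv, seed = seed)
    }
  }))
  rownames(data) <- NULL
  list(data = data, traits = traits)
}
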