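#' Six per-population trait summaries
#'
#' Condenses the fitted Monod and TPC trait surfaces into one row per
#' population x resource type:
#' \enumerate{
#'   \item `scaled_logRstar_min` — log of the lowest R* across temperatures,
#'     z-scored within resource type (so the three resources' different units
#'     and magnitudes are comparable);
#'   \item `TRstar_min` — the experimental temperature of that minimum (C);
#'   \item `net_mu_max_max` — the largest net maximum growth rate across
#'     temperatures (d^-1);
#'   \item `Topt_max` — the highest thermal optimum across resource levels (C);
#'   \item `Tmax_max` — the highest thermal maximum across resource levels (C);
#'   \item `Tbr_max` — the widest thermal breadth across resource levels (C).
#' }
#' Only retained Monod fits and non-excluded TPC medians contribute.
#' Populations missing a trait entirely get NA there (listwise deletion
#' happens per downstream analysis); the dropped/used counts are attached as
#' attribute `log` on the result.
#'
#' @param monod_table per-fit summary table from [batch_monod()] (columns
#'   `population`, `phylum`, `resource_type`, `temperature`, `rstar`,
#'   `net_mu_max`, `retained`), possibly row-bound across resources.
#' @param tpc_table per-fit summary table from [batch_tpc()] (columns
#'   `population`, `resource_type`, `resource_level`, `Topt`, `Tmax`, `Tbr`
#'   and their `_excluded` flags), possibly row-bound across resources.
#' @return data.frame, one row per population x resource type.
#' @export
summarize_traits <- function(monod_table, tpc_table) {
  if (nrow(monod_table) == 0 && nrow(tpc_table) == 0) stop("empty input")
  mk <- unique(rbind(monod_table[, c("population", "resource_type")],
                     tpc_table[, c("population", "resource_type")]))
  dropped <- list()
  rows <- lapply(seq_len(nrow(mk)), function(i) {
    pop <- mk$population[i]; rt <- mk$resource_type[i]
    m <- monod_table[monod_table$population == pop &
                     monod_table$resource_type == rt &
                     monod_table$retained %in% TRUE &
                     is.finite(monod_table$rstar), , drop = FALSE]
    tp <- tpc_table[tpc_table$population == pop &
                    tpc_table$resource_type == rt, , drop = FALSE]
    phylum <- c(m$phylum, tp$phylum)[1]
    out <- data.frame(population = pop, resource_type = rt,
                      phylum = if (is.null(phylum)) NA_character_ else phylum,
                      logRstar_min = NA_real_, TRstar_min = NA_real_,
                      net_mu_max_max = NA_real_, Topt_max = NA_real_,
                      Tmax_max = NA_real_, Tbr_max = NA_real_)
    if (nrow(m)) {
      j <- which.min(m$rstar)
      out$logRstar_min <- log(m$rstar[j])
      out$TRstar_min <- m$temperature[j]
      out$net_mu_max_max <- max(m$net_mu_max, na.rm = TRUE)
    }
    topt <- tp$Topt[!tp$Topt_excluded %in% TRUE]
    tmax <- tp$Tmax[!tp$Tmax_excluded %in% TRUE]
    tbr <- tp$Tbr[!tp$Tbr_excluded %in% TRUE]
    if (any(is.finite(topt))) out$Topt_max <- max(topt, na.rm = TRUE)
    if (any(is.finite(tmax))) out$Tmax_max <- max(tmax, na.rm = TRUE)
    if (any(is.finite(tbr))) out$Tbr_max <- max(tbr, na.rm = TRUE)
    out
  })
  out <- do.call(rbind, rows)
  # z-score log R*_min within resource type
  out$scaled_logRstar_min <- NA_real_
  for (rt in unique(out$resource_type)) {
    sel <- out$resource_type == rt & is.finite(out$logRstar_min)
    v <- out$logRstar_min[sel]
    if (length(v) >= 2 && sd(v) > 0) {
      out$scaled_logRstar_min[sel] <- (v - mean(v)) / sd(v)
    } else {
      dropped[[rt]] <- sprintf(
        "resource %s: %d value(s), cannot standardize log R*_min", rt, length(v))
    }
  }
  attr(out, "log") <- dropped
  out
}

trait_columns <- c("scaled_logRstar_min", "TRstar_min", "net_mu_max_max",
                   "Topt_max", "Tmax_max", "Tbr_max")

#' PCA of the trait summary table
#'
#' Principal components of the six summary traits, centered and scaled.
#' Rows with any missing trait are dropped (count logged as attribute
#' `n_dropped`).
#'
#' @param summary_table from [summarize_traits()].
#' @param columns trait columns to use (default the six summaries).
#' @return list of class `trait_pca`: `var_explained` (percent per axis,
#'   sums to 100), `loadings`, `scores`, `meta` (population/resource/phylum
#'   of retained rows), `n_dropped`.
#' @export
run_pca <- function(summary_table, columns = trait_columns) {
  X <- summary_table[, columns, drop = FALSE]
  keep <- stats::complete.cases(X) &
    apply(X, 1, function(r) all(is.finite(as.numeric(r))))
  if (sum(keep) < 3) stop("need >= 3 complete rows for PCA")
  X <- as.matrix(X[keep, , drop = FALSE])
  if (any(apply(X, 2, sd) == 0)) stop("constant trait column; PCA undefined")
  p <- prcomp(X, center = TRUE, scale. = TRUE)
  ve <- 100 * p$sdev^2 / sum(p$sdev^2)
  structure(list(var_explained = ve, loadings = p$rotation, scores = p$x,
                 meta = summary_table[keep, setdiff(names(summary_table), columns),
                                      drop = FALSE],
                 n_dropped = sum(!keep)),
            class = "trait_pca")
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of whether between-group distances exceed
#' within-group distances; `R` near 0 means no group structure, near 1 means
#' strong separation. Euclidean distances by default (pass a `dist` to
#' override). Implemented on vegan's ANOSIM with a fixed permutation seed.
#'
#' @param x numeric matrix (e.g. PCA scores) or a `dist`.
#' @param grouping factor-coercible group labels (>= 2 groups, each >= 2
#'   members).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutations.
#' @return list: `R` statistic, `p` permutation p-value.
#' @export
anosim_groups <- function(x, grouping, n_perm = 999, seed = 1L) {
  grouping <- as.factor(grouping)
  if (nlevels(droplevels(grouping)) < 2) stop("need >= 2 groups")
  if (any(table(grouping) < 2)) stop("every group needs >= 2 members")
  d <- if (inherits(x, "dist")) x else dist(as.matrix(x))
  set.seed(derive_seed(seed, "anosim"))
  fit <- vegan::anosim(d, grouping, permutations = n_perm)
  list(R = unname(fit$statistic), p = fit$signif)
}

#' Welch's ANOVA with Games-Howell post hoc comparisons
#'
#' Welch's unequal-variance one-way ANOVA, followed by all pairwise
#' Games-Howell comparisons: unequal-variance t statistics with
#' Welch-Satterthwaite degrees of freedom, calibrated against the
#' studentized-range distribution.
#'
#' @param values numeric response.
#' @param grouping group labels (>= 2 groups with >= 2 values each).
#' @return list: `welch` (statistic, df, p.value), `pairs` (data.frame:
#'   group1, group2, diff, t, df, p).
#' @export
welch_games_howell <- function(values, grouping) {
  grouping <- as.factor(grouping)
  keep <- is.finite(values) & !is.na(grouping)
  values <- values[keep]; grouping <- droplevels(grouping[keep])
  k <- nlevels(grouping)
  if (k < 2) stop("need >= 2 groups")
  ns <- tapply(values, grouping, length)
  if (any(ns < 2)) stop("every group needs >= 2 values")
  w <- oneway.test(values ~ grouping, var.equal = FALSE)
  ms <- tapply(values, grouping, mean)
  vs <- tapply(values, grouping, var)
  se2 <- vs / ns
  combs <- utils::combn(levels(grouping), 2)
  pairs <- lapply(seq_len(ncol(combs)), function(j) {
    g1 <- combs[1, j]; g2 <- combs[2, j]
    sed <- sqrt(se2[g1] + se2[g2])
    tstat <- (ms[g1] - ms[g2]) / sed
    df <- (se2[g1] + se2[g2])^2 /
      (se2[g1]^2 / (ns[g1] - 1) + se2[g2]^2 / (ns[g2] - 1))
    p <- ptukey(abs(tstat) * sqrt(2), nmeans = k, df = df, lower.tail = FALSE)
    data.frame(group1 = g1, group2 = g2, diff = unname(ms[g1] - ms[g2]),
               t = unname(tstat), df = unname(df), p = unname(p))
  })
  list(welch = list(statistic = unname(w$statistic),
                    df = unname(w$parameter), p.value = w$p.value),
       pairs = do.call(rbind, pairs))
}

#' Kendall rank-correlation matrix
#'
#' Pairwise Kendall's tau-b (tie-corrected) with two-sided p-values over the
#' trait summary columns; pairwise-complete observations. Constant columns
#' yield NA.
#'
#' @param summary_table data.frame.
#' @param columns columns to correlate (default the six trait summaries).
#' @return list: `tau` and `p` (symmetric matrices), `n` (pairwise sample
#'   sizes).
#' @export
kendall_matrix <- function(summary_table, columns = trait_columns) {
  X <- summary_table[, columns, drop = FALSE]
  if (nrow(X) < 3) stop("need >= 3 rows")
  k <- length(columns)
  tau <- p <- n <- matrix(NA_real_, k, k, dimnames = list(columns, columns))
  diag(tau) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ok <- is.finite(X[[i]]) & is.finite(X[[j]])
      n[i, j] <- n[j, i] <- sum(ok)
      if (sum(ok) < 3 || sd(X[[i]][ok]) == 0 || sd(X[[j]][ok]) == 0) next
      ct <- suppressWarnings(
        cor.test(X[[i]][ok], X[[j]][ok], method = "kendall"))
      tau[i, j] <- tau[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  diag(n) <- colSums(!is.na(X))
  list(tau = tau, p = p, n = n)
}

#' Test whether a trait-trait slope differs among resources
#'
#' Least-squares fit of `y ~ x * resource`; the F test of the interaction
#' block asks whether the x-slope depends on resource identity. When it does
#' not (p above `alpha`), the pooled regression across resources is reported,
#' supporting a single cross-resource relationship.
#'
#' @param y,x numeric trait vectors.
#' @param resource resource labels (>= 2 types).
#' @param alpha pooling threshold (default 0.05).
#' @return list: `p_interaction`, `pooled` (lm of y ~ x when pooling is
#'   supported, else NULL), `fit` (the full interaction lm).
#' @export
interaction_test <- function(y, x, resource, alpha = 0.05) {
  resource <- as.factor(resource)
  keep <- is.finite(y) & is.finite(x) & !is.na(resource)
  y <- y[keep]; x <- x[keep]; resource <- droplevels(resource[keep])
  if (nlevels(resource) < 2) stop("need >= 2 resource types")
  full <- lm(y ~ x * resource)
  reduced <- lm(y ~ x + resource)
  a <- anova(reduced, full)
  p_int <- a$`Pr(>F)`[2]
  # exact (noiseless) fits leave only rounding error in both models; the F
  # ratio is then numerically meaningless — decide from the interaction SS
  ss_int <- a$`Sum of Sq`[2]
  scale_ss <- max(sum((y - mean(y))^2), .Machine$double.eps)
  if (ss_int <= 1e-10 * scale_ss) {
    p_int <- 1
  } else if (is.na(p_int)) {
    p_int <- 0
  }
  pooled <- if (is.na(p_int) || p_int > alpha) lm(y ~ x) else NULL
  list(p_interaction = p_int, pooled = pooled, fit = full)
}

#' Constrained-resampling null for correlations with Tmax_max
#'
#' Traits such as `TRstar_min` or `Topt_max` can only occur at temperatures
#' below a population's thermal maximum, so even random trait placement
#' induces a positive correlation with `Tmax_max` when thermal maxima vary.
#' This null draws, per simulation, one surrogate trait value per population
#' uniformly between its `lower` bound and its `Tmax_max`, computes Kendall's
#' tau against `Tmax_max`, and locates the observed tau within that null
#' distribution.
#'
#' @param tmax_max per-population thermal maxima (the trait correlated
#'   against).
#' @param lower per-population lower sampling bounds (recycled; default the
#'   15 C experimental minimum).
#' @param upper per-population upper sampling bounds (recycled); defaults to
#'   `tmax_max`, which is the constrained null. Setting a common upper bound
#'   removes the constraint and the null centers on zero.
#' @param observed_tau observed Kendall tau to score (optional).
#' @param n_sims number of simulations (>= 100).
#' @param seed integer seed.
#' @return list: `null_tau` (length `n_sims`), `observed_tau`, `percentile`
#'   (fraction of null values at or below the observed; NA when no observed
#'   tau given).
#' @export
null_tau_distribution <- function(tmax_max, lower = 15, upper = NULL,
                                  observed_tau = NULL, n_sims = 1000,
                                  seed = 1L) {
  stopifnot(n_sims >= 100)
  n <- length(tmax_max)
  lower <- rep_len(lower, n)
  upper <- if (is.null(upper)) tmax_max else rep_len(upper, n)
  if (any(lower >= upper)) {
    stop("every lower bound must be below its upper bound")
  }
  set.seed(derive_seed(seed, "null-tau"))
  null_tau <- vapply(seq_len(n_sims), function(s) {
    surrogate <- runif(n, lower, upper)
    suppressWarnings(cor(surrogate, tmax_max, method = "kendall"))
  }, 0)
  # mid-rank percentile: tau is discrete at small n, so ties with the null
  # are split rather than counted fully (keeps the statistic calibrated)
  percentile <- if (is.null(observed_tau)) NA_real_ else
    mean(null_tau < observed_tau) + 0.5 * mean(null_tau == observed_tau)
  list(null_tau = null_tau, observed_tau = observed_tau %||% NA_real_,
       percentile = percentile)
}
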