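#' Bundle posterior draws of one trait along one gradient
#'
#' A gradient series holds, for one population and one trait, a matrix of
#' posterior draws per gradient value (temperature for Monod-derived traits,
#' resource level for TPC-derived traits — log10-transform nutrient levels
#' before construction) plus the error family used when curves are fitted
#' through it.
#'
#' @param x gradient values (length G, >= 2, not all equal).
#' @param draws numeric matrix, draws x G: column j holds posterior draws of
#'   the trait at gradient value `x[j]`.
#' @param family `"gaussian"` or `"gamma"`; gamma (log link) is for traits
#'   bounded below by zero (R*, affinity) and requires all draws > 0.
#' @return Object of class `gradient_series`.
#' @export
gradient_series <- function(x, draws, family = c("gaussian", "gamma")) {
  family <- match.arg(family)
  draws <- as.matrix(draws)
  stopifnot(length(x) == ncol(draws), length(x) >= 2)
  if (length(unique(x)) < 2) stop("gradient values are all equal")
  if (any(diff(order(x)) < 0)) {
    o <- order(x); x <- x[o]; draws <- draws[, o, drop = FALSE]
  }
  if (family == "gamma" && any(draws <= 0, na.rm = TRUE)) {
    stop("gamma family requires strictly positive trait draws")
  }
  structure(list(x = x, draws = draws, family = family),
            class = "gradient_series")
}

smooth_edf <- function(fit) {
  sm <- fit$smooth[[1]]
  sum(fit$edf[sm$first.para:sm$last.para])
}

#' Posterior-bootstrap ensemble of trait-gradient curves
#'
#' For each bootstrap iteration one posterior draw is sampled independently
#' per gradient value, and a penalized cubic regression spline (GAM; basis
#' dimension `min(k, G - 1)`, smoothing by GCV) is fitted through those G
#' points under the series' family. With three or fewer gradient values the
#' pathway is forced to a straight-line model. The smooth-term effective
#' degrees of freedom (EDF; a straight line gives 1) is recorded per fit, and
#' the ensemble mean curve with a 95% band is computed on a fine prediction
#' grid.
#'
#' @param series a [gradient_series()].
#' @param n_boot ensemble size (study-scale default 5000; tests use less).
#' @param seed integer seed (draw subsampling is reproducible).
#' @param k maximum spline basis dimension (default 10, capped at G - 1).
#' @param n_grid prediction grid size (default 200).
#' @return Object of class `shape_ensemble`: `x`, `family`, `pathway`
#'   (`"GAM"` or `"LM"`), `grid`, `pred` (n_boot x n_grid matrix), `edf`
#'   (per fit; NA on the LM pathway), `slopes` (LM pathway), `indices`
#'   (n_boot x G draw indices, reused by linear refits), `mean_curve`
#'   (data.frame grid/mean/lower/upper).
#' @export
bootstrap_fits <- function(series, n_boot = 5000, seed = 1L, k = 10,
                           n_grid = 200) {
  stopifnot(inherits(series, "gradient_series"), n_boot >= 1)
  x <- series$x
  G <- length(x)
  n_draws <- nrow(series$draws)
  set.seed(derive_seed(seed, "bootstrap", n_boot))
  indices <- matrix(sample.int(n_draws, n_boot * G, replace = TRUE), n_boot, G)
  grid <- seq(min(x), max(x), length.out = n_grid)
  fam <- if (series$family == "gamma") Gamma(link = "log") else gaussian()
  pathway <- if (G <= 3) "LM" else "GAM"

  pred <- matrix(NA_real_, n_boot, n_grid)
  edf <- rep(NA_real_, n_boot)
  slopes <- rep(NA_real_, n_boot)
  kk <- min(k, G - 1)
  for (b in seq_len(n_boot)) {
    y <- series$draws[cbind(indices[b, ], seq_len(G))]
    if (pathway == "GAM") {
      # step-failure warnings are routine for GCV on G-point gamma fits
      fit <- try(suppressWarnings(
        mgcv::gam(y ~ s(x, k = kk, bs = "cr"), family = fam,
                  method = "GCV.Cp", data = data.frame(x = x, y = y))),
        silent = TRUE)
      if (inherits(fit, "try-error")) next
      edf[b] <- smooth_edf(fit)
      pred[b, ] <- as.numeric(
        predict(fit, newdata = data.frame(x = grid), type = "response"))
      if (edf[b] > 1.01) {
        # GCV is undefined on exact fits: when a straight line already
        # explains the points to rounding error, the fit is linear
        lf <- lm.fit(cbind(1, x), if (series$family == "gamma") log(y) else y)
        tss <- sum((lf$residuals + lf$fitted.values -
                      mean(lf$fitted.values + lf$residuals))^2)
        if (sum(lf$residuals^2) <= max(1e-10 * tss, 1e-20)) edf[b] <- 1
      }
    } else {
      fit <- try(suppressWarnings(
        glm(y ~ x, family = fam, data = data.frame(x = x, y = y))),
        silent = TRUE)
      if (inherits(fit, "try-error")) next
      slopes[b] <- coef(fit)[["x"]]
      pred[b, ] <- as.numeric(
        predict(fit, newdata = data.frame(x = grid), type = "response"))
    }
  }
  ok <- rowSums(is.na(pred)) < n_grid
  mean_curve <- data.frame(
    grid = grid,
    mean = colMeans(pred[ok, , drop = FALSE]),
    lower = apply(pred[ok, , drop = FALSE], 2, quantile, 0.025),
    upper = apply(pred[ok, , drop = FALSE], 2, quantile, 0.975))
  structure(list(x = x, family = series$family, pathway = pathway,
                 grid = grid, pred = pred, edf = edf, slopes = slopes,
                 indices = indices, draws = series$draws,
                 mean_curve = mean_curve, n_ok = sum(ok)),
            class = "shape_ensemble")
}

# classify one predicted curve by the sign pattern of its first derivative
# on the grid; a crossing must persist for >= `persist` grid steps on both
# sides. Returns list(shape, critical) with shape in
# {"U-shaped","hump-shaped","increasing","decreasing","flat"}.
curve_shape <- function(grid, pred, persist = 2) {
  d1 <- diff(pred)
  s <- sign(d1)
  s[s == 0] <- NA
  runs <- rle(as.vector(s))
  ends <- cumsum(runs$lengths)
  good <- which(!is.na(runs$values) & runs$lengths >= persist)
  if (!length(good)) return(list(shape = "flat", critical = NA_real_))
  vals <- runs$values[good]
  dedup <- c(TRUE, diff(vals) != 0)
  vals <- vals[dedup]
  good <- good[dedup]
  if (length(vals) == 1) {
    return(list(shape = if (vals == 1) "increasing" else "decreasing",
                critical = NA_real_))
  }
  # the first persistent sign change decides the shape; the critical point
  # is where the first persistent run ends
  cross_at <- grid[min(ends[good[1]] + 1, length(grid))]
  shape <- if (vals[1] == -1) "U-shaped" else "hump-shaped"
  list(shape = shape, critical = cross_at)
}

#' Classify the shape of a trait-gradient relationship
#'
#' Applies the linearity gate and probability rules to a bootstrap ensemble:
#' when at least `linearity_gate` (default 80%) of fits have smooth EDF at or
#' below `edf_threshold` (default 1.6), straight lines are refitted to the
#' same bootstrap samples and the label is `increasing`/`decreasing` by slope
#' sign when one sign reaches `lm_threshold` (default 70%). Otherwise each
#' GAM's first derivative is scanned on the prediction grid: a persistent
#' negative-to-positive crossing marks a U shape, positive-to-negative a hump,
#' no crossing a monotonic trend; the modal shape wins when its frequency
#' reaches `gam_threshold` (default 60%). Anything below threshold is
#' `uncertain`.
#'
#' @param ensemble a `shape_ensemble` from [bootstrap_fits()].
#' @param edf_threshold smooth-EDF value at or below which a fit counts as
#'   linear.
#' @param linearity_gate fraction of linear fits that switches to the LM
#'   pathway.
#' @param gam_threshold,lm_threshold modal-probability thresholds.
#' @return Object of class `shape_verdict`: `label`, `probability`,
#'   `pathway`, `frac_linear`, `shape_freq` (named frequencies), `critical`
#'   (mean critical-point location of the winning curved shape, or NA),
#'   `mean_curve`.
#' @export
classify_shape <- function(ensemble, edf_threshold = 1.6,
                           linearity_gate = 0.8, gam_threshold = 0.6,
                           lm_threshold = 0.7) {
  stopifnot(inherits(ensemble, "shape_ensemble"))
  n_boot <- nrow(ensemble$pred)
  frac_linear <- if (ensemble$pathway == "LM") 1 else
    mean(ensemble$edf <= edf_threshold, na.rm = TRUE)
  lm_path <- ensemble$pathway == "LM" || frac_linear >= linearity_gate

  if (lm_path) {
    slopes <- ensemble$slopes
    if (ensemble$pathway == "GAM") {
      # linear refit to the same bootstrap samples (same draw indices)
      fam <- if (ensemble$family == "gamma") Gamma(link = "log") else gaussian()
      G <- length(ensemble$x)
      slopes <- vapply(seq_len(n_boot), function(b) {
        y <- ensemble$draws[cbind(ensemble$indices[b, ], seq_len(G))]
        fit <- try(suppressWarnings(
          glm(y ~ x, family = fam,
              data = data.frame(x = ensemble$x, y = y))), silent = TRUE)
        if (inherits(fit, "try-error")) NA_real_ else coef(fit)[["x"]]
      }, 0)
    }
    p_up <- mean(slopes > 0, na.rm = TRUE)
    p_dn <- mean(slopes < 0, na.rm = TRUE)
    freq <- c("increasing" = p_up, "decreasing" = p_dn)
    winner <- names(freq)[which.max(freq)]
    prob <- max(freq)
    label <- if (prob >= lm_threshold) winner else "uncertain"
    return(structure(list(label = label, probability = prob, pathway = "LM",
                          frac_linear = frac_linear, shape_freq = freq,
                          critical = NA_real_,
                          mean_curve = ensemble$mean_curve),
                     class = "shape_verdict"))
  }

  shapes <- character(n_boot)
  crits <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    if (all(is.na(ensemble$pred[b, ]))) { shapes[b] <- NA_character_; next }
    cs <- curve_shape(ensemble$grid, ensemble$pred[b, ])
    shapes[b] <- if (cs$shape == "flat") "increasing" else cs$shape
    crits[b] <- cs$critical
  }
  lev <- c("U-shaped", "hump-shaped", "increasing", "decreasing")
  freq <- table(factor(shapes, levels = lev)) / sum(!is.na(shapes))
  freq <- setNames(as.numeric(freq), lev)
  winner <- lev[which.max(freq)]
  prob <- max(freq)
  label <- if (prob >= gam_threshold) winner else "uncertain"
  critical <- if (label %in% c("U-shaped", "hump-shaped")) {
    mean(crits[shapes == label], na.rm = TRUE)
  } else NA_real_
  structure(list(label = label, probability = prob, pathway = "GAM",
                 frac_linear = frac_linear, shape_freq = freq,
                 critical = critical, mean_curve = ensemble$mean_curve),
            class = "shape_verdict")
}

#' @export
print.shape_verdict <- function(x, ...) {
  cat(sprintf("Shape: %s (probability %.2f, pathway %s, %.0f%% linear fits)\n",
              x$label, x$probability, x$pathway, 100 * x$frac_linear))
  if (!is.na(x$critical)) cat(sprintf("  critical point near %.2f\n", x$critical))
  invisible(x)
}

#' Mean-species trait-gradient curve
#'
#' Fits one unweighted curve to the across-population means of the median
#' trait values per gradient value, applying the same EDF-gated linear-refit
#' rule and derivative-based shape call as the per-population ensembles.
#'
#' @param med_matrix matrix populations x gradient values of posterior
#'   medians (>= 2 populations).
#' @param x gradient values (length = ncol(med_matrix)).
#' @param family `"gaussian"` or `"gamma"`.
#' @param edf_threshold smooth-EDF linearity rule (default 1.6).
#' @param k maximum basis dimension.
#' @return list of class `mean_species_curve`: `label`, `pathway`, `slope`
#'   (LM pathway), `edf`, `critical`, `curve` (data.frame grid/mean).
#' @export
mean_species_curve <- function(med_matrix, x, family = c("gaussian", "gamma"),
                               edf_threshold = 1.6, k = 10) {
  family <- match.arg(family)
  med_matrix <- as.matrix(med_matrix)
  if (nrow(med_matrix) < 2) {
    stop("mean-species curve needs medians from at least 2 populations")
  }
  stopifnot(ncol(med_matrix) == length(x))
  y <- colMeans(med_matrix, na.rm = TRUE)
  fam <- if (family == "gamma") Gamma(link = "log") else gaussian()
  grid <- seq(min(x), max(x), length.out = 200)
  G <- length(x)
  if (G <= 3) {
    fit <- glm(y ~ x, family = fam, data = data.frame(x = x, y = y))
    slope <- coef(fit)[["x"]]
    return(structure(list(
      label = if (slope > 0) "increasing" else "decreasing", pathway = "LM",
      slope = slope, edf = NA_real_, critical = NA_real_,
      curve = data.frame(grid = grid,
                         mean = predict(fit, data.frame(x = grid),
                                        type = "response"))),
      class = "mean_species_curve"))
  }
  gfit <- suppressWarnings(
    mgcv::gam(y ~ s(x, k = min(k, G - 1), bs = "cr"), family = fam,
              method = "GCV.Cp", data = data.frame(x = x, y = y)))
  edf <- smooth_edf(gfit)
  if (edf > 1.01) {
    # GCV degenerates when a line fits to rounding error (see bootstrap_fits)
    lf <- lm.fit(cbind(1, x), if (family == "gamma") log(y) else y)
    tss <- sum((lf$fitted.values + lf$residuals -
                  mean(lf$fitted.values + lf$residuals))^2)
    if (sum(lf$residuals^2) <= max(1e-10 * tss, 1e-20)) edf <- 1
  }
  if (edf <= edf_threshold) {
    fit <- glm(y ~ x, family = fam, data = data.frame(x = x, y = y))
    slope <- coef(fit)[["x"]]
    return(structure(list(
      label = if (slope > 0) "increasing" else "decreasing", pathway = "LM",
      slope = slope, edf = edf, critical = NA_real_,
      curve = data.frame(grid = grid,
                         mean = predict(fit, data.frame(x = grid),
                                        type = "response"))),
      class = "mean_species_curve"))
  }
  pred <- as.numeric(predict(gfit, data.frame(x = grid), type = "response"))
  cs <- curve_shape(grid, pred)
  label <- if (cs$shape == "flat") "increasing" else cs$shape
  structure(list(label = label, pathway = "GAM", slope = NA_real_, edf = edf,
                 critical = cs$critical,
                 curve = data.frame(grid = grid, mean = pred)),
            class = "mean_species_curve")
}

#' Shape-classify every population x trait of a posterior-draw table
#'
#' Convenience driver for pipeline runs: takes a list of per-unit posterior
#' draw matrices (as produced by [batch_monod()]/[batch_tpc()] fits keyed by
#' population), builds the gradient series and returns one verdict row per
#' population x trait.
#'
#' @param draw_list named list: for each population, a list with `x`
#'   (gradient values) and `draws` (draws x gradient matrix) per trait name.
#' @param family_map named character: error family per trait.
#' @param n_boot,seed,edf_threshold,linearity_gate,gam_threshold,lm_threshold
#'   passed through.
#' @return data.frame: population, trait, label, probability, pathway,
#'   frac_linear, critical.
#' @export
batch_shapes <- function(draw_list, family_map, n_boot = 500, seed = 1L,
                         edf_threshold = 1.6, linearity_gate = 0.8,
                         gam_threshold = 0.6, lm_threshold = 0.7) {
  rows <- list()
  for (pop in names(draw_list)) {
    for (trait in names(draw_list[[pop]])) {
      unit <- draw_list[[pop]][[trait]]
      fam <- family_map[[trait]] %||% "gaussian"
      verdict <- tryCatch({
        ser <- gradient_series(unit$x, unit$draws, family = fam)
        ens <- bootstrap_fits(ser, n_boot = n_boot,
                              seed = derive_seed(seed, "shapes", pop, trait))
        classify_shape(ens, edf_threshold = edf_threshold,
                       linearity_gate = linearity_gate,
                       gam_threshold = gam_threshold,
                       lm_threshold = lm_threshold)
      }, error = function(e) e)
      rows[[paste(pop, trait)]] <- if (inherits(verdict, "error")) {
        data.frame(population = pop, trait = trait, label = NA_character_,
                   probability = NA_real_, pathway = NA_character_,
                   frac_linear = NA_real_, critical = NA_real_,
                   note = conditionMessage(verdict))
      } else {
        data.frame(population = pop, trait = trait, label = verdict$label,
                   probability = verdict$probability,
                   pathway = verdict$pathway,
                   frac_linear = verdict$frac_linear,
                   critical = verdict$critical, note = NA_character_)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
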