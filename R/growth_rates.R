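#' Estimate an exponential growth rate from one RFU time series
#'
#' Fits ln(RFU) against time under four candidate mean structures and picks
#' the best by an information criterion:
#' \itemize{
#'   \item `linear`: a single straight line;
#'   \item `lag`: flat until a lag breakpoint, then a line (continuous);
#'   \item `saturating`: a line that goes flat after a saturation breakpoint;
#'   \item `lag+saturating`: flat, line, flat.
#' }
#' Breakpoints are profiled over the observed time points (least squares for
#' each candidate breakpoint placement, conditional on which the model is
#' linear in its remaining parameters). The reported `mu` is the slope of the
#' exponential segment, in d^-1. Ties in the criterion are broken toward the
#' model with fewer parameters.
#'
#' @param day numeric times in days, strictly increasing.
#' @param rfu positive fluorescence readings, same length (values <= 0 are
#'   floored at 0.1 and flagged).
#' @param min_points minimum observations in the exponential segment
#'   (default 3).
#' @param criterion `"AIC"` (default) or `"AICc"`.
#' @return list of class `growth_rate_estimate`: `mu`, `intercept`, `model`,
#'   `breakpoints` (named, possibly empty), `n_points_used` (points in the
#'   exponential segment), `criterion`, `ic` (criterion value of the chosen
#'   model), `r_squared` (of the exponential segment), `floored` (TRUE if any
#'   reading was floored).
#' @export
estimate_growth_rate <- function(day, rfu, min_points = 3, criterion = c("AIC", "AICc")) {
  criterion <- match.arg(criterion)
  stopifnot(length(day) == length(rfu), min_points >= 3)
  if (length(day) < 4) stop("need at least 4 observations")
  if (any(diff(day) <= 0)) stop("times must be strictly increasing")
  floored <- any(rfu <= 0)
  y <- log(pmax(rfu, 0.1))
  n <- length(y)

  ic_value <- function(rss, k) {
    # k mean parameters + 1 for the residual sd; Gaussian profile likelihood
    kk <- k + 1
    base <- n * log(max(rss, 0) / n) + 2 * kk
    if (criterion == "AICc") {
      if (n - kk - 1 <= 0) return(Inf)
      base <- base + 2 * kk * (kk + 1) / (n - kk - 1)
    }
    base
  }
  # design matrices: all candidates are linear in (a, b) given breakpoints.
  # lag model:      y = a + b * pmax(t - t_lag, 0)
  # saturating:     y = a + b * pmin(t, t_sat)
  # lag+saturating: y = a + b * pmax(pmin(t, t_sat) - t_lag, 0)
  fit_piece <- function(z) {
    X <- cbind(1, z)
    f <- lm.fit(X, y)
    rss <- sum(f$residuals^2)
    list(a = f$coefficients[1], b = f$coefficients[2], rss = rss)
  }
  seg_count <- function(t_lag, t_sat) sum(day >= t_lag & day <= t_sat)

  cands <- list()
  f <- fit_piece(day)
  cands[["linear"]] <- list(model = "linear", mu = f$b, a = f$a, rss = f$rss,
                            k = 2, bp = c(), n_seg = n)
  interior <- day[-c(1, n)]
  best_of <- function(fits) fits[[which.min(vapply(fits, `[[`, 0, "rss"))]]
  lag_fits <- lapply(interior[vapply(interior, function(tl) seg_count(tl, Inf), 0) >= min_points],
                     function(tl) {
                       f <- fit_piece(pmax(day - tl, 0))
                       list(model = "lag", mu = f$b, a = f$a, rss = f$rss, k = 3,
                            bp = c(t_lag = tl), n_seg = seg_count(tl, Inf))
                     })
  if (length(lag_fits)) cands[["lag"]] <- best_of(lag_fits)
  sat_fits <- lapply(interior[vapply(interior, function(ts) seg_count(-Inf, ts), 0) >= min_points],
                     function(ts) {
                       f <- fit_piece(pmin(day, ts))
                       list(model = "saturating", mu = f$b, a = f$a, rss = f$rss, k = 3,
                            bp = c(t_sat = ts), n_seg = seg_count(-Inf, ts))
                     })
  if (length(sat_fits)) cands[["saturating"]] <- best_of(sat_fits)
  pairs <- expand.grid(t_lag = interior, t_sat = interior)
  pairs <- pairs[pairs$t_lag < pairs$t_sat, , drop = FALSE]
  pairs <- pairs[mapply(seg_count, pairs$t_lag, pairs$t_sat) >= min_points, , drop = FALSE]
  if (nrow(pairs)) {
    ls_fits <- lapply(seq_len(nrow(pairs)), function(i) {
      tl <- pairs$t_lag[i]; ts <- pairs$t_sat[i]
      f <- fit_piece(pmax(pmin(day, ts) - tl, 0))
      list(model = "lag+saturating", mu = f$b, a = f$a, rss = f$rss, k = 4,
           bp = c(t_lag = tl, t_sat = ts), n_seg = seg_count(tl, ts))
    })
    cands[["lag+saturating"]] <- best_of(ls_fits)
  }

  ics <- vapply(cands, function(cc) ic_value(cc$rss, cc$k), 0)
  ks <- vapply(cands, `[[`, 0, "k")
  # order by (criterion, parameter count): ties go to the simpler model
  pick <- order(ics, ks)[1]
  ch <- cands[[pick]]

  seg <- if (ch$model == "linear") rep(TRUE, n) else {
    tl <- if ("t_lag" %in% names(ch$bp)) ch$bp[["t_lag"]] else -Inf
    ts <- if ("t_sat" %in% names(ch$bp)) ch$bp[["t_sat"]] else Inf
    day >= tl & day <= ts
  }
  ys <- y[seg]
  r2 <- if (sum(seg) >= 3 && var(ys) > 0) {
    fit <- lm.fit(cbind(1, day[seg]), ys)
    1 - sum(fit$residuals^2) / sum((ys - mean(ys))^2)
  } else NA_real_
  structure(list(mu = unname(ch$mu), intercept = unname(ch$a), model = ch$model,
                 breakpoints = ch$bp, n_points_used = ch$n_seg,
                 criterion = criterion, ic = unname(ics[pick]),
                 r_squared = r2, floored = floored),
            class = "growth_rate_estimate")
}

#' @export
print.growth_rate_estimate <- function(x, ...) {
  cat(sprintf("Growth rate estimate: mu = %.4f d^-1 (model: %s, %d points, %s = %.2f)\n",
              x$mu, x$model, x$n_points_used, x$criterion, x$ic))
  invisible(x)
}

#' Estimate growth rates for every well of a long time-series table
#'
#' Groups the table by (population, resource_type, resource_level,
#' temperature, replicate) and estimates one rate per well. Wells that fail
#' (too few points, missing readings) are emitted with `mu = NA` and the
#' failure reason, never dropped silently.
#'
#' @param table long data.frame with columns `population`, `resource_type`,
#'   `resource_level`, `temperature`, `replicate`, `day`, `rfu` (a `phylum`
#'   column is carried through when present).
#' @param min_points,criterion passed to [estimate_growth_rate()].
#' @return data.frame: one row per well with `mu`, `model`, `n_points_used`,
#'   `r_squared`, `note` (NA when fine).
#' @export
batch_growth_rates <- function(table, min_points = 3, criterion = "AIC") {
  need <- c("population", "resource_type", "resource_level", "temperature",
            "replicate", "day", "rfu")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols)) {
    stop("input table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(table) == 0) {
    out <- table[0, setdiff(need, c("day", "rfu")), drop = FALSE]
    out$mu <- numeric(0); out$model <- character(0)
    out$n_points_used <- integer(0); out$r_squared <- numeric(0)
    out$note <- character(0)
    return(out)
  }
  keys <- c("population", "resource_type", "resource_level", "temperature", "replicate")
  has_phylum <- "phylum" %in% names(table)
  idx <- split(seq_len(nrow(table)),
               interaction(table[keys], drop = TRUE, lex.order = TRUE))
  rows <- lapply(idx, function(ii) {
    d <- table[ii, , drop = FALSE]
    d <- d[order(d$day), , drop = FALSE]
    meta <- d[1, c(keys, if (has_phylum) "phylum"), drop = FALSE]
    ok <- is.finite(d$day) & is.finite(d$rfu)
    est <- tryCatch(
      estimate_growth_rate(d$day[ok], d$rfu[ok], min_points = min_points,
                           criterion = criterion),
      error = function(e) e)
    if (inherits(est, "error")) {
      cbind(meta, data.frame(mu = NA_real_, model = NA_character_,
                             n_points_used = NA_integer_, r_squared = NA_real_,
                             note = conditionMessage(est)))
    } else {
      note <- if (!all(ok)) "dropped non-finite readings"
              else if (est$floored) "readings floored at 0.1 RFU"
              else NA_character_
      cbind(meta, data.frame(mu = est$mu, model = est$model,
                             n_points_used = est$n_points_used,
                             r_squared = est$r_squared, note = note))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
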