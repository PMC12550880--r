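#' Default pipeline configuration
#'
#' All thresholds and sampler settings of the full workflow in one nested
#' list: the external loss rate `m_ext` (0.1 d^-1), the EDF linearity
#' threshold (1.6), the 80% linearity gate, the 60% (GAM) and 70% (LM) shape
#' probability thresholds, the TPC exclusion bounds, sampler settings
#' (4 chains, 10,000 iterations, burn-in = first half) and the bootstrap
#' size (5000). `reduced = TRUE` shrinks sampler and bootstrap sizes for
#' fast smoke runs without touching any scientific constant.
#'
#' @param seed master seed.
#' @param reduced use reduced sampler/bootstrap sizes.
#' @return Nested configuration list (class `pipeline_config`).
#' @export
default_config <- function(seed = 1L, reduced = FALSE) {
  structure(list(
    version = 1L,
    seed = as.integer(seed),
    stages = list(simulate = TRUE, growth = TRUE, monod = TRUE, tpc = TRUE,
                  shapes = TRUE, associate = TRUE),
    design = list(n_populations = 19L, replicates = 4L,
                  resources = c("light", "nitrogen", "phosphorus")),
    simulate = list(noise_sd = 0.05, noise_cv = 0.05, use_timeseries = FALSE),
    sampler = list(chains = 4L,
                   iterations = if (reduced) 2000L else 10000L,
                   burn_fraction = 0.5),
    thresholds = list(m_ext = 0.1, edf = 1.6, linearity_gate = 0.8,
                      gam_shape = 0.6, lm_shape = 0.7, rhat = 1.05,
                      temp_range = c(15, 35), tmax_margin = 5,
                      tmin_margin = 15),
    shapes = list(n_boot = if (reduced) 200L else 5000L),
    associations = list(n_perm = 999L, n_sims = 1000L)
  ), class = c("pipeline_config", "list"))
}

#' Read / write a pipeline configuration
#'
#' YAML round trip; unknown keys are rejected so typos fail loudly.
#'
#' @param path file path.
#' @rdname pipeline_config_io
#' @return `read_config` the configuration list; `write_config` the path,
#'   invisibly.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  template <- default_config()
  extra <- setdiff(names(cfg), names(template))
  if (length(extra)) stop("unknown config keys: ", paste(extra, collapse = ", "))
  out <- utils::modifyList(unclass(template), cfg)
  # yaml scalarizes length-1 vectors; restore required vector fields
  out$thresholds$temp_range <- as.numeric(out$thresholds$temp_range)
  class(out) <- c("pipeline_config", "list")
  validate_config(out)
  out
}

#' @param config configuration list.
#' @rdname pipeline_config_io
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

validate_config <- function(config) {
  th <- config$thresholds
  stopifnot(th$m_ext >= 0,
            th$linearity_gate > 0, th$linearity_gate <= 1,
            th$gam_shape > 0, th$gam_shape <= 1,
            th$lm_shape > 0, th$lm_shape <= 1,
            th$edf > 0, config$sampler$chains >= 2,
            config$sampler$iterations >= 20)
  invisible(config)
}

rate_table_columns <- c("population", "phylum", "resource_type",
                        "resource_level", "temperature", "replicate", "mu")

#' Read / write a growth-rate table
#'
#' CSV interchange with schema-by-name validation and lossless (17
#' significant digit) float serialization.
#'
#' @param path CSV path.
#' @rdname rate_table_io
#' @return `read_rate_table` the validated data.frame (documented column
#'   order); `write_rate_table` the path, invisibly.
#' @export
read_rate_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(rate_table_columns, names(tab))
  if (length(missing_cols)) {
    stop("rate table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  unknown <- setdiff(names(tab), rate_table_columns)
  if (length(unknown)) {
    stop("rate table has unknown column(s): ", paste(unknown, collapse = ", "))
  }
  num_cols <- c("resource_level", "temperature", "replicate", "mu")
  for (cc in num_cols) {
    if (!is.numeric(tab[[cc]])) {
      stop("column '", cc, "' must be numeric")
    }
  }
  tab[, rate_table_columns]
}

#' @param table rate table data.frame.
#' @rdname rate_table_io
#' @export
write_rate_table <- function(table, path) {
  missing_cols <- setdiff(rate_table_columns, names(table))
  if (length(missing_cols)) {
    stop("rate table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- table[, rate_table_columns]
  for (cc in names(out)) {
    if (is.numeric(out[[cc]])) out[[cc]] <- sprintf("%.17g", out[[cc]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

config_hash <- function(config) {
  derive_seed(0L, paste(deparse(unclass(config)), collapse = ""))
}

#' Run the full trait-inference pipeline
#'
#' Executes simulate -> growth rates -> Monod fits -> TPC fits -> shape
#' classification -> trait associations for every configured resource,
#' writing one CSV per stage plus a JSON manifest (config hash, seed, stage
#' row counts) into `outdir`. Reruns with the same config are byte-identical.
#'
#' @param config a [default_config()]-style list.
#' @param outdir output directory (created if needed).
#' @param rate_table optional pre-computed rate table (skips simulation; the
#'   simulate stage must then be disabled or the table is ignored).
#' @return Invisibly, a list with the stage outputs (`rates`, `monod`,
#'   `tpc`, `shapes`, `summary`, `associations`, `manifest`).
#' @export
run_pipeline <- function(config = default_config(), outdir, rate_table = NULL) {
  validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  th <- config$thresholds
  counts <- list()

  if (!config$stages$simulate && is.null(rate_table)) {
    stop("simulate stage disabled and no input rate table supplied")
  }
  if (config$stages$simulate) {
    sim <- simulate_study(n_populations = config$design$n_populations,
                          seed = seed, noise_sd = config$simulate$noise_sd,
                          noise_cv = config$simulate$noise_cv,
                          what = if (config$simulate$use_timeseries)
                            "timeseries" else "rates",
                          resources = config$design$resources)
    if (config$simulate$use_timeseries && config$stages$growth) {
      rate_table <- batch_growth_rates(sim$data)
    } else if (!config$simulate$use_timeseries) {
      rate_table <- sim$data
    }
    truth_path <- file.path(outdir, "true_traits.json")
    jsonlite::write_json(sim$traits, truth_path, digits = NA, dataframe = "rows")
  }
  rate_table$phylum <- rate_table$phylum %||% NA_character_
  write_rate_table(rate_table, file.path(outdir, "rates.csv"))
  counts$rates <- nrow(rate_table)

  monod_tab <- NULL; tpc_tab <- NULL
  monod_fits <- list(); tpc_fits <- list()
  for (rt in intersect(config$design$resources, unique(rate_table$resource_type))) {
    sub <- rate_table[rate_table$resource_type == rt, , drop = FALSE]
    if (config$stages$monod) {
      bm <- batch_monod(sub, m_ext = th$m_ext,
                        iterations = config$sampler$iterations,
                        n_chains = config$sampler$chains, seed = seed,
                        rhat_threshold = th$rhat)
      monod_tab <- rbind(monod_tab, bm$table)
      monod_fits[[rt]] <- bm$fits
    }
    if (config$stages$tpc) {
      bt <- batch_tpc(sub, m_ext = th$m_ext,
                      iterations = config$sampler$iterations,
                      n_chains = config$sampler$chains, seed = seed,
                      rhat_threshold = th$rhat)
      tpc_tab <- rbind(tpc_tab, bt$table)
      tpc_fits[[rt]] <- bt$fits
    }
  }
  if (!is.null(monod_tab)) {
    utils::write.csv(monod_tab, file.path(outdir, "monod_traits.csv"),
                     row.names = FALSE)
    counts$monod <- nrow(monod_tab)
  }
  if (!is.null(tpc_tab)) {
    utils::write.csv(tpc_tab, file.path(outdir, "tpc_traits.csv"),
                     row.names = FALSE)
    counts$tpc <- nrow(tpc_tab)
  }

  shapes_tab <- NULL
  if (config$stages$shapes && length(monod_fits)) {
    shapes_tab <- do.call(rbind, lapply(names(monod_fits), function(rt) {
      dl <- monod_draw_list(monod_fits[[rt]])
      if (!length(dl)) return(NULL)
      st <- batch_shapes(dl,
                         family_map = c(rstar = "gamma", alpha = "gamma",
                                        net_mu_max = "gaussian"),
                         n_boot = config$shapes$n_boot,
                         seed = derive_seed(seed, "shapes", rt),
                         edf_threshold = th$edf,
                         linearity_gate = th$linearity_gate,
                         gam_threshold = th$gam_shape,
                         lm_threshold = th$lm_shape)
      st$resource_type <- rt
      st
    }))
    if (!is.null(shapes_tab)) {
      utils::write.csv(shapes_tab, file.path(outdir, "shapes.csv"),
                       row.names = FALSE)
      counts$shapes <- nrow(shapes_tab)
    }
  }

  summary_tab <- NULL; assoc <- NULL
  if (config$stages$associate && !is.null(monod_tab) && !is.null(tpc_tab)) {
    summary_tab <- summarize_traits(monod_tab, tpc_tab)
    utils::write.csv(summary_tab, file.path(outdir, "trait_summary.csv"),
                     row.names = FALSE)
    counts$summary <- nrow(summary_tab)
    assoc <- tryCatch({
      pca <- run_pca(summary_tab)
      phyla <- pca$meta$phylum
      an <- if (length(unique(phyla)) >= 2 && all(table(phyla) >= 2)) {
        anosim_groups(pca$scores, phyla,
                      n_perm = config$associations$n_perm, seed = seed)
      } else NULL
      kt <- kendall_matrix(summary_tab)
      list(pca_var_explained = pca$var_explained,
           pc12 = sum(pca$var_explained[1:2]),
           anosim = an, kendall_tau = kt$tau, kendall_p = kt$p)
    }, error = function(e) list(note = conditionMessage(e)))
    jsonlite::write_json(assoc, file.path(outdir, "associations.json"),
                         digits = NA, auto_unbox = TRUE, force = TRUE)
  }

  manifest <- list(seed = seed, config_hash = config_hash(config),
                   counts = counts)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(rates = rate_table, monod = monod_tab, tpc = tpc_tab,
                 shapes = shapes_tab, summary = summary_tab,
                 associations = assoc, manifest = manifest))
}

# Rebuild per-population gradient series (draws across temperature) from
# batch_monod fits for the shape stage.
monod_draw_list <- function(fits, max_draws = 500) {
  keys <- strsplit(names(fits), "|", fixed = TRUE)
  pops <- unique(vapply(keys, `[[`, "", 1))
  out <- list()
  for (pop in pops) {
    sel <- which(vapply(keys, `[[`, "", 1) == pop)
    temps <- as.numeric(vapply(keys[sel], `[[`, "", 2))
    o <- order(temps)
    sel <- sel[o]; temps <- temps[o]
    ok <- vapply(sel, function(i) {
      f <- fits[[i]]
      isTRUE(f$retained) && !is.null(f$draws)
    }, TRUE)
    if (sum(ok) < 2) next
    sel <- sel[ok]; temps <- temps[ok]
    get_trait <- function(trait, positive_only) {
      cols <- lapply(sel, function(i) {
        v <- fits[[i]]$draws[[trait]]
        v[!is.finite(v)] <- NA
        idx <- unique(round(seq(1, length(v), length.out = min(max_draws, length(v)))))
        v[idx]
      })
      n <- min(lengths(cols))
      draws <- do.call(cbind, lapply(cols, function(v) v[seq_len(n)]))
      bad <- !is.finite(draws)
      if (positive_only) bad <- bad | draws <= 0  # gamma family needs > 0
      keep <- rowSums(bad) == 0
      if (sum(keep) < 50) return(NULL)
      list(x = temps, draws = draws[keep, , drop = FALSE])
    }
    traits <- list()
    for (trait in c("rstar", "alpha", "net_mu_max")) {
      unit <- get_trait(trait, positive_only = trait %in% c("rstar", "alpha"))
      if (!is.null(unit)) traits[[trait]] <- unit
    }
    if (length(traits)) out[[pop]] <- traits
  }
  out
}
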