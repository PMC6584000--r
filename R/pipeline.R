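#' Pipeline run configuration
#'
#' Bundles everything one end-to-end analysis needs: the synthetic-data (or
#' externally supplied) inputs, the metric list with their response
#' transforms, the effect-distance levels, and the MCMC profile. The
#' per-metric transform map follows the analysis design: log10 for SSC,
#' square root for DLI, logit for the deposition index and for all
#' proportion metrics (silt+clay fraction, cover-score exceedance,
#' mortality).
#'
#' @param sim a [sim_config()] describing the synthetic inputs.
#' @param metrics character vector drawn from `ssc, dli, depo_index,
#'   silt_clay, sediment_ge3, mucus_ge3, mortality_nonzero`.
#' @param ed_levels effect-remaining fractions to report (default
#'   `c(0.1, 0.5)`).
#' @param mcmc a [decay_model_spec()] supplying the MCMC profile (its
#'   transform tag is overridden per metric).
#' @param score_threshold exceedance threshold on the 1-7 scale (default 3).
#' @param seed top-level seed; fanned out to the stages by fixed offsets so
#'   a stage can be re-run in isolation.
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       metrics = c("ssc", "dli", "depo_index", "silt_clay",
                                   "sediment_ge3", "mucus_ge3",
                                   "mortality_nonzero"),
                       ed_levels = c(0.1, 0.5),
                       mcmc = mcmc_test_profile(),
                       score_threshold = 3,
                       seed = 1L) {
  known <- c("ssc", "dli", "depo_index", "silt_clay", "sediment_ge3",
             "mucus_ge3", "mortality_nonzero")
  if (length(metrics) == 0L) stop("metric list must not be empty")
  if (!all(metrics %in% known))
    stop("unknown metric(s): ", paste(setdiff(metrics, known), collapse = ", "))
  if (any(ed_levels <= 0 | ed_levels >= 1))
    stop("ed_levels must lie strictly between 0 and 1")
  sim$seed <- as.integer(seed)
  structure(list(sim = sim, metrics = metrics, ed_levels = ed_levels,
                 mcmc = mcmc, score_threshold = score_threshold,
                 seed = as.integer(seed)),
            class = "run_config")
}

# transform for each pipeline metric
metric_transform <- function(metric) {
  switch(metric,
         ssc = "log10", dli = "sqrt",
         depo_index = "logit", silt_clay = "logit",
         sediment_ge3 = "logit", mucus_ge3 = "logit",
         mortality_nonzero = "logit")
}

#' Run the full distance-decay analysis
#'
#' Orchestrates simulate -> preprocess -> score -> fit -> effect distance
#' into one reproducible run. Water-quality metrics are fitted at the
#' site-by-fortnight grain with site and fortnight random intercepts
#' (baseline fortnights excluded); coral-score and particle-size metrics
#' are site-level pooled proportions fitted as Bayesian simple regressions
#' on the empirical-logit scale. Each fitted metric is inverted to the
#' requested effect-distance levels between the nearest and farthest site
#' distances.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, the ED table, per-metric
#'   fit summaries, observed/fitted curve data files and a JSON run log are
#'   written there as CSV/JSON.
#' @return list of class `ed_run`: `ed_table`, `ed_results`, `fits`
#'   (per-metric `decay_fit`), `dataset`, `site_summaries`, `config`,
#'   `max_rhat`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  ds <- simulate_dataset(config$sim)
  prep <- preprocess_water_quality(ds$water_quality)
  obs <- exclude_dislodged(ds$colonies)
  d_near <- min(ds$sites$distance_km)
  d_far <- max(ds$sites$distance_km)

  fits <- list()
  ed_results <- list()
  site_summaries <- list()
  fit_seed_base <- (config$seed %% 1000000L) * 1000L + 100L

  for (i in seq_along(config$metrics)) {
    metric <- config$metrics[i]
    tr <- metric_transform(metric)
    spec <- config$mcmc
    spec$transform <- transform_tag(tr)
    spec$seed <- as.integer(fit_seed_base + i)

    if (metric %in% c("ssc", "dli", "depo_index")) {
      panel <- prep[prep$metric == metric & prep$fortnight >= 0, ]
      if (nrow(panel) == 0L) stop("stage fit/", metric, ": no dredge-phase ",
                                  "fortnight summaries available")
      dist <- ds$sites$distance_km[match(panel$site_id, ds$sites$site_id)]
      y <- if (tr == "logit") {
        apply_transform(panel$value, tr, n = 60,
                        correction = spec$empirical_logit_correction)
      } else apply_transform(panel$value, tr)
      fit <- fit_decay(y, dist, site = panel$site_id,
                       fortnight = panel$fortnight, spec = spec)
    } else if (metric == "silt_clay") {
      after <- ds$psd[ds$psd$phase == "after_1", ]
      if (nrow(after) == 0L) stop("stage fit/silt_clay: no post-dredging ",
                                  "PSD samples")
      p <- vapply(seq_len(nrow(after)), function(r)
        silt_clay_fraction(after[r, ]), numeric(1))
      y <- apply_transform(p, "logit", n = 100,
                           correction = spec$empirical_logit_correction)
      fit <- fit_decay(y, after$distance_km, spec = spec)
    } else {
      field <- switch(metric, sediment_ge3 = "sediment_score",
                      mucus_ge3 = "mucus_score",
                      mortality_nonzero = "mortality_nonzero")
      ss <- site_exceedance(obs, field, threshold = config$score_threshold,
                            sites = ds$sites)
      if (nrow(ss) < 3L) stop("stage score/", metric,
                              ": too few sites with observations")
      site_summaries[[metric]] <- ss
      y <- apply_transform(ss$proportion, "logit", n = ss$n_obs,
                           correction = spec$empirical_logit_correction)
      fit <- fit_decay(y, ss$distance_km, spec = spec)
    }
    fits[[metric]] <- fit
    for (q in config$ed_levels)
      ed_results[[length(ed_results) + 1L]] <-
        ed_posterior(fit, q, d_near_km = d_near, d_far_km = d_far,
                     metric = metric)
  }

  edt <- ed_table(ed_results)
  rhats <- unlist(lapply(fits, function(f) f$rhat))
  run <- list(ed_table = edt, ed_results = ed_results, fits = fits,
              dataset = ds, site_summaries = site_summaries,
              config = config,
              max_rhat = max(rhats[is.finite(rhats)]))
  class(run) <- "ed_run"
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.ed_run <- function(x, ...) {
  cat(sprintf("Distance-decay run: %d metrics, max split R-hat %.3f\n",
              length(x$fits), x$max_rhat))
  print(x$ed_table, row.names = FALSE)
  invisible(x)
}

#' Observed values and fitted decay curve for one metric
#'
#' Data behind a distance-decay panel: the site-level (or site-fortnight)
#' observed values on the natural scale, and the posterior median and 95%
#' band of the population-mean curve over a log-spaced distance grid.
#'
#' @param run an `ed_run`.
#' @param metric one of the run's metrics.
#' @param n_grid number of curve evaluation points (default 100).
#' @return list with data.frames `observed` (`distance_km, value`) and
#'   `curve` (`distance_km, median, lo95, hi95`, natural scale).
#' @export
decay_curve_data <- function(run, metric, n_grid = 100) {
  stopifnot(inherits(run, "ed_run"))
  fit <- run$fits[[metric]]
  if (is.null(fit)) stop("metric not in run: ", metric)
  dgrid <- 10^seq(log10(min(run$dataset$sites$distance_km)),
                  log10(max(run$dataset$sites$distance_km)),
                  length.out = n_grid)
  pred <- posterior_predict_mean(fit, dgrid, natural_scale = TRUE)
  qs <- apply(pred, 2, stats::quantile, c(0.025, 0.5, 0.975))
  obs <- data.frame(distance_km = fit$data$distance_km,
                    value = invert_transform(fit$data$y, fit$transform))
  list(observed = obs,
       curve = data.frame(distance_km = dgrid, median = qs[2, ],
                          lo95 = qs[1, ], hi95 = qs[3, ]))
}

# Write run artifacts: ED table, fit summaries, curve data, JSON log.
write_run <- function(run, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(run$ed_table, file.path(out_dir, "ed_table.csv"),
                   row.names = FALSE)
  for (metric in names(run$fits)) {
    s <- summary(run$fits[[metric]])
    utils::write.csv(data.frame(parameter = rownames(s), s,
                                row.names = NULL, check.names = FALSE),
                     file.path(out_dir, paste0("fit_", metric, ".csv")),
                     row.names = FALSE)
    cd <- decay_curve_data(run, metric)
    utils::write.csv(cd$curve,
                     file.path(out_dir, paste0("curve_", metric, ".csv")),
                     row.names = FALSE)
    utils::write.csv(cd$observed,
                     file.path(out_dir, paste0("observed_", metric, ".csv")),
                     row.names = FALSE)
  }
  log <- list(package_version = as.character(utils::packageVersion("plumeED")),
              seed = run$config$seed,
              metrics = run$config$metrics,
              ed_levels = run$config$ed_levels,
              mcmc = list(n_chains = run$config$mcmc$n_chains,
                          n_burnin = run$config$mcmc$n_burnin,
                          n_iter = run$config$mcmc$n_iter),
              n_sites = run$config$sim$n_sites,
              max_split_rhat = run$max_rhat)
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
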