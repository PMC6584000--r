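#' Simulation configuration for a synthetic dredging monitoring campaign
#'
#' Describes a monitoring design patterned on a large capital dredging
#' project: sites log-spaced from a few hundred metres to tens of kilometres
#' from the excavation, a ~530-day dredging phase preceded by a baseline,
#' daily water-quality logging (turbidity, light, deposition sensor), tagged
#' coral colonies photographed fortnightly and scored on a 1-7 cover scale,
#' and before/after seabed particle-size compositions.
#'
#' The generator is the analysis model run forward: on the transformed scale
#' of each metric, the dredge-phase mean is linear in log10 distance, with a
#' shared fortnight random intercept (dredging-intensity shocks), a site
#' random intercept, and residual noise; values are then back-transformed to
#' the natural scale. The baseline phase has no distance gradient and sits at
#' the metric's far-field (ambient) level.
#'
#' @param n_sites number of monitoring sites (default 17).
#' @param d_near_km,d_far_km nearest and farthest site distances in km
#'   (defaults 0.19 and 34.8).
#' @param n_days dredging-phase length in days (default 530); day 0 is the
#'   start of dredging.
#' @param baseline_days length of the pre-dredging baseline in days (negative
#'   day indices; default 98, i.e. 7 fortnights).
#' @param metrics named list of per-metric generating parameters. Each entry
#'   is a list with `transform` (name understood by [transform_tag()]),
#'   `intercept` and `slope` (transformed scale, slope per unit log10 km),
#'   and `sd_site`, `sd_fortnight`, `sd_resid` (transformed-scale SDs).
#'   Metrics `ntu`, `dli` and `depo` are used by [simulate_water_quality()].
#' @param colonies_per_site tagged colonies per site (default 50).
#' @param porites_topup minimum number of massive colonies per site, topped
#'   up with extra tagged massives where the random mix falls short
#'   (default 20).
#' @param morphology_mix named proportions over
#'   `encrusting, foliose, corymbose, branching, massive`; must sum to 1.
#' @param smother_logit_intercept,smother_logit_slope logit-linear model (in
#'   log10 km) for the probability that a survey of a susceptible colony
#'   shows a sediment score of 3 or more. Branching and corymbose
#'   morphologies never smother, whatever the distance.
#' @param mucus_logit_intercept,mucus_logit_slope same model for mucous-sheet
#'   scores of massive Porites.
#' @param mortality_logit_intercept,mortality_logit_slope colony-level
#'   probability of non-zero partial mortality (massive Porites).
#' @param dislodged_fraction fraction of colonies flagged as dislodged at a
#'   random survey (missing-at-random; exercises the exclusion filter).
#' @param psd_enrichment_near silt+clay enrichment factor at `d_near_km`
#'   immediately after dredging (default 5); declines linearly on the log10
#'   distance axis to 1 at `d_far_km`.
#' @param psd_relax relative near-field enrichment (above 1) retained in the
#'   later post-dredging surveys; the default `c(1, 0.4, 0.4)` gives
#'   near-field factors 5, 2.6, 2.6 for `after_1..3`.
#' @param psd_base baseline composition percentages
#'   (gravel, sand, silt, clay), summing to 100.
#' @param psd_concentration Dirichlet concentration mass for composition
#'   noise; `Inf` gives the noise-free expectation exactly.
#' @param seed integer seed; all child simulations derive their streams
#'   from it.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_dataset()] for running the generator.
#' @export
sim_config <- function(n_sites = 17,
                       d_near_km = 0.19,
                       d_far_km = 34.8,
                       n_days = 530,
                       baseline_days = 98,
                       metrics = list(
                         ntu  = list(transform = "log10", intercept = 0.9,
                                     slope = -0.8, sd_site = 0.3,
                                     sd_fortnight = 0.2, sd_resid = 0.2),
                         dli  = list(transform = "sqrt", intercept = 1.5,
                                     slope = 1.0, sd_site = 0.3,
                                     sd_fortnight = 0.2, sd_resid = 0.2),
                         depo = list(transform = "logit", intercept = 0,
                                     slope = -0.8, sd_site = 0.3,
                                     sd_fortnight = 0.2, sd_resid = 0.2)
                       ),
                       colonies_per_site = 50,
                       porites_topup = 20,
                       morphology_mix = c(encrusting = 0.15, foliose = 0.10,
                                          corymbose = 0.10, branching = 0.25,
                                          massive = 0.40),
                       smother_logit_intercept = -1.8,
                       smother_logit_slope = -1.9,
                       mucus_logit_intercept = -2.8,
                       mucus_logit_slope = -1.3,
                       mortality_logit_intercept = -3.0,
                       mortality_logit_slope = -1.5,
                       dislodged_fraction = 0.05,
                       psd_enrichment_near = 5,
                       psd_relax = c(1, 0.4, 0.4),
                       psd_base = c(gravel = 10, sand = 75, silt = 10, clay = 5),
                       psd_concentration = 200,
                       seed = 1L) {
  stopifnot(n_sites >= 2, is.numeric(d_near_km), is.numeric(d_far_km))
  if (d_near_km <= 0 || d_far_km <= 0)
    stop("site distances must be positive")
  if (d_near_km >= d_far_km)
    stop("d_near_km must be smaller than d_far_km")
  if (n_days < 0 || baseline_days < 0) stop("day counts must be non-negative")
  morphs <- c("encrusting", "foliose", "corymbose", "branching", "massive")
  if (!setequal(names(morphology_mix), morphs))
    stop("morphology_mix must be named over: ", paste(morphs, collapse = ", "))
  morphology_mix <- morphology_mix[morphs]
  if (abs(sum(morphology_mix) - 1) > 1e-8)
    stop("morphology proportions must sum to 1")
  if (any(morphology_mix < 0)) stop("morphology proportions must be >= 0")
  for (m in names(metrics)) {
    p <- metrics[[m]]
    req <- c("transform", "intercept", "slope", "sd_site", "sd_fortnight",
             "sd_resid")
    if (!all(req %in% names(p)))
      stop("metric '", m, "' must define: ", paste(req, collapse = ", "))
    sds <- unlist(p[c("sd_site", "sd_fortnight", "sd_resid")])
    if (any(sds < 0)) stop("metric '", m, "': SDs must be >= 0")
    transform_tag(p$transform)  # validates the name
  }
  if (dislodged_fraction < 0 || dislodged_fraction > 1)
    stop("dislodged_fraction must be in [0, 1]")
  if (psd_enrichment_near < 1) stop("psd_enrichment_near must be >= 1")
  if (abs(sum(psd_base) - 100) > 1e-6) stop("psd_base must sum to 100")
  cfg <- list(n_sites = as.integer(n_sites), d_near_km = d_near_km,
              d_far_km = d_far_km, n_days = as.integer(n_days),
              baseline_days = as.integer(baseline_days), metrics = metrics,
              colonies_per_site = as.integer(colonies_per_site),
              porites_topup = as.integer(porites_topup),
              morphology_mix = morphology_mix,
              smother_logit_intercept = smother_logit_intercept,
              smother_logit_slope = smother_logit_slope,
              mucus_logit_intercept = mucus_logit_intercept,
              mucus_logit_slope = mucus_logit_slope,
              mortality_logit_intercept = mortality_logit_intercept,
              mortality_logit_slope = mortality_logit_slope,
              dislodged_fraction = dislodged_fraction,
              psd_enrichment_near = psd_enrichment_near,
              psd_relax = psd_relax, psd_base = psd_base,
              psd_concentration = psd_concentration, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Seed scoping helper: runs expr with a local RNG stream so simulations are
# reproducible without clobbering the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Lay out monitoring sites on a log-spaced distance gradient
#'
#' Distances are log10-spaced between the two endpoint distances, both
#' included, mirroring a monitoring design that resolves a gradient spanning
#' two orders of magnitude.
#'
#' @param n_sites number of sites (>= 2).
#' @param d_near_km,d_far_km endpoint distances in km, `0 < near < far`.
#' @param seed accepted for interface symmetry; the layout is deterministic.
#' @return data.frame with columns `site_id`, `distance_km`, distances
#'   strictly increasing.
#' @examples
#' simulate_sites(3, 0.19, 34.8)
#' @export
simulate_sites <- function(n_sites, d_near_km = 0.19, d_far_km = 34.8,
                           seed = NULL) {
  if (n_sites < 2) stop("n_sites must be at least 2")
  if (!is.numeric(d_near_km) || !is.numeric(d_far_km) ||
      d_near_km <= 0 || d_far_km <= 0)
    stop("site distances must be positive")
  if (d_near_km >= d_far_km) stop("d_near_km must be smaller than d_far_km")
  d <- 10^seq(log10(d_near_km), log10(d_far_km), length.out = n_sites)
  d[1] <- d_near_km
  d[n_sites] <- d_far_km
  data.frame(site_id = sprintf("S%02d", seq_len(n_sites)), distance_km = d,
             stringsAsFactors = FALSE)
}

#' Simulate a site-by-fortnight response panel from the decay model
#'
#' Runs the analysis model forward at the grain the mixed model is fitted on:
#' one transformed-scale response per site and fortnight,
#' `y = beta0 + beta1 * log10(d) + u_site + v_fortnight + resid`, with the
#' fortnight intercepts shared across sites. This is the generator used for
#' parameter-recovery experiments; [simulate_water_quality()] produces the
#' raw daily logger streams for exercising the preprocessing chain.
#'
#' @param sites site table from [simulate_sites()].
#' @param n_fortnights number of dredge-phase fortnights (indexed 1..n).
#' @param beta0,beta1 transformed-scale intercept and slope (per log10 km).
#' @param sd_site,sd_fortnight,sd_resid random-effect and residual SDs.
#' @param transform transform tag or name; `value` holds the back-transformed
#'   response.
#' @param seed integer seed.
#' @return data.frame `site_id, distance_km, fortnight, y, value` with the
#'   realised effects attached as `attr(, "truth")`.
#' @export
simulate_decay_panel <- function(sites, n_fortnights, beta0, beta1,
                                 sd_site = 0, sd_fortnight = 0, sd_resid = 0,
                                 transform = "identity", seed = 1L) {
  stopifnot(is.data.frame(sites), n_fortnights >= 1)
  tg <- transform_tag(transform)
  J <- nrow(sites)
  K <- as.integer(n_fortnights)
  with_seed(seed, {
    u <- stats::rnorm(J, 0, sd_site)
    v <- stats::rnorm(K, 0, sd_fortnight)
    grid <- expand.grid(site = seq_len(J), fortnight = seq_len(K))
    eps <- stats::rnorm(nrow(grid), 0, sd_resid)
    y <- beta0 + beta1 * log10(sites$distance_km[grid$site]) +
      u[grid$site] + v[grid$fortnight] + eps
    out <- data.frame(site_id = sites$site_id[grid$site],
                      distance_km = sites$distance_km[grid$site],
                      fortnight = grid$fortnight,
                      y = y,
                      value = invert_transform(y, tg),
                      stringsAsFactors = FALSE)
    attr(out, "truth") <- list(beta0 = beta0, beta1 = beta1,
                               sd_site = sd_site, sd_fortnight = sd_fortnight,
                               sd_resid = sd_resid, u = u, v = v,
                               transform = tg$name)
    out
  })
}

#' Simulate daily water-quality logger records
#'
#' Produces one record per site and day with turbidity (NTU), daily light
#' integral (DLI) and raw deposition-sensor output on their natural scales.
#' During the dredging phase (days `0..n_days-1`) the transformed-scale mean
#' of each metric is `intercept + slope * log10(d)` plus a site random
#' intercept, a fortnight random intercept shared across sites, and daily
#' residual noise. During the baseline (negative days) the distance slope is
#' zero and the mean sits at the far-field (ambient) level
#' `intercept + slope * log10(d_far)`.
#'
#' The deposition channel is emitted in arbitrary instrument units: a
#' per-site multiplicative gain (uncalibrated sensor response) times the
#' inverse-logit of the linear predictor. The per-site min-max normalisation
#' performed by [deposition_index()] removes the gain again.
#'
#' @param config a [sim_config()].
#' @param sites site table from [simulate_sites()].
#' @param seed integer seed.
#' @return data.frame `site_id, day, ntu, dli, depo_raw`; `day` runs from
#'   `-baseline_days` to `n_days - 1`.
#' @export
simulate_water_quality <- function(config, sites, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"), is.data.frame(sites))
  if (config$n_days + config$baseline_days == 0L)
    return(data.frame(site_id = character(), day = integer(),
                      ntu = numeric(), dli = numeric(),
                      depo_raw = numeric(), stringsAsFactors = FALSE))
  days <- seq.int(-config$baseline_days, config$n_days - 1L)
  J <- nrow(sites)
  fort <- fortnight_of(days)                     # includes negative bins
  fort_levels <- sort(unique(fort))
  grid <- expand.grid(site = seq_len(J), di = seq_along(days))
  dredging <- days[grid$di] >= 0
  log10_d <- log10(sites$distance_km[grid$site])
  kf <- match(fort[grid$di], fort_levels)

  channel <- function(par) {
    u <- stats::rnorm(J, 0, par$sd_site)
    v <- stats::rnorm(length(fort_levels), 0, par$sd_fortnight)
    eps <- stats::rnorm(nrow(grid), 0, par$sd_resid)
    ambient <- par$intercept + par$slope * log10(config$d_far_km)
    mu <- ifelse(dredging, par$intercept + par$slope * log10_d, ambient)
    invert_transform(mu + u[grid$site] + v[kf] + eps, par$transform)
  }

  with_seed(seed, {
    ntu <- channel(config$metrics$ntu)
    dli <- channel(config$metrics$dli)
    depo_p <- channel(config$metrics$depo)
    gain <- stats::runif(J, 50, 400)             # arbitrary sensor units
    depo_raw <- depo_p * gain[grid$site]
    out <- data.frame(site_id = sites$site_id[grid$site],
                      day = days[grid$di],
                      ntu = ntu, dli = dli, depo_raw = depo_raw,
                      stringsAsFactors = FALSE)
    out <- out[order(out$site_id, out$day), ]
    rownames(out) <- NULL
    out
  })
}

#' Simulate a tagged-colony survey panel
#'
#' Colonies with fixed site and morphology are surveyed every 14 days over
#' the dredging phase. For smothering-susceptible morphologies (encrusting,
#' foliose, massive) the probability that a survey shows a sediment score of
#' 3 or more (>5% cover) follows an inverse-logit linear model in log10
#' distance; branching and corymbose colonies never smother. Mucous-sheet
#' scores and a colony-level non-zero-mortality flag are generated for
#' massive Porites only. A configurable fraction of colonies is flagged
#' dislodged from a random survey onwards.
#'
#' @param config a [sim_config()].
#' @param sites site table from [simulate_sites()].
#' @param seed integer seed.
#' @return data.frame of colony observations: `colony_id, site_id, day,
#'   morphology, sediment_score, mucus_score, dislodged, mortality_nonzero`.
#' @export
simulate_colony_panel <- function(config, sites, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"), is.data.frame(sites))
  survey_days <- seq.int(0L, length.out = max(0L, ceiling(config$n_days / 14)),
                         by = 14L)
  if (length(survey_days) == 0L)
    return(data.frame(colony_id = character(), site_id = character(),
                      day = integer(), morphology = character(),
                      sediment_score = integer(), mucus_score = integer(),
                      dislodged = logical(), mortality_nonzero = logical(),
                      stringsAsFactors = FALSE))
  morphs <- names(config$morphology_mix)
  score_probs_high <- c(0.55, 0.25, 0.12, 0.06, 0.02)  # categories 3..7
  score_probs_low <- c(0.85, 0.15)                     # categories 1..2
  with_seed(seed, {
    panels <- lapply(seq_len(nrow(sites)), function(j) {
      d <- sites$distance_km[j]
      t <- log10(d)
      morph <- sample(morphs, config$colonies_per_site, replace = TRUE,
                      prob = config$morphology_mix)
      n_massive <- sum(morph == "massive")
      if (n_massive < config$porites_topup)
        morph <- c(morph, rep("massive", config$porites_topup - n_massive))
      nc <- length(morph)
      colony_id <- sprintf("%s-C%03d", sites$site_id[j], seq_len(nc))
      susceptible <- morph %in% c("encrusting", "foliose", "massive")
      p_sed <- stats::plogis(config$smother_logit_intercept +
                             config$smother_logit_slope * t)
      p_muc <- stats::plogis(config$mucus_logit_intercept +
                             config$mucus_logit_slope * t)
      p_mort <- stats::plogis(config$mortality_logit_intercept +
                              config$mortality_logit_slope * t)
      mortality <- morph == "massive" & stats::runif(nc) < p_mort
      dis <- stats::runif(nc) < config$dislodged_fraction
      dis_from <- ifelse(dis, sample(survey_days, nc, replace = TRUE), NA)
      draw_scores <- function(p_exceed, n) {
        sc <- integer(n)
        ex <- stats::runif(n) < p_exceed
        sc[ex] <- sample(3:7, sum(ex), replace = TRUE, prob = score_probs_high)
        sc[!ex] <- sample(1:2, sum(!ex), replace = TRUE, prob = score_probs_low)
        sc
      }
      obs <- expand.grid(ci = seq_len(nc), day = survey_days)
      sed <- rep(1L, nrow(obs))
      act <- susceptible[obs$ci]
      sed[act] <- draw_scores(p_sed, sum(act))
      muc <- rep(NA_integer_, nrow(obs))
      mm <- morph[obs$ci] == "massive"
      muc[mm] <- draw_scores(p_muc, sum(mm))
      data.frame(colony_id = colony_id[obs$ci],
                 site_id = sites$site_id[j],
                 day = obs$day,
                 morphology = morph[obs$ci],
                 sediment_score = sed,
                 mucus_score = muc,
                 dislodged = !is.na(dis_from[obs$ci]) &
                   obs$day >= dis_from[obs$ci],
                 mortality_nonzero = mortality[obs$ci],
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, panels)
    out <- out[order(out$colony_id, out$day), ]
    rownames(out) <- NULL
    out
  })
}

#' Simulate seabed particle-size compositions
#'
#' One `before` composition and one composition per post-dredging survey
#' (`after_1..after_3`) per site. The expected combined silt+clay content
#' after dredging equals the baseline value times an enrichment factor that
#' declines linearly on the log10-distance axis from the configured
#' near-field value to 1 at the far endpoint; later surveys relax the
#' near-field enrichment (partial winnowing of the deposited fines).
#' Compositions are drawn from a Dirichlet with total concentration
#' `psd_concentration`; `Inf` returns the expectation exactly.
#'
#' @param config a [sim_config()].
#' @param sites site table from [simulate_sites()].
#' @param seed integer seed.
#' @return data.frame `site_id, distance_km, phase, gravel, sand, silt, clay`
#'   with each row summing to 100.
#' @export
simulate_psd <- function(config, sites, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"), is.data.frame(sites))
  base <- config$psd_base / 100
  sc0 <- base[["silt"]] + base[["clay"]]
  t <- log10(sites$distance_km)
  tn <- log10(config$d_near_km); tf <- log10(config$d_far_km)
  w <- pmin(pmax((tf - t) / (tf - tn), 0), 1)    # 1 at near, 0 at far
  phases <- c("before", paste0("after_", seq_along(config$psd_relax)))
  rdirichlet1 <- function(alpha) {
    g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
    if (all(g == 0)) g <- alpha                  # numeric guard
    g / sum(g)
  }
  with_seed(seed, {
    rows <- list()
    for (j in seq_len(nrow(sites))) {
      for (ph in seq_along(phases)) {
        if (ph == 1L) {
          enr <- 1
        } else {
          near_factor <- 1 + (config$psd_enrichment_near - 1) *
            config$psd_relax[ph - 1L]
          enr <- 1 + (near_factor - 1) * w[j]
        }
        sc <- min(sc0 * enr, 0.95)
        rest <- (1 - sc) / (1 - sc0)
        mean_comp <- c(base[["gravel"]] * rest, base[["sand"]] * rest,
                       sc * base[["silt"]] / sc0, sc * base[["clay"]] / sc0)
        comp <- if (is.finite(config$psd_concentration)) {
          rdirichlet1(mean_comp * config$psd_concentration)
        } else mean_comp
        rows[[length(rows) + 1L]] <-
          data.frame(site_id = sites$site_id[j],
                     distance_km = sites$distance_km[j],
                     phase = phases[ph],
                     gravel = 100 * comp[1], sand = 100 * comp[2],
                     silt = 100 * comp[3], clay = 100 * comp[4],
                     stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate a complete synthetic monitoring dataset
#'
#' Bundles [simulate_sites()], [simulate_water_quality()],
#' [simulate_colony_panel()] and [simulate_psd()], with per-stage child seeds
#' derived from `config$seed` by fixed offsets so individual stages can be
#' reproduced in isolation.
#'
#' @param config a [sim_config()].
#' @return A list of class `synthetic_dataset` with elements `sites`,
#'   `water_quality`, `colonies`, `psd` and `truth` (the generating
#'   configuration, echoed exactly).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  base <- (config$seed %% 1000000L) * 1000L
  sites <- simulate_sites(config$n_sites, config$d_near_km, config$d_far_km)
  ds <- list(sites = sites,
             water_quality = simulate_water_quality(config, sites,
                                                    seed = base + 1L),
             colonies = simulate_colony_panel(config, sites, seed = base + 2L),
             psd = simulate_psd(config, sites, seed = base + 3L),
             truth = config)
  class(ds) <- "synthetic_dataset"
  ds
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic dredging monitoring dataset\n")
  cat(sprintf("  %d sites, %.2f-%.1f km from source\n", nrow(x$sites),
              min(x$sites$distance_km), max(x$sites$distance_km)))
  cat(sprintf("  water quality: %d site-days; colonies: %d observations; psd: %d samples\n",
              nrow(x$water_quality), nrow(x$colonies), nrow(x$psd)))
  invisible(x)
}

#' Write the four dataset tables as CSV files
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_dataset_csv <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in c("sites", "water_quality", "colonies", "psd")) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(dataset[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
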