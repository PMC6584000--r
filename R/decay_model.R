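#' MCMC specification for the distance-decay model
#'
#' The decay model regresses a transformed response on log10 distance from
#' the dredging source, with optional site and fortnight random intercepts:
#' `y = beta0 + beta1 * log10(d) + u_site + v_fortnight + eps`. Priors are
#' near-flat conjugate choices: `Normal(0, prior_beta_sd^2)` on each fixed
#' effect and `InverseGamma(prior_var_shape, prior_var_rate)` on each
#' variance component. Posteriors are drawn by a Gibbs sampler over the
#' conjugate full conditionals.
#'
#' The default iteration counts (5 chains, 10,000 burn-in, 20,000 kept
#' iterations) are the production profile; [mcmc_test_profile()] gives a
#' desk-scale profile (3 chains, 500 burn-in, 1,500 kept) used throughout
#' the package's own tests and examples.
#'
#' @param transform response transform tag or name (see [transform_tag()]).
#' @param prior_beta_sd prior SD of the fixed effects (default 100).
#' @param prior_var_shape,prior_var_rate inverse-gamma hyper-parameters for
#'   all variance components (default 0.001, 0.001).
#' @param n_chains number of chains (>= 2, for split R-hat).
#' @param n_burnin burn-in iterations discarded per chain.
#' @param n_iter kept iterations per chain.
#' @param seed integer seed; chain `c` uses stream `seed + c`.
#' @param empirical_logit_correction pseudo-count for the empirical logit
#'   (default 0.5); recorded for use by [apply_transform()].
#' @return list of class `decay_model_spec`.
#' @export
decay_model_spec <- function(transform = "identity",
                             prior_beta_sd = 100,
                             prior_var_shape = 0.001,
                             prior_var_rate = 0.001,
                             n_chains = 5,
                             n_burnin = 10000,
                             n_iter = 20000,
                             seed = 1L,
                             empirical_logit_correction = 0.5) {
  if (n_chains < 2) stop("n_chains must be at least 2 (split R-hat needs them)")
  if (n_burnin < 0 || n_iter <= 0) stop("iteration counts must be positive")
  if (prior_beta_sd <= 0 || prior_var_shape <= 0 || prior_var_rate <= 0)
    stop("prior hyper-parameters must be positive")
  structure(list(transform = transform_tag(transform),
                 prior_beta_sd = prior_beta_sd,
                 prior_var_shape = prior_var_shape,
                 prior_var_rate = prior_var_rate,
                 n_chains = as.integer(n_chains),
                 n_burnin = as.integer(n_burnin),
                 n_iter = as.integer(n_iter),
                 seed = as.integer(seed),
                 empirical_logit_correction = empirical_logit_correction),
            class = "decay_model_spec")
}

#' Desk-scale MCMC profile
#'
#' @param transform,seed passed to [decay_model_spec()].
#' @return a `decay_model_spec` with 3 chains, 500 burn-in and 1,500 kept
#'   iterations -- enough for the conjugate, fast-mixing conditionals of
#'   this model while keeping simulation studies quick.
#' @export
mcmc_test_profile <- function(transform = "identity", seed = 1L) {
  decay_model_spec(transform = transform, n_chains = 3, n_burnin = 500,
                   n_iter = 1500, seed = seed)
}

# One Gibbs chain. y is the transformed response; X the fixed-effect design
# (intercept, log10 distance); site/fort are integer group indices or NULL.
#
# All location parameters theta = (beta, u, v) are drawn in one block from
# their joint multivariate-normal full conditional given the variance
# components: theta | . ~ N(Q^-1 W'y / sig2_e, Q^-1) with
# Q = W'W / sig2_e + P, W = [X Z_u Z_v] and P the diagonal prior precision.
# Blocking removes the strong posterior correlation between the intercept
# and the random-intercept means that cripples single-site updates. The
# variance components then have standard inverse-gamma conditionals.
gibbs_chain <- function(y, X, site, fort, spec, sigma_resid_fixed,
                        chain_seed) {
  n <- length(y)
  p <- ncol(X)
  J <- if (is.null(site)) 0L else max(site)
  K <- if (is.null(fort)) 0L else max(fort)
  a0 <- spec$prior_var_shape
  b0 <- spec$prior_var_rate
  tau2 <- spec$prior_beta_sd^2
  known_sigma <- !is.null(sigma_resid_fixed)

  # design with random-effect indicator blocks
  W <- X
  if (J) {
    Zu <- matrix(0, n, J); Zu[cbind(seq_len(n), site)] <- 1
    W <- cbind(W, Zu)
  }
  if (K) {
    Zv <- matrix(0, n, K); Zv[cbind(seq_len(n), fort)] <- 1
    W <- cbind(W, Zv)
  }
  m_loc <- ncol(W)
  WtW <- crossprod(W)
  Wty <- crossprod(W, y)
  iu <- if (J) p + seq_len(J) else integer(0)
  iv <- if (K) p + J + seq_len(K) else integer(0)

  set.seed(chain_seed)
  sig2_e <- if (known_sigma) sigma_resid_fixed^2 else
    stats::var(y) * exp(stats::runif(1, -1, 1))
  sig2_u <- exp(stats::runif(1, -2, 1))
  sig2_v <- exp(stats::runif(1, -2, 1))

  n_tot <- spec$n_burnin + spec$n_iter
  keep <- matrix(NA_real_, spec$n_iter, 2L + J + K + 3L)
  colnames(keep) <- c("beta0", "beta1",
                      if (J) paste0("u[", seq_len(J), "]"),
                      if (K) paste0("v[", seq_len(K), "]"),
                      "sigma_site", "sigma_fortnight", "sigma_resid")
  prior_prec <- numeric(m_loc)
  prior_prec[seq_len(p)] <- 1 / tau2

  for (it in seq_len(n_tot)) {
    # (beta, u, v) | variances, y
    if (J) prior_prec[iu] <- 1 / sig2_u
    if (K) prior_prec[iv] <- 1 / sig2_v
    Q <- WtW / sig2_e
    diag(Q) <- diag(Q) + prior_prec
    ch <- chol(Q)
    mu <- backsolve(ch, forwardsolve(t(ch), Wty / sig2_e))
    theta <- drop(mu + backsolve(ch, stats::rnorm(m_loc)))

    if (J) {
      u <- theta[iu]
      sig2_u <- 1 / stats::rgamma(1, a0 + J / 2, b0 + sum(u^2) / 2)
    }
    if (K) {
      v <- theta[iv]
      sig2_v <- 1 / stats::rgamma(1, a0 + K / 2, b0 + sum(v^2) / 2)
    }
    if (!known_sigma) {
      res <- y - drop(W %*% theta)
      sig2_e <- 1 / stats::rgamma(1, a0 + n / 2, b0 + sum(res^2) / 2)
    }
    if (it > spec$n_burnin)
      keep[it - spec$n_burnin, ] <- c(theta, sqrt(sig2_u), sqrt(sig2_v),
                                      sqrt(sig2_e))
  }
  keep
}

#' Fit the Bayesian distance-decay mixed model by Gibbs sampling
#'
#' Fits `y = beta0 + beta1 * log10(distance_km) + u_site + v_fortnight +
#' eps` on the transformed scale, with normal priors on the fixed effects
#' and inverse-gamma priors on the variance components (see
#' [decay_model_spec()]). Chains are initialised overdispersed; split R-hat
#' is computed for every parameter and a warning is issued when any exceeds
#' 1.05.
#'
#' `y` must already be on the transformed scale (see [apply_transform()]);
#' the spec's transform tag is carried into the returned fit so predictions
#' and effect distances are produced on the natural scale.
#'
#' @param y transformed response vector.
#' @param distance_km positive distances from the dredging source, one per
#'   observation.
#' @param site optional site codes (factor/character/integer); `NULL`
#'   disables the site random effect (e.g. for site-level pooled
#'   proportions with one value per site).
#' @param fortnight optional fortnight indices; `NULL` disables the
#'   fortnight random effect.
#' @param spec a [decay_model_spec()].
#' @param sigma_resid_fixed optional known residual SD; when supplied the
#'   residual variance is held fixed instead of sampled (used for
#'   conjugate-oracle checks).
#' @return An object of class `decay_fit`: list with `draws` (one matrix per
#'   chain, kept iterations by parameters), `rhat`, `transform`,
#'   `site_levels`, `fortnight_levels`, `spec` and the model frame.
#' @export
fit_decay <- function(y, distance_km, site = NULL, fortnight = NULL,
                      spec = decay_model_spec(), sigma_resid_fixed = NULL) {
  stopifnot(inherits(spec, "decay_model_spec"))
  y <- as.numeric(y)
  if (anyNA(y) || anyNA(distance_km)) stop("y and distance_km must be complete")
  if (length(distance_km) != length(y))
    stop("y and distance_km lengths differ")
  if (any(distance_km <= 0)) stop("distances must be positive")
  if (length(unique(distance_km)) < 2L)
    stop("design is singular: a single distance value cannot identify the ",
         "distance slope (collinear with the intercept)")
  site_levels <- fort_levels <- NULL
  site_idx <- fort_idx <- NULL
  if (!is.null(site)) {
    f <- factor(site)
    if (nlevels(f) < 3L) stop("need at least 3 distinct sites")
    site_levels <- levels(f)
    site_idx <- as.integer(f)
  }
  if (!is.null(fortnight)) {
    f <- factor(fortnight)
    if (nlevels(f) < 2L) stop("need at least 2 distinct fortnights ",
                              "(or disable the fortnight effect)")
    fort_levels <- levels(f)
    fort_idx <- as.integer(f)
  }
  X <- cbind(1, log10(distance_km))
  draws <- lapply(seq_len(spec$n_chains), function(cc)
    gibbs_chain(y, X, site_idx, fort_idx, spec, sigma_resid_fixed,
                chain_seed = (spec$seed + cc) %% .Machine$integer.max))
  rhat <- vapply(colnames(draws[[1]]), function(par) {
    split_rhat(sapply(draws, function(d) d[, par]))
  }, numeric(1))
  # variance components that are not in the model carry no information
  drop_par <- c(if (is.null(site_idx)) "sigma_site",
                if (is.null(fort_idx)) "sigma_fortnight",
                if (!is.null(sigma_resid_fixed)) "sigma_resid")
  rhat <- rhat[setdiff(names(rhat), drop_par)]
  bad <- rhat[is.finite(rhat) & rhat > 1.05]
  if (length(bad))
    warning("split R-hat above 1.05 for: ",
            paste(sprintf("%s (%.3f)", names(bad), bad), collapse = ", "))
  fit <- list(draws = draws, rhat = rhat,
              transform = spec$transform,
              site_levels = site_levels, fortnight_levels = fort_levels,
              spec = spec, sigma_resid_fixed = sigma_resid_fixed,
              data = data.frame(y = y, distance_km = distance_km))
  class(fit) <- "decay_fit"
  fit
}

#' Pooled posterior draws of a parameter
#'
#' @param fit a `decay_fit`.
#' @param pars parameter names (default the fixed effects and SDs).
#' @return matrix of pooled draws (all chains stacked) by parameter.
#' @export
posterior_draws <- function(fit, pars = NULL) {
  stopifnot(inherits(fit, "decay_fit"))
  all_pars <- colnames(fit$draws[[1]])
  if (is.null(pars))
    pars <- intersect(c("beta0", "beta1", "sigma_site", "sigma_fortnight",
                        "sigma_resid"), all_pars)
  if (!all(pars %in% all_pars))
    stop("unknown parameter(s): ",
         paste(setdiff(pars, all_pars), collapse = ", "))
  do.call(rbind, lapply(fit$draws, function(d) d[, pars, drop = FALSE]))
}

#' @export
print.decay_fit <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("Bayesian distance-decay fit (%s transform), %d chains x %d draws\n",
              x$transform$name, length(x$draws), nrow(x$draws[[1]])))
  print(round(s, 4))
  invisible(x)
}

#' @export
summary.decay_fit <- function(object, ...) {
  pars <- intersect(c("beta0", "beta1", "sigma_site", "sigma_fortnight",
                      "sigma_resid"), names(object$rhat))
  d <- posterior_draws(object, pars)
  out <- t(apply(d, 2, function(col)
    c(mean = mean(col), sd = stats::sd(col),
      stats::quantile(col, c(0.025, 0.5, 0.975)))))
  out <- cbind(out, rhat = object$rhat[rownames(out)])
  out
}

#' Population-mean posterior predictions
#'
#' Per-draw population-level prediction on the transformed scale,
#' `beta0 + beta1 * log10(d)`, with random effects set to zero (the
#' prediction used for effect-distance calculation).
#'
#' @param fit a `decay_fit`.
#' @param distance_km positive distances.
#' @param natural_scale if `TRUE`, back-transform to the natural scale.
#' @return matrix, draws by distances.
#' @export
posterior_predict_mean <- function(fit, distance_km, natural_scale = FALSE) {
  stopifnot(inherits(fit, "decay_fit"))
  if (any(distance_km <= 0)) stop("distances must be positive")
  b <- posterior_draws(fit, c("beta0", "beta1"))
  pred <- b[, "beta0"] %o% rep(1, length(distance_km)) +
    b[, "beta1"] %o% log10(distance_km)
  if (natural_scale) pred[] <- invert_transform(as.numeric(pred), fit$transform)
  colnames(pred) <- as.character(distance_km)
  pred
}

#' Split R-hat convergence diagnostic
#'
#' The potential-scale-reduction statistic computed after splitting each
#' chain in half, so within-chain trends register as apparent
#' non-convergence. Values close to 1 indicate the chains agree.
#'
#' @param x matrix of draws, iterations by chains.
#' @return the split R-hat; `NA` for a degenerate (zero-variance) input.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  half <- floor(n / 2)
  if (half < 2) return(NA_real_)
  sp <- cbind(x[seq_len(half), , drop = FALSE],
              x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sp)
  means <- colMeans(sp)
  vars <- apply(sp, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((half - 1) / half * W + B / half) / W)
}
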