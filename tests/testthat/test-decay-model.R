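test_that("transforms are correct, invertible, and guard their domains", {
  expect_equal(apply_transform(0.5, "logit"), 0)
  expect_equal(apply_transform(9, "sqrt"), 3)
  expect_equal(apply_transform(1.8, "log10"), 0.2552725, tolerance = 1e-7)
  x <- c(0.05, 0.4, 0.91)
  for (tr in c("identity", "log10", "sqrt", "logit"))
    expect_equal(invert_transform(apply_transform(x, tr), tr), x,
                 tolerance = 1e-12)
  expect_error(apply_transform(-1, "log10"), "positive")
  expect_error(apply_transform(-1, "sqrt"), "non-negative")
  expect_error(apply_transform(1.2, "logit"), "proportions")
  # empirical logit correction for boundary proportions
  expect_error(apply_transform(c(0, 0.5), "logit"), "supply `n`")
  got <- apply_transform(c(0, 0.5, 1), "logit", n = 20)
  expect_equal(got[1], log((0.5 / 21) / (1 - 0.5 / 21)))
  expect_equal(got[3], -got[1])
})

test_that("noise-free data recover the generating line with vanishing residual SD", {
  sites <- simulate_sites(17, 0.19, 34.8)
  d <- rep(sites$distance_km, each = 3)
  y <- 2 - 1 * log10(d)
  fit <- fit_decay(y, d, spec = quick_spec(seed = 4))
  s <- summary(fit)
  expect_lt(abs(s["beta0", "mean"] - 2), 1e-2)
  expect_lt(abs(s["beta1", "mean"] - (-1)), 1e-2)
  expect_lt(s["sigma_resid", "mean"], 0.05)
})

test_that("the sampler matches the conjugate closed-form posterior for beta", {
  # no random effects, known residual SD: the exact posterior is normal
  set.seed(42)
  d <- rep(10^seq(log10(0.19), log10(34.8), length.out = 20), each = 5)
  sigma <- 0.1
  y <- 1.5 - 0.7 * log10(d) + rnorm(length(d), 0, sigma)
  spec <- quick_spec(seed = 9)
  fit <- fit_decay(y, d, spec = spec, sigma_resid_fixed = sigma)
  X <- cbind(1, log10(d))
  V <- solve(crossprod(X) / sigma^2 + diag(1 / 100^2, 2))
  mu <- drop(V %*% crossprod(X, y) / sigma^2)
  b <- posterior_draws(fit, c("beta0", "beta1"))
  n_draws <- nrow(b)
  for (k in 1:2) {
    mcse_mean <- sqrt(V[k, k] / n_draws)
    expect_lt(abs(mean(b[, k]) - mu[k]), 4 * mcse_mean)
    mcse_sd <- sqrt(V[k, k]) / sqrt(2 * n_draws)
    expect_lt(abs(sd(b[, k]) - sqrt(V[k, k])), 4 * mcse_sd)
  }
})

test_that("posterior summaries are invariant to input row order", {
  sites <- simulate_sites(10, 0.19, 34.8)
  pan <- simulate_decay_panel(sites, 12, beta0 = 1, beta1 = -0.6,
                              sd_site = 0.2, sd_fortnight = 0.1,
                              sd_resid = 0.2, seed = 5)
  spec <- quick_spec(seed = 6)
  f1 <- fit_decay(pan$y, pan$distance_km, pan$site_id, pan$fortnight, spec)
  perm <- sample(nrow(pan))
  f2 <- fit_decay(pan$y[perm], pan$distance_km[perm], pan$site_id[perm],
                  pan$fortnight[perm], spec)
  expect_equal(summary(f1), summary(f2), tolerance = 1e-8)
})

test_that("chains agree (split R-hat < 1.05) on well-specified data", {
  sites <- simulate_sites(17, 0.19, 34.8)
  pan <- simulate_decay_panel(sites, 20, beta0 = 0, beta1 = -0.8,
                              sd_site = 0.3, sd_fortnight = 0.2,
                              sd_resid = 0.2, transform = "logit", seed = 8)
  fit <- fit_decay(pan$y, pan$distance_km, pan$site_id, pan$fortnight,
                   mcmc_test_profile("logit", seed = 21))
  expect_true(all(fit$rhat[is.finite(fit$rhat)] < 1.05))
})

test_that("posterior slope concentrates as the panel grows", {
  spec <- quick_spec(seed = 13)
  sd_b1 <- sapply(c(8, 24), function(J) {
    sites <- simulate_sites(J, 0.19, 34.8)
    pan <- simulate_decay_panel(sites, J, beta0 = 0, beta1 = -0.8,
                                sd_site = 0.1, sd_fortnight = 0.1,
                                sd_resid = 0.3, seed = 100 + J)
    fit <- fit_decay(pan$y, pan$distance_km, pan$site_id, pan$fortnight, spec)
    summary(fit)["beta1", "sd"]
  })
  expect_lt(sd_b1[2], sd_b1[1])
})

test_that("degenerate designs are rejected with informative errors", {
  expect_error(fit_decay(1:10, rep(2, 10), spec = quick_spec()),
               "singular|collinear")
  expect_error(fit_decay(1:4, c(1, 2, 1, 2), site = c("a", "a", "b", "b"),
                         spec = quick_spec()), "3 distinct sites")
  expect_error(fit_decay(1:4, c(-1, 2, 3, 4), spec = quick_spec()),
               "positive")
  expect_error(fit_decay(c(1, NA, 3), c(1, 2, 3), spec = quick_spec()),
               "complete")
})

test_that("population-mean predictions are linear in log10 distance per draw", {
  sites <- simulate_sites(6, 0.19, 34.8)
  pan <- simulate_decay_panel(sites, 6, 1, -0.5, 0.1, 0.1, 0.1, seed = 3)
  fit <- fit_decay(pan$y, pan$distance_km, pan$site_id, pan$fortnight,
                   quick_spec(seed = 7))
  b <- posterior_draws(fit, c("beta0", "beta1"))
  pred <- posterior_predict_mean(fit, c(1, 10, 100))
  expect_equal(pred[, "1"], unname(b[, "beta0"]))
  # equal log-distance steps give equal prediction increments
  expect_equal(pred[, "10"] - pred[, "1"], pred[, "100"] - pred[, "10"],
               tolerance = 1e-12)
})

test_that("split R-hat flags disagreeing chains and passes agreeing ones", {
  set.seed(1)
  good <- matrix(rnorm(4000), 1000, 4)
  expect_lt(split_rhat(good), 1.05)
  bad <- good + rep(c(0, 0, 0, 3), each = 1000)
  expect_gt(split_rhat(bad), 1.5)
  expect_true(is.na(split_rhat(matrix(1, 1000, 4))))
})
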